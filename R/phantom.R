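#' Specification of a synthetic multiparametric tumor phantom
#'
#' Describes a piecewise-constant digital phantom emulating the structure the
#' hotspot-overlap analysis runs on: a contrast-enhancing core (CET ellipsoid)
#' strictly inside a FLAIR-hyperintense envelope (FHT = shell outside CET),
#' one hotspot sub-ellipsoid per modality whose intensity is added on top of
#' the compartment baseline, additive per-modality noise, and a spherical
#' background reference ROI in "contralateral" normal tissue.
#'
#' Voxel membership in every ellipsoid is decided by the voxel-center
#' coordinate (quadratic form <= 1) — no partial-volume weighting — matching
#' the discrete mask arithmetic used downstream. The default geometry places
#' nested concentric hotspots (APTw > FET > CBV in extent) offset from the
#' tumor center so each straddles the CET/FHT boundary, reproducing the
#' qualitative structure of multiparametric glioblastoma data: near-complete
#' APTw positivity of CET, partial FET and smaller CBV hotspots, and higher
#' APTw/FET than APTw/CBV overlap.
#'
#' Baselines are on the thresholdable scales (APTw %-asymmetry; FET as
#' tumor-to-background ratio; CBV in percent with white matter at 2.5). The
#' emitted raw FET and CBV maps are these patterns times `fet_scale` /
#' `cbv_scale`, so the normalization stage has real work to undo.
#'
#' @param grid_dim integer length-3, voxels per axis (default `c(64,64,64)`).
#' @param voxel_size_mm isotropic spacing (default 2).
#' @param cet,fht lists `list(center, semiaxes)` in mm, world coordinates
#'   (grid centered on the origin).
#' @param hotspots named list (`aptw`, `fet`, `cbv`) of
#'   `list(center, semiaxes, delta)`; `delta` is the intensity added inside
#'   the hotspot ellipsoid.
#' @param baseline named list of `c(background=, cet=, fht=)` per modality.
#' @param noise_sd named vector of additive noise SD per modality (>= 0), on
#'   the pattern scale.
#' @param noise_model `"gaussian"` (default) or `"rician"` (magnitude of a
#'   complex Gaussian; meant for PET-like maps), per modality or scalar.
#' @param background_roi `list(center, radius)` of the reference sphere; must
#'   lie outside the FHT ellipsoid.
#' @param fet_scale raw-map value of the FET background (e.g. SUV of normal
#'   brain), default 2.0.
#' @param cbv_scale raw CBV units per percent blood volume, default 1.7.
#' @param seed RNG seed used by [generate_phantom()] unless overridden.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(64L, 64L, 64L),
                         voxel_size_mm = 2,
                         cet = list(center = c(0, 0, 0),
                                    semiaxes = c(20, 17, 14)),
                         fht = list(center = c(0, 0, 0),
                                    semiaxes = c(38, 33, 28)),
                         hotspots = list(
                           aptw = list(center = c(10, 0, 0),
                                       semiaxes = c(28, 24, 20), delta = 1.2),
                           fet  = list(center = c(10, 0, 0),
                                       semiaxes = c(23, 20, 17), delta = 1.0),
                           cbv  = list(center = c(10, 0, 0),
                                       semiaxes = c(18, 15, 13), delta = 4.5)),
                         baseline = list(
                           aptw = c(background = 0.5, cet = 3.0, fht = 1.5),
                           fet  = c(background = 1.0, cet = 1.4, fht = 1.2),
                           cbv  = c(background = 2.5, cet = 4.5, fht = 2.2)),
                         noise_sd = c(aptw = 0.2, fet = 0.08, cbv = 0.3),
                         noise_model = "gaussian",
                         background_roi = list(center = c(-48, -35, 0),
                                               radius = 6),
                         fet_scale = 2.0,
                         cbv_scale = 1.7,
                         seed = 1L) {
  spec <- structure(list(grid_dim = as.integer(grid_dim),
                         voxel_size_mm = voxel_size_mm,
                         cet = cet, fht = fht, hotspots = hotspots,
                         baseline = baseline, noise_sd = noise_sd,
                         noise_model = noise_model,
                         background_roi = background_roi,
                         fet_scale = fet_scale, cbv_scale = cbv_scale,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_dim) != 3L || any(spec$grid_dim < 4L))
    stop("phantom_spec: grid_dim must be 3 values >= 4", call. = FALSE)
  if (spec$voxel_size_mm <= 0)
    stop("phantom_spec: voxel size must be > 0", call. = FALSE)
  for (e in c(list(spec$cet, spec$fht), spec$hotspots))
    if (any(e$semiaxes <= 0))
      stop("phantom_spec: all semi-axes must be > 0", call. = FALSE)
  if (any(spec$noise_sd < 0))
    stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  mods <- c("aptw", "fet", "cbv")
  if (!all(mods %in% names(spec$hotspots)) ||
      !all(mods %in% names(spec$baseline)) ||
      !all(mods %in% names(spec$noise_sd)))
    stop("phantom_spec: hotspots, baseline and noise_sd must cover ",
         "aptw, fet and cbv", call. = FALSE)
  # CET strictly inside FHT: every sampled CET surface point must satisfy
  # the FHT quadratic form < 1.
  pts <- ellipsoid_surface_points(spec$cet$center, spec$cet$semiaxes)
  q <- quad_form(pts, spec$fht$center, spec$fht$semiaxes)
  if (any(q >= 1))
    stop("phantom_spec: CET ellipsoid is not strictly inside the FHT ",
         "ellipsoid (geometry error)", call. = FALSE)
  # Background ROI must not touch tumor.
  rq <- quad_form(matrix(spec$background_roi$center, 1), spec$fht$center,
                  spec$fht$semiaxes)
  if (rq <= 1)
    stop("phantom_spec: background ROI center lies inside the FHT ellipsoid",
         call. = FALSE)
  invisible(spec)
}

# ((p - c) / a)^2 summed; p is an n x 3 matrix.
quad_form <- function(p, center, semiaxes) {
  ((p[, 1] - center[1]) / semiaxes[1])^2 +
  ((p[, 2] - center[2]) / semiaxes[2])^2 +
  ((p[, 3] - center[3]) / semiaxes[3])^2
}

# Deterministic quasi-uniform sample of an ellipsoid surface (Fibonacci
# lattice on the sphere, scaled by the semi-axes).
ellipsoid_surface_points <- function(center, semiaxes, n = 2000L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + semiaxes[1] * sin(phi) * cos(theta),
        center[2] + semiaxes[2] * sin(phi) * sin(theta),
        center[3] + semiaxes[3] * cos(phi))
}

# Grid of a phantom spec: centered on the world origin.
phantom_grid <- function(spec) {
  vs <- spec$voxel_size_mm
  origin <- -(spec$grid_dim - 1) * vs / 2
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- origin
  list(dim = spec$grid_dim, spacing = rep(vs, 3), affine = affine)
}

# Ellipsoid membership (voxel-center rule, quadratic form <= 1) as a logical
# array, built from per-axis coordinate vectors without expanding the grid.
ellipsoid_array <- function(axes, center, semiaxes) {
  qx <- ((axes[[1]] - center[1]) / semiaxes[1])^2
  qy <- ((axes[[2]] - center[2]) / semiaxes[2])^2
  qz <- ((axes[[3]] - center[3]) / semiaxes[3])^2
  outer(outer(qx, qy, `+`), qz, `+`) <= 1
}

#' Generate a synthetic multiparametric phantom
#'
#' Renders the piecewise-constant parameter maps described by a
#' [phantom_spec()], adds noise, and enumerates the analytic ground truth
#' (hotspot voxel counts, volumes, relative volumes, pairwise Dice) from the
#' noiseless fields by direct voxel enumeration, independent of the analysis
#' pipeline. Identical `(spec, seed)` gives bit-identical output.
#'
#' @param spec [phantom_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param cutoffs [cutoff_set()] used for the ground-truth hotspot
#'   enumeration.
#' @return list with elements
#'   `maps` (raw `image_volume`s: `aptw`, `fet`, `cbv`),
#'   `noiseless` (`image_volume`s on thresholdable scales: `aptw`, `fet`
#'   = TBR, `cbv` = rCBV percent),
#'   `masks` (`region_mask`s `cet`, `fht`, `background_roi`),
#'   `truth` (see [phantom_truth()]), and `spec`.
#' @export
generate_phantom <- function(spec, seed = spec$seed, cutoffs = cutoff_set()) {
  validate_phantom_spec(spec)
  grid <- phantom_grid(spec)
  gv <- image_volume(array(0, dim = grid$dim), spacing = grid$spacing,
                     affine = grid$affine)
  axes <- world_axes(gv)

  in_cet_full <- ellipsoid_array(axes, spec$cet$center, spec$cet$semiaxes)
  in_fht_full <- ellipsoid_array(axes, spec$fht$center, spec$fht$semiaxes)
  cet <- in_cet_full
  fht <- in_fht_full & !in_cet_full
  if (!any(cet) || !any(fht))
    stop("generate_phantom: a compartment has zero voxels on this grid ",
         "(degenerate spec)", call. = FALSE)

  mods <- c("aptw", "fet", "cbv")
  noise_model <- spec$noise_model
  if (length(noise_model) == 1L)
    noise_model <- stats::setNames(rep(noise_model, 3), mods)

  pattern <- list()
  for (m in mods) {
    b <- spec$baseline[[m]]
    val <- array(b[["background"]], dim = grid$dim)
    val[fht] <- b[["fht"]]
    val[cet] <- b[["cet"]]
    hs <- spec$hotspots[[m]]
    in_hs <- ellipsoid_array(axes, hs$center, hs$semiaxes)
    val[in_hs] <- val[in_hs] + hs$delta
    pattern[[m]] <- val
  }

  set.seed(seed)
  raw <- list()
  scale <- c(aptw = 1, fet = spec$fet_scale, cbv = spec$cbv_scale)
  for (m in mods) {
    sd <- spec$noise_sd[[m]]
    noisy <- if (sd == 0) {
      pattern[[m]]
    } else if (noise_model[[m]] == "rician") {
      e1 <- array(stats::rnorm(length(pattern[[m]]), 0, sd), dim = grid$dim)
      e2 <- array(stats::rnorm(length(pattern[[m]]), 0, sd), dim = grid$dim)
      sqrt((pattern[[m]] + e1)^2 + e2^2)
    } else {
      pattern[[m]] +
        array(stats::rnorm(length(pattern[[m]]), 0, sd), dim = grid$dim)
    }
    raw[[m]] <- noisy * scale[[m]]
  }

  mk_vol <- function(arr, modality)
    image_volume(arr, spacing = grid$spacing, affine = grid$affine,
                 modality = modality)
  mk_mask <- function(arr, label)
    region_mask(array(as.integer(arr), dim = grid$dim),
                spacing = grid$spacing, affine = grid$affine, label = label)

  roi <- ellipsoid_array(axes, spec$background_roi$center,
                         rep(spec$background_roi$radius, 3))

  list(maps = list(aptw = mk_vol(raw$aptw, "APTw"),
                   fet = mk_vol(raw$fet, "FET"),
                   cbv = mk_vol(raw$cbv, "CBV")),
       noiseless = list(aptw = mk_vol(pattern$aptw, "APTw"),
                        fet = mk_vol(pattern$fet, "FET_TBR"),
                        cbv = mk_vol(pattern$cbv, "rCBV")),
       masks = list(cet = mk_mask(cet, "CET"),
                    fht = mk_mask(fht, "FHT"),
                    background_roi = mk_mask(roi, "background")),
       truth = phantom_truth(spec, cutoffs),
       spec = spec)
}

#' Ground truth of a phantom by exhaustive voxel enumeration
#'
#' Recomputes, from the spec alone, the noiseless value of every voxel center
#' (explicit coordinate list, no shared code with the rendering or analysis
#' path) and enumerates compartment sizes, hotspot voxel counts/volumes/
#' relative volumes per compartment and modality, and all pairwise Dice
#' scores per compartment.
#'
#' @inheritParams generate_phantom
#' @return nested list: `compartments` (`n_voxels`, `volume_mm3` for cet and
#'   fht), `hotspots[[compartment]][[modality]]` (`n_voxels`, `volume_mm3`,
#'   `relative_volume`), `dice[[compartment]][[pair]]`.
#' @export
phantom_truth <- function(spec, cutoffs = cutoff_set()) {
  grid <- phantom_grid(spec)
  vs <- spec$voxel_size_mm
  vox_mm3 <- vs^3
  idx <- as.matrix(expand.grid(i = seq_len(grid$dim[1]) - 1,
                               j = seq_len(grid$dim[2]) - 1,
                               k = seq_len(grid$dim[3]) - 1))
  p <- cbind(idx[, 1] * vs + grid$affine[1, 4],
             idx[, 2] * vs + grid$affine[2, 4],
             idx[, 3] * vs + grid$affine[3, 4])

  in_cet <- quad_form(p, spec$cet$center, spec$cet$semiaxes) <= 1
  in_fht_full <- quad_form(p, spec$fht$center, spec$fht$semiaxes) <= 1
  comp <- list(cet = in_cet, fht = in_fht_full & !in_cet)

  mods <- c("aptw", "fet", "cbv")
  value <- list()
  for (m in mods) {
    b <- spec$baseline[[m]]
    v <- rep(b[["background"]], nrow(p))
    v[comp$fht] <- b[["fht"]]
    v[comp$cet] <- b[["cet"]]
    hs <- spec$hotspots[[m]]
    sel <- quad_form(p, hs$center, hs$semiaxes) <= 1
    v[sel] <- v[sel] + hs$delta
    value[[m]] <- v
  }
  cut <- c(aptw = cutoffs$aptw, fet = cutoffs$fet, cbv = cutoffs$cbv)

  out <- list(compartments = list(), hotspots = list(), dice = list())
  for (cn in c("cet", "fht")) {
    inc <- comp[[cn]]
    out$compartments[[cn]] <- list(n_voxels = sum(inc),
                                   volume_mm3 = sum(inc) * vox_mm3)
    hot <- lapply(mods, function(m) inc & value[[m]] > cut[[m]])
    names(hot) <- mods
    out$hotspots[[cn]] <- lapply(hot, function(h)
      list(n_voxels = sum(h), volume_mm3 = sum(h) * vox_mm3,
           relative_volume = sum(h) / sum(inc)))
    dc <- list()
    for (pr in list(c("aptw", "fet"), c("aptw", "cbv"), c("fet", "cbv"))) {
      a <- hot[[pr[1]]]; b <- hot[[pr[2]]]
      dc[[paste(pr, collapse = "_")]] <-
        if (sum(a) + sum(b) == 0) NA_real_
        else 2 * sum(a & b) / (sum(a) + sum(b))
    }
    out$dice[[cn]] <- dc
  }
  out
}

#' Write a phantom to disk
#'
#' Maps and masks as NIfTI-1 (`.nii.gz`), ground truth as JSON.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(phantom$maps))
    write_volume(phantom$maps[[m]], file.path(dir, paste0(m, ".nii.gz")))
  for (m in names(phantom$masks))
    write_volume(phantom$masks[[m]], file.path(dir, paste0("mask_", m, ".nii.gz")))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
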
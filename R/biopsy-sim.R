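#' Effect specification for the synthetic biopsy generator
#'
#' Defines the monotone links between local imaging values (VOI medians of
#' the noiseless phantom maps) and histology. Cellularity (cells per 1/4
#' high-power field, mean of three counted regions) follows a negative
#' binomial whose log-mean is linear in local APTw; with `cell_size = Inf`
#' the counts are noise-free and equal the mean exactly. Vascularity is an
#' ordinal 0/1/2 score from an ordered-logit link on local rCBV:
#' `P(V >= g) = plogis(vasc_slope * (rcbv - vasc_cuts[g]))`.
#'
#' @param cell_base expected cells per 1/4 HPF at `cell_ref` APTw
#'   (default 80).
#' @param cell_slope log-linear effect per APTw %-unit (default 0.45; 0
#'   disables the link).
#' @param cell_ref APTw reference value (default 2.0).
#' @param cell_size negative-binomial size (dispersion); `Inf` = noise-free
#'   deterministic counts. The default 0.4 is strongly overdispersed,
#'   placing the population APTw-cellularity Spearman correlation in the
#'   weak-to-moderate range (about 0.35-0.4) seen in stereotactic biopsy
#'   series.
#' @param vasc_slope ordered-logit slope on the rCBV percent scale
#'   (default 1.0).
#' @param vasc_cuts length-2 increasing cutpoints for grades >= 1 and >= 2
#'   (default `c(3.5, 6.5)` rCBV percent).
#' @return object of class `biopsy_effect_spec`.
#' @export
biopsy_effect_spec <- function(cell_base = 80, cell_slope = 0.45,
                               cell_ref = 2.0, cell_size = 0.4,
                               vasc_slope = 1.0, vasc_cuts = c(3.5, 6.5)) {
  if (cell_base <= 0) stop("cell_base must be > 0", call. = FALSE)
  if (!is.infinite(cell_size) && cell_size <= 0)
    stop("cell_size must be > 0 or Inf", call. = FALSE)
  if (length(vasc_cuts) != 2L || diff(vasc_cuts) <= 0)
    stop("vasc_cuts must be two increasing values", call. = FALSE)
  structure(list(cell_base = cell_base, cell_slope = cell_slope,
                 cell_ref = cell_ref, cell_size = cell_size,
                 vasc_slope = vasc_slope, vasc_cuts = vasc_cuts),
            class = "biopsy_effect_spec")
}

# Brute-force VOI median of a map around world-space centers: for each
# center, enumerate voxels in a bounding box, keep those with voxel center
# within radius, take the median. Self-contained (no sphere_voi /
# sample_biopsies) so the generator stays independent of the analysis path.
brute_voi_median <- function(vol, centers, diameter_mm) {
  r <- diameter_mm / 2
  axes <- world_axes(vol)
  dm <- dim(vol$data)
  out <- numeric(nrow(centers))
  for (b in seq_len(nrow(centers))) {
    cc <- centers[b, ]
    sel <- lapply(1:3, function(a) which(abs(axes[[a]] - cc[a]) <= r))
    if (any(lengths(sel) == 0L)) { out[b] <- NA_real_; next }
    g <- expand.grid(i = sel[[1]], j = sel[[2]], k = sel[[3]])
    d2 <- (axes[[1]][g$i] - cc[1])^2 + (axes[[2]][g$j] - cc[2])^2 +
          (axes[[3]][g$k] - cc[3])^2
    keep <- d2 <= r^2
    if (!any(keep)) { out[b] <- NA_real_; next }
    out[b] <- stats::median(vol$data[cbind(g$i, g$j, g$k)[keep, , drop = FALSE]])
  }
  out
}

#' Precompute VOI medians for every tumor voxel of a phantom
#'
#' For each voxel center inside CET or FHT, the sphere-VOI median of each
#' noiseless map. Amortises the sphere extraction when many biopsy sets are
#' drawn from one phantom (e.g. replicate simulations); consumed by
#' [generate_biopsies()] via `voi_table=`.
#'
#' @param phantom [generate_phantom()] result.
#' @param diameter_mm VOI diameter (default 10, the 1 cm biopsy sphere).
#' @return list with `centers` (n x 3 world mm), `values` (data frame
#'   `aptw`, `fet`, `cbv`), `diameter_mm`.
#' @export
phantom_voi_table <- function(phantom, diameter_mm = 10) {
  tumor <- phantom$masks$cet$data == 1L | phantom$masks$fht$data == 1L
  vol0 <- phantom$noiseless$aptw
  axes <- world_axes(vol0)
  idx <- which(tumor, arr.ind = TRUE)
  centers <- cbind(axes[[1]][idx[, 1]], axes[[2]][idx[, 2]],
                   axes[[3]][idx[, 3]])
  # On-lattice centers: one fixed offset stencil serves every voxel.
  vs <- vol0$spacing
  r <- diameter_mm / 2
  off <- expand.grid(i = seq(-floor(r / vs[1]), floor(r / vs[1])),
                     j = seq(-floor(r / vs[2]), floor(r / vs[2])),
                     k = seq(-floor(r / vs[3]), floor(r / vs[3])))
  off <- off[(off$i * vs[1])^2 + (off$j * vs[2])^2 + (off$k * vs[3])^2 <= r^2, ]
  dm <- dim(vol0$data)
  vals <- lapply(phantom$noiseless, function(v) {
    m <- matrix(NA_real_, nrow(idx), nrow(off))
    for (s in seq_len(nrow(off))) {
      ii <- idx[, 1] + off$i[s]; jj <- idx[, 2] + off$j[s]
      kk <- idx[, 3] + off$k[s]
      ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] &
            kk >= 1 & kk <= dm[3]
      m[ok, s] <- v$data[cbind(ii[ok], jj[ok], kk[ok])]
    }
    apply(m, 1, stats::median, na.rm = TRUE)
  })
  list(centers = centers,
       values = data.frame(aptw = vals$aptw, fet = vals$fet, cbv = vals$cbv),
       diameter_mm = diameter_mm)
}

#' Generate synthetic stereotactic biopsies from a phantom
#'
#' Draws biopsy sites uniformly over the tumor (CET union FHT), reads the
#' local imaging context as the VOI median of the noiseless maps in a 1 cm
#' sphere, and generates histology through the monotone links of a
#' [biopsy_effect_spec()]: negative-binomial cellularity driven by local
#' APTw (mean of three counted regions per biopsy) and ordered-logit
#' vascularity (0/1/2) driven by local rCBV. Generating parameters and the
#' local values are returned as ground truth.
#'
#' @param phantom [generate_phantom()] result.
#' @param n_biopsies number of biopsies (>= 1).
#' @param effect_spec [biopsy_effect_spec()].
#' @param seed RNG seed.
#' @param diameter_mm VOI diameter in mm (default 10).
#' @param jitter if `TRUE` (default) biopsy centers are jittered uniformly
#'   within the voxel, giving generic world coordinates; `FALSE` places them
#'   exactly on voxel centers (required to use `voi_table`).
#' @param voi_table optional [phantom_voi_table()] to reuse precomputed VOI
#'   medians (only with `jitter = FALSE` and matching diameter).
#' @return list with `samples` (data frame: id, x_mm, y_mm, z_mm,
#'   cellularity, vascularity), `truth` (data frame of local VOI medians,
#'   generating means and grade probabilities per biopsy), `effect_spec`,
#'   `diameter_mm`.
#' @export
generate_biopsies <- function(phantom, n_biopsies,
                              effect_spec = biopsy_effect_spec(),
                              seed = 1L, diameter_mm = 10,
                              jitter = TRUE, voi_table = NULL) {
  stopifnot(inherits(effect_spec, "biopsy_effect_spec"))
  if (n_biopsies < 1L)
    stop("generate_biopsies: n_biopsies must be >= 1", call. = FALSE)
  tumor <- phantom$masks$cet$data == 1L | phantom$masks$fht$data == 1L
  if (!any(tumor))
    stop("generate_biopsies: no valid placement region (tumor empty)",
         call. = FALSE)
  set.seed(seed)
  vol0 <- phantom$noiseless$aptw
  vs <- vol0$spacing

  if (!is.null(voi_table)) {
    if (jitter)
      stop("generate_biopsies: voi_table requires jitter = FALSE",
           call. = FALSE)
    if (!isTRUE(all.equal(voi_table$diameter_mm, diameter_mm)))
      stop("generate_biopsies: voi_table diameter mismatch", call. = FALSE)
    pick <- sample.int(nrow(voi_table$centers), n_biopsies, replace = TRUE)
    centers <- voi_table$centers[pick, , drop = FALSE]
    local <- voi_table$values[pick, , drop = FALSE]
  } else {
    axes <- world_axes(vol0)
    idx <- which(tumor, arr.ind = TRUE)
    pick <- sample.int(nrow(idx), n_biopsies, replace = TRUE)
    centers <- cbind(axes[[1]][idx[pick, 1]], axes[[2]][idx[pick, 2]],
                     axes[[3]][idx[pick, 3]])
    if (jitter)
      centers <- centers + matrix(stats::runif(3 * n_biopsies, -0.5, 0.5),
                                  ncol = 3) %*% diag(vs)
    local <- data.frame(
      aptw = brute_voi_median(phantom$noiseless$aptw, centers, diameter_mm),
      fet = brute_voi_median(phantom$noiseless$fet, centers, diameter_mm),
      cbv = brute_voi_median(phantom$noiseless$cbv, centers, diameter_mm))
  }

  es <- effect_spec
  mu <- es$cell_base * exp(es$cell_slope * (local$aptw - es$cell_ref))
  cellularity <- if (is.infinite(es$cell_size)) mu
  else
    vapply(mu, function(m)
      mean(stats::rnbinom(3L, mu = m, size = es$cell_size)), numeric(1))

  p1 <- stats::plogis(es$vasc_slope * (local$cbv - es$vasc_cuts[1]))
  p2 <- stats::plogis(es$vasc_slope * (local$cbv - es$vasc_cuts[2]))
  u <- stats::runif(n_biopsies)
  vascularity <- ifelse(u < p2, 2L, ifelse(u < p1, 1L, 0L))

  samples <- data.frame(id = sprintf("bx%03d", seq_len(n_biopsies)),
                        x_mm = centers[, 1], y_mm = centers[, 2],
                        z_mm = centers[, 3],
                        cellularity = cellularity,
                        vascularity = vascularity)
  truth <- data.frame(id = samples$id, aptw = local$aptw, fet = local$fet,
                      cbv = local$cbv, mu_cellularity = mu,
                      p_vasc_ge1 = p1, p_vasc_ge2 = p2)
  list(samples = samples, truth = truth, effect_spec = es,
       diameter_mm = diameter_mm)
}

#' Monte-Carlo target Spearman correlation of the biopsy generator
#'
#' The population Spearman rho between the local APTw VOI median and
#' generated cellularity for a given phantom and effect spec, estimated from
#' one large draw through the generative link (uniform biopsy placement over
#' tumor voxels, VOI medians from a precomputed table). This is the "true"
#' correlation that finite biopsy samples estimate.
#'
#' @param phantom [generate_phantom()] result.
#' @param effect_spec [biopsy_effect_spec()].
#' @param n_mc Monte-Carlo draw size (default 2e5).
#' @param seed RNG seed for the oracle draw.
#' @param voi_table optional precomputed [phantom_voi_table()].
#' @return list with `rho_cellularity_aptw` and the table used.
#' @export
biopsy_rho_target <- function(phantom, effect_spec = biopsy_effect_spec(),
                              n_mc = 2e5, seed = 99L, voi_table = NULL) {
  if (is.null(voi_table)) voi_table <- phantom_voi_table(phantom)
  set.seed(seed)
  es <- effect_spec
  x <- sample(voi_table$values$aptw, n_mc, replace = TRUE)
  mu <- es$cell_base * exp(es$cell_slope * (x - es$cell_ref))
  cells <- if (is.infinite(es$cell_size)) mu
  else (stats::rnbinom(n_mc, mu = mu, size = es$cell_size) +
        stats::rnbinom(n_mc, mu = mu, size = es$cell_size) +
        stats::rnbinom(n_mc, mu = mu, size = es$cell_size)) / 3
  list(rho_cellularity_aptw = stats::cor(rank(x), rank(cells)),
       voi_table = voi_table)
}
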
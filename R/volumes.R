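#' Image volume container
#'
#' A lightweight container for one co-registered 3D parameter map: a numeric
#' array plus voxel spacing, a voxel-to-world affine (NIfTI convention,
#' 0-based voxel indices) and a modality tag. All maps entering one analysis
#' must share shape and affine (see [same_grid()]).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default `diag(c(spacing, 1))`.
#' @param modality character tag, e.g. `"APTw"`, `"FET"`, `"CBV"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         modality = "other") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array, got ",
         length(dim(data)), " dimensions", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: spacing must be 3 strictly positive values",
         call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("image_volume: affine must be a 4x4 matrix", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, affine = affine,
                 modality = as.character(modality)[1]),
            class = "image_volume")
}

#' Binary region mask container
#'
#' A compartment mask (CET, FHT, necrosis exclusion, background reference ROI
#' or hotspot) on the same grid convention as [image_volume()]. Values are
#' strictly 0/1; on construction, values > 0.5 are mapped to 1 to guard
#' against interpolated masks written by upstream software.
#'
#' @param data 3D array (logical or numeric); values > 0.5 become 1.
#' @param label compartment tag, e.g. `"CET"`, `"FHT"`, `"hotspot"`.
#' @inheritParams image_volume
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        label = "mask") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("region_mask: 'data' must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("region_mask: spacing must be 3 strictly positive values",
         call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("region_mask: affine must be a 4x4 matrix", call. = FALSE)
  bin <- array(0L, dim = dim(data))
  vals <- as.numeric(data)
  vals[is.na(vals)] <- 0
  bin[vals > 0.5] <- 1L
  structure(list(data = bin, spacing = spacing, affine = affine,
                 label = as.character(label)[1]),
            class = "region_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s voxels  spacing %s mm  range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s  %s voxels  %d set (%.0f mm^3)\n",
              x$label, paste(dim(x$data), collapse = "x"),
              sum(x$data), sum(x$data) * prod(x$spacing)))
  invisible(x)
}

grid_dim <- function(x) dim(x$data)

#' Test whether two volumes/masks share an analysis grid
#'
#' Grids are compatible when shapes match and the affines agree element-wise
#' within `tol` (mm). Beyond that, explicit resampling is required.
#'
#' @param a,b `image_volume` or `region_mask` objects.
#' @param tol per-element affine tolerance in mm (default `1e-3`).
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-3) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$affine - b$affine) < tol)
}

stop_grid_mismatch <- function(a, b, where) {
  if (!same_grid(a, b))
    stop(where, ": inputs are not on the same grid (shape/affine mismatch); ",
         "resample first with resample_to_grid()", call. = FALSE)
  invisible(TRUE)
}

# World coordinates of all voxel centers, n x 3 (NIfTI: 0-based indices).
voxel_centers <- function(x) {
  dm <- grid_dim(x)
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  world_from_voxel(x$affine, idx)
}

# affine applied to 0-based voxel index matrix (n x 3) -> world (n x 3)
world_from_voxel <- function(affine, idx) {
  idx <- rbind(t(idx), 1)
  t(affine %*% idx)[, 1:3, drop = FALSE]
}

# world (n x 3) -> continuous 0-based voxel indices (n x 3)
voxel_from_world <- function(affine, world) {
  inv <- solve(affine)
  world <- rbind(t(world), 1)
  t(inv %*% world)[, 1:3, drop = FALSE]
}

# Coordinate arrays (in mm, world space) per axis for an axis-aligned grid;
# used heavily by the phantom. Works for any affine via full expansion.
world_axes <- function(x) {
  aff <- x$affine
  offd <- aff[1:3, 1:3]; diag(offd) <- 0
  if (any(abs(offd) > 1e-9))
    return(NULL)  # oblique; caller must use voxel_centers()
  dm <- grid_dim(x)
  lapply(1:3, function(a) aff[a, a] * (seq_len(dm[a]) - 1) + aff[a, 4])
}
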
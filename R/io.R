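#' Read a parameter map from NIfTI-1
#'
#' Reads a 3D scalar volume (`.nii` / `.nii.gz`), taking spacing and the
#' voxel-to-world affine from the header (sform preferred by RNifti). The
#' reader fails on non-3D data or all-NaN content rather than silently
#' coercing or reorienting.
#'
#' @param path file path.
#' @param modality expected modality tag recorded on the returned volume.
#' @return [image_volume()].
#' @export
load_volume <- function(path, modality = "other") {
  if (!file.exists(path))
    stop("load_volume: file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("load_volume: expected a 3D volume, got ", length(dm),
         " dimensions in ", path, call. = FALSE)
  dat <- array(as.numeric(img), dim = dm)
  if (all(!is.finite(dat)))
    stop("load_volume: volume contains no finite values: ", path,
         call. = FALSE)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  image_volume(dat, spacing = RNifti::pixdim(img)[1:3], affine = aff,
               modality = modality)
}

#' Read a binary mask from NIfTI-1
#'
#' As [load_volume()], then binarised at 0.5 (values > 0.5 become 1), which
#' guards against masks that were interpolated by upstream software.
#'
#' @inheritParams load_volume
#' @param label compartment tag for the mask.
#' @return [region_mask()].
#' @export
load_mask <- function(path, label = "mask") {
  vol <- load_volume(path, modality = label)
  region_mask(vol$data, spacing = vol$spacing, affine = vol$affine,
              label = label)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param x `image_volume` or `region_mask`.
#' @param path output path; `.nii.gz` is compressed transparently.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "region_mask"))
  dat <- x$data
  storage.mode(dat) <- "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  img <- RNifti::`qform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume or mask onto a reference grid
#'
#' Maps voxel centers of the reference grid into the source volume through
#' both affines. Parameter maps are interpolated trilinearly; masks by
#' nearest neighbor, so they remain strictly binary. Reference voxels falling
#' outside the source field of view become `NA` (maps) or 0 (masks); if no
#' reference voxel is covered at all, the fields of view are disjoint and the
#' call errors.
#'
#' A source already on the reference grid (affine agreement within 1e-3 mm)
#' is returned unchanged.
#'
#' @param x `image_volume` or `region_mask`.
#' @param reference an `image_volume`/`region_mask` defining the target grid,
#'   or a list with elements `dim`, `spacing`, `affine`.
#' @return the same type as `x`, on the reference grid.
#' @export
resample_to_grid <- function(x, reference) {
  ref <- if (inherits(reference, c("image_volume", "region_mask"))) {
    list(dim = grid_dim(reference), spacing = reference$spacing,
         affine = reference$affine)
  } else {
    stopifnot(all(c("dim", "affine") %in% names(reference)))
    reference
  }
  if (identical(grid_dim(x), as.integer(ref$dim)) &&
      all(abs(x$affine - ref$affine) < 1e-3))
    return(x)

  dm <- as.integer(ref$dim)
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  world <- world_from_voxel(ref$affine, idx)
  u <- voxel_from_world(x$affine, world)  # continuous 0-based source indices

  sdm <- grid_dim(x)
  inside <- u[, 1] >= 0 & u[, 1] <= sdm[1] - 1 &
            u[, 2] >= 0 & u[, 2] <= sdm[2] - 1 &
            u[, 3] >= 0 & u[, 3] <= sdm[3] - 1
  if (!any(inside))
    stop("resample_to_grid: fields of view are disjoint", call. = FALSE)

  is_mask <- inherits(x, "region_mask")
  out <- rep(if (is_mask) 0 else NA_real_, nrow(u))

  if (is_mask) {
    ui <- round(u[inside, , drop = FALSE]) + 1
    ui[, 1] <- pmin(pmax(ui[, 1], 1), sdm[1])
    ui[, 2] <- pmin(pmax(ui[, 2], 1), sdm[2])
    ui[, 3] <- pmin(pmax(ui[, 3], 1), sdm[3])
    out[inside] <- x$data[cbind(ui[, 1], ui[, 2], ui[, 3])]
  } else {
    out[inside] <- trilinear(x$data, u[inside, , drop = FALSE])
  }
  arr <- array(out, dim = dm)
  if (is_mask)
    region_mask(arr, spacing = ref$spacing, affine = ref$affine,
                label = x$label)
  else
    image_volume(arr, spacing = ref$spacing, affine = ref$affine,
                 modality = x$modality)
}

# Vectorised trilinear interpolation at continuous 0-based indices u (n x 3).
# Callers guarantee u lies inside [0, dim-1] on every axis.
trilinear <- function(data, u) {
  dm <- dim(data)
  i0 <- pmin(floor(u[, 1]), dm[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(u[, 2]), dm[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(u[, 3]), dm[3] - 2); k0 <- pmax(k0, 0)
  fx <- u[, 1] - i0; fy <- u[, 2] - j0; fz <- u[, 3] - k0
  g <- function(di, dj, dk)
    data[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  g(0,0,0) * (1-fx)*(1-fy)*(1-fz) + g(1,0,0) * fx*(1-fy)*(1-fz) +
  g(0,1,0) * (1-fx)*fy*(1-fz)     + g(0,0,1) * (1-fx)*(1-fy)*fz +
  g(1,1,0) * fx*fy*(1-fz)         + g(1,0,1) * fx*(1-fy)*fz +
  g(0,1,1) * (1-fx)*fy*fz         + g(1,1,1) * fx*fy*fz
}
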
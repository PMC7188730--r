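#' Prepare mutually exclusive tumor compartments
#'
#' Builds the two compartments the analysis runs in: contrast-enhancing tumor
#' (CET) and FLAIR-hyperintense tumor (FHT), defined so that FHT excludes all
#' CET voxels. An optional exclusion mask (cystic/necrotic areas) is removed
#' from both. The result is invariant to the order in which the set
#' differences are applied.
#'
#' @param cet CET `region_mask` (may be empty, e.g. non-enhancing lower-grade
#'   glioma).
#' @param flair FLAIR-hyperintensity `region_mask`; must be nonempty.
#' @param exclude optional necrosis/cyst `region_mask` subtracted from both.
#' @return list with elements `cet` and `fht` (`region_mask`, disjoint). The
#'   `fht` element carries attribute `degenerate = TRUE` if it came out empty.
#' @export
prepare_compartments <- function(cet, flair, exclude = NULL) {
  stopifnot(inherits(cet, "region_mask"), inherits(flair, "region_mask"))
  stop_grid_mismatch(cet, flair, "prepare_compartments")
  if (sum(flair$data) == 0L)
    stop("prepare_compartments: FLAIR mask is empty (degenerate input)",
         call. = FALSE)
  ex <- if (is.null(exclude)) 0L else {
    stop_grid_mismatch(flair, exclude, "prepare_compartments")
    exclude$data
  }
  cet_out <- cet$data & !ex
  fht_out <- flair$data & !cet$data & !ex
  cet_m <- region_mask(array(as.integer(cet_out), dim = dim(cet$data)),
                       spacing = cet$spacing, affine = cet$affine,
                       label = "CET")
  fht_m <- region_mask(array(as.integer(fht_out), dim = dim(flair$data)),
                       spacing = flair$spacing, affine = flair$affine,
                       label = "FHT")
  if (sum(fht_m$data) == 0L) {
    warning("prepare_compartments: FHT is empty after exclusion",
            call. = FALSE)
    attr(fht_m, "degenerate") <- TRUE
  }
  list(cet = cet_m, fht = fht_m)
}

#' Mask volume in cubic millimetres
#'
#' Nonzero voxel count times the voxel volume.
#'
#' @param mask `region_mask`.
#' @return volume in mm^3 (scalar).
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  sum(mask$data) * prod(mask$spacing)
}

# Internal mask set algebra; all require an identical grid (callers check).
mask_and <- function(a, b, label = a$label) {
  region_mask(array(as.integer(a$data & b$data), dim = dim(a$data)),
              spacing = a$spacing, affine = a$affine, label = label)
}
mask_diff <- function(a, b, label = a$label) {
  region_mask(array(as.integer(a$data & !b$data), dim = dim(a$data)),
              spacing = a$spacing, affine = a$affine, label = label)
}
mask_count <- function(m) sum(m$data)
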
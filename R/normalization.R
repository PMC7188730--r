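#' Background reference statistic from a contralateral ROI
#'
#' Summarises a parameter map inside a reference ROI placed in normal-appearing
#' tissue of the non-tumor-bearing hemisphere (gray/white matter for FET,
#' white matter for CBV). The arithmetic mean is the default summary; the
#' median is available for robustness against ROI contamination.
#'
#' @param map `image_volume`.
#' @param roi `region_mask`, the reference ROI on the same grid.
#' @param statistic `"mean"` (default) or `"median"`.
#' @param min_voxels minimum ROI size accepted (default 10).
#' @return list with `value`, `n_voxels`, `statistic`.
#' @export
background_reference <- function(map, roi, statistic = c("mean", "median"),
                                 min_voxels = 10) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(map, "image_volume"), inherits(roi, "region_mask"))
  stop_grid_mismatch(map, roi, "background_reference")
  vals <- map$data[roi$data == 1L]
  vals <- vals[is.finite(vals)]
  if (length(vals) < min_voxels)
    stop("background_reference: ROI has ", length(vals),
         " usable voxels, fewer than min_voxels = ", min_voxels,
         call. = FALSE)
  v <- if (statistic == "mean") mean(vals) else stats::median(vals)
  if (!is.finite(v) || v <= 0)
    stop("background_reference: reference statistic must be finite and > 0 ",
         "for ratio construction (got ", format(v), ")", call. = FALSE)
  list(value = v, n_voxels = length(vals), statistic = statistic)
}

#' Scale an activity map to standardized uptake values
#'
#' SUV = activity concentration x body weight / injected activity, with body
#' weight entered in kg and converted to grams (the conventional 1 g/mL tissue
#' density assumption). Decay correction is assumed done upstream.
#'
#' @param activity `image_volume` of decay-corrected activity concentration
#'   (Bq/mL).
#' @param injected_activity_bq injected activity in Bq (> 0).
#' @param body_weight_kg body weight in kg (> 0).
#' @return `image_volume` in SUV units (modality `"FET_SUV"`).
#' @export
compute_suv_scale <- function(activity, injected_activity_bq, body_weight_kg) {
  stopifnot(inherits(activity, "image_volume"))
  if (!is.finite(injected_activity_bq) || injected_activity_bq <= 0)
    stop("compute_suv_scale: injected activity must be > 0", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("compute_suv_scale: body weight must be > 0", call. = FALSE)
  scale <- body_weight_kg * 1000 / injected_activity_bq
  image_volume(activity$data * scale, spacing = activity$spacing,
               affine = activity$affine, modality = "FET_SUV")
}

#' FET tumor-to-background ratio map
#'
#' Voxelwise SUV divided by the background reference mean. When both a gray-
#' and a white-matter ROI reference are supplied, they are averaged with
#' equal weight.
#'
#' @param suv `image_volume` (SUV or any activity scale; TBR is
#'   scale-invariant as long as the reference comes from the same map).
#' @param background a [background_reference()] result, or a list of them to
#'   average with equal weight.
#' @return `image_volume` of TBR (modality `"FET_TBR"`).
#' @export
tbr_map <- function(suv, background) {
  stopifnot(inherits(suv, "image_volume"))
  ref <- reference_value(background, "tbr_map")
  image_volume(suv$data / ref, spacing = suv$spacing, affine = suv$affine,
               modality = "FET_TBR")
}

#' White-matter-referenced rCBV map
#'
#' Normalises a CBV map against the mean of a contralateral normal-appearing
#' white-matter ROI. In `"absolute_percent"` mode (default) the map is scaled
#' so the WM mean equals `wm_percent` (2.5% blood volume in healthy white
#' matter), putting the conventional hotspot cutoff of 5.6 on its native
#' scale; `"ratio"` mode returns the plain ratio to the WM mean.
#'
#' @param cbv `image_volume` of (leakage-corrected) CBV in any consistent
#'   unit.
#' @param wm_reference [background_reference()] over the WM ROI.
#' @param mode `"absolute_percent"` (default) or `"ratio"`.
#' @param wm_percent assumed healthy WM blood volume in percent (default 2.5).
#' @return `image_volume` of rCBV (modality `"rCBV"`).
#' @export
rcbv_map <- function(cbv, wm_reference, mode = c("absolute_percent", "ratio"),
                     wm_percent = 2.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(cbv, "image_volume"))
  ref <- reference_value(wm_reference, "rcbv_map")
  scale <- if (mode == "ratio") 1 / ref else wm_percent / ref
  image_volume(cbv$data * scale, spacing = cbv$spacing, affine = cbv$affine,
               modality = "rCBV")
}

reference_value <- function(background, where) {
  one <- function(b) {
    if (!is.list(b) || is.null(b$value))
      stop(where, ": background must come from background_reference()",
           call. = FALSE)
    b$value
  }
  v <- if (is.list(background) && is.null(background$value))
    mean(vapply(background, one, numeric(1)))
  else one(background)
  if (!is.finite(v) || v <= 0)
    stop(where, ": background reference must be finite and > 0",
         call. = FALSE)
  v
}
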
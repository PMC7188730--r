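#' Hotspot cutoff set
#'
#' The modality-specific thresholds that define a hotspot voxel, applied with
#' a strict greater-than comparison: APTw > 1.79 (%-asymmetry units), FET
#' tumor-to-background ratio > 1.6, rCBV > 5.6 (on the scale where healthy
#' white matter is 2.5%).
#'
#' @param aptw,fet,cbv finite numeric cutoffs.
#' @return object of class `cutoff_set` (named list).
#' @export
cutoff_set <- function(aptw = 1.79, fet = 1.6, cbv = 5.6) {
  vals <- c(aptw = aptw, fet = fet, cbv = cbv)
  if (any(!is.finite(vals)))
    stop("cutoff_set: all cutoffs must be finite", call. = FALSE)
  structure(as.list(vals), class = "cutoff_set")
}

#' Extract a hotspot mask within a compartment
#'
#' A voxel belongs to the hotspot iff it lies in `within` and the map value
#' strictly exceeds the cutoff. Non-finite map values inside the compartment
#' never enter a hotspot; their count is recorded on the result as attribute
#' `qc_dropped` (e.g. voxels outside the PET field of view).
#'
#' @param map `image_volume` on the thresholdable scale (APTw, TBR, rCBV).
#' @param cutoff finite scalar; strict `>`.
#' @param within `region_mask` restricting the search (CET or FHT).
#' @return `region_mask` labelled `"hotspot"`; empty (with a warning) when
#'   `within` is empty.
#' @export
hotspot_mask <- function(map, cutoff, within) {
  stopifnot(inherits(map, "image_volume"), inherits(within, "region_mask"))
  if (!is.finite(cutoff)) stop("hotspot_mask: cutoff must be finite",
                               call. = FALSE)
  stop_grid_mismatch(map, within, "hotspot_mask")
  if (sum(within$data) == 0L)
    warning("hotspot_mask: 'within' mask is empty (degenerate input)",
            call. = FALSE)
  inside <- within$data == 1L
  finite <- is.finite(map$data)
  hot <- inside & finite & map$data > cutoff
  out <- region_mask(array(as.integer(hot), dim = dim(map$data)),
                     spacing = map$spacing, affine = map$affine,
                     label = "hotspot")
  attr(out, "qc_dropped") <- sum(inside & !finite)
  out
}

#' Relative hotspot volume
#'
#' Hotspot voxel count divided by compartment voxel count, in `[0, 1]`. An
#' empty compartment makes the quantity undefined and yields `NA` (reported
#' as missing, never as 0).
#'
#' @param hotspot `region_mask`, a subset of `compartment`.
#' @param compartment `region_mask`.
#' @return fraction in `[0, 1]`, or `NA_real_`.
#' @export
relative_hotspot_volume <- function(hotspot, compartment) {
  stopifnot(inherits(hotspot, "region_mask"),
            inherits(compartment, "region_mask"))
  stop_grid_mismatch(hotspot, compartment, "relative_hotspot_volume")
  if (any(hotspot$data == 1L & compartment$data == 0L))
    stop("relative_hotspot_volume: hotspot extends outside the compartment",
         call. = FALSE)
  n <- sum(compartment$data)
  if (n == 0L) return(NA_real_)
  sum(hotspot$data) / n
}

#' Dice overlap of two binary masks
#'
#' `D = 2 |X intersect Y| / (|X| + |Y|)`, in `[0, 1]`, symmetric in its
#' arguments. When both masks are empty the score is undefined and `NA` is
#' returned (emptiness signals degenerate input, not perfect agreement).
#'
#' @param x,y `region_mask` objects on the same grid.
#' @return Dice score or `NA_real_`.
#' @export
dice <- function(x, y) {
  stopifnot(inherits(x, "region_mask"), inherits(y, "region_mask"))
  stop_grid_mismatch(x, y, "dice")
  nx <- sum(x$data); ny <- sum(y$data)
  if (nx + ny == 0L) return(NA_real_)
  2 * sum(x$data == 1L & y$data == 1L) / (nx + ny)
}

#' Map statistics in FET-positive vs FET-negative subregions
#'
#' Splits a compartment into the FET-positive part (inside the FET hotspot)
#' and its complement, and summarises a map (APTw or CBV) on both sides:
#' median, interquartile range (25th/75th percentiles, linear interpolation)
#' and a two-sided rank-sum p-value comparing the two voxel-value samples.
#' Non-finite map values are dropped and counted (`qc_dropped`). If either
#' side is empty its statistics — and the p-value — are reported missing.
#'
#' @param map `image_volume` (APTw or rCBV).
#' @param compartment `region_mask` (CET or FHT).
#' @param fet_hotspot `region_mask`, must be a subset of `compartment`.
#' @return object of class `subregion_stats`: a list with `modality`,
#'   `compartment`, per-side `n`, `median`, `q25`, `q75`, and `p_value`.
#' @export
subregion_medians <- function(map, compartment, fet_hotspot) {
  stopifnot(inherits(map, "image_volume"),
            inherits(compartment, "region_mask"),
            inherits(fet_hotspot, "region_mask"))
  stop_grid_mismatch(map, compartment, "subregion_medians")
  stop_grid_mismatch(map, fet_hotspot, "subregion_medians")
  if (any(fet_hotspot$data == 1L & compartment$data == 0L))
    stop("subregion_medians: FET hotspot extends outside the compartment",
         call. = FALSE)
  pos_sel <- compartment$data == 1L & fet_hotspot$data == 1L
  neg_sel <- compartment$data == 1L & fet_hotspot$data == 0L
  pos <- map$data[pos_sel]; neg <- map$data[neg_sel]
  qc <- sum(!is.finite(pos)) + sum(!is.finite(neg))
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]

  side <- function(v) {
    if (length(v) == 0L)
      return(list(n = 0L, median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(n = length(v), median = q[2], q25 = q[1], q75 = q[3])
  }
  p <- if (length(pos) > 0L && length(neg) > 0L)
    rank_sum_test(pos, neg)$p_value else NA_real_
  structure(list(modality = map$modality,
                 compartment = compartment$label,
                 fet_positive = side(pos), fet_negative = side(neg),
                 p_value = p, qc_dropped = qc),
            class = "subregion_stats")
}

#' Run the full hotspot-overlap analysis for one patient
#'
#' For each available compartment (CET, FHT; an empty compartment is skipped,
#' as for non-enhancing lower-grade gliomas) and each available modality map,
#' extracts the cutoff hotspot, tabulates absolute (mm^3) and relative
#' hotspot volumes, all pairwise Dice scores, and FET-positive/negative
#' subregion statistics for APTw and CBV. Deterministic: modality processing
#' order does not affect the output.
#'
#' @param maps named list of `image_volume`s on the thresholdable scales;
#'   recognised names `aptw`, `fet` (TBR), `cbv` (rCBV). Missing modalities
#'   are tolerated: volume rows and Dice pairs are emitted for what exists.
#' @param compartments list with `cet` and `fht` `region_mask`s (either may
#'   be empty; see [prepare_compartments()]).
#' @param cutoffs [cutoff_set()].
#' @param patient_id identifier copied into every output row.
#' @return list of data frames: `hotspots` (patient, compartment, modality,
#'   n_voxels, volume_mm3, relative_volume, compartment_mm3), `dice`
#'   (patient, compartment, pair, dice), `subregions` (patient, compartment,
#'   modality, per-side n/median/q25/q75, p_value), plus `hotspot_masks` (a
#'   nested list of `region_mask`s for inspection or writing).
#' @export
run_overlap_analysis <- function(maps, compartments, cutoffs = cutoff_set(),
                                 patient_id = "patient") {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  mod_order <- intersect(c("aptw", "fet", "cbv"), names(maps))
  if (length(mod_order) == 0L)
    stop("run_overlap_analysis: no recognised modality in 'maps'",
         call. = FALSE)
  comp_order <- intersect(c("cet", "fht"), names(compartments))

  hot_rows <- list(); dice_rows <- list(); sub_rows <- list()
  masks_out <- list()
  for (cn in comp_order) {
    comp <- compartments[[cn]]
    if (is.null(comp) || sum(comp$data) == 0L) next  # e.g. LGG without CET
    comp_label <- toupper(cn)
    hs <- list()
    for (m in mod_order)
      hs[[m]] <- hotspot_mask(maps[[m]], cutoffs[[m]], comp)
    masks_out[[cn]] <- hs
    vox_mm3 <- prod(comp$spacing)
    for (m in mod_order) {
      n <- sum(hs[[m]]$data)
      hot_rows[[length(hot_rows) + 1L]] <- data.frame(
        patient = patient_id, compartment = comp_label, modality = m,
        n_voxels = n, volume_mm3 = n * vox_mm3,
        relative_volume = relative_hotspot_volume(hs[[m]], comp),
        compartment_mm3 = mask_volume_mm3(comp))
    }
    pairs <- list(c("aptw", "fet"), c("aptw", "cbv"), c("fet", "cbv"))
    for (pr in pairs) {
      if (!all(pr %in% mod_order)) next
      dice_rows[[length(dice_rows) + 1L]] <- data.frame(
        patient = patient_id, compartment = comp_label,
        pair = paste(pr, collapse = "_"),
        dice = dice(hs[[pr[1]]], hs[[pr[2]]]))
    }
    if ("fet" %in% mod_order) {
      for (m in intersect(c("aptw", "cbv"), mod_order)) {
        s <- subregion_medians(maps[[m]], comp, hs[["fet"]])
        sub_rows[[length(sub_rows) + 1L]] <- data.frame(
          patient = patient_id, compartment = comp_label, modality = m,
          n_pos = s$fet_positive$n, median_pos = s$fet_positive$median,
          q25_pos = s$fet_positive$q25, q75_pos = s$fet_positive$q75,
          n_neg = s$fet_negative$n, median_neg = s$fet_negative$median,
          q25_neg = s$fet_negative$q25, q75_neg = s$fet_negative$q75,
          p_value = s$p_value)
      }
    }
  }
  list(hotspots = do.call(rbind, hot_rows),
       dice = do.call(rbind, dice_rows),
       subregions = do.call(rbind, sub_rows),
       hotspot_masks = masks_out)
}
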
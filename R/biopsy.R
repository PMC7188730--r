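#' Spherical volume of interest at a biopsy site
#'
#' The 1 cm-diameter sphere placed at a stereotactic biopsy coordinate,
#' rendered on the analysis grid: voxels whose centers lie within
#' `diameter/2 + dilation_mm` of the center. The optional dilation absorbs
#' targeting error (stereotactic accuracy is about 3 mm). The voxel set is
#' invariant under translation of the center by whole voxels.
#'
#' @param center_mm world coordinates (length 3, mm).
#' @param diameter_mm sphere diameter (default 10).
#' @param grid an `image_volume` or `region_mask` defining the grid.
#' @param dilation_mm isotropic margin added to the radius (default 0).
#' @return `region_mask` labelled `"VOI"`.
#' @export
sphere_voi <- function(center_mm, diameter_mm = 10, grid, dilation_mm = 0) {
  stopifnot(inherits(grid, c("image_volume", "region_mask")))
  r <- diameter_mm / 2 + dilation_mm
  if (r <= 0) stop("sphere_voi: radius must be > 0", call. = FALSE)
  axes <- world_axes(grid)
  if (is.null(axes)) {  # oblique grid: fall back to full center enumeration
    w <- voxel_centers(grid)
    d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
          (w[, 3] - center_mm[3])^2
    sel <- array(as.integer(d2 <= r^2), dim = grid_dim(grid))
  } else {
    qx <- (axes[[1]] - center_mm[1])^2
    qy <- (axes[[2]] - center_mm[2])^2
    qz <- (axes[[3]] - center_mm[3])^2
    sel <- array(as.integer(outer(outer(qx, qy, `+`), qz, `+`) <= r^2),
                 dim = grid_dim(grid))
  }
  if (sum(sel) == 0L)
    stop("sphere_voi: VOI contains no voxel centers (outside field of view ",
         "or smaller than the voxel grid allows)", call. = FALSE)
  region_mask(sel, spacing = grid$spacing, affine = grid$affine,
              label = "VOI")
}

#' Sample imaging maps in biopsy VOIs
#'
#' For each biopsy and each co-registered map, summarises the map over the
#' spherical VOI at the biopsy's world coordinates. The median is the default
#' summary. Non-finite voxels are dropped; a VOI with no finite voxel in a
#' map yields `NA` for that cell.
#'
#' @param samples data frame with columns `id`, `x_mm`, `y_mm`, `z_mm` (and
#'   typically `cellularity`, `vascularity`, which are carried through).
#'   Biopsy ids must be unique.
#' @param maps named list of `image_volume`s on a shared grid.
#' @param diameter_mm VOI diameter (default 10).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param dilation_mm margin for targeting error (default 0).
#' @return `samples` with one additional numeric column per map.
#' @export
sample_biopsies <- function(samples, maps, diameter_mm = 10,
                            statistic = c("median", "mean"),
                            dilation_mm = 0) {
  statistic <- match.arg(statistic)
  need <- c("id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(samples)))
    stop("sample_biopsies: samples must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$id))
    stop("sample_biopsies: duplicate biopsy ids", call. = FALSE)
  if (nrow(samples) == 0L) {
    for (m in names(maps)) samples[[m]] <- numeric(0)
    return(samples)
  }
  ref <- maps[[1]]
  for (m in maps) stop_grid_mismatch(ref, m, "sample_biopsies")
  fun <- if (statistic == "median") stats::median else mean
  out <- samples
  for (mn in names(maps)) {
    vals <- numeric(nrow(samples))
    for (b in seq_len(nrow(samples))) {
      voi <- sphere_voi(c(samples$x_mm[b], samples$y_mm[b], samples$z_mm[b]),
                        diameter_mm, maps[[mn]], dilation_mm)
      v <- maps[[mn]]$data[voi$data == 1L]
      v <- v[is.finite(v)]
      vals[b] <- if (length(v)) fun(v) else NA_real_
    }
    out[[mn]] <- vals
  }
  out
}

#' Read a biopsy table from CSV
#'
#' Expected columns: `id, x_mm, y_mm, z_mm, cellularity, vascularity` (world
#' coordinates in the maps' NIfTI space; vascularity in {0,1,2}).
#'
#' @param path CSV file.
#' @return data frame, validated.
#' @export
read_biopsy_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_mm", "y_mm", "z_mm", "cellularity", "vascularity")
  if (!all(need %in% names(tbl)))
    stop("read_biopsy_table: missing columns: ",
         paste(setdiff(need, names(tbl)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(tbl$id))
    stop("read_biopsy_table: duplicate biopsy ids", call. = FALSE)
  if (any(!tbl$vascularity %in% 0:2))
    stop("read_biopsy_table: vascularity must be 0, 1 or 2", call. = FALSE)
  if (any(tbl$cellularity < 0))
    stop("read_biopsy_table: cellularity must be >= 0", call. = FALSE)
  tbl
}

#' Correlate VOI imaging values with histology
#'
#' For each modality column: Spearman correlation (midrank ties; see
#' [spearman_cor()]) between the VOI value and cellularity, the median VOI
#' value per vascularity grade (0 = no, 1 = few, 2 = many vascular
#' proliferates), and two-sided rank-sum p-values across grade pairs.
#'
#' @param table output of [sample_biopsies()] including `cellularity` and
#'   `vascularity` columns.
#' @param modalities modality column names (default: those of
#'   `aptw`, `fet`, `cbv` present in the table).
#' @return list of data frames: `cellularity` (modality, n, rho, p_value),
#'   `vascularity` (modality, grade, n, median), `vascularity_tests`
#'   (modality, comparison, p_value).
#' @export
correlate_with_histology <- function(table,
                                     modalities = intersect(
                                       c("aptw", "fet", "cbv"),
                                       names(table))) {
  if (length(modalities) == 0L)
    stop("correlate_with_histology: no modality columns found",
         call. = FALSE)
  cell_rows <- list(); vasc_rows <- list(); test_rows <- list()
  for (m in modalities) {
    ok <- is.finite(table[[m]]) & is.finite(table$cellularity)
    x <- table[[m]][ok]; y <- table$cellularity[ok]
    if (length(x) < 3L)
      stop("correlate_with_histology: need >= 3 complete rows for ", m,
           call. = FALSE)
    sp <- spearman_cor(x, y)
    cell_rows[[m]] <- data.frame(modality = m, n = sp$n, rho = sp$rho,
                                 p_value = sp$p_value)
    okv <- is.finite(table[[m]]) & table$vascularity %in% 0:2
    for (g in 0:2) {
      v <- table[[m]][okv & table$vascularity == g]
      vasc_rows[[paste(m, g)]] <- data.frame(
        modality = m, grade = g, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_)
    }
    for (pr in list(c(0, 1), c(1, 2), c(0, 2))) {
      va <- table[[m]][okv & table$vascularity == pr[1]]
      vb <- table[[m]][okv & table$vascularity == pr[2]]
      p <- if (length(va) && length(vb))
        rank_sum_test(va, vb)$p_value else NA_real_
      test_rows[[paste(m, pr[1], pr[2])]] <- data.frame(
        modality = m, comparison = paste(pr, collapse = "_vs_"),
        p_value = p)
    }
  }
  list(cellularity = do.call(rbind, c(cell_rows, make.row.names = FALSE)),
       vascularity = do.call(rbind, c(vasc_rows, make.row.names = FALSE)),
       vascularity_tests = do.call(rbind, c(test_rows,
                                            make.row.names = FALSE)))
}
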
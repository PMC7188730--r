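test_that("hotspot extraction is strict and equals a brute-force scan", {
  dm <- c(20, 20, 20)
  within <- rand_mask(dm, 0.6, "FHT")
  flat <- image_volume(array(1.79, dim = dm), modality = "APTw")
  expect_identical(sum(hotspot_mask(flat, 1.79, within)$data), 0L)
  above <- image_volume(array(2.79, dim = dm), modality = "APTw")
  expect_identical(hotspot_mask(above, 1.79, within)$data, within$data)

  set.seed(31)
  for (rep in 1:10) {
    map <- rand_map(dm, 0, 4, "APTw")
    w <- rand_mask(dm, 0.5)
    hs <- hotspot_mask(map, 1.79, w)
    want <- which(w$data == 1L & map$data > 1.79)
    expect_identical(which(hs$data == 1L), want)
  }
})

test_that("non-finite voxels never enter a hotspot and are QC-counted", {
  dm <- c(6, 6, 6)
  arr <- array(3, dim = dm); arr[1:5] <- NaN; arr[6] <- NA
  map <- image_volume(arr, modality = "APTw")
  w <- region_mask(array(1L, dim = dm))
  hs <- hotspot_mask(map, 1.79, w)
  expect_identical(sum(hs$data), 210L)
  expect_identical(attr(hs, "qc_dropped"), 6L)
})

test_that("threshold monotonicity: higher cutoff gives nested hotspots", {
  set.seed(41)
  dm <- c(16, 16, 16)
  w <- rand_mask(dm, 0.7)
  for (rep in 1:10) {
    map <- rand_map(dm, 0, 5)
    cuts <- sort(runif(2, 0.5, 4.5))
    lo <- hotspot_mask(map, cuts[1], w)
    hi <- hotspot_mask(map, cuts[2], w)
    expect_identical(sum(hi$data == 1L & lo$data == 0L), 0L)
    expect_lte(relative_hotspot_volume(hi, w),
               relative_hotspot_volume(lo, w))
  }
})

test_that("relative hotspot volume: ratio, bounds and missing cases", {
  dm <- c(10, 10, 10)
  comp_arr <- array(0L, dim = dm); comp_arr[1:100] <- 1L
  comp <- region_mask(comp_arr, label = "CET")
  hs_arr <- array(0L, dim = dm); hs_arr[1:25] <- 1L
  expect_equal(relative_hotspot_volume(region_mask(hs_arr), comp), 0.25)
  expect_equal(relative_hotspot_volume(comp, comp), 1)
  expect_equal(relative_hotspot_volume(region_mask(array(0L, dim = dm)),
                                       comp), 0)
  # empty compartment: undefined, NA not 0
  empty <- region_mask(array(0L, dim = dm))
  expect_identical(relative_hotspot_volume(empty, empty), NA_real_)
  # hotspot outside compartment violates the precondition
  out_arr <- array(0L, dim = dm); out_arr[150] <- 1L
  expect_error(relative_hotspot_volume(region_mask(out_arr), comp),
               "outside")
})

test_that("Dice: forced formula values, symmetry, bounds, missing case", {
  dm <- c(8, 8, 8)
  a <- array(0L, dim = dm); a[c(1, 2)] <- 1L
  b <- array(0L, dim = dm); b[c(2, 3)] <- 1L
  x <- region_mask(a); y <- region_mask(b)
  expect_equal(dice(x, y), 0.5)            # 2*1 / (2+2)
  expect_equal(dice(x, y), dice(y, x))
  expect_equal(dice(x, x), 1)
  disj <- array(0L, dim = dm); disj[5:6] <- 1L
  expect_equal(dice(x, region_mask(disj)), 0)
  none <- region_mask(array(0L, dim = dm))
  expect_identical(dice(none, none), NA_real_)
  expect_error(dice(x, rand_mask(c(4, 4, 4))), "grid")

  set.seed(51)
  for (rep in 1:20) {
    m1 <- rand_mask(dm, runif(1, 0.1, 0.7))
    m2 <- rand_mask(dm, runif(1, 0.1, 0.7))
    d <- dice(m1, m2)
    expect_identical(d, brute_dice(m1$data, m2$data))
    if (is.finite(d)) { expect_gte(d, 0); expect_lte(d, 1) }
  }
})

test_that("subregion medians partition the compartment and match by hand", {
  dm <- c(6, 6, 6)
  # FET-positive voxels {3,4,5}, FET-negative {1,2,3}
  map_arr <- array(0, dim = dm)
  map_arr[1:3] <- c(3, 4, 5); map_arr[4:6] <- c(1, 2, 3)
  comp_arr <- array(0L, dim = dm); comp_arr[1:6] <- 1L
  hot_arr <- array(0L, dim = dm); hot_arr[1:3] <- 1L
  s <- subregion_medians(image_volume(map_arr, modality = "APTw"),
                         region_mask(comp_arr, label = "FHT"),
                         region_mask(hot_arr, label = "hotspot"))
  expect_equal(s$fet_positive$median, 4)
  expect_equal(s$fet_negative$median, 2)
  expect_identical(s$fet_positive$n + s$fet_negative$n, 6L)

  # constant map: both medians equal the constant, IQR zero
  const <- image_volume(array(2.2, dim = dm), modality = "CBV")
  sc <- subregion_medians(const, region_mask(comp_arr),
                          region_mask(hot_arr))
  expect_equal(sc$fet_positive$median, 2.2)
  expect_equal(sc$fet_negative$median, 2.2)
  expect_equal(sc$fet_positive$q75 - sc$fet_positive$q25, 0)

  # empty FET-positive side: stats and p reported missing
  s0 <- subregion_medians(const, region_mask(comp_arr),
                          region_mask(array(0L, dim = dm)))
  expect_identical(s0$fet_positive$median, NA_real_)
  expect_identical(s0$p_value, NA_real_)

  # hotspot outside the compartment violates the precondition
  bad <- array(0L, dim = dm); bad[10] <- 1L
  expect_error(subregion_medians(const, region_mask(comp_arr),
                                 region_mask(bad)), "outside")
})

test_that("phantom-constructed APTw enrichment shows in FET-positive areas", {
  ph <- default_noiseless_phantom()
  hs_fet <- hotspot_mask(ph$noiseless$fet, 1.6, ph$masks$fht)
  s <- subregion_medians(ph$noiseless$aptw, ph$masks$fht, hs_fet)
  expect_gt(s$fet_positive$median, s$fet_negative$median)
})

test_that("full overlap analysis reproduces phantom truth and is order-stable", {
  ph <- default_noiseless_phantom()
  res <- run_overlap_analysis(ph$noiseless, ph$masks[c("cet", "fht")],
                              patient_id = "ph1")
  tr <- ph$truth
  for (cn in c("cet", "fht")) {
    for (m in c("aptw", "fet", "cbv")) {
      row <- res$hotspots[res$hotspots$compartment == toupper(cn) &
                          res$hotspots$modality == m, ]
      expect_identical(row$n_voxels, tr$hotspots[[cn]][[m]]$n_voxels)
      expect_equal(row$volume_mm3, tr$hotspots[[cn]][[m]]$volume_mm3)
      expect_equal(row$relative_volume,
                   tr$hotspots[[cn]][[m]]$relative_volume)
    }
    for (pr in names(tr$dice[[cn]])) {
      row <- res$dice[res$dice$compartment == toupper(cn) &
                      res$dice$pair == pr, ]
      expect_equal(row$dice, tr$dice[[cn]][[pr]])
    }
  }
  # partition conservation in every subregion row
  comp_n <- c(CET = tr$compartments$cet$n_voxels,
              FHT = tr$compartments$fht$n_voxels)
  expect_true(all(res$subregions$n_pos + res$subregions$n_neg ==
                  comp_n[res$subregions$compartment]))
  # permuting the modality list leaves the report identical
  res2 <- run_overlap_analysis(ph$noiseless[c("cbv", "aptw", "fet")],
                               ph$masks[c("cet", "fht")],
                               patient_id = "ph1")
  expect_identical(res2$hotspots, res$hotspots)
  expect_identical(res2$dice, res$dice)
  expect_identical(res2$subregions, res$subregions)
})

test_that("an empty CET compartment is skipped, FHT still analyzed", {
  ph <- default_noiseless_phantom()
  empty_cet <- region_mask(array(0L, dim = dim(ph$masks$cet$data)),
                           spacing = ph$masks$cet$spacing,
                           affine = ph$masks$cet$affine, label = "CET")
  res <- run_overlap_analysis(ph$noiseless,
                              list(cet = empty_cet, fht = ph$masks$fht),
                              patient_id = "lgg1")
  expect_false("CET" %in% res$hotspots$compartment)
  expect_true(all(res$hotspots$compartment == "FHT"))
  expect_identical(nrow(res$hotspots), 3L)
})
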
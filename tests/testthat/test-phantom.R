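test_that("identical spec and seed give bit-identical phantoms and biopsies", {
  sp <- small_spec(noise_sd = c(aptw = 0.2, fet = 0.08, cbv = 0.3))
  a <- generate_phantom(sp, seed = 17)
  b <- generate_phantom(sp, seed = 17)
  expect_identical(a$maps$aptw$data, b$maps$aptw$data)
  expect_identical(a$maps$fet$data, b$maps$fet$data)
  expect_identical(a$maps$cbv$data, b$maps$cbv$data)
  expect_identical(a$truth, b$truth)
  bxa <- generate_biopsies(a, 12, seed = 5)
  bxb <- generate_biopsies(b, 12, seed = 5)
  expect_identical(bxa$samples, bxb$samples)
  c_ <- generate_phantom(sp, seed = 18)
  expect_false(identical(a$maps$aptw$data, c_$maps$aptw$data))
})

test_that("CET and FHT are always disjoint and FHT excludes the core", {
  set.seed(61)
  for (rep in 1:5) {
    sp <- small_spec()
    sp$cet$semiaxes <- sp$cet$semiaxes * runif(1, 0.6, 1.1)
    ph <- generate_phantom(sp)
    expect_identical(sum(ph$masks$cet$data == 1L & ph$masks$fht$data == 1L),
                     0L)
    expect_gt(sum(ph$masks$cet$data), 0L)
    expect_gt(sum(ph$masks$fht$data), 0L)
  }
})

test_that("geometry violations are rejected", {
  expect_error(phantom_spec(cet = list(center = c(0, 0, 0),
                                       semiaxes = c(40, 17, 14))),
               "inside")
  expect_error(phantom_spec(cet = list(center = c(25, 0, 0),
                                       semiaxes = c(20, 17, 14))),
               "inside")
  expect_error(phantom_spec(noise_sd = c(aptw = -0.1, fet = 0, cbv = 0)),
               "noise_sd")
  expect_error(small_spec(background_roi = list(center = c(0, 0, 0),
                                                radius = 4)),
               "ROI")
  sp <- small_spec()
  sp$cet$semiaxes <- c(0.8, 0.8, 0.8)  # no voxel center falls inside
  expect_error(generate_phantom(sp), "degenerate")
})

test_that("noiseless thresholding recovers the hotspot ellipsoid exactly", {
  # flat baseline 1.0 everywhere, +3.0 inside the sub-ellipsoid
  sp <- small_spec(baseline = list(aptw = c(background = 1, cet = 1, fht = 1),
                                   fet = c(background = 1, cet = 1.4,
                                           fht = 1.2),
                                   cbv = c(background = 2.5, cet = 4.5,
                                           fht = 2.2)))
  sp$hotspots$aptw$delta <- 3.0
  ph <- generate_phantom(sp)
  whole <- region_mask(array(1L, dim = dim(ph$noiseless$aptw$data)),
                       spacing = ph$noiseless$aptw$spacing,
                       affine = ph$noiseless$aptw$affine)
  hs <- hotspot_mask(ph$noiseless$aptw, 1.79, whole)
  # oracle: voxel-center-in-ellipsoid enumeration
  want <- brute_ellipsoid_count(dim(whole$data), sp$voxel_size_mm,
                                sp$hotspots$aptw$center,
                                sp$hotspots$aptw$semiaxes)
  expect_identical(sum(hs$data), want)
})

test_that("phantom truth equals brute-force enumeration on the noiseless fields", {
  sp <- small_spec()
  ph <- generate_phantom(sp)
  # oracle: independent per-voxel loop over the whole grid
  dm <- dim(ph$noiseless$aptw$data)
  vs <- sp$voxel_size_mm
  cuts <- c(aptw = 1.79, fet = 1.6, cbv = 5.6)
  n_comp <- c(cet = 0L, fht = 0L)
  n_hot <- matrix(0L, 2, 3, dimnames = list(c("cet", "fht"),
                                            c("aptw", "fet", "cbv")))
  n_int <- array(0L, dim = c(2, 3, 3))
  inside <- function(x, y, z, e)
    ((x - e$center[1]) / e$semiaxes[1])^2 +
    ((y - e$center[2]) / e$semiaxes[2])^2 +
    ((z - e$center[3]) / e$semiaxes[3])^2 <= 1
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      x <- (i - 1) * vs - (dm[1] - 1) * vs / 2
      y <- (j - 1) * vs - (dm[2] - 1) * vs / 2
      z <- (k - 1) * vs - (dm[3] - 1) * vs / 2
      in_cet <- inside(x, y, z, sp$cet)
      in_fht <- inside(x, y, z, sp$fht) && !in_cet
      cn <- if (in_cet) "cet" else if (in_fht) "fht" else next
      n_comp[cn] <- n_comp[cn] + 1L
      hot <- logical(3)
      for (m in seq_along(cuts)) {
        mn <- names(cuts)[m]
        v <- sp$baseline[[mn]][[if (in_cet) "cet" else "fht"]]
        if (inside(x, y, z, sp$hotspots[[mn]]))
          v <- v + sp$hotspots[[mn]]$delta
        hot[m] <- v > cuts[[mn]]
        if (hot[m]) n_hot[cn, mn] <- n_hot[cn, mn] + 1L
      }
      ci <- if (cn == "cet") 1L else 2L
      for (m1 in 1:2) for (m2 in (m1 + 1):3)
        if (hot[m1] && hot[m2])
          n_int[ci, m1, m2] <- n_int[ci, m1, m2] + 1L
    }
  tr <- ph$truth
  for (ci in 1:2) {
    cn <- c("cet", "fht")[ci]
    expect_identical(tr$compartments[[cn]]$n_voxels, n_comp[[cn]])
    for (mn in colnames(n_hot)) {
      expect_identical(tr$hotspots[[cn]][[mn]]$n_voxels, n_hot[cn, mn])
      expect_equal(tr$hotspots[[cn]][[mn]]$relative_volume,
                   n_hot[cn, mn] / n_comp[[cn]])
    }
    pair_idx <- list(aptw_fet = c(1, 2), aptw_cbv = c(1, 3),
                     fet_cbv = c(2, 3))
    for (pn in names(pair_idx)) {
      m1 <- pair_idx[[pn]][1]; m2 <- pair_idx[[pn]][2]
      expect_equal(tr$dice[[cn]][[pn]],
                   2 * n_int[ci, m1, m2] /
                     (n_hot[cn, m1] + n_hot[cn, m2]))
    }
  }
})

test_that("identical hotspot geometry gives truth Dice of exactly 1", {
  sp <- small_spec()
  sp$hotspots$fet$semiaxes <- sp$hotspots$aptw$semiaxes
  sp$hotspots$fet$center <- sp$hotspots$aptw$center
  ph <- generate_phantom(sp)
  expect_identical(ph$truth$dice$cet$aptw_fet, 1)
  expect_identical(ph$truth$dice$fht$aptw_fet, 1)
})

test_that("offset spherical hotspots match exhaustive sphere enumeration", {
  # two spheres radius 6 mm, centers 4 mm apart, 2 mm grid; flat baselines
  # below every cutoff so only the spheres are hot
  sp <- small_spec(baseline = list(aptw = c(background = 1, cet = 1, fht = 1),
                                   fet = c(background = 1, cet = 1, fht = 1),
                                   cbv = c(background = 2.5, cet = 2.5,
                                           fht = 2.5)))
  sp$hotspots$aptw <- list(center = c(0, 0, 0), semiaxes = c(6, 6, 6),
                           delta = 1.2)
  sp$hotspots$fet <- list(center = c(4, 0, 0), semiaxes = c(6, 6, 6),
                          delta = 1.0)
  ph <- generate_phantom(sp)
  # oracle: explicit voxel-center-in-sphere count over the CET+FHT region
  dm <- dim(ph$noiseless$aptw$data); vs <- sp$voxel_size_mm
  na <- 0L; nb <- 0L; nab <- 0L
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2]))
    for (k in seq_len(dm[3])) {
      x <- (i - 1) * vs - (dm[1] - 1) * vs / 2
      y <- (j - 1) * vs - (dm[2] - 1) * vs / 2
      z <- (k - 1) * vs - (dm[3] - 1) * vs / 2
      qf <- (x / sp$fht$semiaxes[1])^2 + (y / sp$fht$semiaxes[2])^2 +
            (z / sp$fht$semiaxes[3])^2
      if (qf > 1) next  # spheres lie well inside FHT
      ina <- x^2 + y^2 + z^2 <= 36
      inb <- (x - 4)^2 + y^2 + z^2 <= 36
      if (ina) na <- na + 1L
      if (inb) nb <- nb + 1L
      if (ina && inb) nab <- nab + 1L
    }
  want <- 2 * nab / (na + nb)
  # the spheres may straddle the CET/FHT boundary; pool both compartments
  pooled <- run_overlap_analysis(ph$noiseless, list(
    cet = region_mask(array(as.integer(ph$masks$cet$data |
                                         ph$masks$fht$data),
                            dim = dm),
                      spacing = ph$masks$cet$spacing,
                      affine = ph$masks$cet$affine, label = "CET")),
    patient_id = "sph")
  got <- pooled$dice$dice[pooled$dice$pair == "aptw_fet"]
  expect_equal(got, want)
})

test_that("biopsy generator: degenerate and strictly monotone regimes", {
  ph <- default_noiseless_phantom()
  # zero effect, zero noise: every cellularity equals the global baseline
  es0 <- biopsy_effect_spec(cell_slope = 0, cell_size = Inf)
  bx0 <- generate_biopsies(ph, 25, es0, seed = 2)
  expect_true(all(bx0$samples$cellularity == es0$cell_base))
  # positive slope, zero noise: Spearman rho with local APTw is exactly 1
  es1 <- biopsy_effect_spec(cell_slope = 0.5, cell_size = Inf)
  bx1 <- generate_biopsies(ph, 40, es1, seed = 3)
  sp <- spearman_cor(bx1$truth$aptw, bx1$samples$cellularity)
  expect_equal(sp$rho, 1)
  # vascularity stays ordinal
  expect_true(all(bx1$samples$vascularity %in% 0:2))
  # biopsy centers always fall inside the tumor
  tumor <- ph$masks$cet$data == 1L | ph$masks$fht$data == 1L
  u <- voxel_from_world(ph$noiseless$aptw$affine,
                        as.matrix(bx1$samples[, c("x_mm", "y_mm", "z_mm")]))
  nearest <- round(u) + 1
  expect_true(all(tumor[cbind(nearest[, 1], nearest[, 2], nearest[, 3])]))
})

test_that("generator VOI medians agree with the analysis sampling path", {
  ph <- default_noiseless_phantom()
  vt <- phantom_voi_table(ph)
  bx <- generate_biopsies(ph, 20, seed = 4, jitter = FALSE, voi_table = vt)
  tab <- sample_biopsies(bx$samples, ph$noiseless)
  expect_equal(tab$aptw, bx$truth$aptw)
  expect_equal(tab$fet, bx$truth$fet)
  expect_equal(tab$cbv, bx$truth$cbv)
  # jittered centers: same agreement through the brute-force generator path
  bxj <- generate_biopsies(ph, 10, seed = 6, jitter = TRUE)
  tabj <- sample_biopsies(bxj$samples, ph$noiseless)
  expect_equal(tabj$aptw, bxj$truth$aptw)
})

test_that("phantom files round-trip through the NIfTI/JSON writers", {
  ph <- generate_phantom(small_spec())
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- load_volume(file.path(dir, "aptw.nii.gz"), "APTw")
  expect_equal(back$data, ph$maps$aptw$data, tolerance = 1e-6)
  cet <- load_mask(file.path(dir, "mask_cet.nii.gz"), "CET")
  expect_identical(cet$data, ph$masks$cet$data)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$compartments$cet$n_voxels,
               ph$truth$compartments$cet$n_voxels)
})
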
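# Brute-force oracles and small fixtures shared across tests. Everything
# here is deliberately written from first principles (plain loops over
# voxels / explicit set arithmetic) so it stays independent of the package's
# implementation paths.

# Dice by explicit set arithmetic on index sets.
brute_dice <- function(a, b) {
  ia <- which(a == 1L); ib <- which(b == 1L)
  if (length(ia) + length(ib) == 0L) return(NA_real_)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Random binary mask on a shared unit grid.
rand_mask <- function(dm, p = 0.3, label = "m") {
  region_mask(array(as.integer(stats::runif(prod(dm)) < p), dim = dm),
              spacing = c(1, 1, 1), label = label)
}

# Random map on the same unit grid.
rand_map <- function(dm, lo = 0, hi = 4, modality = "other") {
  image_volume(array(stats::runif(prod(dm), lo, hi), dim = dm),
               spacing = c(1, 1, 1), modality = modality)
}

# Voxel-center-in-ellipsoid membership by explicit per-voxel looping over an
# axis-aligned grid centered on the origin (the phantom's grid convention).
brute_ellipsoid_count <- function(grid_dim, voxel, center, semiaxes) {
  n <- 0L
  for (i in seq_len(grid_dim[1])) for (j in seq_len(grid_dim[2]))
    for (k in seq_len(grid_dim[3])) {
      x <- (i - 1) * voxel - (grid_dim[1] - 1) * voxel / 2
      y <- (j - 1) * voxel - (grid_dim[2] - 1) * voxel / 2
      z <- (k - 1) * voxel - (grid_dim[3] - 1) * voxel / 2
      q <- ((x - center[1]) / semiaxes[1])^2 +
           ((y - center[2]) / semiaxes[2])^2 +
           ((z - center[3]) / semiaxes[3])^2
      if (q <= 1) n <- n + 1L
    }
  n
}

# A compact phantom used where full 64^3 resolution is not the point.
# Named arguments override the compact defaults.
small_spec <- function(...) {
  args <- list(
    grid_dim = c(32L, 32L, 32L), voxel_size_mm = 2,
    cet = list(center = c(0, 0, 0), semiaxes = c(10, 9, 8)),
    fht = list(center = c(0, 0, 0), semiaxes = c(20, 17, 15)),
    hotspots = list(
      aptw = list(center = c(4, 0, 0), semiaxes = c(14, 12, 10), delta = 1.2),
      fet  = list(center = c(4, 0, 0), semiaxes = c(11, 9, 8),  delta = 1.0),
      cbv  = list(center = c(4, 0, 0), semiaxes = c(8, 7, 6),   delta = 4.5)),
    noise_sd = c(aptw = 0, fet = 0, cbv = 0),
    background_roi = list(center = c(-26, -14, 0), radius = 4))
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

# Noiseless default-geometry phantom at full resolution, built once.
default_noiseless_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(
        phantom_spec(noise_sd = c(aptw = 0, fet = 0, cbv = 0)))
    cache
  }
})
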
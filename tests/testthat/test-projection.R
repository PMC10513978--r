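# independent brute-force reprojection used as the oracle: literal loops,
# explicit path sums, no shared code with the package implementation
brute_force_project <- function(counts, mu, dy, view) {
  d <- dim(counts)
  out <- matrix(0, d[1], d[3])
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) {
    acc <- 0
    for (j in seq_len(d[2])) {
      ray <- mu[i, , k]
      path <- if (view == "anterior") {
        (if (j < d[2]) sum(ray[(j + 1):d[2]]) else 0) + ray[j] / 2
      } else {
        (if (j > 1) sum(ray[1:(j - 1)]) else 0) + ray[j] / 2
      }
      acc <- acc + counts[i, j, k] * exp(-dy * path)
    }
    out[i, k] <- acc
  }
  out
}

mu_map_of <- function(mu, grid) {
  structure(list(mu = mu, grid = grid, mu_water = 0.0151, bone_slope = 0.5),
            class = "mu_map")
}

test_that("projection without attenuation conserves total counts", {
  g <- voxel_grid(c(12, 10, 14), 3.3)
  set.seed(2)
  act <- array(stats::runif(prod(g$shape)), dim = g$shape)
  sv <- noiseless_spect(act, g, fwhm_mm = 0, total = 1e6)
  for (view in c("anterior", "posterior")) {
    p <- project_planar(sv, NULL, view)
    expect_equal(sum(p$pixels), 1e6, tolerance = 1e-10)
  }
})

test_that("zero attenuation gives unit path factors everywhere", {
  g <- voxel_grid(c(6, 8, 6), 3.3)
  mm <- mu_map_of(array(0, dim = g$shape), g)
  for (view in c("anterior", "posterior"))
    expect_equal(path_attenuation(mm, c(3, 4, 2), view), 1)
})

test_that("uniform-slab attenuation matches the closed form", {
  # 4 mm voxels, uniform mu = 0.01/mm; emitter at j = 8 of 20 has 12 full
  # voxels plus half its own between its center and the anterior boundary:
  # 12.5 * 4 = 50 mm of material -> factor exp(-0.5)
  g <- voxel_grid(c(4, 20, 4), 4)
  mu <- array(0.01, dim = g$shape)
  mm <- mu_map_of(mu, g)
  f <- path_attenuation(mm, c(2, 8, 2), "anterior")
  expect_equal(f, exp(-0.5), tolerance = 1e-12)
  # anterior x posterior factors multiply to exp(-mu * D) for any depth
  D <- 20 * 4 * 0.01
  for (j in c(1, 7, 13, 20)) {
    fa <- path_attenuation(mm, c(2, j, 2), "anterior")
    fp <- path_attenuation(mm, c(2, j, 2), "posterior")
    expect_equal(fa * fp, exp(-D), tolerance = 1e-12)
  }
})

test_that("a point source projects to A*exp(-mu*d) and a depth-free geomean", {
  g <- voxel_grid(c(8, 20, 8), 3.3)
  mu0 <- 0.008
  mm <- mu_map_of(array(mu0, dim = g$shape), g)
  A <- 1e5
  combined <- vapply(c(2, 8, 14, 19), function(j) {
    act <- array(0, dim = g$shape)
    act[4, j, 4] <- 1
    sv <- noiseless_spect(act, g, fwhm_mm = 0, total = A)
    pa <- project_planar(sv, mm, "anterior")$pixels[4, 4]
    pp <- project_planar(sv, mm, "posterior")$pixels[4, 4]
    # anterior pixel = A * exp(-mu * d), d = distance to anterior boundary
    d_ant <- (20 - j + 0.5) * 3.3
    expect_equal(pa, A * exp(-mu0 * d_ant), tolerance = 1e-10)
    combine_views(pa, pp, "geometric_mean")
  }, numeric(1))
  # the geometric mean is independent of source depth: A * exp(-mu*D/2)
  expect_equal(max(combined) - min(combined), 0, tolerance = 1e-9 * A)
  expect_equal(combined[1], A * exp(-mu0 * 20 * 3.3 / 2), tolerance = 1e-9 * A)
})

test_that("vectorized projection matches the brute-force oracle", {
  set.seed(5)
  g <- voxel_grid(c(8, 8, 8), 2.7)
  for (rep in 1:5) {
    counts <- array(stats::runif(512), dim = g$shape)
    mu <- array(stats::runif(512, 0, 0.03), dim = g$shape)
    sv <- structure(list(grid = g, counts = counts,
                         meta = list(tracer = "V")), class = "spect_volume")
    mm <- mu_map_of(mu, g)
    for (view in c("anterior", "posterior")) {
      got <- project_planar(sv, mm, view)$pixels
      ref <- brute_force_project(counts, mu, 2.7, view)
      expect_lt(max(abs(got - ref)) / max(ref), 1e-10)
    }
  }
})

test_that("scaling mu up strictly dims every nonzero pixel", {
  g <- voxel_grid(c(8, 8, 8), 3.3)
  set.seed(9)
  counts <- array(stats::runif(512), dim = g$shape)
  sv <- structure(list(grid = g, counts = counts,
                       meta = list(tracer = "V")), class = "spect_volume")
  mu <- array(0.01, dim = g$shape)
  p1 <- project_planar(sv, mu_map_of(mu, g), "anterior")$pixels
  p2 <- project_planar(sv, mu_map_of(2 * mu, g), "anterior")$pixels
  expect_true(all(p2 < p1))
})

test_that("mirroring the volume along y swaps the two views exactly", {
  g <- voxel_grid(c(8, 8, 8), 3.3)
  set.seed(11)
  counts <- array(stats::runif(512), dim = g$shape)
  mu <- array(stats::runif(512, 0, 0.02), dim = g$shape)
  flip <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
  sv <- structure(list(grid = g, counts = counts,
                       meta = list(tracer = "V")), class = "spect_volume")
  svf <- structure(list(grid = g, counts = flip(counts),
                        meta = list(tracer = "V")), class = "spect_volume")
  ant <- project_planar(sv, mu_map_of(mu, g), "anterior")$pixels
  posf <- project_planar(svf, mu_map_of(flip(mu), g), "posterior")$pixels
  expect_equal(ant, posf, tolerance = 1e-12)
})

test_that("mask projection is the union over rays and over lungs", {
  expect_false(any(project_mask(array(0L, c(4, 4, 4)))))
  ph <- small_phantom()
  r <- project_mask(ph$labels, "right")
  l <- project_mask(ph$labels, "left")
  b <- project_mask(ph$labels, "both")
  expect_identical(b, r | l)
  # union over y: at least as large as any single coronal slice cross-section
  slice_area <- max(vapply(seq_len(dim(ph$labels)[2]),
                           function(j) sum(ph$labels[, j, ] > 0L), numeric(1)))
  expect_gte(sum(b), slice_area)
})
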
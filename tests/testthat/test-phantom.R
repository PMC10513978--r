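test_that("voxel cells are half-open and centered on the world origin", {
  g <- voxel_grid(c(10, 11, 12), c(2, 3, 4))
  expect_equal(mean(grid_axis_coords(g, 1)), 0)
  expect_equal(diff(grid_axis_coords(g, 3))[1], 4)
  # a voxel center maps to its own voxel; the upper cell edge to the next
  xc <- grid_axis_coords(g, 1)
  expect_equal(world_to_index(g, c(xc[4], 0, 0))[1], 4L)
  expect_equal(world_to_index(g, c(xc[4] + 1, 0, 0))[1], 5L)   # +h/2 edge
  expect_equal(world_to_index(g, c(xc[4] + 0.999, 0, 0))[1], 4L)
  expect_true(is.na(world_to_index(g, c(1e4, 0, 0))[1]))
})

test_that("uniform specific activity gives fractions equal to volume shares", {
  ph <- small_phantom()
  cnt <- lobe_voxel_counts(ph)
  tr <- true_lobar_fractions(ph, "V")
  expect_equal(unname(tr$lobes), unname(100 * cnt / sum(cnt)), tolerance = 1e-12)
  expect_equal(sum(tr$lobes), 100, tolerance = 1e-9)
  expect_equal(tr$right, sum(tr$lobes[1:3]))
})

test_that("single-lobe activity yields a 0/100 truth pattern", {
  ph <- small_phantom(activity_v = c(RUL = 0, RML = 7, RLL = 0, LUL = 0, LLL = 0))
  tr <- true_lobar_fractions(ph, "V")
  expect_equal(unname(tr$lobes), c(0, 100, 0, 0, 0))
})

test_that("per-lobe activities map to the expected percentages", {
  # activities inversely proportional to lobe volume give per-lobe totals
  # (2000, 1000, 2500, 2500, 2000) -> (20, 10, 25, 25, 20)%
  ph0 <- small_phantom()
  cnt <- lobe_voxel_counts(ph0)
  target <- c(2000, 1000, 2500, 2500, 2000)
  ph <- small_phantom(activity_v = target / cnt)
  tr <- true_lobar_fractions(ph, "V")
  expect_equal(unname(tr$lobes), c(20, 10, 25, 25, 20), tolerance = 1e-9)
  expect_error(true_lobar_fractions(
    small_phantom(activity_q = rep(0, 5)), "Q"), "zero")
})

test_that("truth fractions are stable across rasterization resolution", {
  spec <- phantom_spec()
  # tight field of view holding the whole thorax anatomy that matters
  share <- function(grid) {
    lab <- rasterize_labels(spec, grid)
    cnt <- tabulate(lab[lab > 0L], 5)
    100 * cnt / sum(cnt)
  }
  coarse <- share(voxel_grid(c(128, 128, 128), 3.3))
  fine <- share(voxel_grid(c(240, 160, 240), 1.1))
  expect_lt(max(abs(coarse - fine)), 1.5)
})

test_that("rasterization is deterministic and conserves lung voxels", {
  ph1 <- small_phantom(seed = 42)
  ph2 <- small_phantom(seed = 42)
  expect_identical(ph1$labels, ph2$labels)
  expect_identical(ph1$activity$V, ph2$activity$V)
  expect_equal(sum(lobe_voxel_counts(ph1)), sum(ph1$labels > 0L))
})

test_that("lobectomy removes the lobe and renormalizes the truth", {
  ph <- small_phantom()
  before <- sum(ph$activity$V)
  rml_act <- sum(ph$activity$V[ph$labels == 2L])
  ph2 <- apply_lobectomy(ph, "RML")
  expect_equal(sum(ph2$labels == 2L), 0)
  expect_equal(sum(ph2$activity$V), before - rml_act)   # conservation
  tr <- true_lobar_fractions(ph2, "V")
  expect_equal(unname(tr$lobes[2]), 0)
  expect_equal(sum(tr$lobes), 100, tolerance = 1e-9)
  # left-sided removal: the left lung truth collapses onto the LLL
  ph3 <- apply_lobectomy(small_phantom(), "LUL")
  tr3 <- true_lobar_fractions(ph3, "V")
  expect_equal(tr3$left, unname(tr3$lobes["LLL"]))
  expect_error(apply_lobectomy(ph2, "RML"), "already absent")
})

test_that("emphysema rescales activity with the closed-form truth shift", {
  ph0 <- small_phantom()
  cnt <- lobe_voxel_counts(ph0)
  # equal-activity-share phantom: each lobe carries 20% of the total
  ph <- small_phantom(activity_v = 1 / cnt, activity_q = 1 / cnt)
  expect_equal(unname(true_lobar_fractions(ph, "V")$lobes),
               rep(20, 5), tolerance = 1e-9)
  same <- apply_emphysema(ph, "RUL", activity_factor = 1)
  expect_equal(true_lobar_fractions(same, "V")$lobes,
               true_lobar_fractions(ph, "V")$lobes, tolerance = 1e-12)
  half <- apply_emphysema(ph, "RUL", activity_factor = 0.5)
  trh <- true_lobar_fractions(half, "V")
  expect_equal(unname(trh$lobes["RUL"]), 0.5 * 20 / (0.5 * 20 + 80) * 100,
               tolerance = 1e-9)
  expect_equal(unname(trh$lobes["RUL"]), 100 / 9, tolerance = 1e-9)
  zero <- apply_emphysema(ph, c("LUL", "LLL"), activity_factor = 0)
  expect_equal(true_lobar_fractions(zero, "V")$left, 0)
  expect_equal(unique(zero$hu[zero$labels %in% 4:5]),
               ph$spec$hu_values[["emphysema"]])
  expect_warning(apply_emphysema(ph, character(0)), "no-op")
})

test_that("hotspots multiply activity inside the sphere only", {
  ph <- small_phantom()
  ident <- insert_hotspot(ph, ph$spec$right_lung$center_mm, 20, 1)
  expect_equal(ident$activity$V, ph$activity$V)
  before <- sum(ph$activity$V)
  ctr <- ph$spec$right_lung$center_mm + c(0, 0, 80)   # in the RUL
  hot <- insert_hotspot(ph, ctr, 20, 10)
  tr0 <- true_lobar_fractions(ph, "V")
  tr1 <- true_lobar_fractions(hot, "V")
  expect_gt(tr1$lobes["RUL"], tr0$lobes["RUL"])
  # conservation: total = before + (m-1) * activity inside the sphere
  inside <- sum(ph$activity$V) - sum(ph$activity$V[hot$activity$V == ph$activity$V])
  expect_equal(sum(hot$activity$V), before + (10 - 1) * inside,
               tolerance = 1e-9)
  expect_warning(insert_hotspot(ph, c(0, 0, 300), 5, 2), "no-op")
})

test_that("HU volume encodes air, soft tissue, and parenchyma", {
  ph <- small_phantom()
  hu <- ph$spec$hu_values
  expect_equal(unique(ph$hu[ph$labels > 0L]), hu[["parenchyma"]])
  expect_equal(min(ph$hu), hu[["air"]])
  expect_setequal(unique(as.vector(ph$hu)),
                  unname(hu[c("air", "soft_tissue", "parenchyma")]))
  # activity is zero outside the lungs
  expect_equal(sum(ph$activity$V[ph$labels == 0L]), 0)
})

test_that("anatomical ordering holds across the random spec population", {
  g <- small_grid()
  for (s in 1:100) {
    lab <- rasterize_labels(random_phantom_spec(s), g)
    cnt <- tabulate(lab[lab > 0L], 5)
    expect_true(all(cnt > 0), label = sprintf("all lobes non-empty (seed %d)", s))
    ctr <- function(code, axis) {
      ij <- which(lab == code, arr.ind = TRUE)
      mean(ij[, axis])
    }
    xc <- grid_axis_coords(g, 1)
    expect_lt(max(xc[which(apply(lab, 1, function(s2) any(s2 %in% 1:3)))]), 0)
    expect_gt(min(xc[which(apply(lab, 1, function(s2) any(s2 %in% 4:5)))]), 0)
    expect_gt(ctr(2, 2), ctr(3, 2))              # RML anterior to RLL
    expect_gt(ctr(1, 3), max(ctr(2, 3), ctr(3, 3)))  # RUL superior to both
  }
})

test_that("degenerate geometry is rejected with a named error", {
  sp <- phantom_spec(right_lung = list(center_mm = c(-160, 2, 0),
                                       half_axes_mm = c(55, 75, 125)))
  expect_error(build_phantom(sp, small_grid()), "thorax")
  # horizontal fissure below the oblique everywhere: no RML anywhere
  sp2 <- phantom_spec(fissures = fissure_params(h_right_oblique = 0.45,
                                                theta_right_oblique_deg = 0,
                                                h_right_horizontal = 0.1))
  expect_error(build_phantom(sp2, small_grid()), "RML")
})

test_that("phantom spec JSON and NIfTI round-trips preserve the data", {
  spec <- random_phantom_spec(11)
  tf <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(spec, tf)
  spec2 <- read_phantom_spec(tf)
  expect_equal(spec2$fissures$h_right_oblique, spec$fissures$h_right_oblique)
  expect_equal(spec2$activity_v, spec$activity_v)
  expect_identical(rasterize_labels(spec2, small_grid()),
                   rasterize_labels(spec, small_grid()))

  ph <- small_phantom()
  td <- withr::local_tempdir()
  paths <- write_phantom_nifti(ph, td)
  lab <- read_volume_nifti(paths[["labels"]])
  expect_equal(array(as.integer(lab$vol), dim = dim(lab$vol)), ph$labels)
  expect_equal(lab$grid$spacing_mm, ph$grid$spacing_mm, tolerance = 1e-6)
  act <- read_volume_nifti(paths[["activity_v"]])
  expect_equal(act$vol, ph$activity$V, tolerance = 1e-6)
})
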
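test_that("third-splitting follows the declared rounding rule", {
  heights <- function(H) {
    mask <- matrix(FALSE, 20, H + 10)
    mask[5:15, 6:(5 + H)] <- TRUE
    rois <- build_third_rois(mask)
    vapply(rois$zranges, function(zr) zr[2] - zr[1] + 1, numeric(1))
  }
  expect_equal(unname(heights(30)), c(10, 10, 10))   # superior, middle, inferior
  expect_equal(unname(heights(31)), c(10, 11, 10))   # round(31/3)=10, round(62/3)=21
  expect_equal(unname(heights(32)), c(11, 10, 11))
  # bands partition the bounding box: no overlap, no gap, heights within 1
  for (H in 3:40) {
    h <- heights(H)
    expect_equal(sum(h), H)
    expect_lte(max(h) - min(h), 1)
  }
  # box-shaped mask: each band holds a third of the mask pixels (+/- 1 row)
  mask <- matrix(FALSE, 20, 40)
  mask[5:15, 4:33] <- TRUE
  rois <- build_third_rois(mask)
  counts <- vapply(rois$bands, sum, numeric(1))
  expect_equal(unname(counts), rep(sum(mask) / 3, 3))
  expect_error(build_third_rois(matrix(FALSE, 4, 4)), "empty")
})

test_that("background subtraction follows the clipped linear rule", {
  px <- matrix(0, 40, 40)
  roi <- matrix(FALSE, 40, 40); roi[1:10, 1:10] <- TRUE      # 100 pixels
  px[roi] <- 5                                               # raw sum 500
  bg <- list(xrange = c(30, 34), zrange = c(30, 35))
  px[30:34, 30:35] <- 2                                      # bg mean 2
  expect_equal(as.numeric(background_subtract(px, roi, bg)), 300)
  px[30:34, 30:35] <- 0
  expect_equal(as.numeric(background_subtract(px, roi, bg)), 500)
  px[30:34, 30:35] <- 10
  res <- background_subtract(px, roi, bg)
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "clipped"))
})

test_that("view combination modes behave as named", {
  expect_equal(combine_views(100, 100, "geometric_mean"), 100)
  expect_equal(combine_views(100, 100, "arithmetic_mean"), 100)
  expect_equal(combine_views(100, 100, "anterior_only"), 100)
  expect_equal(combine_views(400, 100, "geometric_mean"), 200)
  expect_equal(combine_views(400, 100, "arithmetic_mean"), 250)
  expect_equal(combine_views(400, 100, "posterior_only"), 100)
  expect_equal(combine_views(0, 100, "geometric_mean"), 0)
})

test_that("left middle redistribution conserves totals exactly", {
  expect_equal(unname(redistribute_left_middle(30, 20, 50)), c(40, 60))
  expect_equal(unname(redistribute_left_middle(0, 0, 0)), c(0, 0))
  expect_equal(unname(redistribute_left_middle(0, 100, 0)), c(50, 50))
  set.seed(4)
  for (i in 1:20) {
    smi <- stats::runif(3, 0, 1e5)
    expect_equal(sum(redistribute_left_middle(smi[1], smi[2], smi[3])),
                 sum(smi))
  }
})

test_that("background ROIs sit outside the body, mirrored on a symmetric phantom", {
  sp <- phantom_spec(right_lung = list(center_mm = c(-63, 2, 0),
                                       half_axes_mm = c(52, 73, 122)),
                     left_lung = list(center_mm = c(63, 2, 0),
                                      half_axes_mm = c(52, 73, 122)))
  ph <- build_phantom(sp, small_grid())
  rois <- build_planar_rois(labels = ph$labels, hu = ph$hu)
  d <- dim(rois$body_mask)
  for (side in c("right", "left")) {
    bg <- rois$bg[[side]]
    expect_false(any(rois$body_mask[bg$xrange[1]:bg$xrange[2],
                                    bg$zrange[1]:bg$zrange[2]]))
  }
  # mirror symmetry in x (even-sized grid: i <-> nx + 1 - i)
  expect_equal(rois$bg$left$xrange, rev(d[1] + 1L - rois$bg$right$xrange))
  expect_equal(rois$bg$left$zrange, rois$bg$right$zrange)
})

test_that("uniform box lungs quantify to exact thirds on the right", {
  bx <- box_lungs()
  sv <- noiseless_spect(bx$activity, bx$grid, fwhm_mm = 0, total = 3e6)
  views <- project_planar_views(sv, NULL)
  rois <- build_planar_rois(masks = bx$masks, body_mask = bx$body_mask,
                            bg_size_px = c(3, 8), bg_gap_px = 1)
  pl <- quantify_planar(views$anterior, views$posterior, rois)
  # right lung counts split exactly in three (30 rows, no attenuation,
  # zero background), and each third maps to the corresponding "lobe"
  expect_equal(unname(pl$lobes[1:3]), rep(pl$right / 3, 3), tolerance = 1e-9)
  # left redistribution: S' = I' = half the left lung
  expect_equal(unname(pl$lobes[4]), unname(pl$lobes[5]), tolerance = 1e-9)
  expect_equal(sum(pl$lobes), 100, tolerance = 1e-9)
})

test_that("planar template inflates the RML against a thin anterior wedge", {
  ph <- build_phantom(phantom_spec())
  sv <- simulate_spect(ph, "V", fwhm_mm = 5, total_counts = 5e6,
                       noise = FALSE)
  views <- project_planar_views(sv, mu_map_from_phantom(ph))
  rois <- build_planar_rois(labels = ph$labels, hu = ph$hu)
  pl <- quantify_planar(views$anterior, views$posterior, rois)
  tr <- true_lobar_fractions(ph, "V")
  expect_gt(pl$lobes["RML"], tr$lobes["RML"])
  expect_lt(pl$lobes["RUL"], tr$lobes["RUL"])
  expect_lt(pl$lobes["RLL"], tr$lobes["RLL"])
  expect_equal(sum(pl$lobes), 100, tolerance = 1e-9)
})

test_that("3D lobar counting on exact labels recovers the truth", {
  ph <- small_phantom(seed = 21)
  sv <- simulate_spect(ph, "V", fwhm_mm = 0, total_counts = 1e6, noise = FALSE)
  lo <- quantify_lobar(sv, ph$labels)
  expect_region_close(lo, true_lobar_fractions(ph, "V"), 1e-9)
  # all counts in one lobe
  only <- small_phantom(activity_v = c(1, 0, 0, 0, 0))
  svo <- simulate_spect(only, "V", fwhm_mm = 0, total_counts = 1e6, noise = FALSE)
  expect_equal(unname(quantify_lobar(svo, only$labels)$lobes),
               c(100, 0, 0, 0, 0))
  # absent lobe (lobectomy) is reported as 0 with a flag
  lob <- apply_lobectomy(small_phantom(), "RML")
  svl <- simulate_spect(lob, "V", fwhm_mm = 0, total_counts = 1e6, noise = FALSE)
  q <- quantify_lobar(svl, lob$labels)
  expect_equal(unname(q$lobes["RML"]), 0)
  expect_match(q$flags, "absent_lobe:RML")
})

test_that("threshold-based planar delineation finds the two lungs", {
  ph <- small_phantom()
  sv <- simulate_spect(ph, "V", fwhm_mm = 5, total_counts = 5e6, noise = FALSE)
  p <- project_planar(sv, NULL, "anterior")
  dl <- delineate_lungs_planar(p)
  truth <- list(right = project_mask(ph$labels, "right"),
                left = project_mask(ph$labels, "left"))
  for (side in c("right", "left")) {
    inter <- sum(dl[[side]] & truth[[side]])
    uni <- sum(dl[[side]] | truth[[side]])
    expect_gt(inter / uni, 0.6)   # generous: blur spreads the silhouette
  }
})
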
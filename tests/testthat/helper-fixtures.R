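# Shared fixtures. Most geometric behavior is resolution-independent, so the
# module tests use a coarse 6.6 mm grid covering the same field of view as
# the default 3.3 mm SPECT grid; acceptance-level checks use the full grid.

small_grid <- function() voxel_grid(c(64L, 64L, 64L), 6.6)

small_phantom <- function(seed = NULL, ...) {
  spec <- if (is.null(seed)) phantom_spec(...) else
    random_phantom_spec(seed, base = phantom_spec(...))
  build_phantom(spec, small_grid())
}

# Rectangular-lung toy: two box "lungs" with uniform activity on a small
# grid, exact thirds, zero attenuation. Analytic expectations are trivial.
box_lungs <- function(n = 40L, spacing = 4) {
  grid <- voxel_grid(rep(n, 3), spacing)
  labels <- array(0L, dim = grid$shape)
  right <- list(x = 6:16, y = 11:30, z = 6:35)   # 30 z-rows
  left <- list(x = 25:35, y = 11:30, z = 6:35)
  labels[right$x, right$y, right$z] <- 1L  # single-code box lungs
  labels[left$x, left$y, left$z] <- 4L
  act <- array(0, dim = grid$shape)
  act[labels > 0L] <- 1
  masks <- list(right = project_mask(labels, "right"),
                left = project_mask(labels, "left"))
  body <- project_volume_mask(labels > 0L)
  list(grid = grid, labels = labels, activity = act, masks = masks,
       body_mask = body, right = right, left = left)
}

noiseless_spect <- function(activity, grid, fwhm_mm = 0, total = 1e6,
                            tracer = "V") {
  simulate_spect(activity, grid = grid, fwhm_mm = fwhm_mm,
                 total_counts = total, noise = FALSE, tracer = tracer)
}

expect_region_close <- function(a, b, tol) {
  expect_lt(max(abs(region_percentages(a) - region_percentages(b))), tol)
}
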
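#' Fissure plane parameters
#'
#' The lobar boundaries are modeled as planes. Each oblique fissure is tilted
#' in the sagittal plane (runs superior-posterior to inferior-anterior, as in
#' normal anatomy); the right horizontal fissure, which bounds the middle
#' lobe, is near-axial. Heights are fractions of the apex-base extent of the
#' owning lung, evaluated at the lung's anteroposterior midline.
#'
#' Defaults were chosen so that a default phantom with uniform specific
#' activity has right-lung lobar shares near 39/18/43 (RUL/RML/RLL) and
#' left-lung shares near 56/44 (LUL/LLL), a realistic clinical regime.
#'
#' @param h_right_oblique,h_right_horizontal,h_left_oblique fractional
#'   fissure heights in (0, 1).
#' @param theta_right_oblique_deg,theta_right_horizontal_deg,theta_left_oblique_deg
#'   sagittal tilt angles in degrees; positive tilt raises the plane
#'   posteriorly (so the inferior lobe reaches higher dorsally).
#' @return a list of class `fissure_params`.
#' @export
fissure_params <- function(h_right_oblique = 0.45,
                           theta_right_oblique_deg = 38,
                           h_right_horizontal = 0.56,
                           theta_right_horizontal_deg = 0,
                           h_left_oblique = 0.46,
                           theta_left_oblique_deg = 38) {
  fp <- list(h_right_oblique = h_right_oblique,
             theta_right_oblique_deg = theta_right_oblique_deg,
             h_right_horizontal = h_right_horizontal,
             theta_right_horizontal_deg = theta_right_horizontal_deg,
             h_left_oblique = h_left_oblique,
             theta_left_oblique_deg = theta_left_oblique_deg)
  hs <- c(fp$h_right_oblique, fp$h_right_horizontal, fp$h_left_oblique)
  if (any(!is.finite(hs)) || any(hs <= 0) || any(hs >= 1))
    stop("fissure fractional heights must lie strictly in (0, 1)")
  structure(fp, class = "fissure_params")
}

#' Parametric description of a digital thorax phantom
#'
#' The thorax is an ellipsoid of soft tissue containing two ellipsoidal
#' lungs; parametric fissure planes divide the right lung into three lobes
#' and the left lung into two. Tracer uptake is specified as per-lobe
#' specific activity (arbitrary units per voxel) separately for ventilation
#' and perfusion, so the ground-truth lobar fractions are known analytically
#' up to voxelization. Optional decorations emulate pathology: emphysema
#' (reduced activity and CT density in selected lobes), ventilation hotspots,
#' and lobectomy.
#'
#' @param thorax_half_axes_mm half-axes of the soft-tissue thorax ellipsoid.
#' @param right_lung,left_lung lists with `center_mm` and `half_axes_mm`.
#'   Note patient x is positive to the LEFT, so the right lung sits at x < 0.
#' @param fissures a [fissure_params()] object.
#' @param activity_v,activity_q per-lobe specific activity (units/voxel),
#'   named RUL, RML, RLL, LUL, LLL.
#' @param hu_values named HU constants: air, soft_tissue, parenchyma,
#'   emphysema.
#' @param emphysema NULL or `list(lobes=, activity_factor=, hu_value=)`.
#' @param hotspots list of `list(center_mm=, radius_mm=, multiplier=,
#'   tracer="V", jitter_mm=0)`.
#' @param lobectomy NULL, or a lobe code/name to remove.
#' @param seed integer; affects only stochastic decorations (hotspot jitter).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(thorax_half_axes_mm = c(150, 105, 180),
                         right_lung = list(center_mm = c(-62, 2, 0),
                                           half_axes_mm = c(55, 75, 125)),
                         left_lung = list(center_mm = c(64, 2, 5),
                                          half_axes_mm = c(50, 72, 120)),
                         fissures = fissure_params(),
                         activity_v = c(RUL = 1, RML = 1, RLL = 1, LUL = 1, LLL = 1),
                         activity_q = c(RUL = 1, RML = 1, RLL = 1, LUL = 1, LLL = 1),
                         hu_values = c(air = -1000, soft_tissue = 40,
                                       parenchyma = -800, emphysema = -950),
                         emphysema = NULL,
                         hotspots = list(),
                         lobectomy = NULL,
                         seed = 1L) {
  act_v <- normalize_lobe_vector(activity_v, "activity_v")
  act_q <- normalize_lobe_vector(activity_q, "activity_q")
  if (any(act_v < 0) || any(act_q < 0))
    stop("specific activities must be >= 0")
  if (!inherits(fissures, "fissure_params")) fissures <- do.call(fissure_params, fissures)
  for (hs in hotspots) {
    if (!is.null(hs$radius_mm) && hs$radius_mm <= 0) stop("hotspot radius must be > 0")
  }
  structure(list(thorax_half_axes_mm = as.numeric(thorax_half_axes_mm),
                 right_lung = right_lung, left_lung = left_lung,
                 fissures = fissures,
                 activity_v = act_v, activity_q = act_q,
                 hu_values = hu_values,
                 emphysema = emphysema, hotspots = hotspots,
                 lobectomy = lobectomy, seed = as.integer(seed)),
            class = "phantom_spec")
}

normalize_lobe_vector <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) != 5L) stop(what, " must have 5 entries (RUL,RML,RLL,LUL,LLL)")
    names(x) <- lobe_names
  }
  if (!all(lobe_names %in% names(x)))
    stop(what, " must be named with ", paste(lobe_names, collapse = ", "))
  as.numeric(x[lobe_names])
}

# Lobe codes for points (y, z) inside one lung, from the fissure planes.
# The oblique plane runs superior-posterior to inferior-anterior (positive
# tilt raises it posteriorly), so the inferior lobe reaches higher dorsally.
fissure_codes_points <- function(y, z, lung, fp, side) {
  zlo <- lung$center_mm[3] - lung$half_axes_mm[3]
  zhi <- lung$center_mm[3] + lung$half_axes_mm[3]
  dy <- y - lung$center_mm[2]
  deg2rad <- pi / 180
  if (side == "right") {
    zobl <- zlo + fp$h_right_oblique * (zhi - zlo) -
      tan(fp$theta_right_oblique_deg * deg2rad) * dy
    zhor <- zlo + fp$h_right_horizontal * (zhi - zlo) +
      tan(fp$theta_right_horizontal_deg * deg2rad) * dy
    code <- rep.int(lobe_codes[["RUL"]], length(z))
    code[z < zhor] <- lobe_codes[["RML"]]
    code[z < zobl] <- lobe_codes[["RLL"]]
  } else {
    zobl <- zlo + fp$h_left_oblique * (zhi - zlo) -
      tan(fp$theta_left_oblique_deg * deg2rad) * dy
    code <- rep.int(lobe_codes[["LUL"]], length(z))
    code[z < zobl] <- lobe_codes[["LLL"]]
  }
  code
}

# Per-lung fissure code map over the (y, z) plane. Returns an ny x nz integer
# matrix of lobe codes, valid wherever the lung mask is true.
fissure_code_map <- function(yc, zc, lung, fp, side) {
  ny <- length(yc); nz <- length(zc)
  Y <- rep(yc, times = nz)
  Z <- rep(zc, each = ny)
  matrix(fissure_codes_points(Y, Z, lung, fp, side), ny, nz)
}

ellipsoid_terms <- function(coords, center, half_axes) {
  lapply(1:3, function(a) ((coords[[a]] - center[a]) / half_axes[a])^2)
}

#' Rasterize the lobe label map of a phantom spec
#'
#' Analytic voxel-center rasterization at any requested grid: a voxel belongs
#' to a lung if its center lies inside the lung ellipsoid, and its lobe code
#' follows from the fissure planes. No resampling of a reference volume is
#' involved, so there are no label-interpolation artifacts. Large grids are
#' processed in z-slabs to bound memory.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [voxel_grid()].
#' @return integer array (nx, ny, nz) of lobe codes (0 = background).
#' @export
rasterize_labels <- function(spec, grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  xc <- grid_axis_coords(grid, 1)
  yc <- grid_axis_coords(grid, 2)
  zc <- grid_axis_coords(grid, 3)
  labels <- array(0L, dim = grid$shape)

  er <- ellipsoid_terms(list(xc, yc, zc), spec$right_lung$center_mm,
                        spec$right_lung$half_axes_mm)
  el <- ellipsoid_terms(list(xc, yc, zc), spec$left_lung$center_mm,
                        spec$left_lung$half_axes_mm)
  exy_r <- outer(er[[1]], er[[2]], "+")
  exy_l <- outer(el[[1]], el[[2]], "+")
  code_r <- fissure_code_map(yc, zc, spec$right_lung, spec$fissures, "right")
  code_l <- fissure_code_map(yc, zc, spec$left_lung, spec$fissures, "left")

  slab <- max(1L, as.integer(floor(2^23 / (nx * ny))))
  k0 <- 1L
  while (k0 <= nz) {
    k1 <- min(nz, k0 + slab - 1L)
    ks <- k0:k1
    rmask <- outer(exy_r, er[[3]][ks], "+") <= 1
    lmask <- outer(exy_l, el[[3]][ks], "+") <= 1
    lab <- array(0L, dim = c(nx, ny, length(ks)))
    if (any(rmask)) {
      codes <- aperm(array(code_r[, ks, drop = FALSE],
                           dim = c(ny, length(ks), nx)), c(3, 1, 2))
      lab[rmask] <- codes[rmask]
    }
    if (any(lmask)) {
      codes <- aperm(array(code_l[, ks, drop = FALSE],
                           dim = c(ny, length(ks), nx)), c(3, 1, 2))
      lab[lmask] <- codes[lmask]
    }
    labels[, , ks] <- lab
    k0 <- k1 + 1L
  }
  labels
}

#' Build a rasterized digital thorax phantom
#'
#' Rasterizes the lobe label map, CT-like HU volume, and per-tracer activity
#' volumes of a [phantom_spec()] at the requested grid, then applies the
#' spec's decorations (emphysema, hotspots, lobectomy) in that order.
#' Deterministic given `(spec, grid)`; the spec seed only drives stochastic
#' decorations such as hotspot center jitter.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [voxel_grid()]; default 128^3 at 3.3 mm.
#' @return an object of class `phantom` with elements `spec`, `grid`,
#'   `labels`, `hu`, `activity` (list with `V` and `Q` arrays), and a lung
#'   voxel cache used for fast fissure re-rasterization.
#' @export
build_phantom <- function(spec, grid = voxel_grid()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "voxel_grid"))
  labels <- rasterize_labels(spec, grid)

  xc <- grid_axis_coords(grid, 1)
  yc <- grid_axis_coords(grid, 2)
  zc <- grid_axis_coords(grid, 3)

  # thorax mask (separable ellipsoid test, built slab-free: grids used with
  # full volumes are expected to fit in memory at SPECT resolution)
  et <- ellipsoid_terms(list(xc, yc, zc), c(0, 0, 0), spec$thorax_half_axes_mm)
  thorax <- outer(outer(et[[1]], et[[2]], "+"), et[[3]], "+") <= 1

  lung_mask <- labels > 0L
  if (any(lung_mask & !thorax))
    stop("degenerate geometry: lung voxels fall outside the thorax ellipsoid")

  counts <- tabulate(labels[lung_mask], nbins = 5L)
  missing <- lobe_names[counts == 0L]
  if (length(missing) > 0L)
    stop("degenerate geometry: lobe(s) ", paste(missing, collapse = ", "),
         " are empty at the requested grid resolution")

  # anatomical side check: right-lung labels must sit at x < midline
  right_any <- apply(labels, 1, function(s) any(s %in% right_lobe_codes))
  left_any <- apply(labels, 1, function(s) any(s %in% left_lobe_codes))
  if (any(right_any & xc >= 0) || any(left_any & xc <= 0))
    stop("degenerate geometry: lung crosses the body midline; ",
         "shrink half-axes or recentre the lungs")

  hu <- array(spec$hu_values[["air"]], dim = grid$shape)
  hu[thorax] <- spec$hu_values[["soft_tissue"]]
  hu[lung_mask] <- spec$hu_values[["parenchyma"]]

  act_v <- array(0, dim = grid$shape)
  act_q <- array(0, dim = grid$shape)
  for (code in 1:5) {
    sel <- labels == code
    act_v[sel] <- spec$activity_v[code]
    act_q[sel] <- spec$activity_q[code]
  }

  cache <- list(
    right = lung_voxel_cache(labels, grid, right_lobe_codes),
    left = lung_voxel_cache(labels, grid, left_lobe_codes)
  )

  ph <- structure(list(spec = spec, grid = grid, labels = labels, hu = hu,
                       activity = list(V = act_v, Q = act_q),
                       cache = cache, removed_lobe = NULL),
                  class = "phantom")

  if (!is.null(spec$emphysema)) {
    e <- spec$emphysema
    ph <- apply_emphysema(ph, e$lobes,
                          activity_factor = e$activity_factor,
                          hu_value = if (is.null(e$hu_value))
                            spec$hu_values[["emphysema"]] else e$hu_value)
  }
  if (length(spec$hotspots) > 0L) {
    centers <- withr::with_seed(spec$seed, {
      lapply(spec$hotspots, function(hs) {
        jit <- if (is.null(hs$jitter_mm)) 0 else hs$jitter_mm
        hs$center_mm + stats::rnorm(3, 0, jit)
      })
    })
    for (i in seq_along(spec$hotspots)) {
      hs <- spec$hotspots[[i]]
      ph <- insert_hotspot(ph, centers[[i]], hs$radius_mm, hs$multiplier,
                           tracer = if (is.null(hs$tracer)) "V" else hs$tracer)
    }
  }
  if (!is.null(spec$lobectomy)) ph <- apply_lobectomy(ph, spec$lobectomy)
  ph
}

# Cache of lung voxel linear indices and their world y/z coordinates,
# enabling fissure re-rasterization without touching the full volume.
lung_voxel_cache <- function(labels, grid, codes) {
  idx <- which(array(labels %in% codes, dim = dim(labels)))
  nx <- grid$shape[1]; ny <- grid$shape[2]
  i0 <- idx - 1L
  j <- (i0 %/% nx) %% ny + 1L
  k <- i0 %/% (nx * ny) + 1L
  list(idx = idx,
       y = grid_axis_coords(grid, 2)[j],
       z = grid_axis_coords(grid, 3)[k])
}

#' @export
print.phantom <- function(x, ...) {
  counts <- vapply(1:5, function(c) sum(x$labels == c), numeric(1))
  cat("<phantom>\n")
  print(x$grid)
  cat("  lobe voxel counts:",
      paste(sprintf("%s=%d", lobe_names, counts), collapse = " "), "\n")
  if (!is.null(x$removed_lobe))
    cat("  lobectomy:", lobe_names[x$removed_lobe], "\n")
  invisible(x)
}

resolve_lobe <- function(lobe) {
  if (is.character(lobe)) {
    if (!lobe %in% lobe_names) stop("unknown lobe name: ", lobe)
    return(lobe_codes[[lobe]])
  }
  lobe <- as.integer(lobe)
  if (!lobe %in% 1:5) stop("lobe code must be in 1..5")
  lobe
}

#' Remove a lung lobe (lobectomy)
#'
#' The removed lobe's labels become background, its HU is replaced by soft
#' tissue (or air), and its activity is zeroed for both tracers; ground-truth
#' fractions computed afterwards are automatically renormalized over the
#' remaining lobes.
#'
#' @param phantom a [build_phantom()] result.
#' @param lobe lobe code (1-5) or name.
#' @param fill replacement tissue for the resected volume.
#' @return the modified phantom.
#' @export
apply_lobectomy <- function(phantom, lobe, fill = c("soft_tissue", "air")) {
  fill <- match.arg(fill)
  code <- resolve_lobe(lobe)
  sel <- phantom$labels == code
  if (!any(sel))
    stop("cannot remove lobe ", lobe_names[code], ": it is already absent")
  phantom$labels[sel] <- 0L
  phantom$hu[sel] <- phantom$spec$hu_values[[fill]]
  phantom$activity$V[sel] <- 0
  phantom$activity$Q[sel] <- 0
  side <- if (code %in% right_lobe_codes) "right" else "left"
  keep <- phantom$labels[phantom$cache[[side]]$idx] != 0L
  phantom$cache[[side]] <- lapply(phantom$cache[[side]], function(v) v[keep])
  phantom$removed_lobe <- code
  phantom
}

#' Apply emphysema-like changes to selected lobes
#'
#' Emphysematous parenchyma has reduced tracer uptake and lower CT density.
#' Activity in the affected lobes is multiplied by `activity_factor` (both
#' tracers) and their HU set to `hu_value`.
#'
#' @param phantom a phantom.
#' @param lobes lobe codes or names.
#' @param activity_factor multiplier in \[0, 1\].
#' @param hu_value replacement HU (default from the spec, typically -950).
#' @return the modified phantom.
#' @export
apply_emphysema <- function(phantom, lobes, activity_factor = 0.5,
                            hu_value = phantom$spec$hu_values[["emphysema"]]) {
  if (length(lobes) == 0L) {
    warning("empty lobe set: emphysema is a no-op")
    return(phantom)
  }
  if (activity_factor < 0 || activity_factor > 1)
    stop("activity_factor must be in [0, 1]")
  codes <- vapply(lobes, resolve_lobe, integer(1))
  sel <- phantom$labels %in% codes
  dim(sel) <- dim(phantom$labels)
  phantom$activity$V[sel] <- phantom$activity$V[sel] * activity_factor
  phantom$activity$Q[sel] <- phantom$activity$Q[sel] * activity_factor
  phantom$hu[sel] <- hu_value
  phantom
}

#' Insert a spherical uptake hotspot
#'
#' Multiplies activity inside a sphere, emulating the focal deposition
#' hotspots seen on ventilation imaging in severe airway obstruction.
#' Hotspot counts are deliberately not subtracted anywhere downstream, so
#' they affect all quantification methods identically.
#'
#' @param phantom a phantom.
#' @param center_mm sphere center (world mm).
#' @param radius_mm sphere radius (> 0).
#' @param multiplier activity multiplier (>= 0).
#' @param tracer "V", "Q" or "both".
#' @return the modified phantom.
#' @export
insert_hotspot <- function(phantom, center_mm, radius_mm, multiplier,
                           tracer = "V") {
  stopifnot(radius_mm > 0, multiplier >= 0)
  tracer <- match.arg(tracer, c("V", "Q", "both"))
  g <- phantom$grid
  xs <- grid_axis_coords(g, 1); ys <- grid_axis_coords(g, 2)
  zs <- grid_axis_coords(g, 3)
  d2 <- outer(outer((xs - center_mm[1])^2, (ys - center_mm[2])^2, "+"),
              (zs - center_mm[3])^2, "+")
  sphere <- d2 <= radius_mm^2
  if (!any(sphere & phantom$labels > 0L)) {
    warning("hotspot sphere does not intersect a lung: no-op")
    return(phantom)
  }
  for (tr in if (tracer == "both") c("V", "Q") else tracer) {
    phantom$activity[[tr]][sphere] <- phantom$activity[[tr]][sphere] * multiplier
  }
  phantom
}

#' Ground-truth relative lobar tracer distribution
#'
#' The fraction of total lung activity in each lobe, in percent:
#' `100 * sum(activity in lobe) / sum(activity in all lobes)`. Whole-lung
#' percentages are the sums over member lobes. This is the oracle against
#' which both quantification methods are judged.
#'
#' @param phantom a phantom.
#' @param tracer "V" (ventilation) or "Q" (perfusion).
#' @return a [lobar_distribution()] with method tag "truth".
#' @export
true_lobar_fractions <- function(phantom, tracer = c("V", "Q")) {
  tracer <- match.arg(tracer)
  act <- phantom$activity[[tracer]]
  sel <- phantom$labels > 0L
  counts <- numeric(5)
  sums <- rowsum(act[sel], phantom$labels[sel])
  counts[as.integer(rownames(sums))] <- sums[, 1]
  tot <- sum(counts)
  if (tot <= 0) stop("total activity is zero: lobar fractions are undefined")
  lobar_distribution(100 * counts / tot, tracer = tracer, method = "truth")
}

#' Lobe voxel counts of a phantom
#' @param phantom a phantom.
#' @return named numeric vector of voxel counts per lobe.
#' @export
lobe_voxel_counts <- function(phantom) {
  structure(vapply(1:5, function(c) sum(phantom$labels == c), numeric(1)),
            names = lobe_names)
}

#' Draw a random phantom spec from the default population ranges
#'
#' Emulates anatomical and physiological variability across subjects:
#' lung and thorax half-axes scaled by up to +/-7%, lung centers shifted by
#' up to +/-5 mm, fissure heights by +/-0.04 and tilts by +/-4 degrees, and
#' per-lobe specific activities drawn log-normally (sdlog 0.15) around the
#' base values, independently for ventilation and perfusion.
#'
#' @param seed integer seed controlling the draw.
#' @param base a [phantom_spec()] to perturb.
#' @return a new `phantom_spec`.
#' @export
random_phantom_spec <- function(seed, base = phantom_spec()) {
  withr::with_seed(as.integer(seed), {
    sc <- function(x, lo = 0.93, hi = 1.07) x * stats::runif(length(x), lo, hi)
    sh <- function(x, d = 5) x + stats::runif(length(x), -d, d)
    fp <- base$fissures
    fiss <- fissure_params(
      h_right_oblique = fp$h_right_oblique + stats::runif(1, -0.04, 0.04),
      theta_right_oblique_deg = fp$theta_right_oblique_deg + stats::runif(1, -4, 4),
      h_right_horizontal = fp$h_right_horizontal + stats::runif(1, -0.04, 0.04),
      theta_right_horizontal_deg = fp$theta_right_horizontal_deg + stats::runif(1, -4, 4),
      h_left_oblique = fp$h_left_oblique + stats::runif(1, -0.04, 0.04),
      theta_left_oblique_deg = fp$theta_left_oblique_deg + stats::runif(1, -4, 4))
    phantom_spec(
      thorax_half_axes_mm = sc(base$thorax_half_axes_mm, 0.95, 1.05),
      right_lung = list(center_mm = sh(base$right_lung$center_mm),
                        half_axes_mm = sc(base$right_lung$half_axes_mm)),
      left_lung = list(center_mm = sh(base$left_lung$center_mm),
                       half_axes_mm = sc(base$left_lung$half_axes_mm)),
      fissures = fiss,
      activity_v = base$activity_v * exp(stats::rnorm(5, 0, 0.15)),
      activity_q = base$activity_q * exp(stats::rnorm(5, 0, 0.15)),
      hu_values = base$hu_values,
      seed = as.integer(seed))
  })
}
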
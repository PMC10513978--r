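# round half away from zero, the declared band-boundary rounding rule
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Bounding box of a 2D mask
#' @param mask logical matrix indexed (x, z).
#' @return list with integer ranges `x = c(lo, hi)`, `z = c(lo, hi)`.
#' @export
mask_bbox <- function(mask) {
  if (!any(mask)) stop("mask is empty: cannot compute a bounding box")
  ij <- which(mask, arr.ind = TRUE)
  list(x = range(ij[, 1]), z = range(ij[, 2]))
}

#' Split a lung delineation into equal thirds
#'
#' Implements the clinical planar template: the bounding box of the lung
#' mask is computed, and its cranio-caudal (z) extent of H pixels is split
#' at boundaries `round(H/3)` and `round(2H/3)` (round half away from zero)
#' into inferior, middle, and superior bands. The superior band is the
#' highest-z third under the package axis convention. Bands span the full
#' bounding-box x-extent and are then intersected with the lung mask
#' (`clip_to_mask = FALSE` keeps the whole rectangles).
#'
#' @param lung_mask logical (nx x nz) delineation of one lung.
#' @param bbox optional bounding box (as from [mask_bbox()]), e.g. a jittered
#'   observer box; defaults to the mask's own box.
#' @param clip_to_mask intersect bands with the lung mask (default TRUE).
#' @return object of class `roi_set`: band masks + z ranges for the
#'   superior/middle/inferior regions.
#' @export
build_third_rois <- function(lung_mask, bbox = NULL, clip_to_mask = TRUE) {
  if (is.null(bbox)) bbox <- mask_bbox(lung_mask)
  zlo <- bbox$z[1]; zhi <- bbox$z[2]
  H <- zhi - zlo + 1L
  if (H < 3L) stop("lung bounding box is too short to split into thirds")
  b1 <- as.integer(round_half_away(H / 3))
  b2 <- as.integer(round_half_away(2 * H / 3))
  # rows 1..H counted from the inferior edge
  zranges <- list(inferior = c(zlo, zlo + b1 - 1L),
                  middle = c(zlo + b1, zlo + b2 - 1L),
                  superior = c(zlo + b2, zhi))
  d <- dim(lung_mask)
  box_mask <- matrix(FALSE, d[1], d[2])
  box_mask[bbox$x[1]:bbox$x[2], ] <- TRUE
  bands <- lapply(zranges, function(zr) {
    b <- box_mask
    b[, setdiff(seq_len(d[2]), zr[1]:zr[2])] <- FALSE
    if (clip_to_mask) b & lung_mask else b
  })
  structure(list(bands = bands[c("superior", "middle", "inferior")],
                 zranges = zranges[c("superior", "middle", "inferior")],
                 bbox = bbox, clip_to_mask = clip_to_mask),
            class = "roi_set")
}

rect_mask <- function(dim2, xrange, zrange) {
  m <- matrix(FALSE, dim2[1], dim2[2])
  m[xrange[1]:xrange[2], zrange[1]:zrange[2]] <- TRUE
  m
}

#' Place a background ROI lateral to a lung
#'
#' Background counts are measured in a rectangle outside the body, offset
#' laterally (away from the body midline) from the lung bounding box and
#' centered on the lung's cranio-caudal midline. The gap is grown until the
#' rectangle clears the body mask; if no placement fits in the image, an
#' error suggests a larger field of view.
#'
#' @param lung_mask logical (nx x nz) lung delineation.
#' @param body_mask logical (nx x nz) body silhouette (the ROI must not
#'   intersect it).
#' @param size_px rectangle size (x, z) in pixels.
#' @param gap_px minimum lateral gap from the lung bounding box.
#' @return list with `xrange` and `zrange` (inclusive pixel index ranges).
#' @export
place_background_roi <- function(lung_mask, body_mask, size_px = c(6, 12),
                                 gap_px = 4) {
  stopifnot(identical(dim(lung_mask), dim(body_mask)))
  d <- dim(lung_mask)
  bbox <- mask_bbox(lung_mask)
  wx <- as.integer(size_px[1]); wz <- as.integer(size_px[2])
  zc <- as.integer(round((bbox$z[1] + bbox$z[2]) / 2))
  zlo <- max(1L, zc - wz %/% 2L)
  zhi <- zlo + wz - 1L
  if (zhi > d[2]) { zhi <- d[2]; zlo <- zhi - wz + 1L }
  if (zlo < 1L) stop("image too small in z for the background ROI; ",
                     "use a larger field of view")
  lateral_low <- mean(bbox$x) < (d[1] + 1) / 2  # lung on the low-x side
  gap_max <- if (lateral_low) bbox$x[1] - 1L - wx else d[1] - bbox$x[2] - wx
  if (gap_max < 1L)
    stop("no valid background ROI placement lateral to the lung; ",
         "use a larger field of view")
  gap0 <- min(as.integer(gap_px), gap_max)
  # prefer the requested gap, then wider (clears the body), then narrower
  for (gap in c(gap0:gap_max, rev(seq_len(gap0 - 1L)))) {
    if (lateral_low) {
      xhi <- bbox$x[1] - gap - 1L
      xlo <- xhi - wx + 1L
    } else {
      xlo <- bbox$x[2] + gap + 1L
      xhi <- xlo + wx - 1L
    }
    if (!any(body_mask[xlo:xhi, zlo:zhi]))
      return(list(xrange = c(xlo, xhi), zrange = c(zlo, zhi)))
  }
  stop("no valid background ROI placement lateral to the lung; ",
       "use a larger field of view")
}

#' Background-subtract the counts in one ROI
#'
#' `corrected = max(0, raw_roi_sum - mean_bg_per_pixel * n_roi_pixels)`.
#' Negative corrected counts are clipped to 0 and flagged via the
#' `"clipped"` attribute.
#'
#' @param pixels planar count matrix.
#' @param roi_mask logical matrix selecting the ROI pixels.
#' @param bg_rect background rectangle from [place_background_roi()].
#' @return corrected count (scalar) with attributes `clipped` and `bg_mean`.
#' @export
background_subtract <- function(pixels, roi_mask, bg_rect) {
  bg_px <- pixels[bg_rect$xrange[1]:bg_rect$xrange[2],
                  bg_rect$zrange[1]:bg_rect$zrange[2]]
  if (length(bg_px) == 0L) stop("background rectangle is empty")
  bg_mean <- mean(bg_px)
  raw <- sum(pixels[roi_mask])
  corrected <- raw - bg_mean * sum(roi_mask)
  clipped <- corrected < 0
  structure(max(0, corrected), clipped = clipped, bg_mean = bg_mean)
}

#' Combine anterior and posterior counts
#'
#' The default geometric mean `sqrt(a * p)` is the clinical standard: for a
#' source in a uniform attenuating slab it is independent of source depth.
#'
#' @param anterior,posterior nonnegative counts.
#' @param mode combination rule.
#' @return combined count.
#' @export
combine_views <- function(anterior, posterior,
                          mode = c("geometric_mean", "arithmetic_mean",
                                   "anterior_only", "posterior_only")) {
  mode <- match.arg(mode)
  stopifnot(all(anterior >= 0), all(posterior >= 0))
  switch(mode,
         geometric_mean = sqrt(anterior * posterior),
         arithmetic_mean = (anterior + posterior) / 2,
         anterior_only = anterior,
         posterior_only = posterior)
}

#' Redistribute the left middle-third counts
#'
#' The left lung has no middle lobe, so the middle-third counts are halved
#' and added to the superior and inferior left counts. Totals are conserved
#' exactly: `S' + I' = S + M + I`.
#'
#' @param superior,middle,inferior nonnegative counts.
#' @return numeric `c(superior, inferior)` after redistribution.
#' @export
redistribute_left_middle <- function(superior, middle, inferior) {
  stopifnot(superior >= 0, middle >= 0, inferior >= 0)
  c(superior = superior + middle / 2, inferior = inferior + middle / 2)
}

#' Build the full planar ROI layout for both lungs
#'
#' Convenience constructor: projects per-lung delineation masks from a lobe
#' label map (or accepts explicit masks), splits each lung into thirds, and
#' places one background rectangle lateral to each lung.
#'
#' @param labels 3D lobe label array (used when `masks` is NULL).
#' @param masks optional list with logical `right` and `left` (nx x nz).
#' @param body_mask logical (nx x nz) body silhouette; defaults to the
#'   projection of `hu > air` when `hu` is given.
#' @param hu optional HU volume used to derive the body mask.
#' @param bg_size_px,bg_gap_px background rectangle geometry.
#' @return list with `right`, `left` (roi_sets) and `bg` (rectangles).
#' @export
build_planar_rois <- function(labels = NULL, masks = NULL, body_mask = NULL,
                              hu = NULL, bg_size_px = c(6, 12), bg_gap_px = 4) {
  if (is.null(masks)) {
    if (is.null(labels)) stop("provide either labels or masks")
    masks <- list(right = project_mask(labels, "right"),
                  left = project_mask(labels, "left"))
  }
  if (is.null(body_mask)) {
    if (is.null(hu)) stop("provide body_mask or an HU volume")
    body_mask <- project_volume_mask(hu > min(hu))
  }
  list(right = build_third_rois(masks$right),
       left = build_third_rois(masks$left),
       bg = list(right = place_background_roi(masks$right, body_mask,
                                              bg_size_px, bg_gap_px),
                 left = place_background_roi(masks$left, body_mask,
                                             bg_size_px, bg_gap_px)),
       masks = masks, body_mask = body_mask)
}

#' Planar equal-thirds lobar quantification
#'
#' The clinical template method: each lung's three bands are
#' background-corrected per view, the views are combined (geometric mean by
#' default), right-lung thirds map directly to RUL/RML/RLL, and the left
#' middle third is redistributed to the left superior and inferior lobes.
#' Percentages are taken over the total of all regions.
#'
#' @param anterior,posterior [planar_image()]s of the same geometry.
#' @param rois a [build_planar_rois()] layout (possibly observer-perturbed).
#' @param combine_mode view combination rule, see [combine_views()].
#' @param tracer tag for the output.
#' @return a [lobar_distribution()] with method tag "planar".
#' @export
quantify_planar <- function(anterior, posterior, rois,
                            combine_mode = "geometric_mean", tracer = "V") {
  stopifnot(inherits(anterior, "planar_image"),
            inherits(posterior, "planar_image"))
  if (!identical(dim(anterior$pixels), dim(posterior$pixels)))
    stop("anterior and posterior images must share geometry")
  flags <- character()
  region_count <- function(side, band) {
    m <- rois[[side]]$bands[[band]]
    ca <- background_subtract(anterior$pixels, m, rois$bg[[side]])
    cp <- background_subtract(posterior$pixels, m, rois$bg[[side]])
    if (isTRUE(attr(ca, "clipped")) || isTRUE(attr(cp, "clipped")))
      flags <<- c(flags, paste0("clipped:", side, "_", band))
    combine_views(as.numeric(ca), as.numeric(cp), combine_mode)
  }
  r <- vapply(c("superior", "middle", "inferior"),
              function(b) region_count("right", b), numeric(1))
  l <- vapply(c("superior", "middle", "inferior"),
              function(b) region_count("left", b), numeric(1))
  lft <- redistribute_left_middle(l[1], l[2], l[3])
  counts <- c(RUL = unname(r[1]), RML = unname(r[2]), RLL = unname(r[3]),
              LUL = unname(lft[1]), LLL = unname(lft[2]))
  total <- sum(counts)
  if (total <= 0)
    stop("zero total corrected counts: cannot form a relative distribution")
  lobar_distribution(100 * counts / total, tracer = tracer, method = "planar",
                     flags = flags)
}

#' 3D SPECT lobar quantification
#'
#' Counts inside each lobe of the label map are summed and expressed as
#' percentages of the five-lobe total; whole-lung values are derived sums.
#' A lobe absent from the label map (lobectomy) is reported as 0% and
#' flagged.
#'
#' @param spect a `spect_volume`.
#' @param labels integer lobe label array on the SPECT grid.
#' @return a [lobar_distribution()] with method tag "lobar_3d".
#' @export
quantify_lobar <- function(spect, labels) {
  stopifnot(inherits(spect, "spect_volume"))
  if (!identical(dim(labels), dim(spect$counts)))
    stop("label map must be on the SPECT grid")
  sel <- labels > 0L
  counts <- numeric(5)
  sums <- rowsum(spect$counts[sel], labels[sel])
  counts[as.integer(rownames(sums))] <- sums[, 1]
  present <- tabulate(labels[sel], nbins = 5L) > 0L
  flags <- if (all(present)) character() else
    paste0("absent_lobe:", paste(lobe_names[!present], collapse = ","))
  tot <- sum(counts)
  if (tot <= 0) stop("zero total counts inside the lobes")
  lobar_distribution(100 * counts / tot, tracer = spect$meta$tracer,
                     method = "lobar_3d", flags = flags)
}

#' Threshold-based planar lung delineation
#'
#' Emulates a manual lung delineation directly on a planar image: pixels at
#' or above `frac` of the image's 99.5th-percentile intensity are kept, and
#' the two largest 4-connected components are returned as the two lungs
#' (assigned to right/left by their mean x position; patient x is positive
#' to the left, i.e. the right lung sits at low x on these images).
#'
#' @param planar a [planar_image()].
#' @param frac threshold fraction (default 0.10).
#' @param quantile_ref reference intensity quantile (default 0.995).
#' @return list of logical masks `right` and `left`.
#' @export
delineate_lungs_planar <- function(planar, frac = 0.10, quantile_ref = 0.995) {
  px <- planar$pixels
  thr <- frac * stats::quantile(px, quantile_ref, names = FALSE)
  fg <- px >= thr & px > 0
  lab <- label_components_2d(fg)
  if (max(lab) < 2L) stop("fewer than two components found above threshold")
  sizes <- tabulate(lab[lab > 0])
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  mx <- vapply(top2, function(cc) mean(which(lab == cc, arr.ind = TRUE)[, 1]),
               numeric(1))
  right_cc <- top2[which.min(mx)]
  left_cc <- top2[which.max(mx)]
  list(right = lab == right_cc, left = lab == left_cc)
}

# 4-connected component labeling of a logical matrix (iterative flood fill)
label_components_2d <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (cur - 1L) %% d[1] + 1L
      j <- (cur - 1L) %/% d[1] + 1L
      nb <- c(if (i > 1L) cur - 1L, if (i < d[1]) cur + 1L,
              if (j > 1L) cur - d[1], if (j < d[2]) cur + d[1])
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      stack <- c(stack, nb)
    }
  }
  lab
}
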
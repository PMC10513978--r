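#' Simulated observer model
#'
#' Observer disagreement is modeled purely through geometric perturbation of
#' the delineations each method relies on — counts are never re-measured.
#' Planar observers jitter the lung bounding-box edges and the background-ROI
#' gap; manual 3D observers displace and tilt the fissure planes (the
#' horizontal fissure, which is hardest to see on CT, gets the largest SD);
#' the automated 3D method is deterministic by default.
#'
#' @param method "planar", "manual_3d" or "automated_3d".
#' @param sigma_px planar bounding-box edge jitter SD, pixels.
#' @param sigma_oblique_mm oblique-fissure height jitter SD, mm.
#' @param sigma_horizontal_mm horizontal-fissure height jitter SD, mm.
#' @param sigma_tilt_deg fissure tilt jitter SD, degrees.
#' @return list of class `observer_model`.
#' @export
observer_model <- function(method = c("planar", "manual_3d", "automated_3d"),
                           sigma_px = 2,
                           sigma_oblique_mm = 3,
                           sigma_horizontal_mm = 6,
                           sigma_tilt_deg = 2) {
  method <- match.arg(method)
  if (method == "automated_3d") {
    sigma_px <- 0; sigma_oblique_mm <- 0
    sigma_horizontal_mm <- 0; sigma_tilt_deg <- 0
  }
  sds <- c(sigma_px, sigma_oblique_mm, sigma_horizontal_mm, sigma_tilt_deg)
  if (any(sds < 0)) stop("observer jitter SDs must be >= 0")
  structure(list(method = method, sigma_px = sigma_px,
                 sigma_oblique_mm = sigma_oblique_mm,
                 sigma_horizontal_mm = sigma_horizontal_mm,
                 sigma_tilt_deg = sigma_tilt_deg),
            class = "observer_model")
}

#' Default observer models for the three methods
#' @return named list of [observer_model()]s.
#' @export
default_observer_models <- function() {
  list(planar = observer_model("planar"),
       manual_3d = observer_model("manual_3d"),
       automated_3d = observer_model("automated_3d"))
}

# deterministic substream seed from a master seed and stream identifiers
substream_seed <- function(master, ...) {
  ids <- c(master, ...)
  s <- 17
  for (v in ids) s <- (s * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(s)
}

#' Re-rasterize lobe labels with observer-perturbed fissure planes
#'
#' Each fissure plane's height is offset by a Normal(0, sigma^2) draw (mm,
#' converted to a fraction of the lung's apex-base extent) and its tilt by a
#' Normal(0, sigma_tilt^2) draw (degrees); labels are recomputed for the lung
#' voxels only, so the lungs' outer boundaries are unchanged. A perturbation
#' that empties a lobe is resampled up to 10 times before erroring.
#'
#' @param phantom a phantom (without lobectomy; resected anatomy cannot be
#'   re-partitioned by intact-lung fissure planes).
#' @param model a manual_3d (or automated_3d) [observer_model()].
#' @param seed integer seed for this observer draw.
#' @return integer label array of the same shape as `phantom$labels`.
#' @export
perturb_fissures <- function(phantom, model, seed) {
  stopifnot(inherits(model, "observer_model"))
  if (!is.null(phantom$removed_lobe))
    stop("fissure perturbation after lobectomy is not supported")
  if (model$sigma_oblique_mm == 0 && model$sigma_horizontal_mm == 0 &&
      model$sigma_tilt_deg == 0)
    return(phantom$labels)
  fp <- phantom$spec$fissures
  ext_r <- 2 * phantom$spec$right_lung$half_axes_mm[3]
  ext_l <- 2 * phantom$spec$left_lung$half_axes_mm[3]
  withr::with_seed(as.integer(seed), {
    for (attempt in 1:10) {
      dh <- stats::rnorm(3, 0, c(model$sigma_oblique_mm,
                                 model$sigma_horizontal_mm,
                                 model$sigma_oblique_mm))
      dt <- stats::rnorm(3, 0, model$sigma_tilt_deg)
      h_ro <- fp$h_right_oblique + dh[1] / ext_r
      h_rh <- fp$h_right_horizontal + dh[2] / ext_r
      h_lo <- fp$h_left_oblique + dh[3] / ext_l
      if (any(c(h_ro, h_rh, h_lo) <= 0) || any(c(h_ro, h_rh, h_lo) >= 1)) next
      fp2 <- fissure_params(h_right_oblique = h_ro,
                            theta_right_oblique_deg = fp$theta_right_oblique_deg + dt[1],
                            h_right_horizontal = h_rh,
                            theta_right_horizontal_deg = fp$theta_right_horizontal_deg + dt[2],
                            h_left_oblique = h_lo,
                            theta_left_oblique_deg = fp$theta_left_oblique_deg + dt[3])
      labels <- phantom$labels
      cr <- phantom$cache$right
      cl <- phantom$cache$left
      labels[cr$idx] <- fissure_codes_points(cr$y, cr$z,
                                             phantom$spec$right_lung, fp2, "right")
      labels[cl$idx] <- fissure_codes_points(cl$y, cl$z,
                                             phantom$spec$left_lung, fp2, "left")
      if (all(tabulate(labels[labels > 0L], nbins = 5L) > 0L)) return(labels)
    }
    stop("fissure perturbation emptied a lobe in 10 consecutive draws; ",
         "reduce the jitter SDs")
  })
}

#' Observer-perturbed planar ROI layout
#'
#' Each lung bounding-box edge is offset by an integer-rounded
#' Normal(0, sigma_px^2) draw before third-splitting; the bands are then
#' re-intersected with the jittered box and the lung mask, and the background
#' rectangle is re-placed with a jittered lateral gap.
#'
#' @param rois a [build_planar_rois()] layout (carries masks and body mask).
#' @param model a planar [observer_model()].
#' @param seed integer seed for this observer draw.
#' @param bg_size_px,bg_gap_px background rectangle geometry.
#' @return a perturbed layout of the same structure.
#' @export
perturb_planar_rois <- function(rois, model, seed,
                                bg_size_px = c(6, 12), bg_gap_px = 4) {
  stopifnot(inherits(model, "observer_model"))
  if (model$sigma_px == 0) return(rois)
  withr::with_seed(as.integer(seed), {
    out <- rois
    for (side in c("right", "left")) {
      mask <- rois$masks[[side]]
      d <- dim(mask)
      bb <- mask_bbox(mask)
      e <- round_half_away(stats::rnorm(4, 0, model$sigma_px))
      bbox <- list(x = c(max(1L, bb$x[1] + e[1]), min(d[1], bb$x[2] + e[2])),
                   z = c(max(1L, bb$z[1] + e[3]), min(d[2], bb$z[2] + e[4])))
      if (bbox$x[1] > bbox$x[2] || (bbox$z[2] - bbox$z[1] + 1) < 3)
        stop("jittered bounding box collapsed for the ", side, " lung")
      out[[side]] <- build_third_rois(mask, bbox = bbox)
      gap <- max(1, bg_gap_px + round_half_away(stats::rnorm(1, 0, model$sigma_px)))
      out$bg[[side]] <- place_background_roi(mask, rois$body_mask,
                                             bg_size_px, gap)
    }
    out
  })
}

#' Interobserver relative standard deviation
#'
#' `100 * sample SD / mean` over the observers' values; requires at least
#' two observers. A zero mean makes the RSD undefined (returned as NA).
#'
#' @param values numeric vector, one value per observer.
#' @return RSD in percent.
#' @export
interobserver_rsd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 observers")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Run a full simulated interobserver study
#'
#' For each phantom, each tracer's SPECT volume and planar views are
#' simulated once (the counts are fixed; observers differ only in their
#' delineations). Each of `n_observers` simulated observers then quantifies
#' every phantom with each method: planar with jittered ROIs, manual 3D with
#' perturbed fissures, automated 3D with the exact label map. Per region,
#' the relative SD across observers is computed per phantom, then averaged
#' over phantoms. Observer k of phantom j draws from substream
#' (seed, j, k), so runs are reproducible and observers independent.
#'
#' @param phantoms list of [build_phantom()] results.
#' @param n_observers number of simulated observers (>= 2; default 3).
#' @param models named list of observer models as in
#'   [default_observer_models()].
#' @param tracers subset of c("V", "Q").
#' @param seed master seed.
#' @param fwhm_mm,total_counts,noise SPECT simulation settings.
#' @param combine_mode planar view combination rule.
#' @return object of class `observer_study`: list with `raw` (per
#'   phantom/observer/method/tracer/region percentages) and `summary`
#'   (mean RSD across phantoms, with its SD, per method/tracer/region).
#' @export
run_observer_study <- function(phantoms, n_observers = 3,
                               models = default_observer_models(),
                               tracers = "V", seed = 1,
                               fwhm_mm = 5, total_counts = 5e6, noise = TRUE,
                               combine_mode = "geometric_mean") {
  if (n_observers < 2) stop("need at least 2 observers")
  raw <- list()
  for (j in seq_along(phantoms)) {
    ph <- phantoms[[j]]
    mu <- mu_map_from_phantom(ph)
    base_rois <- build_planar_rois(labels = ph$labels, hu = ph$hu)
    for (tr in tracers) {
      spect <- simulate_spect(ph, tracer = tr, fwhm_mm = fwhm_mm,
                              total_counts = total_counts, noise = noise,
                              seed = substream_seed(seed, 1, j, match(tr, c("V", "Q"))))
      views <- project_planar_views(spect, mu)
      for (k in seq_len(n_observers)) {
        s <- substream_seed(seed, 2, j, k)
        for (mname in names(models)) {
          model <- models[[mname]]
          dist <- switch(model$method,
            planar = {
              rk <- perturb_planar_rois(base_rois, model,
                                        substream_seed(s, 1))
              quantify_planar(views$anterior, views$posterior, rk,
                              combine_mode = combine_mode, tracer = tr)
            },
            manual_3d = ,
            automated_3d = {
              labs <- perturb_fissures(ph, model, substream_seed(s, 2))
              quantify_lobar(spect, labs)
            })
          raw[[length(raw) + 1L]] <- data.frame(
            phantom = j, observer = k, method = mname, tracer = tr,
            region = region_names,
            percent = unname(region_percentages(dist)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  raw <- do.call(rbind, raw)
  summary <- summarize_observer_rsd(raw)
  structure(list(raw = raw, summary = summary, n_observers = n_observers),
            class = "observer_study")
}

# per-phantom RSD across observers, then mean +/- SD across phantoms
summarize_observer_rsd <- function(raw) {
  key <- interaction(raw$phantom, raw$method, raw$tracer, raw$region,
                     drop = TRUE)
  rsd <- tapply(raw$percent, key, interobserver_rsd)
  parts <- do.call(rbind, strsplit(names(rsd), ".", fixed = TRUE))
  per_phantom <- data.frame(phantom = as.integer(parts[, 1]),
                            method = parts[, 2], tracer = parts[, 3],
                            region = parts[, 4], rsd = as.numeric(rsd),
                            stringsAsFactors = FALSE)
  key2 <- interaction(per_phantom$method, per_phantom$tracer,
                      per_phantom$region, drop = TRUE)
  mean_rsd <- tapply(per_phantom$rsd, key2, mean)
  sd_rsd <- tapply(per_phantom$rsd, key2, stats::sd)
  parts2 <- do.call(rbind, strsplit(names(mean_rsd), ".", fixed = TRUE))
  out <- data.frame(method = parts2[, 1], tracer = parts2[, 2],
                    region = parts2[, 3],
                    mean_rsd = as.numeric(mean_rsd),
                    sd_rsd = as.numeric(sd_rsd),
                    stringsAsFactors = FALSE)
  out$region <- factor(out$region, levels = region_names)
  out[order(out$method, out$tracer, out$region), ]
}

#' @export
print.observer_study <- function(x, ...) {
  cat(sprintf("<observer_study> %d phantoms, %d observers\n",
              length(unique(x$raw$phantom)), x$n_observers))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
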
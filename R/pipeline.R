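#' Study configuration for the full comparison pipeline
#'
#' Bundles every tunable of the end-to-end study: phantom population,
#' simulation settings, quantification options, observer models, and the
#' statistical significance level.
#'
#' @param n_phantoms number of phantoms in the method-comparison arm
#'   (default 43, a typical clinical validation cohort size).
#' @param grid_shape,grid_spacing_mm simulation grid (default 128^3, 3.3 mm).
#' @param tracers tracers to analyze, subset of c("V", "Q").
#' @param fwhm_mm reconstructed-SPECT Gaussian PSF FWHM (mm).
#' @param total_counts expected total counts per SPECT volume.
#' @param noise Poisson counting noise on/off.
#' @param combine_mode planar view combination rule.
#' @param alpha ANOVA significance level, in (0, 1).
#' @param n_observer_phantoms phantoms in the interobserver arm (default 10;
#'   0 disables it).
#' @param n_observers simulated observers (default 3).
#' @param observer_models list as from [default_observer_models()].
#' @param base_spec base [phantom_spec()] the population is drawn around.
#' @param seed master seed; every stage derives substreams from it.
#' @param write_volumes also write phantom volumes as NIfTI (large).
#' @return list of class `study_config`.
#' @export
study_config <- function(n_phantoms = 43,
                         grid_shape = c(128L, 128L, 128L),
                         grid_spacing_mm = 3.3,
                         tracers = c("V", "Q"),
                         fwhm_mm = 5, total_counts = 5e6, noise = TRUE,
                         combine_mode = "geometric_mean",
                         alpha = 0.05,
                         n_observer_phantoms = 10, n_observers = 3,
                         observer_models = default_observer_models(),
                         base_spec = phantom_spec(),
                         seed = 1L,
                         write_volumes = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_phantoms < 2) stop("need n_phantoms >= 2 for the ANOVA stages")
  structure(list(n_phantoms = n_phantoms, grid_shape = grid_shape,
                 grid_spacing_mm = grid_spacing_mm, tracers = tracers,
                 fwhm_mm = fwhm_mm, total_counts = total_counts,
                 noise = noise, combine_mode = combine_mode, alpha = alpha,
                 n_observer_phantoms = n_observer_phantoms,
                 n_observers = n_observers,
                 observer_models = observer_models,
                 base_spec = base_spec, seed = as.integer(seed),
                 write_volumes = write_volumes),
            class = "study_config")
}

set_method_tag <- function(dist, tag) { dist$method <- tag; dist }

#' Quantify one phantom with all three methods (plus truth)
#'
#' Simulates the tracer's SPECT volume, then quantifies it with (a) the
#' planar equal-thirds template on attenuated forward projections, (b) 3D
#' lobar counting on observer-perturbed ("manual") labels, and (c) 3D lobar
#' counting on the exact ("automated") labels, alongside the ground truth.
#' The manual label map is shared between tracers of the same phantom when
#' supplied, mirroring a physician segmenting the CT once.
#'
#' @param phantom a phantom.
#' @param tracer "V" or "Q".
#' @param manual_labels perturbed label array (default: generated from the
#'   manual observer model with the given seed).
#' @param manual_model [observer_model()] for the manual arm.
#' @param seed substream seed for simulation and the manual draw.
#' @param fwhm_mm,total_counts,noise,combine_mode see [study_config()].
#' @return list with `truth`, `planar`, `manual_3d`, `automated_3d`
#'   ([lobar_distribution()]s) and the `spect` volume.
#' @export
quantify_phantom_all <- function(phantom, tracer = "V",
                                 manual_labels = NULL,
                                 manual_model = observer_model("manual_3d"),
                                 seed = 1,
                                 fwhm_mm = 5, total_counts = 5e6,
                                 noise = TRUE,
                                 combine_mode = "geometric_mean") {
  spect <- simulate_spect(phantom, tracer = tracer, fwhm_mm = fwhm_mm,
                          total_counts = total_counts, noise = noise,
                          seed = substream_seed(seed, 11))
  mu <- mu_map_from_phantom(phantom)
  views <- project_planar_views(spect, mu)
  rois <- build_planar_rois(labels = phantom$labels, hu = phantom$hu)
  planar <- quantify_planar(views$anterior, views$posterior, rois,
                            combine_mode = combine_mode, tracer = tracer)
  if (is.null(manual_labels))
    manual_labels <- perturb_fissures(phantom, manual_model,
                                      substream_seed(seed, 12))
  manual <- set_method_tag(quantify_lobar(spect, manual_labels), "manual_3d")
  auto <- set_method_tag(quantify_lobar(spect, phantom$labels), "automated_3d")
  list(truth = true_lobar_fractions(phantom, tracer), planar = planar,
       manual_3d = manual, automated_3d = auto, spect = spect)
}

#' Run the full simulated comparison study
#'
#' Draws a population of random phantoms, quantifies every phantom and
#' tracer with the planar, manual 3D, and automated 3D methods, compares the
#' methods region by region with Welch ANOVA, and (optionally) runs the
#' interobserver arm on a phantom subset. All randomness derives from the
#' master seed, so two runs with the same config produce byte-identical
#' report files.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory for report files (CSV/JSON plus
#'   a run manifest).
#' @return list of class `study_report`: `quantifications` (tidy per-phantom
#'   data frame including truth), `comparisons` (one [compare_methods()]
#'   table per tracer), `observer_study` (or NULL), `config`, and output
#'   `paths` when `out_dir` was given.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  grid <- voxel_grid(config$grid_shape, config$grid_spacing_mm)
  seed <- config$seed
  manual_model <- config$observer_models$manual_3d
  if (is.null(manual_model)) manual_model <- observer_model("manual_3d")

  phantoms <- lapply(seq_len(config$n_phantoms), function(j) {
    build_phantom(random_phantom_spec(substream_seed(seed, 101, j),
                                      base = config$base_spec), grid)
  })

  rows <- list()
  for (j in seq_len(config$n_phantoms)) {
    ph <- phantoms[[j]]
    manual_labels <- perturb_fissures(ph, manual_model,
                                      substream_seed(seed, 303, j))
    for (tr in config$tracers) {
      q <- quantify_phantom_all(
        ph, tracer = tr, manual_labels = manual_labels,
        seed = substream_seed(seed, 202, j, match(tr, c("V", "Q"))),
        fwhm_mm = config$fwhm_mm, total_counts = config$total_counts,
        noise = config$noise, combine_mode = config$combine_mode)
      for (nm in c("truth", "planar", "manual_3d", "automated_3d")) {
        rows[[length(rows) + 1L]] <- cbind(phantom = j,
                                           as.data.frame(q[[nm]]))
      }
    }
  }
  quant <- do.call(rbind, rows)

  comparisons <- lapply(stats::setNames(config$tracers, config$tracers),
    function(tr) {
      compare_methods(quant[quant$tracer == tr & quant$method != "truth", ],
                      methods = c("automated_3d", "manual_3d", "planar"),
                      alpha = config$alpha)
    })

  obs <- NULL
  if (config$n_observer_phantoms >= 1) {
    subset <- phantoms[seq_len(min(config$n_observer_phantoms,
                                   length(phantoms)))]
    obs <- run_observer_study(subset, n_observers = config$n_observers,
                              models = config$observer_models,
                              tracers = config$tracers,
                              seed = substream_seed(seed, 404),
                              fwhm_mm = config$fwhm_mm,
                              total_counts = config$total_counts,
                              noise = config$noise,
                              combine_mode = config$combine_mode)
  }

  report <- structure(list(quantifications = quant, comparisons = comparisons,
                           observer_study = obs, config = config,
                           paths = NULL),
                      class = "study_report")
  if (!is.null(out_dir)) report$paths <- write_study_report(report, out_dir)
  report
}

#' Write a study report bundle to disk
#'
#' Emits, per tracer, the method-comparison table as CSV and JSON; the tidy
#' per-phantom quantifications; the observer-study summary and raw values;
#' and a run manifest (configuration, seed, package and R versions — no
#' timestamps, so identical runs yield byte-identical files).
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory, created if missing.
#' @return named vector of file paths, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(quantifications = file.path(out_dir, "quantifications.csv"),
             manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(report$quantifications, paths["quantifications"],
                   row.names = FALSE)
  for (tr in names(report$comparisons)) {
    pc <- file.path(out_dir, sprintf("comparison_%s.csv", tr))
    pj <- file.path(out_dir, sprintf("comparison_%s.json", tr))
    utils::write.csv(as.data.frame(report$comparisons[[tr]]), pc,
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(report$comparisons[[tr]]), pj,
                         digits = NA, pretty = TRUE)
    paths[paste0("comparison_", tr, "_csv")] <- pc
    paths[paste0("comparison_", tr, "_json")] <- pj
  }
  if (!is.null(report$observer_study)) {
    ps <- file.path(out_dir, "observer_rsd.csv")
    pr <- file.path(out_dir, "observer_raw.csv")
    utils::write.csv(report$observer_study$summary, ps, row.names = FALSE)
    utils::write.csv(report$observer_study$raw, pr, row.names = FALSE)
    paths["observer_rsd"] <- ps
    paths["observer_raw"] <- pr
  }
  manifest <- list(
    config = unclass_recursive(report$config),
    package_version = as.character(utils::packageVersion("lobarquant")),
    r_version = R.version.string,
    welch_formula = "F* = sum(w_i (m_i - m_w)^2)/(k-1) / (1 + 2(k-2)/(k^2-1) Lambda); df2 = (k^2-1)/(3 Lambda)")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d phantoms, tracers: %s\n",
              x$config$n_phantoms, paste(x$config$tracers, collapse = ", ")))
  for (tr in names(x$comparisons)) {
    cat("\n== tracer", tr, "==\n")
    print(x$comparisons[[tr]])
  }
  if (!is.null(x$observer_study)) {
    cat("\n== interobserver variability ==\n")
    print(x$observer_study)
  }
  invisible(x)
}
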
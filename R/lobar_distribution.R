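#' Relative lobar tracer distribution
#'
#' Container for the relative distribution (%) of a tracer over the five
#' lung lobes, plus derived whole-lung percentages. The five lobe values sum
#' to 100; right lung = RUL + RML + RLL, left lung = LUL + LLL.
#'
#' @param lobes_pct numeric vector of 5 percentages, named or in the order
#'   RUL, RML, RLL, LUL, LLL.
#' @param tracer "V" or "Q".
#' @param method one of "planar", "lobar_3d", "truth" (or a free-form tag).
#' @param flags optional character vector of caveats (e.g. absent lobe after
#'   lobectomy, clipped background subtraction).
#' @return an object of class `lobar_distribution`.
#' @export
lobar_distribution <- function(lobes_pct, tracer = "V", method = "truth",
                               flags = character()) {
  lobes <- normalize_lobe_vector(lobes_pct, "lobes_pct")
  names(lobes) <- lobe_names
  if (any(lobes < -1e-9) || any(lobes > 100 + 1e-9))
    stop("lobe percentages must lie in [0, 100]")
  if (abs(sum(lobes) - 100) > 1e-6)
    stop("lobe percentages must sum to 100 (got ", format(sum(lobes)), ")")
  structure(list(lobes = lobes,
                 right = sum(lobes[1:3]),
                 left = sum(lobes[4:5]),
                 tracer = tracer, method = method, flags = flags),
            class = "lobar_distribution")
}

#' Region names reported in study tables: five lobes plus both whole lungs.
#' @export
region_names <- c(lobe_names, "right_lung", "left_lung")

#' Extract the seven reported region percentages
#' @param x a `lobar_distribution`.
#' @return named numeric vector over [region_names].
#' @export
region_percentages <- function(x) {
  stopifnot(inherits(x, "lobar_distribution"))
  c(x$lobes, right_lung = x$right, left_lung = x$left)
}

#' @export
print.lobar_distribution <- function(x, ...) {
  cat(sprintf("<lobar_distribution> tracer=%s method=%s\n", x$tracer, x$method))
  print(round(region_percentages(x), 2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.lobar_distribution <- function(x, ...) {
  data.frame(region = region_names,
             percent = unname(region_percentages(x)),
             tracer = x$tracer, method = x$method,
             stringsAsFactors = FALSE)
}

#' Bind a list of lobar distributions into one tidy data frame
#' @param distributions list of `lobar_distribution` objects.
#' @param phantom optional vector of phantom identifiers (recycled).
#' @param observer optional vector of observer identifiers (recycled).
#' @return data frame with columns phantom, observer (if given), region,
#'   percent, tracer, method.
#' @export
bind_distributions <- function(distributions, phantom = NULL, observer = NULL) {
  rows <- lapply(seq_along(distributions), function(i) {
    df <- as.data.frame(distributions[[i]])
    if (!is.null(phantom))
      df$phantom <- rep_len(phantom, length(distributions))[i]
    if (!is.null(observer))
      df$observer <- rep_len(observer, length(distributions))[i]
    df
  })
  do.call(rbind, rows)
}
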
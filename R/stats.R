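#' Welch's heteroscedastic one-way ANOVA
#'
#' One-way analysis of variance robust to unequal group variances. With
#' groups i = 1..k of sizes n_i, means m_i and variances s_i^2, let
#' w_i = n_i / s_i^2, W = sum(w_i), and m_w = sum(w_i m_i) / W. Then
#' \deqn{F^* = \frac{\sum_i w_i (m_i - m_w)^2 / (k-1)}
#'                  {1 + \frac{2(k-2)}{k^2-1} \Lambda},\quad
#'       \Lambda = \sum_i \frac{(1 - w_i/W)^2}{n_i - 1},}
#' with df1 = k - 1 and df2 = (k^2 - 1) / (3 Lambda); the p-value is the
#' upper tail of the F(df1, df2) distribution. For k = 2 the statistic is
#' the square of the Welch two-sample t statistic.
#'
#' @param x list of numeric samples (one per group), or a numeric vector.
#' @param g grouping factor when `x` is a vector.
#' @return list of class `welch_anova` with `statistic`, `df1`, `df2`,
#'   `p.value`, and per-group summaries.
#' @export
welch_anova <- function(x, g = NULL) {
  groups <- if (is.list(x)) x else split(as.numeric(x), g)
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_len(k))
  n <- vapply(groups, length, numeric(1))
  if (any(n < 2L)) stop("every group needs n >= 2")
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v <= 0))
    stop("zero variance in group(s): ",
         paste(names(groups)[v <= 0], collapse = ", "))
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (n - 1))
  Fstar <- A / (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- stats::pf(Fstar, df1, df2, lower.tail = FALSE)
  structure(list(statistic = Fstar, df1 = df1, df2 = df2, p.value = p,
                 n = n, means = m, variances = v),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch one-way ANOVA: F* = %.4g, df = (%d, %.2f), p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' Mean with a 95% t confidence interval
#'
#' `mean +/- t(0.975, n-1) * s / sqrt(n)`.
#'
#' @param x numeric sample (n >= 2).
#' @param conf confidence level (default 0.95).
#' @return named numeric `c(mean, lo, hi)`.
#' @export
mean_ci95 <- function(x, conf = 0.95) {
  n <- length(x)
  if (n < 2L) stop("need n >= 2 for a confidence interval")
  m <- mean(x)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Compare quantification methods region by region
#'
#' For every region (five lobes plus both whole lungs) and tracer, computes
#' each method's mean, 95% CI, and min-max range across phantoms, plus a
#' Welch one-way ANOVA across methods with a significance flag at `alpha`.
#' Output rows follow the layout of a clinical lobar-quantification report
#' table. Raw p-values are reported; no multiple-testing correction is
#' applied across regions.
#'
#' @param df tidy data frame with columns phantom, method, tracer, region,
#'   percent (as from [bind_distributions()] or the pipeline).
#' @param methods methods to compare (default: all in `df`).
#' @param alpha significance level (default 0.05).
#' @return data frame of class `method_comparison` with one row per
#'   region x tracer x method plus shared test columns F, df1, df2, p,
#'   significant.
#' @export
compare_methods <- function(df, methods = NULL, alpha = 0.05) {
  stopifnot(all(c("phantom", "method", "tracer", "region", "percent")
                %in% names(df)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(methods)) methods <- sort(unique(df$method))
  df <- df[df$method %in% methods, ]
  phantom_sets <- tapply(df$phantom, df$method,
                         function(p) paste(sort(unique(p)), collapse = ","))
  if (length(unique(phantom_sets)) != 1L)
    stop("all methods must be measured on the same phantom set")
  out <- list()
  for (tr in sort(unique(df$tracer))) {
    for (rg in intersect(region_names, unique(df$region))) {
      sub <- df[df$tracer == tr & df$region == rg, ]
      sub <- sub[order(sub$phantom), ]
      groups <- lapply(methods, function(mm) sub$percent[sub$method == mm])
      names(groups) <- methods
      wa <- welch_anova(groups)
      for (mm in methods) {
        x <- groups[[mm]]
        ci <- mean_ci95(x)
        out[[length(out) + 1L]] <- data.frame(
          region = rg, tracer = tr, method = mm,
          n = length(x), mean = ci[["mean"]],
          ci_low = ci[["lo"]], ci_high = ci[["hi"]],
          min = min(x), max = max(x),
          F = wa$statistic, df1 = wa$df1, df2 = wa$df2, p = wa$p.value,
          significant = wa$p.value < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("method_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  y <- x
  for (col in c("mean", "ci_low", "ci_high", "min", "max", "F"))
    y[[col]] <- round(y[[col]], 2)
  y$p <- signif(y$p, 3)
  print.data.frame(y, row.names = FALSE)
  cat(sprintf("alpha = %.3g; raw per-region p-values (no multiplicity correction)\n",
              attr(x, "alpha")))
  invisible(x)
}
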
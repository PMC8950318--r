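#' Encode a dose series for correlation and regression
#'
#' The catecholamine doses are decade-spaced with a zero (0, 0.5, 5, 50 µM),
#' so a raw-scale correlation would be dominated by the top dose. The
#' default ordinal encoding maps the sorted unique doses to 0, 1, 2, ...;
#' `"log10"` uses `log10(dose + delta)`; `"raw"` returns the doses
#' unchanged.
#'
#' @param doses Non-negative concentrations including 0.
#' @param encoding One of `"ordinal"`, `"log10"`, `"raw"`.
#' @param delta Offset for the log encoding (default: smallest nonzero dose
#'   / 10).
#' @return Numeric vector of encoded values, aligned with `doses`.
#' @examples
#' encode_dose(c(0, 0.5, 5, 50))
#' @export
encode_dose <- function(doses, encoding = c("ordinal", "log10", "raw"),
                        delta = NULL) {
  encoding <- match.arg(encoding)
  if (any(doses < 0)) abort("doses must be non-negative")
  switch(encoding,
    ordinal = match(doses, sort(unique(doses))) - 1,
    log10 = {
      delta <- delta %||% (min(doses[doses > 0]) / 10)
      log10(doses + delta)
    },
    raw = doses
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the usual t-transform p-value, as used
#' to associate feature responses with catecholamine levels.
#'
#' @param x,y Paired numeric vectors, at least 3 points, both with nonzero
#'   variance.
#' @param alternative Passed to [stats::cor.test()].
#' @return A tibble `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need >= 3 paired points")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: an input is constant")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = alternative)
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Wald test for an ordinary least-squares slope
#'
#' Fits `y ~ x` and reports the slope with the two-sided p-value of the
#' Wald test of slope = 0. A zero-residual exact fit reports p = 0.
#'
#' @param x,y Paired numeric vectors, at least 3 points; `x` non-constant.
#' @return A tibble `slope`, `se`, `p`, `n`.
#' @export
wald_slope_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) abort("need >= 3 points")
  if (sd(x) == 0) abort("x is constant: slope undefined")
  if (sd(y) == 0) {
    return(tibble(slope = 0, se = 0, p = 1, n = length(x)))
  }
  fit <- suppressWarnings(summary(lm(y ~ x)))$coefficients
  if (nrow(fit) < 2) abort("slope could not be estimated")
  slope <- fit["x", "Estimate"]
  p <- fit["x", "Pr(>|t|)"]
  # a zero-residual exact fit has se = 0 and an undefined t; report p = 0
  if (!is.finite(p)) p <- if (slope == 0) 1 else 0
  tibble(slope = slope, se = fit["x", "Std. Error"], p = p, n = length(x))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups: exact-distribution
#' p-values when both groups have at most 8 untied observations, the
#' normal approximation with tie and continuity correction otherwise.
#' `U` counts pairs where a group-a value exceeds a group-b value, so
#' swapping groups maps `U` to `n1*n2 - U`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of `group_a` relative to `group_b`).
#' @return A tibble `U`, `p`, `n_a`, `n_b`, `median_a`, `median_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
#' @export
mann_whitney_u <- function(group_a, group_b, alternative = "two.sided") {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !has_ties && length(group_a) <= 8 && length(group_b) <= 8
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = alternative,
                exact = exact, correct = TRUE)
  )
  tibble(U = unname(wt$statistic), p = wt$p.value,
         n_a = length(group_a), n_b = length(group_b),
         median_a = median(group_a), median_b = median(group_b))
}

# Vectorised Pearson + OLS Wald statistics of every column of y against x.
# Same closed forms as pearson_r()/wald_slope_test(), computed by matrix
# algebra so feature tables stay fast; constant columns report r = 0, p = 1.
dose_association <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- sweep(y, 2, colMeans(y))
  syy <- colSums(yc^2)
  sxy <- as.vector(crossprod(xc, yc))
  const <- syy == 0

  r <- ifelse(const, 0, sxy / sqrt(sxx * pmax(syy, .Machine$double.xmin)))
  r <- pmin(pmax(r, -1), 1)
  t_r <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  r_p <- ifelse(const, 1, 2 * pt(-abs(t_r), n - 2))

  slope <- sxy / sxx
  rss <- pmax(syy - sxy^2 / sxx, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  t_w <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  wald_p <- ifelse(const, 1, 2 * pt(-abs(t_w), n - 2))

  tibble(r = unname(r), r_p = unname(r_p),
         slope = unname(ifelse(const, 0, slope)), wald_p = unname(wald_p))
}

#' Select dose-responding features
#'
#' Applies the joint selection rule for dose-responders: a feature is
#' selected if, at the 4 h or the 24 h time point, it shows (i) a maximum
#' absolute log2 fold change above `lfc_threshold` across treated doses,
#' (ii) an absolute Pearson correlation of log2 intensity with encoded dose
#' above `r_threshold` with p below `alpha`, and (iii) a significant Wald
#' test of the regression slope of log2 intensity on encoded dose
#' (p below `alpha`). Correlation and regression pool all donors within the
#' time point.
#'
#' @param fc Long fold-change table from [log2_fold_change()].
#' @param table The [sample_table()] the fold changes came from (normally
#'   after [quantile_normalize()]).
#' @param lfc_threshold Minimum max |log2 FC| (default 1, i.e. twofold).
#' @param r_threshold Minimum |Pearson r| (default 0.8).
#' @param alpha Significance level for both tests (default 0.05).
#' @param dose_encoding Dose encoding for correlation/regression, see
#'   [encode_dose()].
#' @param times Treated time points at which the gates are evaluated.
#' @param pseudo Pseudo-intensity for the log2 transform of intensities
#'   (default as in [log2_fold_change()]).
#' @return A tibble of class `cf_responders`: one row per feature x time
#'   with `max_abs_lfc`, `r`, `r_p`, `slope`, `wald_p`, `pass` (gates met at
#'   that time) and `selected` (gates met at any time, constant per
#'   feature).
#' @export
select_responders <- function(fc, table, lfc_threshold = 1,
                              r_threshold = 0.8, alpha = 0.05,
                              dose_encoding = "ordinal",
                              times = c(4, 24), pseudo = NULL) {
  table <- sample_table(table)
  if (lfc_threshold < 0 || r_threshold < 0 || r_threshold > 1 ||
      alpha <= 0 || alpha > 1) {
    abort("thresholds outside valid ranges")
  }
  feats <- feature_cols(table)
  if (!setequal(unique(fc$feature), feats)) {
    abort("fold-change table and sample table disagree on features")
  }
  times <- intersect(times, unique(table$time))
  if (length(times) == 0) abort("no requested time point present")

  m <- intensity_matrix(table)
  if (is.null(pseudo)) {
    nz <- m[m > 0]
    pseudo <- if (length(nz) > 0) min(nz) / 2 else 0
  }

  max_lfc <- fc |>
    dplyr::filter(.data$time %in% times, .data$dose > 0) |>
    dplyr::group_by(.data$feature, .data$time) |>
    dplyr::summarise(max_abs_lfc = max(abs(.data$lfc)), .groups = "drop")

  stats_tbl <- purrr::map_dfr(times, function(t) {
    idx <- table$time == t
    x <- encode_dose(table$dose[idx], dose_encoding)
    logm <- log2(m[idx, , drop = FALSE] + pseudo)
    dose_association(x, logm) |>
      dplyr::mutate(feature = feats, time = t, .before = 1)
  })

  res <- max_lfc |>
    dplyr::inner_join(stats_tbl, by = c("feature", "time")) |>
    dplyr::mutate(pass = .data$max_abs_lfc > lfc_threshold &
                    abs(.data$r) > r_threshold & .data$r_p < alpha &
                    .data$wald_p < alpha) |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(selected = any(.data$pass)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$feature, .data$time)
  class(res) <- c("cf_responders", class(res))
  res
}

#' @export
glance.cf_responders <- function(x, ...) {
  tibble(n_features = dplyr::n_distinct(x$feature),
         n_selected = dplyr::n_distinct(x$feature[x$selected]),
         n_times = dplyr::n_distinct(x$time))
}

#' Feature identifiers selected as dose-responders
#'
#' @param x A `cf_responders` tibble from [select_responders()].
#' @return Character vector of selected feature ids.
#' @export
selected_features <- function(x) {
  sort(unique(x$feature[x$selected]))
}

#' @export
autoplot.cf_responders <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$r, y = .data$max_abs_lfc,
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$time), labeller = "label_both") +
    ggplot2::labs(x = "Pearson r (log2 intensity vs encoded dose)",
                  y = "max |log2 FC| across treated doses",
                  colour = "selected") +
    ggplot2::theme_minimal()
}
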
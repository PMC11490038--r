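#' Descriptive statistics for a viability series
#'
#' Mean with sample standard deviation (n - 1 denominator) and median with
#' interquartile range (Q3 - Q1, linear interpolation between order
#' statistics, i.e. quantile type 7).
#'
#' @param values numeric vector, at least one finite value.
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `iqr`.
#' @export
#' @examples
#' descriptives(c(1, 2, 3, 4, 5))
descriptives <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("descriptives() needs at least one finite value",
                            call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = stats::sd(values),
    median = stats::median(values),
    iqr = q[2] - q[1]
  )
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around [stats::shapiro.test()] used to document departure from
#' normality; the downstream comparisons are nonparametric regardless of the
#' outcome. Constant input is reported as degenerate rather than an error.
#'
#' @param values numeric vector with 3 to 5000 finite values.
#' @return One-row tibble: `statistic`, `p_value`, `n`, `degenerate`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("shapiro_wilk() needs between 3 and 5000 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          n = length(values), degenerate = TRUE))
  }
  fit <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(fit$statistic),
                 p_value = fit$p.value,
                 n = length(values), degenerate = FALSE)
}

#' Two-sided Wilcoxon test, paired or unpaired
#'
#' Paired mode is the signed-rank test (zero differences dropped, ties
#' mid-ranked); unpaired mode the rank-sum test. The exact null distribution
#' is used when the effective sample size is at most 29 and the data carry no
#' ties (nor zero differences); otherwise the normal approximation with
#' continuity correction applies. The method actually used is recorded in the
#' result. Degenerate paired input (all differences zero) is flagged with
#' p = 1.
#'
#' @param x,y numeric vectors; equal length required for paired mode.
#' @param mode `"paired"` or `"unpaired"`.
#' @param exact logical override of the automatic exact/approximate switch.
#' @return One-row tibble: `statistic` (V for paired, W for unpaired),
#'   `p_value`, `n` (pairs after zero removal, or `n1 + n2`), `method`,
#'   `degenerate`.
#' @export
#' @examples
#' wilcoxon_test(c(1, 2, 3), c(4, 5, 6), mode = "unpaired")$p_value  # 0.1
wilcoxon_test <- function(x, y, mode = c("paired", "unpaired"), exact = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), is.numeric(y))
  if (mode == "paired") {
    if (length(x) != length(y)) {
      stop("paired mode requires equal-length vectors", call. = FALSE)
    }
    d <- x - y
    d <- d[is.finite(d)]
    nz <- d[d != 0]
    if (!length(nz)) {
      return(tibble::tibble(statistic = NA_real_, p_value = 1,
                            n = 0L, method = "degenerate", degenerate = TRUE))
    }
    has_ties <- anyDuplicated(abs(nz)) > 0 || length(nz) < length(d)
    use_exact <- if (is.null(exact)) length(nz) <= 29 && !has_ties else exact
    fit <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = use_exact,
                         correct = TRUE, alternative = "two.sided")
    )
    n_eff <- length(nz)
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    has_ties <- anyDuplicated(c(x, y)) > 0
    use_exact <- if (is.null(exact)) max(length(x), length(y)) <= 29 && !has_ties else exact
    fit <- suppressWarnings(
      stats::wilcox.test(x, y, paired = FALSE, exact = use_exact,
                         correct = TRUE, alternative = "two.sided")
    )
    n_eff <- length(x) + length(y)
  }
  tibble::tibble(
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    n = as.integer(n_eff),
    method = if (use_exact && !has_ties) "exact" else "normal_approx",
    degenerate = FALSE
  )
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / k`, optionally truncated to a fixed number of decimals for report
#' display (0.05 over a family of 6 displays as 0.008).
#'
#' @param alpha familywise level in (0, 1).
#' @param k family size, at least 1.
#' @param decimals decimal places for display truncation, or `NULL` (default)
#'   for the full-precision threshold.
#' @return The per-comparison threshold.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 5)               # 0.01
#' bonferroni_alpha(0.05, 6, decimals = 3) # 0.008
bonferroni_alpha <- function(alpha, k, decimals = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (k < 1) stop("family size k must be at least 1", call. = FALSE)
  out <- alpha / k
  if (!is.null(decimals)) out <- trunc(out * 10^decimals) / 10^decimals
  out
}

#' Format a p-value the way the comparison reports print it
#'
#' Four significant figures, switching to scientific notation below 1e-4.
#' @param p numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, sprintf("%.4e", p), sprintf("%.4f", p)))
}
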
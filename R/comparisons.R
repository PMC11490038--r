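intra_pairs <- function() {
  post <- setdiff(bv_timepoints(), "BASAL")
  rbind(
    data.frame(a = "BASAL", b = post),
    data.frame(a = "5MIN", b = setdiff(post, "5MIN"))
  )
}

pull_bv <- function(table, gel, timepoint) {
  sel <- table[table$gel == gel & table$timepoint == timepoint, , drop = FALSE]
  sel <- sel[order(sel$subject_id), , drop = FALSE]
  stats::setNames(sel$bv_pct, sel$subject_id)
}

#' Run the intra- and inter-gel comparison families
#'
#' Reproduces the comparison structure of a two-gel substantivity trial on a
#' long-format viability table. Per gel, paired (signed-rank) Wilcoxon tests
#' compare baseline against every post-application time and the five-minute
#' sample against every later time (nine pairs per gel); per timepoint, an
#' independent (rank-sum) Wilcoxon test compares the two gels. Each family is
#' judged against its Bonferroni-adjusted level: `alpha / intra_family`
#' (default 0.05/5 = 0.01) within gels and `alpha / inter_family` (default
#' 0.05/6, displayed 0.008) between gels.
#'
#' @param table tibble with columns `subject_id`, `gel`, `timepoint`,
#'   `bv_pct` (one row per subject x gel x timepoint; filter to one
#'   experiment/layer first).
#' @param alpha familywise level (default 0.05).
#' @param intra_family,inter_family Bonferroni family sizes (defaults 5
#'   and 6).
#' @param alpha_decimals display truncation of the adjusted thresholds
#'   (default 3).
#' @param paired_inter use paired tests between gels (the crossover design
#'   would permit it); off by default, matching the independent-samples
#'   convention.
#' @return A `bv_comparisons` tibble: `family`, `gel`, `pair`, `test`, `n`,
#'   `statistic`, `p_value`, `method`, `adjusted_alpha`, `significant`.
#'   Missing design cells are skipped with a warning.
#' @export
run_comparisons <- function(table, alpha = 0.05, intra_family = 5,
                            inter_family = 6, alpha_decimals = 3,
                            paired_inter = FALSE) {
  stopifnot(all(c("subject_id", "gel", "timepoint", "bv_pct") %in% names(table)))
  table <- dplyr::filter(table, !is.na(.data$bv_pct))
  alpha_intra <- bonferroni_alpha(alpha, intra_family)
  alpha_inter <- bonferroni_alpha(alpha, inter_family)
  rows <- list()
  skipped <- character()

  for (gel in intersect(bv_gels(), unique(as.character(table$gel)))) {
    pairs <- intra_pairs()
    for (k in seq_len(nrow(pairs))) {
      a <- pull_bv(table, gel, pairs$a[k])
      b <- pull_bv(table, gel, pairs$b[k])
      common <- intersect(names(a), names(b))
      label <- paste(pairs$a[k], "vs", pairs$b[k])
      if (length(common) < 2) {
        skipped <- c(skipped, paste0(gel, ": ", label))
        next
      }
      fit <- wilcoxon_test(a[common], b[common], mode = "paired")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = "INTRA_GEL", gel = gel, pair = label, test = "paired",
        n = fit$n, statistic = fit$statistic, p_value = fit$p_value,
        method = fit$method, adjusted_alpha = alpha_intra,
        significant = fit$p_value < alpha_intra
      )
    }
  }

  gels_present <- intersect(bv_gels(), unique(as.character(table$gel)))
  if (length(gels_present) == 2) {
    for (tp in bv_timepoints()) {
      a <- pull_bv(table, "TEST", tp)
      b <- pull_bv(table, "CONTROL", tp)
      if (paired_inter) {
        common <- intersect(names(a), names(b))
        ok <- length(common) >= 2
        if (ok) fit <- wilcoxon_test(a[common], b[common], mode = "paired")
      } else {
        ok <- length(a) >= 2 && length(b) >= 2
        if (ok) fit <- wilcoxon_test(a, b, mode = "unpaired")
      }
      if (!ok) {
        skipped <- c(skipped, paste0("TEST vs CONTROL at ", tp))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = "INTER_GEL", gel = NA_character_,
        pair = paste("TEST vs CONTROL at", tp),
        test = if (paired_inter) "paired" else "unpaired",
        n = fit$n, statistic = fit$statistic, p_value = fit$p_value,
        method = fit$method, adjusted_alpha = alpha_inter,
        significant = fit$p_value < alpha_inter
      )
    }
  } else {
    skipped <- c(skipped, "inter-gel family (single gel present)")
  }

  if (length(skipped)) {
    warning("skipped comparison(s): ", paste(skipped, collapse = "; "),
            call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  attr(out, "alpha_intra") <- alpha_intra
  attr(out, "alpha_inter") <- alpha_inter
  attr(out, "alpha_decimals") <- alpha_decimals
  class(out) <- c("bv_comparisons", class(out))
  out
}

#' @rdname run_comparisons
#' @param x a `bv_comparisons` table.
#' @param ... unused.
#' @method tidy bv_comparisons
#' @export
tidy.bv_comparisons <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "bv_comparisons")
  attr(out, "alpha") <- NULL
  attr(out, "alpha_intra") <- NULL
  attr(out, "alpha_inter") <- NULL
  attr(out, "alpha_decimals") <- NULL
  out
}

#' @rdname run_comparisons
#' @method glance bv_comparisons
#' @export
glance.bv_comparisons <- function(x, ...) {
  dec <- attr(x, "alpha_decimals")
  tibble::tibble(
    n_comparisons = nrow(x),
    n_intra = sum(x$family == "INTRA_GEL"),
    n_inter = sum(x$family == "INTER_GEL"),
    n_significant_intra = sum(x$significant[x$family == "INTRA_GEL"]),
    n_significant_inter = sum(x$significant[x$family == "INTER_GEL"]),
    alpha = attr(x, "alpha"),
    alpha_intra = attr(x, "alpha_intra"),
    alpha_inter_display = trunc(attr(x, "alpha_inter") * 10^dec) / 10^dec
  )
}

#' Render a trial table and its comparisons as text
#'
#' Produces the familiar report layout: one descriptives block per gel
#' (mean +/- SD and median (IQR) at each sampling time), the intra-gel
#' significance row per gel (nine pairwise tests) and the inter-gel row (one
#' test per timepoint), with p-values at display precision and `NS` marking
#' non-significance at the family's adjusted level.
#'
#' @param table long-format viability table (one experiment/layer).
#' @param comparisons a `bv_comparisons` result for the same table; computed
#'   if omitted.
#' @param title heading line.
#' @return Character vector of report lines (print with `cat(..., sep =
#'   "\n")`).
#' @export
format_trial_table <- function(table, comparisons = NULL,
                               title = "BACTERIAL VIABILITY") {
  if (is.null(comparisons)) {
    comparisons <- suppressWarnings(run_comparisons(table))
  }
  dec <- attr(comparisons, "alpha_decimals") %||% 3
  lines <- c(title, strrep("-", nchar(title)))
  for (gel in intersect(bv_gels(), unique(as.character(table$gel)))) {
    lines <- c(lines, paste0("[", gel, "] mean +/- SD | median (IQR)"))
    for (tp in bv_timepoints()) {
      v <- table$bv_pct[table$gel == gel & table$timepoint == tp]
      v <- v[!is.na(v)]
      if (!length(v)) next
      d <- descriptives(v)
      lines <- c(lines, sprintf("  %-6s %6.2f%% +/- %5.2f%% | %6.2f%% (%5.2f%%)",
                                tp, d$mean, d$sd, d$median, d$iqr))
    }
  }
  sig_label <- function(row) {
    if (!row$significant) "NS" else paste0("p = ", format_p(row$p_value))
  }
  intra <- comparisons[comparisons$family == "INTRA_GEL", , drop = FALSE]
  if (nrow(intra)) {
    lines <- c(lines, sprintf(
      "INTRA-GEL (paired Wilcoxon, significance level p < %s)",
      format(attr(comparisons, "alpha_intra"))))
    for (gel in unique(intra$gel)) {
      sel <- intra[intra$gel == gel, , drop = FALSE]
      lines <- c(lines, paste0("  [", gel, "]"))
      for (k in seq_len(nrow(sel))) {
        lines <- c(lines, sprintf("    %-14s %s", sel$pair[k], sig_label(sel[k, ])))
      }
    }
  }
  inter <- comparisons[comparisons$family == "INTER_GEL", , drop = FALSE]
  if (nrow(inter)) {
    lines <- c(lines, sprintf(
      "INTER-GEL (independent Wilcoxon, significance level p < %s)",
      format(trunc(attr(comparisons, "alpha_inter") * 10^dec) / 10^dec)))
    for (k in seq_len(nrow(inter))) {
      lines <- c(lines, sprintf("    %-26s %s", inter$pair[k], sig_label(inter[k, ])))
    }
  }
  lines
}
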
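# Simulated crossover substantivity trials: correlated truncated-normal BV
# trajectories per subject, parameterised by per-(gel, timepoint) summary
# statistics.

#' Built-in viability summary statistics of a gel substantivity trial
#'
#' Per-(gel, timepoint) mean and SD of bacterial viability (%) describing the
#' trajectory of a single-application chlorhexidine-gel crossover trial in
#' each niche and biofilm layer: high viability at baseline (roughly 84--91%),
#' a collapse five minutes after application (strongest in biofilm, to a few
#' percent) and slow partial recovery over seven hours, with the TEST
#' (chlorhexidine + cymenol) and CONTROL (chlorhexidine) products closely
#' matched throughout. These are the default parameters of
#' [generate_trial()].
#'
#' @param experiment `"SALIVA"` or `"BIOFILM"`.
#' @param layer for biofilm: `"FULL"` (default), `"UPPER"` or `"LOWER"`.
#' @return Tibble with columns `gel`, `timepoint`, `mean`, `sd`.
#' @export
reference_summaries <- function(experiment = c("SALIVA", "BIOFILM"),
                                layer = c("FULL", "UPPER", "LOWER")) {
  experiment <- match.arg(experiment)
  layer <- match.arg(layer)
  key <- if (experiment == "SALIVA") "SALIVA" else paste0("BIOFILM_", layer)
  vals <- switch(key,
    SALIVA = list(
      TEST = list(mean = c(87.00, 26.50, 28.90, 34.20, 36.90, 40.40),
                  sd = c(6.90, 8.20, 6.50, 16.00, 16.90, 18.60)),
      CONTROL = list(mean = c(88.90, 31.60, 36.00, 33.40, 40.10, 37.50),
                     sd = c(8.90, 24.70, 22.10, 14.50, 18.40, 18.10))),
    BIOFILM_FULL = list(
      TEST = list(mean = c(91.00, 5.80, 3.70, 7.10, 12.50, 21.30),
                  sd = c(7.60, 14.70, 9.70, 9.30, 16.50, 22.10)),
      CONTROL = list(mean = c(88.40, 7.40, 5.30, 11.80, 12.60, 14.30),
                     sd = c(10.30, 15.20, 10.60, 21.10, 17.70, 18.70))),
    BIOFILM_UPPER = list(
      TEST = list(mean = c(91.29, 3.94, 5.42, 8.02, 10.87, 24.13),
                  sd = c(7.79, 10.73, 12.38, 10.14, 16.16, 25.65)),
      CONTROL = list(mean = c(89.26, 9.16, 7.44, 14.37, 12.65, 15.96),
                     sd = c(10.21, 19.77, 14.24, 24.60, 18.17, 22.69))),
    BIOFILM_LOWER = list(
      TEST = list(mean = c(86.29, 3.83, 9.04, 8.20, 13.08, 22.06),
                  sd = c(12.87, 11.28, 23.06, 10.71, 17.83, 27.65)),
      CONTROL = list(mean = c(83.81, 7.82, 8.71, 10.17, 10.58, 10.45),
                     sd = c(18.31, 19.24, 18.24, 18.51, 18.59, 18.62)))
  )
  dplyr::bind_rows(lapply(names(vals), function(g) {
    tibble::tibble(gel = g, timepoint = bv_timepoints(),
                   mean = vals[[g]]$mean, sd = vals[[g]]$sd)
  }))
}

#' Specification of a simulated crossover trial
#'
#' @param n_subjects subjects (default 29); each receives both gels
#'   (crossover).
#' @param summaries tibble of per-(gel, timepoint) `mean` and `sd` of BV%,
#'   defaults to [reference_summaries()] for `experiment`/`layer`.
#' @param rho within-subject correlation of the BV draws in `[0, 1)`,
#'   induced by a shared additive subject effect (default 0.5).
#' @param experiment,layer design labels carried into the output table and
#'   used for the default `summaries`.
#' @return A list of class `bv_trial_spec`.
#' @export
trial_spec <- function(n_subjects = 29, summaries = NULL, rho = 0.5,
                       experiment = c("SALIVA", "BIOFILM"),
                       layer = c("FULL", "UPPER", "LOWER")) {
  experiment <- match.arg(experiment)
  layer <- match.arg(layer)
  if (is.null(summaries)) summaries <- reference_summaries(experiment, layer)
  stopifnot(n_subjects >= 2, rho >= 0, rho < 1,
            all(c("gel", "timepoint", "mean", "sd") %in% names(summaries)),
            all(summaries$mean >= 0), all(summaries$mean <= 100),
            all(summaries$sd > 0))
  structure(list(n_subjects = n_subjects, summaries = summaries, rho = rho,
                 experiment = experiment, layer = layer),
            class = "bv_trial_spec")
}

#' Simulate a crossover trial viability table
#'
#' Per subject and gel, viability at each timepoint is drawn as
#' `mean + sd * (sqrt(rho) * u + sqrt(1 - rho) * e)` with a standard-normal
#' subject effect `u` (shared across all of that subject's draws, inducing
#' within-subject correlation `rho`) and independent noise `e`, then clamped
#' to `[0, 100]`. Deterministic for a fixed seed.
#'
#' @param spec a [trial_spec()].
#' @param seed integer seed.
#' @return A list with `table` -- a long-format tibble (`subject_id`, `gel`,
#'   `experiment`, `timepoint`, `layer`, `bv_pct`) -- and `truth` (the
#'   generating summaries and `rho`).
#' @export
#' @examples
#' tr <- generate_trial(trial_spec(n_subjects = 8), seed = 1)
#' head(tr$table)
generate_trial <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "bv_trial_spec"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_trial(spec, seed = NULL)))
  }
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  u <- stats::setNames(stats::rnorm(spec$n_subjects), subjects)
  rows <- lapply(subjects, function(s) {
    g <- spec$summaries
    e <- stats::rnorm(nrow(g))
    z <- sqrt(spec$rho) * u[[s]] + sqrt(1 - spec$rho) * e
    tibble::tibble(
      subject_id = s,
      gel = g$gel,
      experiment = spec$experiment,
      timepoint = g$timepoint,
      layer = if (spec$experiment == "SALIVA") "FULL" else spec$layer,
      bv_pct = pmin(pmax(g$mean + g$sd * z, 0), 100)
    )
  })
  table <- dplyr::bind_rows(rows)
  table$timepoint <- factor(table$timepoint, levels = bv_timepoints())
  table$gel <- factor(table$gel, levels = bv_gels())
  list(table = table, truth = list(summaries = spec$summaries, rho = spec$rho))
}
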
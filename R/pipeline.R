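#' Run the full quantification and analysis pipeline
#'
#' Reads a sample manifest, quantifies every stack (classification,
#' epithelial-nucleus exclusion, slice gating, thickness and layers),
#' aggregates fields into samples, assembles the long-format trial table and
#' runs the intra-/inter-gel comparison families per experiment and layer.
#' Individual unreadable stacks are logged and skipped; the run continues and
#' the summary lists the failures. Output is deterministic for fixed inputs.
#'
#' @param manifest path to a manifest CSV (see [read_manifest()]) or an
#'   already-read manifest tibble.
#' @param config a [bv_config()] list or path to a YAML config.
#' @param out_dir output directory (created if needed); `NULL` skips writing
#'   and just returns the tables.
#' @return (Invisibly) a list of tibbles: `per_slice`, `per_field`,
#'   `per_sample`, `trial_table`, `comparisons`, `failures`; when `out_dir`
#'   is given each is written as CSV there, together with the resolved
#'   config (`config.yaml`, with its MD5 in `run_log.txt`) and a rendered
#'   text report per experiment/layer.
#' @export
run_pipeline <- function(manifest, config = bv_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (is.character(manifest)) manifest <- read_manifest(manifest)

  per_slice <- list()
  per_field <- list()
  failures <- list()
  fields_obj <- list()
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    res <- tryCatch({
      stack <- read_stack(row$path,
                          channel_map = config$channel_map,
                          slice_order = config$slice_order,
                          z_step_um = config$z_step_um,
                          pixel_size_um = config$pixel_size_um,
                          field_id = row$field_id)
      quantify_field(stack, config, experiment = as.character(row$experiment))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        subject_id = row$subject_id, gel = as.character(row$gel),
        experiment = as.character(row$experiment),
        timepoint = as.character(row$timepoint),
        field_id = row$field_id, path = row$path,
        error = conditionMessage(res))
      next
    }
    fields_obj[[length(fields_obj) + 1L]] <- list(row = row, field = res)
  }

  # harmonised layer mode re-splits biofilm fields with the common span
  if (config$layer_mode == "harmonised" && length(fields_obj)) {
    mfts <- dplyr::bind_rows(lapply(fields_obj, function(fo) {
      tibble::tibble(gel = as.character(fo$row$gel),
                     timepoint = as.character(fo$row$timepoint),
                     experiment = as.character(fo$row$experiment),
                     mft_um = fo$field$summary$mft_um)
    }))
    biofilm <- mfts[mfts$experiment == "BIOFILM", , drop = FALSE]
    if (nrow(biofilm)) {
      span <- harmonised_thickness(biofilm)
      fields_obj <- lapply(fields_obj, function(fo) {
        if (fo$field$experiment == "BIOFILM") fo$field <- relayer_field(fo$field, span)
        fo
      })
    }
  }

  for (fo in fields_obj) {
    row <- fo$row
    design <- tibble::tibble(subject_id = row$subject_id,
                             gel = as.character(row$gel),
                             experiment = as.character(row$experiment),
                             timepoint = as.character(row$timepoint))
    per_slice[[length(per_slice) + 1L]] <-
      dplyr::bind_cols(design, field_id = row$field_id, tidy(fo$field))
    per_field[[length(per_field) + 1L]] <-
      dplyr::bind_cols(design, glance(fo$field))
  }
  per_slice <- dplyr::bind_rows(per_slice)
  per_field <- dplyr::bind_rows(per_field)
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(subject_id = character(), gel = character(),
                   experiment = character(), timepoint = character(),
                   field_id = character(), path = character(),
                   error = character())
  per_sample <- if (nrow(per_field)) aggregate_samples(per_field) else
    tibble::tibble()

  trial_table <- build_trial_table(per_sample)
  comparisons <- run_all_comparisons(trial_table, config)

  out <- list(per_slice = per_slice, per_field = per_field,
              per_sample = per_sample, trial_table = trial_table,
              comparisons = comparisons, failures = failures)
  if (!is.null(out_dir)) write_pipeline_outputs(out, trial_table, config, out_dir)
  invisible(out)
}

#' Long-format trial table from sample summaries
#'
#' One row per subject x gel x experiment x timepoint x layer: `FULL` rows
#' carry the overall sample viability (for both niches) and, for biofilm,
#' `UPPER`/`LOWER` rows carry the layer means.
#'
#' @param per_sample tibble from [aggregate_samples()].
#' @return Trial-table tibble with `bv_pct` in `[0, 100]`.
#' @export
build_trial_table <- function(per_sample) {
  if (!nrow(per_sample)) {
    return(tibble::tibble(subject_id = character(), gel = character(),
                          experiment = character(), timepoint = character(),
                          layer = character(), bv_pct = double()))
  }
  base <- per_sample[!per_sample$missing, , drop = FALSE]
  full <- dplyr::transmute(base, .data$subject_id, .data$gel, .data$experiment,
                           .data$timepoint, layer = "FULL",
                           bv_pct = .data$mean_bv)
  layers <- base[base$experiment == "BIOFILM", , drop = FALSE]
  upper <- dplyr::transmute(layers, .data$subject_id, .data$gel,
                            .data$experiment, .data$timepoint, layer = "UPPER",
                            bv_pct = .data$upper_bv)
  lower <- dplyr::transmute(layers, .data$subject_id, .data$gel,
                            .data$experiment, .data$timepoint, layer = "LOWER",
                            bv_pct = .data$lower_bv)
  dplyr::bind_rows(full, upper, lower)
}

run_all_comparisons <- function(trial_table, config = bv_config()) {
  if (!nrow(trial_table)) return(tibble::tibble())
  combos <- dplyr::distinct(trial_table, .data$experiment, .data$layer)
  res <- lapply(seq_len(nrow(combos)), function(k) {
    sub <- trial_table[trial_table$experiment == combos$experiment[k] &
                         trial_table$layer == combos$layer[k], , drop = FALSE]
    cmp <- tryCatch(
      suppressWarnings(run_comparisons(
        sub, alpha = config$alpha, intra_family = config$intra_family,
        inter_family = config$inter_family,
        alpha_decimals = config$alpha_decimals)),
      error = function(e) NULL)
    if (is.null(cmp) || !nrow(cmp)) return(NULL)
    dplyr::bind_cols(tibble::tibble(experiment = combos$experiment[k],
                                    layer = combos$layer[k]),
                     tidy(cmp))
  })
  dplyr::bind_rows(res)
}

write_pipeline_outputs <- function(out, trial_table, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    df <- as.data.frame(df)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(out$per_slice, "per_slice.csv")
  wr(out$per_field, "per_field.csv")
  wr(out$per_sample, "per_sample.csv")
  wr(out$trial_table, "trial_table.csv")
  wr(out$comparisons, "comparisons.csv")
  wr(out$failures, "failures.csv")
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg <- unclass(config)
  cfg$channel_map <- as.list(cfg$channel_map)
  yaml::write_yaml(cfg, cfg_path)
  report <- character()
  combos <- if (nrow(trial_table)) {
    dplyr::distinct(trial_table, .data$experiment, .data$layer)
  } else tibble::tibble(experiment = character(), layer = character())
  for (k in seq_len(nrow(combos))) {
    sub <- trial_table[trial_table$experiment == combos$experiment[k] &
                         trial_table$layer == combos$layer[k], , drop = FALSE]
    lines <- tryCatch(
      suppressWarnings(format_trial_table(
        sub, title = sprintf("BACTERIAL VIABILITY - %s (%s layer)",
                             combos$experiment[k], combos$layer[k]))),
      error = function(e) character())
    report <- c(report, lines, "")
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  writeLines(c(
    sprintf("bvquant %s", as.character(utils::packageVersion("bvquant"))),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("fields quantified: %d", nrow(out$per_field)),
    sprintf("fields failed: %d", nrow(out$failures))
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Write a simulated stack (TIFF + ground-truth JSON) to disk
#'
#' @param spec a [stack_spec()].
#' @param tiff_path,truth_path output paths.
#' @param seed integer seed.
#' @return The generated object, invisibly.
#' @export
simulate_stack_files <- function(spec, tiff_path, truth_path, seed = 1) {
  gen <- generate_stack(spec, seed = seed)
  write_stack(gen$stack, tiff_path)
  truth <- gen$truth
  truth$nuclei <- lapply(seq_len(nrow(truth$nuclei)), function(k) {
    list(nucleus_id = truth$nuclei$nucleus_id[k],
         slice = truth$nuclei$slice[k],
         pixels = truth$nuclei$pixels[[k]])
  })
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(gen)
}

#' Write a simulated trial (CSV + ground-truth JSON) to disk
#'
#' @param spec a [trial_spec()].
#' @param csv_path,truth_path output paths.
#' @param seed integer seed.
#' @return The generated object, invisibly.
#' @export
simulate_trial_files <- function(spec, csv_path, truth_path, seed = 1) {
  gen <- generate_trial(spec, seed = seed)
  utils::write.csv(as.data.frame(gen$table), csv_path, row.names = FALSE)
  jsonlite::write_json(gen$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(gen)
}
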
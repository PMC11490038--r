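#' Per-slice viability with minimum-area gating
#'
#' Computes, for each optical section, the bacterial viability percentage
#' `100 * viable / (viable + non-viable)` and whether the section carries
#' enough bacterial aggregate area to enter field-level means. A slice is
#' included when its viable + non-viable pixel area reaches `min_area_um2`
#' (default 250 um^2, about 4,750 pixels at the default pixel size); slices
#' with no bacterial pixels have undefined viability and are never included.
#'
#' @param counts tibble of per-slice tallies ([class_counts()]); needs columns
#'   `viable_px` and `nonviable_px`.
#' @param pixel_size_um lateral pixel edge in um.
#' @param min_area_um2 inclusion gate in um^2 (default 250).
#' @return The input tibble with `aggregate_area_um2`, `bv_pct` and `included`
#'   appended.
#' @export
#' @examples
#' counts <- tibble::tibble(slice = 1L, viable_px = 75L, nonviable_px = 25L)
#' slice_viability(counts, pixel_size_um = 1)$bv_pct  # 75
slice_viability <- function(counts, pixel_size_um, min_area_um2 = 250) {
  stopifnot(pixel_size_um > 0, min_area_um2 > 0,
            all(c("viable_px", "nonviable_px") %in% names(counts)))
  dplyr::mutate(
    counts,
    aggregate_area_um2 = (.data$viable_px + .data$nonviable_px) * pixel_size_um^2,
    bv_pct = ifelse(.data$viable_px + .data$nonviable_px > 0,
                    100 * .data$viable_px / (.data$viable_px + .data$nonviable_px),
                    NA_real_),
    included = .data$aggregate_area_um2 >= min_area_um2
  )
}

#' Maximum field thickness (MFT)
#'
#' The MFT is the distance between the substrate and the peaks of the highest
#' bacterial cell clusters: with slices ordered surface to base, it spans from
#' the shallowest slice whose largest bacterial (viable or non-viable)
#' connected component reaches `min_aggregate_px` pixels down to the base,
#' `(n_slices - topmost + 1) * z_step_um`. Returns 0 when no slice qualifies.
#'
#' @param classmap a `bv_classmap`, ordered surface to base.
#' @param z_step_um slice spacing in um (defaults to the classmap metadata).
#' @param min_aggregate_px cluster-size gate in pixels (see
#'   [min_aggregate_px()]).
#' @param connectivity 4 or 8 for the cluster components.
#' @return Thickness in um.
#' @export
compute_mft <- function(classmap, z_step_um = classmap$z_step_um,
                        min_aggregate_px = bvquant::min_aggregate_px(),
                        connectivity = 8) {
  stopifnot(inherits(classmap, "bv_classmap"), min_aggregate_px >= 1)
  n <- length(classmap$labels)
  for (i in seq_len(n)) {
    mask <- classmap$labels[[i]] != CLASS_BACKGROUND
    if (!any(mask)) next
    if (sum(mask) < min_aggregate_px) next  # no component can reach the gate
    labels <- label_components(mask, connectivity)
    if (max(tabulate(labels[labels > 0L])) >= min_aggregate_px) {
      return((n - i + 1) * z_step_um)
    }
  }
  0
}

#' Split the MFT span into upper and lower layers
#'
#' The slices spanning the maximum field thickness are divided at MFT/2
#' measured from the surface: the surface half is the upper layer and the base
#' half the lower layer. With an odd number of in-span slices the middle slice
#' joins the upper layer. Slices above the span (no qualifying clusters yet)
#' carry `NA`.
#'
#' @param slices per-slice tibble (ordered surface to base, one row per
#'   slice, with a `slice` column).
#' @param mft_um maximum field thickness in um; 0 leaves every slice
#'   unassigned.
#' @param z_step_um slice spacing in um.
#' @return The input tibble with a `layer` column (`"UPPER"`, `"LOWER"` or
#'   `NA`).
#' @export
split_layers <- function(slices, mft_um, z_step_um) {
  stopifnot(z_step_um > 0, "slice" %in% names(slices))
  n <- nrow(slices)
  layer <- rep(NA_character_, n)
  n_span <- as.integer(round(mft_um / z_step_um))
  if (n_span > 0) {
    n_span <- min(n_span, n)
    top <- n - n_span + 1L
    n_upper <- ceiling(n_span / 2)
    layer[seq(top, length.out = n_upper)] <- "UPPER"
    if (n_span > n_upper) {
      layer[seq(top + n_upper, n)] <- "LOWER"
    }
  }
  dplyr::mutate(slices, layer = layer)
}

layer_mean <- function(slices, which_layer, mode = "slice_mean") {
  sel <- slices[slices$included & !is.na(slices$layer) &
                  slices$layer == which_layer, , drop = FALSE]
  if (!nrow(sel)) return(NA_real_)
  if (mode == "pixel_pooled") {
    return(100 * sum(sel$viable_px) / sum(sel$viable_px + sel$nonviable_px))
  }
  mean(sel$bv_pct)
}

#' Quantify one imaged field
#'
#' Runs the full per-field pipeline: pixel classification, epithelial-nucleus
#' exclusion (recording viability before and after), minimum-area slice
#' gating, maximum field thickness and the upper/lower layer split. For the
#' saliva experiment the stack is first collapsed to its overall
#' maximum-intensity projection and quantified as a single section (no
#' thickness or layers).
#'
#' @param stack a `bv_stack`.
#' @param config a [bv_config()] list.
#' @param experiment `"BIOFILM"` (default) or `"SALIVA"`.
#' @return A `bv_field` object; [tidy()] returns the per-slice table
#'   (`slice`, counts, `bv_before`, `bv_pct`, `aggregate_area_um2`,
#'   `included`, `layer`, `excluded_px`, `n_flagged`), [glance()] the one-row
#'   field summary (`field_id`, `n_slices`, `n_included`, `mean_bv`,
#'   `mean_bv_before`, `mft_um`, `upper_bv`, `lower_bv`, `field_excluded`).
#' @export
quantify_field <- function(stack, config = bv_config(),
                           experiment = c("BIOFILM", "SALIVA")) {
  stopifnot(inherits(stack, "bv_stack"))
  experiment <- match.arg(experiment)
  if (experiment == "SALIVA") stack <- project_stack(stack)
  cm <- classify_stack(stack, config$green_thr, config$red_thr)
  crit <- epithelial_criteria(config$epithelial$min_area_px,
                              config$epithelial$min_solidity,
                              config$epithelial$min_mean_intensity)
  excl <- remove_epithelial(cm, stack, crit, config$epithelial$connectivity)
  counts <- class_counts(excl$classmap)
  slices <- slice_viability(counts, config$pixel_size_um, config$min_area_um2)
  slices$bv_before <- excl$report$bv_before
  slices$excluded_px <- excl$report$excluded_px
  slices$n_flagged <- excl$report$n_flagged
  if (experiment == "BIOFILM") {
    mft <- compute_mft(excl$classmap, config$z_step_um,
                       min_aggregate_px(config),
                       config$epithelial$connectivity)
    slices <- split_layers(slices, mft, config$z_step_um)
  } else {
    mft <- NA_real_
    slices$layer <- NA_character_
  }
  inc <- slices[slices$included, , drop = FALSE]
  summary <- tibble::tibble(
    field_id = stack$field_id,
    n_slices = nrow(slices),
    n_included = nrow(inc),
    mean_bv = if (nrow(inc)) mean(inc$bv_pct) else NA_real_,
    mean_bv_before = if (nrow(inc)) mean(inc$bv_before) else NA_real_,
    mft_um = mft,
    upper_bv = if (experiment == "BIOFILM") layer_mean(slices, "UPPER", config$layer_bv) else NA_real_,
    lower_bv = if (experiment == "BIOFILM") layer_mean(slices, "LOWER", config$layer_bv) else NA_real_,
    field_excluded = nrow(inc) == 0L
  )
  structure(
    list(field_id = stack$field_id, experiment = experiment, slices = slices,
         summary = summary, classmap = excl$classmap,
         components = excl$components, config = config),
    class = "bv_field"
  )
}

#' @export
print.bv_field <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bv_field> %s (%s): mean BV %.2f%% over %d/%d slices",
              s$field_id, x$experiment,
              ifelse(is.na(s$mean_bv), NaN, s$mean_bv),
              s$n_included, s$n_slices))
  if (!is.na(s$mft_um)) {
    cat(sprintf(" | MFT %.2f um | upper %.2f%% / lower %.2f%%",
                s$mft_um, s$upper_bv, s$lower_bv))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname quantify_field
#' @param x a `bv_field`.
#' @param ... unused.
#' @method tidy bv_field
#' @export
tidy.bv_field <- function(x, ...) x$slices

#' @rdname quantify_field
#' @method glance bv_field
#' @export
glance.bv_field <- function(x, ...) x$summary

#' Aggregate fields into sample-level summaries
#'
#' One sample = one (subject, gel, experiment, timepoint) cell of the design;
#' its viability is the unweighted mean of the per-field means (overall and
#' per layer), and its mean thickness the mean of the per-field maximum field
#' thicknesses. Fields whose every slice failed the area gate are dropped; a
#' sample whose fields are all excluded is flagged missing. Field counts
#' outside the design (10--15 fields for saliva, up to 6 for biofilm) produce
#' a warning only.
#'
#' @param fields tibble of per-field summaries ([glance()] rows) joined with
#'   design columns `subject_id`, `gel`, `experiment`, `timepoint`.
#' @return A tibble with one row per sample: design columns, `n_fields`,
#'   `mean_bv`, `mean_bv_before`, `upper_bv`, `lower_bv`,
#'   `mean_thickness_um`, `missing`.
#' @export
aggregate_samples <- function(fields) {
  needed <- c("subject_id", "gel", "experiment", "timepoint", "mean_bv",
              "mft_um", "upper_bv", "lower_bv", "field_excluded")
  stopifnot(all(needed %in% names(fields)))
  out <- fields |>
    dplyr::group_by(.data$subject_id, .data$gel, .data$experiment,
                    .data$timepoint) |>
    dplyr::summarise(
      n_fields = dplyr::n(),
      n_used = sum(!.data$field_excluded),
      mean_bv = mean(.data$mean_bv[!.data$field_excluded]),
      mean_bv_before = mean(.data$mean_bv_before[!.data$field_excluded]),
      upper_bv = mean(.data$upper_bv[!.data$field_excluded], na.rm = TRUE),
      lower_bv = mean(.data$lower_bv[!.data$field_excluded], na.rm = TRUE),
      mean_thickness_um = mean(.data$mft_um[!.data$field_excluded]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      missing = .data$n_used == 0L,
      upper_bv = ifelse(is.nan(.data$upper_bv), NA_real_, .data$upper_bv),
      lower_bv = ifelse(is.nan(.data$lower_bv), NA_real_, .data$lower_bv)
    )
  saliva_bad <- out$experiment == "SALIVA" & (out$n_fields < 10 | out$n_fields > 15)
  biofilm_bad <- out$experiment == "BIOFILM" & out$n_fields > 6
  if (any(saliva_bad, na.rm = TRUE) || any(biofilm_bad, na.rm = TRUE)) {
    warning("field counts outside the sampling design (saliva 10-15, ",
            "biofilm up to 6) for ",
            sum(saliva_bad, na.rm = TRUE) + sum(biofilm_bad, na.rm = TRUE),
            " sample(s)", call. = FALSE)
  }
  out
}

#' Harmonised layer thickness across the design
#'
#' Alternative to the per-field MFT/2 split: a single common layer span equal
#' to the minimum, over (gel x timepoint) cells, of the median per-field MFT.
#' Useful when layers must be depth-comparable across samples.
#'
#' @param fields per-field summary tibble with `gel`, `timepoint`, `mft_um`.
#' @return The common layer thickness in um.
#' @export
harmonised_thickness <- function(fields) {
  stopifnot(all(c("gel", "timepoint", "mft_um") %in% names(fields)))
  med <- fields |>
    dplyr::filter(!is.na(.data$mft_um), .data$mft_um > 0) |>
    dplyr::group_by(.data$gel, .data$timepoint) |>
    dplyr::summarise(median_mft = stats::median(.data$mft_um), .groups = "drop")
  if (!nrow(med)) return(0)
  min(med$median_mft)
}

#' Re-split a field's slices with a fixed layer span
#'
#' Used by the harmonised layer mode: the top `span_um` of each field's MFT
#' span is divided into equal upper and lower layers; slices deeper than
#' `span_um` below the span top are left unassigned.
#'
#' @param field a `bv_field` (biofilm experiment).
#' @param span_um common span in um (see [harmonised_thickness()]).
#' @return The field with re-assigned layers and recomputed layer means.
#' @export
relayer_field <- function(field, span_um) {
  stopifnot(inherits(field, "bv_field"), field$experiment == "BIOFILM")
  cfg <- field$config
  slices <- field$slices
  n <- nrow(slices)
  mft <- field$summary$mft_um
  layer <- rep(NA_character_, n)
  n_field_span <- as.integer(round(mft / cfg$z_step_um))
  n_common <- min(as.integer(round(span_um / cfg$z_step_um)), n_field_span)
  if (n_common > 0 && n_field_span > 0) {
    top <- n - n_field_span + 1L
    n_upper <- ceiling(n_common / 2)
    layer[seq(top, length.out = n_upper)] <- "UPPER"
    if (n_common > n_upper) {
      layer[seq(top + n_upper, length.out = n_common - n_upper)] <- "LOWER"
    }
  }
  field$slices$layer <- layer
  field$summary$upper_bv <- layer_mean(field$slices, "UPPER", cfg$layer_bv)
  field$summary$lower_bv <- layer_mean(field$slices, "LOWER", cfg$layer_bv)
  field
}
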
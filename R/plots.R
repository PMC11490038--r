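# ggplot2 displays for classified slices, depth profiles and trial
# trajectories.

classmap_long <- function(classmap, slice) {
  lab <- classmap$labels[[slice]]
  tibble::tibble(
    row = rep(seq_len(nrow(lab)), times = ncol(lab)),
    col = rep(seq_len(ncol(lab)), each = nrow(lab)),
    class = factor(class_levels()[as.vector(lab) + 1L], levels = class_levels())
  )
}

#' Plot a classified optical section
#'
#' Viable pixels in green, non-viable in red, background near-black --
#' mirroring the fluorescence image the classification came from.
#'
#' @param object a `bv_classmap`.
#' @param slice slice index (default 1).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot bv_classmap
#' @export
autoplot.bv_classmap <- function(object, slice = 1, ...) {
  df <- classmap_long(object, slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(BACKGROUND = "grey10",
                                          VIABLE = "#2ecc40",
                                          NONVIABLE = "#ff4136"),
                               drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("field %s, slice %d", object$field_id, slice),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Viability depth profile of a quantified field
#'
#' Per-slice viability (after epithelial exclusion) against depth below the
#' surface, with gated-out slices hollow and layer membership coloured.
#'
#' @param field a `bv_field` from [quantify_field()].
#' @return A ggplot.
#' @export
plot_depth_profile <- function(field) {
  stopifnot(inherits(field, "bv_field"))
  df <- field$slices
  df$depth_um <- (df$slice - 1) * field$config$z_step_um
  df$layer <- factor(ifelse(is.na(df$layer), "unassigned", df$layer),
                     levels = c("UPPER", "LOWER", "unassigned"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_um, y = .data$bv_pct)) +
    ggplot2::geom_line(colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$layer,
                                     shape = .data$included), na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "depth below surface (um)", y = "bacterial viability (%)",
                  title = sprintf("field %s (MFT %.2f um)", field$field_id,
                                  field$summary$mft_um)) +
    ggplot2::theme_minimal()
}

#' Mean viability trajectories of a trial table
#'
#' Mean +/- SD of viability per gel across the six sampling times, one panel
#' per experiment/layer present in the table.
#'
#' @param table long-format trial table (`gel`, `timepoint`, `bv_pct`, and
#'   optionally `experiment`, `layer`).
#' @return A ggplot.
#' @export
plot_bv_trajectories <- function(table) {
  stopifnot(all(c("gel", "timepoint", "bv_pct") %in% names(table)))
  df <- table
  if (!"layer" %in% names(df)) df$layer <- "FULL"
  if (!"experiment" %in% names(df)) df$experiment <- ""
  df$timepoint <- factor(as.character(df$timepoint), levels = bv_timepoints())
  agg <- df |>
    dplyr::group_by(.data$experiment, .data$layer, .data$gel, .data$timepoint) |>
    dplyr::summarise(mean = mean(.data$bv_pct, na.rm = TRUE),
                     sd = stats::sd(.data$bv_pct, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                    colour = .data$gel, group = .data$gel)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                          ymax = pmin(.data$mean + .data$sd, 100))) +
    ggplot2::facet_wrap(~ .data$experiment + .data$layer) +
    ggplot2::labs(x = "sampling time", y = "bacterial viability (%)",
                  colour = "gel") +
    ggplot2::theme_minimal()
}
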
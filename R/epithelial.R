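#' Epithelial-nucleus filter criteria
#'
#' Epithelial cell nuclei appear as compact, large, bright red regions inside
#' the red-dominant pixel population and must not be counted as non-viable
#' bacteria. A component is flagged as a nucleus when it jointly satisfies all
#' three criteria: pixel area strictly greater than `min_area_px`, solidity
#' strictly greater than `min_solidity`, and mean red intensity of at least
#' `min_mean_intensity`.
#'
#' @param min_area_px minimum pixel area, exclusive bound (default 200).
#' @param min_solidity minimum solidity, exclusive bound (default 0.70).
#' @param min_mean_intensity minimum mean red intensity, inclusive bound
#'   (default 180, 0--255 scale).
#' @return A named list of class `bv_epithelial_criteria`.
#' @export
epithelial_criteria <- function(min_area_px = 200, min_solidity = 0.70,
                                min_mean_intensity = 180) {
  stopifnot(min_area_px >= 1, min_solidity > 0, min_solidity <= 1,
            min_mean_intensity > 0, min_mean_intensity < 255)
  structure(list(min_area_px = min_area_px, min_solidity = min_solidity,
                 min_mean_intensity = min_mean_intensity),
            class = "bv_epithelial_criteria")
}

#' Flag components that meet the epithelial-nucleus criteria
#'
#' @param components tibble from [find_red_components()].
#' @param criteria an [epithelial_criteria()] list.
#' @return The input tibble with a logical `flagged` column appended.
#' @export
#' @examples
#' comps <- tibble::tibble(slice = 1L, component_id = 1L, area_px = 500L,
#'                         solidity = 0.85, mean_red = 200, pixels = list(1:500))
#' flag_epithelial(comps)$flagged  # TRUE
flag_epithelial <- function(components, criteria = epithelial_criteria()) {
  stopifnot(all(c("area_px", "solidity", "mean_red") %in% names(components)))
  dplyr::mutate(
    components,
    flagged = .data$area_px > criteria$min_area_px &
      .data$solidity > criteria$min_solidity &
      .data$mean_red >= criteria$min_mean_intensity
  )
}

#' Remove flagged epithelial components from the non-viable population
#'
#' Relabels every pixel of a flagged component as background, so it no longer
#' contributes to the non-viable bacterial count, and records per slice the
#' viability before and after the removal. Viable pixels are never touched,
#' so per-slice viability can only rise.
#'
#' @param classmap a `bv_classmap`.
#' @param flagged tibble from [flag_epithelial()] (derived from this
#'   classmap).
#' @return A list with elements `classmap` (pixels of flagged components
#'   relabelled background) and `report`, a tibble with one row per slice:
#'   `slice`, `bv_before`, `bv_after` (percentages, `NA` when no bacterial
#'   pixels), `excluded_px`, `n_flagged`.
#' @export
exclude_epithelial <- function(classmap, flagged) {
  stopifnot(inherits(classmap, "bv_classmap"),
            all(c("slice", "pixels", "flagged") %in% names(flagged)))
  npx <- length(classmap$labels[[1]])
  labels <- classmap$labels
  hits <- flagged[flagged$flagged, , drop = FALSE]
  for (k in seq_len(nrow(hits))) {
    i <- hits$slice[k]
    px <- hits$pixels[[k]]
    if (i < 1 || i > length(labels) || any(px < 1) || any(px > npx)) {
      stop("flagged component references pixels outside the classmap",
           call. = FALSE)
    }
    if (any(labels[[i]][px] != CLASS_NONVIABLE)) {
      stop("flagged component pixels are not non-viable in this classmap",
           call. = FALSE)
    }
    labels[[i]][px] <- CLASS_BACKGROUND
  }
  out <- classmap
  out$labels <- labels
  bv_of <- function(counts) {
    denom <- counts$viable_px + counts$nonviable_px
    ifelse(denom > 0, 100 * counts$viable_px / denom, NA_real_)
  }
  before <- class_counts(classmap)
  after <- class_counts(out)
  report <- tibble::tibble(
    slice = before$slice,
    bv_before = bv_of(before),
    bv_after = bv_of(after),
    excluded_px = before$nonviable_px - after$nonviable_px,
    n_flagged = vapply(before$slice, function(i) sum(hits$slice == i), integer(1))
  )
  list(classmap = out, report = report)
}

#' Detect and remove epithelial nuclei in one call
#'
#' Convenience wrapper chaining [find_red_components()], [flag_epithelial()]
#' and [exclude_epithelial()].
#'
#' @param classmap a `bv_classmap`.
#' @param stack the source `bv_stack`.
#' @param criteria an [epithelial_criteria()] list.
#' @param connectivity 4 or 8.
#' @return As [exclude_epithelial()], plus the flagged component table under
#'   `components`.
#' @export
remove_epithelial <- function(classmap, stack,
                              criteria = epithelial_criteria(),
                              connectivity = 8) {
  comps <- find_red_components(classmap, stack, connectivity = connectivity)
  comps <- flag_epithelial(comps, criteria)
  res <- exclude_epithelial(classmap, comps)
  res$components <- comps
  res
}
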
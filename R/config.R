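#' Pipeline configuration
#'
#' Builds the validated configuration list used by every stage of the
#' quantification pipeline. Defaults are the constants the analysis is
#' calibrated to: classification thresholds of 100 on the 0--255 intensity
#' scale, the epithelial-nucleus criteria (area > 200 px, solidity > 0.70,
#' mean red intensity >= 180), the 250 um^2 minimum aggregate area per optical
#' section, a 0.71 um z-step, and Bonferroni-adjusted significance levels of
#' 0.01 (intra-gel, family of 5) and 0.008 (inter-gel, family of 6, displayed
#' at 3 decimals).
#'
#' @param ... named configuration overrides; unknown keys are an error.
#'
#' @return A named list of class `bv_config`.
#' @details Keys and defaults:
#' \describe{
#'   \item{green_thr, red_thr}{pixel-classification thresholds, 0--255 scale
#'     (both 100).}
#'   \item{epithelial}{list with `min_area_px` (200), `min_solidity` (0.70),
#'     `min_mean_intensity` (180), `connectivity` (8).}
#'   \item{min_area_um2}{minimum viable+non-viable aggregate area for a slice
#'     to enter field means, in um^2 (250).}
#'   \item{z_step_um}{optical-section spacing in um (0.71).}
#'   \item{pixel_size_um}{lateral pixel edge in um (0.2294, chosen so that
#'     250 um^2 is approximately 4,750 pixels).}
#'   \item{min_aggregate_px}{cluster-size gate for the maximum field thickness;
#'     `NULL` derives the pixel equivalent of `min_area_um2`.}
#'   \item{alpha, intra_family, inter_family, alpha_decimals}{familywise level
#'     (0.05), Bonferroni family sizes (5 intra-gel, 6 inter-gel) and display
#'     precision (3 decimals) for the adjusted thresholds.}
#'   \item{channel_map}{named integer vector mapping TIFF sample index to
#'     channels; default `c(green = 2, red = 1)` (RGB pages).}
#'   \item{bit_depth}{nominal input bit depth (8); deeper data are linearly
#'     rescaled to 0--255.}
#'   \item{slice_order}{`"surface_first"` (default) or `"base_first"`; the
#'     latter reverses slices on read.}
#'   \item{layer_mode}{`"per_field"` (default) or `"harmonised"` layer split.}
#'   \item{layer_bv}{`"slice_mean"` (default) or `"pixel_pooled"` layer
#'     viability aggregation.}
#' }
#' @export
#' @examples
#' cfg <- bv_config()
#' cfg$green_thr
#' bv_config(green_thr = 120)$green_thr
bv_config <- function(...) {
  defaults <- list(
    green_thr = 100,
    red_thr = 100,
    epithelial = list(
      min_area_px = 200,
      min_solidity = 0.70,
      min_mean_intensity = 180,
      connectivity = 8
    ),
    min_area_um2 = 250,
    z_step_um = 0.71,
    pixel_size_um = 0.2294,
    min_aggregate_px = NULL,
    alpha = 0.05,
    intra_family = 5,
    inter_family = 6,
    alpha_decimals = 3,
    channel_map = c(green = 2L, red = 1L),
    bit_depth = 8,
    slice_order = "surface_first",
    layer_mode = "per_field",
    layer_bv = "slice_mean"
  )
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("all configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  for (key in names(overrides)) {
    if (key == "epithelial") {
      epi <- overrides[[key]]
      bad <- setdiff(names(epi), names(defaults$epithelial))
      if (length(bad)) {
        stop("unknown epithelial key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      cfg$epithelial[names(epi)] <- epi
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "bv_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$green_thr > 0, cfg$green_thr < 255,
    cfg$red_thr > 0, cfg$red_thr < 255,
    cfg$epithelial$min_area_px >= 1,
    cfg$epithelial$min_solidity > 0, cfg$epithelial$min_solidity <= 1,
    cfg$epithelial$min_mean_intensity > 0,
    cfg$epithelial$min_mean_intensity < 255,
    cfg$epithelial$connectivity %in% c(4, 8),
    cfg$min_area_um2 > 0,
    cfg$z_step_um > 0,
    cfg$pixel_size_um > 0,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$intra_family >= 1, cfg$inter_family >= 1,
    cfg$slice_order %in% c("surface_first", "base_first"),
    cfg$layer_mode %in% c("per_field", "harmonised"),
    cfg$layer_bv %in% c("slice_mean", "pixel_pooled")
  )
  if (!is.null(cfg$min_aggregate_px)) stopifnot(cfg$min_aggregate_px >= 1)
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; omitted keys keep their defaults (see
#' [bv_config()]).
#'
#' @param path path to a YAML file.
#' @return A `bv_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$channel_map)) {
    raw$channel_map <- unlist(raw$channel_map)
    storage.mode(raw$channel_map) <- "integer"
  }
  do.call(bv_config, raw)
}

#' Cluster-size gate in pixels for thickness measurement
#'
#' The maximum field thickness is anchored at the shallowest slice whose
#' largest bacterial connected component reaches this size. By default it is
#' the pixel equivalent of the slice-inclusion area gate (250 um^2, about
#' 4,750 pixels at the default pixel size).
#'
#' @param cfg a `bv_config` list.
#' @return Integer pixel count.
#' @export
min_aggregate_px <- function(cfg = bv_config()) {
  if (!is.null(cfg$min_aggregate_px)) return(as.integer(cfg$min_aggregate_px))
  as.integer(round(cfg$min_area_um2 / cfg$pixel_size_um^2))
}

#' @export
print.bv_config <- function(x, ...) {
  cat("<bv_config>\n")
  flat <- x
  flat$epithelial <- NULL
  for (k in names(flat)) {
    v <- flat[[k]]
    if (is.null(v)) v <- "auto"
    cat(sprintf("  %-18s %s\n", k, paste(v, collapse = ", ")))
  }
  e <- x$epithelial
  cat(sprintf("  epithelial         area > %s px, solidity > %s, mean red >= %s, %s-connectivity\n",
              e$min_area_px, e$min_solidity, e$min_mean_intensity,
              e$connectivity))
  invisible(x)
}
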
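#' Two-channel confocal z-stack
#'
#' Container for a registered pair of green (SYTO 9) and red (propidium
#' iodide) intensity stacks. Intensities live on the 0--255 scale the
#' classification thresholds are defined on; slice 1 is the biofilm surface
#' and the last slice the substrate.
#'
#' @param green,red lists of numeric matrices (one per optical section), equal
#'   length and per-slice dimensions, values in `[0, 255]`.
#' @param z_step_um distance between optical sections in um.
#' @param pixel_size_um lateral pixel edge length in um.
#' @param field_id opaque field identifier.
#' @return An object of class `bv_stack`.
#' @export
#' @examples
#' g <- list(matrix(150, 4, 4)); r <- list(matrix(30, 4, 4))
#' z_stack(g, r, field_id = "demo")
z_stack <- function(green, red, z_step_um = 0.71, pixel_size_um = 0.2294,
                    field_id = NA_character_) {
  if (is.matrix(green)) green <- list(green)
  if (is.matrix(red)) red <- list(red)
  stopifnot(is.list(green), is.list(red))
  if (length(green) != length(red)) {
    stop("green and red must have the same number of slices", call. = FALSE)
  }
  if (length(green) == 0L) stop("stack must contain at least one slice", call. = FALSE)
  dims <- lapply(green, dim)
  for (i in seq_along(green)) {
    if (!is.matrix(green[[i]]) || !is.matrix(red[[i]])) {
      stop("slices must be matrices", call. = FALSE)
    }
    if (!identical(dim(green[[i]]), dims[[1]]) ||
        !identical(dim(red[[i]]), dims[[1]])) {
      stop("all slices must share the same dimensions", call. = FALSE)
    }
    rng <- range(green[[i]], red[[i]])
    if (rng[1] < 0 || rng[2] > 255) {
      stop("intensities must lie in [0, 255]; normalise deeper data first",
           call. = FALSE)
    }
  }
  stopifnot(z_step_um > 0, pixel_size_um > 0)
  structure(
    list(green = green, red = red, z_step_um = z_step_um,
         pixel_size_um = pixel_size_um, field_id = field_id),
    class = "bv_stack"
  )
}

#' @export
print.bv_stack <- function(x, ...) {
  d <- dim(x$green[[1]])
  cat(sprintf(
    "<bv_stack> %d slice(s) of %d x %d px | z-step %.3g um | pixel %.4g um | field %s\n",
    n_slices(x), d[1], d[2], x$z_step_um, x$pixel_size_um, x$field_id))
  invisible(x)
}

#' Number of optical sections in a stack or class map
#' @param x a `bv_stack` or `bv_classmap`.
#' @return Integer slice count.
#' @export
n_slices <- function(x) {
  if (inherits(x, "bv_stack")) return(length(x$green))
  if (inherits(x, "bv_classmap")) return(length(x$labels))
  stop("n_slices() needs a bv_stack or bv_classmap", call. = FALSE)
}

#' Read a two-channel z-stack from a multi-page TIFF
#'
#' Pages are optical sections; each page must carry at least two samples per
#' pixel, resolved to the green and red channels through `channel_map`. Data
#' deeper than 8 bits are linearly rescaled so the full bit range maps onto
#' 0--255 (the scale the classification thresholds are quoted on).
#'
#' @param path TIFF / OME-TIFF file path.
#' @param channel_map named integer vector with entries `green` and `red`
#'   giving the sample index of each channel (default `c(green = 2, red = 1)`,
#'   i.e. RGB pages).
#' @param slice_order `"surface_first"` (default) or `"base_first"`; base-first
#'   files are reversed so that slice 1 is always the biofilm surface.
#' @param z_step_um,pixel_size_um,field_id stack metadata (see [z_stack()]).
#' @return A `bv_stack`.
#' @export
read_stack <- function(path, channel_map = c(green = 2L, red = 1L),
                       slice_order = "surface_first",
                       z_step_um = 0.71, pixel_size_um = 0.2294,
                       field_id = NA_character_) {
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  stopifnot(all(c("green", "red") %in% names(channel_map)))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path, " (",
                                             conditionMessage(e), ")",
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pull_channel <- function(page, idx) {
    if (length(dim(page)) < 3L) {
      stop("stack pages must carry two resolvable channels; found a ",
           "single-channel page", call. = FALSE)
    }
    if (idx > dim(page)[3]) {
      stop("channel_map index ", idx, " exceeds the ", dim(page)[3],
           " samples per pixel in the file", call. = FALSE)
    }
    # readTIFF normalises by the file bit depth, so * 255 performs the
    # linear rescale onto the 0-255 thresholding scale for any depth.
    round(page[, , idx] * 255, 7)
  }
  green <- lapply(pages, pull_channel, idx = channel_map[["green"]])
  red <- lapply(pages, pull_channel, idx = channel_map[["red"]])
  dims <- vapply(green, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) {
    stop("ragged slice shapes in ", path, call. = FALSE)
  }
  if (identical(slice_order, "base_first")) {
    green <- rev(green)
    red <- rev(red)
  }
  if (is.na(field_id)) field_id <- sub("\\.[^.]*$", "", basename(path))
  z_stack(green, red, z_step_um = z_step_um, pixel_size_um = pixel_size_um,
          field_id = field_id)
}

#' Write a stack to a multi-page RGB TIFF
#'
#' The red and green channels are placed in the corresponding RGB samples
#' (blue is zero), one page per optical section; 8-bit intensities round-trip
#' exactly through [read_stack()].
#'
#' @param stack a `bv_stack`.
#' @param path output file.
#' @param bits_per_sample 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 8) {
  stopifnot(inherits(stack, "bv_stack"))
  pages <- lapply(seq_len(n_slices(stack)), function(i) {
    d <- dim(stack$green[[i]])
    a <- array(0, c(d[1], d[2], 3))
    a[, , 1] <- stack$red[[i]] / 255
    a[, , 2] <- stack$green[[i]] / 255
    a
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Maximum-intensity projection of a stack
#'
#' Collapses the z-series to a single optical section by taking, per channel
#' and per pixel, the maximum intensity across slices. This is the overall
#' projection on which salivary-flora viability is quantified.
#'
#' @param stack a `bv_stack`.
#' @param method projection operator; only `"max"` is implemented.
#' @return A single-slice `bv_stack` with the same lateral geometry.
#' @export
#' @examples
#' s <- z_stack(list(matrix(10, 2, 2), matrix(200, 2, 2)),
#'              list(matrix(0, 2, 2), matrix(50, 2, 2)))
#' project_stack(s)$green[[1]][1, 1]  # 200
project_stack <- function(stack, method = "max") {
  stopifnot(inherits(stack, "bv_stack"))
  method <- match.arg(method, "max")
  if (n_slices(stack) == 0L) stop("cannot project an empty stack", call. = FALSE)
  z_stack(
    green = list(Reduce(pmax, stack$green)),
    red = list(Reduce(pmax, stack$red)),
    z_step_um = stack$z_step_um,
    pixel_size_um = stack$pixel_size_um,
    field_id = stack$field_id
  )
}

#' Timepoints, gels and experiments of the sampling design
#'
#' The six sampling times of the substantivity design (baseline, five minutes
#' and one, three, five and seven hours after a single gel application), the
#' two products (TEST = chlorhexidine + cymenol, CONTROL = chlorhexidine) and
#' the two niches (SALIVA, BIOFILM).
#' @return Character vector of levels, in design order.
#' @export
bv_timepoints <- function() c("BASAL", "5MIN", "1H", "3H", "5H", "7H")

#' @rdname bv_timepoints
#' @export
bv_gels <- function() c("TEST", "CONTROL")

#' @rdname bv_timepoints
#' @export
bv_experiments <- function() c("SALIVA", "BIOFILM")

#' Read and validate a sample manifest
#'
#' The manifest maps acquisitions to the design: one row per imaged field with
#' columns `subject_id`, `gel` (TEST/CONTROL), `experiment` (SALIVA/BIOFILM),
#' `timepoint` (BASAL, 5MIN, 1H, 3H, 5H, 7H), `field_id` and `path` (stack
#' file, resolved relative to the manifest unless absolute).
#'
#' @param path CSV file path.
#' @return A tibble with factor-encoded design columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "gel", "experiment", "timepoint", "field_id", "path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(df$timepoint), bv_timepoints())
  if (length(bad_tp)) {
    stop("unknown timepoint(s): ", paste(bad_tp, collapse = ", "),
         " (expected ", paste(bv_timepoints(), collapse = ", "), ")",
         call. = FALSE)
  }
  bad_gel <- setdiff(unique(df$gel), bv_gels())
  if (length(bad_gel)) {
    stop("unknown gel(s): ", paste(bad_gel, collapse = ", "), call. = FALSE)
  }
  bad_exp <- setdiff(unique(df$experiment), bv_experiments())
  if (length(bad_exp)) {
    stop("unknown experiment(s): ", paste(bad_exp, collapse = ", "), call. = FALSE)
  }
  key <- df[, c("subject_id", "gel", "experiment", "timepoint", "field_id")]
  if (anyDuplicated(key)) {
    stop("duplicate (subject, gel, experiment, timepoint, field) rows in manifest",
         call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df$timepoint <- factor(df$timepoint, levels = bv_timepoints())
  df$gel <- factor(df$gel, levels = bv_gels())
  df$experiment <- factor(df$experiment, levels = bv_experiments())
  tibble::as_tibble(df)
}
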
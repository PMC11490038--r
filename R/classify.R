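# Integer label codes used inside class maps.
CLASS_BACKGROUND <- 0L
CLASS_VIABLE <- 1L
CLASS_NONVIABLE <- 2L

class_levels <- function() c("BACKGROUND", "VIABLE", "NONVIABLE")

#' Classify one optical section into viable / non-viable / background pixels
#'
#' A pixel is counted as a viable bacterium when its SYTO 9 (green) intensity
#' exceeds `green_thr` while its propidium iodide (red) intensity stays below
#' `red_thr`; it is non-viable whenever red exceeds `red_thr`, which covers
#' both red-only and the visually orange double-high pixels (PI entry marks a
#' compromised membrane regardless of the SYTO 9 level). All comparisons are
#' strict, so a pixel sitting exactly on a threshold joins neither counted
#' population and remains background.
#'
#' @param green,red numeric matrices of identical dimensions, 0--255 scale.
#' @param green_thr,red_thr classification thresholds (defaults 100).
#' @return Integer matrix: 0 background, 1 viable, 2 non-viable.
#' @export
#' @examples
#' classify_slice(matrix(150), matrix(50))   # 1 = viable
#' classify_slice(matrix(150), matrix(150))  # 2 = non-viable ("orange")
#' classify_slice(matrix(100), matrix(100))  # 0 = background (boundary)
classify_slice <- function(green, red, green_thr = 100, red_thr = 100) {
  if (!identical(dim(green), dim(red))) {
    stop("green and red rasters must have identical dimensions", call. = FALSE)
  }
  out <- matrix(CLASS_BACKGROUND, nrow(green), ncol(green))
  out[green > green_thr & red < red_thr] <- CLASS_VIABLE
  out[red > red_thr] <- CLASS_NONVIABLE
  out
}

#' Classify every slice of a stack
#'
#' @param stack a `bv_stack`.
#' @param green_thr,red_thr thresholds on the 0--255 scale (defaults 100).
#' @return A `bv_classmap`: per-slice integer label rasters plus the stack
#'   geometry (z-step, pixel size, field id).
#' @seealso [classify_slice()] for the pixel rule, [class_counts()] for
#'   tallies.
#' @export
classify_stack <- function(stack, green_thr = 100, red_thr = 100) {
  stopifnot(inherits(stack, "bv_stack"))
  labels <- purrr::map2(stack$green, stack$red, classify_slice,
                        green_thr = green_thr, red_thr = red_thr)
  structure(
    list(labels = labels, z_step_um = stack$z_step_um,
         pixel_size_um = stack$pixel_size_um, field_id = stack$field_id),
    class = "bv_classmap"
  )
}

#' @export
print.bv_classmap <- function(x, ...) {
  d <- dim(x$labels[[1]])
  cat(sprintf("<bv_classmap> %d slice(s) of %d x %d px | field %s\n",
              length(x$labels), d[1], d[2], x$field_id))
  print(class_counts(x), n = 5)
  invisible(x)
}

#' Per-slice pixel tallies of a class map
#'
#' @param classmap a `bv_classmap` (or a single integer label matrix).
#' @return A tibble with one row per slice: `slice`, `viable_px`,
#'   `nonviable_px`, `background_px`. The three counts always sum to the pixel
#'   count of the slice.
#' @export
class_counts <- function(classmap) {
  labels <- if (is.matrix(classmap)) list(classmap) else classmap$labels
  purrr::imap_dfr(labels, function(lab, i) {
    tibble::tibble(
      slice = as.integer(i),
      viable_px = sum(lab == CLASS_VIABLE),
      nonviable_px = sum(lab == CLASS_NONVIABLE),
      background_px = sum(lab == CLASS_BACKGROUND)
    )
  })
}

#' Write a class map as a label TIFF for visual QC
#'
#' Labels are encoded as grey levels: background 0, viable 128, non-viable 255.
#' @param classmap a `bv_classmap`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_classmap <- function(classmap, path) {
  pages <- lapply(classmap$labels, function(lab) {
    m <- matrix(0, nrow(lab), ncol(lab))
    m[lab == CLASS_VIABLE] <- 128 / 255
    m[lab == CLASS_NONVIABLE] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
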
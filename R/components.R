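# Connected-component machinery for red-dominant (non-viable) regions.
#
# Labeling builds the pixel-adjacency graph of the foreground (right/down and,
# for 8-connectivity, the two diagonal forward neighbours -- each undirected
# edge once) and takes its connected components. Exact for any shape and
# configurable connectivity; a brute-force flood fill serves as the oracle in
# the test suite.

#' Label connected components of a logical mask
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of component labels (0 = background), numbered
#'   consecutively in raster order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (!length(idx)) return(out)
  compact <- integer(nr * nc)
  compact[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  }
  edges <- integer(0)
  for (off in offsets) {
    r2 <- rows + off[1]; c2 <- cols + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    nb <- r2[ok] + (c2[ok] - 1L) * nr
    hit <- compact[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(compact[idx[ok]][hit], compact[nb][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  membership <- igraph::components(g)$membership
  out[idx] <- match(membership, unique(membership))
  out
}

# Convex-hull pixel area of a pixel set, scikit-image convention: the hull is
# taken over the four corners of every member pixel and its area is the count
# of pixels (in the bounding box) whose centre lies inside or on that polygon.
# A single pixel or any solid rectangle therefore has solidity exactly 1.
convex_hull_px_area <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(n)
  corners_r <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  corners_c <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  h <- grDevices::chull(corners_c, corners_r)
  hx <- corners_c[h]; hy <- corners_r[h]
  rr <- seq(min(rows), max(rows))
  cc <- seq(min(cols), max(cols))
  grid_r <- rep(rr, times = length(cc))
  grid_c <- rep(cc, each = length(rr))
  inside <- pracma::inpolygon(grid_c, grid_r, hx, hy, boundary = TRUE)
  sum(inside)
}

component_features_slice <- function(labels, red, slice_index) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    return(tibble::tibble(
      slice = integer(), component_id = integer(), area_px = integer(),
      solidity = double(), mean_red = double(), pixels = list()
    ))
  }
  px <- lapply(ids, function(id) which(labels == id))
  nr <- nrow(labels)
  tibble::tibble(
    slice = as.integer(slice_index),
    component_id = as.integer(ids),
    area_px = vapply(px, length, integer(1)),
    solidity = vapply(px, function(p) {
      rows <- ((p - 1L) %% nr) + 1L
      cols <- ((p - 1L) %/% nr) + 1L
      length(p) / convex_hull_px_area(rows, cols)
    }, double(1)),
    mean_red = vapply(px, function(p) mean(red[p]), double(1)),
    pixels = px
  )
}

#' Extract candidate epithelial components from the non-viable population
#'
#' Builds connected components of the NONVIABLE-labelled (red-dominant) pixels
#' of each slice and computes, per component, its pixel area, solidity
#' (area / convex-hull pixel area) and mean red intensity -- the three
#' morphological properties the epithelial-nucleus filter tests.
#'
#' @param classmap a `bv_classmap`.
#' @param stack the source `bv_stack` (supplies the red raster for mean
#'   intensities).
#' @param connectivity 4 or 8 (default 8).
#' @return A tibble with one row per component: `slice`, `component_id`,
#'   `area_px`, `solidity`, `mean_red` and a `pixels` list-column of linear
#'   indices. Components are disjoint and jointly cover every non-viable
#'   pixel of their slice.
#' @export
find_red_components <- function(classmap, stack, connectivity = 8) {
  stopifnot(inherits(classmap, "bv_classmap"), inherits(stack, "bv_stack"))
  if (length(classmap$labels) != n_slices(stack) ||
      !identical(dim(classmap$labels[[1]]), dim(stack$red[[1]]))) {
    stop("classmap and stack shapes disagree", call. = FALSE)
  }
  purrr::imap_dfr(classmap$labels, function(lab, i) {
    labels <- label_components(lab == CLASS_NONVIABLE, connectivity)
    component_features_slice(labels, stack$red[[i]], i)
  })
}
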
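# Ground-truthed synthetic two-channel stacks.
#
# The generator paints what the classifier is designed to see: bacterial
# aggregates as small flat-core disks (radius 1-4 px, so their areas stay well
# under the 200 px epithelial gate) with a dim sub-threshold halo, and
# epithelial nuclei as large bright-red solid ellipses that satisfy the
# nucleus criteria by construction. Uniform background noise stays below the
# classification thresholds, so the painted core masks are exactly the pixels
# the classifier counts and every ground-truth quantity is known without
# approximation.

disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

ellipse_offsets <- function(a, b, theta) {
  r <- ceiling(max(a, b))
  d <- expand.grid(dr = -r:r, dc = -r:r)
  u <- d$dc * cos(theta) + d$dr * sin(theta)
  v <- -d$dc * sin(theta) + d$dr * cos(theta)
  d[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
}

#' Specification of a synthetic two-channel stack
#'
#' Defaults emulate a 48-hour in situ biofilm field: thickness drawn uniformly
#' from 11--19 um (rounded to whole 0.71 um sections), bacterial aggregates of
#' radius 1--4 px dense enough that every in-biofilm slice clears the 250 um^2
#' area gate at the default pixel size, and optional epithelial nuclei that
#' meet the exclusion criteria by construction (solid ellipses with semi-axes
#' 9--14 px, red intensity 190--235).
#'
#' @param width,height slice dimensions in pixels.
#' @param viable_fraction target viable fraction of bacterial area, scalar or
#'   one value per biofilm slice, in `[0, 1]`.
#' @param mft_um biofilm thickness in um; `NULL` draws uniformly from
#'   `thickness_range_um`.
#' @param thickness_range_um range for the thickness draw (default `c(11,
#'   19)`).
#' @param n_empty_top empty (noise-only) slices above the biofilm surface.
#' @param n_blobs_per_slice bacterial aggregates painted per biofilm slice.
#' @param blob_radius_range inclusive integer range of aggregate radii in px.
#' @param n_epithelial number of planted epithelial nuclei (default 0).
#' @param noise_max uniform background noise ceiling, intensity units
#'   (default 40, safely below the 100 classification thresholds).
#' @param z_step_um,pixel_size_um stack geometry (defaults 0.71 and 0.2294).
#' @param field_id field identifier.
#' @return A list of class `bv_stack_spec`.
#' @export
stack_spec <- function(width = 256, height = 256, viable_fraction = 0.9,
                       mft_um = NULL, thickness_range_um = c(11, 19),
                       n_empty_top = 2, n_blobs_per_slice = 250,
                       blob_radius_range = c(1, 4), n_epithelial = 0,
                       noise_max = 40, z_step_um = 0.71,
                       pixel_size_um = 0.2294, field_id = "synthetic") {
  stopifnot(width > 16, height > 16,
            all(viable_fraction >= 0), all(viable_fraction <= 1),
            n_empty_top >= 0, n_blobs_per_slice >= 1,
            blob_radius_range[1] >= 1, blob_radius_range[2] >= blob_radius_range[1],
            n_epithelial >= 0, noise_max >= 0, noise_max < 100,
            z_step_um > 0, pixel_size_um > 0)
  structure(
    list(width = width, height = height, viable_fraction = viable_fraction,
         mft_um = mft_um, thickness_range_um = thickness_range_um,
         n_empty_top = n_empty_top, n_blobs_per_slice = n_blobs_per_slice,
         blob_radius_range = blob_radius_range, n_epithelial = n_epithelial,
         noise_max = noise_max, z_step_um = z_step_um,
         pixel_size_um = pixel_size_um, field_id = field_id),
    class = "bv_stack_spec"
  )
}

# Place a mask (data.frame of dr/dc offsets) at a free integer centre.
# occupancy marks painted-or-margin pixels; returns centre or NULL.
place_free <- function(occupancy, offsets, margin, max_tries = 200) {
  nr <- nrow(occupancy); nc <- ncol(occupancy)
  rad_r <- max(abs(offsets$dr)) + margin
  rad_c <- max(abs(offsets$dc)) + margin
  if (2 * rad_r + 1 > nr || 2 * rad_c + 1 > nc) return(NULL)
  for (t in seq_len(max_tries)) {
    cr <- sample.int(nr - 2 * rad_r, 1) + rad_r
    cc <- sample.int(nc - 2 * rad_c, 1) + rad_c
    win <- occupancy[(cr - rad_r):(cr + rad_r), (cc - rad_c):(cc + rad_c)]
    if (!any(win)) return(c(cr, cc))
  }
  NULL
}

mask_indices <- function(centre, offsets, nr) {
  (centre[1] + offsets$dr) + (centre[2] + offsets$dc - 1L) * nr
}

#' Generate a ground-truthed synthetic stack
#'
#' Paints bacterial aggregates (green-dominant viable, red-dominant
#' non-viable, apportioned so the realised viable area fraction matches the
#' spec as closely as the discrete blob areas allow) and optional epithelial
#' nuclei into a two-channel z-stack, surface first, with noise-only slices
#' above the biofilm. Deterministic for a fixed seed.
#'
#' @param spec a [stack_spec()].
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG state).
#' @return A list with elements `stack` (a [z_stack()]), and `truth`: a list
#'   with `per_slice` (tibble of true per-slice viable/non-viable core pixel
#'   counts and viable fraction), `nuclei` (tibble of planted nucleus masks),
#'   `mft_um` (true thickness) and `n_bio_slices`.
#' @export
generate_stack <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "bv_stack_spec"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, generate_stack(spec, seed = NULL)))
  }
  mft <- spec$mft_um %||%
    stats::runif(1, spec$thickness_range_um[1], spec$thickness_range_um[2])
  k <- max(1L, as.integer(round(mft / spec$z_step_um)))
  mft <- k * spec$z_step_um
  n <- k + spec$n_empty_top
  vf <- spec$viable_fraction
  if (length(vf) == 1L) vf <- rep(vf, k)
  if (length(vf) != k) {
    stop("viable_fraction must be scalar or one value per biofilm slice (",
         k, ")", call. = FALSE)
  }
  nr <- spec$height; nc <- spec$width
  halo_value <- 50
  radii_set <- seq(spec$blob_radius_range[1], spec$blob_radius_range[2])
  core_offsets <- lapply(radii_set, disk_offsets)
  halo_offsets <- lapply(radii_set, function(r) disk_offsets(r + 1L))
  names(core_offsets) <- names(halo_offsets) <- radii_set

  green <- red <- vector("list", n)
  per_slice <- vector("list", n)
  nuclei <- list()
  nuc_slices <- if (spec$n_epithelial > 0) {
    sample(seq(spec$n_empty_top + 1L, n), spec$n_epithelial, replace = TRUE)
  } else integer()

  for (i in seq_len(n)) {
    g <- matrix(0, nr, nc)
    r <- matrix(0, nr, nc)
    occupancy <- matrix(FALSE, nr, nc)
    tv <- tn <- 0L
    if (i > spec$n_empty_top) {
      j <- i - spec$n_empty_top
      radii <- sample(radii_set, spec$n_blobs_per_slice, replace = TRUE)
      areas <- vapply(as.character(radii), function(key) nrow(core_offsets[[key]]),
                      integer(1))
      # largest-first greedy split: a blob joins the viable class whenever
      # that moves the running viable area closer to the target, so the
      # realised fraction sits within half the largest blob area of the spec
      ord <- order(areas, decreasing = TRUE)
      target <- vf[j] * sum(areas)
      viable_flag <- logical(length(radii))
      run <- 0L
      for (b in ord) {
        if (abs(run + areas[b] - target) <= abs(run - target)) {
          viable_flag[b] <- TRUE
          run <- run + areas[b]
        }
      }
      for (nuc in which(nuc_slices == i)) {
        axes <- stats::runif(2, 9, 14)
        off <- ellipse_offsets(axes[1], axes[2], stats::runif(1, 0, pi))
        guard <- disk_offsets(ceiling(max(axes)) + 2L)
        centre <- place_free(occupancy, guard, margin = 0L)
        if (is.null(centre)) {
          stop("cannot place epithelial nucleus: frame too crowded", call. = FALSE)
        }
        value <- stats::runif(1, 190, 235)
        idx <- mask_indices(centre, off, nr)
        r[idx] <- pmax(r[idx], value)
        occupancy[mask_indices(centre, guard, nr)] <- TRUE
        nuclei[[length(nuclei) + 1L]] <- tibble::tibble(
          nucleus_id = length(nuclei) + 1L, slice = i,
          area_px = nrow(off),
          pixels = list(mask_indices(centre, off, nr))
        )
      }
      for (b in seq_along(radii)) {
        key <- as.character(radii[b])
        halo <- halo_offsets[[key]]
        centre <- place_free(occupancy, halo, margin = 1L)
        if (is.null(centre)) {
          stop("spec demands more aggregate area than the frame can hold ",
               "without overlap", call. = FALSE)
        }
        core <- core_offsets[[key]]
        peak <- stats::runif(1, 160, 240)
        halo_idx <- mask_indices(centre, halo, nr)
        core_idx <- mask_indices(centre, core, nr)
        if (viable_flag[b]) {
          g[halo_idx] <- pmax(g[halo_idx], halo_value)
          g[core_idx] <- pmax(g[core_idx], peak)
          tv <- tv + nrow(core)
        } else {
          r[halo_idx] <- pmax(r[halo_idx], halo_value)
          r[core_idx] <- pmax(r[core_idx], peak)
          tn <- tn + nrow(core)
        }
        occupancy[halo_idx] <- TRUE
      }
    }
    if (spec$noise_max > 0) {
      g <- pmin(g + matrix(stats::runif(nr * nc, 0, spec$noise_max), nr, nc), 255)
      r <- pmin(r + matrix(stats::runif(nr * nc, 0, spec$noise_max), nr, nc), 255)
    }
    green[[i]] <- g
    red[[i]] <- r
    per_slice[[i]] <- tibble::tibble(
      slice = i, true_viable_px = tv, true_nonviable_px = tn,
      true_viable_fraction = if (tv + tn > 0) tv / (tv + tn) else NA_real_
    )
  }

  list(
    stack = z_stack(green, red, z_step_um = spec$z_step_um,
                    pixel_size_um = spec$pixel_size_um,
                    field_id = spec$field_id),
    truth = list(
      per_slice = dplyr::bind_rows(per_slice),
      nuclei = if (length(nuclei)) dplyr::bind_rows(nuclei) else
        tibble::tibble(nucleus_id = integer(), slice = integer(),
                       area_px = integer(), pixels = list()),
      mft_um = mft,
      n_bio_slices = k
    )
  )
}

#' Deterministic hand-placed fixture stack
#'
#' A 64 x 64 x 6 stack (pixel size 1 um so the 250 um^2 gate is 250 px)
#' covering every classification branch -- viable, non-viable, orange
#' (double-high), background, exact-threshold boundary pixels -- plus one
#' epithelial nucleus and one slice whose bacterial area falls below the gate.
#' The expected class map (before epithelial exclusion) is built alongside
#' from the same placements, so the fixture is its own oracle.
#'
#' @return A list: `stack` (a [z_stack()]), `classmap` (expected
#'   `bv_classmap`), `nucleus` (slice and pixel indices of the planted
#'   nucleus), `subarea_slice` (index of the below-gate slice).
#' @export
fixture_small <- function() {
  nr <- nc <- 64L
  blank <- function() matrix(0, nr, nc)
  lab_blank <- function() matrix(CLASS_BACKGROUND, nr, nc)
  green <- replicate(6, blank(), simplify = FALSE)
  red <- replicate(6, blank(), simplify = FALSE)
  labs <- replicate(6, lab_blank(), simplify = FALSE)
  put <- function(slice, rows, cols, g, r, lab) {
    green[[slice]][rows, cols] <<- g
    red[[slice]][rows, cols] <<- r
    labs[[slice]][rows, cols] <<- lab
  }
  # slice 1: surface, background only
  # slice 2: sub-area slice -- 25 viable + 9 non-viable px (< 250 px gate)
  put(2, 10:14, 10:14, 150, 50, CLASS_VIABLE)
  put(2, 30:32, 30:32, 40, 150, CLASS_NONVIABLE)
  # slice 3: every classification branch
  put(3, 5:24, 5:24, 150, 50, CLASS_VIABLE)            # 400 px viable
  put(3, 30:39, 5:24, 50, 150, CLASS_NONVIABLE)        # 200 px red-only
  put(3, 45:49, 5:14, 150, 150, CLASS_NONVIABLE)       # 50 px orange
  put(3, 55, 5, 100, 100, CLASS_BACKGROUND)            # boundary both
  put(3, 55, 7, 150, 100, CLASS_BACKGROUND)            # green high, red at 100
  put(3, 55, 9, 100, 50, CLASS_BACKGROUND)             # green at 100
  # slice 4: epithelial nucleus (18x18 = 324 px, red 200) among bacteria
  put(4, 5:22, 5:22, 30, 200, CLASS_NONVIABLE)
  put(4, 30:44, 5:24, 150, 50, CLASS_VIABLE)           # 300 px viable
  put(4, 50:54, 5:14, 40, 150, CLASS_NONVIABLE)        # 50 px small red
  # slice 5: viable dominant
  put(5, 5:24, 5:29, 150, 50, CLASS_VIABLE)            # 500 px
  put(5, 40:44, 5:24, 30, 150, CLASS_NONVIABLE)        # 100 px
  # slice 6: base, viable only
  put(6, 5:19, 5:24, 150, 50, CLASS_VIABLE)            # 300 px
  stack <- z_stack(green, red, z_step_um = 0.71, pixel_size_um = 1,
                   field_id = "fixture_small")
  classmap <- structure(
    list(labels = labs, z_step_um = 0.71, pixel_size_um = 1,
         field_id = "fixture_small"),
    class = "bv_classmap"
  )
  nucleus_px <- as.integer(outer(5:22, (5:22 - 1L) * nr, `+`))
  list(stack = stack, classmap = classmap,
       nucleus = list(slice = 4L, pixels = sort(nucleus_px)),
       subarea_slice = 2L)
}
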
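test_that("slice viability applies the BV formula and the area gate", {
  counts <- tibble::tibble(
    slice = 1:4,
    viable_px = c(75L, 100L, 4750L, 0L),
    nonviable_px = c(25L, 140L, 0L, 0L))
  out <- slice_viability(counts, pixel_size_um = 1, min_area_um2 = 250)
  expect_equal(out$bv_pct, c(75, 100 * 100 / 240, 100, NA))
  expect_equal(out$included, c(FALSE, FALSE, TRUE, FALSE))
  # at the default pixel size, 4750 aggregate pixels sit at ~250 um^2
  out2 <- slice_viability(tibble::tibble(slice = 1L, viable_px = 4750L,
                                         nonviable_px = 0L),
                          pixel_size_um = 0.2294)
  expect_equal(out2$aggregate_area_um2, 4750 * 0.2294^2, tolerance = 1e-12)
  expect_true(abs(out2$aggregate_area_um2 - 250) < 1)
  # 240 um^2 fails the 250 um^2 gate
  out3 <- slice_viability(tibble::tibble(slice = 1L, viable_px = 240L,
                                         nonviable_px = 0L), pixel_size_um = 1)
  expect_false(out3$included)
})

test_that("MFT spans from the shallowest qualifying cluster to the base", {
  mk_cm <- function(active, n = 14, block = 20) {
    labs <- lapply(seq_len(n), function(i) {
      m <- matrix(0L, 32, 32)
      if (i %in% active) m[1:block, 1:block] <- 1L
      m
    })
    classify_stack(stack_from_labels(labs))
  }
  # aggregates in every slice of a 14-slice stack
  expect_equal(compute_mft(mk_cm(1:14), z_step_um = 0.71, min_aggregate_px = 100),
               14 * 0.71)
  # aggregates only in the base slice
  expect_equal(compute_mft(mk_cm(14), z_step_um = 0.71, min_aggregate_px = 100),
               0.71)
  # empty stack
  expect_equal(compute_mft(mk_cm(integer(0)), z_step_um = 0.71,
                           min_aggregate_px = 100), 0)
  # clusters below the gate do not anchor the thickness
  cm <- mk_cm(1:14, block = 5)  # 25-px clusters
  expect_equal(compute_mft(cm, z_step_um = 0.71, min_aggregate_px = 100), 0)
  # raising the gate never increases MFT
  cm2 <- mk_cm(3:14, block = 20)
  mfts <- vapply(c(10, 100, 400, 401), function(th)
    compute_mft(cm2, z_step_um = 0.71, min_aggregate_px = th), numeric(1))
  expect_true(all(diff(mfts) <= 0))
})

test_that("layer split partitions the span with the middle slice upper", {
  slices <- tibble::tibble(slice = 1:14)
  even <- split_layers(slices, mft_um = 14 * 0.71, z_step_um = 0.71)
  expect_equal(sum(even$layer == "UPPER", na.rm = TRUE), 7L)
  expect_equal(sum(even$layer == "LOWER", na.rm = TRUE), 7L)
  # 13 in-span slices: 7 upper, 6 lower; slice 1 above the span stays NA
  odd <- split_layers(slices, mft_um = 13 * 0.71, z_step_um = 0.71)
  expect_true(is.na(odd$layer[1]))
  expect_equal(sum(odd$layer == "UPPER", na.rm = TRUE), 7L)
  expect_equal(sum(odd$layer == "LOWER", na.rm = TRUE), 6L)
  # partition: upper and lower are disjoint and cover the span
  span <- odd$slice[!is.na(odd$layer)]
  expect_equal(span, 2:14)
  # degenerate: zero thickness assigns nothing
  none <- split_layers(slices, mft_um = 0, z_step_um = 0.71)
  expect_true(all(is.na(none$layer)))
})

test_that("field summaries equal brute-force re-aggregation", {
  spec <- stack_spec(width = 128, height = 128, n_blobs_per_slice = 80,
                     viable_fraction = 0.6, mft_um = 6)
  gen <- generate_stack(spec, seed = 77)
  cfg <- bv_config(min_aggregate_px = 40, min_area_um2 = 50)
  f <- quantify_field(gen$stack, cfg)
  sl <- tidy(f)
  inc <- sl[sl$included, ]
  expect_equal(glance(f)$mean_bv, mean(inc$bv_pct))
  expect_equal(glance(f)$mean_bv_before, mean(inc$bv_before))
  expect_equal(glance(f)$upper_bv,
               mean(inc$bv_pct[inc$layer %in% "UPPER"]))
  expect_equal(glance(f)$lower_bv,
               mean(inc$bv_pct[inc$layer %in% "LOWER"]))
  # recombining layer means weighted by slice counts gives the overall mean
  n_up <- sum(inc$layer %in% "UPPER"); n_lo <- sum(inc$layer %in% "LOWER")
  if (n_up + n_lo == nrow(inc)) {
    expect_equal((glance(f)$upper_bv * n_up + glance(f)$lower_bv * n_lo) /
                   (n_up + n_lo),
                 glance(f)$mean_bv)
  }
  expect_true(all(sl$bv_pct >= 0 & sl$bv_pct <= 100, na.rm = TRUE))
})

test_that("a field whose slices all fail the gate is excluded", {
  lab <- matrix(0L, 16, 16); lab[1:3, 1:3] <- 1L
  s <- stack_from_labels(list(lab, lab))
  f <- quantify_field(s, bv_config(pixel_size_um = 1))
  expect_true(glance(f)$field_excluded)
  expect_true(is.na(glance(f)$mean_bv))
})

test_that("sample summaries average fields and flag empty samples", {
  fields <- tibble::tibble(
    subject_id = "S01", gel = "TEST", experiment = "BIOFILM",
    timepoint = "BASAL",
    mean_bv = c(20, 40), mean_bv_before = c(18, 39),
    mft_um = c(10, 12), upper_bv = c(25, 45), lower_bv = c(15, 35),
    field_excluded = FALSE)
  s <- aggregate_samples(fields)
  expect_equal(s$mean_bv, 30)
  expect_equal(s$upper_bv, 35)
  expect_equal(s$mean_thickness_um, 11)
  expect_false(s$missing)
  # single field: sample equals field
  s1 <- aggregate_samples(fields[1, ])
  expect_equal(s1$mean_bv, 20)
  # all fields excluded -> missing
  fields$field_excluded <- TRUE
  s2 <- aggregate_samples(fields)
  expect_true(s2$missing)
  # saliva with too few fields warns only
  fs <- fields
  fs$experiment <- "SALIVA"; fs$field_excluded <- FALSE
  expect_warning(aggregate_samples(fs), "field counts")
})

test_that("harmonised thickness is the minimum of the cell medians", {
  fields <- tibble::tibble(
    gel = rep(c("TEST", "CONTROL"), each = 3),
    timepoint = "BASAL",
    mft_um = c(10, 12, 14, 8, 9, 20))
  expect_equal(harmonised_thickness(fields), 9)
})
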
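test_that("stack generation is deterministic under a fixed seed", {
  spec <- stack_spec(width = 96, height = 96, n_blobs_per_slice = 40,
                     mft_um = 4, n_epithelial = 1)
  a <- generate_stack(spec, seed = 123)
  b <- generate_stack(spec, seed = 123)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$per_slice, b$truth$per_slice)
  c <- generate_stack(spec, seed = 124)
  expect_false(identical(a$stack, c$stack))
})

test_that("generated stacks carry the spec geometry and intensity contract", {
  spec <- stack_spec(width = 96, height = 96, n_blobs_per_slice = 40,
                     mft_um = 7.1, n_empty_top = 2)
  gen <- generate_stack(spec, seed = 7)
  expect_equal(gen$truth$n_bio_slices, 10L)  # 7.1 / 0.71
  expect_equal(gen$truth$mft_um, 7.1)
  expect_equal(n_slices(gen$stack), 12L)
  rng <- range(unlist(gen$stack$green), unlist(gen$stack$red))
  expect_gte(rng[1], 0); expect_lte(rng[2], 255)
  # empty top slices hold no classifiable pixels
  cm <- classify_stack(gen$stack)
  expect_equal(sum(cm$labels[[1]] != 0L), 0L)
  expect_equal(sum(cm$labels[[2]] != 0L), 0L)
})

test_that("classified content reproduces the painted ground truth exactly", {
  spec <- stack_spec(width = 128, height = 128, n_blobs_per_slice = 70,
                     viable_fraction = 0.3, mft_um = 5)
  gen <- generate_stack(spec, seed = 15)
  counts <- class_counts(classify_stack(gen$stack))
  truth <- gen$truth$per_slice
  expect_equal(counts$viable_px, truth$true_viable_px)
  expect_equal(counts$nonviable_px, truth$true_nonviable_px)
})

test_that("realised viable fraction tracks the requested fraction to within
           half the largest blob area", {
  for (p in c(0.1, 0.5, 0.9)) {
    spec <- stack_spec(width = 128, height = 128, n_blobs_per_slice = 70,
                       viable_fraction = p, mft_um = 3)
    gen <- generate_stack(spec, seed = round(1000 * p))
    ps <- gen$truth$per_slice
    bio <- ps[!is.na(ps$true_viable_fraction), ]
    # discretisation bound: half the largest blob core (radius 4 -> 49 px)
    # over the slice's bacterial area
    bound <- 0.5 * 49 / (bio$true_viable_px + bio$true_nonviable_px)
    expect_true(all(abs(bio$true_viable_fraction - p) <= bound + 1e-9),
                info = sprintf("p=%.2f", p))
  }
})

test_that("planted nuclei satisfy the flag criteria by construction and
           bacterial blobs never do", {
  spec <- stack_spec(width = 160, height = 160, n_blobs_per_slice = 50,
                     n_epithelial = 3, mft_um = 4)
  gen <- generate_stack(spec, seed = 31)
  expect_equal(nrow(gen$truth$nuclei), 3L)
  expect_true(all(gen$truth$nuclei$area_px > 200))
  comps <- flag_epithelial(find_red_components(classify_stack(gen$stack),
                                               gen$stack))
  expect_equal(sum(comps$flagged), 3L)
  unflagged <- comps[!comps$flagged, ]
  expect_true(all(unflagged$area_px <= 200))
})

test_that("an overfull spec fails with a generation error", {
  spec <- stack_spec(width = 48, height = 48, n_blobs_per_slice = 400,
                     mft_um = 2)
  expect_error(generate_stack(spec, seed = 1), "frame")
})

test_that("trial generation is deterministic, truncated and crossover-shaped", {
  spec <- trial_spec(n_subjects = 29)
  a <- generate_trial(spec, seed = 5)
  b <- generate_trial(spec, seed = 5)
  expect_identical(a$table, b$table)
  expect_equal(nrow(a$table), 29 * 2 * 6)
  expect_true(all(a$table$bv_pct >= 0 & a$table$bv_pct <= 100))
  # each subject appears under both gels at all six times
  tab <- table(a$table$subject_id, a$table$gel)
  expect_true(all(tab == 6))
})

test_that("the subject effect induces the requested within-subject correlation", {
  flat <- tibble::tibble(gel = rep(c("TEST", "CONTROL"), each = 6),
                         timepoint = rep(bv_timepoints(), 2),
                         mean = 50, sd = 10)
  spec <- trial_spec(n_subjects = 400, summaries = flat, rho = 0.6)
  gen <- generate_trial(spec, seed = 8)
  wide <- tidyr::pivot_wider(
    gen$table[gen$table$gel == "TEST", c("subject_id", "timepoint", "bv_pct")],
    names_from = "timepoint", values_from = "bv_pct")
  r <- cor(wide$BASAL, wide$`5MIN`)
  expect_true(abs(r - 0.6) < 0.12)
  # rho = 0: essentially uncorrelated
  spec0 <- trial_spec(n_subjects = 400, summaries = flat, rho = 0)
  gen0 <- generate_trial(spec0, seed = 8)
  wide0 <- tidyr::pivot_wider(
    gen0$table[gen0$table$gel == "TEST", c("subject_id", "timepoint", "bv_pct")],
    names_from = "timepoint", values_from = "bv_pct")
  expect_true(abs(cor(wide0$BASAL, wide0$`5MIN`)) < 0.12)
})

test_that("reference summaries cover both niches and all layers", {
  for (exp in c("SALIVA", "BIOFILM")) {
    s <- reference_summaries(exp)
    expect_equal(nrow(s), 12L)
    expect_true(all(s$mean >= 0 & s$mean <= 100))
    expect_true(all(s$sd > 0))
  }
  expect_equal(reference_summaries("BIOFILM", "FULL")$mean[1], 91)
  expect_equal(reference_summaries("SALIVA")$mean[1], 87)
  expect_false(identical(reference_summaries("BIOFILM", "UPPER"),
                         reference_summaries("BIOFILM", "LOWER")))
})

test_that("the small fixture covers the advertised branches", {
  fx <- fixture_small()
  cm <- classify_stack(fx$stack)
  expect_identical(cm$labels, fx$classmap$labels)
  cfg <- bv_config(pixel_size_um = 1)
  f <- quantify_field(fx$stack, cfg)
  sl <- tidy(f)
  # the sub-area slice fails the 250 um^2 gate
  expect_false(sl$included[fx$subarea_slice])
  # the planted nucleus is flagged and raises that slice's viability
  expect_equal(sl$n_flagged[fx$nucleus$slice], 1L)
  expect_gt(sl$bv_pct[fx$nucleus$slice], sl$bv_before[fx$nucleus$slice])
  flagged <- f$components[f$components$flagged, ]
  expect_equal(sort(flagged$pixels[[1]]), fx$nucleus$pixels)
})
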
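test_that("component labeling agrees with flood fill at both connectivities", {
  set.seed(31)
  for (rep in 1:8) {
    mask <- matrix(runif(14 * 14) < 0.35, 14, 14)
    for (conn in c(4, 8)) {
      got <- label_components(mask, conn)
      ref <- oracle_label(mask, conn)
      # same partition: bijection between label sets
      expect_equal(max(got), max(ref))
      expect_true(all((got > 0) == (ref > 0)))
      for (id in seq_len(max(got))) {
        expect_equal(length(unique(ref[got == id])), 1L)
      }
    }
  }
})

test_that("diagonal touching merges under 8- but not 4-connectivity", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- mask[2, 2] <- TRUE
  expect_equal(max(label_components(mask, 8)), 1L)
  expect_equal(max(label_components(mask, 4)), 2L)
})

test_that("component geometry: solid blocks and notched blocks", {
  # 3x3 solid block: one component, area 9, solidity 1
  lab <- matrix(0L, 8, 8); lab[3:5, 3:5] <- 2L
  s <- stack_from_labels(lab)
  comps <- find_red_components(classify_stack(s), s)
  expect_equal(nrow(comps), 1L)
  expect_equal(comps$area_px, 9L)
  expect_equal(comps$solidity, 1)
  expect_equal(comps$mean_red, 150)
  # 2x3 block minus a corner: area 5, convex-hull pixel area 6
  lab2 <- matrix(0L, 8, 8); lab2[3:4, 3:5] <- 2L; lab2[4, 5] <- 0L
  s2 <- stack_from_labels(lab2)
  comps2 <- find_red_components(classify_stack(s2), s2)
  expect_equal(comps2$area_px, 5L)
  expect_equal(comps2$solidity, 5 / 6, tolerance = 1e-12)
  # single pixel has solidity exactly 1
  lab3 <- matrix(0L, 5, 5); lab3[3, 3] <- 2L
  s3 <- stack_from_labels(lab3)
  expect_equal(find_red_components(classify_stack(s3), s3)$solidity, 1)
})

test_that("components cover all non-viable pixels disjointly", {
  set.seed(32)
  lab <- matrix(sample(0:2, 20 * 20, TRUE, prob = c(0.6, 0.2, 0.2)), 20, 20)
  s <- stack_from_labels(lab)
  cm <- classify_stack(s)
  comps <- find_red_components(cm, s)
  all_px <- sort(unlist(comps$pixels))
  expect_equal(all_px, which(cm$labels[[1]] == 2L))
  expect_equal(anyDuplicated(all_px), 0L)
})

test_that("flagging is the conjunction of the three criteria", {
  mk <- function(area, sol, red) {
    tibble::tibble(slice = 1L, component_id = 1L, area_px = area,
                   solidity = sol, mean_red = red, pixels = list(integer()))
  }
  expect_true(flag_epithelial(mk(500, 0.85, 200))$flagged)
  expect_false(flag_epithelial(mk(150, 0.90, 220))$flagged)  # area fails
  expect_false(flag_epithelial(mk(500, 0.60, 220))$flagged)  # solidity fails
  expect_false(flag_epithelial(mk(500, 0.85, 170))$flagged)  # intensity fails
  # bounds: area and solidity are exclusive, intensity inclusive
  expect_false(flag_epithelial(mk(200, 0.90, 220))$flagged)
  expect_false(flag_epithelial(mk(500, 0.70, 220))$flagged)
  expect_true(flag_epithelial(mk(500, 0.85, 180))$flagged)
})

test_that("tightening any single criterion never flags more components", {
  set.seed(33)
  comps <- tibble::tibble(
    slice = 1L, component_id = 1:60,
    area_px = sample(50:800, 60, TRUE),
    solidity = runif(60, 0.3, 1),
    mean_red = runif(60, 100, 255),
    pixels = replicate(60, integer(), simplify = FALSE))
  n_flagged <- function(crit) sum(flag_epithelial(comps, crit)$flagged)
  base <- n_flagged(epithelial_criteria())
  expect_lte(n_flagged(epithelial_criteria(min_area_px = 400)), base)
  expect_lte(n_flagged(epithelial_criteria(min_solidity = 0.9)), base)
  expect_lte(n_flagged(epithelial_criteria(min_mean_intensity = 220)), base)
})

test_that("exclusion relabels flagged pixels and reports both viabilities", {
  # 100 viable px, 700 non-viable of which one flagged 500-px block
  lab <- matrix(0L, 40, 40)
  lab[1:10, 1:10] <- 1L                      # 100 viable
  lab[12:31, 1:25] <- 2L                     # 500 px compact bright block
  lab[34:37, 1:38] <- 2L                     # 152 px elongated
  lab[39:40, 1:24] <- 2L                     # 48 px
  s <- stack_from_labels(lab, nonviable_red = 150)
  # brighten only the big block so it alone passes the intensity test
  s$red[[1]][12:31, 1:25] <- 200
  cm <- classify_stack(s)
  res <- remove_epithelial(cm, s)
  expect_equal(sum(res$components$flagged), 1L)
  rep1 <- res$report
  expect_equal(rep1$bv_before, 100 * 100 / 800)
  expect_equal(rep1$bv_after, 100 * 100 / 300)
  expect_equal(rep1$excluded_px, 500L)
  # viable pixels untouched
  expect_equal(sum(res$classmap$labels[[1]] == 1L), 100L)
})

test_that("exclusion is an identity when nothing is flagged, and BV-after is
           100% when every non-viable pixel goes", {
  lab <- matrix(0L, 10, 10); lab[1:3, 1:3] <- 1L; lab[5:6, 5:6] <- 2L
  s <- stack_from_labels(lab)
  cm <- classify_stack(s)
  res <- remove_epithelial(cm, s)  # 4-px component can't be flagged
  expect_identical(res$classmap$labels, cm$labels)
  expect_equal(res$report$bv_before, res$report$bv_after)
  # force-flag everything via absurdly permissive criteria
  res2 <- remove_epithelial(cm, s, epithelial_criteria(1, 0.01, 1))
  expect_equal(res2$report$bv_after, 100)
  expect_gte(res2$report$bv_after, res2$report$bv_before)
})

test_that("exclusion never lowers per-slice viability on random stacks", {
  set.seed(34)
  for (rep in 1:5) {
    lab <- matrix(sample(0:2, 30 * 30, TRUE), 30, 30)
    s <- stack_from_labels(lab, nonviable_red = sample(150:250, 1))
    res <- remove_epithelial(classify_stack(s), s)
    ok <- !is.na(res$report$bv_before)
    expect_true(all(res$report$bv_after[ok] >= res$report$bv_before[ok]))
  }
})

test_that("planted nuclei are recovered exactly on generator stacks", {
  spec <- stack_spec(width = 160, height = 160, n_blobs_per_slice = 60,
                     n_epithelial = 2, mft_um = 5)
  gen <- generate_stack(spec, seed = 5)
  cm <- classify_stack(gen$stack)
  comps <- flag_epithelial(find_red_components(cm, gen$stack))
  expect_equal(sum(comps$flagged), nrow(gen$truth$nuclei))
})
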
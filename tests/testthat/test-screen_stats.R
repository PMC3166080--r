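test_that("Welch t-test matches the textbook example and stats::t.test", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  tt <- t.test(a, b)  # independent implementation as oracle
  expect_equal(two_sample_t(a, b), tt$p.value, tolerance = 1e-12)
  expect_equal(two_sample_t(a, b), 0.02131164, tolerance = 1e-6)
  w <- httscreen:::welch_stats(a, b)
  expect_equal(w$t, -3.674235, tolerance = 1e-5)
  expect_equal(w$df, 4, tolerance = 1e-9)
  # random-sample agreement with the reference implementation
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5, 2)
    expect_equal(two_sample_t(x, y), t.test(x, y)$p.value, tolerance = 1e-10)
  }
})

test_that("identical and degenerate samples are handled as specified", {
  s <- c(1, 2, 3, 4, 5)
  expect_equal(two_sample_t(s, s), 1)
  # both variances zero, unequal means: clipped to the floor, not an error
  expect_equal(two_sample_t(c(2, 2), c(5, 5)), 1e-300)
  expect_equal(two_sample_t(c(2, 2), c(2, 2)), 1)
  expect_error(two_sample_t(1, c(1, 2)), "insufficient")
})

test_that("the test is symmetric in its arguments", {
  set.seed(10)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(8, 1)
    expect_equal(two_sample_t(x, y), two_sample_t(y, x), tolerance = 1e-12)
  }
})

test_that("type-I error is calibrated under the null", {
  set.seed(3)
  rej <- mean(replicate(10000,
                        two_sample_t(rnorm(10), rnorm(10)) < 0.05))
  expect_gte(rej, 0.045)
  expect_lte(rej, 0.055)
})

test_that("Fisher combination follows the closed form", {
  # all ones: no evidence, X = 0, combined p = 1
  r <- fisher_combine(rep(1, 8))
  expect_equal(r$fisher_statistic, 0)
  expect_equal(r$df, 16L)
  expect_equal(r$combined_p, 1)
  # k = 2 closed form: survival of chi-square_4 is e^{-x/2}(1 + x/2)
  r2 <- fisher_combine(c(0.05, 0.05))
  X <- -2 * (log(0.05) + log(0.05))
  expect_equal(r2$fisher_statistic, X, tolerance = 1e-12)
  expect_equal(r2$combined_p, exp(-X / 2) * (1 + X / 2), tolerance = 1e-12)
  expect_equal(r2$combined_p, 0.01747866, tolerance = 1e-6)
})

test_that("Fisher combination validates, clips, and is monotone", {
  expect_error(fisher_combine(c(0.5, 1.2)), "0, 1")
  expect_error(fisher_combine(c(0.5, -0.1)), "0, 1")
  expect_error(fisher_combine(numeric(0)), "at least one")
  # zero inputs are clipped to the floor, giving a tiny combined p
  r0 <- fisher_combine(c(0, 0.5))
  expect_gt(r0$combined_p, 0)
  expect_lt(r0$combined_p, 1e-250)
  # decreasing any p_i can only decrease the combined p
  base <- c(0.2, 0.4, 0.6, 0.8)
  p0 <- fisher_combine(base)$combined_p
  for (i in seq_along(base)) {
    lower <- base; lower[i] <- base[i] / 2
    expect_lt(fisher_combine(lower)$combined_p, p0)
  }
})

test_that("self-comparison of a reference population gives combined p = 1", {
  set.seed(12)
  ref <- random_feature_table(10)
  r <- morphology_rescue_test(ref, ref)
  expect_equal(unname(r$per_feature_p), rep(1, 8))
  expect_equal(r$combined_p, 1)
  expect_equal(r$df, 16L)
})

test_that("rescue-test errors name the failing feature", {
  ref <- random_feature_table(6)
  bad <- ref[1, ]
  expect_error(morphology_rescue_test(bad, ref), "pct_small_neuromere")
  expect_error(morphology_rescue_test(ref[, -1], ref), "missing")
})

test_that("untreated mutant profiles are far from control profiles", {
  scr <- generate_screen(tiny_layout(n_treatments = 3L, n_vehicle = 8L),
                         fields_per_well = 3L, seed = 5)
  res <- run_screen(scr, min_images = 3L)
  feats <- res$features
  mut <- feats[feats$genotype == "HTT138Q" & feats$treatment_kind == "VEHICLE", ]
  ctl <- feats[feats$genotype == "HTT15Q", ]
  expect_gte(nrow(mut), 20)
  expect_gte(nrow(ctl), 20)
  r <- morphology_rescue_test(mut, ctl)
  expect_lt(r$combined_p, 1e-6)
})

test_that("aggregation suppression arithmetic is exact", {
  same <- c(100, 200, 300)
  r <- aggregation_suppression_test(same, same)
  expect_equal(r$log2_ratio, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, 0)

  r2 <- aggregation_suppression_test(c(400, 500, 600), c(900, 1000, 1100))
  expect_equal(r2$log2_ratio, -1)

  r3 <- aggregation_suppression_test(c(300, 300, 300), c(1200, 1200, 1201))
  expect_equal(r3$log2_ratio, -2, tolerance = 1e-3)
  expect_equal(r3$direction, -1)
  expect_lt(r3$p_value, 0.05)

  expect_error(aggregation_suppression_test(c(1, 2), c(0, 0)), "undefined")
  expect_error(aggregation_suppression_test(numeric(0), c(1, 2)), "nonempty")
})

test_that("the log2 ratio is antisymmetric under group swap", {
  set.seed(14)
  for (i in 1:10) {
    a <- rpois(6, 300) + 1; b <- rpois(6, 800) + 1
    ra <- aggregation_suppression_test(a, b)
    rb <- aggregation_suppression_test(b, a)
    expect_equal(ra$log2_ratio, -rb$log2_ratio, tolerance = 1e-12)
    expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
  }
})

test_that("the screen threshold is mean minus m sd with sane edge cases", {
  expect_error(screen_threshold(c(0, 1)), "at least 3")
  t1 <- screen_threshold(c(0.5, 0.5, 0.5))
  expect_equal(t1$sd_log2, 0)
  expect_equal(t1$cutoff, 0.5)
  t2 <- screen_threshold(c(-1, 0, 1))
  expect_equal(t2$mean_log2, 0)
  expect_equal(t2$sd_log2, 1)
  expect_equal(t2$cutoff, -2)
  # a null screen flags roughly the normal 2-sd tail
  set.seed(2)
  r <- rnorm(352, 0, 0.5)
  th <- screen_threshold(r)
  frac <- mean(r <= th$cutoff)
  expect_gte(frac, 0.008)
  expect_lte(frac, 0.045)
})

test_that("two-stage hit calling applies the gates in order", {
  th <- structure(list(mean_log2 = 0, sd_log2 = 0.25, multiplier = 2,
                       cutoff = -0.5, n = 40L), class = "screen_threshold")
  agg <- tibble::tibble(
    treatment_id = c("supp_rescued", "supp_only", "inactive", "weak_ratio"),
    log2_ratio = c(-1.5, -2.0, 0.1, -0.4),
    agg_p = c(1e-6, 1e-10, 0.5, 1e-4),
    direction = c(-1, -1, 1, -1))
  morph <- tibble::tibble(
    treatment_id = c("supp_rescued", "supp_only", "inactive", "weak_ratio"),
    morph_combined_p = c(0.15, 1e-12, 0.9, 0.2))
  hits <- call_hits(agg, morph, th)
  cls <- setNames(as.character(hits$classification), hits$treatment_id)
  expect_equal(cls[["supp_rescued"]], "DUAL_HIT")
  expect_equal(cls[["supp_only"]], "AGG_SUPPRESSOR_ONLY")
  expect_equal(cls[["inactive"]], "INACTIVE")          # stage-1 p gate
  expect_equal(cls[["weak_ratio"]], "INACTIVE")        # 2-sd gate (AND rule)
  # under the OR rule the p-criterion alone suffices
  hits_or <- call_hits(agg, morph, th, stage1_rule = "or")
  expect_equal(as.character(
    hits_or$classification[hits_or$treatment_id == "weak_ratio"]),
    "DUAL_HIT")
  # DUAL_HIT implies both stage flags
  expect_true(all(hits$aggregation_suppressed[hits$classification == "DUAL_HIT"]))
  expect_true(all(hits$morphology_rescued[hits$classification == "DUAL_HIT"]))
})

test_that("partial reversion, exacerbation and exclusion are reported", {
  th <- structure(list(mean_log2 = 0, sd_log2 = 0.25, multiplier = 2,
                       cutoff = -0.5, n = 10L), class = "screen_threshold")
  agg <- tibble::tibble(
    treatment_id = c("partial", "toxic", "lonely"),
    log2_ratio = c(-1, -1.2, -1),
    agg_p = c(1e-5, 1e-6, 1e-5),
    direction = c(-1, -1, -1))
  morph <- tibble::tibble(
    treatment_id = c("partial", "toxic"),
    morph_combined_p = c(0.003, 1e-20),
    mean_neurite_length = c(30, 10),
    mean_neuromere_area = c(120, 60))
  baseline <- list(morph_combined_p = 1e-8, mean_neurite_length = 25,
                   mean_neuromere_area = 100)
  hits <- call_hits(agg, morph, th, baseline = baseline)
  expect_true(hits$partial_rescue[hits$treatment_id == "partial"])
  expect_equal(as.character(
    hits$classification[hits$treatment_id == "partial"]),
    "AGG_SUPPRESSOR_ONLY")
  expect_equal(as.character(
    hits$classification[hits$treatment_id == "toxic"]), "EXACERBATING")
  expect_equal(as.character(
    hits$classification[hits$treatment_id == "lonely"]), "EXCLUDED")
  expect_match(hits$reason[hits$treatment_id == "lonely"], "morphology")
  # explicit upstream exclusions are carried through
  hits2 <- call_hits(agg[1, ], morph[1, ], th,
                     excluded = tibble::tibble(treatment_id = "fewimg",
                                               reason = "fewer than 6"))
  expect_equal(as.character(
    hits2$classification[hits2$treatment_id == "fewimg"]), "EXCLUDED")
})
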
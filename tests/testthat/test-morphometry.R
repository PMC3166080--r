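test_that("well-separated point clusters are fitted to their locations", {
  x <- rep(c(4, 6, 8), times = c(40, 30, 20)) +
    rep(c(-0.002, 0, 0.002), length.out = 90)  # near-point clusters
  m <- fit_area_bins(x)
  expect_equal(m$means, c(4, 6, 8), tolerance = 0.01)
  expect_equal(m$weights, c(4, 3, 2) / 9, tolerance = 0.01)
  expect_true(all(diff(m$means) > 0))
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("the EM recovers generating parameters and labels", {
  set.seed(1)
  comp <- sample.int(3, 3000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  x <- rnorm(3000, c(4, 6, 8)[comp], 0.2)
  m <- fit_area_bins(x)
  expect_true(all(abs(m$means - c(4, 6, 8)) < 0.1))
  expect_true(all(abs(m$weights - c(0.5, 0.3, 0.2)) < 0.05))
  acc <- mean(as.integer(assign_area_bin(x, m)) == comp)
  expect_gte(acc, 0.99)
})

test_that("the EM agrees with an independent mixture implementation", {
  library(mclust)
  set.seed(1)
  comp <- sample.int(3, 1500, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  x <- rnorm(1500, c(4, 6, 8)[comp], 0.2)
  own <- fit_area_bins(x)
  ref <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(own$means, sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  ord <- order(ref$parameters$mean)
  expect_equal(own$weights, ref$parameters$pro[ord], tolerance = 0.02)
})

test_that("EM log-likelihood is nondecreasing and the fit is order-invariant", {
  set.seed(2)
  x <- rnorm(600, rep(c(5, 7, 9), each = 200), 0.4)
  m <- fit_area_bins(x)
  expect_true(all(diff(m$loglik_trace) > -1e-9))
  m_perm <- fit_area_bins(sample(x))
  expect_equal(m$means, m_perm$means, tolerance = 1e-9)
  expect_equal(m$weights, m_perm$weights, tolerance = 1e-9)
  expect_equal(m$sds, m_perm$sds, tolerance = 1e-9)
})

test_that("degenerate binning inputs are rejected", {
  expect_error(fit_area_bins(c(1, 1, 1, 2, 2)), "degenerate")
  expect_error(fit_length_groups(rep(c(10, 20), 20)), "degenerate")
})

test_that("bin assignment is maximum-posterior with ties to the smaller bin", {
  m <- structure(
    list(weights = c(0.5, 0.3, 0.2), means = c(4, 6, 8),
         sds = c(0.3, 0.3, 0.3), fitted_n = 100L),
    class = "area_bin_model")
  expect_equal(as.character(assign_area_bin(4, m)), "small")
  expect_equal(as.character(assign_area_bin(8, m)), "large")
  # equal weights/sds: the midpoint posterior ties exactly -> smaller bin
  m2 <- structure(
    list(weights = c(1, 1, 1) / 3, means = c(4, 6, 8),
         sds = c(0.3, 0.3, 0.3), fitted_n = 100L),
    class = "area_bin_model")
  expect_equal(as.character(assign_area_bin(5, m2)), "small")
  expect_equal(as.character(assign_area_bin(7, m2)), "medium")
  # brute-force posterior oracle on random values
  set.seed(3)
  xs <- runif(200, 3, 9)
  post <- sapply(1:3, function(j)
    m$weights[j] * dnorm(xs, m$means[j], m$sds[j]))
  oracle <- apply(post, 1, which.max)
  expect_equal(as.integer(assign_area_bin(xs, m)), oracle)
})

test_that("K-means recovers separated length groups deterministically", {
  x <- rep(c(10, 50, 200), times = c(30, 30, 30)) +
    rep(c(-0.01, 0, 0.01), each = 30)
  m <- fit_length_groups(x)
  expect_equal(m$centers, c(10, 50, 200), tolerance = 0.001)

  set.seed(2)
  g <- sample.int(3, 2000, replace = TRUE)
  y <- rgamma(2000, shape = 100, scale = c(0.1, 0.5, 2)[g])
  km <- fit_length_groups(y)
  expect_equal(km$centers, c(10, 50, 200), tolerance = 0.1)
  km_perm <- fit_length_groups(sample(y))
  expect_equal(km$centers, km_perm$centers, tolerance = 1e-9)
})

test_that("length assignment is nearest-center with midpoint ties short", {
  m <- structure(list(centers = c(10, 50, 200), fitted_n = 90L),
                 class = "length_group_model")
  expect_equal(as.character(assign_length_group(c(12, 60, 500), m)),
               c("short", "medium", "long"))
  expect_equal(as.character(assign_length_group(30, m)), "short")   # midpoint
  expect_equal(as.character(assign_length_group(125, m)), "medium") # midpoint
})

test_that("the feature vector has eight entries with forced arithmetic", {
  seg <- structure(
    list(neuromere_areas = c(10000, 100, 100, 2, 2),
         neurite_segment_lengths = numeric(0),
         aggregate_pixel_count = 0L,
         neuromere_pixel_mask_size = 100L, neurite_pixel_mask_size = 0L,
         pixel_size_um = 897 / 1392),
    class = "segmentation_result")
  am <- structure(
    list(weights = c(1, 1, 1) / 3, means = log2(c(2, 100, 10000)),
         sds = c(0.5, 0.5, 0.5), fitted_n = 100L),
    class = "area_bin_model")
  lm <- structure(list(centers = c(10, 50, 200), fitted_n = 90L),
                  class = "length_group_model")
  fv <- compute_features(seg, am, lm)
  expect_equal(fv$pct_small_neuromere, 40)
  expect_equal(fv$pct_medium_neuromere, 40)
  expect_equal(fv$pct_large_neuromere, 20)
  expect_equal(fv$mean_neuromere_area, 2040.8)
  expect_true(fv$zero_neurites)
  expect_equal(fv$mean_neurite_length, 0)
  expect_equal(unname(unlist(fv[morphology_features()])),
               c(40, 40, 20, 2040.8, 0, 0, 0, 0))
  expect_length(morphology_features(), 8L)
  expect_true(all(morphology_features() %in% names(fv)))
})

test_that("percentages always sum to 100 and ignore object duplication", {
  am <- structure(
    list(weights = c(1, 1, 1) / 3, means = c(4, 6, 8),
         sds = c(0.5, 0.5, 0.5), fitted_n = 100L),
    class = "area_bin_model")
  lm <- structure(list(centers = c(10, 50, 200), fitted_n = 90L),
                  class = "length_group_model")
  set.seed(5)
  for (i in 1:20) {
    areas <- 2^runif(sample(1:12, 1), 3.5, 9)
    lens <- exp(runif(sample(0:8, 1), 2, 5.5))
    seg <- structure(
      list(neuromere_areas = areas, neurite_segment_lengths = lens,
           aggregate_pixel_count = 0L, neuromere_pixel_mask_size = 10L,
           neurite_pixel_mask_size = 10L, pixel_size_um = 0.64),
      class = "segmentation_result")
    fv <- compute_features(seg, am, lm)
    expect_equal(fv$pct_small_neuromere + fv$pct_medium_neuromere +
                   fv$pct_large_neuromere, 100, tolerance = 1e-9)
    if (length(lens) > 0) {
      expect_equal(fv$pct_short_neurite + fv$pct_medium_neurite +
                     fv$pct_long_neurite, 100, tolerance = 1e-9)
    }
    # duplicating every object leaves all percentages unchanged
    seg2 <- seg
    seg2$neuromere_areas <- rep(areas, 2)
    seg2$neurite_segment_lengths <- rep(lens, 2)
    fv2 <- compute_features(seg2, am, lm)
    pct_cols <- grep("^pct_", morphology_features(), value = TRUE)
    expect_equal(fv2[pct_cols], fv[pct_cols], tolerance = 1e-9)
  }
})

test_that("fields without neuromeres cannot be profiled", {
  seg <- structure(
    list(neuromere_areas = numeric(0), neurite_segment_lengths = numeric(0),
         aggregate_pixel_count = 0L, neuromere_pixel_mask_size = 0L,
         neurite_pixel_mask_size = 0L, pixel_size_um = 0.64),
    class = "segmentation_result")
  expect_error(compute_features(seg, NULL, NULL), "cell profiles")
})

test_that("mutant cultures show shorter neurites than controls on average", {
  ctl <- control_params()
  mut <- mutant_params()
  mean_len <- function(p, seeds) {
    mean(vapply(seeds, function(s) {
      f <- generate_culture_field(p, seed = s)
      seg <- segment_morphology(f$morphology)
      if (length(seg$neurite_segment_lengths) == 0) return(0)
      mean(seg$neurite_segment_lengths)
    }, numeric(1)))
  }
  expect_gt(mean_len(ctl, 1:20), mean_len(mut, 1:20))
})

test_that("the reporter-distribution ratio behaves arithmetically", {
  seg <- structure(
    list(neuromere_areas = 100, neurite_segment_lengths = numeric(0),
         aggregate_pixel_count = 0L, neuromere_pixel_mask_size = 150L,
         neurite_pixel_mask_size = 50L, pixel_size_um = 0.64),
    class = "segmentation_result")
  expect_equal(reporter_distribution_ratio(0, seg), 0)
  expect_equal(reporter_distribution_ratio(50, c(150, 50)), 0.25)
  empty <- seg
  empty$neuromere_pixel_mask_size <- 0L
  empty$neurite_pixel_mask_size <- 0L
  expect_error(reporter_distribution_ratio(10, empty), "undefined")
})

test_that("the ratio scales linearly with soluble coverage on noiseless fields", {
  p <- noiseless(control_params())
  f <- generate_culture_field(p, seed = 31)
  seg <- segment_morphology(f$morphology)
  n_rep <- count_soluble_pixels(f$reporter, 1000)
  ratio <- reporter_distribution_ratio(n_rep, seg)
  # the numerator is a pixel count over the fixed neuronal masks, so
  # doubling the counted soluble pixels doubles the ratio exactly
  expect_equal(reporter_distribution_ratio(2 * n_rep, seg), 2 * ratio)
  # in the control condition soluble reporter fills the neuronal mask
  expect_gt(ratio, 0.5)
})

test_that("tidiers expose models as tibbles", {
  set.seed(6)
  x <- rnorm(300, rep(c(4, 6, 8), each = 100), 0.3)
  m <- fit_area_bins(x)
  td <- tidy(m)
  expect_equal(nrow(td), 3L)
  expect_named(td, c("bin", "weight", "mean", "sd"))
  expect_equal(glance(m)$n, 300L)
  lm <- fit_length_groups(exp(runif(100, 2, 5)))
  expect_equal(nrow(tidy(lm)), 3L)
})
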
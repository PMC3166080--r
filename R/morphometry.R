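# Eight-metric morphology profile: GMM binning of log2 neuromere areas,
# K-means grouping of neurite segment lengths, per-field percentages.

AREA_BINS <- c("small", "medium", "large")
LENGTH_GROUPS <- c("short", "medium", "long")

#' Names of the eight morphology features, in canonical order
#'
#' Three neuromere-bin percentages, mean neuromere area (um^2), three
#' neurite-group percentages, and mean neurite segment length (um).
#'
#' @return Character vector of length 8.
#' @export
morphology_features <- function() {
  c("pct_small_neuromere", "pct_medium_neuromere", "pct_large_neuromere",
    "mean_neuromere_area",
    "pct_short_neurite", "pct_medium_neurite", "pct_long_neurite",
    "mean_neurite_length")
}

#' Fit the three-bin Gaussian mixture of log2 neuromere areas
#'
#' Log2-transformed neuromere areas are well described by a three-component
#' univariate normal mixture, giving small/medium/large bins. The mixture is
#' fitted by EM with deterministic initialisation (means at the 1/6, 3/6,
#' 5/6 sample quantiles, equal weights, common sd), so the fit depends only
#' on the data. Convergence: log-likelihood improvement < 1e-8 or 500
#' iterations. Components are reported sorted by mean.
#'
#' @param log2_areas Numeric vector of log2 areas (um^2), pooled over the
#'   model-fitting population (typically all vehicle wells of a screen).
#' @param seed Unused (the fit is deterministic); kept so callers can treat
#'   both binning fits uniformly.
#' @return An `area_bin_model` with `weights`, `means`, `sds` (ascending
#'   means), `fitted_n`, `loglik`, `loglik_trace`, `iterations`,
#'   `converged`.
#' @export
fit_area_bins <- function(log2_areas, seed = NULL) {
  x <- as.numeric(log2_areas)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 3L)
    stop("degenerate input: need at least 3 distinct log2 areas to fit ",
         "three bins", call. = FALSE)
  k <- 3L
  mu <- as.numeric(quantile(x, c(1, 3, 5) / 6, names = FALSE))
  if (any(duplicated(mu)))
    mu <- seq(min(x), max(x), length.out = k + 2)[2:(k + 1)]
  sg <- rep(max(sd(x), 1e-3), k)
  w <- rep(1 / k, k)
  sd_floor <- 1e-3

  n <- length(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  dens <- matrix(0, n, k)
  for (iter in seq_len(500L)) {
    for (j in seq_len(k)) dens[, j] <- w[j] * dnorm(x, mu[j], sg[j])
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < 1e-8) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    for (j in seq_len(k)) {
      sg[j] <- sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j])
    }
    sg <- pmax(sg, sd_floor)
  }
  ord <- order(mu)
  structure(
    list(weights = w[ord], means = mu[ord], sds = sg[ord],
         fitted_n = n, loglik = ll_trace[length(ll_trace)],
         loglik_trace = ll_trace, iterations = iter, converged = converged),
    class = "area_bin_model"
  )
}

#' @export
print.area_bin_model <- function(x, ...) {
  cat("<area_bin_model> three-component normal mixture on log2 area\n")
  print(data.frame(bin = AREA_BINS, weight = round(x$weights, 4),
                   mean = round(x$means, 4), sd = round(x$sds, 4)))
  cat(sprintf("fitted on n = %d (loglik %.3f, %d iterations%s)\n",
              x$fitted_n, x$loglik, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Assign log2 areas to size bins by maximum posterior probability
#'
#' Ties break toward the smaller bin.
#'
#' @param log2_area Numeric vector of log2 areas.
#' @param model An [fit_area_bins()] model.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
assign_area_bin <- function(log2_area, model) {
  stopifnot(inherits(model, "area_bin_model"))
  post <- sapply(seq_len(3L), function(j) {
    model$weights[j] * dnorm(log2_area, model$means[j], model$sds[j])
  })
  if (is.null(dim(post))) post <- matrix(post, nrow = 1L)
  # max.col(..., "first") realises the tie-to-smaller rule
  factor(AREA_BINS[max.col(post, ties.method = "first")],
         levels = AREA_BINS)
}

#' Fit the three neurite length groups by K-means
#'
#' Neurite segment lengths are clustered into short/medium/long groups by
#' Lloyd's algorithm with deterministic initial centers at the 10th, 50th
#' and 90th percentiles (max 300 iterations).
#'
#' @param lengths Numeric vector of segment lengths (um), pooled over the
#'   model-fitting population.
#' @param seed Unused (the fit is deterministic); kept for interface
#'   symmetry with [fit_area_bins()].
#' @return A `length_group_model` with ascending `centers` and `fitted_n`.
#' @export
fit_length_groups <- function(lengths, seed = NULL) {
  x <- as.numeric(lengths)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 3L)
    stop("degenerate input: need at least 3 distinct lengths to fit three ",
         "groups", call. = FALSE)
  init <- as.numeric(quantile(x, c(0.1, 0.5, 0.9), names = FALSE))
  if (any(duplicated(init)))
    init <- as.numeric(quantile(unique(x), c(0.1, 0.5, 0.9), names = FALSE))
  if (any(duplicated(init)))
    init <- sort(unique(x))[round(seq(1, length(unique(x)), length.out = 3))]
  km <- suppressWarnings(
    kmeans(x, centers = matrix(init, ncol = 1), iter.max = 300L,
           algorithm = "Lloyd")
  )
  structure(
    list(centers = sort(as.numeric(km$centers)), fitted_n = length(x)),
    class = "length_group_model"
  )
}

#' @export
print.length_group_model <- function(x, ...) {
  cat("<length_group_model> K-means centers (um):",
      paste(sprintf("%s = %.2f", LENGTH_GROUPS, x$centers), collapse = ", "),
      sprintf("(n = %d)\n", x$fitted_n))
  invisible(x)
}

#' Assign lengths to the nearest K-means group
#'
#' Midpoint ties go to the shorter group.
#'
#' @param length Numeric vector of lengths (um).
#' @param model A [fit_length_groups()] model.
#' @return Factor with levels `short`, `medium`, `long`.
#' @export
assign_length_group <- function(length, model) {
  stopifnot(inherits(model, "length_group_model"))
  d <- abs(outer(length, model$centers, `-`))
  factor(LENGTH_GROUPS[max.col(-d, ties.method = "first")],
         levels = LENGTH_GROUPS)
}

#' Compute the eight-metric morphology profile of one field
#'
#' Bin counts are converted to percentages of the field's own object totals
#' (controlling for cell-number variation between wells), and object-level
#' arithmetic means complete the profile. Fields without neuromeres cannot
#' be profiled (they are excluded upstream as lacking cell profiles);
#' fields without neurites get zero-valued neurite features and are flagged
#' rather than dropped, since dropping them would bias toward healthy
#' fields.
#'
#' @param seg A [segment_morphology()] result.
#' @param areas_model An [fit_area_bins()] model.
#' @param lengths_model A [fit_length_groups()] model.
#' @return One-row tibble: the eight features of [morphology_features()] in
#'   order, plus `n_neuromeres`, `n_neurites` and the `zero_neurites` flag.
#' @export
compute_features <- function(seg, areas_model, lengths_model) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (length(seg$neuromere_areas) == 0L)
    stop("cannot profile a field without neuromeres (lacks cell profiles)",
         call. = FALSE)
  bins <- assign_area_bin(log2(seg$neuromere_areas), areas_model)
  pct_nm <- 100 * as.vector(table(bins)) / length(bins)
  lens <- seg$neurite_segment_lengths
  if (length(lens) > 0L) {
    grp <- assign_length_group(lens, lengths_model)
    pct_nl <- 100 * as.vector(table(grp)) / length(grp)
    mean_len <- mean(lens)
  } else {
    pct_nl <- c(0, 0, 0)
    mean_len <- 0
  }
  tibble::tibble(
    pct_small_neuromere = pct_nm[1], pct_medium_neuromere = pct_nm[2],
    pct_large_neuromere = pct_nm[3],
    mean_neuromere_area = mean(seg$neuromere_areas),
    pct_short_neurite = pct_nl[1], pct_medium_neurite = pct_nl[2],
    pct_long_neurite = pct_nl[3],
    mean_neurite_length = mean_len,
    n_neuromeres = length(seg$neuromere_areas),
    n_neurites = length(lens),
    zero_neurites = length(lens) == 0L
  )
}

#' Reporter-distribution ratio (reporter pixels per neuronal area)
#'
#' The soluble-reporter redistribution readout: aggregate-free reporter
#' pixels above the soluble threshold, divided by the neuronal area (the
#' neuromere plus neurite mask sizes in pixels).
#'
#' @param reporter_pixels Count of aggregate-free reporter-positive pixels
#'   (see [count_soluble_pixels()]).
#' @param seg A `segmentation_result`, or a numeric vector of the two mask
#'   sizes as returned by [neuronal_mask_sizes()].
#' @return Non-negative ratio.
#' @export
reporter_distribution_ratio <- function(reporter_pixels, seg) {
  sizes <- if (inherits(seg, "segmentation_result")) {
    neuronal_mask_sizes(seg)
  } else {
    as.numeric(seg)
  }
  denom <- sum(sizes)
  if (denom <= 0)
    stop("undefined ratio: neuronal area is zero", call. = FALSE)
  stopifnot(reporter_pixels >= 0)
  reporter_pixels / denom
}
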
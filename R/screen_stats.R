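# Per-feature Welch t-tests, Fisher combination, plate-normalised log2
# aggregate ratios, the 2-SD screen cutoff, and two-stage hit calling.

HIT_CLASSES <- c("INACTIVE", "AGG_SUPPRESSOR_ONLY", "DUAL_HIT",
                 "EXACERBATING", "EXCLUDED")

# Welch (unequal-variance) two-sample statistics. Identical groups give
# t = 0, p = 1; two zero-variance groups with different means give the
# p-value floor rather than a division error.
welch_stats <- function(a, b, p_floor = 1e-300) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("insufficient data: both samples need n >= 2 (got ", na, " and ",
         nb, ")", call. = FALSE)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(ma - mb) * Inf, df = na + nb - 2, p = p_floor))
  }
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = max(min(p, 1), p_floor))
}

#' Two-sided Welch two-sample t-test p-value
#'
#' The per-feature test of the screen statistics. Welch's unequal-variance
#' form is used as a robust default. Identical samples give p = 1.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param p_floor Lower clip for numerically zero p-values (default 1e-300,
#'   for log-safety in Fisher combination).
#' @return A p-value in `(0, 1]`.
#' @export
two_sample_t <- function(sample_a, sample_b, p_floor = 1e-300) {
  welch_stats(sample_a, sample_b, p_floor)$p
}

#' Combine per-feature p-values by Fisher's method
#'
#' The statistic X = -2 * sum(log(p_i)) follows a chi-squared distribution
#' with 2k degrees of freedom under the joint null; the combined p-value is
#' its survival probability at X. Inputs below `p_floor` are clipped first
#' for log-safety.
#'
#' @param per_feature_p Numeric vector of k >= 1 p-values in `(0, 1]`.
#' @param p_floor Lower clip (default 1e-300).
#' @return A `feature_test_result`: `per_feature_p`, `fisher_statistic`,
#'   `df = 2k`, `combined_p`.
#' @export
fisher_combine <- function(per_feature_p, p_floor = 1e-300) {
  p <- as.numeric(per_feature_p)
  if (length(p) < 1L)
    stop("need at least one p-value to combine", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]; got ",
         paste(format(p[is.na(p) | p < 0 | p > 1]), collapse = ", "),
         call. = FALSE)
  p <- pmax(p, p_floor)
  k <- length(p)
  X <- -2 * sum(log(p))
  structure(
    list(per_feature_p = p, fisher_statistic = X, df = 2L * k,
         combined_p = pchisq(X, df = 2 * k, lower.tail = FALSE)),
    class = "feature_test_result"
  )
}

#' @export
print.feature_test_result <- function(x, ...) {
  cat(sprintf(
    "<feature_test_result> k = %d features, X = %.4f on %d df, combined p = %s\n",
    length(x$per_feature_p), x$fisher_statistic, x$df,
    format_p(x$combined_p)))
  invisible(x)
}

# Display convention: stored at full precision, printed as 0 below 1e-15.
format_p <- function(p) {
  ifelse(p < 1e-15, "0", format(signif(p, 6)))
}

#' Test reversion of the morphology profile toward the control state
#'
#' One two-sided Welch test per feature -- e.g. the small-neuromere
#' percentage of treated Htt138Q fields versus that of Htt15Q vehicle
#' fields -- combined across the eight features by Fisher's method. A high
#' combined p-value means the treated morphology is statistically similar
#' to the control profile.
#'
#' @param treated,reference Data frames of per-field feature vectors (one
#'   row per field) containing the [morphology_features()] columns.
#' @param features Feature columns to test (default all eight).
#' @param p_floor Lower p-value clip.
#' @return A `feature_test_result` with named `per_feature_p`.
#' @export
morphology_rescue_test <- function(treated, reference,
                                   features = morphology_features(),
                                   p_floor = 1e-300) {
  missing_t <- setdiff(features, names(treated))
  missing_r <- setdiff(features, names(reference))
  if (length(missing_t) || length(missing_r))
    stop("feature columns missing: ",
         paste(unique(c(missing_t, missing_r)), collapse = ", "),
         call. = FALSE)
  ps <- vapply(features, function(f) {
    tryCatch(
      two_sample_t(treated[[f]], reference[[f]], p_floor),
      error = function(e) stop("feature '", f, "': ", conditionMessage(e),
                               call. = FALSE)
    )
  }, numeric(1))
  out <- fisher_combine(ps, p_floor)
  names(out$per_feature_p) <- features
  out
}

#' Test suppression of aggregate formation against in-plate vehicle wells
#'
#' The aggregation readout: log2 of the ratio of mean aggregate pixel
#' counts (treated / DMSO-treated Htt138Q wells of the same plate), with a
#' two-sided Welch t-test over per-field counts and the direction of the
#' mean difference.
#'
#' @param treated,dmso Numeric vectors of per-field aggregate pixel counts.
#' @param p_floor Lower p-value clip.
#' @return An `aggregate_test_result`: `log2_ratio`, `p_value`, `direction`
#'   (-1/0/1), group means and sizes.
#' @export
aggregation_suppression_test <- function(treated, dmso, p_floor = 1e-300) {
  if (length(treated) == 0L || length(dmso) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  m_t <- mean(treated); m_d <- mean(dmso)
  if (m_d <= 0)
    stop("undefined ratio: vehicle mean aggregate count is zero ",
         "(miscalibrated aggregate threshold?)", call. = FALSE)
  w <- welch_stats(treated, dmso, p_floor)
  structure(
    list(log2_ratio = log2(m_t / m_d), p_value = w$p,
         direction = sign(m_t - m_d),
         mean_treated = m_t, mean_dmso = m_d,
         n_treated = length(treated), n_dmso = length(dmso)),
    class = "aggregate_test_result"
  )
}

#' @export
print.aggregate_test_result <- function(x, ...) {
  cat(sprintf(
    "<aggregate_test_result> log2 ratio = %.4f (means %.1f vs %.1f), p = %s\n",
    x$log2_ratio, x$mean_treated, x$mean_dmso, format_p(x$p_value)))
  invisible(x)
}

#' Screen-wide 2-SD cutoff on log2 aggregate ratios
#'
#' The screen's hit line: `m` standard deviations below the mean log2 ratio
#' observed across the whole screen data set (sample sd, n - 1 denominator).
#'
#' @param log2_ratios Numeric vector of per-treatment log2 ratios (>= 3
#'   finite values).
#' @param m Multiplier (default 2).
#' @return A `screen_threshold`: `mean_log2`, `sd_log2`, `multiplier`,
#'   `cutoff = mean - m * sd`.
#' @export
screen_threshold <- function(log2_ratios, m = 2) {
  r <- log2_ratios[is.finite(log2_ratios)]
  if (length(r) < 3L)
    stop("insufficient data: need at least 3 finite log2 ratios", call. = FALSE)
  stopifnot(m > 0)
  mu <- mean(r); s <- sd(r)
  structure(
    list(mean_log2 = mu, sd_log2 = s, multiplier = m, cutoff = mu - m * s,
         n = length(r)),
    class = "screen_threshold"
  )
}

#' @export
print.screen_threshold <- function(x, ...) {
  cat(sprintf(
    "<screen_threshold> mean %.4f, sd %.4f, cutoff (mean - %g sd) = %.4f over %d ratios\n",
    x$mean_log2, x$sd_log2, x$multiplier, x$cutoff, x$n))
  invisible(x)
}

#' Two-stage hit classification
#'
#' Stage 1 (aggregation): a treatment suppresses aggregation when its Welch
#' p-value is below `alpha` with a negative direction and -- under the
#' default `"and"` rule -- its log2 ratio falls at or below the screen's
#' 2-SD cutoff (`"or"` accepts either criterion, `"p"` uses the p-value
#' criterion alone, matching the p < 0.05 footnote convention of tabulated
#' results). Stage 2 (morphology) re-evaluates only suppressed treatments:
#' combined p > `alpha` means the profile has reverted to the control state
#' (`DUAL_HIT`); combined p in `[rescue_floor, alpha]` is flagged as a
#' partial reversion but stays `AGG_SUPPRESSOR_ONLY`; treatments whose
#' profile diverges from control even more than the untreated mutant
#' baseline, with worse feature means, are `EXACERBATING`.
#'
#' @param agg Tibble with columns `treatment_id, log2_ratio, agg_p,
#'   direction` (see [aggregation_suppression_test()]).
#' @param morph Tibble with columns `treatment_id, morph_combined_p` and,
#'   for the exacerbation check, optionally `mean_neurite_length` and
#'   `mean_neuromere_area` (treated group means).
#' @param threshold A [screen_threshold()].
#' @param alpha Significance level (default 0.05).
#' @param rescue_floor Lower combined-p bound of the partial-reversion band
#'   (default 1e-6).
#' @param stage1_rule `"and"` (default), `"or"`, or `"p"`.
#' @param baseline Optional untreated-mutant reference: a list with
#'   `morph_combined_p` and optionally `mean_neurite_length`,
#'   `mean_neuromere_area`, used for the `EXACERBATING` call.
#' @param excluded Optional tibble `treatment_id, reason` of treatments
#'   excluded upstream; carried through as `EXCLUDED`.
#' @return A `hit_table` tibble: one row per treatment with test values,
#'   `aggregation_suppressed`, `morphology_rescued`, `partial_rescue`,
#'   `classification`, `reason`.
#' @export
call_hits <- function(agg, morph, threshold, alpha = 0.05,
                      rescue_floor = 1e-6,
                      stage1_rule = c("and", "or", "p"),
                      baseline = NULL, excluded = NULL) {
  stage1_rule <- match.arg(stage1_rule)
  stopifnot(inherits(threshold, "screen_threshold"), alpha > 0, alpha < 1)
  tab <- dplyr::full_join(tibble::as_tibble(agg), tibble::as_tibble(morph),
                          by = "treatment_id")
  if (!"mean_neurite_length" %in% names(tab))
    tab$mean_neurite_length <- NA_real_
  if (!"mean_neuromere_area" %in% names(tab))
    tab$mean_neuromere_area <- NA_real_

  missing_either <- is.na(tab$agg_p) | is.na(tab$morph_combined_p)
  p_crit <- tab$agg_p < alpha & tab$direction < 0
  r_crit <- tab$log2_ratio <= threshold$cutoff & tab$direction < 0
  suppressed <- switch(stage1_rule,
    "and" = p_crit & r_crit,
    "or" = p_crit | r_crit,
    "p" = p_crit
  )
  suppressed[missing_either] <- FALSE

  rescued <- suppressed & tab$morph_combined_p > alpha
  partial <- suppressed & !rescued &
    tab$morph_combined_p >= rescue_floor & tab$morph_combined_p <= alpha

  exacerb <- rep(FALSE, nrow(tab))
  if (!is.null(baseline) && is.finite(baseline$morph_combined_p %||% NA)) {
    worse_means <- rep(TRUE, nrow(tab))
    if (!is.null(baseline$mean_neurite_length))
      worse_means <- worse_means &
        !is.na(tab$mean_neurite_length) &
        tab$mean_neurite_length < baseline$mean_neurite_length
    if (!is.null(baseline$mean_neuromere_area))
      worse_means <- worse_means &
        !is.na(tab$mean_neuromere_area) &
        tab$mean_neuromere_area < baseline$mean_neuromere_area
    exacerb <- suppressed & !rescued &
      tab$morph_combined_p <= baseline$morph_combined_p & worse_means
  }

  cls <- rep("INACTIVE", nrow(tab))
  cls[suppressed] <- "AGG_SUPPRESSOR_ONLY"
  cls[exacerb] <- "EXACERBATING"
  cls[rescued] <- "DUAL_HIT"
  cls[missing_either] <- "EXCLUDED"

  reason <- rep("", nrow(tab))
  reason[missing_either] <- dplyr::case_when(
    is.na(tab$agg_p[missing_either]) &
      is.na(tab$morph_combined_p[missing_either]) ~ "missing both tests",
    is.na(tab$agg_p[missing_either]) ~ "missing aggregation test",
    TRUE ~ "missing morphology test"
  )

  out <- tibble::tibble(
    treatment_id = tab$treatment_id,
    log2_ratio = tab$log2_ratio,
    agg_p = tab$agg_p,
    direction = tab$direction,
    morph_combined_p = tab$morph_combined_p,
    mean_neurite_length = tab$mean_neurite_length,
    mean_neuromere_area = tab$mean_neuromere_area,
    aggregation_suppressed = suppressed,
    morphology_rescued = rescued,
    partial_rescue = partial,
    classification = factor(cls, levels = HIT_CLASSES),
    reason = reason
  )
  if (!is.null(excluded) && nrow(excluded) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      treatment_id = excluded$treatment_id,
      aggregation_suppressed = FALSE, morphology_rescued = FALSE,
      partial_rescue = FALSE,
      classification = factor("EXCLUDED", levels = HIT_CLASSES),
      reason = excluded$reason
    ))
  }
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("hit_table", class(out))
  out
}
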
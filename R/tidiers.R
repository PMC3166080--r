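# broom-style tidy()/glance() methods for the fitted objects.

#' @describeIn fit_area_bins One row per mixture component.
#' @param x The fitted model.
#' @param ... Unused.
#' @export
tidy.area_bin_model <- function(x, ...) {
  tibble::tibble(
    bin = factor(AREA_BINS, levels = AREA_BINS),
    weight = x$weights, mean = x$means, sd = x$sds
  )
}

#' @describeIn fit_area_bins One-row fit summary.
#' @export
glance.area_bin_model <- function(x, ...) {
  tibble::tibble(
    n = x$fitted_n, loglik = x$loglik, iterations = x$iterations,
    converged = x$converged
  )
}

#' @describeIn fit_length_groups One row per length group.
#' @param x The fitted model.
#' @param ... Unused.
#' @export
tidy.length_group_model <- function(x, ...) {
  tibble::tibble(
    group = factor(LENGTH_GROUPS, levels = LENGTH_GROUPS),
    center = x$centers
  )
}

#' @describeIn fit_length_groups One-row fit summary.
#' @export
glance.length_group_model <- function(x, ...) {
  tibble::tibble(n = x$fitted_n)
}

#' @describeIn fisher_combine One row per combined feature p-value.
#' @param x The test result.
#' @param ... Unused.
#' @export
tidy.feature_test_result <- function(x, ...) {
  nm <- names(x$per_feature_p) %||% paste0("p", seq_along(x$per_feature_p))
  tibble::tibble(feature = nm, p_value = as.numeric(x$per_feature_p))
}

#' @describeIn fisher_combine One-row summary with the Fisher statistic.
#' @export
glance.feature_test_result <- function(x, ...) {
  tibble::tibble(
    k = length(x$per_feature_p), fisher_statistic = x$fisher_statistic,
    df = x$df, combined_p = x$combined_p
  )
}

#' @describeIn aggregation_suppression_test One-row tidy summary.
#' @param x The test result.
#' @param ... Unused.
#' @export
tidy.aggregate_test_result <- function(x, ...) {
  tibble::tibble(
    log2_ratio = x$log2_ratio, p_value = x$p_value, direction = x$direction,
    mean_treated = x$mean_treated, mean_dmso = x$mean_dmso,
    n_treated = x$n_treated, n_dmso = x$n_dmso
  )
}

#' @describeIn screen_threshold One-row tidy summary.
#' @param x The threshold object.
#' @param ... Unused.
#' @export
tidy.screen_threshold <- function(x, ...) {
  tibble::tibble(
    mean_log2 = x$mean_log2, sd_log2 = x$sd_log2,
    multiplier = x$multiplier, cutoff = x$cutoff, n = x$n
  )
}
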
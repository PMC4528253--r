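#' Tidy a separation report
#'
#' One row per report: class means, normalized known mean, fold
#' difference, U statistic, p-value and class sizes.
#'
#' @param x a [separation_report()].
#' @param ... unused.
#' @return a one-row tibble.
#' @method tidy separation_report
#' @export
tidy.separation_report <- function(x, ...) {
  tibble::tibble(
    ranking_factor = x$ranking_factor,
    mean_known = x$mean_known, mean_unknown = x$mean_unknown,
    normalized_mean_known = x$normalized_mean_known,
    fold_difference = x$fold_difference,
    statistic = x$U, p.value = x$p_value, method = x$method,
    n_known = x$n_known, n_unknown = x$n_unknown
  )
}

#' @rdname tidy.separation_report
#' @method glance separation_report
#' @export
glance.separation_report <- function(x, ...) {
  tibble::tibble(statistic = x$U, p.value = x$p_value,
                 n = x$n_known + x$n_unknown, method = x$method)
}

#' Tidy a hotspot ranking
#'
#' Returns the ranked table with audit factors, one row per hotspot,
#' list-columns dropped.
#'
#' @param x an `fp_ranking` from [rank_hotspots()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy fp_ranking
#' @export
tidy.fp_ranking <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out[!vapply(out, is.list, logical(1))]
}

#' @rdname tidy.fp_ranking
#' @method glance fp_ranking
#' @export
glance.fp_ranking <- function(x, ...) {
  tibble::tibble(
    n_hotspots = nrow(x),
    n_known = sum(x$known_function),
    n_families = dplyr::n_distinct(x$family_id),
    median_fp = median(x$fp),
    max_fold_over_median = max(x$fold_over_median, na.rm = TRUE),
    pct_known_above_median = if (any(x$known_function)) {
      100 * mean(x$fp[x$known_function] > x$family_median_fp[x$known_function])
    } else NA_real_
  )
}
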
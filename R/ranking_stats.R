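#' Mann-Whitney U test (exact small-sample enumeration, tie-aware)
#'
#' Two-sided rank-sum test of `x` versus `y`. The statistic is
#' `U = #{(i,j): x_i > y_j} + 0.5 #{x_i = y_j}`. For small samples
#' (both sizes at most `exact_max`) the null distribution of U is
#' enumerated over all `choose(n+m, n)` assignments of the pooled values,
#' so ties are handled exactly; the two-sided p-value is the permutation
#' tail probability `P(|U* - nm/2| >= |U - nm/2|)`. Larger samples use
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric vectors (each nonempty).
#' @param exact_max enumeration limit per sample (default 8).
#' @return list with `U`, `p_value`, `method` ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n <= exact_max && m <= exact_max) {
    # null distribution by enumeration of which pooled ranks go to x
    combs <- combn(n + m, n)
    u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    dev <- abs(U - n * m / 2)
    p <- mean(abs(u_all - n * m / 2) >= dev - 1e-9)
    list(U = U, p_value = p, method = "exact")
  } else {
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (n * m / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (U - n * m / 2)
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corr.
    list(U = U, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

#' Known- versus unknown-function separation for one ranking factor
#'
#' Compares a per-hotspot ranking factor (total PTMs, SASA,
#' modifiable-residue conservation, FP, ...) between hotspots with known
#' and unknown function: class means, the known mean normalized so the
#' unknown class sits at 1, their fold difference, and a two-sided
#' Mann-Whitney test ([mann_whitney_u()]). By default the raw factor
#' values are compared; `use_ranks = TRUE` switches to ordinal ranks for
#' sensitivity analysis.
#'
#' @param data data frame with the factor column and a logical
#'   known-function column.
#' @param value column (tidy-eval) holding the factor values.
#' @param known column (tidy-eval) holding the logical labels.
#' @param factor_label label stored in the report.
#' @param use_ranks compare ordinal ranks instead of raw values.
#' @return object of class `separation_report` (a list).
#' @export
separation_report <- function(data, value, known, factor_label = NULL,
                              use_ranks = FALSE) {
  v <- dplyr::pull(data, {{ value }})
  k <- dplyr::pull(data, {{ known }})
  if (is.null(factor_label)) {
    factor_label <- rlang::as_name(rlang::enquo(value))
  }
  stopifnot(is.logical(k), length(v) == length(k))
  if (!any(k) || !any(!k)) {
    stop("both a known and an unknown class are required", call. = FALSE)
  }
  if (use_ranks) v <- rank(v)
  mw <- mann_whitney_u(v[k], v[!k])
  mean_known <- mean(v[k]); mean_unknown <- mean(v[!k])
  structure(list(
    ranking_factor = factor_label,
    mean_known = mean_known, mean_unknown = mean_unknown,
    normalized_mean_known = mean_known / mean_unknown,
    fold_difference = mean_known / mean_unknown,
    U = mw$U, p_value = mw$p_value, method = mw$method,
    n_known = sum(k), n_unknown = sum(!k),
    use_ranks = use_ranks
  ), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report> ", x$ranking_factor, ": known ",
      signif(x$mean_known, 4), " vs unknown ", signif(x$mean_unknown, 4),
      " (", signif(x$fold_difference, 3), "-fold), U = ", x$U,
      ", p = ", signif(x$p_value, 3), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Known fraction above FP thresholds
#'
#' For each threshold `t` (a multiple of the grouping median FP), counts
#' hotspots with `fp >= t x median` and the fraction of those with known
#' function. Thresholds beyond the maximum FP give zero counts and an
#' undefined (NA) fraction.
#'
#' @param ranking an `fp_ranking` from [rank_hotspots()].
#' @param thresholds numeric vector of multiples over the median.
#' @return tibble: `threshold`, `n_known`, `n_unknown`, `pct_known`.
#' @export
known_fraction_vs_threshold <- function(ranking,
                                        thresholds = c(0, 0.5, 1, 2, 5,
                                                       10, 20, 50)) {
  purrr::map_dfr(thresholds, function(t) {
    sel <- ranking$fp >= t * ranking$family_median_fp
    nk <- sum(ranking$known_function[sel])
    nu <- sum(!ranking$known_function[sel])
    tibble::tibble(
      threshold = t, n_known = nk, n_unknown = nu,
      pct_known = if (nk + nu > 0) nk / (nk + nu) else NA_real_
    )
  })
}

#' Per-protein PTM load
#'
#' Total observed PTMs for a protein divided by its full length in
#' residues. Proteins without a length are skipped with a warning.
#'
#' @param records PTM record tibble.
#' @param protein_lengths named numeric vector `protein_id -> length`.
#' @return tibble: `protein_id`, `n_ptms`, `length`, `load`.
#' @export
ptm_load <- function(records, protein_lengths) {
  counts <- records |>
    dplyr::count(.data$protein_id, name = "n_ptms")
  counts$length <- unname(protein_lengths[counts$protein_id])
  bad <- is.na(counts$length) | counts$length <= 0
  if (any(bad)) {
    warning("no valid length for protein(s): ",
            paste(counts$protein_id[bad], collapse = ", "),
            "; skipped", call. = FALSE)
    counts <- counts[!bad, , drop = FALSE]
  }
  dplyr::mutate(counts, load = .data$n_ptms / .data$length)
}

#' PTM enrichment within a residue region
#'
#' Fraction of a member's (or family's) PTM records falling inside a
#' 1-based closed residue interval, with a per-modification-type
#' breakdown — e.g. how many of a family's phosphorylations sit in a
#' disordered N-terminal tail.
#'
#' @param records PTM record tibble (optionally pre-filtered to one
#'   protein).
#' @param start,end region bounds (1-based, closed).
#' @return list with `n_region`, `n_total`, `fraction`, and `per_type`
#'   (tibble: mod_type, n_region, n_total, fraction).
#' @export
region_enrichment <- function(records, start, end) {
  stopifnot(start >= 1, end >= start)
  inside <- records$residue_index >= start & records$residue_index <= end
  per_type <- records |>
    dplyr::mutate(inside = inside) |>
    dplyr::group_by(.data$mod_type) |>
    dplyr::summarise(n_region = sum(.data$inside), n_total = dplyr::n(),
                     fraction = mean(.data$inside), .groups = "drop")
  list(n_region = sum(inside), n_total = nrow(records),
       fraction = if (nrow(records) > 0) mean(inside) else 0,
       per_type = per_type)
}

#' Distribution of PTM-type multiplicity across hotspots
#'
#' Fractions of hotspots carrying exactly one, exactly two, and three or
#' more distinct PTM types, plus a co-occurrence table counting hotspots
#' that contain each unordered pair of types.
#'
#' @param hotspots hotspot tibble from [build_hotspots()].
#' @return list with `fractions` (named: `single`, `double`,
#'   `three_plus`; sums to 1) and `pairs` (tibble: type_a, type_b, n).
#' @export
multi_type_distribution <- function(hotspots) {
  stopifnot(nrow(hotspots) >= 1)
  nt <- hotspots$n_types
  fr <- c(single = mean(nt == 1), double = mean(nt == 2),
          three_plus = mean(nt >= 3))
  pairs <- purrr::map_dfr(hotspots$per_type_counts, function(cnt) {
    types <- sort(names(cnt))
    if (length(types) < 2) return(NULL)
    cmb <- combn(types, 2)
    tibble::tibble(type_a = cmb[1, ], type_b = cmb[2, ])
  })
  pairs <- if (nrow(pairs) > 0) {
    dplyr::count(pairs, .data$type_a, .data$type_b, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  } else {
    tibble::tibble(type_a = character(), type_b = character(),
                   n = integer())
  }
  list(fractions = fr, pairs = pairs)
}
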
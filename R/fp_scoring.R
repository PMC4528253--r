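#' Weights and thresholds of the Function Potential score
#'
#' All tunable constants of the FP calculation in one block. Defaults:
#' interface boost `w_if = 1` (an interface residue doubles its interface
#' score), burial threshold `burial_threshold = 0.05` on relative SASA,
#' `buried_penalty = burial_threshold` (a buried residue scores as if its
#' relative SASA sat exactly at the threshold, so the exposed and buried
#' branches join continuously), `prc_scale = 100` (PRC enters as a
#' percent), `cs_scale = 1`, and `ps_mode = "linear"` (`"log"` selects a
#' log-damped PTM score `1 + ln(count)` that saturates high counts).
#'
#' @param w_if interface boost, >= 0.
#' @param burial_threshold relative-SASA threshold in (0, 1).
#' @param buried_penalty SASA factor used on the buried branch.
#' @param prc_scale scale applied to PRC (default 100 -> percent).
#' @param cs_scale scale applied to CS.
#' @param ps_mode `"linear"` or `"log"`.
#' @return object of class `fp_weights`.
#' @export
fp_weights <- function(w_if = 1, burial_threshold = 0.05,
                       buried_penalty = burial_threshold,
                       prc_scale = 100, cs_scale = 1,
                       ps_mode = c("linear", "log")) {
  ps_mode <- match.arg(ps_mode)
  stopifnot(w_if >= 0, burial_threshold > 0, burial_threshold < 1,
            buried_penalty > 0, prc_scale > 0, cs_scale > 0)
  structure(list(w_if = w_if, burial_threshold = burial_threshold,
                 buried_penalty = buried_penalty, prc_scale = prc_scale,
                 cs_scale = cs_scale, ps_mode = ps_mode),
            class = "fp_weights")
}

#' PTM score (PS): the intensity term of FP
#'
#' Defaults to the raw observation count; the log-damped alternative
#' `1 + ln(count)` tempers very deep hotspots.
#'
#' @param total_ptms positive integer vector of hotspot counts.
#' @param mode `"linear"` (default) or `"log"`.
#' @return numeric vector.
#' @export
ptm_score <- function(total_ptms, mode = c("linear", "log")) {
  mode <- match.arg(mode)
  stopifnot(all(total_ptms >= 1))
  if (mode == "linear") as.numeric(total_ptms) else 1 + log(total_ptms)
}

#' Interface score (IS): PS boosted at protein interfaces
#'
#' `IS = PS * (1 + w_if)` when the hotspot residue sits at an inter-chain
#' interface, else `IS = PS`.
#'
#' @param ps PTM score vector, > 0.
#' @param interface logical vector.
#' @param w_if interface boost (default 1).
#' @return numeric vector.
#' @export
interface_score <- function(ps, interface, w_if = 1) {
  stopifnot(all(ps > 0), length(interface) == length(ps))
  ps * ifelse(interface, 1 + w_if, 1)
}

#' Function Potential score per hotspot
#'
#' Joins hotspots to the projection target's per-residue structural
#' information by alignment column and computes, for each hotspot,
#'
#' exposed branch (relative SASA >= threshold, or disordered unresolved):
#' `FP = IS x relative_sasa x (cs_scale x CS) x (prc_scale x PRC)`
#'
#' buried branch (`FP_b`):
#' `FP_b = IS x buried_penalty x (cs_scale x CS) x (prc_scale x PRC)`
#'
#' so FP increases with observation count, accessibility, interface
#' residence and conservation, and the two branches agree at the burial
#' threshold when `buried_penalty = burial_threshold`. All factors are
#' kept in the output for audit. Hotspots whose column has no structural
#' record (unresolved, not disordered) are skipped with a warning.
#'
#' @param hotspots tibble from [build_hotspots()].
#' @param info tibble from [residue_structure_info()].
#' @param weights an [fp_weights()] object.
#' @return tibble with one row per scored hotspot: hotspot fields plus
#'   `PS`, `IS`, `relative_sasa`, `interface`, `branch`, `fp`.
#' @export
score_hotspots <- function(hotspots, info, weights = fp_weights()) {
  stopifnot(inherits(weights, "fp_weights"))
  idx <- match(hotspots$column, info$column)
  miss <- is.na(idx)
  if (any(miss)) {
    warning(sum(miss), " hotspot(s) without structural information ",
            "skipped (column(s) ",
            paste(hotspots$column[miss], collapse = ", "), ")",
            call. = FALSE)
  }
  hs <- hotspots[!miss, , drop = FALSE]
  ri <- info[idx[!miss], , drop = FALSE]

  ps <- ptm_score(hs$total_ptms, mode = weights$ps_mode)
  is_ <- interface_score(ps, ri$interface, w_if = weights$w_if)
  exposed <- ri$relative_sasa >= weights$burial_threshold |
    ri$disordered_unresolved
  sasa_factor <- ifelse(exposed, ri$relative_sasa, weights$buried_penalty)
  fp <- is_ * sasa_factor * (weights$cs_scale * hs$CS) *
    (weights$prc_scale * hs$PRC)

  dplyr::bind_cols(
    hs,
    tibble::tibble(
      PS = ps, IS = is_,
      relative_sasa = ri$relative_sasa,
      interface = ri$interface,
      disordered_unresolved = ri$disordered_unresolved,
      branch = ifelse(exposed, "exposed", "buried"),
      fp = fp
    )
  )
}

#' Rank hotspots by Function Potential
#'
#' Orders scored hotspots by descending FP within the chosen grouping
#' (per family, or pooled across families), with deterministic
#' tie-breaking by total PTMs (descending) then column (ascending), and
#' attaches the grouping median FP and each hotspot's fold over that
#' median.
#'
#' @param scored tibble from [score_hotspots()].
#' @param group_by `"family"` (median within each `family_id`) or
#'   `"pooled"` (one median across everything).
#' @return tibble of class `fp_ranking`, sorted, with `rank`,
#'   `family_median_fp`, `fold_over_median` added.
#' @export
rank_hotspots <- function(scored, group_by = c("family", "pooled")) {
  group_by <- match.arg(group_by)
  stopifnot(nrow(scored) >= 1)
  g <- if (group_by == "family") scored$family_id else "all"
  out <- scored |>
    dplyr::mutate(.grp = g) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::arrange(dplyr::desc(.data$fp), dplyr::desc(.data$total_ptms),
                   .data$column, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  family_median_fp = median(.data$fp),
                  fold_over_median = ifelse(.data$family_median_fp > 0,
                                            .data$fp / .data$family_median_fp,
                                            NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select(-".grp")
  class(out) <- c("fp_ranking", class(out))
  attr(out, "group_by") <- group_by
  out
}

#' Write a scored-hotspot table to TSV
#'
#' @param ranking an `fp_ranking` (or scored-hotspot tibble).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fp_table <- function(ranking, path) {
  flat <- ranking |>
    dplyr::mutate(
      per_type_counts = vapply(.data$per_type_counts, function(x)
        as.character(jsonlite::toJSON(as.list(x), auto_unbox = TRUE)),
        character(1))
    ) |>
    dplyr::select(-dplyr::any_of(c("contributing", "observed_res")))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
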
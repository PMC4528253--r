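#' Column conservation score (CS)
#'
#' Fraction of non-gap rows at an alignment column carrying the modal
#' residue. Gaps are excluded from both numerator and denominator by
#' default (`count_gaps = FALSE`); with `count_gaps = TRUE` gapped rows
#' stay in the denominator, so gaps count against conservation. An
#' all-gap column scores 0. A custom scorer (e.g. similarity-class
#' weighting) can be plugged in via `scorer`.
#'
#' @param alignment a [family_alignment()].
#' @param column 1-based column index.
#' @param count_gaps keep gapped rows in the denominator?
#' @param scorer optional `function(residues_chr) -> numeric in [0,1]`
#'   applied to the column's non-gap residues, overriding the modal rule.
#' @return numeric in \[0, 1\].
#' @export
column_conservation <- function(alignment, column, count_gaps = FALSE,
                                scorer = NULL) {
  col <- column_residues(alignment, column)
  res <- col[col != "-"]
  if (length(res) == 0) return(0)
  if (!is.null(scorer)) return(scorer(res))
  denom <- if (count_gaps) length(col) else length(res)
  max(table(res)) / denom
}

#' Modifiable-residue conservation (PRC)
#'
#' Fraction of non-gap rows at a column whose residue belongs to the union
#' of modifiable-residue sets for the hotspot's modification types
#' (S/T/Y for phosphorylation, K for ubiquitination, ...). For
#' `other:<label>` types the residues actually observed modified at the
#' column stand in for the table entry.
#'
#' @param alignment a [family_alignment()].
#' @param column 1-based column index.
#' @param mod_types nonempty character vector of normalized PTM types.
#' @param observed residues observed modified at the column (for `other:`).
#' @return numeric in \[0, 1\].
#' @export
modifiable_residue_conservation <- function(alignment, column, mod_types,
                                            observed = character()) {
  stopifnot(length(mod_types) >= 1)
  col <- column_residues(alignment, column)
  res <- col[col != "-"]
  if (length(res) == 0) return(0)
  ok <- modifiable_residues(mod_types, observed = observed)
  mean(res %in% ok)
}

column_residues <- function(alignment, column) {
  if (column < 1 || column > alignment$width) {
    stop("column ", column, " out of range 1..", alignment$width,
         call. = FALSE)
  }
  vapply(alignment$members, substr, character(1), column, column)
}

#' Build PTM hotspots from records and a family alignment
#'
#' Maps each deduplicated PTM record to its alignment column through the
#' member's residue-to-column map and aggregates per column: one hotspot
#' per column receiving at least one PTM. A hotspot carries the total PTM
#' count ("hotspot intensity"), per-type counts, the number of distinct
#' PTM types, whether any contributing record has known function, column
#' conservation (CS) and modifiable-residue conservation (PRC).
#'
#' Records are cross-validated against the alignment: a record whose
#' residue letter disagrees with the member sequence at that position is
#' excluded with a warning (catches off-by-one and isoform mismatches),
#' as are records beyond the member length and records on proteins absent
#' from `id_map`.
#'
#' @param records deduplicated PTM record tibble (see [deduplicate_ptms()]).
#' @param alignment a [family_alignment()].
#' @param id_map named character vector `protein_id -> member_id`; by
#'   default protein ids are assumed to equal member ids.
#' @param count_gaps passed to [column_conservation()].
#' @return tibble with one row per hotspot: `family_id`, `column`,
#'   `total_ptms`, `n_types`, `per_type_counts` (list of named integer
#'   vectors), `contributing` (list of tibbles: member_id, residue_index,
#'   mod_type), `known_function`, `CS`, `PRC`.
#' @export
build_hotspots <- function(records, alignment, id_map = NULL,
                           count_gaps = FALSE) {
  if (is.null(id_map)) {
    ids <- unique(records$protein_id)
    id_map <- setNames(ids, ids)
  }
  recs <- records
  recs$member_id <- unname(id_map[recs$protein_id])

  unmapped <- is.na(recs$member_id) | !recs$member_id %in% names(alignment$members)
  if (any(unmapped)) {
    warning(sum(unmapped), " record(s) on proteins absent from the alignment: ",
            paste(unique(recs$protein_id[unmapped]), collapse = ", "),
            call. = FALSE)
    recs <- recs[!unmapped, , drop = FALSE]
  }
  if (nrow(recs) > 0) {
    mlen <- vapply(recs$member_id,
                   function(m) length(alignment$residue_to_column[[m]]),
                   integer(1))
    too_long <- recs$residue_index > mlen
    if (any(too_long)) {
      warning(sum(too_long), " record(s) with residue_index beyond member ",
              "length excluded", call. = FALSE)
      recs <- recs[!too_long, , drop = FALSE]
    }
  }
  if (nrow(recs) > 0) {
    seq_res <- vapply(seq_len(nrow(recs)), function(i) {
      substr(member_sequence(alignment, recs$member_id[i]),
             recs$residue_index[i], recs$residue_index[i])
    }, character(1))
    mismatch <- seq_res != recs$residue
    if (any(mismatch)) {
      warning(sum(mismatch), " record(s) whose residue letter disagrees ",
              "with the alignment sequence excluded: ",
              paste(unique(paste0(recs$member_id[mismatch], ":",
                                  recs$residue_index[mismatch])),
                    collapse = ", "), call. = FALSE)
      recs <- recs[!mismatch, , drop = FALSE]
    }
  }
  if (nrow(recs) == 0) {
    return(tibble::tibble(
      family_id = character(), column = integer(), total_ptms = integer(),
      n_types = integer(), per_type_counts = list(), contributing = list(),
      known_function = logical(), CS = numeric(), PRC = numeric()
    ))
  }

  recs$column <- vapply(seq_len(nrow(recs)), function(i) {
    alignment$residue_to_column[[recs$member_id[i]]][recs$residue_index[i]]
  }, integer(1))

  hs <- recs |>
    dplyr::group_by(column = .data$column) |>
    dplyr::summarise(
      total_ptms = dplyr::n(),
      n_types = dplyr::n_distinct(.data$mod_type),
      per_type_counts = list(table_to_counts(.data$mod_type)),
      contributing = list(dplyr::pick("member_id", "residue_index",
                                      "mod_type")),
      known_function = any(.data$known_function),
      observed_res = list(unique(.data$residue)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$column)

  hs$CS <- vapply(hs$column, function(cc)
    column_conservation(alignment, cc, count_gaps = count_gaps), numeric(1))
  hs$PRC <- vapply(seq_len(nrow(hs)), function(i)
    modifiable_residue_conservation(alignment, hs$column[i],
                                    names(hs$per_type_counts[[i]]),
                                    observed = hs$observed_res[[i]]),
    numeric(1))
  hs$family_id <- alignment$family_id
  hs |>
    dplyr::select("family_id", "column", "total_ptms", "n_types",
                  "per_type_counts", "contributing", "known_function",
                  "CS", "PRC")
}

table_to_counts <- function(types) {
  tab <- table(types)
  setNames(as.integer(tab), names(tab))
}

#' Write a hotspot table to TSV
#'
#' List-columns are serialized to JSON cells so the table round-trips as
#' plain text.
#'
#' @param hotspots hotspot tibble from [build_hotspots()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hotspot_table <- function(hotspots, path) {
  flat <- hotspots |>
    dplyr::mutate(
      per_type_counts = vapply(.data$per_type_counts, function(x)
        as.character(jsonlite::toJSON(as.list(x), auto_unbox = TRUE)),
        character(1)),
      contributing = vapply(.data$contributing, function(x)
        as.character(jsonlite::toJSON(x)), character(1))
    )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
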
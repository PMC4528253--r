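#' Read a table of experimentally observed PTM records
#'
#' Reads a TSV (header row required) of per-site post-translational
#' modification observations into a validated tibble, one row per record.
#' A column-name map (`dialect`) adapts headers from heterogeneous source
#' databases without bespoke parsers per source.
#'
#' Required columns (after dialect mapping): `protein_id`, `residue_index`,
#' `residue`, `mod_type`. Optional columns default when absent:
#' `organism` (NA), `evidence` (NA), `experimental` (TRUE),
#' `known_function` (FALSE), `citation` (NA).
#'
#' @param path path to a tab-separated file with a header row (UTF-8).
#' @param dialect named character vector mapping canonical column names to
#'   the names used in the file, e.g. `c(protein_id = "uniprot_ac")`.
#' @return a tibble of PTM records. Rows whose `residue_index` does not
#'   parse as a positive integer are rejected with an error naming the line.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\tresidue_index\tresidue\tmod_type",
#'              "P1\t7\tS\tphosphorylation"), tf)
#' read_ptm_table(tf)
#' @export
read_ptm_table <- function(path, dialect = character()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    return(empty_ptm_tbl())
  }
  # apply dialect: canonical <- file column
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (src %in% names(raw)) names(raw)[names(raw) == src] <- canon
  }
  required <- c("protein_id", "residue_index", "residue", "mod_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("PTM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_ptm_tbl())

  idx <- suppressWarnings(as.integer(raw$residue_index))
  bad <- which(is.na(idx) | idx < 1)
  if (length(bad) > 0) {
    # +1 for the header row so the message points at file lines
    stop("unparseable residue_index at file line(s): ",
         paste(bad + 1L, collapse = ", "),
         " (values: ", paste(raw$residue_index[bad], collapse = ", "), ")",
         call. = FALSE)
  }

  res <- toupper(trimws(raw$residue))
  bad_res <- which(!res %in% AA_LETTERS)
  if (length(bad_res) > 0) {
    stop("invalid residue letter at file line(s): ",
         paste(bad_res + 1L, collapse = ", "), call. = FALSE)
  }

  opt_chr <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else NA_character_
  }
  opt_lgl <- function(col, default) {
    if (!col %in% names(raw)) return(rep(default, nrow(raw)))
    v <- tolower(trimws(raw[[col]]))
    out <- v %in% c("true", "t", "1", "yes")
    out[is.na(v) | v == ""] <- default
    out
  }

  tibble::tibble(
    protein_id     = as.character(raw$protein_id),
    organism       = opt_chr("organism"),
    residue_index  = idx,
    residue        = res,
    mod_type       = normalize_mod_type(as.character(raw$mod_type)),
    evidence       = opt_chr("evidence"),
    experimental   = opt_lgl("experimental", TRUE),
    known_function = opt_lgl("known_function", FALSE),
    citation       = opt_chr("citation")
  )
}

empty_ptm_tbl <- function() {
  tibble::tibble(
    protein_id = character(), organism = character(),
    residue_index = integer(), residue = character(),
    mod_type = character(), evidence = character(),
    experimental = logical(), known_function = logical(),
    citation = character()
  )
}

#' Collapse redundant PTM records
#'
#' Source databases overlap heavily; the nonredundant unit is the key
#' `(protein_id, residue_index, mod_type)`. Duplicates are merged:
#' `known_function` is OR-merged, citations and evidence labels are
#' concatenated (`;`-joined, deduplicated), `experimental` is OR-merged.
#' Output is sorted by key, so deduplication is deterministic and
#' idempotent.
#'
#' @param records a PTM record tibble (see [read_ptm_table()]).
#' @return a tibble with one row per key.
#' @export
deduplicate_ptms <- function(records) {
  if (nrow(records) == 0) return(records)
  conflicts <- records |>
    dplyr::group_by(.data$protein_id, .data$residue_index) |>
    dplyr::summarise(n_res = dplyr::n_distinct(.data$residue),
                     .groups = "drop") |>
    dplyr::filter(.data$n_res > 1)
  if (nrow(conflicts) > 0) {
    stop("conflicting residue letters for ",
         paste(conflicts$protein_id, conflicts$residue_index,
               sep = ":", collapse = ", "), call. = FALSE)
  }
  join_vals <- function(x) {
    x <- unique(x[!is.na(x) & nzchar(x)])
    if (length(x) == 0) NA_character_ else paste(x, collapse = ";")
  }
  records |>
    dplyr::group_by(.data$protein_id, .data$residue_index, .data$mod_type) |>
    dplyr::summarise(
      organism = dplyr::first(.data$organism),
      residue = dplyr::first(.data$residue),
      evidence = join_vals(.data$evidence),
      experimental = any(.data$experimental),
      known_function = any(.data$known_function),
      citation = join_vals(.data$citation),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(names(empty_ptm_tbl()))) |>
    dplyr::arrange(.data$protein_id, .data$residue_index, .data$mod_type)
}

#' Filter PTM records by evidence class and organism
#'
#' Keeps experimentally observed records (dropping predicted sites) and,
#' optionally, records whose organism satisfies a caller-supplied predicate
#' (the analysis is usually restricted to eukaryotes; the predicate keeps
#' taxonomy out of this package). Counts of removed records are reported
#' by reason via `message()`.
#'
#' @param records PTM record tibble.
#' @param keep_experimental_only drop records with `experimental = FALSE`.
#' @param organism_keep `NULL`, or a predicate `function(organism) -> logical`.
#' @return filtered tibble, original row order preserved.
#' @export
filter_ptms <- function(records, keep_experimental_only = TRUE,
                        organism_keep = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (keep_experimental_only) {
    drop_pred <- !records$experimental
    if (any(drop_pred)) {
      message(sum(drop_pred), " predicted (non-experimental) record(s) removed")
    }
    keep <- keep & !drop_pred
  }
  if (!is.null(organism_keep)) {
    ok <- as.logical(organism_keep(records$organism))
    ok[is.na(ok)] <- FALSE
    if (any(!ok & keep)) {
      message(sum(!ok & keep), " record(s) removed by organism filter")
    }
    keep <- keep & ok
  }
  if (!any(keep) && nrow(records) > 0) {
    warning("all PTM records removed by filters", call. = FALSE)
  }
  records[keep, , drop = FALSE]
}

#' Attach known-function annotations to PTM records
#'
#' Marks records with literature-documented biological function. The
#' annotation table carries the same key as the records
#' (`protein_id`, `residue_index`, `mod_type`) plus an optional `citation`.
#' Matching records get `known_function = TRUE` and the citation appended;
#' annotation rows matching no record are reported as orphans (warning,
#' not an error).
#'
#' @param records PTM record tibble.
#' @param function_table tibble/data.frame with columns `protein_id`,
#'   `residue_index`, `mod_type` and optionally `citation`.
#' @return the records tibble with updated flags.
#' @export
annotate_known_function <- function(records, function_table) {
  ft <- tibble::as_tibble(function_table)
  stopifnot(all(c("protein_id", "residue_index", "mod_type") %in% names(ft)))
  ft$residue_index <- as.integer(ft$residue_index)
  ft$mod_type <- normalize_mod_type(as.character(ft$mod_type))
  if (!"citation" %in% names(ft)) ft$citation <- NA_character_

  key <- function(d) paste(d$protein_id, d$residue_index, d$mod_type, sep = "\r")
  rk <- key(records)
  fk <- key(ft)
  orphan <- !fk %in% rk
  if (any(orphan)) {
    warning(sum(orphan), " known-function annotation(s) match no record: ",
            paste(utils::head(paste(ft$protein_id[orphan],
                                    ft$residue_index[orphan], sep = ":"), 5),
                  collapse = ", "), call. = FALSE)
  }
  hits <- match(rk, fk)
  flagged <- !is.na(hits)
  records$known_function <- records$known_function | flagged
  new_cit <- vapply(seq_len(nrow(records)), function(i) {
    if (!flagged[i]) return(records$citation[i])
    cits <- unique(c(records$citation[i], ft$citation[fk %in% rk[i]]))
    cits <- cits[!is.na(cits) & nzchar(cits)]
    if (length(cits) == 0) NA_character_ else paste(cits, collapse = ";")
  }, character(1))
  records$citation <- new_cit
  records
}
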
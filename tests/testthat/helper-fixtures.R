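# Small in-code builders shared across test files.

make_records <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      protein_id = r[[1]], organism = r$organism %||% "yeast",
      residue_index = as.integer(r[[2]]), residue = r[[3]],
      mod_type = r[[4]],
      evidence = r$evidence %||% "testdb",
      experimental = r$experimental %||% TRUE,
      known_function = r$known_function %||% FALSE,
      citation = r$citation %||% NA_character_
    )
  }))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_tsv_file <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# minimal PDB text: one ATOM line per row of a data frame with
# chain, resno, resid, elety, x, y, z (+ optional alt, occ, elesy)
write_pdb_file <- function(df, path = tempfile(fileext = ".pdb"),
                           models = NULL) {
  fmt <- function(d, start_no = 1L) {
    sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(d)) + start_no - 1L,
      substr(paste0(" ", d$elety), 1, 4),
      d[["alt"]] %||% rep(" ", nrow(d)),
      d$resid, d$chain, d$resno, d$x, d$y, d$z,
      d[["occ"]] %||% rep(1, nrow(d)), rep(0, nrow(d)),
      d[["elesy"]] %||% substr(d$elety, 1, 1))
  }
  if (is.null(models)) {
    writeLines(c(fmt(df), "END"), path)
  } else {
    out <- character(0)
    for (k in seq_along(models)) {
      out <- c(out, sprintf("MODEL     %4d", k), fmt(models[[k]]), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  }
  path
}

# brute-force all-pairs inter-chain contact oracle
oracle_interface <- function(model, cutoff = 5.0) {
  at <- model$atoms
  hits <- c()
  for (i in seq_len(nrow(at))) {
    d2 <- (at$x - at$x[i])^2 + (at$y - at$y[i])^2 + (at$z - at$z[i])^2
    if (any(d2 < cutoff^2 & at$chain != at$chain[i])) {
      hits <- c(hits, i)
    }
  }
  unique(paste(at$chain[hits], at$resno[hits], at$insert[hits]))
}

# brute-force column-grouping oracle for hotspot counts
oracle_hotspot_counts <- function(records, alignment) {
  cols <- integer(0)
  for (i in seq_len(nrow(records))) {
    m <- records$protein_id[i]
    if (!m %in% names(alignment$members)) next
    r2c <- alignment$residue_to_column[[m]]
    if (records$residue_index[i] > length(r2c)) next
    seq_i <- ptmfp::member_sequence(alignment, m)
    if (substr(seq_i, records$residue_index[i],
               records$residue_index[i]) != records$residue[i]) next
    cols <- c(cols, r2c[records$residue_index[i]])
  }
  table(cols)
}
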
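#' Family alignment object
#'
#' A `family_alignment` holds the aligned members of one protein family
#' plus explicit residue-to-column maps in both directions. Alignment
#' columns and residue indices are 1-based throughout; the gap character is
#' `-` (`.` is accepted on input and treated as `-`).
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths, gaps as `-`).
#' @param family_id family identifier string.
#' @return an object of class `family_alignment` with elements
#'   `family_id`, `members` (named aligned strings), `width`,
#'   `residue_to_column` (per member, integer vector: ungapped residue
#'   index -> column) and `column_to_residue` (per member, integer vector
#'   of length `width`, `NA` at gaps).
#' @export
family_alignment <- function(sequences, family_id = "family") {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("aligned sequences must be named by member id", call. = FALSE)
  }
  sequences <- toupper(chartr(".", "-", sequences))
  w <- unique(nchar(sequences))
  if (length(w) != 1) {
    ragged <- names(sequences)[nchar(sequences) != nchar(sequences)[1]]
    stop("ragged alignment: member(s) ", paste(ragged, collapse = ", "),
         " differ in length", call. = FALSE)
  }
  if (w < 1) stop("alignment has zero columns", call. = FALSE)

  r2c <- lapply(sequences, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] != "-")
  })
  c2r <- lapply(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- rep(NA_integer_, length(ch))
    out[ch != "-"] <- seq_len(sum(ch != "-"))
    out
  })
  structure(
    list(family_id = family_id, members = sequences, width = w,
         residue_to_column = r2c, column_to_residue = c2r),
    class = "family_alignment"
  )
}

#' @export
print.family_alignment <- function(x, ...) {
  cat("<family_alignment> ", x$family_id, ": ", length(x$members),
      " members x ", x$width, " columns\n", sep = "")
  invisible(x)
}

#' Ungapped sequence of one alignment member
#' @param alignment a `family_alignment`.
#' @param member_id member name.
#' @return character scalar (no gaps).
#' @export
member_sequence <- function(alignment, member_id) {
  s <- alignment$members[[member_id]]
  if (is.null(s)) stop("unknown member: ", member_id, call. = FALSE)
  gsub("-", "", s, fixed = TRUE)
}

#' Read an aligned FASTA file into a family alignment
#'
#' @param path aligned FASTA file (equal-length sequences; `-` or `.` gaps).
#' @param family_id family identifier attached to the object.
#' @return a [family_alignment()].
#' @export
read_alignment <- function(path, family_id = "family") {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 1) stop("no sequences in ", path, call. = FALSE)
  seqs <- as.character(aa)
  # FASTA headers may carry descriptions; member id = first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  family_alignment(seqs, family_id = family_id)
}

#' Align a family with an external aligner
#'
#' Shells out to a multiple-sequence aligner that reads FASTA on a file
#' argument and writes aligned FASTA to stdout (muscle- or mafft-style),
#' then parses the result with [read_alignment()]. The package never
#' bundles an aligner: if none is available the pipeline is still fully
#' usable with pre-aligned FASTA input.
#'
#' @param fasta_path unaligned FASTA file.
#' @param family_id family identifier.
#' @param aligner_cmd character vector: command and arguments; the input
#'   path is appended as the final argument. `NULL` probes for `muscle`
#'   then `mafft --auto`.
#' @return a [family_alignment()].
#' @export
align_family <- function(fasta_path, family_id = "family",
                         aligner_cmd = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 1) {
    s <- as.character(seqs)
    names(s) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
    return(family_alignment(s, family_id = family_id))
  }
  if (is.null(aligner_cmd)) {
    if (nzchar(Sys.which("mafft"))) {
      aligner_cmd <- c("mafft", "--auto", "--quiet")
    } else {
      stop("no multiple-sequence aligner found on PATH; ",
           "supply aligner_cmd or pre-aligned FASTA to read_alignment()",
           call. = FALSE)
    }
  }
  exe <- aligner_cmd[[1]]
  if (!nzchar(Sys.which(exe))) {
    stop("aligner '", exe, "' not found on PATH; ",
         "supply pre-aligned FASTA to read_alignment() instead",
         call. = FALSE)
  }
  out <- tempfile(fileext = ".afa")
  args <- c(aligner_cmd[-1], fasta_path)
  message("aligning with: ", paste(c(exe, args), collapse = " "))
  status <- system2(exe, args, stdout = out, stderr = FALSE)
  if (status != 0 || !file.size(out) > 0) {
    stop("aligner '", exe, "' failed (exit ", status, ")", call. = FALSE)
  }
  read_alignment(out, family_id = family_id)
}
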
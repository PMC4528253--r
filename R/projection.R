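#' Map alignment columns onto structure residues
#'
#' Pairs one alignment member with one structure chain and produces the
#' column -> author residue number map used to project hotspots. The
#' chain's one-letter sequence is first searched as an exact substring of
#' the member's ungapped sequence; failing that, a pairwise alignment
#' (local, BLOSUM62) resolves unresolved internal stretches. Pairings
#' with under 90 percent identity over the mapped span are rejected as a
#' wrong chain/member pairing. The numbering offset between author and
#' member coordinates is reported via message.
#'
#' @param alignment a [family_alignment()].
#' @param member_id the alignment member the chain represents.
#' @param model a `structure_model`.
#' @param chain_id chain of `model` to map; default first chain.
#' @param min_identity identity threshold on the mapped span (default 0.9).
#' @return object of class `target_map`: list with `family_id`,
#'   `member_id`, `chain_id` and `map`, a tibble with one row per member
#'   residue: `residue_index`, `column`, `resno`, `insert`, `resolved`.
#'   `resno` is `NA` for residues absent from the structure.
#' @export
map_alignment_to_structure <- function(alignment, member_id, model,
                                       chain_id = NULL,
                                       min_identity = 0.9) {
  if (is.null(chain_id)) chain_id <- model$atoms$chain[1]
  cres <- chain_residues(model, chain_id)
  chain_seq <- paste(cres$resletter, collapse = "")
  mseq <- member_sequence(alignment, member_id)

  # member residue index for each chain residue (NA if unalignable)
  chain_to_member <- rep(NA_integer_, nrow(cres))
  pos <- regexpr(chain_seq, mseq, fixed = TRUE)
  if (pos > 0) {
    chain_to_member <- seq.int(pos, length.out = nrow(cres))
    identity <- 1
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(chain_seq), Biostrings::AAString(mseq),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ci <- Biostrings::start(Biostrings::pattern(aln)) - 1L
    mi <- Biostrings::start(Biostrings::subject(aln)) - 1L
    n_match <- 0L
    n_mapped <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-") ci <- ci + 1L
      if (sa[k] != "-") mi <- mi + 1L
      if (pa[k] != "-" && sa[k] != "-") {
        chain_to_member[ci] <- mi
        n_mapped <- n_mapped + 1L
        if (pa[k] == sa[k]) n_match <- n_match + 1L
      }
    }
    identity <- if (n_mapped > 0) n_match / n_mapped else 0
  }
  coverage <- mean(!is.na(chain_to_member))
  if (identity < min_identity || coverage < 0.5) {
    stop(sprintf(
      paste0("chain %s matches member %s at %.1f%% identity / %.0f%% ",
             "coverage: wrong pairing?"),
      chain_id, member_id, 100 * identity, 100 * coverage),
      call. = FALSE)
  }
  mapped <- which(!is.na(chain_to_member))
  if (length(mapped) > 0) {
    offs <- unique(cres$resno[mapped] - chain_to_member[mapped])
    message("author-numbering offset(s) for chain ", chain_id, ": ",
            paste(offs, collapse = ", "))
  }

  r2c <- alignment$residue_to_column[[member_id]]
  map <- tibble::tibble(
    residue_index = seq_len(nchar(mseq)),
    column = r2c,
    resno = NA_integer_, insert = NA_character_
  )
  map$resno[chain_to_member[mapped]] <- cres$resno[mapped]
  map$insert[chain_to_member[mapped]] <- cres$insert[mapped]
  map$resolved <- !is.na(map$resno)
  if (anyDuplicated(map$resno[map$resolved]) > 0) {
    stop("column-to-residue map is not injective for chain ", chain_id,
         call. = FALSE)
  }
  structure(list(family_id = alignment$family_id, member_id = member_id,
                 chain_id = chain_id, map = map),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat("<target_map> ", x$family_id, "/", x$member_id, " -> chain ",
      x$chain_id, ": ", sum(x$map$resolved), "/", nrow(x$map),
      " residues resolved\n", sep = "")
  invisible(x)
}

#' Read a per-residue disorder annotation
#'
#' TSV of residue ranges annotated as intrinsically disordered, with
#' columns `member_id`, `start`, `end` (1-based, closed).
#'
#' @param path TSV file.
#' @return tibble with `member_id`, `residue_index`, one row per
#'   disordered residue.
#' @export
read_disorder_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = "cii", progress = FALSE)
  stopifnot(all(c("member_id", "start", "end") %in% names(d)))
  tidyr::unnest(
    dplyr::mutate(d, residue_index = purrr::map2(.data$start, .data$end,
                                                 seq)),
    "residue_index") |>
    dplyr::select("member_id", "residue_index") |>
    dplyr::distinct()
}

#' Per-residue structural information for a projection target
#'
#' Combines the isolated-chain SASA, the interface set, and the disorder
#' annotation into one record per member residue. Resolved residues take
#' their computed SASA and interface flag; residues absent from the
#' structure take the maximum SASA of their residue type (relative SASA
#' 1, fully exposed) if annotated disordered — unresolved termini such as
#' flexible tails are solvent-exposed in vivo even though the crystal
#' cannot see them — and are otherwise excluded from scoring with a
#' warning. `buried` marks resolved residues whose relative SASA falls
#' below `burial_threshold`.
#'
#' @param alignment a [family_alignment()].
#' @param target_map a [map_alignment_to_structure()] result.
#' @param sasa_tbl per-residue SASA from [shrake_rupley_sasa()] on the
#'   mapped chain.
#' @param interface_tbl interface residues from
#'   [detect_interface_residues()] (may cover all chains).
#' @param disorder `NULL`, or tibble (`member_id`, `residue_index`) from
#'   [read_disorder_tsv()].
#' @param burial_threshold relative-SASA threshold below which a residue
#'   counts as buried (default 0.05).
#' @param assume_terminal_disorder treat unresolved terminal runs of at
#'   most `max_terminal_run` residues as disordered even without an
#'   annotation.
#' @param max_terminal_run run-length limit for the terminal heuristic.
#' @return tibble: `member_id`, `residue_index`, `column`, `resletter`,
#'   `resno`, `sasa`, `relative_sasa`, `buried`, `interface`,
#'   `disordered_unresolved`.
#' @export
residue_structure_info <- function(alignment, target_map, sasa_tbl,
                                   interface_tbl = NULL, disorder = NULL,
                                   burial_threshold = 0.05,
                                   assume_terminal_disorder = FALSE,
                                   max_terminal_run = 30L) {
  member_id <- target_map$member_id
  mseq <- strsplit(member_sequence(alignment, member_id), "")[[1]]
  map <- target_map$map
  n <- length(mseq)
  stopifnot(nrow(map) == n)

  dis_idx <- integer(0)
  if (!is.null(disorder)) {
    dis_idx <- disorder$residue_index[disorder$member_id == member_id]
  }
  if (assume_terminal_disorder) {
    runs <- unresolved_terminal_runs(map$resolved, max_terminal_run)
    dis_idx <- union(dis_idx, runs)
  }

  iface_key <- character(0)
  if (!is.null(interface_tbl) && nrow(interface_tbl) > 0) {
    iface_key <- paste(interface_tbl$chain, interface_tbl$resno,
                       interface_tbl$insert)
  }

  sasa_by_resno <- setNames(sasa_tbl$sasa,
                            paste(sasa_tbl$resno, sasa_tbl$insert))
  rs_by_resno <- setNames(sasa_tbl$relative_sasa,
                          paste(sasa_tbl$resno, sasa_tbl$insert))

  out <- tibble::tibble(
    member_id = member_id,
    residue_index = map$residue_index,
    column = map$column,
    resletter = mseq,
    resno = map$resno,
    sasa = NA_real_, relative_sasa = NA_real_,
    buried = FALSE, interface = FALSE, disordered_unresolved = FALSE
  )
  res <- map$resolved
  key <- paste(map$resno[res], map$insert[res])
  out$sasa[res] <- unname(sasa_by_resno[key])
  out$relative_sasa[res] <- unname(rs_by_resno[key])
  out$buried[res] <- out$relative_sasa[res] < burial_threshold
  out$interface[res] <- paste(target_map$chain_id, map$resno[res],
                              map$insert[res]) %in% iface_key

  unres_dis <- !res & out$residue_index %in% dis_idx
  out$sasa[unres_dis] <- max_sasa(out$resletter[unres_dis])
  out$relative_sasa[unres_dis] <- 1
  out$disordered_unresolved[unres_dis] <- TRUE

  dropped <- !res & !unres_dis
  if (any(dropped)) {
    warning(sum(dropped), " unresolved residue(s) without disorder ",
            "annotation excluded from scoring: ",
            paste(utils::head(out$residue_index[dropped], 8), collapse = ", "),
            call. = FALSE)
  }
  out[!dropped, , drop = FALSE]
}

unresolved_terminal_runs <- function(resolved, max_run) {
  n <- length(resolved)
  idx <- integer(0)
  lead <- match(TRUE, resolved) - 1L
  if (is.na(lead)) lead <- n
  if (lead > 0 && lead <= max_run) idx <- c(idx, seq_len(lead))
  trail <- n - max(which(resolved), 0L)
  if (length(which(resolved)) > 0 && trail > 0 && trail <= max_run) {
    idx <- c(idx, seq.int(n - trail + 1L, n))
  }
  idx
}

#' Color label for a hotspot's PTM count
#'
#' Visualization color code by observation frequency: 0 keeps the default
#' model color, then green (1), yellow (2), orange (3), magenta (4) and
#' red (5 or more).
#'
#' @param total_ptms non-negative integer vector.
#' @return character vector of color labels.
#' @examples
#' color_for_count(0:6)
#' @export
color_for_count <- function(total_ptms) {
  if (any(total_ptms < 0)) stop("total_ptms must be >= 0", call. = FALSE)
  pal <- c("green", "yellow", "orange", "magenta")
  out <- rep("red", length(total_ptms))
  out[total_ptms == 0] <- "default"
  mid <- total_ptms >= 1 & total_ptms <= 4
  out[mid] <- pal[total_ptms[mid]]
  out
}

#' Write a colored structural projection of hotspots
#'
#' Emits (i) a copy of the structure with each mapped hotspot residue's
#' B-factor set to its total PTM count (0 elsewhere), (ii) a PyMOL-style
#' command script that selects each hotspot residue, shows its side chain
#' as van der Waals spheres (sphere scale 1.0) and applies
#' [color_for_count()], and (iii) a sidecar TSV listing hotspot columns
#' that could not be mapped onto the structure (not fatal).
#'
#' @param model a `structure_model`.
#' @param target_map a [map_alignment_to_structure()] result.
#' @param hotspots hotspot tibble from [build_hotspots()].
#' @param out_prefix path prefix; writes `<prefix>.pdb`, `<prefix>.pml`,
#'   `<prefix>_unmapped.tsv`.
#' @return named character vector of the paths written, invisibly.
#' @export
write_projection <- function(model, target_map, hotspots, out_prefix) {
  map <- target_map$map
  col2resno <- setNames(map$resno, map$column)
  hs <- hotspots
  hs$resno <- unname(col2resno[as.character(hs$column)])
  mapped <- !is.na(hs$resno)

  pdb <- model$pdb
  pdb$atom$b <- 0
  script <- character(0)
  for (i in which(mapped)) {
    sel_atoms <- pdb$atom$chain == target_map$chain_id &
      pdb$atom$resno == hs$resno[i]
    pdb$atom$b[sel_atoms] <- hs$total_ptms[i]
    colr <- color_for_count(hs$total_ptms[i])
    nm <- sprintf("hs_c%d", hs$column[i])
    script <- c(script,
      sprintf("# hotspot column %d -> chain %s resi %d (%d PTMs)",
              hs$column[i], target_map$chain_id, hs$resno[i],
              hs$total_ptms[i]),
      sprintf("select %s, chain %s and resi %d", nm,
              target_map$chain_id, hs$resno[i]),
      sprintf("show spheres, %s and sidechain", nm),
      sprintf("set sphere_scale, 1.0, %s", nm),
      if (colr != "default") sprintf("color %s, %s", colr, nm))
  }

  paths <- c(pdb = paste0(out_prefix, ".pdb"),
             script = paste0(out_prefix, ".pml"),
             unmapped = paste0(out_prefix, "_unmapped.tsv"))
  bio3d::write.pdb(pdb, file = paths[["pdb"]])
  writeLines(script, paths[["script"]])
  readr::write_tsv(
    hs[!mapped, c("family_id", "column", "total_ptms")],
    paths[["unmapped"]], progress = FALSE)
  invisible(paths)
}
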
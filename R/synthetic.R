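#' Specification for a synthetic protein-family fixture
#'
#' Describes a toy family with planted PTM hotspots used to validate the
#' whole pipeline end to end with no external data. Members descend from
#' a random ancestor by i.i.d. substitution; hotspot columns in the
#' "known-function" class are held more conserved and carry more planted
#' PTM observations than the "unknown" class, and all hotspot columns are
#' seeded with residues modifiable by their assigned PTM type — the
#' signal structure the Function Potential score is designed to detect.
#' A disordered N-terminal tail (omitted from the synthetic structure)
#' emulates unresolved flexible termini.
#'
#' Defaults encode the reference study conditions used by the package's
#' validation suite: 30 members, 10 known + 40 unknown hotspots, planted
#' counts with class means 5 and 1.5 (drawn as `1 + Poisson(mean - 1)`),
#' column retention probabilities 0.95 and 0.6.
#'
#' @param n_members family size.
#' @param seq_length ancestor length in residues.
#' @param sub_rate background per-site substitution probability.
#' @param indel_rate per-member probability of one short deletion run.
#' @param n_known,n_unknown planted hotspot counts per class.
#' @param count_mean_known,count_mean_unknown mean planted PTMs per
#'   hotspot by class.
#' @param cons_known,cons_unknown per-member probability of retaining the
#'   ancestral residue at a hotspot column, by class.
#' @param mod_types palette of PTM types assigned to hotspots.
#' @param tail_len disordered N-terminal prefix length (residues).
#' @param tail_frac fraction of hotspots placed inside the tail.
#' @param null_mode if `TRUE`, the known class uses the unknown class's
#'   count and conservation parameters (identical distributions; used to
#'   check that no spurious separation is reported).
#' @param seed RNG seed; fixed seed gives byte-identical fixtures.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_members = 30, seq_length = 150, sub_rate = 0.35,
                         indel_rate = 0.1, n_known = 10, n_unknown = 40,
                         count_mean_known = 5, count_mean_unknown = 1.5,
                         cons_known = 0.95, cons_unknown = 0.6,
                         mod_types = c("phosphorylation", "ubiquitination",
                                       "acetylation", "methylation"),
                         tail_len = 12, tail_frac = 0.15,
                         null_mode = FALSE, seed = 1) {
  stopifnot(sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            cons_known >= 0, cons_known <= 1, cons_unknown >= 0,
            cons_unknown <= 1, tail_frac >= 0, tail_frac <= 1,
            count_mean_known >= 1, count_mean_unknown >= 1,
            seq_length > tail_len,
            n_known + n_unknown <= seq_length / 2)
  if (null_mode) {
    count_mean_known <- count_mean_unknown
    cons_known <- cons_unknown
  }
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic family with planted hotspot columns
#'
#' Builds the ancestor, selects hotspot columns (constrained to residues
#' modifiable by their assigned PTM type), mutates members independently
#' (hotspot columns at their class retention probability, background at
#' `sub_rate`), and applies short deletions so the true alignment carries
#' gaps. Member 1 (`M01`) is deletion-free and serves as the structural
#' target downstream.
#'
#' @param spec a [fixture_spec()].
#' @return list with `alignment` (a [family_alignment()], the true
#'   alignment), and `truth` (tibble: `column`, `class` "known"/"unknown",
#'   `mod_type`, `in_tail`).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  L <- spec$seq_length
  anc <- sample(AA_LETTERS, L, replace = TRUE)

  n_hs <- spec$n_known + spec$n_unknown
  tail_cols <- seq_len(spec$tail_len)
  n_tail <- min(round(spec$tail_frac * n_hs), spec$tail_len)
  hs_cols <- c(sample(tail_cols, n_tail),
               sample(setdiff(seq_len(L), tail_cols),
                      n_hs - n_tail))
  cls <- sample(rep(c("known", "unknown"), c(spec$n_known, spec$n_unknown)))
  types <- sample(spec$mod_types, n_hs, replace = TRUE)
  # tail hotspots are phosphosites in flexible termini
  types[hs_cols <= spec$tail_len] <- "phosphorylation"
  for (i in seq_len(n_hs)) {
    anc[hs_cols[i]] <- sample(modifiable_residues(types[i]), 1)
  }

  retain <- rep(1 - spec$sub_rate, L)
  retain[hs_cols[cls == "known"]] <- spec$cons_known
  retain[hs_cols[cls == "unknown"]] <- spec$cons_unknown

  member_ids <- sprintf("M%02d", seq_len(spec$n_members))
  rows <- vapply(seq_len(spec$n_members), function(m) {
    s <- anc
    mut <- runif(L) > retain
    if (any(mut)) {
      s[mut] <- vapply(which(mut), function(p)
        sample(setdiff(AA_LETTERS, anc[p]), 1), character(1))
    }
    # one short deletion run per affected member; never in member 1
    if (m > 1 && runif(1) < spec$indel_rate) {
      len <- sample(1:3, 1)
      start <- sample(setdiff(seq_len(L - len), outer(hs_cols, 0:3, "-")), 1)
      s[seq.int(start, length.out = len)] <- "-"
    }
    paste(s, collapse = "")
  }, character(1))
  aln <- family_alignment(setNames(rows, member_ids), family_id = "synthfam")

  truth <- tibble::tibble(column = hs_cols, class = cls, mod_type = types,
                          in_tail = hs_cols <= spec$tail_len) |>
    dplyr::arrange(.data$column)
  list(alignment = aln, truth = truth)
}

#' Plant PTM records at the truth columns
#'
#' For each planted hotspot, draws its observation count
#' (`1 + Poisson(mean - 1)` with the class mean), samples that many
#' distinct members among those carrying a modifiable residue at the
#' column, and emits one record per (member, column). Every record of a
#' known-class hotspot appears in the companion known-function table.
#'
#' @param spec a [fixture_spec()].
#' @param family result of [generate_family()].
#' @return list with `records` (PTM record tibble), `function_table`
#'   (tibble: protein_id, residue_index, mod_type, citation), and
#'   `truth` (the input truth joined with realized counts).
#' @export
plant_ptms <- function(spec, family) {
  set.seed(spec$seed + 1L)
  aln <- family$alignment
  truth <- family$truth
  recs <- list()
  fun_rows <- list()
  counts <- integer(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    col <- truth$column[i]
    type <- truth$mod_type[i]
    mean_n <- if (truth$class[i] == "known") spec$count_mean_known
              else spec$count_mean_unknown
    n_want <- 1L + rpois(1, mean_n - 1)
    ok_res <- modifiable_residues(type)
    res_at <- column_residues(aln, col)
    eligible <- names(res_at)[res_at %in% ok_res]
    if (length(eligible) == 0) next
    members <- sample(eligible, min(n_want, length(eligible)))
    counts[i] <- length(members)
    ridx <- vapply(members, function(m) aln$column_to_residue[[m]][col],
                   integer(1))
    rec <- tibble::tibble(
      protein_id = members, organism = "synthetic eukaryote",
      residue_index = unname(ridx), residue = unname(res_at[members]),
      mod_type = type, evidence = "synthetic", experimental = TRUE,
      known_function = FALSE, citation = NA_character_
    )
    recs[[length(recs) + 1]] <- rec
    if (truth$class[i] == "known") {
      fun_rows[[length(fun_rows) + 1]] <- tibble::tibble(
        protein_id = rec$protein_id, residue_index = rec$residue_index,
        mod_type = rec$mod_type, citation = sprintf("planted:c%d", col))
    }
  }
  truth$planted_count <- counts
  list(records = dplyr::bind_rows(empty_ptm_tbl(), recs),
       function_table = dplyr::bind_rows(
         tibble::tibble(protein_id = character(), residue_index = integer(),
                        mod_type = character(), citation = character()),
         fun_rows),
       truth = truth[truth$planted_count > 0, , drop = FALSE])
}

# cylindrical coordinates of an idealised alpha-helix backbone
HELIX_GEOM <- list(
  N  = c(r = 1.56, dtheta = -28.6, dz = -0.91),
  CA = c(r = 2.30, dtheta = 0,     dz = 0),
  C  = c(r = 1.99, dtheta = 26.9,  dz = 1.05),
  O  = c(r = 2.00, dtheta = 26.9,  dz = 2.28),
  CB = c(r = 3.68, dtheta = -6.0,  dz = -0.60)
)

#' Generate an idealised helical structure for a member sequence
#'
#' Emits a PDB file holding an ideal alpha-helix (backbone N, CA, C, O
#' plus C-beta; 100 degrees twist and 1.5 Angstrom rise per residue, so
#' consecutive CA-CA distances are ~3.8 Angstrom) for the residues after
#' a disordered N-terminal prefix, which is omitted from the coordinates
#' — emulating a flexible tail the crystal cannot resolve — and listed in
#' a companion disorder TSV. Author numbering equals the member residue
#' index, so the structure starts at `disordered_prefix_len + 1`.
#'
#' @param sequence member amino-acid sequence (string).
#' @param disordered_prefix_len residues omitted at the N terminus.
#' @param pdb_path,disorder_path output files.
#' @param member_id id written into the disorder TSV.
#' @param chain_id chain identifier for the PDB.
#' @return named character vector of the paths written, invisibly.
#' @export
generate_structure <- function(sequence, disordered_prefix_len = 0,
                               pdb_path, disorder_path = NULL,
                               member_id = "M01", chain_id = "A") {
  res <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(res) > disordered_prefix_len)
  idx <- seq.int(disordered_prefix_len + 1L, length(res))

  atoms <- purrr::map_dfr(idx, function(i) {
    t0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    elety <- names(HELIX_GEOM)
    if (res[i] == "G") elety <- setdiff(elety, "CB")
    purrr::map_dfr(elety, function(el) {
      g <- HELIX_GEOM[[el]]
      th <- t0 + g[["dtheta"]] * pi / 180
      tibble::tibble(resno = i, elety = el,
                     x = g[["r"]] * cos(th), y = g[["r"]] * sin(th),
                     z = z0 + g[["dz"]],
                     resid = bio3d::aa123(res[i]))
    })
  })
  bio3d::write.pdb(
    file = pdb_path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = atoms$resno, resid = atoms$resid, chain = chain_id,
    elety = atoms$elety, eleno = seq_len(nrow(atoms)),
    o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms)))

  paths <- c(pdb = pdb_path)
  if (!is.null(disorder_path)) {
    dis <- if (disordered_prefix_len > 0) {
      tibble::tibble(member_id = member_id, start = 1L,
                     end = disordered_prefix_len)
    } else {
      tibble::tibble(member_id = character(), start = integer(),
                     end = integer())
    }
    readr::write_tsv(dis, disorder_path, progress = FALSE)
    paths <- c(paths, disorder = disorder_path)
  }
  invisible(paths)
}

#' Write a complete synthetic fixture to disk
#'
#' Generates a family, plants PTMs, builds the structural target for
#' member `M01`, and writes every file the pipeline consumes: unaligned
#' and aligned FASTA, PDB, disorder TSV, PTM TSV, known-function TSV, and
#' a JSON truth file.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named list of paths plus the in-memory `family` and `planted`
#'   objects, invisibly.
#' @export
generate_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  family <- generate_family(spec)
  planted <- plant_ptms(spec, family)
  aln <- family$alignment

  p <- list(
    fasta = file.path(dir, "family.fasta"),
    alignment = file.path(dir, "family_aligned.fasta"),
    pdb = file.path(dir, "target.pdb"),
    disorder = file.path(dir, "disorder.tsv"),
    ptm = file.path(dir, "ptms.tsv"),
    functions = file.path(dir, "known_function.tsv"),
    truth = file.path(dir, "truth.json")
  )
  unaligned <- Biostrings::AAStringSet(
    vapply(names(aln$members), function(m) member_sequence(aln, m),
           character(1)))
  Biostrings::writeXStringSet(unaligned, p$fasta)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$members),
                              p$alignment)
  generate_structure(member_sequence(aln, "M01"),
                     disordered_prefix_len = spec$tail_len,
                     pdb_path = p$pdb, disorder_path = p$disorder,
                     member_id = "M01")
  readr::write_tsv(planted$records, p$ptm, progress = FALSE)
  readr::write_tsv(planted$function_table, p$functions, progress = FALSE)
  jsonlite::write_json(planted$truth, p$truth, digits = NA)
  invisible(c(p, list(family = family, planted = planted, spec = spec)))
}
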
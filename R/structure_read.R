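# van der Waals radii (Angstrom) by element; unknown heavy elements fall
# back to 1.70.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
VDW_DEFAULT <- 1.70

# Theoretical maximum solvent-accessible surface area per residue type
# (Angstrom^2), used to express SASA as relative SASA and to assign
# full exposure to disordered unresolved residues (Tien et al. 2013,
# theoretical column).
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

#' Theoretical maximum SASA for a residue type
#' @param residue one-letter amino-acid code(s).
#' @return numeric vector of maxima in Angstrom^2.
#' @export
max_sasa <- function(residue) {
  out <- MAX_SASA[toupper(residue)]
  out[is.na(out)] <- mean(MAX_SASA)
  unname(out)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a heavy-atom structure model suitable for
#' SASA and interface computation. Only the first model of multi-model
#' (NMR-style) files is kept; alternate locations are resolved to the
#' highest occupancy, ties broken alphabetically by altloc id; hydrogens
#' are dropped; HETATM ligands and non-standard residues are ignored for
#' downstream geometry (reported via message). Element is inferred from
#' the atom name when the element column is blank, and each heavy atom is
#' assigned a van der Waals radius from a built-in element table
#' (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, default 1.70 Angstrom).
#'
#' @param path PDB file.
#' @return object of class `structure_model`: list with `structure_id`,
#'   `atoms` (tibble: chain, resno, insert, resid, resletter, elety,
#'   element, x, y, z, radius) and `pdb` (the underlying bio3d object,
#'   kept for writing projections).
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- tibble::as_tibble(pdb$atom)
  n_het <- sum(at$type == "HETATM")
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  if (n_het > 0) message(n_het, " HETATM record(s) ignored")

  # standard amino acids only
  letter <- suppressWarnings(bio3d::aa321(at$resid))
  std <- !is.na(letter) & letter != "X"
  if (any(!std)) message(sum(!std), " non-standard residue atom(s) ignored")
  at <- at[std, , drop = FALSE]
  letter <- letter[std]

  element <- toupper(trimws(at$elesy))
  blank <- is.na(element) | !nzchar(element)
  element[blank] <- infer_element(at$elety[blank])
  heavy <- element != "H" & element != "D"
  at <- at[heavy, , drop = FALSE]
  letter <- letter[heavy]
  element <- element[heavy]

  # altloc: keep highest occupancy, ties alphabetical
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(grp, -occ, alt)
  keep_first <- !duplicated(grp[ord])
  keep <- sort(ord[keep_first])
  at <- at[keep, , drop = FALSE]
  letter <- letter[keep]
  element <- element[keep]

  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  radius <- unname(VDW_RADII[element])
  radius[is.na(radius)] <- VDW_DEFAULT

  structure(
    list(
      structure_id = tools::file_path_sans_ext(basename(path)),
      atoms = tibble::tibble(
        chain = at$chain, resno = as.integer(at$resno),
        insert = ifelse(is.na(at$insert), "", at$insert),
        resid = at$resid, resletter = letter,
        elety = at$elety, element = element,
        x = at$x, y = at$y, z = at$z, radius = radius
      ),
      pdb = pdb
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$structure_id, ": ",
      length(unique(x$atoms$chain)), " chain(s), ",
      nrow(dplyr::distinct(x$atoms, .data$chain, .data$resno, .data$insert)),
      " residues, ", nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

infer_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  first <- toupper(substr(nm, 1, 1))
  # two-letter elements are not expected among standard amino-acid atoms
  first[first == ""] <- "C"
  first
}

#' One-letter residue sequence of a structure chain
#'
#' Residues in author order with their author numbering, for mapping a
#' chain onto an alignment member.
#'
#' @param model a `structure_model`.
#' @param chain_id chain identifier.
#' @return tibble with `resno`, `insert`, `resletter`.
#' @export
chain_residues <- function(model, chain_id) {
  at <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop("no such chain: ", chain_id, call. = FALSE)
  dplyr::distinct(at, .data$resno, .data$insert, .data$resletter)
}
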
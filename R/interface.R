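#' Detect inter-chain interface residues
#'
#' A residue is an interface residue iff any of its heavy atoms lies
#' within `contact_cutoff` of a heavy atom in a *different* chain.
#' Same-chain contacts never count, which excludes artificial same-chain
#' interactions by construction; structures with a single chain yield an
#' empty result. Neighbor search uses a uniform spatial grid whose result
#' is identical to the all-pairs scan.
#'
#' @param model a `structure_model` from [read_structure()].
#' @param contact_cutoff heavy-atom distance cutoff in Angstrom
#'   (default 5.0).
#' @return tibble with columns `chain`, `resno`, `insert` — one row per
#'   interface residue.
#' @export
detect_interface_residues <- function(model, contact_cutoff = 5.0) {
  at <- model$atoms
  empty <- tibble::tibble(chain = character(), resno = integer(),
                          insert = character())
  if (length(unique(at$chain)) < 2) return(empty)
  xyz <- cbind(at$x, at$y, at$z)
  nbrs <- grid_neighbors(xyz, rep(contact_cutoff / 2, nrow(at)))
  hit <- vapply(seq_len(nrow(at)), function(i) {
    js <- nbrs[[i]]
    any(at$chain[js] != at$chain[i])
  }, logical(1))
  if (!any(hit)) return(empty)
  dplyr::distinct(at[hit, , drop = FALSE], .data$chain, .data$resno,
                  .data$insert) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)
}
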
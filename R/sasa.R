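#' Deterministic sphere point lattice (golden-section spiral)
#'
#' Near-uniform points on the unit sphere; fully deterministic, so SASA
#' values are reproducible byte-for-byte.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Uniform spatial grid neighbor search. Returns, for each atom i, the
# indices j != i with |x_i - x_j| < cutoff_i + cutoff_j (cutoffs are
# per-atom interaction radii). Contract: identical to the all-pairs scan.
grid_neighbors <- function(xyz, cutoffs) {
  n <- nrow(xyz)
  cell <- 2 * max(cutoffs)
  ix <- floor(xyz[, 1] / cell)
  iy <- floor(xyz[, 2] / cell)
  iz <- floor(xyz[, 3] / cell)
  key <- paste(ix, iy, iz)
  bins <- split(seq_len(n), key)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  lapply(seq_len(n), function(i) {
    cand <- unlist(lapply(seq_len(27), function(k) {
      bins[[paste(ix[i] + offsets$dx[k], iy[i] + offsets$dy[k],
                  iz[i] + offsets$dz[k])]]
    }), use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand) == 0) return(integer(0))
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    lim <- (cutoffs[i] + cutoffs[cand])^2
    cand[d2 < lim]
  })
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` lattice points on each atom's solvent-expanded
#' sphere (radius `r_vdw + probe_radius`) and counts the fraction not
#' occluded by any neighboring atom's expanded sphere. Deterministic:
#' fixed point lattice, no random numbers.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe_radius solvent probe radius, default 1.4 Angstrom (water).
#' @param n_points lattice points per atom, default 960.
#' @return numeric vector of per-atom SASA (Angstrom^2).
#' @export
sasa_atoms <- function(xyz, radii, probe_radius = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) >= 1, length(radii) == nrow(xyz), all(radii > 0))
  n <- nrow(xyz)
  rext <- radii + probe_radius
  pts <- sphere_points(n_points)
  nbrs <- grid_neighbors(xyz, rext)
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * rext[i]
    p1 <- p[, 1] + xyz[i, 1]
    p2 <- p[, 2] + xyz[i, 2]
    p3 <- p[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nbrs[[i]]) {
      d2 <- (p1 - xyz[j, 1])^2 + (p2 - xyz[j, 2])^2 + (p3 - xyz[j, 3])^2
      acc <- acc & (d2 > rext[j]^2)
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rext[i]^2 * mean(acc)
  }
  out
}

#' Per-residue SASA of an isolated chain
#'
#' Computes Shrake-Rupley SASA on one chain taken in isolation (other
#' chains removed first), so that binding partners in the crystal cannot
#' depress the accessibility of interface residues; residue SASA is the
#' sum over its heavy atoms.
#'
#' @param model a `structure_model` from [read_structure()].
#' @param chain_id chain to compute; default the first chain.
#' @param probe_radius,n_points see [sasa_atoms()].
#' @return tibble: `chain`, `resno`, `insert`, `resletter`, `sasa`,
#'   `relative_sasa` (= min(1, sasa / max_sasa(residue type))).
#' @export
shrake_rupley_sasa <- function(model, chain_id = NULL, probe_radius = 1.4,
                               n_points = 960) {
  at <- model$atoms
  if (is.null(chain_id)) chain_id <- at$chain[1]
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy atoms in chain ", chain_id, call. = FALSE)
  a_sasa <- sasa_atoms(cbind(at$x, at$y, at$z), at$radius,
                       probe_radius = probe_radius, n_points = n_points)
  at$atom_sasa <- a_sasa
  at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert,
                    .data$resletter) |>
    dplyr::summarise(sasa = sum(.data$atom_sasa), .groups = "drop") |>
    dplyr::mutate(relative_sasa = pmin(1, .data$sasa /
                                         max_sasa(.data$resletter))) |>
    dplyr::arrange(.data$resno, .data$insert)
}
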
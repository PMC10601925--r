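# Reindexing of the all-atom expansion into the variable set
# (protein atoms, solvent particles, relative hydrogen displacements).
# The water center is the oxygen site, so the relative oxygen displacement is
# identically zero and is dropped from the variable set.

#' Partition atoms into solute / oxygen / hydrogen index lists
#'
#' Builds the index bookkeeping for the change of variables from per-atom
#' displacements to (solute atoms, solvent particles, relative hydrogen
#' displacements).  Solvent units are ordered by their oxygen's atom index, so
#' the partition is invariant to permutations of the input atom order.
#'
#' @param sys a [molecular_system()].
#' @return list of class `partition_index` with `p_idx`, `o_idx`, `h1_idx`,
#'   `h2_idx` (1-based atom indices, hydrogen lists aligned per water), `n_p`,
#'   `n_s`.
#' @export
classify_atoms <- function(sys) {
  at <- sys$atoms
  p_idx <- which(at$role == "protein")
  o_idx <- which(at$role == "water_O")
  ord <- order(o_idx)
  o_idx <- o_idx[ord]
  mol_o <- at$molecule[o_idx]
  h1_all <- which(at$role == "water_H1")
  h2_all <- which(at$role == "water_H2")
  h1_idx <- h1_all[match(mol_o, at$molecule[h1_all])]
  h2_idx <- h2_all[match(mol_o, at$molecule[h2_all])]
  if (anyNA(h1_idx) || anyNA(h2_idx))
    stop("topology error: water molecule missing a hydrogen site")
  structure(list(p_idx = p_idx, o_idx = o_idx, h1_idx = h1_idx,
                 h2_idx = h2_idx, n_p = length(p_idx), n_s = length(o_idx)),
            class = "partition_index")
}

# Expand atom indices to their three coordinate rows.
.coord_rows <- function(idx) {
  if (!length(idx)) return(integer())
  as.vector(t(outer(3L * (idx - 1L), 1:3, `+`)))
}

# Change-of-variables matrix T (3n x 3n) mapping
# (delta_p, delta_s, D1, D2) -> per-atom displacements.
.cov_matrix <- function(part) {
  n <- part$n_p + 3L * part$n_s
  Tm <- matrix(0, 3L * n, 3L * n)
  np3 <- 3L * part$n_p
  ns3 <- 3L * part$n_s
  rp <- .coord_rows(part$p_idx)
  ro <- .coord_rows(part$o_idx)
  r1 <- .coord_rows(part$h1_idx)
  r2 <- .coord_rows(part$h2_idx)
  if (length(rp)) Tm[cbind(rp, seq_len(np3))] <- 1
  cs <- np3 + seq_len(ns3)
  Tm[cbind(ro, cs)] <- 1
  Tm[cbind(r1, cs)] <- 1
  Tm[cbind(r2, cs)] <- 1
  Tm[cbind(r1, np3 + ns3 + seq_len(ns3))] <- 1
  Tm[cbind(r2, np3 + 2L * ns3 + seq_len(ns3))] <- 1
  Tm
}

#' Aggregate the expansion into summed solute/solvent/hydrogen blocks
#'
#' Applies the exact linear change of variables `delta = T delta_tilde` to the
#' second-order expansion: the force row of a solvent particle is the sum of
#' its oxygen and hydrogen forces, solvent Hessian blocks are sums over the
#' member-atom blocks, and the relative-hydrogen blocks are carried unsummed.
#' The quadratic form in the new variables equals the original surface
#' exactly.
#'
#' @param expansion a [compute_expansion()] result (or any list with `V0`,
#'   `f`, `H`).
#' @param part a [classify_atoms()] partition.
#' @param masses per-atom masses (amu), length n.
#' @return list of class `aggregated_blocks` with `V0`, `f_ps`, `f_12`,
#'   `H_psps`, `H_ps12`, `H_1212`, `M12` (6 n_s diagonal as a vector), the
#'   partition and the atom masses.
#' @export
aggregate_blocks <- function(expansion, part, masses) {
  n <- part$n_p + 3L * part$n_s
  stopifnot(length(expansion$f) == 3L * n, length(masses) == n)
  H <- expansion$H
  f <- expansion$f
  rp <- .coord_rows(part$p_idx)
  ro <- .coord_rows(part$o_idx)
  r1 <- .coord_rows(part$h1_idx)
  r2 <- .coord_rows(part$h2_idx)
  # exploit the sparsity of the change of variables: every reduced block is
  # a sum of at most nine index-sliced submatrices of H
  Rs <- H[ro, , drop = FALSE] + H[r1, , drop = FALSE] + H[r2, , drop = FALSE]
  f_ps <- c(f[rp], f[ro] + f[r1] + f[r2])
  f_12 <- c(f[r1], f[r2])
  H_psps <- rbind(
    cbind(H[rp, rp, drop = FALSE],
          H[rp, ro, drop = FALSE] + H[rp, r1, drop = FALSE] +
            H[rp, r2, drop = FALSE]),
    cbind(Rs[, rp, drop = FALSE],
          Rs[, ro, drop = FALSE] + Rs[, r1, drop = FALSE] +
            Rs[, r2, drop = FALSE]))
  H_ps12 <- rbind(
    cbind(H[rp, r1, drop = FALSE], H[rp, r2, drop = FALSE]),
    cbind(Rs[, r1, drop = FALSE], Rs[, r2, drop = FALSE]))
  H_1212 <- rbind(
    cbind(H[r1, r1, drop = FALSE], H[r1, r2, drop = FALSE]),
    cbind(H[r2, r1, drop = FALSE], H[r2, r2, drop = FALSE]))
  m12 <- rep(masses[c(part$h1_idx, part$h2_idx)], each = 3L)
  structure(list(V0 = expansion$V0,
                 f_ps = f_ps, f_12 = f_12,
                 H_psps = H_psps, H_ps12 = H_ps12, H_1212 = H_1212,
                 M12 = m12, part = part, masses = masses),
            class = "aggregated_blocks")
}

# Full force vector / Hessian in the reduced variable ordering
# (delta_ps, Delta_12), for oracles and surface evaluation.
.tilde_full <- function(blocks) {
  f <- c(blocks$f_ps, blocks$f_12)
  H <- rbind(cbind(blocks$H_psps, blocks$H_ps12),
             cbind(t(blocks$H_ps12), blocks$H_1212))
  list(f = f, H = H)
}

#' Evaluate the reduced-variable surface at (delta_ps, Delta_12)
#'
#' @param blocks an [aggregate_blocks()] result.
#' @param delta_ps displacement of solute atoms and solvent particles.
#' @param delta_12 relative hydrogen displacements.
#' @return potential energy (kcal/mol).
#' @export
eval_tilde_surface <- function(blocks, delta_ps, delta_12) {
  tf <- .tilde_full(blocks)
  eval_surface(blocks$V0, tf$f, tf$H, c(delta_ps, delta_12))
}

#' Positions, masses and labels of the coarse-grained units
#'
#' A unit is either a solute atom or a solvent particle located at its
#' oxygen.  Solvent-particle masses are full water masses.
#'
#' @param sys a [molecular_system()].
#' @param part a [classify_atoms()] partition.
#' @return list with `positions` (N x 3), `masses` (length N), `labels`,
#'   `n_p`, `n_s`.
#' @export
unit_table <- function(sys, part) {
  at <- sys$atoms
  pos <- rbind(sys$coords[part$p_idx, , drop = FALSE],
               sys$coords[part$o_idx, , drop = FALSE])
  mass <- c(at$mass[part$p_idx],
            at$mass[part$o_idx] + at$mass[part$h1_idx] + at$mass[part$h2_idx])
  labels <- c(at$type_label[part$p_idx], rep("solvent", part$n_s))
  list(positions = pos, masses = mass, labels = labels,
       n_p = part$n_p, n_s = part$n_s)
}
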
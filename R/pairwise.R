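# Coarse-grained pairwise force matrices: the direct part (summed all-atom
# pair forces per unit pair), the indirect part mediated by the collective
# hydrogen dynamics, the antisymmetrized combination, the five-component
# decomposition of single entries, and projection to effective scalars.

# unit id per atom: solute atoms are their own units 1..n_p, all three sites
# of water w map to unit n_p + w.
.atom_units <- function(part) {
  n <- part$n_p + 3L * part$n_s
  u <- integer(n)
  u[part$p_idx] <- seq_len(part$n_p)
  u[part$o_idx] <- part$n_p + seq_len(part$n_s)
  u[part$h1_idx] <- part$n_p + seq_len(part$n_s)
  u[part$h2_idx] <- part$n_p + seq_len(part$n_s)
  u
}

# hydrogen slot per atom (row block in the Delta_12 ordering), 0 otherwise
.hyd_slots <- function(part) {
  n <- part$n_p + 3L * part$n_s
  s <- integer(n)
  s[part$h1_idx] <- seq_len(part$n_s)
  s[part$h2_idx] <- part$n_s + seq_len(part$n_s)
  s
}

# accumulate m 3-vector entries into a 3N x N matrix of (unit row, unit col)
.accum_entries <- function(M, urow, ucol, vals) {
  nr <- nrow(M)
  for (d in 1:3) {
    idx <- (ucol - 1) * nr + 3 * (urow - 1) + d
    s <- rowsum(vals[, d], idx)
    ii <- as.numeric(rownames(s))
    M[ii] <- M[ii] + s[, 1L]
  }
  M
}

# entry swap: S[(i,j)] = M[(j,i)] for 3-vector entries of a 3N x N matrix
.swap_entries <- function(M) {
  N <- ncol(M)
  arr <- array(M, c(3L, N, N))
  matrix(aperm(arr, c(1L, 3L, 2L)), 3L * N, N)
}

#' Build coarse-grained pairwise force matrices
#'
#' The direct matrix holds, for every ordered unit pair, the sum of all-atom
#' pair forces between the units' member atoms (a solvent row/column sums the
#' oxygen and both hydrogen contributions); it is exactly antisymmetric.  The
#' indirect matrix carries the force mediated by the collective hydrogen
#' dynamics, `-H_ps,12 H_1212^-1 F_12<-ps` taken columnwise, and is not
#' antisymmetric in general.  Rows of `direct + indirect` sum to the
#' coarse-grained force vector.
#'
#' @param pd a [compute_pair_decomposition()] result.
#' @param blocks an [aggregate_blocks()] result from the same conformation.
#' @param part the [classify_atoms()] partition.
#' @return list of class `cg_pair_forces` with `F_direct`, `dF` (both 3N x N
#'   matrices of 3-vector entries, N = n_p + n_s), `n_p`, `n_s`; `F_antisym`
#'   is added by [antisymmetrize()].
#' @export
build_pair_matrices <- function(pd, blocks, part) {
  if (pd$n != part$n_p + 3L * part$n_s)
    stop("pair decomposition and partition disagree on atom count")
  dpm <- .direct_pair_matrices(pd, part)
  dF <- -blocks$H_ps12 %*% .solve_h1212(blocks, dpm$F12ps)$X
  structure(list(F_direct = dpm$Fd, dF = dF, n_p = part$n_p,
                 n_s = part$n_s),
            class = "cg_pair_forces")
}

# direct pairwise force matrix and the hydrogen-row force matrix, before any
# linear solve
.direct_pair_matrices <- function(pd, part) {
  N <- part$n_p + part$n_s
  units <- .atom_units(part)
  slots <- .hyd_slots(part)

  i <- c(pd$i, pd$bonded$i)
  j <- c(pd$j, pd$bonded$j)
  Ft <- rbind(pd$F_elec + pd$F_vdw, pd$bonded$F)   # force on i from j
  ui <- units[i]; uj <- units[j]

  Fd <- matrix(0, 3L * N, N)
  inter <- ui != uj
  if (any(inter)) {
    Fd <- .accum_entries(Fd, ui[inter], uj[inter], Ft[inter, , drop = FALSE])
    Fd <- .accum_entries(Fd, uj[inter], ui[inter], -Ft[inter, , drop = FALSE])
  }

  F12ps <- matrix(0, 6L * part$n_s, N)
  hi <- slots[i] > 0L
  if (any(hi))
    F12ps <- .accum_entries(F12ps, slots[i][hi], uj[hi], Ft[hi, , drop = FALSE])
  hj <- slots[j] > 0L
  if (any(hj))
    F12ps <- .accum_entries(F12ps, slots[j][hj], ui[hj], -Ft[hj, , drop = FALSE])
  list(Fd = Fd, F12ps = F12ps)
}

#' Antisymmetrize the coarse-grained pairwise forces
#'
#' Replaces each indirect entry by the arithmetic average of the force
#' exerted on i by j and the reversed force exerted on j by i:
#' `F''[i,j] = F_direct[i,j] + (dF[i,j] - dF[j,i]) / 2`.  The result is
#' exactly antisymmetric.
#'
#' @param cgpf a [build_pair_matrices()] result.
#' @return `cgpf` with `F_antisym` added.
#' @export
antisymmetrize <- function(cgpf) {
  cgpf$F_antisym <- cgpf$F_direct + (cgpf$dF - .swap_entries(cgpf$dF)) / 2
  cgpf
}

#' Diagnostic: pairwise-difference energy form vs the force vector
#'
#' Compares the linear energy term written with antisymmetric pairwise
#' forces, `sum_{i<j} (delta_i - delta_j)' F''[i,j]`, with `fp' delta`, for a
#' given displacement.  The two agree exactly when the indirect force matrix
#' is balanced (its column sums match the antisymmetrized row sums); the gap
#' quantifies how much the antisymmetrization redistributes.
#'
#' @param cgpf an [antisymmetrize()]d pair-force set.
#' @param fp the coarse-grained force vector.
#' @param delta displacement over units (length 3N).
#' @return list with `pairwise_form`, `force_form`, `gap`.
#' @export
antisym_diagnostic <- function(cgpf, fp, delta) {
  N <- cgpf$n_p + cgpf$n_s
  Fa <- cgpf$F_antisym
  s <- 0
  dm <- matrix(delta, 3L, N)
  for (jj in seq_len(N)) {
    ent <- matrix(Fa[, jj], 3L, N)     # entries (i, jj) for all i
    # sum over i < jj of (delta_i - delta_jj)' F[i, jj]; full double sum over
    # ordered pairs halves by antisymmetry
    s <- s + sum((dm - dm[, jj]) * ent) / 2
  }
  f_form <- sum(fp * delta)
  list(pairwise_form = s, force_form = f_form, gap = s - f_form)
}

#' Row-sum check of the pairwise force matrices
#'
#' @param cgpf a [build_pair_matrices()] result.
#' @return 3N vector of row sums of `F_direct + dF`; reproduces the
#'   coarse-grained force vector.
#' @export
pair_row_sums <- function(cgpf) {
  rowSums(cgpf$F_direct + cgpf$dF)
}

# atom indices belonging to one unit
.unit_atoms <- function(part, u) {
  if (u <= part$n_p) part$p_idx[u]
  else {
    w <- u - part$n_p
    c(part$o_idx[w], part$h1_idx[w], part$h2_idx[w])
  }
}

#' Five-component decomposition of one atom-solvent entry
#'
#' Splits the antisymmetrized pairwise force entry and the coarse-grained
#' Hessian entry for units (a, b) into the oxygen-electrostatic,
#' oxygen-van-der-Waals, hydrogen-electrostatic, hydrogen-van-der-Waals and
#' indirect (collective-hydrogen-dynamics) components, where "oxygen" and
#' "hydrogen" refer to the sites of the source unit `b`.  The five force
#' components sum to the antisymmetrized entry; the five spring components
#' sum to the `(a, b)` block of the coarse-grained Hessian.
#'
#' @param a,b unit indices; `b` must be a solvent particle.
#' @param pd a [compute_pair_decomposition()] result.
#' @param cgpf an [antisymmetrize()]d pair-force set.
#' @param cg the [coarse_grain()] surface (for the indirect spring).
#' @param blocks the [aggregate_blocks()] input.
#' @param part the partition.
#' @return list with `force` (five 3-vectors plus `s_dir`, `s_all`) and
#'   `spring` (five 3 x 3 matrices plus `s_dir`, `s_all`).
#' @export
decompose_entry <- function(a, b, pd, cgpf, cg, blocks, part) {
  if (b <= part$n_p) stop("index error: b must be a solvent particle")
  units <- .atom_units(part)
  w <- b - part$n_p
  o_atom <- part$o_idx[w]
  h_atoms <- c(part$h1_idx[w], part$h2_idx[w])

  fwd <- units[pd$i] == a & units[pd$j] == b
  rev <- units[pd$i] == b & units[pd$j] == a

  sum_force <- function(Fm, src_sel) {
    v <- numeric(3L)
    r1 <- fwd & pd$j %in% src_sel
    if (any(r1)) v <- v + colSums(Fm[r1, , drop = FALSE])
    r2 <- rev & pd$i %in% src_sel
    if (any(r2)) v <- v - colSums(Fm[r2, , drop = FALSE])
    v
  }
  sum_spring <- function(Hm, src_sel) {
    B <- matrix(0, 3L, 3L)
    r1 <- fwd & pd$j %in% src_sel
    if (any(r1)) B <- B + matrix(colSums(Hm[r1, , drop = FALSE]), 3L, 3L)
    r2 <- rev & pd$i %in% src_sel
    if (any(r2)) B <- B + t(matrix(colSums(Hm[r2, , drop = FALSE]), 3L, 3L))
    B
  }

  N <- part$n_p + part$n_s
  ra <- (3L * (a - 1L) + 1L):(3L * a)
  rb <- (3L * (b - 1L) + 1L):(3L * b)
  s_ind_f <- (cgpf$dF[ra, b] - cgpf$dF[rb, a]) / 2
  Schur <- cg$Hp - blocks$H_psps
  s_ind_k <- Schur[ra, rb]

  force <- list(o_elec = sum_force(pd$F_elec, o_atom),
                o_vdw = sum_force(pd$F_vdw, o_atom),
                h_elec = sum_force(pd$F_elec, h_atoms),
                h_vdw = sum_force(pd$F_vdw, h_atoms),
                s_indir = s_ind_f)
  spring <- list(o_elec = sum_spring(pd$Hb_elec, o_atom),
                 o_vdw = sum_spring(pd$Hb_vdw, o_atom),
                 h_elec = sum_spring(pd$Hb_elec, h_atoms),
                 h_vdw = sum_spring(pd$Hb_vdw, h_atoms),
                 s_indir = s_ind_k)
  force$s_dir <- force$o_elec + force$o_vdw + force$h_elec + force$h_vdw
  force$s_all <- force$s_dir + force$s_indir
  spring$s_dir <- spring$o_elec + spring$o_vdw + spring$h_elec + spring$h_vdw
  spring$s_all <- spring$s_dir + spring$s_indir
  list(force = force, spring = spring)
}

#' Project a pair entry onto the inter-unit direction
#'
#' The direction convention is `rhat = (x_i - x_j) / |x_i - x_j|`, so a
#' positive effective force is repulsive.  The effective spring constant is
#' the quadratic form of the 3 x 3 entry in that direction (invariant under
#' transposition of the entry).
#'
#' @param entry_force 3-vector force on i exerted by j.
#' @param entry_spring 3 x 3 Hessian entry for (i, j).
#' @param x_i,x_j unit positions (A).
#' @return list with `f_ij` (kcal/mol/A) and `k_ij` (kcal/mol/A^2).
#' @export
effective_scalars <- function(entry_force, entry_spring, x_i, x_j) {
  d <- x_i - x_j
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("zero separation between units")
  rhat <- d / r
  list(f_ij = sum(entry_force * rhat),
       k_ij = drop(crossprod(rhat, entry_spring %*% rhat)),
       r_ij = r)
}
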
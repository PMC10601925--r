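# Per-conformation pipeline: expansion -> partition -> coarse-graining ->
# pairwise matrices -> interaction records.  One record per (atom, solvent)
# and per canonical (solvent, solvent) pair within the record cutoff, with
# the five force and spring components projected on the inter-unit direction.

# project m x 9 column-major 3x3 blocks onto per-row unit vectors
.project_blocks <- function(B, rhat) {
  k <- numeric(nrow(B))
  for (a in 1:3) for (b in 1:3)
    k <- k + rhat[, a] * B[, (b - 1L) * 3L + a] * rhat[, b]
  k
}

#' Analyze a single conformation into interaction records
#'
#' Runs the full coarse-graining pipeline at the system's current coordinates
#' and returns one record per interacting unit pair within `record_cutoff`:
#' the pair distance, the five effective-force and five effective-spring
#' components projected on the inter-unit direction (positive force =
#' repulsive), their direct and total sums, and optionally the mode-based
#' motion correlation.
#'
#' @param sys a [molecular_system()] containing at least one water.
#' @param policy analysis-stage [nonbonded_policy()]; defaults to
#'   untruncated interactions to avoid truncation artifacts.
#' @param record_cutoff record pairs only when the unit distance is at most
#'   this many A.
#' @param correlations if TRUE, also compute motion correlations from the
#'   coarse-grained Hessian eigenmodes.
#' @param zero_count number of smallest-|lambda| modes excluded from the
#'   correlation weighting.
#' @return list with data.frames `atom_solvent` and `solvent_solvent`, the
#'   coarse surface `cg`, `blocks`, and the unit table.
#' @export
analyze_frame <- function(sys, policy = nonbonded_policy("untruncated"),
                          record_cutoff = 12, correlations = FALSE,
                          zero_count = 6L) {
  pt <- .pair_terms(sys, policy)
  pd <- .pd_from_terms(pt)
  ex <- .assemble_expansion(pt)
  part <- classify_atoms(sys)
  if (part$n_s < 1L) stop("system has no waters to coarse-grain")
  blocks <- aggregate_blocks(ex, part, sys$atoms$mass)
  # one factorization serves the surface, the force correction and the
  # indirect pairwise matrix
  dpm <- .direct_pair_matrices(pd, part)
  nps3 <- 3L * (part$n_p + part$n_s)
  sol <- .solve_h1212(blocks, cbind(blocks$f_12, t(blocks$H_ps12),
                                    dpm$F12ps))
  a <- sol$X[, 1L]
  K <- sol$X[, 1L + seq_len(nps3), drop = FALSE]
  Y <- sol$X[, -seq_len(1L + nps3), drop = FALSE]
  Hp <- blocks$H_psps - blocks$H_ps12 %*% K
  Hp <- (Hp + t(Hp)) / 2
  cg <- structure(list(V0p = blocks$V0 - 0.5 * sum(blocks$f_12 * a),
                       fp = blocks$f_ps - drop(blocks$H_ps12 %*% a),
                       Hp = Hp,
                       solve_report = list(condition = sol$condition,
                                           pseudo_inverse = sol$pseudo_inverse,
                                           dropped = sol$dropped)),
                  class = "cg_surface")
  cgpf <- antisymmetrize(structure(
    list(F_direct = dpm$Fd, dF = -blocks$H_ps12 %*% Y,
         n_p = part$n_p, n_s = part$n_s),
    class = "cg_pair_forces"))
  ut <- unit_table(sys, part)
  N <- part$n_p + part$n_s
  X <- ut$positions

  # candidate record pairs (I < J), excluding solute-solute
  sI <- integer(); sJ <- integer()
  if (part$n_p > 0L) {
    ps <- expand.grid(I = seq_len(part$n_p),
                      J = part$n_p + seq_len(part$n_s))
    sI <- ps$I; sJ <- ps$J
  }
  if (part$n_s > 1L) {
    ssI <- rep(part$n_p + seq_len(part$n_s - 1L),
               (part$n_s - 1L):1L)
    ssJ <- part$n_p + sequence((part$n_s - 1L):1L, from = 2L:part$n_s)
    sI <- c(sI, ssI); sJ <- c(sJ, ssJ)
  }
  dvec <- X[sI, , drop = FALSE] - X[sJ, , drop = FALSE]
  r <- sqrt(rowSums(dvec * dvec))
  keep <- r <= record_cutoff
  sI <- sI[keep]; sJ <- sJ[keep]; r <- r[keep]
  rhat <- dvec[keep, , drop = FALSE] / r
  m <- length(sI)
  if (m == 0L) {
    cols <- c("i", "j", "i_label", "j_label", "r",
              paste0("f_", c("o_elec", "o_vdw", "h_elec", "h_vdw",
                             "s_indir", "s_dir", "s_all")),
              paste0("k_", c("o_elec", "o_vdw", "h_elec", "h_vdw",
                             "s_indir", "s_dir", "s_all")),
              if (correlations) "c", "r_offset")
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(list(atom_solvent = empty, solvent_solvent = empty,
                cg = cg, blocks = blocks, units = ut, part = part))
  }
  reckey <- (sI - 1) * N + sJ

  # direct components: accumulate the all-atom nonbonded pair terms by
  # (canonical unit pair, source-site type)
  units <- .atom_units(part)
  roles <- sys$atoms$role
  ui <- units[pd$i]; uj <- units[pd$j]
  cross <- ui != uj
  I <- pmin(ui, uj)[cross]; J <- pmax(ui, uj)[cross]
  pkey <- (I - 1) * N + J
  inrec <- match(pkey, reckey)
  sel <- which(cross)[!is.na(inrec)]
  rec_of <- inrec[!is.na(inrec)]
  sgn <- ifelse(ui[sel] < uj[sel], 1, -1)
  src <- ifelse(sgn > 0, pd$j[sel], pd$i[sel])
  is_h <- roles[src] %in% c("water_H1", "water_H2")

  comp_names <- c("o_elec", "o_vdw", "h_elec", "h_vdw")
  Fc <- array(0, c(m, 3L, 4L))
  Kc <- matrix(0, m, 4L)
  srcF <- list(pd$F_elec, pd$F_vdw)
  srcH <- list(pd$Hb_elec, pd$Hb_vdw)
  for (tt in 1:2) {                  # 1 = elec, 2 = vdw
    for (hh in c(FALSE, TRUE)) {     # source oxygen/solute vs hydrogen
      rows <- sel[is_h == hh]
      if (!length(rows)) next
      ro <- rec_of[is_h == hh]
      s2 <- sgn[is_h == hh]
      Fv <- srcF[[tt]][rows, , drop = FALSE] * s2
      comp <- c(1L, 3L, 2L, 4L)[(tt - 1L) * 2L + 1L + hh]
      for (d in 1:3) {
        sgrp <- rowsum(Fv[, d], ro)
        ii <- as.integer(rownames(sgrp))
        Fc[ii, d, comp] <- Fc[ii, d, comp] + sgrp[, 1L]
      }
      Hb <- srcH[[tt]][rows, , drop = FALSE]
      flip <- s2 < 0
      if (any(flip)) Hb[flip, ] <- Hb[flip, .t9, drop = FALSE]
      kproj <- .project_blocks(Hb, rhat[ro, , drop = FALSE])
      sgrp <- rowsum(kproj, ro)
      ii <- as.integer(rownames(sgrp))
      Kc[ii, comp] <- Kc[ii, comp] + sgrp[, 1L]
    }
  }

  # indirect entries
  ridx <- function(u) 3L * (u - 1L)
  dF <- cgpf$dF
  sInd <- matrix(0, m, 3L)
  for (d in 1:3)
    sInd[, d] <- (dF[cbind(ridx(sI) + d, sJ)] - dF[cbind(ridx(sJ) + d, sI)]) / 2
  f_s_indir <- rowSums(sInd * rhat)
  Schur <- cg$Hp - blocks$H_psps
  kInd <- numeric(m)
  for (a in 1:3) for (b in 1:3)
    kInd <- kInd + rhat[, a] * Schur[cbind(ridx(sI) + a, ridx(sJ) + b)] * rhat[, b]

  f_comp <- matrix(0, m, 4L)
  for (cc in 1:4)
    f_comp[, cc] <- rowSums(matrix(Fc[, , cc], m, 3L) * rhat)
  colnames(f_comp) <- paste0("f_", comp_names)
  colnames(Kc) <- paste0("k_", comp_names)

  out <- data.frame(i = sI, j = sJ,
                    i_label = ut$labels[sI], j_label = ut$labels[sJ],
                    r = r)
  out <- cbind(out, f_comp,
               f_s_indir = f_s_indir,
               f_s_dir = rowSums(f_comp),
               Kc,
               k_s_indir = kInd,
               k_s_dir = rowSums(Kc))
  out$f_s_all <- out$f_s_dir + out$f_s_indir
  out$k_s_all <- out$k_s_dir + out$k_s_indir

  if (correlations) {
    modes <- mode_decompose(cg$Hp, ut$masses, zero_count = zero_count)
    Cm <- correlation_matrix(modes)
    out$c <- Cm[cbind(sI, sJ)]
  }

  as_rec <- out$i <= part$n_p
  atom_solvent <- out[as_rec, , drop = FALSE]
  if (nrow(atom_solvent)) {
    vdw_r <- sys$atoms$lj_rmin_half[part$p_idx][atom_solvent$i]
    atom_solvent$r_offset <- atom_solvent$r - vdw_r
  } else atom_solvent$r_offset <- numeric(0)
  solvent_solvent <- out[!as_rec, , drop = FALSE]
  if (nrow(solvent_solvent)) solvent_solvent$r_offset <- solvent_solvent$r
  else solvent_solvent$r_offset <- numeric(0)

  list(atom_solvent = atom_solvent, solvent_solvent = solvent_solvent,
       cg = cg, blocks = blocks, units = ut, part = part)
}

#' Collect interaction records over an ensemble of conformations
#'
#' @param frames list of n x 3 coordinate matrices (one per conformation).
#' @param sys the [molecular_system()] supplying topology and parameters.
#' @inheritParams analyze_frame
#' @param progress if TRUE, print a dot every 25 frames.
#' @return list with long-format data.frames `atom_solvent` and
#'   `solvent_solvent`, each with a `frame` column.
#' @export
collect_records <- function(frames, sys,
                            policy = nonbonded_policy("untruncated"),
                            record_cutoff = 12, correlations = FALSE,
                            zero_count = 6L, progress = FALSE) {
  if (!length(frames)) stop("empty ensemble")
  stopifnot(record_cutoff > 0)
  as_l <- vector("list", length(frames))
  ss_l <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    sys$coords <- frames[[k]]
    fr <- analyze_frame(sys, policy, record_cutoff, correlations, zero_count)
    if (nrow(fr$atom_solvent)) fr$atom_solvent$frame <- k
    if (nrow(fr$solvent_solvent)) fr$solvent_solvent$frame <- k
    as_l[[k]] <- fr$atom_solvent
    ss_l[[k]] <- fr$solvent_solvent
    if (progress && k %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  list(atom_solvent = do.call(rbind, as_l),
       solvent_solvent = do.call(rbind, ss_l))
}
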
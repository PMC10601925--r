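# The coarse-graining reduction itself: eliminate the relative hydrogen
# displacements by the stationarity condition (the gradient of the quadratic
# surface with respect to the mass-weighted hydrogen coordinates vanishes)
# and propagate the corrections into (V0', f', H').

# Solve H_1212 X = B robustly.  Uses a dense LU solve; if the reciprocal
# condition estimate is below `tol_cond`, falls back to an eigendecomposition
# pseudo-inverse in mass-weighted coordinates (the stationarity condition is
# posed in mass-weighted coordinates, which fixes the metric under which
# null directions are truncated), dropping |lambda| < 1e-8 * max|lambda|.
.solve_h1212 <- function(blocks, B, tol_cond = 1e-10, tol_drop = 1e-8) {
  A <- blocks$H_1212
  B <- as.matrix(B)
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (is.finite(rc) && rc > tol_cond) {
    return(list(X = solve(A, B), condition = 1 / rc, pseudo_inverse = FALSE,
                dropped = 0L))
  }
  ms <- sqrt(blocks$M12)
  Am <- A / (ms %o% ms)      # M^-1/2 A M^-1/2
  ee <- eigen(Am, symmetric = TRUE)
  mx <- max(abs(ee$values))
  if (mx == 0) stop("degenerate system: H_1212 is identically zero")
  keep <- abs(ee$values) >= tol_drop * mx
  if (!any(keep)) stop("degenerate system: all hydrogen modes dropped")
  if (any(!keep)) {
    # name the waters dominating the dropped (near-null) directions
    null_vecs <- ee$vectors[, !keep, drop = FALSE]
    w <- rowSums(null_vecs^2)
    ns <- length(w) / 6L
    per_water <- rowsum(w, rep(c(seq_len(ns), seq_len(ns)), each = 3L))
    off <- which(per_water > 0.5)
    attr(keep, "offending_waters") <- off
  }
  V <- ee$vectors[, keep, drop = FALSE]
  Bm <- B / ms
  X <- (V %*% (crossprod(V, Bm) / ee$values[keep])) / ms
  list(X = X, condition = mx / min(abs(ee$values[keep])),
       pseudo_inverse = TRUE, dropped = sum(!keep),
       offending_waters = attr(keep, "offending_waters"))
}

#' Constrained hydrogen response to a solute/solvent displacement
#'
#' Returns the relative hydrogen displacements that make the gradient of the
#' quadratic surface with respect to the (mass-weighted) hydrogen coordinates
#' vanish at the given `delta_ps`, i.e. the stationary point
#' `Delta_12 = H_1212^-1 (f_12 - H_12,ps delta_ps)`.
#'
#' @param blocks an [aggregate_blocks()] result.
#' @param delta_ps displacement vector over solute atoms + solvent particles.
#' @return the 6 n_s vector `Delta_12`.
#' @export
hydrogen_response <- function(blocks, delta_ps) {
  rhs <- blocks$f_12 - drop(crossprod(blocks$H_ps12, delta_ps))
  drop(.solve_h1212(blocks, rhs)$X)
}

#' Coarse-grain the quadratic surface over solute atoms + solvent particles
#'
#' Substitutes the constrained hydrogen response into the reduced-variable
#' surface.  The result is again quadratic, with
#' `H' = H_psps - H_ps,12 H_1212^-1 H_12,ps` (a Schur complement),
#' `f' = f_ps - H_ps,12 H_1212^-1 f_12`, and
#' `V0' = V0 - 1/2 f_12' H_1212^-1 f_12` (a diagnostic constant that never
#' affects forces or spring constants).  With zero forces this reduces to the
#' classical normal-mode-analysis model reduction.
#'
#' @param blocks an [aggregate_blocks()] result.
#' @return list of class `cg_surface` with `V0p`, `fp`, `Hp` and a
#'   `solve_report` (condition estimate, pseudo-inverse flag, dropped
#'   eigenvalue count).
#' @export
coarse_grain <- function(blocks) {
  sol <- .solve_h1212(blocks, cbind(blocks$f_12, t(blocks$H_ps12)))
  a <- sol$X[, 1L]
  K <- sol$X[, -1L, drop = FALSE]          # H_1212^-1 H_12,ps
  Hp <- blocks$H_psps - blocks$H_ps12 %*% K
  Hp <- (Hp + t(Hp)) / 2
  fp <- blocks$f_ps - drop(blocks$H_ps12 %*% a)
  V0p <- blocks$V0 - 0.5 * sum(blocks$f_12 * a)
  structure(list(V0p = V0p, fp = fp, Hp = Hp,
                 solve_report = list(condition = sol$condition,
                                     pseudo_inverse = sol$pseudo_inverse,
                                     dropped = sol$dropped)),
            class = "cg_surface")
}

#' Evaluate the coarse-grained surface
#'
#' @param cg a [coarse_grain()] result.
#' @param delta_ps displacement over solute atoms + solvent particles.
#' @return potential energy (kcal/mol); equals the reduced-variable surface
#'   evaluated at `(delta_ps, hydrogen_response(delta_ps))`.
#' @export
eval_cg_surface <- function(cg, delta_ps) {
  eval_surface(cg$V0p, cg$fp, cg$Hp, delta_ps)
}
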
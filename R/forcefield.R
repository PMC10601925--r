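# Minimal molecular-mechanics engine: Coulomb + 12-6 Lennard-Jones nonbonded
# terms (optionally smoothly switched to zero), harmonic bonds and harmonic
# angles, with analytic energies, forces, Hessians and a per-pair, per-term
# decomposition.  Units: A, kcal/mol, amu, elementary charge.

#' Atom roles recognised by the engine
#'
#' Every atom is either a solute ("protein") atom or one of the three sites of
#' a water molecule.  The water roles drive the partition into solvent
#' particles and relative hydrogen displacements.
#'
#' @format Character vector of the four role names.
#' @export
atom_roles <- c("protein", "water_O", "water_H1", "water_H2")

#' Construct a molecular system
#'
#' Bundles atoms, coordinates and bonded topology into the container consumed
#' by [compute_expansion()] and the coarse-graining pipeline.  Nonbonded
#' exclusions (all 1-2 and 1-3 pairs) are derived from the bond list.
#'
#' @param atoms data.frame with columns `element`, `type_label`, `charge` (e),
#'   `lj_epsilon` (kcal/mol), `lj_rmin_half` (A), `mass` (amu), `role` (one of
#'   [atom_roles]) and `molecule` (integer molecule id).
#' @param coords numeric n x 3 matrix of Cartesian coordinates in A.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices), `kb`
#'   (kcal/mol/A^2) and `b0` (A); the bond energy is `kb * (b - b0)^2`
#'   (CHARMM convention, no 1/2).
#' @param angles data.frame with columns `i`, `j`, `k` (with `j` the vertex),
#'   `ktheta` (kcal/mol/rad^2) and `theta0` (rad); energy
#'   `ktheta * (theta - theta0)^2`.
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, coords, bonds = NULL, angles = NULL) {
  coords <- as.matrix(coords)
  stopifnot(is.data.frame(atoms), ncol(coords) == 3L,
            nrow(coords) == nrow(atoms))
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  req <- c("element", "type_label", "charge", "lj_epsilon", "lj_rmin_half",
           "mass", "role", "molecule")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$mass <= 0)) stop("all masses must be positive")
  if (any(atoms$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  if (!all(atoms$role %in% atom_roles))
    stop("unknown atom role(s): ", paste(setdiff(atoms$role, atom_roles), collapse = ", "))
  n <- nrow(atoms)
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          kb = numeric(), b0 = numeric())
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(),
                                            k = integer(), ktheta = numeric(),
                                            theta0 = numeric())
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k)
  if (length(idx) && (min(idx) < 1L || max(idx) > n))
    stop("bond/angle atom indices out of range")
  # check each water molecule carries exactly one O and the two H sites
  wat <- atoms$role != "protein"
  if (any(wat)) {
    for (m in unique(atoms$molecule[wat])) {
      r <- sort(atoms$role[atoms$molecule == m])
      if (!identical(r, sort(c("water_O", "water_H1", "water_H2"))))
        stop("water molecule ", m, " must have exactly one water_O, water_H1, water_H2")
    }
  }
  sys <- structure(list(atoms = atoms, coords = coords, bonds = bonds,
                        angles = angles), class = "molecular_system")
  sys$exclusions <- .exclusion_pairs(sys)
  sys
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$role == "protein"), " solute, ",
      sum(x$atoms$role == "water_O"), " waters), ",
      nrow(x$bonds), " bonds, ", nrow(x$angles), " angles\n", sep = "")
  invisible(x)
}

# All 1-2 and 1-3 pairs as a 2-column matrix with i < j.
.exclusion_pairs <- function(sys) {
  b <- sys$bonds
  p12 <- cbind(pmin(b$i, b$j), pmax(b$i, b$j))
  # 1-3: two bonds sharing an atom
  nbr <- split(c(b$j, b$i), c(b$i, b$j))
  p13 <- matrix(integer(), 0L, 2L)
  for (a in names(nbr)) {
    ns <- unique(nbr[[a]])
    if (length(ns) >= 2L) {
      cmb <- utils::combn(sort(ns), 2L)
      p13 <- rbind(p13, t(cmb))
    }
  }
  ex <- unique(rbind(p12, p13))
  ex[ex[, 1L] != ex[, 2L], , drop = FALSE]
}

#' Nonbonded truncation policy
#'
#' `"untruncated"` evaluates Coulomb and Lennard-Jones terms at all distances
#' (the convention used at the analysis stage, where truncation artifacts must
#' be avoided).  `"switched"` multiplies each pair potential by a C-squared
#' quintic switching function that takes it smoothly from its full value at
#' `switch_start` to zero at `cutoff` (the convention used during sampling).
#'
#' @param mode "untruncated" or "switched".
#' @param switch_start distance (A) at which switching begins.
#' @param cutoff distance (A) beyond which switched interactions vanish.
#' @param coulomb_constant Coulomb prefactor in kcal*A/(mol*e^2).
#' @return An object of class `nonbonded_policy`.
#' @export
nonbonded_policy <- function(mode = c("untruncated", "switched"),
                             switch_start = 7.8, cutoff = 12,
                             coulomb_constant = 332.0637) {
  mode <- match.arg(mode)
  if (mode == "switched" && !(switch_start < cutoff))
    stop("switch_start must be < cutoff for switched policy")
  structure(list(mode = mode, switch_start = switch_start, cutoff = cutoff,
                 coulomb_constant = coulomb_constant),
            class = "nonbonded_policy")
}

# C2 quintic smoothstep and its first two derivatives wrt r, on [ron, roff].
.switch_fun <- function(r, ron, roff) {
  t <- (r - ron) / (roff - ron)
  t <- pmin(pmax(t, 0), 1)
  s <- 1 - t^3 * (10 - 15 * t + 6 * t^2)
  ds <- -(30 * t^2 - 60 * t^3 + 30 * t^4) / (roff - ron)
  d2s <- -(60 * t - 180 * t^2 + 120 * t^3) / (roff - ron)^2
  list(s = s, ds = ds, d2s = d2s)
}

# Apply switching to (u, up, upp) triples.
.apply_switch <- function(u, up, upp, r, policy) {
  if (policy$mode != "switched") return(list(u = u, up = up, upp = upp))
  sw <- .switch_fun(r, policy$switch_start, policy$cutoff)
  list(u   = u * sw$s,
       up  = up * sw$s + u * sw$ds,
       upp = upp * sw$s + 2 * up * sw$ds + u * sw$d2s)
}

# Nonbonded pair list (i < j) minus exclusions, as a 2-column integer matrix.
.nb_pairs <- function(sys) {
  n <- nrow(sys$atoms)
  if (n < 2L) return(matrix(integer(), 0L, 2L))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  keep <- rep(TRUE, length(i))
  ex <- sys$exclusions
  if (NROW(ex)) {
    n1 <- as.double(n) + 1
    keep[match(ex[, 1L] * n1 + ex[, 2L], i * n1 + j, nomatch = 0L)] <- FALSE
  }
  cbind(i[keep], j[keep])
}

# Scalar pair-potential derivatives (u, u', u'') for elec and vdw at given r.
.nb_scalars <- function(sys, policy, ip, jp, r) {
  at <- sys$atoms
  qq <- policy$coulomb_constant * at$charge[ip] * at$charge[jp]
  ue <- qq / r
  upe <- -qq / r^2
  uppe <- 2 * qq / r^3
  eps <- sqrt(at$lj_epsilon[ip] * at$lj_epsilon[jp])
  rmin <- at$lj_rmin_half[ip] + at$lj_rmin_half[jp]
  s6 <- (rmin / r)^6
  s12 <- s6^2
  uv <- eps * (s12 - 2 * s6)
  upv <- (12 * eps / r) * (s6 - s12)
  uppv <- (eps / r^2) * (156 * s12 - 84 * s6)
  e <- .apply_switch(ue, upe, uppe, r, policy)
  v <- .apply_switch(uv, upv, uppv, r, policy)
  list(elec = e, vdw = v)
}

# Harmonic-angle energy/gradient/Hessian for one (i, j, k) triple, vertex j.
# Returns E, grad (9-vector, order i,j,k) and 9 x 9 Hessian.
.angle_term <- function(xi, xj, xk, ktheta, theta0) {
  u <- xi - xj; v <- xk - xj
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  uh <- u / nu; vh <- v / nv
  c0 <- sum(uh * vh)
  c0 <- min(max(c0, -1), 1)
  s0 <- sqrt(max(1 - c0^2, .Machine$double.eps))
  th <- acos(c0)
  I3 <- diag(3)
  # gradient and Hessian of c = cos(theta) in (u, v)
  gc_u <- (vh - c0 * uh) / nu
  gc_v <- (uh - c0 * vh) / nv
  Hc_uu <- (-(vh %o% uh) - (uh %o% vh) - c0 * I3 + 3 * c0 * (uh %o% uh)) / nu^2
  Hc_vv <- (-(uh %o% vh) - (vh %o% uh) - c0 * I3 + 3 * c0 * (vh %o% vh)) / nv^2
  Hc_uv <- (I3 - (vh %o% vh) - (uh %o% uh) + c0 * (uh %o% vh)) / (nu * nv)
  gc <- c(gc_u, gc_v)
  Hc <- rbind(cbind(Hc_uu, Hc_uv), cbind(t(Hc_uv), Hc_vv))
  # theta = acos(c):  dth/dc = -1/s,  d2th/dc2 = -c/s^3
  gth <- (-1 / s0) * gc
  Hth <- (-1 / s0) * Hc + (-c0 / s0^3) * (gc %o% gc)
  # chain to (xi, xj, xk):  u = xi - xj, v = xk - xj
  A <- matrix(0, 6, 9)
  A[1:3, 1:3] <- I3; A[1:3, 4:6] <- -I3
  A[4:6, 7:9] <- I3; A[4:6, 4:6] <- -I3
  gx <- drop(t(A) %*% gth)
  Hx <- t(A) %*% Hth %*% A
  dth <- th - theta0
  list(E = ktheta * dth^2,
       grad = 2 * ktheta * dth * gx,
       hess = 2 * ktheta * (gx %o% gx) + 2 * ktheta * dth * Hx,
       theta = th)
}

# 3x3 block family for a central pair term u(r):
#   off-diagonal Hessian block (i,j) = -(u'' rr^T + (u'/r)(I - rr^T))
# returned as an m x 9 matrix in column-major 3x3 order.
.central_blocks <- function(up, upp, r, rhat) {
  m <- length(r)
  G <- matrix(0, m, 9L)
  for (a in 1:3) for (b in 1:3) {
    k <- (b - 1L) * 3L + a
    G[, k] <- upp * rhat[, a] * rhat[, b] +
      (up / r) * ((a == b) - rhat[, a] * rhat[, b])
  }
  -G
}

# Index of the transpose of a column-major 3x3 flattened to 9.
.t9 <- c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L)

# Full per-term pair computation.  Returns pair tables for nonbonded and
# bonded terms plus angle diagonal data, from which both the assembled
# expansion and the pair decomposition are built (so that reassembly is exact
# by construction).
.pair_terms <- function(sys, policy) {
  n <- nrow(sys$atoms)
  x <- sys$coords
  prs <- .nb_pairs(sys)
  if (policy$mode == "switched" && nrow(prs)) {
    d <- x[prs[, 1L], , drop = FALSE] - x[prs[, 2L], , drop = FALSE]
    keep <- rowSums(d * d) < policy$cutoff^2
    prs <- prs[keep, , drop = FALSE]
  }
  ip <- prs[, 1L]; jp <- prs[, 2L]
  d <- x[ip, , drop = FALSE] - x[jp, , drop = FALSE]
  r2 <- rowSums(d * d)
  if (any(r2 < 1e-12)) stop("coincident atoms in nonbonded pair list")
  r <- sqrt(r2)
  rhat <- d / r
  sc <- .nb_scalars(sys, policy, ip, jp, r)
  # force on i from j along rhat (j -> i): f = -u'(r) rhat
  F_elec <- -sc$elec$up * rhat
  F_vdw <- -sc$vdw$up * rhat
  Hb_elec <- .central_blocks(sc$elec$up, sc$elec$upp, r, rhat)
  Hb_vdw <- .central_blocks(sc$vdw$up, sc$vdw$upp, r, rhat)
  E_nb <- sum(sc$elec$u) + sum(sc$vdw$u)

  # bonds (central terms)
  b <- sys$bonds
  if (nrow(b)) {
    ib <- pmin(b$i, b$j); jb <- pmax(b$i, b$j)
    db <- x[ib, , drop = FALSE] - x[jb, , drop = FALSE]
    rb <- sqrt(rowSums(db * db))
    if (any(rb < 1e-12)) stop("coincident bonded atoms")
    rhb <- db / rb
    dr <- rb - b$b0
    ub <- b$kb * dr^2
    upb <- 2 * b$kb * dr
    uppb <- 2 * b$kb
    Fb <- -upb * rhb
    Hbb <- .central_blocks(upb, uppb, rb, rhb)
    E_bond <- sum(ub)
  } else {
    ib <- jb <- integer(); Fb <- matrix(0, 0L, 3L); Hbb <- matrix(0, 0L, 9L)
    E_bond <- 0
  }

  # angles: accumulate forces (attributed to the end-vertex pairs), pairwise
  # Hessian blocks and per-atom diagonal blocks
  ang <- sys$angles
  E_ang <- 0
  a_pairs <- matrix(integer(), 0L, 2L)
  a_F <- matrix(0, 0L, 3L); a_Hb <- matrix(0, 0L, 9L)
  diag_extra <- list()   # atom index -> 3x3 accumulated
  if (nrow(ang)) {
    np3 <- 3L * nrow(ang)
    a_pairs <- matrix(0L, np3, 2L)
    a_F <- matrix(0, np3, 3L); a_Hb <- matrix(0, np3, 9L)
    for (t in seq_len(nrow(ang))) {
      i <- ang$i[t]; j <- ang$j[t]; k <- ang$k[t]
      at <- .angle_term(x[i, ], x[j, ], x[k, ], ang$ktheta[t], ang$theta0[t])
      E_ang <- E_ang + at$E
      g <- at$grad; Hx <- at$hess
      fi <- -g[1:3]; fk <- -g[7:9]
      row0 <- 3L * (t - 1L)
      # pair (i, j): force on i attributed to vertex j; Hessian block (i, j)
      o1 <- order(c(i, j))
      p1 <- sort(c(i, j))
      a_pairs[row0 + 1L, ] <- p1
      B_ij <- Hx[1:3, 4:6]
      if (i < j) { a_F[row0 + 1L, ] <- fi;  a_Hb[row0 + 1L, ] <- as.vector(B_ij) }
      else       { a_F[row0 + 1L, ] <- -fi; a_Hb[row0 + 1L, ] <- as.vector(t(B_ij)) }
      # pair (k, j)
      p2 <- sort(c(k, j))
      a_pairs[row0 + 2L, ] <- p2
      B_kj <- Hx[7:9, 4:6]
      if (k < j) { a_F[row0 + 2L, ] <- fk;  a_Hb[row0 + 2L, ] <- as.vector(B_kj) }
      else       { a_F[row0 + 2L, ] <- -fk; a_Hb[row0 + 2L, ] <- as.vector(t(B_kj)) }
      # pair (i, k): zero force attribution, nonzero Hessian coupling
      p3 <- sort(c(i, k))
      a_pairs[row0 + 3L, ] <- p3
      B_ik <- Hx[1:3, 7:9]
      a_Hb[row0 + 3L, ] <- if (i < k) as.vector(B_ik) else as.vector(t(B_ik))
      # diagonal blocks
      for (nm in list(list(i, Hx[1:3, 1:3]), list(j, Hx[4:6, 4:6]),
                      list(k, Hx[7:9, 7:9]))) {
        key <- as.character(nm[[1L]])
        diag_extra[[key]] <- if (is.null(diag_extra[[key]])) nm[[2L]]
                             else diag_extra[[key]] + nm[[2L]]
      }
    }
  }

  list(n = n,
       nb = list(i = ip, j = jp, F_elec = F_elec, F_vdw = F_vdw,
                 Hb_elec = Hb_elec, Hb_vdw = Hb_vdw, r = r, rhat = rhat),
       bond = list(i = ib, j = jb, F = Fb, Hb = Hbb),
       angle = list(pairs = a_pairs, F = a_F, Hb = a_Hb,
                    diag = diag_extra),
       V0 = E_nb + E_bond + E_ang)
}

# Merge bonded-pair contributions (bond central + angle attribution) into a
# single bonded table with unique (i, j) rows, i < j.
.bonded_table <- function(pt) {
  i <- c(pt$bond$i, pt$angle$pairs[, 1L])
  j <- c(pt$bond$j, pt$angle$pairs[, 2L])
  FF <- rbind(pt$bond$F, pt$angle$F)
  HH <- rbind(pt$bond$Hb, pt$angle$Hb)
  if (!length(i))
    return(list(i = integer(), j = integer(),
                F = matrix(0, 0L, 3L), Hb = matrix(0, 0L, 9L)))
  key <- paste(i, j)
  grp <- match(key, unique(key))
  Fm <- rowsum(FF, grp, reorder = FALSE)
  Hm <- rowsum(HH, grp, reorder = FALSE)
  first <- !duplicated(key)
  list(i = i[first], j = j[first], F = Fm, Hb = Hm)
}

#' Second-order expansion of the potential-energy surface
#'
#' Evaluates the potential energy, analytic forces and the analytic Hessian of
#' the configured force field at the system's conformation, i.e. the pieces of
#' the quadratic surface `V(delta) = V0 - f' delta + 1/2 delta' H delta` in
#' atom displacements `delta` (force = negative energy gradient).
#'
#' @param sys a [molecular_system()].
#' @param policy a [nonbonded_policy()].
#' @return list of class `second_order_expansion` with `V0` (kcal/mol), `f`
#'   (3n vector, kcal/mol/A) and `H` (3n x 3n symmetric, kcal/mol/A^2).
#' @export
compute_expansion <- function(sys, policy = nonbonded_policy()) {
  .assemble_expansion(.pair_terms(sys, policy))
}

# Assembly of (V0, f, H) from a .pair_terms() result.
.assemble_expansion <- function(pt) {
  n <- pt$n
  f <- numeric(3L * n)
  H <- matrix(0, 3L * n, 3L * n)

  add_central <- function(i, j, FF, HB) {
    if (!length(i)) return(invisible())
    # forces
    fi <- rowsum(rbind(FF, -FF), c(i, j))
    ats <- as.integer(rownames(fi))
    for (d in 1:3) f[3L * (ats - 1L) + d] <<- f[3L * (ats - 1L) + d] + fi[, d]
    # off-diagonal blocks H[i, j] (+ symmetric transpose)
    for (a in 1:3) for (b in 1:3) {
      k <- (b - 1L) * 3L + a
      ridx <- 3L * (i - 1L) + a; cidx <- 3L * (j - 1L) + b
      H[cbind(ridx, cidx)] <<- H[cbind(ridx, cidx)] + HB[, k]
      H[cbind(cidx, ridx)] <<- H[cbind(cidx, ridx)] + HB[, k]
    }
    # diagonal blocks accumulate -block for both i and j
    Dsum <- rowsum(rbind(HB, HB), c(i, j))
    ats <- as.integer(rownames(Dsum))
    for (a in 1:3) for (b in 1:3) {
      k <- (b - 1L) * 3L + a
      idx <- cbind(3L * (ats - 1L) + a, 3L * (ats - 1L) + b)
      H[idx] <<- H[idx] - Dsum[, k]
    }
    invisible()
  }

  add_central(pt$nb$i, pt$nb$j, pt$nb$F_elec + pt$nb$F_vdw,
              pt$nb$Hb_elec + pt$nb$Hb_vdw)
  add_central(pt$bond$i, pt$bond$j, pt$bond$F, pt$bond$Hb)

  # angle contributions (forces via attribution, Hessian blocks + diagonals);
  # merge duplicate pairs first so indexed assignment never collides
  ap <- pt$angle
  if (nrow(ap$pairs)) {
    key <- paste(ap$pairs[, 1L], ap$pairs[, 2L])
    grp <- match(key, unique(key))
    first <- !duplicated(key)
    i <- ap$pairs[first, 1L]; j <- ap$pairs[first, 2L]
    Fm <- rowsum(ap$F, grp, reorder = FALSE)
    Hm <- rowsum(ap$Hb, grp, reorder = FALSE)
    fi <- rowsum(rbind(Fm, -Fm), c(i, j))
    ats <- as.integer(rownames(fi))
    for (d in 1:3) f[3L * (ats - 1L) + d] <- f[3L * (ats - 1L) + d] + fi[, d]
    for (a in 1:3) for (b in 1:3) {
      k <- (b - 1L) * 3L + a
      ridx <- 3L * (i - 1L) + a; cidx <- 3L * (j - 1L) + b
      H[cbind(ridx, cidx)] <- H[cbind(ridx, cidx)] + Hm[, k]
      H[cbind(cidx, ridx)] <- H[cbind(cidx, ridx)] + Hm[, k]
    }
    for (key in names(ap$diag)) {
      at <- as.integer(key)
      sl <- (3L * (at - 1L) + 1L):(3L * at)
      H[sl, sl] <- H[sl, sl] + ap$diag[[key]]
    }
  }

  structure(list(V0 = pt$V0, f = f, H = H), class = "second_order_expansion")
}

#' Per-pair, per-term force and Hessian-block decomposition
#'
#' Splits the nonbonded and bonded interactions into ordered-pair force
#' 3-vectors and unordered-pair 3 x 3 Hessian blocks, separately for the
#' electrostatic, van der Waals and bonded terms.  Forces are stored on the
#' lower-index atom (`force on i exerted by j`, with `i < j`); the reverse
#' force is its negation and the `(j, i)` Hessian block the transpose.
#' Summing force blocks over partners and terms reproduces the force vector
#' of [compute_expansion()] exactly.
#'
#' @inheritParams compute_expansion
#' @return list of class `pair_decomposition` with elements `i`, `j` (atom
#'   indices, i < j), `F_elec`, `F_vdw` (m x 3), `Hb_elec`, `Hb_vdw` (m x 9,
#'   column-major blocks), the analogous `bonded` table, and `r`, `rhat` for
#'   the nonbonded pairs.
#' @export
compute_pair_decomposition <- function(sys, policy = nonbonded_policy()) {
  .pd_from_terms(.pair_terms(sys, policy))
}

.pd_from_terms <- function(pt) {
  bd <- .bonded_table(pt)
  structure(list(n = pt$n,
                 i = pt$nb$i, j = pt$nb$j,
                 F_elec = pt$nb$F_elec, F_vdw = pt$nb$F_vdw,
                 Hb_elec = pt$nb$Hb_elec, Hb_vdw = pt$nb$Hb_vdw,
                 r = pt$nb$r, rhat = pt$nb$rhat,
                 bonded = bd, V0 = pt$V0),
            class = "pair_decomposition")
}

#' Reassemble the force vector from a pair decomposition
#'
#' @param pd a [compute_pair_decomposition()] result.
#' @return 3n force vector; equals `compute_expansion()$f` up to the exact
#'   floating-point summation order.
#' @export
reassemble_forces <- function(pd) {
  n <- pd$n
  f <- numeric(3L * n)
  add <- function(i, j, FF) {
    if (!length(i)) return(invisible())
    s <- rowsum(rbind(FF, -FF), c(i, j))
    ats <- as.integer(rownames(s))
    for (d in 1:3) f[3L * (ats - 1L) + d] <<- f[3L * (ats - 1L) + d] + s[, d]
  }
  add(pd$i, pd$j, pd$F_elec + pd$F_vdw)
  add(pd$bonded$i, pd$bonded$j, pd$bonded$F)
  f
}

#' Evaluate a quadratic potential-energy surface
#'
#' @param V0 constant term (kcal/mol).
#' @param f force vector (negative gradient) at the expansion point.
#' @param H Hessian matrix.
#' @param delta displacement vector.
#' @return `V0 - f' delta + 1/2 delta' H delta`.
#' @export
eval_surface <- function(V0, f, H, delta) {
  drop(V0 - sum(f * delta) + 0.5 * crossprod(delta, H %*% delta))
}

#' Finite-difference consistency report
#'
#' Compares the analytic force vector against central finite differences of
#' the energy, and the analytic Hessian against central finite differences of
#' the analytic force, at the given step.
#'
#' @inheritParams compute_expansion
#' @param step displacement step in A.
#' @return list with `max_force_dev` (kcal/mol/A), `max_hessian_dev`
#'   (kcal/mol/A^2) and the analytic expansion.
#' @export
finite_difference_check <- function(sys, policy = nonbonded_policy(),
                                    step = 1e-5) {
  stopifnot(step > 0)
  ex <- compute_expansion(sys, policy)
  n <- nrow(sys$atoms)
  x0 <- sys$coords
  energy_at <- function(xc) {
    s2 <- sys; s2$coords <- xc
    .pair_terms(s2, policy)$V0
  }
  force_at <- function(xc) {
    s2 <- sys; s2$coords <- xc
    compute_expansion(s2, policy)$f
  }
  fnum <- numeric(3L * n)
  Hnum <- matrix(0, 3L * n, 3L * n)
  for (a in seq_len(n)) for (d in 1:3) {
    k <- 3L * (a - 1L) + d
    xp <- x0; xp[a, d] <- xp[a, d] + step
    xm <- x0; xm[a, d] <- xm[a, d] - step
    fnum[k] <- -(energy_at(xp) - energy_at(xm)) / (2 * step)
    Hnum[, k] <- -(force_at(xp) - force_at(xm)) / (2 * step)
  }
  list(max_force_dev = max(abs(ex$f - fnum)),
       max_hessian_dev = max(abs(ex$H - Hnum)),
       expansion = ex)
}
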
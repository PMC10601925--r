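# Seeded generators: rigid-TIP3P water droplets around optional probe
# particles, Metropolis Monte-Carlo sampling at 298 K with rigid-body water
# moves, frame subsampling, solvent-layer selection, and random quadratic
# systems used as oracle fuel.

.kB <- 0.0019872041   # kcal/mol/K

#' TIP3P force-field parameters
#'
#' Reads the bundled three-site water parameter file (charges, Lennard-Jones
#' coefficients, flexible-water bond/angle constants, masses).
#'
#' @return list with data.frames `atoms`, `bonds`, `angles`.
#' @export
tip3p_params <- function() {
  read_param_file(system.file("extdata", "tip3p.prm", package = "cgdelta",
                              mustWork = TRUE))
}

#' Specification of a single-site probe particle
#'
#' Stands in for a protein atom at the droplet center: a point charge with
#' Lennard-Jones parameters.
#'
#' @param label type label used in interaction records.
#' @param charge partial charge (e).
#' @param lj_epsilon Lennard-Jones well depth (kcal/mol); the default is a
#'   methine-carbon-like value.
#' @param lj_rmin_half half of the Lennard-Jones minimum distance (A).
#' @param mass mass (amu).
#' @param offset position relative to the droplet center (A).
#' @return list of class `probe_spec`.
#' @export
probe_spec <- function(label, charge = 0, lj_epsilon = 0.02,
                       lj_rmin_half = 2.275, mass = 12.011,
                       offset = c(0, 0, 0)) {
  stopifnot(nchar(label) > 0, lj_epsilon >= 0, mass > 0)
  structure(list(label = label, charge = charge, lj_epsilon = lj_epsilon,
                 lj_rmin_half = lj_rmin_half, mass = mass,
                 offset = as.numeric(offset)),
            class = "probe_spec")
}

#' Monte-Carlo sampler configuration
#'
#' @param n_waters number of water molecules.
#' @param seed mandatory RNG seed.
#' @param radius droplet radius (A); default from `density`.
#' @param density target number density of waters (1/A^3); the liquid value
#'   0.0334 corresponds to 0.997 g/cm^3.
#' @param temperature sampling temperature (K).
#' @param trans_step maximum rigid-body translation per move (A).
#' @param rot_step maximum rigid-body rotation per move (rad).
#' @param n_frames number of frames to emit.
#' @param burn_in sweeps discarded before the first frame.
#' @param frame_interval sweeps between emitted frames.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(n_waters, seed, radius = NULL, density = 0.0334,
                           temperature = 298, trans_step = 0.2,
                           rot_step = 0.35, n_frames = 200L,
                           burn_in = 200L, frame_interval = 10L) {
  stopifnot(n_waters >= 1, temperature > 0, trans_step > 0, rot_step > 0,
            n_frames >= 1, burn_in >= 0, frame_interval >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (is.null(radius)) radius <- (n_waters / (density * 4 * pi / 3))^(1 / 3)
  structure(list(n_waters = as.integer(n_waters), seed = as.integer(seed),
                 radius = radius, density = density,
                 temperature = temperature, trans_step = trans_step,
                 rot_step = rot_step, n_frames = as.integer(n_frames),
                 burn_in = as.integer(burn_in),
                 frame_interval = as.integer(frame_interval)),
            class = "sampler_config")
}

# rotation matrix about unit axis by angle (Rodrigues)
.rot_mat <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# ideal-geometry water sites (O at origin) for given bond length and angle
.water_sites <- function(b0, theta0, R = diag(3)) {
  h1 <- b0 * c(sin(theta0 / 2), 0, cos(theta0 / 2))
  h2 <- b0 * c(-sin(theta0 / 2), 0, cos(theta0 / 2))
  rbind(c(0, 0, 0), drop(R %*% h1), drop(R %*% h2))
}

#' Build a water droplet around optional probe particles
#'
#' Places `n_waters` rigid ideal-geometry TIP3P waters uniformly inside a
#' sphere by rejection sampling (oxygen-oxygen separations above 2.4 A,
#' clearance around the probes), with random orientations; probes sit at the
#' droplet center.  Deterministic for a given seed.
#'
#' @param config a [sampler_config()].
#' @param probes list of [probe_spec()] objects.
#' @return a [molecular_system()].
#' @export
build_droplet <- function(config, probes = list()) {
  if (inherits(probes, "probe_spec")) probes <- list(probes)
  set.seed(config$seed)
  par <- tip3p_params()
  pa <- par$atoms
  o_row <- pa[pa$role == "water_O", ]
  h_row <- pa[pa$role == "water_H", ]
  b0 <- par$bonds$b0[1L]
  theta0 <- par$angles$theta0[1L]
  R <- config$radius
  nw <- config$n_waters

  probe_pos <- do.call(rbind, lapply(probes, function(p) p$offset))
  clearance <- if (length(probes))
    vapply(probes, function(p) max(2.4, 0.85 * (p$lj_rmin_half + o_row$lj_rmin_half)),
           numeric(1)) else numeric(0)
  # grow the sphere so the probes' excluded cores do not raise the density
  R <- (R^3 + sum(clearance^3))^(1 / 3)
  if (length(clearance)) R <- max(R, max(clearance) + 1.2)

  O <- matrix(0, nw, 3L)
  placed <- 0L
  attempts <- 0L
  while (placed < nw) {
    attempts <- attempts + 1L
    if (attempts > 1e4L * nw) stop("packing failure: could not place waters")
    p <- stats::runif(3, -R, R)
    if (sum(p^2) > R^2) next
    if (length(probes) &&
        any(sqrt(rowSums((probe_pos - rep(p, each = nrow(probe_pos)))^2)) < clearance))
      next
    if (placed > 0L &&
        min(rowSums((O[seq_len(placed), , drop = FALSE] -
                       rep(p, each = placed))^2)) < 2.4^2) next
    placed <- placed + 1L
    O[placed, ] <- p
  }

  coords <- matrix(0, 0L, 3L)
  atoms <- list()
  mol <- 0L
  for (p in probes) {
    mol <- mol + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = "X", type_label = p$label, charge = p$charge,
      lj_epsilon = p$lj_epsilon, lj_rmin_half = p$lj_rmin_half,
      mass = p$mass, role = "protein", molecule = mol)
    coords <- rbind(coords, p$offset)
  }
  bonds <- list(); angles <- list()
  for (w in seq_len(nw)) {
    mol <- mol + 1L
    ax <- stats::rnorm(3)
    Rm <- .rot_mat(ax, stats::runif(1, 0, 2 * pi))
    sites <- .water_sites(b0, theta0, Rm)
    sites <- sites + rep(O[w, ], each = 3L)
    base <- nrow(coords)
    coords <- rbind(coords, sites)
    atoms[[length(atoms) + 1L]] <- data.frame(
      element = c("O", "H", "H"),
      type_label = c(o_row$type_label, h_row$type_label, h_row$type_label),
      charge = c(o_row$charge, h_row$charge, h_row$charge),
      lj_epsilon = c(o_row$lj_epsilon, h_row$lj_epsilon, h_row$lj_epsilon),
      lj_rmin_half = c(o_row$lj_rmin_half, h_row$lj_rmin_half, h_row$lj_rmin_half),
      mass = c(o_row$mass, h_row$mass, h_row$mass),
      role = c("water_O", "water_H1", "water_H2"), molecule = mol)
    bonds[[length(bonds) + 1L]] <- data.frame(
      i = base + 1L, j = base + 2L:3L,
      kb = par$bonds$kb[1L], b0 = b0)
    angles[[length(angles) + 1L]] <- data.frame(
      i = base + 2L, j = base + 1L, k = base + 3L,
      ktheta = par$angles$ktheta[1L], theta0 = theta0)
  }
  rownames(coords) <- NULL
  out <- molecular_system(do.call(rbind, atoms), coords,
                          bonds = do.call(rbind, bonds),
                          angles = do.call(rbind, angles))
  attr(out, "droplet_radius") <- R
  out
}

# interaction energy of one water (3 sites) with a set of other atoms under
# the given policy, plus a flat-bottom spherical restraint on its oxygen.
# ox/oy/oz are the other atoms' coordinate columns; cq = C * q_other,
# eo/ro their LJ parameters.  Written with scalar-column arithmetic: this is
# the sampler's inner loop.
.water_env_energy <- function(xw, ox, oy, oz, cq, eo, ro, qw, ew, rw,
                              policy, restraint_radius, restraint_k = 2) {
  E <- 0
  switched <- policy$mode == "switched"
  co2 <- policy$cutoff^2
  for (a in 1:3) {
    dx <- ox - xw[a, 1L]; dy <- oy - xw[a, 2L]; dz <- oz - xw[a, 3L]
    r2 <- dx * dx + dy * dy + dz * dz
    if (switched) {
      sel <- r2 < co2
      if (!any(sel)) next
      r <- sqrt(r2[sel])
      rmin <- rw[a] + ro[sel]
      s6 <- (rmin * rmin / r2[sel])^3
      u <- qw[a] * cq[sel] / r + sqrt(ew[a] * eo[sel]) * (s6 * s6 - 2 * s6)
      t <- (r - policy$switch_start) / (policy$cutoff - policy$switch_start)
      t[t < 0] <- 0
      E <- E + sum(u * (1 - t^3 * (10 - 15 * t + 6 * t^2)))
    } else {
      r <- sqrt(r2)
      rmin <- rw[a] + ro
      s6 <- (rmin * rmin / r2)^3
      E <- E + sum(qw[a] * cq / r + sqrt(ew[a] * eo) * (s6 * s6 - 2 * s6))
    }
  }
  dO2 <- xw[1L, 1L]^2 + xw[1L, 2L]^2 + xw[1L, 3L]^2
  if (dO2 > restraint_radius^2)
    E <- E + restraint_k * (sqrt(dO2) - restraint_radius)^2
  E
}

#' Metropolis Monte-Carlo sampling of rigid waters
#'
#' Samples the droplet at the configured temperature with rigid-body water
#' moves (translation plus rotation about the oxygen), accepting moves by the
#' Metropolis criterion under the given (typically switched) nonbonded
#' policy.  Probe atoms stay fixed.  A soft flat-bottom spherical restraint
#' on the oxygens prevents evaporation; it acts only during sampling and is
#' not part of the analysis-stage potential.
#'
#' @param sys a [build_droplet()] system.
#' @param config the [sampler_config()] (its seed drives all randomness).
#' @param policy sampling-stage [nonbonded_policy()]; default switched
#'   7.8/12 A.
#' @return list with `frames` (list of coordinate matrices),
#'   `acceptance_rate`, `energies` (sampler energy at each frame) and the
#'   resolved config.
#' @export
mc_sample <- function(sys, config,
                      policy = nonbonded_policy("switched")) {
  set.seed(config$seed + 1L)
  at <- sys$atoms
  x <- sys$coords
  wat_mol <- sort(unique(at$molecule[at$role == "water_O"]))
  widx <- lapply(wat_mol, function(m) {
    c(which(at$molecule == m & at$role == "water_O"),
      which(at$molecule == m & at$role == "water_H1"),
      which(at$molecule == m & at$role == "water_H2"))
  })
  nw <- length(widx)
  q <- at$charge; eps <- at$lj_epsilon; rmh <- at$lj_rmin_half
  n_at <- nrow(x)
  others <- lapply(widx, function(ia) setdiff(seq_len(n_at), ia))
  cq_o <- lapply(others, function(oidx) policy$coulomb_constant * q[oidx])
  eps_o <- lapply(others, function(oidx) eps[oidx])
  rmh_o <- lapply(others, function(oidx) rmh[oidx])
  kT <- .kB * config$temperature
  rrad <- attr(sys, "droplet_radius")
  if (is.null(rrad)) rrad <- config$radius
  total_sweeps <- config$burn_in +
    (config$n_frames - 1L) * config$frame_interval
  frames <- vector("list", config$n_frames)
  energies <- numeric(config$n_frames)
  nf <- 0L
  n_acc <- 0; n_try <- 0
  acc_window <- 0
  for (sweep in 0:total_sweeps) {
    if (sweep > 0L) {
      for (w in seq_len(nw)) {
        ia <- widx[[w]]
        oidx <- others[[w]]
        ox <- x[oidx, 1L]; oy <- x[oidx, 2L]; oz <- x[oidx, 3L]
        xw <- x[ia, , drop = FALSE]
        e_old <- .water_env_energy(xw, ox, oy, oz, cq_o[[w]], eps_o[[w]],
                                   rmh_o[[w]], q[ia], eps[ia], rmh[ia],
                                   policy, rrad)
        tr <- stats::runif(3, -config$trans_step, config$trans_step)
        ax <- stats::rnorm(3)
        ang <- stats::runif(1, -config$rot_step, config$rot_step)
        Rm <- .rot_mat(ax, ang)
        xnew <- xw
        xnew[2:3, ] <- t(Rm %*% t(xw[2:3, ] - rep(xw[1L, ], each = 2L))) +
          rep(xw[1L, ], each = 2L)
        xnew <- xnew + rep(tr, each = 3L)
        e_new <- .water_env_energy(xnew, ox, oy, oz, cq_o[[w]], eps_o[[w]],
                                   rmh_o[[w]], q[ia], eps[ia], rmh[ia],
                                   policy, rrad)
        n_try <- n_try + 1
        if (e_new <= e_old || stats::runif(1) < exp(-(e_new - e_old) / kT)) {
          x[ia, ] <- xnew
          n_acc <- n_acc + 1
          acc_window <- acc_window + 1
        }
      }
      if (sweep %% 50L == 0L) {
        if (acc_window == 0)
          stop("step-size error: no moves accepted over a 50-sweep window")
        acc_window <- 0
      }
    }
    if (sweep >= config$burn_in &&
        (sweep - config$burn_in) %% config$frame_interval == 0L &&
        nf < config$n_frames) {
      nf <- nf + 1L
      frames[[nf]] <- x
      energies[nf] <- NA_real_
    }
  }
  list(frames = frames, acceptance_rate = n_acc / max(n_try, 1),
       energies = energies, config = config)
}

#' Frame-subsampling index list
#'
#' Time points `burn_in, burn_in + interval, ...` up to and including
#' `total_span` (all in the same time unit).
#'
#' @param total_span trajectory length.
#' @param interval sampling interval.
#' @param burn_in discarded initial span.
#' @return numeric vector of sampled time points.
#' @export
subsample_frames <- function(total_span, interval, burn_in) {
  stopifnot(interval > 0)
  if (burn_in > total_span) stop("burn_in exceeds the trajectory span")
  k <- floor((total_span - burn_in) / interval + 1e-9)
  burn_in + interval * (0:k)
}

#' Select the solvent layer around the solute
#'
#' Keeps whole waters whose oxygen lies within `thickness` A of the nearest
#' solute atom (boundary included).
#'
#' @param sys a [molecular_system()] with at least one solute atom.
#' @param thickness layer thickness (A).
#' @return the subset [molecular_system()].
#' @export
select_solvent_layer <- function(sys, thickness = 12) {
  at <- sys$atoms
  p <- which(at$role == "protein")
  if (!length(p)) stop("system has no solute atoms")
  Xp <- sys$coords[p, , drop = FALSE]
  keep_mol <- at$molecule[p]
  o <- which(at$role == "water_O")
  for (oi in o) {
    d2 <- rowSums((Xp - rep(sys$coords[oi, ], each = nrow(Xp)))^2)
    if (min(d2) <= thickness^2)
      keep_mol <- c(keep_mol, at$molecule[oi])
  }
  subset_system(sys, which(at$molecule %in% keep_mol))
}

#' Subset a system to a set of atoms
#'
#' Bonds and angles are kept only when all member atoms survive; indices are
#' remapped.
#'
#' @param sys a [molecular_system()].
#' @param atom_idx atom indices to keep.
#' @return the subset [molecular_system()].
#' @export
subset_system <- function(sys, atom_idx) {
  atom_idx <- sort(unique(atom_idx))
  map <- match(seq_len(nrow(sys$atoms)), atom_idx)
  b <- sys$bonds
  b <- b[b$i %in% atom_idx & b$j %in% atom_idx, , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  a <- sys$angles
  a <- a[a$i %in% atom_idx & a$j %in% atom_idx & a$k %in% atom_idx, ,
         drop = FALSE]
  a$i <- map[a$i]; a$j <- map[a$j]; a$k <- map[a$k]
  molecular_system(sys$atoms[atom_idx, , drop = FALSE],
                   sys$coords[atom_idx, , drop = FALSE], b, a)
}

#' Random quadratic system for reduction oracles
#'
#' Generates a random symmetric Hessian (positive-definite or indefinite),
#' random forces and masses, and a valid solute/water partition over
#' `n_p + 3 n_s` atoms, for exercising the coarse-graining algebra on
#' systems with no molecular-mechanics structure.
#'
#' @param seed RNG seed.
#' @param n_p number of solute atoms.
#' @param n_s number of waters.
#' @param definiteness `"pd"` or `"indefinite"`.
#' @return list with `expansion` (V0, f, H), `masses`, `part`.
#' @export
random_quadratic_system <- function(seed, n_p, n_s,
                                    definiteness = c("pd", "indefinite")) {
  definiteness <- match.arg(definiteness)
  stopifnot(n_p >= 0, n_s >= 1)
  set.seed(seed)
  n <- n_p + 3L * n_s
  n3 <- 3L * n
  A <- matrix(stats::rnorm(n3 * n3), n3, n3)
  H <- if (definiteness == "pd") crossprod(A) / n3 + diag(0.5, n3)
       else (A + t(A)) / 2
  f <- stats::rnorm(n3)
  masses <- stats::runif(n, 1, 16)
  part <- structure(list(
    p_idx = seq_len(n_p),
    o_idx = n_p + 3L * (seq_len(n_s) - 1L) + 1L,
    h1_idx = n_p + 3L * (seq_len(n_s) - 1L) + 2L,
    h2_idx = n_p + 3L * (seq_len(n_s) - 1L) + 3L,
    n_p = as.integer(n_p), n_s = as.integer(n_s)),
    class = "partition_index")
  list(expansion = list(V0 = stats::rnorm(1), f = f, H = H),
       masses = masses, part = part)
}
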
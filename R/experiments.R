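# Canned desk-scale experiments: a Boltzmann-sampled water droplet analyzed
# for solvent-solvent structure and motion correlations, and probe-in-water
# droplets analyzed for the hydrophilic degree.  The default arguments are
# the package's reference study conditions; tests and the acceptance script
# run these functions as-is.

#' Solvent-solvent structure and correlation experiment
#'
#' Samples a pure TIP3P droplet by Metropolis Monte Carlo at 298 K, runs the
#' coarse-graining pipeline on every frame, bins the solvent-solvent
#' effective pairwise forces at 0.1 A with 5-95 percent trimming, integrates
#' the force curve to an effective pair potential, and fits the exponential
#' decay ratio of the solvent-solvent motion correlation over 5-10 A.
#'
#' The droplet's correlation curve plateaus at a small negative offset at
#' large separations (a finite free system's displacement covariances are
#' constrained to balance), so the decay fit subtracts a baseline estimated
#' from the outermost 1 A of unmasked bins; if that still leaves nonpositive
#' values in the window, the baseline is lowered just below the window
#' minimum as a numerical safeguard.
#'
#' @param seed RNG seed driving droplet construction and sampling.
#' @param n_waters droplet size (waters).
#' @param n_frames frames analyzed.
#' @param frame_interval sweeps between frames.
#' @param burn_in sweeps discarded before the first frame.
#' @param min_count minimum records per profile bin.
#' @return list with the sampled `records`, the force curve `fcurve`, the
#'   integrated potential `potential`, `r_min` (argmin of the potential over
#'   the 2-4 A search range), the correlation curve `ccurve`, `decay_ratio`
#'   and the `baseline` used.
#' @export
solvent_structure_experiment <- function(seed, n_waters = 100,
                                         n_frames = 200,
                                         frame_interval = 5L,
                                         burn_in = 300L,
                                         min_count = 25L) {
  cfg <- sampler_config(n_waters = n_waters, seed = seed,
                        burn_in = burn_in, n_frames = n_frames,
                        frame_interval = frame_interval)
  sys <- build_droplet(cfg)
  run <- mc_sample(sys, cfg)
  rec <- collect_records(run$frames, sys, correlations = TRUE)
  ss <- rec$solvent_solvent

  fcurve <- bin_profile(ss, "f_s_all", min_count = min_count)
  pot <- integrate_force_to_potential(fcurve)
  sel <- pot$x >= 2 & pot$x <= 4
  r_min <- pot$x[sel][which.min(pot$U[sel])]

  ccurve <- bin_profile(ss, "c", min_count = min_count)
  good <- !ccurve$masked
  xs <- ccurve$x[good]
  tail_sel <- good & ccurve$x > max(xs) - 1
  b <- mean(ccurve$mean[tail_sel])
  win <- !ccurve$masked & ccurve$x >= 5 & ccurve$x <= 10
  if (any(ccurve$mean[win] - b <= 0))
    b <- min(ccurve$mean[win]) - 0.005
  ratio <- decay_ratio(ccurve[good, ], window = c(5, 10), baseline = b)

  list(records = ss, fcurve = fcurve, potential = pot, r_min = r_min,
       ccurve = ccurve, decay_ratio = ratio, baseline = b,
       acceptance_rate = run$acceptance_rate)
}

#' Probe hydrophilicity experiment
#'
#' Samples a droplet around a fixed central probe (a methine-carbon-like
#' Lennard-Jones site, optionally charged), collects atom-solvent
#' interaction records, and evaluates the hydrophilic degree from the mean
#' effective pairwise force and the spring-integrated approximated force.
#'
#' @param seed RNG seed.
#' @param charge probe charge (e).
#' @param n_waters droplet size.
#' @param n_frames frames analyzed.
#' @param frame_interval sweeps between frames.
#' @param burn_in sweeps discarded before the first frame.
#' @param label probe type label.
#' @return list with `records`, `fcurve`, `fhat`, `kcurve` and the
#'   [hydrophilic_degree()] `result`.
#' @export
probe_hydrophilicity_experiment <- function(seed, charge,
                                            n_waters = 80,
                                            n_frames = 300,
                                            frame_interval = 5L,
                                            burn_in = 300L,
                                            label = if (charge == 0)
                                              "neutral_probe" else "charged_probe") {
  cfg <- sampler_config(n_waters = n_waters, seed = seed,
                        burn_in = burn_in, n_frames = n_frames,
                        frame_interval = frame_interval)
  sys <- build_droplet(cfg, list(probe_spec(label, charge = charge)))
  run <- mc_sample(sys, cfg)
  rec <- collect_records(run$frames, sys)
  as_rec <- rec$atom_solvent
  fcurve <- bin_profile(as_rec, "f_s_all")
  kcurve <- bin_profile(as_rec, "k_s_all")
  fhat <- integrate_spring_to_force(kcurve)
  res <- hydrophilic_degree(fcurve, fhat)
  list(records = as_rec, fcurve = fcurve, kcurve = kcurve, fhat = fhat,
       result = res, acceptance_rate = run$acceptance_rate)
}
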
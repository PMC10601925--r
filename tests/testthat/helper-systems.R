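# Small systems built in code, plus memoized droplet ensembles shared by the
# slower statistical tests.

protein_atom <- function(label = "probe", charge = 0, eps = 0.1,
                         rmh = 2.0, mass = 12.011, mol = 1L) {
  data.frame(element = "X", type_label = label, charge = charge,
             lj_epsilon = eps, lj_rmin_half = rmh, mass = mass,
             role = "protein", molecule = mol)
}

# two solute atoms at distance r along x
two_atom_system <- function(r, q1 = 0, q2 = 0, eps1 = 0, eps2 = 0,
                            rmh1 = 1, rmh2 = 1) {
  atoms <- rbind(protein_atom("a1", q1, eps1, rmh1, mol = 1L),
                 protein_atom("a2", q2, eps2, rmh2, mol = 2L))
  molecular_system(atoms, rbind(c(0, 0, 0), c(r, 0, 0)))
}

# a single ideal-geometry water at `center` with orientation seed
one_water <- function(center = c(0, 0, 0), seed = 1) {
  cfg <- sampler_config(n_waters = 1, seed = seed, burn_in = 0L,
                        n_frames = 1L)
  sys <- build_droplet(cfg)
  sys$coords <- sys$coords - rep(sys$coords[1, ], each = 3) +
    rep(center, each = 3)
  sys
}

# water dimer at given O-O separation
water_dimer <- function(sep = 2.9, seed = 4) {
  cfg <- sampler_config(n_waters = 2, seed = seed, burn_in = 0L,
                        n_frames = 1L)
  sys <- build_droplet(cfg)
  # move the second water to the requested separation along x
  d <- sys$coords[4, ] - sys$coords[1, ]
  shift <- c(sep, 0, 0) - d
  sys$coords[4:6, ] <- sys$coords[4:6, ] + rep(shift, each = 3)
  sys
}

# droplet with an optional probe, thin wrapper with small defaults
small_droplet <- function(n_waters, seed, probe = NULL) {
  cfg <- sampler_config(n_waters = n_waters, seed = seed, burn_in = 0L,
                        n_frames = 1L)
  build_droplet(cfg, if (is.null(probe)) list() else list(probe))
}

# random solute/water mechanical system (real force field, random geometry)
random_mm_system <- function(n_waters, seed, probe_charge = 0.3) {
  small_droplet(n_waters, seed,
                probe_spec("probe", charge = probe_charge))
}

run_pipeline <- function(sys, policy = nonbonded_policy("untruncated")) {
  pd <- compute_pair_decomposition(sys, policy)
  ex <- compute_expansion(sys, policy)
  part <- classify_atoms(sys)
  blocks <- aggregate_blocks(ex, part, sys$atoms$mass)
  cg <- coarse_grain(blocks)
  cgpf <- antisymmetrize(build_pair_matrices(pd, blocks, part))
  list(pd = pd, ex = ex, part = part, blocks = blocks, cg = cg,
       cgpf = cgpf, ut = unit_table(sys, part))
}

# --- memoized heavy ensembles (shared across test files) ------------------

.cg_test_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.cg_test_cache[[name]]))
    assign(name, fn(), envir = .cg_test_cache)
  .cg_test_cache[[name]]
}

water_study <- function() {
  cached("water", function() solvent_structure_experiment(seed = 1301L))
}

probe_study <- function() {
  cached("probes", function() list(
    neutral = probe_hydrophilicity_experiment(1302L, charge = 0),
    charged = probe_hydrophilicity_experiment(1303L, charge = 0.5)))
}
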
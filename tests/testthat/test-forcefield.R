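# Force-field engine: analytic energies, forces, Hessians, pair terms.

test_that("two neutral LJ atoms at the potential minimum feel no force", {
  eps <- 0.2; rmh <- 1.6
  sys <- two_atom_system(2 * rmh, eps1 = eps, eps2 = eps,
                         rmh1 = rmh, rmh2 = rmh)
  ex <- compute_expansion(sys)
  expect_lt(max(abs(ex$f)), 1e-12)
  expect_equal(ex$V0, -eps, tolerance = 1e-12)
})

test_that("an isolated ideal-geometry water has zero intramolecular force", {
  sys <- one_water(seed = 3)
  ex <- compute_expansion(sys)
  expect_lt(max(abs(ex$f)), 1e-9)
  # bond/angle stiffness present even at equilibrium geometry
  expect_gt(max(abs(ex$H)), 100)
})

test_that("analytic forces and Hessian match finite differences", {
  # a random 5-atom charged LJ cluster
  set.seed(17)
  atoms <- do.call(rbind, lapply(1:5, function(k)
    protein_atom(paste0("t", k), charge = stats::runif(1, -0.5, 0.5),
                 eps = stats::runif(1, 0.05, 0.2),
                 rmh = stats::runif(1, 1.2, 2), mol = k)))
  sys <- molecular_system(atoms, matrix(stats::rnorm(15, sd = 3), 5, 3))
  fd <- finite_difference_check(sys, step = 1e-5)
  scale <- max(abs(fd$expansion$f))
  expect_lt(fd$max_force_dev / scale, 1e-6)
  expect_lt(fd$max_hessian_dev / max(abs(fd$expansion$H)), 1e-6)

  # water dimer (bonds + angles + nonbonded)
  fd2 <- finite_difference_check(water_dimer(2.9), step = 1e-5)
  expect_lt(fd2$max_force_dev, 1e-5)
  expect_lt(fd2$max_hessian_dev, 1e-4)

  # a single atom sees no interactions at all
  sys1 <- molecular_system(protein_atom("lone"), matrix(0, 1, 3))
  fd1 <- finite_difference_check(sys1)
  expect_identical(fd1$max_force_dev, 0)
  expect_identical(fd1$max_hessian_dev, 0)
})

test_that("the switching function is smooth enough for second derivatives", {
  # pair straddling the switching region
  sys <- two_atom_system(4.5, q1 = 0.4, q2 = -0.3, eps1 = 0.1, eps2 = 0.1,
                         rmh1 = 1.5, rmh2 = 1.5)
  pol <- nonbonded_policy("switched", switch_start = 3.5, cutoff = 6)
  fd <- finite_difference_check(sys, pol, step = 1e-5)
  expect_lt(fd$max_force_dev, 1e-5)
  expect_lt(fd$max_hessian_dev, 1e-5)
  # beyond the cutoff everything vanishes
  sysfar <- two_atom_system(7, q1 = 0.4, q2 = -0.3)
  exfar <- compute_expansion(sysfar, pol)
  expect_identical(exfar$V0, 0)
  expect_lt(max(abs(exfar$f)), 1e-15)
})

test_that("Coulomb pair decomposition matches the closed form", {
  q1 <- 1; q2 <- -1; r <- 2
  sys <- two_atom_system(r, q1 = q1, q2 = q2)
  pol <- nonbonded_policy()
  pd <- compute_pair_decomposition(sys, pol)
  expect_equal(nrow(pd$F_elec), 1L)
  fmag <- pol$coulomb_constant * q1 * abs(q2) / r^2
  # attractive: force on atom 1 points toward atom 2 (+x)
  expect_equal(pd$F_elec[1, ], c(fmag, 0, 0), tolerance = 1e-12)
  expect_lt(max(abs(pd$F_vdw)), 1e-15)
  expect_equal(pd$V0, -pol$coulomb_constant / r, tolerance = 1e-12)
})

test_that("excluded 1-2 pairs carry no nonbonded blocks", {
  sys <- one_water(seed = 5)
  pd <- compute_pair_decomposition(sys)
  expect_identical(length(pd$i), 0L)        # all three pairs are 1-2/1-3
  expect_identical(sort(unique(c(pd$bonded$i, pd$bonded$j))), 1:3)
})

test_that("pair forces reassemble the force vector and Hessian blocks", {
  sys <- random_mm_system(4, seed = 21)
  pol <- nonbonded_policy("untruncated")
  pd <- compute_pair_decomposition(sys, pol)
  ex <- compute_expansion(sys, pol)
  expect_lt(max(abs(reassemble_forces(pd) - ex$f)), 1e-9)
  # off-diagonal Hessian blocks agree with the assembled matrix exactly
  for (k in seq_along(pd$i)) {
    i <- pd$i[k]; j <- pd$j[k]
    blk <- matrix(pd$Hb_elec[k, ] + pd$Hb_vdw[k, ], 3, 3)
    expect_identical(blk, ex$H[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])
  }
})

test_that("rigid translation leaves the expansion invariant", {
  sys <- random_mm_system(3, seed = 8)
  ex <- compute_expansion(sys)
  sys2 <- sys
  sys2$coords <- sys$coords + rep(c(5.1, -2.2, 0.7), each = nrow(sys$coords))
  ex2 <- compute_expansion(sys2)
  expect_equal(ex2$V0, ex$V0, tolerance = 1e-10)
  expect_lt(max(abs(ex2$f - ex$f)), 1e-8)
  # Hessian 3-block row sums vanish (no net force under translation)
  n <- nrow(sys$atoms)
  rs <- ex$H %*% kronecker(rep(1, n), diag(3))
  expect_lt(max(abs(rs)), 1e-8)
})

test_that("degenerate and invalid geometries are rejected", {
  sys <- two_atom_system(2, q1 = 0.1, q2 = 0.1)
  sys$coords[2, ] <- sys$coords[1, ]
  expect_error(compute_expansion(sys), "coincident")
  atoms <- protein_atom("a")
  expect_error(molecular_system(atoms, matrix(c(1, Inf, 0), 1, 3)), "finite")
})
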
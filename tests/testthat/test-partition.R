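# Partition / aggregation: index bookkeeping and the exact change of
# variables into (solute, solvent particle, relative hydrogen) coordinates.

test_that("atoms classify into solute and aligned water site lists", {
  sys <- small_droplet(2, seed = 2, probe = probe_spec("p"))
  part <- classify_atoms(sys)
  expect_identical(part$n_p, 1L)
  expect_identical(part$n_s, 2L)
  expect_identical(length(part$h1_idx), 2L)
  # hydrogens aligned per water
  expect_identical(sys$atoms$molecule[part$h1_idx],
                   sys$atoms$molecule[part$o_idx])

  wbox <- small_droplet(3, seed = 9)
  pw <- classify_atoms(wbox)
  expect_identical(pw$n_p, 0L)
  expect_identical(pw$n_s, 3L)
})

test_that("classification is invariant to the input atom order", {
  sys <- small_droplet(3, seed = 13, probe = probe_spec("p"))
  part <- classify_atoms(sys)
  set.seed(1)
  perm <- sample(nrow(sys$atoms))
  sys2 <- sys
  sys2$atoms <- sys$atoms[perm, ]
  sys2$coords <- sys$coords[perm, , drop = FALSE]
  part2 <- classify_atoms(sys2)
  # same physical oxygens, in the same (oxygen-sorted) solvent order up to
  # relabeling: compare coordinates
  expect_equal(sort(sys$coords[part$o_idx, 1]),
               sort(sys2$coords[part2$o_idx, 1]))
  expect_identical(part2$n_p, part$n_p)
  expect_identical(part2$n_s, part$n_s)
})

test_that("missing hydrogens raise a topology error", {
  sys <- small_droplet(1, seed = 2)
  at <- sys$atoms
  at$role[2] <- "water_H2"   # two second-hydrogens, no first
  expect_error(molecular_system(at, sys$coords, sys$bonds, sys$angles),
               "water molecule")
})

test_that("aggregation sums the right blocks and is exactly linear", {
  rq <- random_quadratic_system(31, n_p = 2, n_s = 2)
  part <- rq$part
  # all-zero Hessian aggregates to zero
  z <- aggregate_blocks(list(V0 = 0, f = numeric(3 * 8),
                             H = matrix(0, 24, 24)), part, rq$masses)
  expect_identical(max(abs(z$H_psps)), 0)
  expect_identical(max(abs(z$H_1212)), 0)

  # one water: H_ss equals the brute-force sum of the nine site blocks
  rq1 <- random_quadratic_system(7, n_p = 1, n_s = 1)
  bl <- aggregate_blocks(rq1$expansion, rq1$part, rq1$masses)
  H <- rq1$expansion$H
  idx <- function(a) (3 * (a - 1) + 1):(3 * a)
  S <- matrix(0, 3, 3)
  for (a in c(rq1$part$o_idx, rq1$part$h1_idx, rq1$part$h2_idx))
    for (b in c(rq1$part$o_idx, rq1$part$h1_idx, rq1$part$h2_idx))
      S <- S + H[idx(a), idx(b)]
  expect_equal(bl$H_psps[4:6, 4:6], S, tolerance = 1e-12)
  # solvent force row sums the three site forces
  f <- rq1$expansion$f
  expect_equal(bl$f_ps[4:6],
               f[idx(rq1$part$o_idx)] + f[idx(rq1$part$h1_idx)] +
                 f[idx(rq1$part$h2_idx)], tolerance = 1e-12)

  # linearity
  rqa <- random_quadratic_system(41, 1, 2)
  rqb <- random_quadratic_system(42, 1, 2)
  mix <- list(V0 = 2 * rqa$expansion$V0 - rqb$expansion$V0,
              f = 2 * rqa$expansion$f - rqb$expansion$f,
              H = 2 * rqa$expansion$H - rqb$expansion$H)
  ba <- aggregate_blocks(rqa$expansion, rqa$part, rqa$masses)
  bb <- aggregate_blocks(rqb$expansion, rqa$part, rqa$masses)
  bm <- aggregate_blocks(mix, rqa$part, rqa$masses)
  expect_equal(bm$H_ps12, 2 * ba$H_ps12 - bb$H_ps12, tolerance = 1e-12)
  expect_equal(bm$f_12, 2 * ba$f_12 - bb$f_12, tolerance = 1e-12)
})

test_that("the reduced-variable surface reproduces the original energy", {
  # change-of-variables exactness over 100 random systems/displacements
  worst <- 0
  for (s in 1:100) {
    rq <- random_quadratic_system(1000 + s, n_p = sample(0:3, 1),
                                  n_s = sample(1:4, 1),
                                  definiteness = "indefinite")
    part <- rq$part
    bl <- aggregate_blocks(rq$expansion, part, rq$masses)
    n <- part$n_p + 3 * part$n_s
    dps <- stats::rnorm(3 * (part$n_p + part$n_s))
    d12 <- stats::rnorm(6 * part$n_s)
    full <- numeric(3 * n)
    idx <- function(a) (3 * (a - 1) + 1):(3 * a)
    for (k in seq_len(part$n_p)) full[idx(part$p_idx[k])] <-
        dps[(3 * (k - 1) + 1):(3 * k)]
    for (w in seq_len(part$n_s)) {
      ds <- dps[3 * part$n_p + (3 * (w - 1) + 1):(3 * w)]
      full[idx(part$o_idx[w])] <- ds
      full[idx(part$h1_idx[w])] <- ds + d12[(3 * (w - 1) + 1):(3 * w)]
      full[idx(part$h2_idx[w])] <- ds +
        d12[3 * part$n_s + (3 * (w - 1) + 1):(3 * w)]
    }
    v1 <- eval_surface(rq$expansion$V0, rq$expansion$f, rq$expansion$H, full)
    v2 <- eval_tilde_surface(bl, dps, d12)
    worst <- max(worst, abs(v1 - v2) / max(1, abs(v1)))
  }
  expect_lt(worst, 1e-9)
})

test_that("swapping the two hydrogens of a water leaves the surface alone", {
  sys <- small_droplet(3, seed = 23, probe = probe_spec("p", charge = 0.4))
  res <- run_pipeline(sys)
  sys2 <- sys
  r1 <- which(sys$atoms$role == "water_H1")
  r2 <- which(sys$atoms$role == "water_H2")
  sys2$atoms$role[r1] <- "water_H2"
  sys2$atoms$role[r2] <- "water_H1"
  res2 <- run_pipeline(sys2)
  expect_equal(res2$cg$Hp, res$cg$Hp, tolerance = 1e-10)
  expect_equal(res2$cg$fp, res$cg$fp, tolerance = 1e-10)
  expect_equal(res2$cg$V0p, res$cg$V0p, tolerance = 1e-10)
})
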
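# Pairwise force matrices, antisymmetrization, component decomposition and
# effective scalars.

test_that("uncoupled hydrogens give a purely direct pair matrix", {
  sys <- random_mm_system(3, seed = 31)
  res <- run_pipeline(sys)
  bl <- res$blocks
  bl$H_ps12 <- matrix(0, nrow(bl$H_ps12), ncol(bl$H_ps12))
  cgpf <- antisymmetrize(build_pair_matrices(res$pd, bl, res$part))
  expect_identical(max(abs(cgpf$dF)), 0)
  expect_equal(cgpf$F_antisym, cgpf$F_direct, tolerance = 0)
})

test_that("the indirect entry reproduces the explicit matrix chain", {
  sys <- random_mm_system(1, seed = 32, probe_charge = 0.5)
  res <- run_pipeline(sys)
  # independent dense algebra for the whole indirect matrix
  dpm <- cgdelta:::.direct_pair_matrices(res$pd, res$part)
  ref <- -res$blocks$H_ps12 %*% solve(res$blocks$H_1212) %*% dpm$F12ps
  expect_equal(res$cgpf$dF, ref, tolerance = 1e-10)
  # and the hydrogen-row force matrix columns sum to f_12
  expect_equal(rowSums(dpm$F12ps), res$blocks$f_12, tolerance = 1e-9)
})

test_that("pairwise rows sum back to the coarse-grained force vector", {
  sys <- random_mm_system(4, seed = 33)
  res <- run_pipeline(sys)
  expect_lt(max(abs(pair_row_sums(res$cgpf) - res$cg$fp)), 1e-8)
})

test_that("antisymmetrization matches the literal entrywise formula", {
  sys <- random_mm_system(2, seed = 34)
  res <- run_pipeline(sys)
  cgpf <- res$cgpf
  N <- cgpf$n_p + cgpf$n_s
  for (i in seq_len(N)) for (j in seq_len(N)) {
    bi <- (3 * (i - 1) + 1):(3 * i)
    bj <- (3 * (j - 1) + 1):(3 * j)
    ref <- cgpf$F_direct[bi, j] +
      (cgpf$dF[bi, j] - cgpf$dF[bj, i]) / 2
    expect_equal(cgpf$F_antisym[bi, j], ref, tolerance = 1e-12)
  }
  # exact antisymmetry
  sw <- cgdelta:::.swap_entries
  expect_identical(max(abs(cgpf$F_antisym + sw(cgpf$F_antisym))), 0)
  expect_identical(max(abs(cgpf$F_direct + sw(cgpf$F_direct))), 0)
})

test_that("a symmetric indirect matrix cancels out of the antisymmetrized force", {
  sys <- random_mm_system(2, seed = 35)
  res <- run_pipeline(sys)
  cgpf <- res$cgpf
  sw <- cgdelta:::.swap_entries
  cgpf$dF <- (cgpf$dF + sw(cgpf$dF)) / 2     # force it symmetric
  cgpf <- antisymmetrize(cgpf)
  expect_lt(max(abs(cgpf$F_antisym - cgpf$F_direct)), 1e-12)
})

test_that("generic coupled systems break indirect antisymmetry", {
  sys <- random_mm_system(4, seed = 36, probe_charge = 0.4)
  res <- run_pipeline(sys)
  sw <- cgdelta:::.swap_entries
  expect_gt(max(abs(res$cgpf$dF + sw(res$cgpf$dF))), 1e-6)
})

test_that("the five components sum exactly to the full entries", {
  sys <- random_mm_system(3, seed = 37, probe_charge = 0.6)
  res <- run_pipeline(sys)
  for (b in res$part$n_p + seq_len(res$part$n_s)) {
    de <- decompose_entry(1L, b, res$pd, res$cgpf, res$cg, res$blocks,
                          res$part)
    bi <- 1:3; bj <- (3 * (b - 1) + 1):(3 * b)
    expect_lt(max(abs(de$force$s_all - res$cgpf$F_antisym[bi, b])), 1e-9)
    expect_lt(max(abs(de$spring$s_all - res$cg$Hp[bi, bj])), 1e-9)
  }
  expect_error(decompose_entry(1L, 1L, res$pd, res$cgpf, res$cg,
                               res$blocks, res$part), "index error")
})

test_that("uncharged or epsilon-free probes drop the matching components", {
  sys0 <- random_mm_system(2, seed = 38, probe_charge = 0)
  res0 <- run_pipeline(sys0)
  de <- decompose_entry(1L, res0$part$n_p + 1L, res0$pd, res0$cgpf,
                        res0$cg, res0$blocks, res0$part)
  expect_identical(max(abs(de$force$o_elec)), 0)
  expect_identical(max(abs(de$force$h_elec)), 0)

  sysE <- small_droplet(2, seed = 39,
                        probe = probe_spec("ghost", charge = 0.3,
                                           lj_epsilon = 0))
  resE <- run_pipeline(sysE)
  deE <- decompose_entry(1L, 2L, resE$pd, resE$cgpf, resE$cg, resE$blocks,
                         resE$part)
  expect_identical(max(abs(deE$force$o_vdw)), 0)
  expect_identical(max(abs(deE$force$h_vdw)), 0)
})

test_that("effective scalars follow the repulsion-positive convention", {
  # force along rhat
  es <- effective_scalars(c(2, 0, 0), diag(3) * 5,
                          x_i = c(3, 0, 0), x_j = c(0, 0, 0))
  expect_equal(es$f_ij, 2)
  expect_equal(es$k_ij, 5)   # isotropic spring projects to itself
  expect_error(effective_scalars(c(1, 0, 0), diag(3), c(1, 1, 1),
                                 c(1, 1, 1)), "zero separation")

  # isolated Coulomb pair: f = -dV/dr and k = d f / dr analytically
  C <- nonbonded_policy()$coulomb_constant
  q1 <- 0.8; q2 <- -0.5; r <- 3.2
  sys <- two_atom_system(r, q1 = q1, q2 = q2)
  pd <- compute_pair_decomposition(sys)
  es <- effective_scalars(pd$F_elec[1, ], matrix(pd$Hb_elec[1, ], 3, 3),
                          sys$coords[1, ], sys$coords[2, ])
  expect_equal(es$f_ij, -C * q1 * abs(q2) / r^2, tolerance = 1e-12)
  expect_equal(es$k_ij, 2 * C * q1 * abs(q2) / r^3, tolerance = 1e-12)
})

test_that("record collection matches brute-force pair counting", {
  # two waters far apart: no records
  sys <- small_droplet(2, seed = 40)
  sys$coords[4:6, ] <- sys$coords[4:6, ] +
    rep(c(15, 0, 0) - (sys$coords[4, ] - sys$coords[1, ]), each = 3)
  rec <- collect_records(list(sys$coords), sys, record_cutoff = 12)
  expect_identical(nrow(rec$solvent_solvent), 0L)

  # probe + one water at 3 A: exactly one atom-solvent record
  sysp <- small_droplet(1, seed = 41, probe = probe_spec("p", charge = 0.2))
  sysp$coords[2:4, ] <- sysp$coords[2:4, ] +
    rep(c(3, 0, 0) - sysp$coords[2, ], each = 3)
  recp <- collect_records(list(sysp$coords), sysp)
  expect_identical(nrow(recp$atom_solvent), 1L)
  expect_equal(recp$atom_solvent$r, 3, tolerance = 1e-12)

  # droplet over several frames: counts equal a brute-force scan
  cfg <- sampler_config(n_waters = 12, seed = 42, burn_in = 5L,
                        n_frames = 5L, frame_interval = 2L)
  sysd <- build_droplet(cfg, list(probe_spec("p", charge = 0.2)))
  run <- mc_sample(sysd, cfg)
  cutoff <- 6
  rec <- collect_records(run$frames, sysd, record_cutoff = cutoff)
  o <- which(sysd$atoms$role == "water_O")
  n_as <- 0L; n_ss <- 0L
  for (f in run$frames) {
    d_po <- sqrt(colSums((t(f[o, ]) - f[1, ])^2))
    n_as <- n_as + sum(d_po <= cutoff)
    doo <- as.matrix(stats::dist(f[o, ]))
    n_ss <- n_ss + sum(doo[upper.tri(doo)] <= cutoff)
  }
  expect_identical(nrow(rec$atom_solvent), n_as)
  expect_identical(nrow(rec$solvent_solvent), n_ss)
  expect_error(collect_records(list(), sysd), "empty ensemble")
})

test_that("spring projections are symmetric in the pair order", {
  sys <- random_mm_system(3, seed = 44, probe_charge = 0.3)
  res <- run_pipeline(sys)
  fr <- analyze_frame(sys)
  ss <- fr$solvent_solvent
  for (k in seq_len(min(nrow(ss), 5))) {
    i <- ss$i[k]; j <- ss$j[k]
    bi <- (3 * (i - 1) + 1):(3 * i); bj <- (3 * (j - 1) + 1):(3 * j)
    kij <- effective_scalars(numeric(3), res$cg$Hp[bi, bj],
                             res$ut$positions[i, ], res$ut$positions[j, ])$k_ij
    kji <- effective_scalars(numeric(3), res$cg$Hp[bj, bi],
                             res$ut$positions[j, ], res$ut$positions[i, ])$k_ij
    expect_equal(kij, kji, tolerance = 1e-10)
  }
})
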
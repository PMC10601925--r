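# The reduction itself: stationary hydrogen response, Schur-complement
# surface, degenerate handling.

test_that("the hydrogen response is stationary (and zero at the origin)", {
  rq <- random_quadratic_system(51, 1, 2)
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  bl0 <- bl
  bl0$f_12 <- numeric(length(bl$f_12))
  d0 <- hydrogen_response(bl0, numeric(length(bl$f_ps)))
  expect_lt(max(abs(d0)), 1e-12)

  dps <- stats::rnorm(length(bl$f_ps))
  d12 <- hydrogen_response(bl, dps)
  # gradient of the reduced-variable surface wrt Delta_12 vanishes
  grad <- -bl$f_12 + drop(crossprod(bl$H_ps12, dps)) + drop(bl$H_1212 %*% d12)
  expect_lt(max(abs(grad)), 1e-8)
})

test_that("the response matches a dense numerical minimizer", {
  rq <- random_quadratic_system(52, 1, 2)      # PD => stationary = argmin
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  dps <- stats::rnorm(length(bl$f_ps), sd = 0.5)
  d12 <- hydrogen_response(bl, dps)
  obj <- function(z) eval_tilde_surface(bl, dps, z)
  grd <- function(z) -bl$f_12 + drop(crossprod(bl$H_ps12, dps)) +
    drop(bl$H_1212 %*% z)
  opt <- stats::optim(numeric(length(d12)), obj, grd, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(d12 - opt$par)), 1e-6)
})

test_that("hydrogen masses do not affect the invertible-case response", {
  rq <- random_quadratic_system(53, 1, 3)
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  dps <- stats::rnorm(length(bl$f_ps))
  d12 <- hydrogen_response(bl, dps)
  bl2 <- bl
  bl2$M12 <- bl$M12 * 7.3
  expect_equal(hydrogen_response(bl2, dps), d12, tolerance = 1e-12)
})

test_that("decoupled hydrogen blocks leave the solute surface untouched", {
  rq <- random_quadratic_system(54, 2, 2)
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  bl$H_ps12 <- matrix(0, nrow(bl$H_ps12), ncol(bl$H_ps12))
  cg <- coarse_grain(bl)
  expect_equal(cg$fp, bl$f_ps, tolerance = 0)
  expect_equal(cg$Hp, (bl$H_psps + t(bl$H_psps)) / 2, tolerance = 0)
  # constant shift depends only on f_12 and H_1212
  a <- solve(bl$H_1212, bl$f_12)
  expect_equal(cg$V0p, bl$V0 - 0.5 * sum(bl$f_12 * a), tolerance = 1e-10)
})

test_that("with zero force the reduction is the textbook Schur complement", {
  rq <- random_quadratic_system(55, 2, 3)
  ex <- rq$expansion
  ex$f <- numeric(length(ex$f))
  bl <- aggregate_blocks(ex, rq$part, rq$masses)
  cg <- coarse_grain(bl)
  expect_lt(max(abs(cg$fp)), 1e-12)
  # independent textbook formula, written out literally
  A <- bl$H_psps; B <- bl$H_ps12; D <- bl$H_1212
  schur <- A - B %*% solve(D) %*% t(B)
  expect_equal(cg$Hp, (schur + t(schur)) / 2, tolerance = 1e-9)
})

test_that("the coarse surface equals the full surface at the response", {
  for (s in 1:5) {
    rq <- random_quadratic_system(60 + s, 1, 2)
    bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
    cg <- coarse_grain(bl)
    for (k in 1:50) {
      dps <- stats::rnorm(length(bl$f_ps), sd = 0.7)
      v1 <- eval_cg_surface(cg, dps)
      v2 <- eval_tilde_surface(bl, dps, hydrogen_response(bl, dps))
      expect_lt(abs(v1 - v2) / max(1, abs(v1)), 1e-8)
    }
  }
})

test_that("positive-definite input yields a positive-definite reduction", {
  rq <- random_quadratic_system(71, 2, 3)      # PD generator
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  cg <- coarse_grain(bl)
  expect_gt(min(eigen(cg$Hp, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("an identically singular hydrogen block is reported", {
  rq <- random_quadratic_system(72, 1, 1)
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  bl$H_1212 <- matrix(0, nrow(bl$H_1212), ncol(bl$H_1212))
  expect_error(coarse_grain(bl), "degenerate")
})

test_that("a rank-deficient hydrogen block falls back to the pseudo-inverse", {
  rq <- random_quadratic_system(73, 1, 2)
  bl <- aggregate_blocks(rq$expansion, rq$part, rq$masses)
  # collapse one direction: make the last row/col dependent
  n <- nrow(bl$H_1212)
  bl$H_1212[n, ] <- bl$H_1212[n - 1, ]
  bl$H_1212[, n] <- bl$H_1212[, n - 1]
  bl$f_12[n] <- bl$f_12[n - 1]   # consistent right-hand side
  cg <- coarse_grain(bl)
  expect_true(cg$solve_report$pseudo_inverse)
  expect_gt(cg$solve_report$dropped, 0)
})
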
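test_that("modulation weights: identity at lambda = 0, closed form, normalization", {
  m <- two_state_meta()
  expect_equal(modulation_weights(m, 0), frame_probs(m))
  expect_equal(modulation_weights(m, log(3)), c(0.75, 0.25), tolerance = 1e-12)
  for (lam in c(-700, -5, 0.3, 100, 700)) {
    w <- modulation_weights(m, lam)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(is.finite(w)))
  }
})

test_that("constrained averages recover plain means and the two-state value", {
  m <- two_state_meta()
  expect_equal(constrained_average(m, 0, "B"), 5)
  expect_equal(constrained_average(m, log(3), "B"), 2.5, tolerance = 1e-12)
  expect_error(constrained_average(m, 0, "nope"), "unknown observable")
  # the CV at the solved lambda returns the target
  big <- random_meta(500, seed = 2)
  for (s in c(3, 8, 13)) {
    sol <- solve_lambda(big, s)
    expect_equal(constrained_average(big, sol$lam, "cv"), s, tolerance = 1e-6)
  }
})

test_that("lambda solver reproduces closed forms and flags impossible targets", {
  m <- two_state_meta()
  expect_equal(solve_lambda(m, 0.5)$lam, 0, tolerance = 1e-8)
  sol <- solve_lambda(m, 0.25)
  expect_equal(sol$lam, log(3), tolerance = 1e-8)
  expect_equal(sol$entropy, log(2 / 3) + 0.25 * log(3), tolerance = 1e-8)
  expect_true(sol$converged)
  expect_lte(sol$entropy, 1e-10)

  unif <- meta_ensemble(data.frame(cv = 0:16))
  expect_equal(solve_lambda(unif, 8)$lam, 0, tolerance = 1e-8)

  expect_error(solve_lambda(m, 1.5), "unreachable")
  expect_error(solve_lambda(m, 0), "unreachable")
  flat <- meta_ensemble(data.frame(cv = rep(2, 5)))
  expect_error(solve_lambda(flat, 2), "unreachable|degenerate")
})

test_that("cross-entropy is -KL: zero at the metastatistics mean, else negative,
           with dSc/ds = lambda", {
  m <- random_meta(400, seed = 9)
  mean_cv <- sum(frame_probs(m) * m$frames$cv)
  sol0 <- solve_lambda(m, mean_cv)
  expect_equal(sol0$lam, 0, tolerance = 1e-6)
  expect_equal(sol0$entropy, 0, tolerance = 1e-8)
  sgrid <- seq(2, 15, by = 0.05)
  sols <- lapply(sgrid, function(s) solve_lambda(m, s))
  Sc <- vapply(sols, `[[`, numeric(1), "entropy")
  lam <- vapply(sols, `[[`, numeric(1), "lam")
  expect_true(all(Sc <= 1e-10))
  expect_true(all(diff(lam) < 0))         # lambda(s) strictly decreasing
  # thermodynamic identity on the interior of the grid
  dSc <- (Sc[-(1:2)] - Sc[1:(length(Sc) - 2)]) / (sgrid[3] - sgrid[1])
  expect_equal(dSc, lam[-c(1, length(lam))], tolerance = 1e-3)
})

test_that("small ensembles match direct enumeration to 1e-12", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:20, 1)
    m <- meta_ensemble(data.frame(cv = runif(n, 0, 16), B = rnorm(n)),
                       weights = sample(1:4, n, replace = TRUE))
    s <- runif(1, min(m$frames$cv) + 0.05 * diff(range(m$frames$cv)),
               max(m$frames$cv) - 0.05 * diff(range(m$frames$cv)))
    sol <- solve_lambda(m, s)
    oracle <- maxent_enum(m, sol$lam)
    expect_equal(sol$entropy, oracle$Sc, tolerance = 1e-12)
    expect_equal(constrained_average(m, sol$lam, "B"), oracle$avg(m$frames$B),
                 tolerance = 1e-12)
    expect_equal(modulation_weights(m, sol$lam), oracle$P, tolerance = 1e-12)
  }
})

test_that("tilted ensembles are recovered when constrained back to the base mean", {
  # draw from exp(-lam0 * xi) tilt of a uniform grid, constrain to the
  # untilted mean: the solver should undo the tilt
  set.seed(4)
  xi_levels <- seq(0, 16, by = 0.25)
  lam0 <- 0.3
  p_tilt <- exp(-lam0 * xi_levels); p_tilt <- p_tilt / sum(p_tilt)
  draw <- sample(xi_levels, 1e5, replace = TRUE, prob = p_tilt)
  m <- meta_ensemble(data.frame(cv = draw))
  sol <- solve_lambda(m, mean(xi_levels))
  expect_equal(sol$lam, -lam0, tolerance = 0.02)
})

test_that("lambda error propagates through the constrained variance", {
  m <- two_state_meta()
  sol <- solve_lambda(m, 0.5)           # p = 1/2, Var = 1/4
  expect_equal(lambda_error(m, sol, 0.01), 0.04, tolerance = 1e-8)
  expect_equal(lambda_error(m, sol, 0), 0)
  sol$converged <- FALSE
  expect_error(lambda_error(m, sol, 0.01), "converged")
})

test_that("free-energy profiles honour the reference convention and the entropy bound", {
  m <- random_meta(300, seed = 5)
  cfg <- run_config(cv_grid = c(4, 8, 12, 14), reference_s = 14)
  m$frames$H0 <- rep(0, nrow(m$frames))
  m <- meta_ensemble(m$frames, weights = m$weights)
  prof <- free_energy_profile(m, cfg, "H0")
  expect_equal(prof$grid$F[prof$grid$s == 14], 0)
  # H = 0: before the reference shift F = -T kB Sc >= 0 (Sc <= 0 everywhere)
  expect_true(all(prof$grid$Sc <= 1e-10))
  expect_equal(prof$grid$F,
               -300 * 0.0019872041 * (prof$grid$Sc - prof$grid$Sc[prof$grid$s == 14]),
               tolerance = 1e-10)
  expect_true(all(diff(prof$grid$s) > 0))
  cfg_bad <- run_config(cv_grid = c(4, 40), reference_s = 14)
  expect_error(free_energy_profile(m, cfg_bad, "H0"), "unreachable")
})

test_that("profiles match a brute-force oracle on enumerable ensembles", {
  set.seed(8)
  n <- 12
  m <- meta_ensemble(data.frame(cv = seq(1, 16, length.out = n), H = rnorm(n, 5)),
                     weights = c(1, 2, 1, 3, 1, 1, 2, 1, 1, 4, 1, 1))
  cfg <- run_config(temperature = 300, cv_grid = c(4, 8, 14), reference_s = 14)
  prof <- free_energy_profile(m, cfg, "H")
  brute <- vapply(cfg$cv_grid, function(s) {
    sol <- solve_lambda(m, s)
    o <- maxent_enum(m, sol$lam)
    o$avg(m$frames$H) - 300 * 0.0019872041 * o$Sc
  }, numeric(1))
  brute <- brute - brute[3]
  expect_equal(prof$grid$F, brute, tolerance = 1e-10)
})

test_that("block errors vanish for constants and scale like sqrt(block size)", {
  m <- random_meta(5000, seed = 6)
  m$frames$const <- rep(2.5, 5000)
  m <- meta_ensemble(m$frames, weights = m$weights)
  sch <- blocking_scheme(n_blocks = 10, block_size = 400, stride = 10)
  expect_equal(block_error(m, sch, 0.1, "const"), 0, tolerance = 1e-12)

  set.seed(10)
  w <- meta_ensemble(data.frame(cv = rnorm(80000), B = rnorm(80000)))
  e1 <- block_error(w, blocking_scheme(10, 8000, 10), 0, "B")
  e2 <- block_error(w, blocking_scheme(20, 4000, 20), 0, "B")
  expect_equal(e2 / e1, sqrt(2), tolerance = 0.35)
  expect_error(block_error(w, blocking_scheme(100, 9000, 100), 0, "B"),
               "too short")
  expect_error(blocking_scheme(n_blocks = 200, stride = 100), "stride")
})

test_that("energy-component differences are linear and match hand sums", {
  m <- meta_ensemble(data.frame(cv = c(2, 12), U_el = c(-100, -40),
                                U_vdw = c(-30, -20), H = c(-130, -60)))
  cfg <- run_config(cv_grid = c(4, 10), reference_s = 10)
  d <- component_differences(m, cfg, s_hi = 10, s_lo = 4,
                             components = c("U_el", "U_vdw", "H"))
  # linearity: the H difference equals the sum of its parts
  expect_equal(d$delta[d$component == "H"],
               sum(d$delta[d$component != "H"]), tolerance = 1e-10)
  # hand enumeration at the two solved tilts
  sol_lo <- solve_lambda(m, 4); sol_hi <- solve_lambda(m, 10)
  o_lo <- maxent_enum(m, sol_lo$lam); o_hi <- maxent_enum(m, sol_hi$lam)
  expect_equal(d$delta[d$component == "U_el"],
               o_lo$avg(m$frames$U_el) - o_hi$avg(m$frames$U_el),
               tolerance = 1e-10)
  z <- component_differences(m, cfg, s_hi = 6, s_lo = 6, components = "U_el")
  expect_equal(z$delta, 0)
  expect_error(component_differences(m, cfg, components = "missing"), "missing")
  # second-level difference against a reference ensemble
  dd <- component_differences(m, cfg, s_hi = 10, s_lo = 4,
                              components = "U_el", reference = m)
  expect_equal(dd$delta_delta, 0, tolerance = 1e-12)
})
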
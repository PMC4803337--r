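test_that("identical regressors collapse SUR to per-equation OLS", {
  tr <- make_trees(30, seed = 41)
  sys <- sur_spec("M2", "M2", "M2", "M2")
  sf <- fit_sur(tr, sys)
  for (cm in components()) {
    ols <- fit_allom(tr, cm, "M2")
    expect_equal(coef(sf)[[cm]], coef(ols), tolerance = 1e-8)
  }
  expect_true(sf$converged)
})

test_that("a diagonal working covariance reproduces per-equation OLS", {
  tr <- make_trees(40, seed = 42)
  sys <- sur_spec("M1", "M4", "M3", "M2")
  sf <- fit_sur(tr, sys, sigma_structure = "diagonal")
  for (cm in components()) {
    ols <- fit_allom(tr, cm, sys[[cm]]$id)
    expect_equal(coef(sf)[[cm]], coef(ols), tolerance = 1e-8)
  }
})

test_that("iterated FGLS matches the dense stacked-GLS oracle", {
  for (seed in c(7, 8)) {
    tr <- make_trees(50, seed = seed)
    sys <- sur_spec("M1", "M4", "M3", "M2")
    ds <- lapply(components(), function(cm) {
      build_design(sys[[cm]], tr, cm)
    })
    oracle <- stacked_gls_oracle(lapply(ds, `[[`, "X"),
                                 lapply(ds, `[[`, "y"))
    sf <- fit_sur(tr, sys)
    expect_equal(unname(unlist(coef(sf))), unname(oracle), tolerance = 1e-8)
  }
})

test_that("SUR recovers generating coefficients within 3 standard errors", {
  cfg <- synthetic_config(sigma_log = 0.15, rho = 0.5)
  cfg$groups <- cfg$groups["young"]
  cfg$groups$young$n <- 300L
  trees <- simulate_trees(cfg, seed = 71)
  sys <- do.call(sur_spec,
                 lapply(cfg$groups$young$beta[components()], `[[`, "spec"))
  sf <- fit_sur(trees, sys)
  expect_true(sf$converged)
  for (cm in components()) {
    truth <- cfg$groups$young$beta[[cm]]$beta
    est <- coef(sf)[[cm]]
    se <- sqrt(diag(sf$vcov[[cm]]))
    expect_true(all(abs(est - truth) < 3 * se),
                info = sprintf("component %s", cm))
  }
})

test_that("additive total prediction is the exact component sum", {
  cfg <- synthetic_config()
  cfg$groups <- cfg$groups["mature"]
  cfg$groups$mature$n <- 1000L
  trees <- simulate_trees(cfg, seed = 13)
  sys <- sur_spec("M1", "M4", "M1", "M3")
  sf <- fit_sur(trees, sys)
  comp <- predict_components(sf, trees)
  tot <- predict_total(sf, trees)
  expect_true(all(comp > 0))
  expect_lt(max(abs(tot - rowSums(comp)) / tot), 1e-12)
  expect_equal(predict(sf, type = "total"), tot)
  expect_equal(predict(sf, type = "both")[, "total"], tot)

  # exact-fit limit: noise-free truth is reproduced with CF = 1
  nf <- make_noisefree_trees(25, seed = 6)
  sys_nf <- sur_spec("M2", "M3", "M3", "M5")
  sf_nf <- fit_sur(nf, sys_nf)
  expect_equal(unname(sf_nf$cf), rep(1, 4), tolerance = 1e-10)
  expect_equal(predict_total(sf_nf), total_biomass(nf), tolerance = 1e-8)
})

test_that("estimation is invariant to relabelling the equations", {
  tr <- make_trees(35, seed = 44)
  sys <- sur_spec(trunk = "M1", branch = "M4", leaf = "M3", root = "M2")
  sf <- fit_sur(tr, sys)
  # swap the trunk and root series and their specs: each equation sees the
  # same data, so the coefficients must move with the labels
  tr2 <- tr
  tr2$w_trunk_kg <- tr$w_root_kg
  tr2$w_root_kg <- tr$w_trunk_kg
  sys2 <- sur_spec(trunk = "M2", branch = "M4", leaf = "M3", root = "M1")
  sf2 <- fit_sur(tr2, sys2)
  expect_equal(coef(sf2)$trunk, coef(sf)$root, tolerance = 1e-10)
  expect_equal(coef(sf2)$root, coef(sf)$trunk, tolerance = 1e-10)
  expect_equal(coef(sf2)$branch, coef(sf)$branch, tolerance = 1e-10)
})

test_that("joint estimation is at least as efficient as OLS", {
  # four equations with differing regressor sets and strongly correlated
  # errors; empirical sampling SDs over replicates
  cfg <- synthetic_config(sigma_log = 0.15, rho = 0.8)
  cfg$groups <- cfg$groups["young"]
  cfg$groups$young$n <- 50L
  # decouple H and CR from D so the regressor sets genuinely differ
  cfg$groups$young$H_link <- c(intercept = log(12), slope = 0, sd = 0.5)
  cfg$groups$young$CR_link <- c(intercept = log(3), slope = 0, sd = 0.5)
  cfg$groups$young$beta <- list(
    trunk  = list(spec = "M1", beta = c(-2.0, 2.4)),
    branch = list(spec = "M2", beta = c(-3.0, 1.8, 0.7)),
    leaf   = list(spec = "M3", beta = c(-2.2, 1.2, 0.8)),
    root   = list(spec = "M4", beta = c(-3.5, 0.8))
  )
  sys <- sur_spec("M1", "M2", "M3", "M4")
  nrep <- 300
  sur_est <- vector("list", nrep)
  ols_est <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    trees <- simulate_trees(cfg, seed = 1000 + r)
    sf <- fit_sur(trees, sys)
    sur_est[[r]] <- unlist(coef(sf))
    ols_est[[r]] <- unlist(lapply(components(), function(cm) {
      coef(fit_allom(trees, cm, sys[[cm]]$id))
    }))
  }
  sd_sur <- apply(do.call(rbind, sur_est), 2, sd)
  sd_ols <- apply(do.call(rbind, ols_est), 2, sd)
  expect_true(all(sd_sur <= sd_ols),
              info = paste(round(sd_sur / sd_ols, 3), collapse = " "))
})

test_that("cross-equation residual correlations are recovered", {
  cfg <- synthetic_config(sigma_log = 0.15, rho = 0.9)
  cfg$groups <- cfg$groups["young"]
  cfg$groups$young$n <- 5000L
  trees <- simulate_trees(cfg, seed = 91)
  sys <- do.call(sur_spec,
                 lapply(cfg$groups$young$beta[components()], `[[`, "spec"))
  sf <- fit_sur(trees, sys)
  R <- residual_cross_correlation(sf)
  expect_equal(unname(diag(R)), rep(1, 4))
  se <- (1 - 0.9^2) / sqrt(5000)
  expect_true(all(abs(R[upper.tri(R)] - 0.9) < 3 * se))

  cfg0 <- synthetic_config(sigma_log = 0.15, rho = 0)
  cfg0$groups <- cfg$groups
  trees0 <- simulate_trees(cfg0, seed = 92)
  R0 <- residual_cross_correlation(fit_sur(trees0, sys))
  expect_true(all(abs(R0[upper.tri(R0)]) < 3 / sqrt(5000)))
})

test_that("non-convergence is reported, not hidden", {
  tr <- make_trees(25, seed = 55)
  sys <- sur_spec("M1", "M4", "M3", "M2")
  expect_warning(sf <- fit_sur(tr, sys, tol = 1e-14, max_iter = 1),
                 "did not converge")
  expect_false(sf$converged)
  expect_equal(sf$iterations, 1L)
})
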
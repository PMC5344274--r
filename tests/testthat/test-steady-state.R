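test_that("the analytic tumor branch matches the hand-derived fixed point", {
  ss <- steady_states(emt_params())
  expect_equal(ss$tumor$M_star, FIXED_POINT[["M"]], tolerance = 1e-9)
  expect_equal(ss$tumor$E_star, FIXED_POINT[["E"]], tolerance = 1e-9)
  expect_true(ss$tumor$admissible)
  expect_true(ss$tumor$stable)
  expect_equal(ss$tumor_free$M_star, 0)
  expect_equal(ss$tumor_free$E_star, 0)
  expect_false(ss$tumor_free$stable)
})

test_that("the equilibrium M:E ratio is beta4/alpha3 and rhs vanishes there", {
  set.seed(21)
  for (rep in 1:10) {
    p <- emt_params(alpha3 = runif(1, 0.005, 0.1),
                    beta3 = runif(1, 0.3, 0.6),
                    beta4 = runif(1, 1e-4, 0.01))
    ss <- steady_states(p)$tumor
    expect_equal(ss$M_star / ss$E_star, p[["beta4"]] / p[["alpha3"]],
                 tolerance = 1e-12)
    if (ss$admissible) {
      rhs <- model_rhs(c(M = ss$M_star, E = ss$E_star), p)
      expect_lt(max(abs(rhs)),
                1e-9 * (1 + abs(ss$M_star) + abs(ss$E_star)))
    }
  }
})

test_that("raising epithelial death beyond the threshold loses the tumor branch", {
  ss <- steady_states(emt_params(beta3 = 0.7))
  expect_false(ss$tumor$admissible)
  expect_true(ss$tumor$M_star < 0 || ss$tumor$E_star < 0)
  expect_true(ss$tumor_free$stable)
})

test_that("tumor branch is undefined without mesenchymal death", {
  ss <- steady_states(emt_params(alpha3 = 0))
  expect_false(ss$tumor$admissible)
  expect_true(is.na(ss$tumor$M_star))
})

test_that("beta_star gives the transcritical threshold", {
  expect_equal(beta_star(emt_params()), BETA_STAR_BASELINE, tolerance = 1e-12)
  # without EMT the threshold is the net epithelial growth beta1 - beta2
  expect_equal(beta_star(emt_params(beta4 = 0)), 0.87 - 0.25)
  expect_error(beta_star(emt_params(alpha3 = 0)), "alpha3")
  # the 33%-raised treatment death rate stays below the threshold:
  # treatment alone cannot eradicate the tumor
  expect_lt(0.4 * 1.33, beta_star(emt_params()))
  ss <- steady_states(emt_params(beta3 = 0.532))
  expect_true(ss$tumor$admissible && ss$tumor$stable)
})

test_that("stability classification flags non-fixed points", {
  expect_warning(res <- classify_stability(c(M = 5, E = 5), emt_params()),
                 "not a fixed point")
  expect_false(res$at_fixed_point)
  expect_silent(classify_stability(c(M = 0, E = 0), emt_params()))
})

test_that("branch stability exchanges exactly once, at beta_star", {
  scan <- bifurcation_scan(emt_params(), c(0.3, 0.8), n = 201)
  expect_true(scan$crossed)
  expect_equal(scan$beta_star, BETA_STAR_BASELINE, tolerance = 1e-12)
  br <- scan$branches
  # at the bifurcation point itself the branches coincide and the leading
  # eigenvalue is zero: neither branch is asymptotically stable there
  off <- abs(br$beta3 - scan$beta_star) > 1e-9
  below <- br$beta3 < scan$beta_star & off
  above <- br$beta3 > scan$beta_star & off
  expect_true(all(br$tumor_stable[below] & !br$free_stable[below]))
  expect_true(all(!br$tumor_stable[above] & br$free_stable[above]))
  # admissibility of the tumor branch is lost past the threshold
  expect_true(all(br$tumor_admissible == below |
                    abs(br$beta3 - scan$beta_star) < 1e-9))
  expect_warning(out <- bifurcation_scan(emt_params(), c(0.3, 0.5), n = 11),
                 "does not span")
  expect_false(out$crossed)
})

test_that("trajectories converge to the stable branch on both sides", {
  scan <- bifurcation_scan(emt_params(), c(0.6, 0.7), n = 5,
                           verify_dynamics = TRUE, t_end = 3000)
  v <- scan$verification
  att <- vapply(v, `[[`, character(1), "attractor")
  b3 <- vapply(v, `[[`, numeric(1), "beta3")
  expect_true(all(att[b3 < BETA_STAR_BASELINE] == "tumor"))
  expect_true(all(att[b3 > BETA_STAR_BASELINE] == "tumor_free"))
  # below threshold, both small and large inocula land on the same branch
  tum <- v[b3 < BETA_STAR_BASELINE]
  finals <- t(vapply(tum, `[[`, numeric(2), "final"))
  expect_equal(finals[1, ], finals[2, ], tolerance = 1e-3)
})

test_that("EMT rate dominates the sensitivity ranking for both schemes", {
  for (scheme in c("forward", "central")) {
    rep <- sensitivity_scan(emt_params(), fraction = 0.05, t_eval = 500,
                            scheme = scheme)
    expect_true(is.logical(attr(rep, "converged")))
    ranked <- rep$parameter[order(rep$rank)]
    expect_identical(ranked[1], "beta4")
    expect_identical(ranked[2], "alpha1")
  }
  # the strict steady-state flag (|rhs| < 1e-6 (1 + |x|)) trips at longer
  # horizons once the residual decays fully
  long <- sensitivity_scan(emt_params(), fraction = 0.05, t_eval = 1000,
                           params = "beta4")
  expect_true(attr(long, "converged"))
})

test_that("small-fraction sensitivity approaches the analytic derivative", {
  # central-difference oracle on the closed-form equilibrium expression;
  # restricted to beta parameters (the closed form fixes alpha1 = alpha2)
  p <- emt_params()
  analytic <- function(nm, h = 1e-7) {
    f <- function(v) {
      q <- unclass(p); q[nm] <- v
      steady_states(as_emt_params(q))$tumor$M_star
    }
    v <- p[[nm]]
    (f(v * (1 + h)) - f(v * (1 - h))) / (2 * h * v)
  }
  rep <- sensitivity_scan(p, fraction = 1e-3, scheme = "central",
                          params = c("beta1", "beta3", "beta4"))
  for (nm in c("beta1", "beta3", "beta4")) {
    fd <- rep$coefficient[rep$parameter == nm]
    expect_equal(fd, analytic(nm), tolerance = 0.01)
  }
})

test_that("zero-valued parameters have undefined relative sensitivity", {
  rep <- sensitivity_scan(emt_params(beta4 = 0), fraction = 0.05,
                          t_eval = 50, params = c("beta1", "beta4"))
  expect_true(is.na(rep$coefficient[rep$parameter == "beta4"]))
  expect_false(is.na(rep$coefficient[rep$parameter == "beta1"]))
})

test_that("death-rate sweep maps inadmissible cells to tumor-free zero", {
  p <- emt_params()
  sw <- sweep_death_rates(p, alpha3_grid = c(0.02, 0.021),
                          beta3_grid = c(0.4, 0.401, 0.7))
  expect_equal(sw$delta_E[1, 1], 0)                  # baseline cell
  expect_equal(dim(sw$E_star), c(2, 3))
  # beta3 = 0.7 exceeds beta_star at every alpha3 in the grid -> eradicated
  expect_true(all(sw$E_star[, 3] == 0))
  # equal absolute increments: M death moves the steady state more than
  # E death (about 1.8 vs 0.9 cells per 0.001)
  h <- 0.001
  sw2 <- sweep_death_rates(p, alpha3_grid = c(0.02, 0.02 + h),
                           beta3_grid = c(0.4, 0.4 + h))
  dE_alpha <- abs(sw2$E_star[2, 1] - sw2$E_star[1, 1])
  dE_beta <- abs(sw2$E_star[1, 2] - sw2$E_star[1, 1])
  expect_gt(dE_alpha, dE_beta)
  expect_equal(dE_alpha, 1.8, tolerance = 0.1)
  expect_equal(dE_beta, 0.9, tolerance = 0.1)
})

test_that("empty sweep grids return an empty result", {
  sw <- sweep_death_rates(emt_params(), numeric(0), numeric(0))
  expect_equal(dim(sw$E_star), c(0, 0))
})
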
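test_that("the marginal covariance has the stated block structure", {
  v <- c(1, 2, 3)
  exps <- c("A", "A", "B")
  yrs <- c(3, 5, 4)
  # all components zero: the fixed-effect limit
  expect_equal(marginal_covariance(v, exps, yrs), diag(v))
  # CAR off-diagonal: tau2 * rho^|dyear| within experiment
  V <- marginal_covariance(v, exps, yrs, tau2_car = 1, rho_car = 0.5)
  expect_equal(V[1, 2], 0.25)
  expect_equal(V[1, 3], 0)   # different experiments
  expect_equal(diag(V), v + 1)
  # experiment intercept fills the block, dataset intercept the diagonal
  V2 <- marginal_covariance(v, exps, yrs, sigma2_exp = 0.3,
                            sigma2_dataset = 0.2)
  expect_equal(V2[1, 2], 0.3)
  expect_equal(diag(V2), v + 0.5)
  expect_true(isSymmetric(V2))
  expect_true(all(eigen(V2, only.values = TRUE)$values > 0))
})

test_that("the restricted log-likelihood matches its closed form and is permutation invariant", {
  # k = 3, intercept-only, unit variances, zero effects:
  # -1/2 [2 log 2pi + log 3]
  ll <- reml_loglik(c(0, 0, 0), matrix(1, 3, 1), c(1, 1, 1),
                    c("A", "B", "C"), c(1, 2, 3))
  expect_equal(ll, -0.5 * (2 * log(2 * pi) + log(3)), tolerance = 1e-12)
  expect_equal(ll, -2.38718, tolerance = 1e-5)

  inst <- random_instance(101)
  perm <- sample(inst$k)
  ll1 <- do.call(reml_loglik, c(list(inst$y, inst$X, inst$v,
                                     inst$experiment, inst$year),
                                inst$theta))
  ll2 <- do.call(reml_loglik, c(list(inst$y[perm],
                                     inst$X[perm, , drop = FALSE],
                                     inst$v[perm], inst$experiment[perm],
                                     inst$year[perm]),
                                inst$theta))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("block-wise REML agrees with the dense contrast oracle and metafor", {
  for (s in 1:20) {
    inst <- random_instance(s, p = if (s %% 3 == 0) 2L else 1L)
    V <- do.call(marginal_covariance,
                 c(list(inst$v, inst$experiment, inst$year), inst$theta))
    ll_engine <- do.call(reml_loglik, c(list(inst$y, inst$X, inst$v,
                                             inst$experiment, inst$year),
                                        inst$theta))
    expect_equal(ll_engine, oracle_reml(inst$y, inst$X, V),
                 tolerance = 1e-9)
  }
  skip_if_not_installed("metafor")
  # metafor reports the contrast-form REML likelihood, which differs from
  # the |X'V^-1X| form by the constant  1/2 log|X'X|
  es <- sim_effects(k = 30, n_exp = 10, tau2_car = 0.05, rho_car = 0.6,
                    seed = 8)
  es$dataset <- paste(es$experiment_id, es$year)
  fit <- meta_fit(es)
  mf <- suppressWarnings(metafor::rma.mv(
    estimate, variance,
    random = list(~ 1 | experiment_id / dataset, ~ year | experiment_id),
    struct = "CAR", data = es, method = "REML"))
  expect_equal(unname(fit$beta), unname(coef(mf)), tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(mf$se), tolerance = 1e-3)
  expect_equal(fit$loglik + 0.5 * log(fit$k),
               as.numeric(logLik(mf)), tolerance = 1e-4)
})

test_that("pinning variance components recovers closed-form weighted estimators", {
  # inverse-variance mean: v = {1,2,4}, y = {1,1,4} -> 2.5/1.75
  es <- data.frame(estimate = c(1, 1, 4), variance = c(1, 2, 4),
                   experiment_id = c("A", "B", "C"), year = 1:3)
  fit <- meta_fit(es, random = FALSE)
  expect_equal(unname(fit$beta), 2.5 / 1.75, tolerance = 1e-12)
  expect_equal(unname(fit$beta), 1.42857, tolerance = 1e-5)
  expect_equal(unname(fit$se), sqrt(1 / 1.75), tolerance = 1e-12)

  # a single effect: the estimate is the observation
  one <- data.frame(estimate = 0.7, variance = 0.09,
                    experiment_id = "A", year = 1)
  f1 <- meta_fit(one, random = FALSE)
  expect_equal(unname(f1$beta), 0.7)
  expect_equal(unname(f1$se), 0.3)
})

test_that("the CAR term with rho = 0 is an independent per-effect variance", {
  inst <- random_instance(55)
  base <- reml_loglik(inst$y, inst$X, inst$v, inst$experiment, inst$year,
                      sigma2_exp = 0.2, sigma2_dataset = 0.1,
                      tau2_car = 0.3, rho_car = 0)
  equiv <- reml_loglik(inst$y, inst$X, inst$v, inst$experiment, inst$year,
                       sigma2_exp = 0.2, sigma2_dataset = 0.4,
                       tau2_car = 0, rho_car = 0)
  expect_equal(base, equiv, tolerance = 1e-6)
})

test_that("estimates are invariant to experiment relabelling and year shifts", {
  es <- sim_effects(k = 24, n_exp = 8, tau2_car = 0.08, rho_car = 0.5,
                    seed = 12)
  fit <- meta_fit(es)
  es2 <- es
  es2$experiment_id <- chartr("E", "Z", es$experiment_id)
  es2$year <- es$year + 57L
  fit2 <- meta_fit(es2)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-8)
  expect_equal(fit$rho_car, fit2$rho_car, tolerance = 1e-6)
})

test_that("Wald intervals use normal quantiles and respect the level", {
  es <- data.frame(estimate = c(0, 1), variance = c(1, 1),
                   experiment_id = c("A", "B"), year = 1:2)
  fit <- meta_fit(es, random = FALSE)
  # manufactured: se of pooled = sqrt(1/2)
  ci <- wald_ci(fit)
  expect_equal(ci$ci_ub - ci$estimate, qnorm(0.975) * sqrt(0.5),
               tolerance = 1e-10)
  narrow <- wald_ci(fit, level = 0.5)
  expect_lt(narrow$ci_ub - narrow$ci_lb, ci$ci_ub - ci$ci_lb)

  # degenerate zero-SE coefficient: zero-width interval, p = 0
  fit0 <- fit
  fit0$vcov_beta[] <- 0
  fit0$se[] <- 0
  fit0$beta[] <- 0.4
  ci0 <- wald_ci(fit0)
  expect_equal(ci0$ci_lb, ci0$ci_ub)
  expect_equal(ci0$pval, 0)
  # the 1.95996 quantile itself
  expect_equal(qnorm(0.975), 1.95996, tolerance = 1e-5)
})

test_that("Q, QE and Qm follow their weighted definitions", {
  es <- data.frame(estimate = c(1, 1, 1), variance = c(2, 2, 2),
                   experiment_id = c("A", "B", "C"), year = 1:3)
  qs <- q_statistics(meta_fit(es, random = FALSE))
  expect_equal(qs$Q_total, 0)

  es2 <- data.frame(estimate = c(0, 2), variance = c(1, 1),
                    experiment_id = c("A", "B"), year = 1:2)
  qs2 <- q_statistics(meta_fit(es2, random = FALSE))
  expect_equal(qs2$Q_total, 2)
  expect_equal(qs2$Q_df, 1L)
  expect_equal(qs2$Q_p, pchisq(2, 1, lower.tail = FALSE))

  # saturated moderator model: QE undefined
  es2$x <- c(0, 1)
  sat <- meta_fit(es2, mods = ~ x, random = FALSE)
  expect_true(is.na(q_statistics(sat)$QE))

  # Qm is the Wald chi-square on the slope
  es3 <- sim_effects(k = 30, n_exp = 15, seed = 4)
  es3$x <- rnorm(30)
  f3 <- meta_fit(es3, mods = ~ x)
  qs3 <- q_statistics(f3)
  expect_equal(qs3$Qm, (f3$beta[["x"]] / f3$se[["x"]])^2, tolerance = 1e-8)
  expect_equal(qs3$Qm_df, 1L)
  expect_gt(qs3$QE, 0)
})

test_that("REML recovers effect-level generating parameters on average", {
  # effect-level recovery at known sampling variances: mean of the pooled
  # estimate across replicates should sit within Monte Carlo error of the
  # generating mean (the flux-level version runs in the acceptance suite)
  mus <- vapply(1:40, function(s) {
    es <- sim_effects(k = 60, n_exp = 20, mu = 0.5, sigma2_exp = 0.1,
                      sigma2_dataset = 0.05, tau2_car = 0.05,
                      rho_car = 0.6, seed = 1000 + s)
    unname(meta_fit(es)$beta[1L])
  }, numeric(1))
  mc_se <- sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - 0.5), 4 * mc_se + 0.005)
})

test_that("the CAR model improves AIC when true effects are autocorrelated", {
  es <- sim_effects(k = 80, n_exp = 10, mu = 0.5, sigma2_exp = 0.02,
                    sigma2_dataset = 0.01, tau2_car = 0.3, rho_car = 0.9,
                    v_range = c(0.01, 0.03), seed = 21)
  fit_car <- meta_fit(es, car = TRUE)
  fit_nocar <- meta_fit(es, car = FALSE)
  expect_lt(meta_aic(fit_car), meta_aic(fit_nocar))
})

test_that("model serialization round-trips through JSON", {
  es <- sim_effects(k = 20, n_exp = 8, seed = 31)
  es$TN <- runif(20, 0.1, 0.5)
  es$CN <- runif(20, 10, 18)
  fit <- meta_fit(es, mods = ~ TN + CN)
  p <- tempfile(fileext = ".json")
  meta_to_json(fit, p)
  back <- meta_from_json(p)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$vcov_beta, fit$vcov_beta, tolerance = 1e-12)
})
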
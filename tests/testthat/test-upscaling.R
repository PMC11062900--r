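mk_profile_stack <- function(tn = c(0.4, 0.5), soc = c(5, 6),
                             bd = c(1.2, 1.3), tops = c(0, 30),
                             bottoms = c(30, 60), rel = 0.2) {
  layers <- list()
  z95 <- qnorm(0.95)
  for (i in seq_along(tops)) {
    for (v in c("TN", "SOC", "BD")) {
      m <- switch(v, TN = tn[i], SOC = soc[i], BD = bd[i])
      s <- rel * m
      nm <- function(st) sprintf("%s_%s_%g_%g", v, st, tops[i], bottoms[i])
      layers[[nm("mean")]] <- matrix(m, 1, 1)
      layers[[nm("q05")]] <- matrix(m - z95 * s, 1, 1)
      layers[[nm("q95")]] <- matrix(m + z95 * s, 1, 1)
    }
  }
  layers$baseline_er <- matrix(300, 1, 1)
  soil_stack(layers, cellsize = 1000)
}

test_that("mineral-layer extraction classifies horizons and depth-weights", {
  # single 0-60 interval passing all thresholds: output equals the inputs
  st <- mk_profile_stack(tn = 0.4, soc = 5, bd = 1.2, tops = 0,
                         bottoms = 60)
  cells <- extract_mineral_layer(st)
  expect_true(cells$valid)
  expect_equal(cells$tn_mean, 0.4)
  expect_equal(cells$soc_mean, 5)

  # organic top layer (SOC 20% > 0.1 g/g): only 30-60 cm contributes
  st2 <- mk_profile_stack(tn = c(0.4, 0.5), soc = c(20, 5),
                          bd = c(0.5, 1.2))
  cells2 <- extract_mineral_layer(st2)
  expect_true(cells2$valid)
  expect_equal(cells2$tn_mean, 0.5)
  expect_equal(cells2$soc_mean, 5)

  # both layers organic: invalid cell
  st3 <- mk_profile_stack(tn = c(1.6, 1.5), soc = c(25, 20),
                          bd = c(0.4, 0.5))
  cells3 <- extract_mineral_layer(st3)
  expect_false(cells3$valid)
  expect_true(is.na(cells3$tn_mean))

  # two mineral layers: thickness-weighted mean
  st4 <- mk_profile_stack(tn = c(0.2, 0.6), soc = c(3, 6),
                          bd = c(1.1, 1.4))
  cells4 <- extract_mineral_layer(st4)
  expect_equal(cells4$tn_mean, 0.4)

  # a BD below 1 g/cm3 disqualifies an otherwise mineral horizon
  st5 <- mk_profile_stack(tn = c(0.2, 0.6), soc = c(3, 6),
                          bd = c(0.9, 1.4))
  expect_equal(extract_mineral_layer(st5)$tn_mean, 0.6)
})

test_that("percentile bands invert to standard deviations", {
  expect_equal(sd_from_percentiles(5, 5), 0)
  z <- qnorm(0.95)
  expect_equal(sd_from_percentiles(-z, z), 1)
  expect_equal(sd_from_percentiles(10, 20), 10 / (2 * z))
  expect_equal(sd_from_percentiles(10, 20), 3.03978, tolerance = 1e-5)
  expect_error(sd_from_percentiles(3, 2), "masked")
})

test_that("the truncated-mean location adjustment hits its target", {
  # truncation far below the mean: adjustment is negligible
  adj <- adjust_truncated_mean(10, 0.1, 10 - 10 * 0.1 * 10)
  expect_equal(adj$mu, 10, tolerance = 1e-6)
  # heavy truncation: adjusted location sits below the target and the
  # truncated-normal mean identity holds at the root
  adj2 <- adjust_truncated_mean(0.2, 0.15, 0.01)
  expect_lt(adj2$mu, 0.2)
  lam <- function(a) dnorm(a) / (1 - pnorm(a))
  alpha <- (0.01 - adj2$mu) / 0.15
  expect_equal(adj2$mu + 0.15 * lam(alpha), 0.2, tolerance = 1e-8)
})

test_that("soil sampling is seeded, respects degenerate sds and the floor", {
  # zero sds: every draw equals the mean pair
  s <- sample_soil(0.3, 0, 4, 0, n_draws = 10, seed = 5)
  expect_equal(unique(s$tn), 0.3)
  expect_equal(unique(s$soc), 4)

  a <- sample_soil(0.2, 0.15, 5, 1.5, n_draws = 500, seed = 7)
  b <- sample_soil(0.2, 0.15, 5, 1.5, n_draws = 500, seed = 7)
  expect_identical(a, b)
  c <- sample_soil(0.2, 0.15, 5, 1.5, n_draws = 500, seed = 8)
  expect_false(identical(a, c))
  # truncation floor at 5% of the mean
  expect_true(all(a$tn >= 0.05 * 0.2))
  expect_true(all(a$soc >= 0.05 * 5))
  # draws stay positively correlated
  expect_gt(cor(a$tn, a$soc), 0.6)
})

test_that("C:N bias correction is the chosen linear map of the raw ratio", {
  expect_equal(cn_bias_correct(0.25, 5), 20)              # identity
  expect_equal(cn_bias_correct(0.25, 5, 2, 0.9), 20)      # 2 + 0.9 * 20
  raw <- cn_bias_correct(c(0.2, 0.25, 0.3), 5)
  corr <- cn_bias_correct(c(0.2, 0.25, 0.3), 5, 1, 0.8)
  expect_true(all(diff(order(raw)) == diff(order(corr))))  # monotone
  expect_error(cn_bias_correct(-0.1, 5), "positive")

  # bootstrap regressions on identity data recover the identity
  set.seed(1)
  x <- runif(200, 10, 20)
  reg <- fit_cn_regressions(x, x, n = 20, seed = 3)
  expect_equal(nrow(reg), 20L)
  expect_equal(mean(reg$slope), 1, tolerance = 1e-6)
  expect_equal(mean(reg$intercept), 0, tolerance = 1e-5)
})

test_that("the mixture sd matches hand values and collapses correctly", {
  expect_equal(mixture_sd(rep(3, 5), rep(0, 5)), 0)
  expect_equal(mixture_sd(c(0, 2), c(0, 0)), 1)
  # with zero SEs it is the population sd of the means
  m <- c(1, 4, 6, 9)
  expect_equal(mixture_sd(m, 0), sd(m) * sqrt(3 / 4), tolerance = 1e-12)
  # quick Monte Carlo cross-check (the 1e6-draw version runs in the
  # acceptance suite)
  set.seed(2)
  means <- rnorm(50); ses <- runif(50, 0.1, 1)
  comp <- sample.int(50, 2e5, replace = TRUE)
  draws <- rnorm(2e5, means[comp], ses[comp])
  expect_equal(mixture_sd(means, ses), sd(draws), tolerance = 0.02)
})

test_that("upscaling collapses exactly in its degenerate limits", {
  cells <- make_cells(tn = c(0.2, 0.4), cn = c(12, 16))
  cfg <- run_config(mc_draws = 50, seed = 3)

  # zero soil sds + zero coefficient covariance: exact plug-in
  res <- upscale_grid(cells, surface_model(), cfg)
  rom <- 0.05 - 0.16 * cells$tn_mean + 0.01 * (cells$soc_mean / cells$tn_mean)
  expect_equal(res$pct_change_mean, 100 * (exp(rom) - 1), tolerance = 1e-12)
  expect_equal(res$pct_change_sd, c(0, 0))
  expect_equal(res$abs_change, cells$baseline_er * (exp(rom) - 1),
               tolerance = 1e-12)
  expect_true(all(is.na(res$uncertainty_ratio)))  # combined sd is zero

  # zero soil sds with parameter uncertainty: sd equals the per-draw
  # prediction SE and the input-only share is zero
  vc <- diag(c(1e-4, 1e-4, 1e-6))
  dimnames(vc) <- list(c("(Intercept)", "TN", "CN"),
                       c("(Intercept)", "TN", "CN"))
  res2 <- upscale_grid(cells, surface_model(vc), cfg)
  se_expect <- sqrt(1e-4 + 1e-4 * cells$tn_mean^2 +
                      1e-6 * (cells$soc_mean / cells$tn_mean)^2)
  expect_equal(res2$pct_change_sd,
               100 * exp(rom) * se_expect, tolerance = 1e-10)
  expect_equal(res2$uncertainty_ratio, c(0, 0))

  # soil variability with zero coefficient covariance: ratio is exactly 1
  cells3 <- make_cells(tn = 0.3, cn = 14, tn_sd = 0.06, soc_sd = 0.8)
  res3 <- upscale_grid(cells3, surface_model(), cfg)
  expect_equal(res3$uncertainty_ratio, 1)
  expect_equal(decompose_uncertainty(cells3, surface_model(), cfg), 1)

  # invalid cells pass through as nodata
  cells4 <- make_cells(tn = c(0.3, 0.3), cn = c(14, 14))
  cells4$valid[2] <- FALSE
  res4 <- upscale_grid(cells4, surface_model(), cfg)
  expect_true(res4$valid[1])
  expect_false(res4$valid[2])
  expect_true(is.na(res4$pct_change_mean[2]))
})

test_that("predicted change falls with TN and rises with C:N", {
  cfg <- run_config(mc_draws = 20, seed = 2)
  tn_grid <- make_cells(tn = seq(0.1, 0.9, length.out = 5), cn = 14)
  res_tn <- upscale_grid(tn_grid, surface_model(), cfg)
  # C:N is held at 14 by construction (soc = tn * cn), so only the TN
  # coefficient acts
  expect_true(all(diff(res_tn$pct_change_mean) < 0))
  cn_grid <- make_cells(tn = 0.3, cn = seq(10, 20, length.out = 5))
  res_cn <- upscale_grid(cn_grid, surface_model(), cfg)
  expect_true(all(diff(res_cn$pct_change_mean) > 0))
})

test_that("identical seeds reproduce upscaling bit for bit; seeds differ otherwise", {
  cells <- make_cells(tn = c(0.25, 0.35), cn = c(13, 15),
                      tn_sd = 0.05, soc_sd = 0.7)
  cfg <- run_config(mc_draws = 40)
  r1 <- upscale_grid(cells, surface_model(), cfg, seed = 10)
  r2 <- upscale_grid(cells, surface_model(), cfg, seed = 10)
  expect_identical(r1, r2)
  r3 <- upscale_grid(cells, surface_model(), cfg, seed = 11)
  expect_false(identical(r1$pct_change_mean, r3$pct_change_mean))
})

test_that("regional totals convert areas and fluxes to PgC", {
  # +25% on 100 gC m-2 yr-1 over 1e12 m2 -> 0.025 PgC
  n <- 4
  cells <- make_cells(tn = rep(0.3, n), cn = rep(14, n), baseline = 100,
                      area = 1e12 / n)
  res <- data.frame(cell_id = cells$cell_id, valid = TRUE,
                    abs_change = 25, abs_change_sd = 0)
  tot <- regional_totals(res, cells)
  expect_equal(tot$baseline_pg, 0.1)
  expect_equal(tot$delta_pg, 0.025)
  expect_equal(tot$delta_pct, 25)

  # zero change
  res0 <- res; res0$abs_change <- 0
  expect_equal(regional_totals(res0, cells)$delta_pg, 0)

  # doubling areas doubles totals
  cells2 <- cells; cells2$area <- cells$area * 2
  expect_equal(regional_totals(res, cells2)$delta_pg, 0.05)
  expect_error(regional_totals(res, transform(cells, area = NA)), "area")
})
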
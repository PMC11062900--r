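# Independent oracles and small data builders shared across tests.

# Dense restricted log-likelihood oracle: the likelihood of the error
# contrasts K'y with K an orthonormal basis of the orthogonal complement
# of the design column space, evaluated with plain dense linear algebra
# (determinant + solve), then shifted by the -1/2 log|X'X| constant that
# separates the contrast convention from the |X' V^-1 X| form the engine
# reports. Shares no code with the block-wise engine.
oracle_reml <- function(y, X, V) {
  X <- as.matrix(X)
  k <- length(y)
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):k, drop = FALSE]
  W <- t(K) %*% V %*% K
  z <- drop(crossprod(K, y))
  ld <- determinant(W, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  ll <- -0.5 * ((k - p) * log(2 * pi) + as.numeric(ld$modulus) +
                  drop(crossprod(z, solve(W, z))))
  ll - 0.5 * as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
}

# Dense GLS coefficients at fixed covariance.
oracle_gls <- function(y, X, V) {
  X <- as.matrix(X)
  Vi_X <- solve(V, X)
  drop(solve(crossprod(X, Vi_X), crossprod(Vi_X, y)))
}

# Random small meta-analytic instance (k <= 8) with a clustered
# year/experiment layout and random variance components.
random_instance <- function(seed, p = 1L) {
  set.seed(seed)
  k <- sample(3:8, 1L)
  experiment <- sample(sprintf("E%d", 1:3), k, replace = TRUE)
  # one dataset per experiment x year: years are distinct within experiment
  year <- integer(k)
  for (e in unique(experiment)) {
    i <- which(experiment == e)
    year[i] <- sample(2000:2010, length(i))
  }
  v <- runif(k, 0.05, 0.5)
  X <- if (p == 1L) matrix(1, k, 1) else cbind(1, matrix(rnorm(k * (p - 1)), k))
  theta <- list(sigma2_exp = runif(1, 0, 0.5),
                sigma2_dataset = runif(1, 0, 0.3),
                tau2_car = runif(1, 0, 0.4),
                rho_car = runif(1, 0, 0.95))
  y <- rnorm(k, 0.5, 0.7)
  list(y = y, X = X, v = v, experiment = experiment, year = year,
       theta = theta, k = k, p = ncol(X))
}

# Effect-level simulator: draws per-dataset effects directly from the
# multilevel CAR model with known sampling variances (no flux layer).
sim_effects <- function(k = 40L, n_exp = 20L, mu = 0.5,
                        sigma2_exp = 0.1, sigma2_dataset = 0.05,
                        tau2_car = 0, rho_car = 0,
                        v_range = c(0.02, 0.12), seed = 1L) {
  set.seed(seed)
  experiment <- sort(rep_len(sprintf("E%02d", seq_len(n_exp)), k))
  year <- stats::ave(seq_len(k), experiment, FUN = seq_along) + 2000L
  v <- runif(k, v_range[1L], v_range[2L])
  u_exp <- rnorm(n_exp, 0, sqrt(sigma2_exp))[match(experiment,
                                                   sort(unique(experiment)))]
  car <- numeric(k)
  if (tau2_car > 0) {
    for (e in unique(experiment)) {
      i <- which(experiment == e)
      S <- tau2_car * rho_car^abs(outer(year[i], year[i], "-"))
      car[i] <- drop(chol(S + diag(1e-12, length(i))) %*% rnorm(length(i)))
    }
  }
  data.frame(
    estimate = mu + u_exp + rnorm(k, 0, sqrt(sigma2_dataset)) + car +
      rnorm(k, 0, sqrt(v)),
    variance = v, experiment_id = experiment, year = year)
}

# Minimal flux table builder: one dataset, given plot-day values.
make_flux <- function(values_by_plot, treatment_by_plot,
                      experiment_id = "E1", site_id = "S1",
                      year = 2010, unit = "gCO2 m-2 d-1") {
  rows <- lapply(seq_along(values_by_plot), function(i) {
    vals <- values_by_plot[[i]]
    data.frame(site_id = site_id, experiment_id = experiment_id,
               plot_id = paste0("P", i), treatment = treatment_by_plot[i],
               date = as.Date(sprintf("%d-07-01", year)) + seq_along(vals) - 1,
               er_value = vals, er_unit = unit)
  })
  do.call(rbind, rows)
}

# Cell table builder for upscaling tests.
make_cells <- function(tn, cn, tn_sd = 0, soc_sd = 0, baseline = 300,
                       area = 1e6) {
  data.frame(cell_id = seq_along(tn), area = area,
             tn_mean = tn, tn_sd = tn_sd,
             soc_mean = tn * cn, soc_sd = soc_sd,
             baseline_er = baseline, valid = TRUE)
}

# The reference soil-driver surface used across upscaling tests:
# lnROM = 0.05 - 0.16 TN + 0.01 C:N, optionally with coefficient
# covariance.
surface_model <- function(vcov = NULL) {
  beta <- c("(Intercept)" = 0.05, TN = -0.16, CN = 0.01)
  if (is.null(vcov)) vcov <- matrix(0, 3, 3, dimnames = list(names(beta),
                                                             names(beta)))
  list(beta = beta, vcov_beta = vcov)
}
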
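#' Marginal covariance of effect sizes under the multilevel CAR model
#'
#' The model for the per-dataset effects is
#' `y_i = x_i' beta + u_exp(i) + u_ds(i) + c_exp(i)(year_i) + e_i`, with
#' independent experiment intercepts (variance `sigma2_exp`),
#' dataset-within-experiment intercepts (variance `sigma2_dataset`), a
#' continuous-time AR(1) process of true effects over years within each
#' experiment (variance `tau2_car`, correlation `rho_car^|year_i - year_j|`)
#' and known sampling variances `v_i`. The implied marginal covariance is
#' `V[i,j] = v_i 1(i=j) + sigma2_dataset 1(i=j) + sigma2_exp 1(same exp)
#'  + tau2_car rho_car^|dyear| 1(same exp)`,
#' block-diagonal by experiment.
#'
#' @param v sampling variances.
#' @param experiment experiment identifiers (any atomic type).
#' @param year integer measurement years.
#' @param sigma2_exp,sigma2_dataset,tau2_car variance components (>= 0).
#' @param rho_car CAR correlation per unit year, in `[0, 1)`.
#' @return a symmetric positive semi-definite `k x k` matrix.
#' @export
marginal_covariance <- function(v, experiment, year,
                                sigma2_exp = 0, sigma2_dataset = 0,
                                tau2_car = 0, rho_car = 0) {
  .check_theta(sigma2_exp, sigma2_dataset, tau2_car, rho_car)
  k <- length(v)
  stopifnot(length(experiment) == k, length(year) == k)
  V <- matrix(0, k, k)
  same <- outer(experiment, experiment, "==")
  V[same] <- sigma2_exp
  if (tau2_car > 0) {
    dy <- abs(outer(year, year, "-"))
    V <- V + same * tau2_car * rho_car^dy
  }
  diag(V) <- diag(V) + v + sigma2_dataset
  V
}

.check_theta <- function(sigma2_exp, sigma2_dataset, tau2_car, rho_car) {
  stopifnot(sigma2_exp >= 0, sigma2_dataset >= 0, tau2_car >= 0,
            rho_car >= 0, rho_car < 1)
}

# Precompute block structure: indices and |year| difference matrices per
# experiment. X is the fixed-effect design; y the effects; v the sampling
# variances.
.prep_blocks <- function(y, X, v, experiment, year) {
  stopifnot(length(y) == nrow(X), length(v) == length(y),
            length(experiment) == length(y), length(year) == length(y))
  if (anyNA(y) || anyNA(X) || anyNA(v)) stop("NA in effects or design")
  if (any(v <= 0)) stop("sampling variances must be positive")
  X <- as.matrix(X)
  idx <- split(seq_along(y), as.character(experiment))
  blocks <- lapply(idx, function(i) {
    yr <- year[i]
    list(i = i, dy = abs(outer(yr, yr, "-")),
         Xy = cbind(X[i, , drop = FALSE], y[i]), v = v[i])
  })
  list(y = y, X = X, v = v, blocks = blocks,
       k = length(y), p = ncol(X))
}

# Core block-wise Gaussian computations shared by REML and ML. Returns
# log|V|, the accumulated crossproducts, beta-hat (GLS) and the residual
# quadratic form, or NULL if any block is numerically singular.
.gauss_core <- function(prep, theta) {
  tryCatch(.gauss_core_unsafe(prep, theta), error = function(e) NULL)
}

.gauss_core_unsafe <- function(prep, theta) {
  p <- prep$p
  ldetV <- 0
  M <- matrix(0, p + 1L, p + 1L)
  for (b in prep$blocks) {
    nb <- length(b$v)
    if (nb == 1L) {
      vb <- b$v + theta$sigma2_dataset + theta$sigma2_exp + theta$tau2_car
      if (vb <= 0) return(NULL)
      ldetV <- ldetV + log(vb)
      M <- M + crossprod(b$Xy) / vb
      next
    }
    Vb <- matrix(theta$sigma2_exp, nb, nb)
    if (theta$tau2_car > 0) {
      Vb <- Vb + theta$tau2_car * theta$rho_car^b$dy
    }
    diag(Vb) <- diag(Vb) + b$v + theta$sigma2_dataset +
      if (theta$tau2_car > 0) 0 else theta$tau2_car
    R <- chol(Vb)
    ldetV <- ldetV + 2 * sum(log(diag(R)))
    Z <- backsolve(R, b$Xy, transpose = TRUE)
    M <- M + crossprod(Z)
  }
  A <- M[1:p, 1:p, drop = FALSE]
  bvec <- M[1:p, p + 1L]
  Ra <- chol(A)
  ldetA <- 2 * sum(log(diag(Ra)))
  u <- backsolve(Ra, bvec, transpose = TRUE)
  beta <- backsolve(Ra, u)
  quad <- M[p + 1L, p + 1L] - sum(u^2)
  list(ldetV = ldetV, ldetA = ldetA, beta = beta, quad = max(quad, 0),
       chol_A = Ra)
}

#' Restricted log-likelihood of the multilevel CAR meta-model
#'
#' `-1/2 [ (k-p) log 2 pi + log|V| + log|X' V^-1 X| + r' V^-1 r ]` with
#' `r = y - X beta_hat` and `beta_hat` the generalized least squares
#' estimate at the given variance components. Numerically singular
#' covariances return `-Inf` (optimizer-safe).
#'
#' @param y effect estimates.
#' @param X fixed-effect design matrix (full column rank, `k > p`).
#' @inheritParams marginal_covariance
#' @return a scalar restricted log-likelihood.
#' @export
reml_loglik <- function(y, X, v, experiment, year,
                        sigma2_exp = 0, sigma2_dataset = 0,
                        tau2_car = 0, rho_car = 0) {
  .check_theta(sigma2_exp, sigma2_dataset, tau2_car, rho_car)
  X <- as.matrix(X)
  prep <- .prep_blocks(y, X, v, experiment, year)
  if (prep$k <= prep$p) stop("k must exceed the number of fixed effects")
  g <- .gauss_core(prep, list(sigma2_exp = sigma2_exp,
                              sigma2_dataset = sigma2_dataset,
                              tau2_car = tau2_car, rho_car = rho_car))
  if (is.null(g)) return(-Inf)
  -0.5 * ((prep$k - prep$p) * log(2 * pi) + g$ldetV + g$ldetA + g$quad)
}

#' Maximum (profile) log-likelihood of the multilevel CAR meta-model
#'
#' `-1/2 [ k log 2 pi + log|V| + r' V^-1 r ]` at the GLS `beta_hat`; used
#' for AIC model comparison and McFadden pseudo-R-squared.
#'
#' @inheritParams reml_loglik
#' @return a scalar log-likelihood.
#' @export
ml_loglik <- function(y, X, v, experiment, year,
                      sigma2_exp = 0, sigma2_dataset = 0,
                      tau2_car = 0, rho_car = 0) {
  .check_theta(sigma2_exp, sigma2_dataset, tau2_car, rho_car)
  X <- as.matrix(X)
  prep <- .prep_blocks(y, X, v, experiment, year)
  g <- .gauss_core(prep, list(sigma2_exp = sigma2_exp,
                              sigma2_dataset = sigma2_dataset,
                              tau2_car = tau2_car, rho_car = rho_car))
  if (is.null(g)) return(-Inf)
  -0.5 * (prep$k * log(2 * pi) + g$ldetV + g$quad)
}

#' Generalized least squares coefficients at fixed variance components
#'
#' `beta_hat = (X' V^-1 X)^-1 X' V^-1 y` with `V` the marginal covariance
#' of [marginal_covariance()], computed through the engine's block-wise
#' path; mainly useful for validation against dense linear algebra.
#'
#' @inheritParams reml_loglik
#' @return `list(beta, vcov_beta)`.
#' @export
meta_gls <- function(y, X, v, experiment, year,
                     sigma2_exp = 0, sigma2_dataset = 0,
                     tau2_car = 0, rho_car = 0) {
  .check_theta(sigma2_exp, sigma2_dataset, tau2_car, rho_car)
  prep <- .prep_blocks(y, as.matrix(X), v, experiment, year)
  g <- .gauss_core(prep, list(sigma2_exp = sigma2_exp,
                              sigma2_dataset = sigma2_dataset,
                              tau2_car = tau2_car, rho_car = rho_car))
  if (is.null(g)) stop("singular covariance")
  list(beta = drop(g$beta), vcov_beta = chol2inv(g$chol_A))
}

# Transformed-parameter objective. Active components are optimized on the
# log-variance scale and rho on the logit scale (upper bound 1 - 1e-6),
# so the search is unconstrained.
.theta_from_par <- function(par, active) {
  th <- list(sigma2_exp = 0, sigma2_dataset = 0, tau2_car = 0, rho_car = 0)
  j <- 1L
  for (nm in c("sigma2_exp", "sigma2_dataset", "tau2_car")) {
    if (active[nm]) { th[[nm]] <- exp(par[j]); j <- j + 1L }
  }
  if (active["rho_car"]) {
    th$rho_car <- (1 - 1e-6) * stats::plogis(par[j])
  }
  th
}

#' Fit the multilevel random-effects meta-model by REML
#'
#' Fixed effects (intercept-only pooling or moderator metaregression) with
#' nested experiment and dataset random intercepts and a continuous-time
#' AR(1) structure of true effects over years within experiment. Variance
#' components are estimated by maximizing the restricted log-likelihood
#' with `nlminb` from four deterministic starting points (near-zero,
#' moment-based, and inflated/deflated perturbations), searching on
#' log-variance / logit-correlation scales; `method = "ML"` maximizes the
#' profile likelihood instead (for AIC and pseudo-R-squared).
#'
#' @param es `data.frame` with columns `estimate`, `variance`,
#'   `experiment_id`, `year` (one row per dataset); moderator columns may
#'   be present and referenced by `mods`.
#' @param mods optional one-sided formula for the fixed effects, evaluated
#'   in `es` (default intercept-only `~ 1`). Categorical moderators are
#'   dummy-coded by `model.matrix`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param random if `FALSE`, all variance components are pinned to zero
#'   and the fit reduces to the closed-form inverse-variance weighted
#'   (fixed-effect) estimator.
#' @param car if `FALSE`, the CAR term is dropped (three-level model
#'   only); used for AIC comparison of the temporal structure.
#' @param verbose print optimization progress.
#' @return an object of class `"meta_fit"`: coefficients `beta` with
#'   `vcov_beta = (X' V^-1 X)^-1`, variance components (`sigma2_exp`,
#'   `sigma2_dataset`, `tau2_car`, `rho_car`), `loglik` (of `method`),
#'   `k`, `p`, `converged` and `boundary` flags, and the data needed by
#'   [q_statistics()], [wald_ci()] and [predict.meta_fit()].
#' @examples
#' es <- data.frame(estimate = c(0.5, 0.7, 0.2), variance = c(.04, .05, .06),
#'                  experiment_id = c("A", "A", "B"), year = c(1, 2, 1))
#' fit <- meta_fit(es, random = FALSE)
#' coef(fit)
#' @export
meta_fit <- function(es, mods = NULL, method = c("REML", "ML"),
                     random = TRUE, car = TRUE, verbose = FALSE) {
  method <- match.arg(method)
  need <- c("estimate", "variance", "experiment_id", "year")
  if (!all(need %in% names(es))) {
    stop("es must have columns ", paste(need, collapse = ", "))
  }
  y <- es$estimate
  v <- es$variance
  if (is.null(mods)) mods <- ~ 1
  trms <- stats::terms(mods, data = es)
  mf <- stats::model.frame(trms, es, na.action = stats::na.fail)
  X <- stats::model.matrix(trms, mf)
  xlev <- stats::.getXlevels(trms, mf)
  k <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  if (k < p + (random && k > 1)) stop("k must be at least p + 1")

  active <- c(sigma2_exp = random, sigma2_dataset = random,
              tau2_car = random && car, rho_car = random && car)
  prep <- .prep_blocks(y, X, v, es$experiment_id, es$year)

  if (!any(active)) {
    g <- .gauss_core(prep, list(sigma2_exp = 0, sigma2_dataset = 0,
                                tau2_car = 0, rho_car = 0))
    if (is.null(g)) stop("singular weighted design")
    theta <- list(sigma2_exp = 0, sigma2_dataset = 0, tau2_car = 0,
                  rho_car = 0)
    ll <- if (k > p) {
      if (method == "REML") {
        -0.5 * ((k - p) * log(2 * pi) + g$ldetV + g$ldetA + g$quad)
      } else {
        -0.5 * (k * log(2 * pi) + g$ldetV + g$quad)
      }
    } else NA_real_
    return(.mk_fit(g, theta, ll, prep, es, trms, xlev, method,
                   converged = TRUE, random = FALSE, car = FALSE))
  }

  obj <- function(par) {
    th <- .theta_from_par(par, active)
    g <- .gauss_core(prep, th)
    if (is.null(g)) return(1e10)
    val <- if (method == "REML") {
      0.5 * ((k - p) * log(2 * pi) + g$ldetV + g$ldetA + g$quad)
    } else {
      0.5 * (k * log(2 * pi) + g$ldetV + g$quad)
    }
    if (!is.finite(val)) 1e10 else val
  }

  # moment-based scale for the starts: DerSimonian-Laird-type total
  # heterogeneity from the intercept-only weighted fit
  w <- 1 / v
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  t2 <- max((Q - (k - 1)) / max(c_dl, 1e-12), 1e-3 * stats::median(v))
  lv <- function(x) log(pmax(x, 1e-8))
  starts <- list(
    c(lv(rep(1e-4 * t2, 3)), stats::qlogis(0.10)),
    c(lv(rep(t2 / 3, 3)),    stats::qlogis(0.50)),
    c(lv(rep(2 * t2, 3)),    stats::qlogis(0.85)),
    c(lv(c(t2, 0.05 * t2, 0.05 * t2)), stats::qlogis(0.30))
  )
  sel <- c(active[1:3], active[4])
  starts <- lapply(starts, function(s) s[sel])

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- tryCatch(
      stats::nlminb(s, obj, control = list(rel.tol = 1e-12,
                                           iter.max = 500L,
                                           eval.max = 1000L)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (verbose) message("start obj: ", format(o$objective))
    if (is.null(best) || o$objective < best$objective - 1e-12) {
      best <- o
      conv <- o$convergence == 0
    }
  }
  if (is.null(best)) {
    stop("REML optimization failed from all starting points")
  }
  # polish pass: restart at the best optimum; convergence is declared when
  # the restart cannot improve the objective beyond tolerance (robust to
  # nlminb's 'false convergence' on boundary ridges, e.g. rho -> 1)
  polish <- tryCatch(
    stats::nlminb(best$par, obj, control = list(rel.tol = 1e-12,
                                                iter.max = 200L)),
    error = function(e) NULL)
  if (!is.null(polish) && is.finite(polish$objective) &&
      polish$objective <= best$objective) {
    conv <- (best$objective - polish$objective) < 1e-6
    best <- polish
  }
  theta <- .theta_from_par(best$par, active)
  g <- .gauss_core(prep, theta)
  ll <- -best$objective
  .mk_fit(g, theta, ll, prep, es, trms, xlev, method,
          converged = conv, random = random, car = car)
}

.mk_fit <- function(g, theta, ll, prep, es, trms, xlev, method,
                    converged, random, car) {
  p <- prep$p
  vcov_beta <- chol2inv(g$chol_A)
  beta <- drop(g$beta)
  names(beta) <- colnames(prep$X)
  dimnames(vcov_beta) <- list(colnames(prep$X), colnames(prep$X))
  boundary <- c(sigma2_exp = theta$sigma2_exp < 1e-7,
                sigma2_dataset = theta$sigma2_dataset < 1e-7,
                tau2_car = theta$tau2_car < 1e-7)
  structure(list(
    beta = beta, vcov_beta = vcov_beta, se = sqrt(diag(vcov_beta)),
    sigma2_exp = theta$sigma2_exp, sigma2_dataset = theta$sigma2_dataset,
    tau2_car = theta$tau2_car, rho_car = theta$rho_car,
    loglik = ll, method = method, k = prep$k, p = p,
    converged = converged, boundary = boundary,
    random = random, car = car,
    terms = trms, xlev = xlev,
    y = prep$y, v = prep$v, X = prep$X,
    experiment_id = es$experiment_id, year = es$year
  ), class = "meta_fit")
}

#' @export
coef.meta_fit <- function(object, ...) object$beta

#' @export
vcov.meta_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.meta_fit <- function(object, ...) {
  n_theta <- if (!object$random) 0L else if (object$car) 4L else 2L
  structure(object$loglik, df = object$p + n_theta,
            nobs = object$k, class = "logLik")
}

#' AIC from a maximum-likelihood refit
#'
#' Refits the model by ML on the same data and structure (REML
#' log-likelihoods are not comparable across fixed-effect structures) and
#' returns `-2 logLik + 2 (p + n_theta)`; used e.g. to compare the model
#' with and without the CAR term.
#'
#' @param fit a `"meta_fit"`.
#' @return a scalar AIC.
#' @export
meta_aic <- function(fit) {
  ml <- if (fit$method == "ML") fit else .refit(fit, method = "ML")
  n_theta <- if (!fit$random) 0L else if (fit$car) 4L else 2L
  -2 * ml$loglik + 2 * (fit$p + n_theta)
}

.refit <- function(fit, method = "ML", random = fit$random, car = fit$car) {
  es <- data.frame(estimate = fit$y, variance = fit$v,
                   experiment_id = fit$experiment_id, year = fit$year)
  prep <- .prep_blocks(fit$y, fit$X, fit$v, fit$experiment_id, fit$year)
  # re-optimize via meta_fit on a design-matrix passthrough
  meta_fit_X(es, fit$X, method = method, random = random, car = car,
             trms = fit$terms, xlev = fit$xlev)
}

# Internal variant taking an explicit design matrix (used for refits where
# the model frame is already built).
meta_fit_X <- function(es, X, method = "REML", random = TRUE, car = TRUE,
                       trms = NULL, xlev = NULL) {
  es2 <- es
  Xd <- as.data.frame(X)
  names(Xd) <- paste0(".x", seq_len(ncol(X)))
  es2 <- cbind(es2[c("estimate", "variance", "experiment_id", "year")], Xd)
  f <- stats::as.formula(paste("~ 0 +", paste(names(Xd), collapse = " + ")))
  fit <- meta_fit(es2, mods = f, method = method, random = random, car = car)
  names(fit$beta) <- colnames(X)
  dimnames(fit$vcov_beta) <- list(colnames(X), colnames(X))
  colnames(fit$X) <- colnames(X)
  if (!is.null(trms)) { fit$terms <- trms; fit$xlev <- xlev }
  fit
}

#' Wald coefficient table with normal confidence intervals
#'
#' @param fit a converged `"meta_fit"`.
#' @param level confidence level (default 0.95).
#' @return `data.frame(term, estimate, se, ci_lb, ci_ub, zval, pval)`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "meta_fit"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$beta
  se <- fit$se
  zval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  data.frame(term = names(est), estimate = est, se = se,
             ci_lb = est - z * se, ci_ub = est + z * se,
             zval = zval,
             pval = 2 * stats::pnorm(abs(zval), lower.tail = FALSE),
             row.names = NULL)
}

#' Heterogeneity and moderator test statistics
#'
#' `Q_total` is Cochran's Q of the intercept-only inverse-variance
#' weighted fit (`w_i = 1/v_i`, df `k - 1`); `QE` is the residual weighted
#' heterogeneity of the fitted fixed-effect structure (df `k - p`, `NA`
#' when saturated); `Qm` is the omnibus Wald chi-square on the
#' non-intercept coefficients of the fitted model (all coefficients when
#' there is no intercept), measuring moderator importance. P-values are
#' from the chi-square distribution.
#'
#' @param fit a `"meta_fit"`.
#' @return a list of class `"heterogeneity_tests"` with elements
#'   `Q_total, Q_df, Q_p, QE, QE_df, QE_p, Qm, Qm_df, Qm_p`.
#' @export
q_statistics <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  y <- fit$y; v <- fit$v; X <- fit$X
  k <- fit$k; p <- fit$p
  w <- 1 / v
  yw <- sum(w * y) / sum(w)
  Q_total <- sum(w * (y - yw)^2)
  Q_df <- k - 1L

  if (k > p) {
    XtW <- t(X * w)
    beta_fe <- solve(XtW %*% X, XtW %*% y)
    r <- y - drop(X %*% beta_fe)
    QE <- sum(w * r^2)
    QE_df <- k - p
  } else {
    QE <- NA_real_; QE_df <- 0L
  }

  idx <- which(names(fit$beta) != "(Intercept)")
  if (length(idx)) {
    b <- fit$beta[idx]
    Qm <- drop(t(b) %*% solve(fit$vcov_beta[idx, idx, drop = FALSE], b))
    Qm_df <- length(idx)
  } else {
    Qm <- 0; Qm_df <- 0L
  }
  structure(list(
    Q_total = Q_total, Q_df = Q_df,
    Q_p = stats::pchisq(Q_total, Q_df, lower.tail = FALSE),
    QE = QE, QE_df = QE_df,
    QE_p = if (is.na(QE)) NA_real_ else
      stats::pchisq(QE, QE_df, lower.tail = FALSE),
    Qm = Qm, Qm_df = Qm_df,
    Qm_p = if (Qm_df > 0) stats::pchisq(Qm, Qm_df, lower.tail = FALSE)
           else NA_real_
  ), class = "heterogeneity_tests")
}

#' Fixed-effect predictions with standard errors
#'
#' `mean = x*' beta_hat`, `SE = sqrt(x*' vcov_beta x*)` -- the prediction
#' uncertainty of the mean response at the moderator values, without
#' random-effect variance (the quantity propagated through the spatial
#' upscaling).
#'
#' @param object a converged `"meta_fit"`.
#' @param newdata `data.frame` of moderator values matching the model
#'   formula; omit for the fitted design.
#' @param ... unused.
#' @return `data.frame(fit, se)`.
#' @export
predict.meta_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    Xs <- object$X
  } else {
    tt <- stats::delete.response(object$terms)
    vars <- all.vars(tt)
    miss <- setdiff(vars, names(newdata))
    if (length(miss)) {
      stop("newdata is missing moderator(s): ", paste(miss, collapse = ", "))
    }
    mf <- stats::model.frame(tt, newdata, xlev = object$xlev,
                             na.action = stats::na.fail)
    Xs <- stats::model.matrix(tt, mf)
  }
  mu <- drop(Xs %*% object$beta)
  se <- sqrt(pmax(rowSums((Xs %*% object$vcov_beta) * Xs), 0))
  data.frame(fit = mu, se = se)
}

#' Serialize a fitted meta-model to JSON
#'
#' Round-trippable representation (coefficients, covariance, variance
#' components) consumed by the upscaling stage.
#'
#' @param fit a `"meta_fit"`.
#' @param path output path; if `NULL` the JSON string is returned.
#' @export
meta_to_json <- function(fit, path = NULL) {
  obj <- list(beta = as.list(fit$beta),
              vcov_beta = unclass(fit$vcov_beta),
              sigma2_exp = fit$sigma2_exp,
              sigma2_dataset = fit$sigma2_dataset,
              tau2_car = fit$tau2_car, rho_car = fit$rho_car,
              loglik = fit$loglik, method = fit$method,
              k = fit$k, p = fit$p, converged = fit$converged)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Load a model prediction surface from JSON
#'
#' Reads coefficients and their covariance back into a minimal object
#' usable by the upscaling stage (see [upscale_grid()]).
#'
#' @param path JSON file written by [meta_to_json()].
#' @return a list with `beta` and `vcov_beta`.
#' @export
meta_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  beta <- unlist(obj$beta)
  vc <- as.matrix(obj$vcov_beta)
  dimnames(vc) <- list(names(beta), names(beta))
  list(beta = beta, vcov_beta = vc,
       sigma2_exp = obj$sigma2_exp, sigma2_dataset = obj$sigma2_dataset,
       tau2_car = obj$tau2_car, rho_car = obj$rho_car)
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("<meta_fit> ", x$method, ", k = ", x$k, ", p = ", x$p,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(wald_ci(x), digits = 4)
  if (x$random) {
    cat(sprintf(
      "sigma2_exp = %.4g  sigma2_dataset = %.4g  tau2_car = %.4g  rho_car = %.3f\n",
      x$sigma2_exp, x$sigma2_dataset, x$tau2_car, x$rho_car))
    if (any(x$boundary)) {
      cat("boundary variance component(s):",
          paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
    }
  } else {
    cat("fixed-effect model (variance components pinned to 0)\n")
  }
  cat("logLik:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
print.heterogeneity_tests <- function(x, ...) {
  cat(sprintf("Q  = %.2f (df %d, p %.3g)\n", x$Q_total, x$Q_df, x$Q_p))
  if (!is.na(x$QE)) {
    cat(sprintf("QE = %.2f (df %d, p %.3g)\n", x$QE, x$QE_df, x$QE_p))
  }
  if (x$Qm_df > 0) {
    cat(sprintf("Qm = %.2f (df %d, p %.3g)\n", x$Qm, x$Qm_df, x$Qm_p))
  }
  invisible(x)
}
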
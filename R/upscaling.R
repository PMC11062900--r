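#' Standard deviation from percentile bands
#'
#' Converts per-cell 5th/95th percentile soil layers to a normal-theory
#' standard deviation: `(q95 - q05) / (2 * qnorm(0.95))`.
#'
#' @param q05,q95 percentile values (`q95 >= q05`).
#' @return standard deviation(s).
#' @examples
#' sd_from_percentiles(10, 20)  # 3.03978
#' @export
sd_from_percentiles <- function(q05, q95) {
  if (any(q95 < q05, na.rm = TRUE)) {
    stop("q95 < q05; such cells must be masked upstream")
  }
  (q95 - q05) / (2 * stats::qnorm(0.95))
}

#' Mineral-layer soil properties per grid cell
#'
#' Classifies each depth interval of each cell as mineral iff
#' TN <= `tn_max` (g/g) and SOC <= `soc_max` (g/g) and bulk density >=
#' `bd_min` (g/cm^3) -- organic horizons are nitrogen- and carbon-rich and
#' light -- and returns thickness-weighted means of TN and SOC (and of
#' their percentile-derived standard deviations) over the mineral
#' intervals within `depth_max`. Cells with no mineral interval, or
#' masked in the stack, are flagged invalid.
#'
#' @param stack a [soil_stack()] with TN/SOC in % by mass and BD in
#'   g/cm^3.
#' @param config a [run_config()] carrying the thresholds.
#' @return a `data.frame` of cells: `cell_id, row, col, area` (m^2),
#'   `tn_mean, tn_sd, soc_mean, soc_sd` (% by mass), `baseline_er`
#'   (gC m^-2 yr^-1, `NA` if the stack has no `baseline_er` layer) and
#'   `valid`.
#' @export
extract_mineral_layer <- function(stack, config = run_config()) {
  stopifnot(inherits(stack, "soil_stack"))
  d <- stack$depths
  dims <- dim(stack$layers[[1L]])
  n <- prod(dims)
  lay <- function(v, s, i) {
    stack$layers[[sprintf("%s_%s_%g_%g", v, s, d$top[i], d$bottom[i])]]
  }
  wsum <- matrix(0, dims[1L], dims[2L])
  acc <- list(tn_mean = wsum, tn_sd = wsum, soc_mean = wsum, soc_sd = wsum)
  for (i in seq_len(nrow(d))) {
    if (d$top[i] >= config$depth_max) next
    thick <- min(d$bottom[i], config$depth_max) - d$top[i]
    tn <- lay("TN", "mean", i); soc <- lay("SOC", "mean", i)
    bd <- lay("BD", "mean", i)
    mineral <- (tn / 100 <= config$tn_max) & (soc / 100 <= config$soc_max) &
      (bd >= config$bd_min)
    mineral[is.na(mineral)] <- FALSE
    w <- thick * mineral
    acc$tn_mean <- acc$tn_mean + w * tn
    acc$soc_mean <- acc$soc_mean + w * soc
    acc$tn_sd <- acc$tn_sd +
      w * sd_from_percentiles(lay("TN", "q05", i), lay("TN", "q95", i))
    acc$soc_sd <- acc$soc_sd +
      w * sd_from_percentiles(lay("SOC", "q05", i), lay("SOC", "q95", i))
    wsum <- wsum + w
  }
  valid <- stack$valid & wsum > 0
  div <- ifelse(wsum > 0, wsum, NA_real_)
  base <- stack$layers[["baseline_er"]]
  data.frame(
    cell_id = seq_len(n),
    row = as.vector(row(div)), col = as.vector(col(div)),
    area = stack$cellsize^2,
    tn_mean = as.vector(acc$tn_mean / div),
    tn_sd = as.vector(acc$tn_sd / div),
    soc_mean = as.vector(acc$soc_mean / div),
    soc_sd = as.vector(acc$soc_sd / div),
    baseline_er = if (is.null(base)) NA_real_ else as.vector(base),
    valid = as.vector(valid)
  )
}

# Mean of a normal truncated below at a, in a numerically stable form.
.truncnorm_mean <- function(mu, sd, a) {
  alpha <- (a - mu) / sd
  lambda <- exp(stats::dnorm(alpha, log = TRUE) -
                stats::pnorm(alpha, lower.tail = FALSE, log.p = TRUE))
  mu + sd * lambda
}

#' Location adjustment for a truncated-normal target mean
#'
#' Solves, by scalar root-finding on the truncated-normal mean identity,
#' for the location `mu` such that a normal(`mu`, `sd`) truncated below at
#' `lower` has expectation `target`. Truncation discards low values and
#' inflates the mean, so the adjusted location lies below the target.
#'
#' @param target desired mean of the truncated distribution.
#' @param sd standard deviation (unchanged by the adjustment).
#' @param lower truncation point (must be `< target`).
#' @return `list(mu, adjusted_ok)`; on root-finding failure `mu = target`
#'   and `adjusted_ok = FALSE` (callers fall back to floor clipping).
#' @export
adjust_truncated_mean <- function(target, sd, lower) {
  stopifnot(lower < target, sd >= 0)
  if (sd == 0) return(list(mu = target, adjusted_ok = TRUE))
  f <- function(mu) .truncnorm_mean(mu, sd, lower) - target
  r <- tryCatch(
    stats::uniroot(f, c(target - 10 * sd, target + sd),
                   extendInt = "upX", tol = 1e-12),
    error = function(e) NULL)
  if (is.null(r)) return(list(mu = target, adjusted_ok = FALSE))
  list(mu = r$root, adjusted_ok = TRUE)
}

# Quantile of a normal truncated below at a.
.qtruncnorm <- function(p, mu, sd, a) {
  pa <- stats::pnorm(a, mu, sd)
  stats::qnorm(pa + p * (1 - pa), mu, sd)
}

#' Correlated truncated sampling of soil inputs
#'
#' Draws (TN, SOC) pairs for one grid cell. Each marginal is a normal
#' distribution truncated below at `trunc_frac` of its target mean (no
#' negative concentrations), with its location adjusted by
#' [adjust_truncated_mean()] so the truncated mean equals the target; the
#' two marginals are coupled by a Gaussian copula with the configured
#' TN-SOC correlation, so the realized correlation of the draws tracks
#' the stated value (rectangle truncation of a joint normal would
#' attenuate it; see the methods vignette). Zero-sd variables collapse to
#' their means. Cells where the adjustment fails (pathological sd >> mean)
#' fall back to untruncated sampling clipped at the floor and are flagged.
#'
#' @param tn_mean,tn_sd,soc_mean,soc_sd target moments (% by mass).
#' @param n_draws number of pairs (>= 2).
#' @param corr TN-SOC correlation.
#' @param trunc_frac truncation point as a fraction of each mean.
#' @param seed integer seed for this cell's substream.
#' @return `data.frame(tn, soc)` with attribute `"clipped"` (logical).
#' @export
sample_soil <- function(tn_mean, tn_sd, soc_mean, soc_sd,
                        n_draws, corr = 0.8273, trunc_frac = 0.05,
                        seed = 1L) {
  cells <- data.frame(tn_mean = tn_mean, tn_sd = tn_sd,
                      soc_mean = soc_mean, soc_sd = soc_sd)
  s <- .sample_soil_matrix(cells, n_draws, corr, trunc_frac, seed)
  structure(data.frame(tn = s$tn[1L, ], soc = s$soc[1L, ]),
            clipped = s$clipped[1L])
}

# Vectorized sampler over many cells; one latent normal pair per
# (cell, draw), transformed through each cell's truncated marginal.
.sample_soil_matrix <- function(cells, n_draws, corr, trunc_frac, seed) {
  n_cells <- nrow(cells)
  stopifnot(n_draws >= 2L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  z1 <- matrix(stats::rnorm(n_cells * n_draws), n_cells, n_draws)
  z2 <- corr * z1 +
    sqrt(1 - corr^2) * matrix(stats::rnorm(n_cells * n_draws),
                              n_cells, n_draws)
  draw_var <- function(target, sd, z) {
    out <- matrix(rep(target, n_draws), n_cells, n_draws)
    clipped <- logical(n_cells)
    for (i in which(sd > 0)) {
      a <- trunc_frac * target[i]
      adj <- adjust_truncated_mean(target[i], sd[i], a)
      if (adj$adjusted_ok) {
        out[i, ] <- .qtruncnorm(stats::pnorm(z[i, ]), adj$mu, sd[i], a)
      } else {
        out[i, ] <- pmax(target[i] + sd[i] * z[i, ], a)
        clipped[i] <- TRUE
      }
    }
    list(x = out, clipped = clipped)
  }
  tn <- draw_var(cells$tn_mean, cells$tn_sd, z1)
  soc <- draw_var(cells$soc_mean, cells$soc_sd, z2)
  list(tn = tn$x, soc = soc$x, clipped = tn$clipped | soc$clipped)
}

#' Bootstrap regressions for the C:N derivation bias
#'
#' The upscaling derives C:N as SOC/TN, which is a biased proxy for
#' measured C:N. The bias model is a set of linear regressions of
#' reported C:N on SOC/TN-computed C:N, fitted to bootstrap resamples of
#' the calibration scatter; each Monte Carlo iteration uses one
#' regression.
#'
#' @param reported_cn measured C:N values.
#' @param computed_cn SOC/TN-derived C:N for the same records.
#' @param n number of bootstrap regressions (default 100).
#' @param seed integer seed.
#' @return `data.frame(intercept, slope)` with `n` rows.
#' @export
fit_cn_regressions <- function(reported_cn, computed_cn, n = 100L,
                               seed = 1L) {
  stopifnot(length(reported_cn) == length(computed_cn),
            length(reported_cn) >= 3L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- length(reported_cn)
  coefs <- t(vapply(seq_len(n), function(j) {
    i <- sample.int(m, m, replace = TRUE)
    stats::coef(stats::lm(reported_cn[i] ~ computed_cn[i]))
  }, numeric(2L)))
  data.frame(intercept = coefs[, 1L], slope = coefs[, 2L])
}

#' Apply a C:N bias regression to sampled soil values
#'
#' @param tn,soc sampled TN and SOC (same units).
#' @param intercept,slope coefficients of the bias regression used for
#'   this Monte Carlo iteration.
#' @return corrected C:N values: `intercept + slope * (soc / tn)`.
#' @export
cn_bias_correct <- function(tn, soc, intercept = 0, slope = 1) {
  if (any(tn <= 0)) stop("tn must be positive (ensured by truncation)")
  intercept + slope * (soc / tn)
}

#' Standard deviation of an equal-weight normal mixture
#'
#' Combines Monte Carlo prediction means and their standard errors into
#' one spread: `sqrt(mean(MEAN^2 + SE^2) - mean(MEAN)^2)`.
#'
#' @param means vector of component means.
#' @param ses vector of component standard errors (recycled if length 1).
#' @return a scalar standard deviation.
#' @examples
#' mixture_sd(c(0, 2), c(0, 0))  # 1
#' @export
mixture_sd <- function(means, ses) {
  if (length(ses) == 1L) ses <- rep(ses, length(means))
  stopifnot(length(means) == length(ses), length(means) >= 1L,
            all(ses >= 0))
  n <- length(means)
  sqrt(max(sum(means^2 + ses^2) / n - (sum(means) / n)^2, 0))
}

# Prediction surface: mean and SE of the lnROM response at (TN, C:N),
# from either a fitted meta_fit whose formula uses TN and CN, or a plain
# list(beta, vcov_beta) with coefficients named (Intercept), TN, CN.
.predict_surface <- function(model, TN, CN) {
  if (inherits(model, "meta_fit")) {
    return(predict_with_se(model, data.frame(TN = TN, CN = CN)))
  }
  beta <- model$beta
  Xs <- matrix(0, length(TN), length(beta))
  colnames(Xs) <- names(beta)
  if ("(Intercept)" %in% names(beta)) Xs[, "(Intercept)"] <- 1
  if ("TN" %in% names(beta)) Xs[, "TN"] <- TN
  if ("CN" %in% names(beta)) Xs[, "CN"] <- CN
  mu <- drop(Xs %*% beta)
  V <- model$vcov_beta
  se <- if (is.null(V) || all(V == 0)) rep(0, length(TN)) else
    sqrt(pmax(rowSums((Xs %*% V) * Xs), 0))
  data.frame(fit = mu, se = se)
}

#' Monte Carlo upscaling of the soil-driver model across grid cells
#'
#' For each valid cell, draws `mc_draws` correlated truncated (TN, SOC)
#' samples, derives bias-corrected C:N (iteration `j` uses bootstrap
#' regression `j`, recycled), evaluates the fitted lnROM model at each
#' sample (prediction mean and standard error), and combines the draws on
#' the lnROM scale with [mixture_sd()]. Results are transformed to
#' percent change (`100 (exp(m) - 1)`; spread by the delta method), an
#' absolute change against baseline respiration, and the
#' uncertainty-source ratio: the propagation is computed twice on the
#' identical soil draws, once with and once without the model's
#' coefficient covariance, and `uncertainty_ratio = sd(input only) /
#' sd(combined)` in `(0, 1]`.
#'
#' @param cells cell table from [extract_mineral_layer()] (or built
#'   directly); `tn_mean`/`soc_mean` in % by mass.
#' @param model a converged `"meta_fit"` on the lnROM scale with
#'   moderators `TN` and `CN`, or a `list(beta, vcov_beta)` as from
#'   [meta_from_json()].
#' @param config a [run_config()] (`mc_draws`, correlation, truncation).
#' @param cn_regressions `data.frame(intercept, slope)` from
#'   [fit_cn_regressions()]; defaults to the identity (no bias
#'   correction).
#' @param seed root seed; the soil-draw substream is derived from it.
#' @param n_draws override of `config$mc_draws`.
#' @return a `data.frame` per cell: `cell_id`, `pct_change_mean`,
#'   `pct_change_sd`, `cv`, `uncertainty_ratio`, `abs_change`,
#'   `abs_change_sd`, `clipped`, `valid` (invalid cells carry `NA`
#'   results).
#' @export
upscale_grid <- function(cells, model, config = run_config(),
                         cn_regressions = NULL, seed = config$seed,
                         n_draws = config$mc_draws) {
  if (is.null(cn_regressions)) {
    cn_regressions <- data.frame(intercept = 0, slope = 1)
  }
  if (!"valid" %in% names(cells)) cells$valid <- TRUE
  if (!"baseline_er" %in% names(cells)) cells$baseline_er <- NA_real_
  ok <- which(cells$valid & cells$tn_mean > 0 & cells$soc_mean > 0)
  out <- data.frame(cell_id = cells$cell_id,
                    pct_change_mean = NA_real_, pct_change_sd = NA_real_,
                    cv = NA_real_, uncertainty_ratio = NA_real_,
                    abs_change = NA_real_, abs_change_sd = NA_real_,
                    clipped = FALSE, valid = FALSE)
  if (!length(ok)) return(out)
  sub <- cells[ok, , drop = FALSE]
  s <- .sample_soil_matrix(sub, n_draws,
                           corr = config$tn_soc_correlation,
                           trunc_frac = config$truncation_fraction,
                           seed = substream_seed(seed, "soil_draws"))
  nr <- nrow(cn_regressions)
  MEANS <- matrix(0, length(ok), n_draws)
  SES <- matrix(0, length(ok), n_draws)
  for (j in seq_len(n_draws)) {
    r <- cn_regressions[((j - 1L) %% nr) + 1L, ]
    cn <- cn_bias_correct(s$tn[, j], s$soc[, j], r$intercept, r$slope)
    pr <- .predict_surface(model, s$tn[, j], cn)
    MEANS[, j] <- pr$fit
    SES[, j] <- pr$se
  }
  mbar <- rowMeans(MEANS)
  sd_comb <- sqrt(pmax(rowMeans(MEANS^2 + SES^2) - mbar^2, 0))
  sd_input <- sqrt(pmax(rowMeans(MEANS^2) - mbar^2, 0))
  pct_mean <- 100 * (exp(mbar) - 1)
  pct_sd <- 100 * exp(mbar) * sd_comb
  out$pct_change_mean[ok] <- pct_mean
  out$pct_change_sd[ok] <- pct_sd
  out$cv[ok] <- ifelse(abs(pct_mean) < 1e-6, NA_real_,
                       pct_sd / abs(pct_mean))
  out$uncertainty_ratio[ok] <- ifelse(sd_comb == 0, NA_real_,
                                      sd_input / sd_comb)
  out$abs_change[ok] <- sub$baseline_er * (exp(mbar) - 1)
  out$abs_change_sd[ok] <- sub$baseline_er * exp(mbar) * sd_comb
  out$clipped[ok] <- s$clipped
  out$valid[ok] <- TRUE
  out
}

#' Upscale a single grid cell
#'
#' @inheritParams upscale_grid
#' @param cell a one-row cell `data.frame` (see [upscale_grid()]).
#' @return a one-row result `data.frame`.
#' @export
upscale_cell <- function(cell, model, config = run_config(),
                         cn_regressions = NULL, seed = config$seed,
                         n_draws = config$mc_draws) {
  stopifnot(nrow(cell) == 1L)
  if (!"cell_id" %in% names(cell)) cell$cell_id <- 1L
  upscale_grid(cell, model, config, cn_regressions, seed, n_draws)
}

#' Uncertainty-source decomposition for a cell
#'
#' Runs the Monte Carlo propagation twice on identical soil-draw
#' substreams -- once with combined parameter + input uncertainty, once
#' with the metaregression parameters fixed at their mean estimates --
#' and returns the ratio of the resulting standard deviations,
#' `input only / combined`, in `(0, 1]` (`NA` when the combined sd is 0).
#'
#' @inheritParams upscale_cell
#' @return a scalar ratio.
#' @export
decompose_uncertainty <- function(cell, model, config = run_config(),
                                  cn_regressions = NULL,
                                  seed = config$seed,
                                  n_draws = config$mc_draws) {
  upscale_cell(cell, model, config, cn_regressions, seed,
               n_draws)$uncertainty_ratio
}

#' Regional totals of baseline and warmed respiration
#'
#' Area-weighted sums over valid cells, in PgC yr^-1 (gC m^-2 yr^-1 x
#' m^2 x 1e-15). The spread of the regional change treats cells as
#' independent (per-cell soil errors; no spatial correlation is
#' modelled), so `sd = sqrt(sum((area x abs_change_sd)^2))`.
#'
#' @param results output of [upscale_grid()].
#' @param cells the matching cell table (areas and baseline fluxes).
#' @return a list: `baseline_pg`, `warmed_pg`, `delta_pg`, `delta_sd_pg`,
#'   `delta_pct` and `n_cells`.
#' @export
regional_totals <- function(results, cells) {
  m <- merge(results, cells[c("cell_id", "area", "baseline_er")],
             by = "cell_id")
  if (any(is.na(m$area))) stop("missing cell area")
  m <- m[m$valid & !is.na(m$baseline_er), , drop = FALSE]
  to_pg <- 1e-15
  baseline <- sum(m$area * m$baseline_er) * to_pg
  delta <- sum(m$area * m$abs_change) * to_pg
  delta_sd <- sqrt(sum((m$area * m$abs_change_sd * to_pg)^2))
  list(baseline_pg = baseline, warmed_pg = baseline + delta,
       delta_pg = delta, delta_sd_pg = delta_sd,
       delta_pct = 100 * delta / baseline, n_cells = nrow(m))
}
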
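#' Known-truth configuration for the synthetic study generator
#'
#' Defines the generating conditions of a synthetic warming synthesis:
#' the observed hierarchy (sites > experiments > dataset-years > plots x
#' treatments), the generating effect-size model (pooled effect, variance
#' components, CAR correlation of true effects over years), driver-effect
#' slopes, and the flux noise model. Defaults mirror the structure of the
#' tundra synthesis the package targets: 136 dataset-years across 56
#' experiments at 28 sites, a pooled warming effect of 0.57 standardized
#' units, and positively skewed daily fluxes with ~16 measurement days
#' per plot per growing season.
#'
#' @param n_sites,n_experiments,n_datasets hierarchy targets.
#' @param plots_min,plots_max plots per treatment (uniform draw).
#' @param mu pooled true effect on the Hedges' g scale.
#' @param sigma2_exp,sigma2_dataset,tau2_car,rho_car generating variance
#'   components and CAR correlation of the true effects.
#' @param moderator_slopes named numeric vector: per-driver slope of the
#'   true effect on the centered control-plot driver value (default:
#'   none).
#' @param flux_base median control flux, gCO2 m^-2 d^-1.
#' @param daily_sd_log sd of the multiplicative lognormal daily noise.
#' @param plot_cv between-plot coefficient of variation of true plot
#'   means.
#' @param n_days measurement days per plot per growing season.
#' @param max_years_per_experiment cap on repeated measurement years.
#' @param tn_dtn_correlation correlation between the control TN level and
#'   the warming-induced TN change (negative: nitrogen-poor soils show
#'   larger warming-induced TN shifts).
#' @param missing_frac named numeric vector: per-driver fraction of
#'   datasets with the driver missing (exercises complete-case
#'   discipline).
#' @param seed root seed for the generator.
#' @return an object of class `"truth_config"`.
#' @export
truth_config <- function(n_sites = 28L, n_experiments = 56L,
                         n_datasets = 136L,
                         plots_min = 3L, plots_max = 8L,
                         mu = 0.57, sigma2_exp = 0.1,
                         sigma2_dataset = 0.05, tau2_car = 0.05,
                         rho_car = 0.6,
                         moderator_slopes = numeric(0),
                         flux_base = 3, daily_sd_log = 0.35,
                         plot_cv = 0.15, n_days = 16L,
                         max_years_per_experiment = 13L,
                         tn_dtn_correlation = -0.43,
                         missing_frac = numeric(0),
                         seed = 1L) {
  stopifnot(n_sites >= 1L, n_experiments >= n_sites,
            n_datasets >= n_experiments,
            n_datasets <= n_experiments * max_years_per_experiment,
            plots_min >= 2L, plots_max >= plots_min,
            sigma2_exp >= 0, sigma2_dataset >= 0, tau2_car >= 0,
            rho_car >= 0, rho_car < 1,
            flux_base > 0, daily_sd_log >= 0, plot_cv >= 0, n_days >= 1L,
            abs(tn_dtn_correlation) <= 1)
  structure(as.list(environment()), class = "truth_config")
}

# Offset of the warmed-plot mean that makes the computed Hedges' g
# unbiased for the target effect g: delta = g * pooled sd of plot-level
# seasonal means, where the plot-mean variance combines between-plot
# spread and averaged-down lognormal daily noise. Solved by a short fixed
# point since delta enters the warmed-side variance.
.warmed_offset <- function(g, base, sigma_b, s_log, n_days) {
  vdaily <- (exp(s_log^2) - 1) / n_days
  vc <- sigma_b^2 + (base^2 + sigma_b^2) * vdaily
  delta <- g * sqrt(vc)
  for (it in 1:4) {
    bw <- pmax(base + delta, 0.05 * base)
    vw <- sigma_b^2 + (bw^2 + sigma_b^2) * vdaily
    delta <- g * sqrt((vc + vw) / 2)
  }
  delta
}

#' Simulate a plot-level flux and driver database with known truth
#'
#' Generates a synthetic warming-experiment database with the configured
#' hierarchy: experiments nested in sites, 1 to
#' `max_years_per_experiment` consecutive measurement years per
#' experiment, per-dataset true effects
#' `mu + u_exp + u_dataset + car_exp(year) + sum(slope * centered driver)`,
#' and plot-level daily fluxes (positive, lognormal daily noise around
#' plot means) calibrated so that the Hedges' g computed by the
#' effect-size pipeline is unbiased for the dataset's true effect. Driver
#' tables carry control-plot conditions (TN, C:N, soil moisture) and full
#' treatment/control summary blocks for warming-induced changes in air
#' and soil temperature, soil moisture and TN (the latter correlated with
#' the control TN level via `tn_dtn_correlation`).
#'
#' @param config a [truth_config()].
#' @return a list: `flux` (plot-day table as in [read_flux_table()]),
#'   `drivers` (long driver table as in [read_driver_table()]),
#'   `experiments` (`experiment_id, site_id, start_year`), and `truth`
#'   (generating parameters plus the per-dataset true effects and driver
#'   values).
#' @export
simulate_database <- function(config = truth_config()) {
  stopifnot(inherits(config, "truth_config"))
  cf <- config
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(cf$seed, "database"))

  sites <- sprintf("S%02d", seq_len(cf$n_sites))
  site_base <- cf$flux_base * exp(stats::rnorm(cf$n_sites, 0, 0.25))
  exp_site <- c(seq_len(cf$n_sites),
                sample(cf$n_sites, cf$n_experiments - cf$n_sites,
                       replace = TRUE))
  exp_ids <- sprintf("E%03d", seq_len(cf$n_experiments))
  start_year <- sample(1994:2015, cf$n_experiments, replace = TRUE)

  # distribute dataset-years: every experiment measured at least once
  n_years <- rep(1L, cf$n_experiments)
  extra <- cf$n_datasets - cf$n_experiments
  while (extra > 0L) {
    i <- sample.int(cf$n_experiments, 1L)
    if (n_years[i] < cf$max_years_per_experiment) {
      n_years[i] <- n_years[i] + 1L
      extra <- extra - 1L
    }
  }
  first_dur <- sample(0:12, cf$n_experiments, replace = TRUE,
                      prob = 0.85^(0:12))

  ds <- do.call(rbind, lapply(seq_len(cf$n_experiments), function(i) {
    yrs <- start_year[i] + first_dur[i] + seq_len(n_years[i]) - 1L
    data.frame(experiment_id = exp_ids[i], site_id = sites[exp_site[i]],
               year = yrs, duration = yrs - start_year[i])
  }))
  n_ds <- nrow(ds)

  # true-effect components
  u_exp <- stats::rnorm(cf$n_experiments, 0, sqrt(cf$sigma2_exp))
  ds$u_exp <- u_exp[match(ds$experiment_id, exp_ids)]
  ds$u_ds <- stats::rnorm(n_ds, 0, sqrt(cf$sigma2_dataset))
  ds$car <- 0
  if (cf$tau2_car > 0) {
    for (i in seq_len(cf$n_experiments)) {
      rows <- which(ds$experiment_id == exp_ids[i])
      yr <- ds$year[rows]
      S <- cf$tau2_car * cf$rho_car^abs(outer(yr, yr, "-"))
      ds$car[rows] <- drop(chol(S + diag(1e-12, length(yr))) %*%
                             stats::rnorm(length(yr)))
    }
  }

  # drivers: control TN (% mineral layer), C:N, soil moisture; latent
  # normals reused so the TN vs delta-TN correlation knob is exact
  z_tn <- stats::rnorm(n_ds)
  ds$TN <- exp(log(0.30) + 0.40 * z_tn)
  ds$CN <- stats::rnorm(n_ds, 14, 2.5)
  ds$soil_moisture <- pmin(pmax(stats::rnorm(n_ds, 45, 15), 5), 95)
  r <- cf$tn_dtn_correlation
  z_dtn <- r * z_tn + sqrt(1 - r^2) * stats::rnorm(n_ds)
  ds$dTN_smd <- -0.1 + 0.4 * z_dtn

  ds$true_g <- cf$mu + ds$u_exp + ds$u_ds + ds$car
  for (nm in names(cf$moderator_slopes)) {
    if (!nm %in% names(ds)) stop("unknown moderator in slopes: ", nm)
    ds$true_g <- ds$true_g +
      cf$moderator_slopes[[nm]] * (ds[[nm]] - mean(ds[[nm]]))
  }

  # plot-level daily fluxes
  exp_base <- site_base[exp_site] * exp(stats::rnorm(cf$n_experiments, 0, 0.1))
  flux <- vector("list", n_ds)
  for (i in seq_len(n_ds)) {
    base <- exp_base[match(ds$experiment_id[i], exp_ids)]
    sigma_b <- cf$plot_cv * base
    delta <- .warmed_offset(ds$true_g[i], base, sigma_b, cf$daily_sd_log,
                            cf$n_days)
    n_pc <- sample(cf$plots_min:cf$plots_max, 1L)
    n_pw <- sample(cf$plots_min:cf$plots_max, 1L)
    pool <- seq(as.Date(sprintf("%d-06-01", ds$year[i])),
                as.Date(sprintf("%d-08-31", ds$year[i])), by = "day")
    days <- sort(sample(pool, min(cf$n_days, length(pool))))
    mk <- function(trt, n_p, b) {
      lev <- pmax(stats::rnorm(n_p, b, sigma_b), 0.05 * base)
      nd <- length(days)
      data.frame(
        site_id = ds$site_id[i], experiment_id = ds$experiment_id[i],
        plot_id = paste0(ds$experiment_id[i], "_", substr(trt, 1, 1),
                         rep(seq_len(n_p), each = nd)),
        treatment = trt, date = rep(days, n_p),
        er_value = rep(lev, each = nd) *
          exp(stats::rnorm(n_p * nd, -cf$daily_sd_log^2 / 2,
                           cf$daily_sd_log)),
        er_unit = "gCO2 m-2 d-1")
    }
    flux[[i]] <- rbind(mk("control", n_pc, base),
                       mk("warmed", n_pw, pmax(base + delta, 0.05 * base)))
  }
  flux <- do.call(rbind, flux)
  rownames(flux) <- NULL

  # long driver table
  drv <- list()
  add_block <- function(name, cmean, csd, wmean, wsd, n_c, n_w) {
    data.frame(
      experiment_id = rep(ds$experiment_id, 6L),
      year = rep(ds$year, 6L),
      driver = name,
      statistic = rep(c("control_mean", "control_sd", "warmed_mean",
                        "warmed_sd", "n_control", "n_warmed"),
                      each = nrow(ds)),
      value = c(cmean, csd, wmean, wsd, n_c, n_w))
  }
  n_rep <- sample(cf$plots_min:cf$plots_max, n_ds, replace = TRUE)
  tn_sd <- 0.15 * ds$TN
  drv$TN <- add_block("TN", ds$TN, tn_sd, ds$TN + ds$dTN_smd * tn_sd,
                      tn_sd, n_rep, n_rep)
  at_c <- stats::rnorm(n_ds, 8, 1.5)
  drv$air_temperature <- add_block("air_temperature", at_c, rep(1.0, n_ds),
                                   at_c + 1.4, rep(1.0, n_ds), n_rep, n_rep)
  st_c <- stats::rnorm(n_ds, 6, 1.2)
  drv$soil_temperature <- add_block("soil_temperature", st_c, rep(0.8, n_ds),
                                    st_c + 0.4, rep(0.8, n_ds), n_rep, n_rep)
  drv$soil_moisture <- add_block("soil_moisture", ds$soil_moisture,
                                 rep(6, n_ds), ds$soil_moisture - 1.6,
                                 rep(6, n_ds), n_rep, n_rep)
  ctx <- function(name, vals) {
    data.frame(experiment_id = ds$experiment_id, year = ds$year,
               driver = name, statistic = "control_mean", value = vals)
  }
  drv$CN <- ctx("CN", ds$CN)
  drivers <- do.call(rbind, drv)
  rownames(drivers) <- NULL
  for (nm in names(cf$missing_frac)) {
    keys <- unique(ds[c("experiment_id", "year")])
    drop <- keys[stats::runif(nrow(keys)) < cf$missing_frac[[nm]], ]
    sel <- drivers$driver == nm &
      paste(drivers$experiment_id, drivers$year) %in%
        paste(drop$experiment_id, drop$year)
    drivers <- drivers[!sel, , drop = FALSE]
  }

  experiments <- data.frame(experiment_id = exp_ids,
                            site_id = sites[exp_site],
                            start_year = start_year)
  list(flux = flux, drivers = drivers, experiments = experiments,
       truth = list(config = cf, datasets = ds, experiments = experiments))
}

#' Simulate soil and baseline-respiration rasters with known truth
#'
#' Smooth spatial fields for mineral-layer TN, SOC and bulk density on a
#' two-interval depth profile (0-30 / 30-60 cm), with 5th/95th percentile
#' layers generated from known per-cell standard deviations through the
#' same normal-theory identity that [sd_from_percentiles()] inverts, a
#' configurable fraction of organic-only cells (all intervals fail the
#' mineral thresholds) and of cells with an organic top layer, and a
#' positive baseline annual respiration field.
#'
#' @param n grid edge length (cells); the grid is `n x n`.
#' @param cellsize cell edge, m.
#' @param tn_base mineral TN level, % by mass.
#' @param cn_base mineral C:N level (SOC is TN x C:N).
#' @param rel_sd per-cell relative sd of TN and SOC.
#' @param organic_fraction fraction of fully organic (invalid) cells.
#' @param organic_top_fraction fraction of cells whose 0-30 cm layer is
#'   organic (mineral properties then come from 30-60 cm only).
#' @param baseline_er mean baseline respiration, gC m^-2 yr^-1.
#' @param seed integer seed.
#' @return a list: `stack` (a [soil_stack()]), and `truth` (per-cell true
#'   mineral TN, SOC, C:N and the sd fields).
#' @export
simulate_rasters <- function(n = 20L, cellsize = 1000,
                             tn_base = 0.3, cn_base = 14,
                             rel_sd = 0.25,
                             organic_fraction = 0.1,
                             organic_top_fraction = 0.2,
                             baseline_er = 250,
                             seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, "rasters"))
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  smooth <- function(amp, phase) {
    matrix(1 + amp * sin(2 * pi * xy$x / n + phase) *
                 cos(2 * pi * xy$y / n + phase), n, n)
  }
  z95 <- stats::qnorm(0.95)
  tn <- tn_base * smooth(0.35, 0.3) *
    matrix(exp(stats::rnorm(n * n, 0, 0.08)), n, n)
  cn <- cn_base * smooth(0.15, 1.7)
  soc <- tn * cn
  bd <- 1.3 * smooth(0.08, 2.4)
  tn_sd <- rel_sd * tn
  soc_sd <- rel_sd * soc
  bd_sd <- 0.05 * bd

  mk_layers <- function(top, bottom, tn, soc, bd, tn_sd, soc_sd, bd_sd) {
    out <- list()
    nm <- function(v, s) sprintf("%s_%s_%g_%g", v, s, top, bottom)
    for (v in c("TN", "SOC", "BD")) {
      m <- switch(v, TN = tn, SOC = soc, BD = bd)
      s <- switch(v, TN = tn_sd, SOC = soc_sd, BD = bd_sd)
      out[[nm(v, "mean")]] <- m
      out[[nm(v, "q05")]] <- m - z95 * s
      out[[nm(v, "q95")]] <- m + z95 * s
    }
    out
  }
  organic <- matrix(stats::runif(n * n) < organic_fraction, n, n)
  org_top <- matrix(stats::runif(n * n) < organic_top_fraction, n, n) |
    organic
  o <- function(mineral, organic_val, mask) {
    m <- mineral
    m[mask] <- organic_val
    m
  }
  top <- mk_layers(0, 30,
                   o(tn, 1.6, org_top), o(soc, 30, org_top),
                   o(bd, 0.4, org_top),
                   o(tn_sd, 0.2, org_top), o(soc_sd, 4, org_top),
                   o(bd_sd, 0.05, org_top))
  bot <- mk_layers(30, 60,
                   o(tn, 1.6, organic), o(soc, 30, organic),
                   o(bd, 0.4, organic),
                   o(tn_sd, 0.2, organic), o(soc_sd, 4, organic),
                   o(bd_sd, 0.05, organic))
  layers <- c(top, bot)
  layers$baseline_er <- baseline_er * smooth(0.25, 0.9)
  list(stack = soil_stack(layers, cellsize = cellsize),
       truth = list(tn = tn, soc = soc, cn = cn, bd = bd,
                    tn_sd = tn_sd, soc_sd = soc_sd,
                    organic = organic, organic_top = org_top,
                    baseline_er = layers$baseline_er))
}

#' Write a soil stack to a directory of ESRI ASCII grids
#'
#' @param stack a [soil_stack()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths (readable by
#'   [read_soil_rasters()]).
#' @export
write_soil_rasters <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(stack$layers[[nm]], p, xll = stack$xll, yll = stack$yll,
              cellsize = stack$cellsize)
    p
  }, character(1L))
  paths
}
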
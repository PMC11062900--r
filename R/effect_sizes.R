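#' Flux unit standardization
#'
#' Converts ecosystem respiration measurements to the common unit
#' gCO2 m^-2 d^-1. Recognized input units: `"gCO2 m-2 d-1"`,
#' `"gCO2 m-2 h-1"`, `"mgCO2 m-2 h-1"`, `"umol CO2 m-2 s-1"`,
#' `"gC m-2 d-1"`. Conversions use molar masses CO2 = 44.009 g/mol and
#' C = 12.011 g/mol, and 86400 s/d.
#'
#' @param value numeric flux values.
#' @param unit character vector of unit strings (recycled if length 1).
#' @return numeric values in gCO2 m^-2 d^-1.
#' @examples
#' standardize_units(1, "umol CO2 m-2 s-1")  # 3.80238
#' @export
standardize_units <- function(value, unit) {
  factors <- c(
    "gCO2 m-2 d-1"     = 1,
    "gCO2 m-2 h-1"     = 24,
    "mgCO2 m-2 h-1"    = 24 / 1000,
    "umol CO2 m-2 s-1" = 1e-6 * 44.009 * 86400,
    "gC m-2 d-1"       = 44.009 / 12.011
  )
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  stopifnot(length(unit) == length(value))
  unknown <- setdiff(unique(unit), names(factors))
  if (length(unknown)) {
    stop("unknown flux unit(s): ", paste(unknown, collapse = ", "))
  }
  value * unname(factors[unit])
}

# molar-mass ratio used to express CO2 fluxes as carbon
.c_per_co2 <- 12.011 / 44.009

#' Single-pass outlier filter per dataset
#'
#' Removes plot-day observations lying outside `mean +/- k * sd` of their
#' dataset (experiment x year), with both treatments pooled, in a single
#' pass: mean and sd are those of the full dataset, not recomputed after
#' removals. Datasets with zero spread trigger a warning and lose nothing.
#'
#' @param flux flux `data.frame` (columns `experiment_id`, `year`,
#'   `er_value`, ...), typically from [read_flux_table()] after
#'   [standardize_units()].
#' @param k rule multiplier (default 3).
#' @return `list(flux = retained rows, report = per-dataset data.frame
#'   with n_removed/n_total, fraction_removed = global fraction)`.
#' @export
filter_outliers <- function(flux, k = 3) {
  stopifnot(k > 0)
  dt <- data.table::as.data.table(flux)
  er_value <- n_removed <- n_total <- NULL  # R CMD check
  dt[, `:=`(.mu = mean(er_value), .sd = stats::sd(er_value)),
     by = c("experiment_id", "year")]
  if (any(dt$.sd == 0, na.rm = TRUE)) {
    warning("dataset(s) with zero spread: no outliers can be flagged there")
  }
  keep <- is.na(dt$.sd) | dt$.sd == 0 |
    abs(dt$er_value - dt$.mu) <= k * dt$.sd
  report <- dt[, list(n_removed = sum(!keep[.I]), n_total = .N),
               by = c("experiment_id", "year")]
  out <- dt[keep]
  out[, c(".mu", ".sd") := NULL]
  out_df <- as.data.frame(out)
  attr(out_df, "outlier_filtered") <- TRUE
  list(flux = out_df,
       report = as.data.frame(report),
       fraction_removed = sum(report$n_removed) / sum(report$n_total))
}

#' Growing-season treatment summaries per dataset
#'
#' For each dataset (experiment x year) and treatment: per plot, the mean
#' over its retained daily values, converted from gCO2 to grams of carbon
#' in CO2 (x 12.011/44.009); then the mean, sd and n across plot means.
#' Plots, not plot-days, are the replication unit. Datasets where either
#' treatment has fewer than 2 plots are excluded and reported.
#'
#' @param flux retained flux rows in gCO2 m^-2 d^-1.
#' @return `list(summaries, exclusions)`; `summaries` has one row per
#'   dataset with columns `mean_c, sd_c, n_c, mean_w, sd_w, n_w` in
#'   gC m^-2 d^-1.
#' @export
season_summaries <- function(flux) {
  dt <- data.table::as.data.table(flux)
  er_value <- plot_mean <- treatment <- NULL  # R CMD check
  plots <- dt[, list(plot_mean = mean(er_value) * .c_per_co2),
              by = c("experiment_id", "year", "treatment", "plot_id")]
  trt <- plots[, list(mean = mean(plot_mean),
                      sd = stats::sd(plot_mean),
                      n = .N),
               by = c("experiment_id", "year", "treatment")]
  wide <- data.table::dcast(trt, experiment_id + year ~ treatment,
                            value.var = c("mean", "sd", "n"))
  for (nm in c("mean_control", "sd_control", "n_control",
               "mean_warmed", "sd_warmed", "n_warmed")) {
    if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
  }
  ok <- !is.na(wide$n_control) & wide$n_control >= 2L &
        !is.na(wide$n_warmed) & wide$n_warmed >= 2L
  exclusions <- data.frame(
    experiment_id = wide$experiment_id[!ok],
    year = wide$year[!ok],
    reason = rep("fewer than 2 plots in a treatment", sum(!ok)))
  out <- as.data.frame(wide[ok])
  names(out) <- sub("_control$", "_c", names(out))
  names(out) <- sub("_warmed$", "_w", names(out))
  out <- out[c("experiment_id", "year",
               "mean_c", "sd_c", "n_c", "mean_w", "sd_w", "n_w")]
  out$n_c <- as.integer(out$n_c)
  out$n_w <- as.integer(out$n_w)
  list(summaries = out, exclusions = exclusions)
}

#' Hedges' g standardized mean difference
#'
#' `d = (m_w - m_c) / s_p` with the (n-1)-weighted pooled sd
#' `s_p = sqrt(((n_w-1) s_w^2 + (n_c-1) s_c^2) / (n_w + n_c - 2))`,
#' small-sample correction `J = 1 - 3/(4 m - 1)` with `m = n_w + n_c - 2`,
#' `g = J d`, and sampling variance
#' `J^2 [ (n_w + n_c)/(n_w n_c) + d^2 / (2 (n_w + n_c)) ]`.
#' All arguments are vectorized.
#'
#' @param mean_c,sd_c,n_c control mean, sd and number of plots.
#' @param mean_w,sd_w,n_w warmed-treatment mean, sd and number of plots.
#' @return `data.frame(estimate, variance, reason)`; rows with zero pooled
#'   sd carry `NA` estimates and reason `"zero pooled variance"`.
#' @examples
#' hedges_smd(10, 2, 5, 12, 2, 5)  # g = 0.90323
#' @export
hedges_smd <- function(mean_c, sd_c, n_c, mean_w, sd_w, n_w) {
  m <- n_w + n_c - 2
  sp <- sqrt(((n_w - 1) * sd_w^2 + (n_c - 1) * sd_c^2) / m)
  d <- (mean_w - mean_c) / sp
  J <- 1 - 3 / (4 * m - 1)
  g <- J * d
  v <- J^2 * ((n_w + n_c) / (n_w * n_c) + d^2 / (2 * (n_w + n_c)))
  bad <- !is.na(sp) & sp == 0
  g[bad] <- NA_real_
  v[bad] <- NA_real_
  data.frame(estimate = g, variance = v,
             reason = ifelse(bad, "zero pooled variance", NA_character_))
}

#' Log ratio of means (lnROM)
#'
#' `ln(m_w / m_c)` with sampling variance
#' `s_w^2/(n_w m_w^2) + s_c^2/(n_c m_c^2)`. Requires positive means.
#'
#' @inheritParams hedges_smd
#' @return `data.frame(estimate, variance, reason)`.
#' @export
log_rom <- function(mean_c, sd_c, n_c, mean_w, sd_w, n_w) {
  bad <- mean_c <= 0 | mean_w <= 0
  est <- ifelse(bad, NA_real_, log(mean_w / mean_c))
  v <- ifelse(bad, NA_real_,
              sd_w^2 / (n_w * mean_w^2) + sd_c^2 / (n_c * mean_c^2))
  data.frame(estimate = est, variance = v,
             reason = ifelse(bad, "nonpositive mean", NA_character_))
}

#' Raw mean difference
#'
#' `m_w - m_c` with sampling variance `s_w^2/n_w + s_c^2/n_c`; used for
#' drivers where absolute changes (e.g. degrees C) are the interpretable
#' scale.
#'
#' @inheritParams hedges_smd
#' @return `data.frame(estimate, variance)`.
#' @export
raw_md <- function(mean_c, sd_c, n_c, mean_w, sd_w, n_w) {
  data.frame(estimate = mean_w - mean_c,
             variance = sd_w^2 / n_w + sd_c^2 / n_c)
}

#' Percent change implied by a log ratio of means
#'
#' @param rom lnROM value(s).
#' @return `100 * (exp(rom) - 1)`.
#' @examples
#' percent_change(log(1.3))  # 30
#' @export
percent_change <- function(rom) 100 * (exp(rom) - 1)

#' Per-dataset effect sizes from plot-level flux records
#'
#' The full effect-size pipeline: unit standardization, the single-pass
#' outlier filter (applied exactly once; asserted), growing-season
#' treatment summaries, and the chosen effect size per dataset.
#'
#' @param flux flux table from [read_flux_table()] (or the synthetic
#'   generator), any recognized units.
#' @param config a [run_config()]; supplies `outlier_k`.
#' @param es_type `"SMD"` (Hedges' g), `"lnROM"` or `"MD"`.
#' @param start_years optional `data.frame(experiment_id, start_year)` of
#'   treatment start years; when supplied, each effect size carries
#'   `duration = year - start_year` (0 = first summer of warming).
#' @return `list(effects, removal_report, exclusions)`; `effects` has one
#'   row per retained dataset: `experiment_id, year, es_type, estimate,
#'   variance, n_control, n_warmed, duration`.
#' @export
dataset_effect_sizes <- function(flux, config = run_config(),
                                 es_type = c("SMD", "lnROM", "MD"),
                                 start_years = NULL) {
  es_type <- match.arg(es_type)
  if (!"year" %in% names(flux)) {
    flux$year <- as.integer(format(as.Date(flux$date), "%Y"))
  }
  flux$er_value <- standardize_units(flux$er_value, flux$er_unit)
  flux$er_unit <- "gCO2 m-2 d-1"
  if (isTRUE(attr(flux, "outlier_filtered"))) {
    stop("flux table already outlier-filtered; the filter is single-pass ",
         "and must run exactly once")
  }
  filt <- filter_outliers(flux, k = config$outlier_k)
  ss <- season_summaries(filt$flux)
  s <- ss$summaries
  es <- switch(es_type,
    SMD   = hedges_smd(s$mean_c, s$sd_c, s$n_c, s$mean_w, s$sd_w, s$n_w),
    lnROM = log_rom(s$mean_c, s$sd_c, s$n_c, s$mean_w, s$sd_w, s$n_w),
    MD    = cbind(raw_md(s$mean_c, s$sd_c, s$n_c, s$mean_w, s$sd_w, s$n_w),
                  reason = NA_character_))
  out <- data.frame(experiment_id = s$experiment_id, year = s$year,
                    es_type = es_type,
                    estimate = es$estimate, variance = es$variance,
                    n_control = s$n_c, n_warmed = s$n_w,
                    duration = NA_integer_)
  rejected <- data.frame(experiment_id = out$experiment_id[!is.na(es$reason)],
                         year = out$year[!is.na(es$reason)],
                         reason = es$reason[!is.na(es$reason)])
  out <- out[is.na(es$reason) & out$variance > 0, , drop = FALSE]
  if (!is.null(start_years)) {
    idx <- match(out$experiment_id, start_years$experiment_id)
    out$duration <- as.integer(out$year - start_years$start_year[idx])
    if (any(out$duration < 0, na.rm = TRUE)) {
      stop("negative warming duration: measurement year precedes start year")
    }
  }
  rownames(out) <- NULL
  list(effects = out,
       removal_report = filt$report,
       fraction_removed = filt$fraction_removed,
       exclusions = rbind(ss$exclusions, rejected))
}

#' Effect sizes for environmental drivers
#'
#' Computes Hedges' g or raw mean differences for each (dataset, driver)
#' with a complete six-statistic block in a driver table; used for the
#' indirect-warming-effect metaregressions.
#'
#' @param drivers output of [read_driver_table()].
#' @param es_type `"SMD"` or `"MD"`.
#' @return `data.frame(experiment_id, year, driver, es_type, estimate,
#'   variance)`, complete cases only.
#' @export
driver_effect_sizes <- function(drivers, es_type = c("SMD", "MD")) {
  es_type <- match.arg(es_type)
  w <- driver_summaries(drivers)
  ok <- stats::complete.cases(
    w[c("control_mean", "control_sd", "warmed_mean", "warmed_sd",
        "n_control", "n_warmed")])
  w <- w[ok, , drop = FALSE]
  es <- if (es_type == "SMD") {
    hedges_smd(w$control_mean, w$control_sd, w$n_control,
               w$warmed_mean, w$warmed_sd, w$n_warmed)
  } else {
    cbind(raw_md(w$control_mean, w$control_sd, w$n_control,
                 w$warmed_mean, w$warmed_sd, w$n_warmed),
          reason = NA_character_)
  }
  out <- data.frame(experiment_id = w$experiment_id, year = w$year,
                    driver = w$driver, es_type = es_type,
                    estimate = es$estimate, variance = es$variance)
  out[is.na(es$reason) & out$variance > 0, , drop = FALSE]
}
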
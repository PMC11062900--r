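#' Run configuration
#'
#' Collects every tunable constant of the pipeline in one validated object:
#' the growing-season month sets, the outlier rule multiplier, Monte Carlo
#' settings for the upscaling stage, the mineral-layer classification
#' thresholds and the root random seed from which all per-stage substreams
#' are derived.
#'
#' @param growing_season_months named list mapping `site_id` to an integer
#'   vector of calendar months; sites not listed use `default_season`.
#'   Southern-hemisphere sites typically override with `c(10:12, 1:2)`.
#' @param default_season integer months of the default growing season
#'   (June-August).
#' @param outlier_k multiplier `k` of the `mean +/- k * sd` daily-flux
#'   outlier rule, applied once per dataset with treatments pooled.
#' @param mc_draws number of Monte Carlo soil samples per grid cell.
#' @param truncation_fraction lower truncation point of the soil sampling
#'   distributions, as a fraction of the target mean.
#' @param tn_soc_correlation correlation between total nitrogen (TN) and
#'   soil organic carbon (SOC) used when sampling soil inputs.
#' @param seed root integer seed; see [substream_seed()].
#' @param tn_max,soc_max,bd_min mineral-layer thresholds: a depth interval
#'   is mineral iff TN <= `tn_max` (g/g) and SOC <= `soc_max` (g/g) and
#'   bulk density >= `bd_min` (g/cm^3).
#' @param depth_max maximum soil depth considered, cm.
#'
#' @return an object of class `"tundresp_config"` (a named list).
#' @examples
#' cfg <- run_config(seed = 42)
#' site_season(cfg, "AUS_1")  # default June-August
#' @export
run_config <- function(growing_season_months = list(),
                       default_season = 6:8,
                       outlier_k = 3,
                       mc_draws = 100L,
                       truncation_fraction = 0.05,
                       tn_soc_correlation = 0.8273,
                       seed = 1L,
                       tn_max = 0.01,
                       soc_max = 0.1,
                       bd_min = 1,
                       depth_max = 60) {
  stopifnot(is.numeric(outlier_k), length(outlier_k) == 1L, outlier_k > 0)
  mc_draws <- as.integer(mc_draws)
  if (mc_draws < 2L) stop("mc_draws must be >= 2")
  if (!(truncation_fraction > 0 && truncation_fraction < 1)) {
    stop("truncation_fraction must lie in (0, 1)")
  }
  if (!(abs(tn_soc_correlation) < 1)) {
    stop("tn_soc_correlation must satisfy |rho| < 1")
  }
  if (!is.list(growing_season_months)) {
    stop("growing_season_months must be a named list of month vectors")
  }
  months_ok <- function(m) all(m %in% 1:12) && length(m) >= 1L
  if (!months_ok(default_season) ||
      !all(vapply(growing_season_months, months_ok, logical(1L)))) {
    stop("growing-season months must be integers in 1..12")
  }
  structure(list(
    growing_season_months = growing_season_months,
    default_season = as.integer(default_season),
    outlier_k = outlier_k,
    mc_draws = mc_draws,
    truncation_fraction = truncation_fraction,
    tn_soc_correlation = tn_soc_correlation,
    seed = as.integer(seed),
    tn_max = tn_max,
    soc_max = soc_max,
    bd_min = bd_min,
    depth_max = depth_max
  ), class = "tundresp_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; absent keys take
#' the defaults.
#'
#' @param path path to a YAML file.
#' @return a `"tundresp_config"` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Growing-season months for a site
#'
#' @param config a `"tundresp_config"` object.
#' @param site_id site identifier.
#' @return integer vector of months.
#' @export
site_season <- function(config, site_id) {
  m <- config$growing_season_months[[as.character(site_id)]]
  if (is.null(m)) config$default_season else as.integer(m)
}

#' Derive a per-stage random substream seed
#'
#' All randomness in the pipeline flows from the single root seed in the
#' configuration. Each stochastic stage draws its own seed
#' deterministically from the root seed and a stage label, so stages can be
#' re-run independently and the upscaling decomposition can replay
#' identical soil-draw substreams. The derivation is a fixed integer hash
#' (multiplicative, modulo the Mersenne prime 2^31 - 1) of the label mixed
#' with the root seed.
#'
#' @param seed root integer seed.
#' @param stage character stage label, e.g. `"soil_draws"`.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 48271) %% m
  as.integer(h) + 1L
}

#' @export
print.tundresp_config <- function(x, ...) {
  cat("<tundresp run configuration>\n")
  cat("  default growing season: months",
      paste(x$default_season, collapse = ","), "\n")
  if (length(x$growing_season_months)) {
    cat("  site overrides:",
        paste(names(x$growing_season_months), collapse = ", "), "\n")
  }
  cat("  outlier k:", x$outlier_k,
      "| MC draws:", x$mc_draws,
      "| truncation:", x$truncation_fraction, "of mean\n")
  cat("  TN-SOC correlation:", x$tn_soc_correlation, "\n")
  cat("  mineral thresholds: TN <=", x$tn_max, "g/g, SOC <=", x$soc_max,
      "g/g, BD >=", x$bd_min, "g/cm3, depth <=", x$depth_max, "cm\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
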
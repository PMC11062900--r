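#' Read a plot-level flux table
#'
#' Reads the canonical long-format CSV of plot-day ecosystem respiration
#' (ER) measurements: one row per plot per day, columns `site_id`,
#' `experiment_id`, `plot_id`, `treatment` (`control`/`warmed`), `date`
#' (ISO-8601), `er_value`, `er_unit`. Rows whose month falls outside the
#' configured growing season for their site are dropped (with a reported
#' count); the remaining rows are keyed by dataset, i.e. the unique
#' experiment x measurement-year combination.
#'
#' @param path delimited text file with a header.
#' @param config a [run_config()] object (growing-season month sets).
#' @param permissive if `TRUE`, rows with unparseable dates or numbers are
#'   dropped and reported instead of aborting the run.
#' @return a `data.frame` with the input columns plus `year`, carrying the
#'   number of season-filtered rows in attribute `"n_out_of_season"`.
#' @export
read_flux_table <- function(path, config = run_config(), permissive = FALSE) {
  required <- c("site_id", "experiment_id", "plot_id", "treatment",
                "date", "er_value", "er_unit")
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("flux table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[required]
  bad_treat <- !x$treatment %in% c("control", "warmed")
  if (any(bad_treat)) {
    stop("treatment must be 'control' or 'warmed'; offending row(s): ",
         paste(utils::head(which(bad_treat), 5L), collapse = ", "))
  }
  date <- as.Date(x$date, format = "%Y-%m-%d")
  er <- suppressWarnings(as.numeric(x$er_value))
  bad <- which(is.na(date) | is.na(er))
  if (length(bad)) {
    msg <- paste0(length(bad), " row(s) with unparseable date or er_value",
                  " (first: row ", bad[1L], ")")
    if (!permissive) stop(msg) else warning(msg, "; rows dropped")
    keep <- setdiff(seq_len(nrow(x)), bad)
    x <- x[keep, , drop = FALSE]
    date <- date[keep]
    er <- er[keep]
  }
  if (any(er < 0)) stop("er_value must be >= 0")
  x$date <- date
  x$er_value <- er
  x$year <- as.integer(format(date, "%Y"))
  month <- as.integer(format(date, "%m"))

  in_season <- vapply(seq_len(nrow(x)), function(i) {
    month[i] %in% site_season(config, x$site_id[i])
  }, logical(1L))
  n_out <- sum(!in_season)
  if (n_out) {
    message(n_out, " row(s) outside the configured growing season dropped")
  }
  x <- x[in_season, , drop = FALSE]

  key <- paste(x$experiment_id, x$plot_id, x$treatment, x$date, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (experiment_id, plot_id, treatment, date) record(s), ",
         "first: ", gsub("\r", " / ", key[duplicated(key)][1L]))
  }
  rownames(x) <- NULL
  attr(x, "n_out_of_season") <- n_out
  x
}

#' Read an environmental driver table
#'
#' Long-format driver summaries keyed by dataset: columns `experiment_id`,
#' `year`, `driver`, `statistic`, `value`. Recognized statistics are
#' `control_mean`, `control_sd`, `warmed_mean`, `warmed_sd`, `n_control`,
#' `n_warmed`; context-dependency drivers may carry control means only,
#' while indirect-effect drivers need the full six-statistic block.
#'
#' @param path delimited text file with a header.
#' @return a `data.frame` keyed by (experiment_id, year, driver, statistic).
#' @export
read_driver_table <- function(path) {
  required <- c("experiment_id", "year", "driver", "statistic", "value")
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("driver table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[required]
  stats_ok <- c("control_mean", "control_sd", "warmed_mean", "warmed_sd",
                "n_control", "n_warmed")
  bad <- !x$statistic %in% stats_ok
  if (any(bad)) {
    stop("unknown statistic(s): ",
         paste(unique(x$statistic[bad]), collapse = ", "))
  }
  x$year <- as.integer(x$year)
  x$value <- as.numeric(x$value)
  is_n <- x$statistic %in% c("n_control", "n_warmed")
  if (any(is_n & (is.na(x$value) | x$value < 0))) {
    stop("negative or missing replicate count in driver table")
  }
  key <- paste(x$experiment_id, x$year, x$driver, x$statistic, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate driver statistic for key: ",
         gsub("\r", " / ", key[duplicated(key)][1L]))
  }
  x
}

#' Reshape a driver table to one row per (dataset, driver)
#'
#' @param drivers output of [read_driver_table()].
#' @return wide `data.frame` with one column per statistic; statistics not
#'   supplied are `NA`.
#' @export
driver_summaries <- function(drivers) {
  dt <- data.table::as.data.table(drivers)
  wide <- data.table::dcast(
    dt, experiment_id + year + driver ~ statistic, value.var = "value")
  for (s in c("control_mean", "control_sd", "warmed_mean", "warmed_sd",
              "n_control", "n_warmed")) {
    if (!s %in% names(wide)) wide[[s]] <- NA_real_
  }
  as.data.frame(wide)
}
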
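#' Assign warming-duration age classes
#'
#' Durations (measurement year minus treatment start year; 0 is the first
#' summer of warming) are grouped into four classes by closed integer
#' intervals: 0-4, 5-9, 10-14 and 15+.
#'
#' @param duration integer vector of durations (>= 0).
#' @return a factor with levels `"0-4", "5-9", "10-14", "15+"`.
#' @export
assign_age_class <- function(duration) {
  if (any(is.na(duration)) || any(duration < 0)) {
    stop("durations must be known and non-negative")
  }
  cut(duration, breaks = c(-0.5, 4.5, 9.5, 14.5, Inf),
      labels = c("0-4", "5-9", "10-14", "15+"))
}

#' McFadden pseudo-R-squared
#'
#' `1 - logLik_ML(model) / logLik_ML(null)`, both models fitted by maximum
#' likelihood on the identical complete-case subset.
#'
#' @param fit_ml,null_ml `"meta_fit"` objects with `method = "ML"`.
#' @return a scalar.
#' @export
pseudo_r2 <- function(fit_ml, null_ml) {
  stopifnot(fit_ml$method == "ML", null_ml$method == "ML",
            fit_ml$k == null_ml$k)
  1 - fit_ml$loglik / null_ml$loglik
}

#' Single-factor metaregression
#'
#' Fits one moderator at a time against the effect sizes, with the full
#' random-effects structure, on the complete-case subset for that
#' moderator (no imputation; the subset size is reported). Continuous
#' moderators enter unstandardized so slopes stay on the driver scale;
#' categorical moderators are dummy-coded against their first level.
#' Returns the REML fit, the heterogeneity/moderator tests, and McFadden
#' pseudo-R-squared from ML refits of the model and the intercept-only
#' null on the same subset.
#'
#' @param es effect-size `data.frame` (`estimate`, `variance`,
#'   `experiment_id`, `year`).
#' @param moderators `data.frame` keyed by `experiment_id`, `year` with
#'   one column per moderator.
#' @param name column of `moderators` to test.
#' @param min_n minimum number of datasets with moderator values
#'   (default 3).
#' @return a list of class `"single_factor_fit"`: `fit`, `tests`,
#'   `pseudo_r2`, `n`, `moderator`, and a one-row `summary` data.frame.
#' @export
fit_single_factor <- function(es, moderators, name, min_n = 3L) {
  stopifnot(name %in% names(moderators))
  es <- es[setdiff(names(es), name)]  # the moderator table is authoritative
  m <- merge(es, moderators[c("experiment_id", "year", name)],
             by = c("experiment_id", "year"))
  m <- m[!is.na(m[[name]]), , drop = FALSE]
  if (nrow(m) < min_n) {
    stop("moderator '", name, "': only ", nrow(m),
         " dataset(s) with values (need >= ", min_n, ")")
  }
  x <- m[[name]]
  if (is.character(x)) x <- factor(x)
  no_contrast <- if (is.factor(x)) nlevels(droplevels(x)) < 2L
                 else stats::var(x) == 0
  if (no_contrast) stop("moderator '", name, "': no contrast")
  m[[name]] <- x
  f <- stats::as.formula(paste("~", paste0("`", name, "`")))
  fit <- meta_fit(m, mods = f, method = "REML")
  tests <- q_statistics(fit)
  fit_ml <- meta_fit(m, mods = f, method = "ML")
  null_ml <- meta_fit(m, mods = ~ 1, method = "ML")
  r2 <- pseudo_r2(fit_ml, null_ml)
  ci <- wald_ci(fit)
  slope <- ci[ci$term != "(Intercept)", , drop = FALSE]
  structure(list(
    moderator = name, n = nrow(m), fit = fit, tests = tests,
    pseudo_r2 = r2,
    summary = data.frame(
      moderator = name, n = nrow(m),
      term = slope$term, estimate = slope$estimate, se = slope$se,
      ci_lb = slope$ci_lb, ci_ub = slope$ci_ub,
      Qm = tests$Qm, Qm_df = tests$Qm_df, Qm_p = tests$Qm_p,
      QE = tests$QE, pseudo_r2 = r2)
  ), class = "single_factor_fit")
}

#' @export
print.single_factor_fit <- function(x, ...) {
  cat("<single-factor metaregression> moderator:", x$moderator,
      " n =", x$n, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Temporal patterns of the warming response
#'
#' Three views of how effects evolve with warming duration:
#' (a) an age-class factor model giving per-class mean effects (with tests
#' against zero) and the omnibus Qm for class differences; (b) a duration
#' slope within each age class (classes with fewer than 3 datasets or no
#' duration contrast report `NA`); (c) a single duration slope across all
#' datasets.
#'
#' @param es effect sizes with a `duration` column.
#' @return a list of class `"temporal_analysis"`: `class_means`
#'   (per-class estimate/CI/p), `class_qm` (heterogeneity tests of the
#'   factor model), `class_slopes` (per-class duration slopes), and
#'   `overall_slope` (a `"single_factor_fit"`).
#' @export
temporal_analysis <- function(es) {
  if (!"duration" %in% names(es) || any(is.na(es$duration))) {
    stop("durations must be known for all effects")
  }
  es$age_class <- assign_age_class(es$duration)

  present <- levels(es$age_class)[table(es$age_class) > 0]
  es$age_class <- factor(as.character(es$age_class), levels = present)

  # (a) class means and class importance (a single observed class reduces
  # to the intercept-only pooled mean)
  fit_means <- if (nlevels(es$age_class) > 1L) {
    meta_fit(es, mods = ~ 0 + age_class)
  } else {
    meta_fit(es)
  }
  cm <- wald_ci(fit_means)
  cm$term <- if (nlevels(es$age_class) > 1L) {
    sub("^age_class", "", cm$term)
  } else {
    levels(es$age_class)
  }
  names(cm)[names(cm) == "term"] <- "age_class"
  cm$n <- as.integer(table(es$age_class)[cm$age_class])
  class_qm <- if (nlevels(es$age_class) > 1L) {
    q_statistics(meta_fit(es, mods = ~ age_class))
  } else NULL

  # (b) within-class duration slopes (all four canonical classes; absent
  # or contrast-free classes report NA)
  slopes <- lapply(c("0-4", "5-9", "10-14", "15+"), function(cl) {
    sub <- es[as.character(es$age_class) == cl, , drop = FALSE]
    if (nrow(sub) < 3L || stats::var(sub$duration) == 0) {
      return(data.frame(age_class = cl, n = nrow(sub), slope = NA_real_,
                        se = NA_real_, Qm = NA_real_, Qm_p = NA_real_))
    }
    f <- meta_fit(sub, mods = ~ duration)
    qs <- q_statistics(f)
    data.frame(age_class = cl, n = nrow(sub),
               slope = f$beta[["duration"]], se = f$se[["duration"]],
               Qm = qs$Qm, Qm_p = qs$Qm_p)
  })
  class_slopes <- do.call(rbind, slopes)

  # (c) overall duration slope
  overall <- fit_single_factor(
    es, es[c("experiment_id", "year", "duration")], "duration")

  structure(list(class_means = cm, class_qm = class_qm,
                 class_slopes = class_slopes, overall_slope = overall),
            class = "temporal_analysis")
}

#' @export
print.temporal_analysis <- function(x, ...) {
  cat("Per-class mean effects:\n")
  print(x$class_means, digits = 3)
  if (!is.null(x$class_qm)) {
    cat("\nAge-class importance:\n")
    print(x$class_qm)
  }
  cat("\nPer-class duration slopes:\n")
  print(x$class_slopes, digits = 3)
  cat("\nOverall duration slope:\n")
  print(x$overall_slope$summary, digits = 3)
  invisible(x)
}

#' Prediction with standard error at new moderator values
#'
#' Convenience wrapper around [predict.meta_fit()] for the upscaling
#' stage.
#'
#' @param fit a converged `"meta_fit"`.
#' @param newdata `data.frame` of moderator values.
#' @return `data.frame(fit, se)`.
#' @export
predict_with_se <- function(fit, newdata) {
  if (!fit$converged) stop("refusing to predict from a non-converged fit")
  predict(fit, newdata = newdata)
}

#' Pairwise moderator correlation report
#'
#' Pre-fit collinearity screen: pairwise complete-case Pearson
#' correlations among numeric moderators, exported for inspection (no
#' automatic exclusion is applied).
#'
#' @param moderators moderator `data.frame`.
#' @return correlation matrix of the numeric columns.
#' @export
moderator_correlations <- function(moderators) {
  num <- moderators[vapply(moderators, is.numeric, logical(1L))]
  num <- num[setdiff(names(num), c("year"))]
  stats::cor(num, use = "pairwise.complete.obs")
}
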
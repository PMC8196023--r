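# Posterior contrasts of paired phenophases: changes in the duration of the
# growth (green up -> leaf senescence), flowering (start -> end) and
# fruiting (fruiting -> seed dispersal) periods, plus baseline timing from
# treatment-only model intercepts.

#' Phenoperiod duration contrast
#'
#' The change in a phenoperiod's duration under warming is the difference
#' between the end phenophase's treatment-effect posterior and the start
#' phenophase's, both in day units. The two fits are independent, so their
#' draws carry no joint ordering; draws are paired by index after a
#' fixed-seed random permutation of the end draws, which makes the interval
#' of the difference reproducible without imposing spurious correlation.
#'
#' @param fit_start,fit_end `posterior_fit` objects for the start and end
#'   phenophases (treatment-only models).
#' @param scaling_start,scaling_end optional scaling records; default to the
#'   ones carried by the fits.
#' @param seed seed for the pairing permutation.
#' @param period optional period label; inferred from [phenoperiod_pairs()]
#'   when the two phenophases match a known pair.
#' @return List of class `duration_contrast`: `period`, `start`, `end`,
#'   `draws` (days; positive = lengthening), `mean`, `sd`, `eti90`, `eti95`,
#'   `effect_90`, `effect_95`, `n_draws`.
#' @export
duration_contrast <- function(fit_start, fit_end, scaling_start = NULL,
                              scaling_end = NULL, seed = 1, period = NULL) {
  stopifnot(inherits(fit_start, "posterior_fit"),
            inherits(fit_end, "posterior_fit"))
  days_start <- beta_days(fit_start, scaling_start)
  days_end <- beta_days(fit_end, scaling_end)
  n <- min(length(days_start), length(days_end))
  set.seed(seed)
  days_end <- days_end[sample.int(length(days_end))]
  d <- days_end[seq_len(n)] - days_start[seq_len(n)]
  if (is.null(period)) {
    pp <- phenoperiod_pairs()
    hit <- pp$start == fit_start$phenophase & pp$end == fit_end$phenophase
    period <- if (any(hit)) pp$period[hit] else
      paste(fit_end$phenophase, "-", fit_start$phenophase)
  }
  e90 <- compute_eti(d, 0.90)
  e95 <- compute_eti(d, 0.95)
  structure(list(period = period, start = fit_start$phenophase,
                 end = fit_end$phenophase, draws = d,
                 mean = mean(d), sd = sd(d), eti90 = e90, eti95 = e95,
                 effect_90 = unname(e90[1] > 0 | e90[2] < 0),
                 effect_95 = unname(e95[1] > 0 | e95[2] < 0),
                 n_draws = n),
            class = "duration_contrast")
}

# internal: treatment-effect draws of a fit in day units
beta_days <- function(fit, scaling = NULL) {
  if (is.null(scaling)) scaling <- fit$scaling
  if (is.null(scaling)) stop("no scaling record for ", fit$phenophase)
  sc <- scaling$scale[match(fit$phenophase, scaling$phenophase)]
  if (is.na(sc)) stop("scaling record lacks phenophase ", fit$phenophase)
  fit$draws[, "beta"] * sc
}

# internal: intercept draws of a fit in DOY units
alpha_doy <- function(fit, scaling = NULL) {
  if (is.null(scaling)) scaling <- fit$scaling
  i <- match(fit$phenophase, scaling$phenophase)
  if (is.na(i)) stop("scaling record lacks phenophase ", fit$phenophase)
  scaling$center[i] + fit$draws[, "alpha"] * scaling$scale[i]
}

#' Baseline phenophase timing and phenoperiod lengths
#'
#' Un-standardizes the intercepts of treatment-only fits to the day-of-year
#' scale, giving the average day each phenophase occurred, and differences
#' paired phenophases to estimate mean phenoperiod lengths (e.g. the
#' growing-season length between green up and leaf senescence).
#'
#' @param fits named list of `posterior_fit` objects, names = phenophases.
#' @param scaling optional shared scaling record.
#' @param seed seed for the pairing permutation of period-length draws.
#' @return List: `baseline` (data frame `phenophase`, `mean_doy`, `sd`) and
#'   `periods` (data frame `period`, `start`, `end`, `length_mean`,
#'   `length_sd`; only pairs with both fits present).
#' @export
baseline_intercepts <- function(fits, scaling = NULL, seed = 1) {
  stopifnot(length(fits) > 0)
  doy_draws <- lapply(fits, alpha_doy, scaling = scaling)
  baseline <- data.frame(
    phenophase = names(fits),
    mean_doy = vapply(doy_draws, mean, numeric(1)),
    sd = vapply(doy_draws, sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pp <- phenoperiod_pairs()
  rows <- list()
  set.seed(seed)
  for (i in seq_len(nrow(pp))) {
    if (!(pp$start[i] %in% names(fits)) || !(pp$end[i] %in% names(fits))) {
      message("period '", pp$period[i], "' skipped: missing phenophase fit")
      next
    }
    ds <- doy_draws[[pp$start[i]]]
    de <- doy_draws[[pp$end[i]]]
    n <- min(length(ds), length(de))
    de <- de[sample.int(length(de))]
    len <- de[seq_len(n)] - ds[seq_len(n)]
    rows[[pp$period[i]]] <- data.frame(
      period = pp$period[i], start = pp$start[i], end = pp$end[i],
      length_mean = mean(len), length_sd = sd(len),
      stringsAsFactors = FALSE
    )
  }
  periods <- if (length(rows)) do.call(rbind, rows) else
    data.frame(period = character(), start = character(), end = character(),
               length_mean = numeric(), length_sd = numeric())
  rownames(periods) <- NULL
  list(baseline = baseline, periods = periods)
}

#' @export
print.duration_contrast <- function(x, ...) {
  cat("Phenoperiod duration contrast:", x$period,
      sprintf("(%s -> %s)\n", x$start, x$end))
  cat(sprintf("  change: %+.2f +/- %.2f days; 90%% ETI [%.2f, %.2f]; ",
              x$mean, x$sd, x$eti90[1], x$eti90[2]))
  cat(if (x$effect_90) "effect at 90%\n" else "no effect at 90%\n")
  invisible(x)
}
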
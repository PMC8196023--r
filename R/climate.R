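# Ambient-climate predictors: donor-regression infilling of daily series,
# 30-day phenophase-specific climate windows, site means and site-year
# anomalies, and the group-means-centered predictors for the interaction
# models.
#
# Sign convention: anomalies are warm-year-positive (yearly window mean minus
# the all-year site mean), recorded in the output metadata.

#' Infill missing daily temperatures
#'
#' Fills missing days of a site's daily mean temperature series by linear
#' regression of the target on a donor series over their shared non-missing
#' days. Days the regression cannot fill (no donor, or a degenerate fit)
#' fall back to the long-term day-of-year mean across the target's other
#' years; days that neither source can fill stay missing. Every filled day
#' is flagged.
#'
#' @param series data frame `site`, `year`, `doy`, `tmean`, `is_missing` for
#'   one site (multiple years allowed).
#' @param donor_series optional data frame with the same columns (any site)
#'   overlapping the target by `year` x `doy`.
#' @return `series` with missing `tmean` filled where possible and a logical
#'   `infilled` column.
#' @export
infill_missing <- function(series, donor_series = NULL) {
  out <- series
  out$infilled <- FALSE
  miss <- which(is.na(out$tmean))
  if (!length(miss)) return(out)

  if (!is.null(donor_series)) {
    key_t <- paste(out$year, out$doy)
    key_d <- paste(donor_series$year, donor_series$doy)
    donor_t <- donor_series$tmean[match(key_t, key_d)]
    shared <- !is.na(out$tmean) & !is.na(donor_t)
    if (sum(shared) >= 10 && sd(donor_t[shared]) > 0) {
      fit <- lm(out$tmean[shared] ~ donor_t[shared])
      pred <- coef(fit)[1] + coef(fit)[2] * donor_t[miss]
      fill <- !is.na(pred)
      out$tmean[miss[fill]] <- pred[fill]
      out$infilled[miss[fill]] <- TRUE
      miss <- miss[!fill]
    }
  }
  if (length(miss)) {
    doy_mean <- tapply(out$tmean[!is.na(out$tmean)],
                       out$doy[!is.na(out$tmean)], mean)
    pred <- doy_mean[as.character(out$doy[miss])]
    fill <- !is.na(pred)
    out$tmean[miss[fill]] <- pred[fill]
    out$infilled[miss[fill]] <- TRUE
  }
  out
}

#' Phenophase-specific climate window
#'
#' The 30 days up to and including a species' mean event day at a site:
#' `[mean - 30, mean]`, clipped at DOY 1.
#'
#' @param mean_event_doy numeric vector of mean event days.
#' @return Data frame `start`, `end` (integer DOY), one row per input.
#' @export
#' @examples
#' compute_climate_window(180) # 150 -- 180
compute_climate_window <- function(mean_event_doy) {
  end <- round(mean_event_doy)
  start <- pmax(end - 30L, 1L)
  if (any(end - 30L < 1L)) {
    message("climate window(s) clipped at DOY 1")
  }
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' Mean event days for climate windows
#'
#' Mean interval midpoint (day scale) per species x site x phenophase across
#' all years and both treatments, defining where each species' climate
#' window sits at each site.
#'
#' @param intervals prepared observation table with `midpoint` (day scale).
#' @return Data frame `species`, `site`, `phenophase`, `mean_doy`, with
#'   window `start`/`end` columns appended.
#' @export
climate_windows <- function(intervals) {
  ag <- aggregate(midpoint ~ species + site + phenophase, data = intervals,
                  FUN = mean)
  names(ag)[names(ag) == "midpoint"] <- "mean_doy"
  cbind(ag, compute_climate_window(ag$mean_doy))
}

#' Site means and site-year anomalies over climate windows
#'
#' For each species x site x phenophase window: the per-year window mean
#' temperature, the count of infilled window days (years with more than
#' `max_infilled` infilled days, or any unfilled day, are dropped), the site
#' mean across retained years, and the warm-year-positive anomaly (yearly
#' mean minus site mean).
#'
#' @param filled_series infilled daily series (all sites) with `infilled`
#'   flags, as from [infill_missing()].
#' @param windows window table from [climate_windows()].
#' @param max_infilled maximum infilled days tolerated per window-year.
#' @return Data frame of class `climate_window_stats`: `species`, `site`,
#'   `phenophase`, `start`, `end`, `year`, `year_mean`, `n_infilled`,
#'   `site_mean`, `anomaly`. Attribute `anomaly_sign` records the
#'   convention.
#' @export
site_anomaly_means <- function(filled_series, windows, max_infilled = 5) {
  res <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    s <- filled_series[filled_series$site == win$site &
                         filled_series$doy >= win$start &
                         filled_series$doy <= win$end, ]
    if (nrow(s) == 0L) next
    ym <- aggregate(cbind(tmean = s$tmean, infilled = s$infilled,
                          unfilled = is.na(s$tmean)),
                    by = list(year = s$year), FUN = mean)
    ym$n_infilled <- round(ym$infilled * (win$end - win$start + 1L))
    keep <- ym$n_infilled <= max_infilled & ym$unfilled == 0
    ym <- ym[keep, , drop = FALSE]
    if (nrow(ym) == 0L) next
    site_mean <- mean(ym$tmean)
    res[[w]] <- data.frame(
      species = win$species, site = win$site, phenophase = win$phenophase,
      start = win$start, end = win$end, year = ym$year,
      year_mean = ym$tmean, n_infilled = ym$n_infilled,
      site_mean = site_mean, anomaly = ym$tmean - site_mean,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(species = character(), site = character(),
                      phenophase = character(), start = integer(),
                      end = integer(), year = integer(),
                      year_mean = numeric(), n_infilled = integer(),
                      site_mean = numeric(), anomaly = numeric())
  }
  rownames(out) <- NULL
  attr(out, "anomaly_sign") <- "warm_year_positive (yearly - site mean)"
  class(out) <- c("climate_window_stats", "data.frame")
  out
}

#' Group-means-centered climate predictors
#'
#' Joins window statistics to replicate estimates by species x site x
#' phenophase x year and returns the two temperature predictors of the
#' climate interaction model: the between-site component `site_temp`
#' (site-level window mean, centered on the grand mean so the treatment main
#' effect stays interpretable) and the within-site component `temp_anomaly`
#' (site-year deviation, zero-mean within each site stratum by
#' construction). Replicates without matching climate (window-years dropped
#' by the infill cap) get NA and are excluded from climate models only.
#'
#' @param replicates a `replicate_estimates` table.
#' @param stats a `climate_window_stats` table.
#' @return `replicates` with `site_temp` and `temp_anomaly` columns;
#'   attribute `site_temp_center` records the subtracted grand mean and
#'   `anomaly_sign` the sign convention.
#' @export
group_means_center <- function(replicates, stats) {
  key_r <- paste(replicates$species, replicates$site, replicates$phenophase,
                 replicates$year)
  key_s <- paste(stats$species, stats$site, stats$phenophase, stats$year)
  idx <- match(key_r, key_s)
  site_mean <- stats$site_mean[idx]
  center <- mean(unique(data.frame(k = paste(stats$species, stats$site,
                                             stats$phenophase),
                                   m = stats$site_mean))$m)
  out <- replicates
  out$site_temp <- site_mean - center
  out$temp_anomaly <- stats$anomaly[idx]
  n_un <- sum(is.na(idx))
  if (n_un > 0) {
    message(n_un, " replicate(s) without matching climate window-years; ",
            "excluded from climate models")
  }
  attr(out, "site_temp_center") <- center
  attr(out, "anomaly_sign") <- attr(stats, "anomaly_sign")
  attr(out, "scaling") <- attr(replicates, "scaling")
  class(out) <- class(replicates)
  out
}
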
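# Synthetic ITEX-like data generation: experiment design, ground-truth
# parameters, true event days, census censoring, climate series, snowmelt.

#' Generate a multi-site warming-experiment design
#'
#' Builds a long-format design table emulating a multi-site tundra warming
#' experiment: sites contain subsites, subsites contain paired warmed (OTC)
#' and control (CTL) plots, and each plot is observed for a set of species,
#' years and phenophases. Species are assigned to a random subset of sites to
#' mimic incomplete species coverage across a network; sites may observe
#' different numbers of years.
#'
#' Defaults emulate the scale of the International Tundra Experiment
#' synthesis this package models: 18 sites, ~3 subsites per site, >100
#' species, observation series up to 20 years, and all six phenophases.
#'
#' @param n_sites,n_subsites_per_site,n_species,n_years,n_plots_per_treatment
#'   design dimensions, all >= 1. `n_years` is the maximum series length; with
#'   `vary_years = TRUE` each site observes a random 1..`n_years`-year span
#'   ending in the final year.
#' @param seed integer seed fixing the random stream.
#' @param species_site_prob probability that a given species is monitored at a
#'   given site (each species is guaranteed at least one site and each site at
#'   least one species).
#' @param vary_years logical; if `TRUE` sites differ in series length.
#' @param phenophases character subset of [phenophase_levels()].
#' @return A data frame with one row per plot x species x year x phenophase:
#'   columns `site`, `subsite`, `plot`, `treatment` ("OTC"/"CTL"), `species`,
#'   `year`, `phenophase`, `latitude`, `moisture` ("dry"/"moist"/"wet"),
#'   `deployment` ("year_round"/"summer_only"), `years_of_warming`.
#' @export
#' @examples
#' d <- generate_design(2, 2, 3, 2, 5, seed = 1, vary_years = FALSE)
#' length(unique(d$subsite)) # 4
#' length(unique(d$plot))    # 40
generate_design <- function(n_sites = 18, n_subsites_per_site = 3,
                            n_species = 110, n_years = 20,
                            n_plots_per_treatment = 5, seed = 1,
                            species_site_prob = 0.3, vary_years = TRUE,
                            phenophases = phenophase_levels()) {
  counts <- c(n_sites, n_subsites_per_site, n_species, n_years,
              n_plots_per_treatment)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be positive integers")
  }
  check_phenophase(phenophases)
  set.seed(seed)

  sites <- sprintf("site%02d", seq_len(n_sites))
  latitude <- round(runif(n_sites, 40, 79), 2)
  deployment <- sample(c("year_round", "summer_only"), n_sites, replace = TRUE)
  names(latitude) <- names(deployment) <- sites

  # species -> site membership; guarantee non-empty margins
  memb <- matrix(runif(n_species * n_sites) < species_site_prob,
                 nrow = n_species)
  for (i in seq_len(n_species)) {
    if (!any(memb[i, ])) memb[i, sample.int(n_sites, 1)] <- TRUE
  }
  for (k in seq_len(n_sites)) {
    if (!any(memb[, k])) memb[sample.int(n_species, 1), k] <- TRUE
  }
  species <- sprintf("species%03d", seq_len(n_species))

  last_year <- 2000L + n_years
  site_first_year <- if (vary_years && n_years > 1L) {
    last_year - sample.int(n_years, n_sites, replace = TRUE) + 1L
  } else {
    rep(2001L, n_sites)
  }
  names(site_first_year) <- sites

  blocks <- vector("list", n_sites * n_subsites_per_site)
  b <- 0L
  for (k in seq_len(n_sites)) {
    spp_k <- species[memb[, k]]
    years_k <- seq.int(site_first_year[k], last_year)
    for (j in seq_len(n_subsites_per_site)) {
      subsite <- sprintf("%s_ss%d", sites[k], j)
      moisture <- sample(c("dry", "moist", "wet"), 1)
      plots <- c(sprintf("%s_otc%d", subsite, seq_len(n_plots_per_treatment)),
                 sprintf("%s_ctl%d", subsite, seq_len(n_plots_per_treatment)))
      trt <- rep(c("OTC", "CTL"), each = n_plots_per_treatment)
      g <- expand.grid(plot_i = seq_along(plots), species = spp_k,
                       year = years_k, phenophase = phenophases,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      b <- b + 1L
      blocks[[b]] <- data.frame(
        site = sites[k], subsite = subsite, plot = plots[g$plot_i],
        treatment = trt[g$plot_i], species = g$species, year = g$year,
        phenophase = g$phenophase, latitude = latitude[k],
        moisture = moisture, deployment = deployment[k],
        years_of_warming = g$year - site_first_year[k] + 1L,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Ground-truth parameters for the generative model
#'
#' Assembles the generative counterpart of the stage-2 hierarchical model:
#' per-phenophase global intercepts (baseline event day of year) and warming
#' effects (days; negative = advance), group-level intercept/slope standard
#' deviations and correlations for species, site, site:year and site:subsite,
#' the residual SD, interaction coefficients for the spatiotemporal
#' predictors, and snowmelt settings.
#'
#' Default effect sizes correspond to the treatment shifts this package is
#' designed to detect: advances of roughly 0.7 (green up), 2.4 (flowering),
#' 1.9 (end of flowering), 2.6 (fruiting) and 2.9 (seed dispersal) days and a
#' 0.8-day delay of leaf senescence under ~1.4 degC of chamber warming.
#' Default intercepts give a ~50-day baseline growing season (green up to
#' senescence) and an ~18-day flowering period.
#'
#' @param intercept named numeric, baseline event DOY per phenophase.
#' @param trt_effect named numeric, warming effect in days per phenophase.
#' @param sd_species,sd_site,sd_site_year,sd_site_subsite length-2 numeric
#'   `c(intercept SD, slope SD)` in days (>= 0).
#' @param rho length-4 numeric in \[-1, 1\]: intercept-slope correlation for
#'   species, site, site:year, site:subsite.
#' @param sigma_resid residual SD in days (> 0).
#' @param interactions named numeric coefficients (days per unit predictor)
#'   modifying the warming effect: `years_of_warming`, `latitude`,
#'   `moisture_moist`, `moisture_wet`, `deployment_summer_only`, `site_temp`
#'   (per degC of site offset), `temp_anomaly` (per degC of site-year
#'   anomaly). Unnamed entries default to 0.
#' @param snowmelt list with `mean`, `sd` (DOY of plot snowmelt) and
#'   `otc_advance` (days by which chambers advance snowmelt where deployed
#'   year-round).
#' @return An object of class `truth_parameters`.
#' @export
make_truth <- function(intercept = c(green_up = 160, flowering = 175,
                                     end_of_flowering = 193, fruiting = 198,
                                     seed_dispersal = 208,
                                     leaf_senescence = 210),
                       trt_effect = c(green_up = -0.7, flowering = -2.4,
                                      end_of_flowering = -1.9,
                                      fruiting = -2.6, seed_dispersal = -2.9,
                                      leaf_senescence = 0.8),
                       sd_species = c(4, 1), sd_site = c(6, 1.5),
                       sd_site_year = c(3, 0.75), sd_site_subsite = c(2, 0.75),
                       rho = c(0, 0, 0, 0), sigma_resid = 5,
                       interactions = NULL,
                       snowmelt = list(mean = 140, sd = 4, otc_advance = 1.02)) {
  check_phenophase(names(intercept))
  check_phenophase(names(trt_effect))
  gsd <- data.frame(
    group = c("species", "site", "site_year", "site_subsite"),
    sd_intercept = c(sd_species[1], sd_site[1], sd_site_year[1],
                     sd_site_subsite[1]),
    sd_slope = c(sd_species[2], sd_site[2], sd_site_year[2],
                 sd_site_subsite[2]),
    rho = rho, stringsAsFactors = FALSE
  )
  if (any(gsd$sd_intercept < 0) || any(gsd$sd_slope < 0)) {
    stop("group SDs must be non-negative")
  }
  if (any(abs(gsd$rho) > 1)) stop("correlations must lie in [-1, 1]")
  if (sigma_resid <= 0) stop("sigma_resid must be positive")
  ia <- c(years_of_warming = 0, latitude = 0, moisture_moist = 0,
          moisture_wet = 0, deployment_summer_only = 0, site_temp = 0,
          temp_anomaly = 0)
  if (!is.null(interactions)) {
    bad <- setdiff(names(interactions), names(ia))
    if (length(bad)) stop("unknown interaction coefficient(s): ",
                          paste(bad, collapse = ", "))
    ia[names(interactions)] <- unlist(interactions)
  }
  structure(list(intercept = intercept, trt_effect = trt_effect,
                 group_sd = gsd, sigma_resid = sigma_resid,
                 interactions = ia, snowmelt = snowmelt,
                 site_offsets = NULL, year_anomalies = NULL),
            class = "truth_parameters")
}

# internal: bivariate-normal group deviations for one grouping factor,
# one draw per phenophase x level
draw_deviations <- function(levels, phenophases, sd_i, sd_s, rho) {
  g <- expand.grid(level = levels, phenophase = phenophases,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  z1 <- rnorm(nrow(g))
  z2 <- rnorm(nrow(g))
  g$dev_intercept <- sd_i * z1
  g$dev_slope <- sd_s * (rho * z1 + sqrt(1 - rho^2) * z2)
  g
}

#' Simulate true phenological event days
#'
#' Draws one true (real-valued) event day of year per design row from the
#' generative hierarchical model: global intercept plus group deviations
#' (species, site, site:year, site:subsite), plus, on warmed plots, the global
#' warming effect, group slope deviations and any interaction terms, plus
#' residual noise.
#'
#' Interaction terms involving ambient temperature (`site_temp`,
#' `temp_anomaly`) require `truth$site_offsets` / `truth$year_anomalies`,
#' which [simulate_climate()] provides (see [attach_climate_truth()]).
#'
#' @param design design table from [generate_design()].
#' @param truth a `truth_parameters` object.
#' @param seed integer seed.
#' @param enforce_order if `TRUE`, residuals are redrawn (rejection) until
#'   phenophases occur in seasonal order within each plot x species x year;
#'   off by default since each phenophase is modeled independently.
#' @return `design` with a numeric `true_doy` column; realized group
#'   deviations are attached as `attr(, "deviations")`.
#' @export
simulate_events <- function(design, truth, seed = 1, enforce_order = FALSE) {
  stopifnot(inherits(truth, "truth_parameters"))
  phases <- unique(design$phenophase)
  missing_ph <- setdiff(phases, names(truth$intercept))
  if (length(missing_ph)) {
    stop("truth lacks parameters for phenophase(s): ",
         paste(missing_ph, collapse = ", "))
  }
  set.seed(seed)

  design$site_year <- paste(design$site, design$year, sep = ":")
  keys <- list(species = design$species, site = design$site,
               site_year = design$site_year, site_subsite = design$subsite)
  gsd <- truth$group_sd
  devs <- list()
  dev_i <- dev_s <- numeric(nrow(design))
  for (g in gsd$group) {
    row <- gsd[gsd$group == g, ]
    d <- draw_deviations(unique(keys[[g]]), phases,
                         row$sd_intercept, row$sd_slope, row$rho)
    idx <- match(paste(keys[[g]], design$phenophase),
                 paste(d$level, d$phenophase))
    dev_i <- dev_i + d$dev_intercept[idx]
    dev_s <- dev_s + d$dev_slope[idx]
    d$group <- g
    devs[[g]] <- d
  }

  trt <- as.numeric(design$treatment == "OTC")
  slope <- truth$trt_effect[design$phenophase] + dev_s +
    interaction_shift(design, truth)
  eta <- truth$intercept[design$phenophase] + dev_i + trt * slope
  doy <- eta + rnorm(nrow(design), 0, truth$sigma_resid)

  if (enforce_order) {
    ord <- match(design$phenophase, phenophase_levels())
    unit <- paste(design$plot, design$species, design$year)
    for (it in 1:50) {
      bad <- unlist(lapply(split(seq_len(nrow(design)), unit), function(i) {
        i <- i[order(ord[i])]
        if (is.unsorted(doy[i])) i else integer(0)
      }), use.names = FALSE)
      if (!length(bad)) break
      doy[bad] <- eta[bad] + rnorm(length(bad), 0, truth$sigma_resid)
    }
  }

  design$true_doy <- as.numeric(doy)
  design$site_year <- NULL
  attr(design, "deviations") <- do.call(rbind, devs)
  design
}

# internal: per-row warming-effect shift from interaction coefficients
interaction_shift <- function(design, truth) {
  ia <- truth$interactions
  shift <- numeric(nrow(design))
  if (ia[["years_of_warming"]] != 0) {
    yw <- design$years_of_warming
    shift <- shift + ia[["years_of_warming"]] * (yw - mean(unique(yw)))
  }
  if (ia[["latitude"]] != 0) {
    site_lat <- tapply(design$latitude, design$site, "[", 1)
    shift <- shift + ia[["latitude"]] * (design$latitude - mean(site_lat))
  }
  if (ia[["moisture_moist"]] != 0 || ia[["moisture_wet"]] != 0) {
    shift <- shift + ia[["moisture_moist"]] * (design$moisture == "moist") +
      ia[["moisture_wet"]] * (design$moisture == "wet")
  }
  if (ia[["deployment_summer_only"]] != 0) {
    shift <- shift +
      ia[["deployment_summer_only"]] * (design$deployment == "summer_only")
  }
  if (ia[["site_temp"]] != 0) {
    off <- truth$site_offsets
    if (is.null(off)) stop("site_temp interaction requires climate truth; ",
                           "run simulate_climate()/attach_climate_truth()")
    shift <- shift + ia[["site_temp"]] * (off[design$site] - mean(off))
  }
  if (ia[["temp_anomaly"]] != 0) {
    an <- truth$year_anomalies
    if (is.null(an)) stop("temp_anomaly interaction requires climate truth; ",
                          "run simulate_climate()/attach_climate_truth()")
    idx <- match(paste(design$site, design$year),
                 paste(an$site, an$year))
    shift <- shift + ia[["temp_anomaly"]] * an$anomaly[idx]
  }
  shift
}

#' Census-schedule configuration
#'
#' @param interval_min,interval_max bounds (days) of the uniform census
#'   cadence between consecutive visits.
#' @param season_start,season_end DOY bounds of the census season; the first
#'   visit falls uniformly within a week after `season_start`.
#' @param p_late_start probability that a plot-year's censusing starts
#'   `late_start_delay` days late, so early events precede the first visit
#'   (exercising the fallback lower-bound rule downstream).
#' @param late_start_delay days added to the first visit for late starts.
#' @param random_missing_prob probability that a recorded event is lost at
#'   random (in addition to events after the last visit, which are always
#'   missing).
#' @return A list of class `census_config`.
#' @export
census_config <- function(interval_min = 3, interval_max = 10,
                          season_start = 130, season_end = 280,
                          p_late_start = 0.05, late_start_delay = 40,
                          random_missing_prob = 0.05) {
  stopifnot(interval_min >= 1, interval_max >= interval_min,
            season_end > season_start)
  structure(list(interval_min = interval_min, interval_max = interval_max,
                 season_start = season_start, season_end = season_end,
                 p_late_start = p_late_start,
                 late_start_delay = late_start_delay,
                 random_missing_prob = random_missing_prob),
            class = "census_config")
}

#' Generate census visit schedules
#'
#' One strictly increasing sequence of visit days per subsite x year, shared
#' by every plot of the subsite (observers census all plots of an
#' experimental location on the same day), with cadence drawn uniformly from
#' `interval_min:interval_max`. The table is expanded to one row per plot x
#' visit so downstream code can treat it as a per-plot visit history.
#'
#' @param design design table (only `site`, `subsite`, `plot`, `year` used).
#' @param config a [census_config()].
#' @param seed integer seed.
#' @return Data frame `site`, `subsite`, `plot`, `year`, `doy` (one row per
#'   plot x visit, ordered).
#' @export
make_census_schedules <- function(design, config = census_config(), seed = 1) {
  stopifnot(inherits(config, "census_config"))
  set.seed(seed)
  sy <- unique(design[c("site", "subsite", "year")])
  n <- nrow(sy)
  first <- config$season_start + sample.int(7, n, replace = TRUE) - 1L +
    ifelse(runif(n) < config$p_late_start, config$late_start_delay, 0L)
  max_visits <- ceiling((config$season_end - config$season_start + 7 +
                           config$late_start_delay) / config$interval_min) + 1L
  gaps <- matrix(sample(seq.int(config$interval_min, config$interval_max),
                        n * max_visits, replace = TRUE), nrow = n)
  doys <- first + cbind(0L, t(apply(gaps, 1, cumsum)))
  keep <- doys <= config$season_end
  idx <- which(keep, arr.ind = TRUE)
  per_subsite <- data.frame(sy[idx[, 1], , drop = FALSE],
                            doy = doys[idx], row.names = NULL)
  plots <- unique(design[c("subsite", "plot", "year")])
  m <- merge(per_subsite, plots, by = c("subsite", "year"))
  out <- m[order(m$plot, m$year, m$doy),
           c("site", "subsite", "plot", "year", "doy")]
  rownames(out) <- NULL
  out
}

#' Censor true event days by the census schedule
#'
#' Converts true event days into census-bounded observations: the recorded
#' day is the first visit at or after the true event; the prior visit is the
#' visit immediately before the recorded one (absent when the event preceded
#' all visits). Events after the last visit are missing, and recorded events
#' may additionally be lost at random.
#'
#' @param true_events output of [simulate_events()].
#' @param schedules output of [make_census_schedules()].
#' @param config the [census_config()] used (for `random_missing_prob`).
#' @param seed integer seed for the random-missingness draws.
#' @return A phenology observation table: design columns plus integer `doy`
#'   (NA when missing), integer `prior_visit` (NA when no prior visit) and
#'   logical `is_missing`.
#' @export
censor_by_census <- function(true_events, schedules, config = census_config(),
                             seed = 1) {
  if (nrow(schedules) == 0L) stop("empty census schedule")
  set.seed(seed)
  key_ev <- paste(true_events$plot, true_events$year)
  key_sc <- paste(schedules$plot, schedules$year)
  visits <- split(schedules$doy, key_sc)

  doy <- prior <- rep(NA_integer_, nrow(true_events))
  for (k in names(visits)) {
    i <- which(key_ev == k)
    if (!length(i)) next
    v <- sort(visits[[k]])
    pos <- findInterval(true_events$true_doy[i], v,
                        left.open = TRUE) + 1L  # first visit >= true day
    ok <- pos <= length(v)
    doy[i[ok]] <- v[pos[ok]]
    has_prior <- ok & pos > 1L
    prior[i[has_prior]] <- v[pos[has_prior] - 1L]
  }
  out <- true_events
  out$doy <- doy
  out$prior_visit <- prior
  lost <- runif(nrow(out)) < config$random_missing_prob
  out$is_missing <- is.na(doy) | lost
  out$doy[lost] <- NA_integer_
  out$prior_visit[lost] <- NA_integer_
  out
}

#' Climate-simulation configuration
#'
#' @param t_peak mean air temperature (degC) at the seasonal peak.
#' @param t_amplitude peak-to-trough seasonal range (degC); `t_amplitude = 0`
#'   gives a flat annual curve.
#' @param peak_doy DOY of the seasonal peak.
#' @param site_offset_sd SD (degC) of time-invariant site temperature offsets.
#' @param anomaly_sd SD (degC) of site-year anomalies (0 gives identical
#'   yearly curves up to daily noise).
#' @param noise_sd SD (degC) of day-to-day noise.
#' @param missing_prob probability a daily value is missing.
#' @return A list of class `climate_config`.
#' @export
climate_config <- function(t_peak = 12, t_amplitude = 30, peak_doy = 200,
                           site_offset_sd = 2, anomaly_sd = 1, noise_sd = 1.5,
                           missing_prob = 0.05) {
  stopifnot(t_amplitude >= 0, site_offset_sd >= 0, anomaly_sd >= 0,
            noise_sd >= 0, missing_prob >= 0, missing_prob < 1)
  structure(as.list(environment()), class = "climate_config")
}

#' Simulate daily site temperature series
#'
#' One daily mean air-temperature series per site x year: a cosine seasonal
#' curve plus a time-invariant site offset, a site-year anomaly and daily
#' noise, with values removed at random to exercise infilling. Site offsets
#' and year anomalies are returned so interaction coefficients estimated from
#' climate windows can be checked against ground truth.
#'
#' @param design design table (defines sites and their observed years).
#' @param config a [climate_config()].
#' @param seed integer seed.
#' @param anomalies optional data frame `site`, `year`, `anomaly` to inject
#'   specific year anomalies (e.g. a known +2 degC year) instead of drawing
#'   them.
#' @return List of class `climate_sim`: `series` (data frame `site`, `year`,
#'   `doy`, `tmean`, `is_missing`), `site_offsets` (named numeric),
#'   `year_anomalies` (data frame `site`, `year`, `anomaly`).
#' @export
simulate_climate <- function(design, config = climate_config(), seed = 1,
                             anomalies = NULL) {
  stopifnot(inherits(config, "climate_config"))
  set.seed(seed)
  sy <- unique(design[c("site", "year")])
  sites <- unique(sy$site)
  off <- setNames(rnorm(length(sites), 0, config$site_offset_sd), sites)
  if (is.null(anomalies)) {
    sy$anomaly <- rnorm(nrow(sy), 0, config$anomaly_sd)
  } else {
    idx <- match(paste(sy$site, sy$year), paste(anomalies$site, anomalies$year))
    sy$anomaly <- anomalies$anomaly[idx]
    if (anyNA(sy$anomaly)) stop("anomalies must cover every site-year")
  }
  doys <- 1:365
  seasonal <- config$t_peak - config$t_amplitude *
    (1 - cos(2 * pi * (doys - config$peak_doy) / 365)) / 2
  n <- nrow(sy) * length(doys)
  series <- data.frame(
    site = rep(sy$site, each = length(doys)),
    year = rep(sy$year, each = length(doys)),
    doy = rep(doys, nrow(sy)),
    tmean = rep(seasonal, nrow(sy)) + rep(off[sy$site], each = length(doys)) +
      rep(sy$anomaly, each = length(doys)) + rnorm(n, 0, config$noise_sd),
    stringsAsFactors = FALSE
  )
  series$is_missing <- runif(n) < config$missing_prob
  series$tmean[series$is_missing] <- NA_real_
  structure(list(series = series, site_offsets = off,
                 year_anomalies = sy[c("site", "year", "anomaly")]),
            class = "climate_sim")
}

#' Attach simulated climate truth to ground-truth parameters
#'
#' Copies realized site offsets and year anomalies from a [simulate_climate()]
#' result into a `truth_parameters` object so [simulate_events()] can apply
#' temperature interaction coefficients consistently with the climate series.
#'
#' @param truth a `truth_parameters` object.
#' @param climate a `climate_sim` object.
#' @return The updated `truth_parameters`.
#' @export
attach_climate_truth <- function(truth, climate) {
  stopifnot(inherits(truth, "truth_parameters"),
            inherits(climate, "climate_sim"))
  truth$site_offsets <- climate$site_offsets
  truth$year_anomalies <- climate$year_anomalies
  truth
}

# internal: plot-level snowmelt table
simulate_snowmelt <- function(design, truth) {
  py <- unique(design[c("site", "subsite", "plot", "year", "treatment",
                        "deployment")])
  sm <- truth$snowmelt
  py$snowmelt_doy <- rnorm(nrow(py), sm$mean, sm$sd) -
    sm$otc_advance * (py$treatment == "OTC" & py$deployment == "year_round")
  py$snowmelt_doy <- round(py$snowmelt_doy, 1)
  rownames(py) <- NULL
  py
}

#' Simulate a complete synthetic phenology study
#'
#' End-to-end wrapper: design, climate series (with ground-truth offsets and
#' anomalies wired into the event model), true event days, census schedules,
#' censored observations, and plot snowmelt days.
#'
#' @param design a design table, or `NULL` to generate one from the `...`
#'   arguments of [generate_design()].
#' @param truth a `truth_parameters` object (default [make_truth()]).
#' @param census a [census_config()].
#' @param climate a [climate_config()].
#' @param seed integer master seed (sub-seeds for each component derive from
#'   it).
#' @param enforce_order passed to [simulate_events()].
#' @param ... passed to [generate_design()] when `design` is `NULL`.
#' @return List of class `phenology_sim`: `observations`, `schedules`,
#'   `events`, `climate`, `snowmelt`, `truth`, `design`.
#' @export
#' @examples
#' sim <- simulate_phenology(n_sites = 2, n_subsites_per_site = 1,
#'                           n_species = 3, n_years = 2,
#'                           n_plots_per_treatment = 3, seed = 7,
#'                           vary_years = FALSE)
#' head(sim$observations)
simulate_phenology <- function(design = NULL, truth = make_truth(),
                               census = census_config(),
                               climate = climate_config(), seed = 1,
                               enforce_order = FALSE, ...) {
  if (is.null(design)) design <- generate_design(..., seed = seed)
  clim <- simulate_climate(design, climate, seed = seed + 1L)
  truth <- attach_climate_truth(truth, clim)
  events <- simulate_events(design, truth, seed = seed + 2L,
                            enforce_order = enforce_order)
  schedules <- make_census_schedules(design, census, seed = seed + 3L)
  obs <- censor_by_census(events, schedules, census, seed = seed + 4L)
  set.seed(seed + 5L)
  snow <- simulate_snowmelt(design, truth)
  structure(list(observations = obs, schedules = schedules, events = events,
                 climate = clim, snowmelt = snow, truth = truth,
                 design = design),
            class = "phenology_sim")
}
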
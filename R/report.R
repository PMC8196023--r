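# Pipeline orchestration: per-phenophase prep -> stage-1 -> stage-2 ->
# contrasts, replicate census tables and the snowmelt contrast.

# small stable polynomial hash of a serialized config (self-describing
# outputs; not cryptographic)
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults are the
#' analysis rules this package implements (filter thresholds, priors,
#' sampler settings); generator sizes default to a moderate design suitable
#' for validation runs.
#'
#' @param phenophases phenophases to analyze.
#' @param interactions character vector of interaction models to fit per
#'   phenophase (subset of `"years"`, `"latitude"`, `"moisture"`,
#'   `"deployment"`, `"climate"`); empty for none.
#' @param truth `truth_parameters` for simulation.
#' @param prep a [prep_config()].
#' @param census a [census_config()].
#' @param climate a [climate_config()].
#' @param sampler a [model_spec()].
#' @param seed master seed.
#' @param ... design-size arguments passed to [generate_design()]
#'   (`n_sites`, `n_subsites_per_site`, `n_species`, `n_years`,
#'   `n_plots_per_treatment`, ...).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(phenophases = phenophase_levels(),
                            interactions = character(0),
                            truth = make_truth(), prep = prep_config(),
                            census = census_config(),
                            climate = climate_config(),
                            sampler = model_spec(), seed = 1, ...) {
  design_args <- list(...)
  structure(list(phenophases = phenophases, interactions = interactions,
                 truth = truth, prep = prep, census = census,
                 climate = climate, sampler = sampler, seed = seed,
                 design_args = design_args),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Simulates a study (unless observations are supplied), prepares the
#' observations, estimates replicate-level event timing, fits the
#' treatment-only hierarchical model per phenophase (plus any requested
#' interaction models), contrasts paired phenophases for duration changes,
#' and assembles census and snowmelt summaries. Per-phenophase model
#' failures are isolated and reported rather than aborting the run.
#'
#' @param config a [pipeline_config()].
#' @param sim optional pre-built `phenology_sim` (from
#'   [simulate_phenology()]); when `NULL` one is generated from the config.
#' @return List of class `pipeline_result`: `effects` (combined effect
#'   summary table), `fits`, `interaction_fits`, `durations`, `baseline`,
#'   `replicates`, `prep`, `census`, `snowmelt`, `errors`, `config_hash`,
#'   `seed`, `scaling`.
#' @export
run_pipeline <- function(config = pipeline_config(), sim = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(sim)) {
    sim <- do.call(simulate_phenology,
                   c(list(truth = config$truth, census = config$census,
                          climate = config$climate, seed = config$seed,
                          phenophases = config$phenophases),
                     config$design_args))
  }
  obs <- sim$observations
  obs <- obs[obs$phenophase %in% config$phenophases, , drop = FALSE]
  prep <- prep_observations(obs, sim$schedules, config$prep)
  replicates <- estimate_replicates(prep)

  # climate predictors (needed only if the climate interaction is requested,
  # but the census table reports climate replicate counts regardless)
  donor_pool <- sim$climate$series
  filled <- do.call(rbind, lapply(split(donor_pool, donor_pool$site),
                                  function(s) {
    donor <- donor_pool[donor_pool$site != s$site[1] &
                          !is.na(donor_pool$tmean), ]
    if (nrow(donor) == 0L) return(infill_missing(s, NULL))
    donor_mean <- aggregate(tmean ~ year + doy, data = donor, FUN = mean)
    donor_mean$is_missing <- FALSE
    donor_mean$site <- "donor"
    infill_missing(s, donor_mean)
  }))
  windows <- climate_windows(prep$intervals)
  cstats <- site_anomaly_means(filled, windows)
  replicates <- group_means_center(replicates, cstats)

  fits <- list()
  interaction_fits <- list()
  errors <- list()
  for (ph in intersect(config$phenophases,
                       unique(replicates$phenophase))) {
    rep_ph <- replicates[replicates$phenophase == ph, ]
    attr(rep_ph, "scaling") <- prep$scaling
    spec_ph <- config$sampler
    spec_ph$seed <- config$sampler$seed +
      match(ph, phenophase_levels())
    fits[[ph]] <- tryCatch(fit_treatment_model(rep_ph, spec_ph),
                           error = function(e) e)
    if (inherits(fits[[ph]], "error")) {
      errors[[paste0("treatment_", ph)]] <- conditionMessage(fits[[ph]])
      fits[[ph]] <- NULL
      next
    }
    for (ia in config$interactions) {
      key <- paste(ph, ia, sep = ":")
      interaction_fits[[key]] <- tryCatch(
        fit_interaction_model(rep_ph, ia, spec_ph),
        error = function(e) e)
      if (inherits(interaction_fits[[key]], "error")) {
        errors[[paste0("interaction_", key)]] <-
          conditionMessage(interaction_fits[[key]])
        interaction_fits[[key]] <- NULL
      }
    }
  }

  effects <- do.call(rbind, c(
    lapply(fits, summarize_effects),
    lapply(interaction_fits, summarize_effects)
  ))
  rownames(effects) <- NULL

  durations <- list()
  pp <- phenoperiod_pairs()
  for (i in seq_len(nrow(pp))) {
    if (pp$start[i] %in% names(fits) && pp$end[i] %in% names(fits)) {
      durations[[pp$period[i]]] <- duration_contrast(
        fits[[pp$start[i]]], fits[[pp$end[i]]], seed = config$seed)
    }
  }
  baseline <- if (length(fits)) baseline_intercepts(fits, seed = config$seed)
              else NULL

  structure(list(
    effects = effects, fits = fits, interaction_fits = interaction_fits,
    durations = durations, baseline = baseline, replicates = replicates,
    prep = prep, census = census_table(prep, replicates),
    snowmelt = snowmelt_contrast(sim$snowmelt),
    errors = errors, seed = config$seed,
    config_hash = config_hash(list(
      phenophases = config$phenophases,
      interactions = config$interactions, seed = config$seed,
      design = config$design_args,
      sampler = unclass(config$sampler), prep = unclass(config$prep))),
    scaling = prep$scaling
  ), class = "pipeline_result")
}

#' Replicate census table
#'
#' Counts, per phenophase after all filters: observations, species, sites,
#' subsites, years, replicates, and replicates available to climate models
#' (which can be fewer when window-years are dropped by the infill cap).
#'
#' @param prep a `prep_result`.
#' @param replicates a `replicate_estimates` table, optionally carrying the
#'   climate predictor columns from [group_means_center()].
#' @return Data frame, one row per phenophase.
#' @export
census_table <- function(prep, replicates) {
  iv <- prep$intervals
  phases <- unique(iv$phenophase)
  if (length(phases) == 0L) {
    return(data.frame(phenophase = character(), observations = integer(),
                      species = integer(), sites = integer(),
                      subsites = integer(), years = integer(),
                      replicates = integer(),
                      replicates_climate = integer()))
  }
  rows <- lapply(phases, function(ph) {
    o <- iv[iv$phenophase == ph, ]
    r <- replicates[replicates$phenophase == ph, ]
    n_clim <- if (!is.null(r$site_temp)) {
      sum(is.finite(r$site_temp) & is.finite(r$temp_anomaly))
    } else {
      nrow(r)
    }
    data.frame(phenophase = ph, observations = nrow(o),
               species = length(unique(o$species)),
               sites = length(unique(o$site)),
               subsites = length(unique(o$subsite)),
               years = length(unique(o$year)),
               replicates = nrow(r), replicates_climate = n_clim,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$phenophase, phenophase_levels())), ]
  rownames(out) <- NULL
  out
}

#' Chamber effect on snowmelt timing at year-round sites
#'
#' Mean warmed-minus-control difference in plot snowmelt day, restricted to
#' subsites whose chambers are deployed year-round (chambers deployed only
#' in summer arrive after snowmelt, so no contrast is defined there).
#' Differences are taken per subsite x year, then averaged.
#'
#' @param snowmelt data frame `site`, `subsite`, `plot`, `year`,
#'   `treatment`, `deployment`, `snowmelt_doy`.
#' @return List: `mean_diff` (days, negative = advance in OTC), `sd`, `n`
#'   (subsite-year cells). Empty data (no year-round sites) give `n = 0`
#'   and NA estimates with a note attribute.
#' @export
snowmelt_contrast <- function(snowmelt) {
  yr <- snowmelt[snowmelt$deployment == "year_round", , drop = FALSE]
  if (nrow(yr) == 0L) {
    out <- list(mean_diff = NA_real_, sd = NA_real_, n = 0L)
    attr(out, "note") <- "no year-round sites; snowmelt contrast undefined"
    return(out)
  }
  ag <- aggregate(snowmelt_doy ~ subsite + year + treatment, data = yr,
                  FUN = mean)
  w <- ag[ag$treatment == "OTC", ]
  ct <- ag[ag$treatment == "CTL", ]
  idx <- match(paste(w$subsite, w$year), paste(ct$subsite, ct$year))
  d <- w$snowmelt_doy[!is.na(idx)] - ct$snowmelt_doy[idx[!is.na(idx)]]
  list(mean_diff = mean(d), sd = if (length(d) > 1) sd(d) else NA_real_,
       n = length(d))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("phenowarm pipeline result (config", x$config_hash, ", seed",
      x$seed, ")\n")
  cat("fitted phenophases:", paste(names(x$fits), collapse = ", "), "\n")
  if (!is.null(x$effects)) {
    cat("\nTreatment and interaction effects (days):\n")
    print(x$effects, digits = 3)
  }
  if (length(x$durations)) {
    cat("\nPhenoperiod duration changes:\n")
    for (d in x$durations) print(d)
  }
  if (length(x$errors)) {
    cat("\nIsolated failures:\n")
    for (nm in names(x$errors)) cat(" ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}
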
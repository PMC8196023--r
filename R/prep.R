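# Preparation of raw censored phenology observations: prior-visit bounds,
# missingness / minimum-replication / outlier filters, per-phenophase
# standardization. Thresholds default to the analysis rules this package
# implements and are all exposed through prep_config().

#' Preparation thresholds
#'
#' @param max_missing_frac maximum tolerated fraction of missing observations
#'   in a species x subsite x year cell (green up and leaf senescence only).
#' @param min_obs_per_treatment minimum observations required in each of the
#'   OTC and CTL treatments for a species x subsite x year cell.
#' @param outlier_sd cells whose warmed-minus-control midpoint difference
#'   deviates from the phenophase mean by more than this many SDs are
#'   removed.
#' @param fallback_weeks_days days subtracted from a species' minimum
#'   prior-visit day when an event preceded all visits (3 weeks).
#' @param fallback_floors named DOY floors for the fallback bound.
#' @return List of class `prep_config`.
#' @export
prep_config <- function(max_missing_frac = 0.2, min_obs_per_treatment = 2,
                        outlier_sd = 4, fallback_weeks_days = 21,
                        fallback_floors = c(green_up = 100, flowering = 120,
                                            end_of_flowering = 120)) {
  structure(as.list(environment()), class = "prep_config")
}

# internal: species x subsite x year cell key (within phenophase)
cell_key <- function(obs) {
  paste(obs$phenophase, obs$species, obs$subsite, obs$year, sep = "|")
}

new_ledger <- function(rule, dropped, retained) {
  data.frame(rule = rule, dropped = dropped, retained = retained,
             stringsAsFactors = FALSE)
}

#' Assign prior-visit lower bounds
#'
#' Ensures every non-missing observation carries a lower bound. When a visit
#' history is supplied, the prior visit is recomputed as the most recent
#' visit in the same plot and year strictly before the recorded day. For
#' observations whose event preceded all visits (no prior visit), the bound
#' falls back to the species' minimum assigned prior-visit day (within the
#' phenophase, across all years) minus `fallback_weeks_days`, clamped below
#' at a phenophase floor (DOY 100 for green up, 120 for flowering and end of
#' flowering; other phenophases use 100 with a warning).
#'
#' @param observations phenology observation table (`doy`, `prior_visit`,
#'   `is_missing`, keys).
#' @param visit_history optional visit table (`plot`, `year`, `doy`) as from
#'   [make_census_schedules()].
#' @param config a [prep_config()].
#' @return The observations with complete `prior_visit` for all non-missing
#'   rows and a logical `fallback_bound` column.
#' @export
assign_prior_visits <- function(observations, visit_history = NULL,
                                config = prep_config()) {
  obs <- observations
  if (!is.null(visit_history)) {
    key_o <- paste(obs$plot, obs$year)
    visits <- split(visit_history$doy, paste(visit_history$plot,
                                             visit_history$year))
    for (k in unique(key_o)) {
      v <- sort(visits[[k]])
      if (is.null(v)) next
      i <- which(key_o == k & !is.na(obs$doy))
      pos <- findInterval(obs$doy[i] - 1L, v)  # last visit < doy
      obs$prior_visit[i] <- ifelse(pos >= 1L, v[pmax(pos, 1L)], NA_integer_)
    }
  }
  obs$fallback_bound <- FALSE
  need <- which(is.na(obs$prior_visit) & !is.na(obs$doy))
  if (length(need)) {
    floors <- config$fallback_floors
    unstated <- setdiff(unique(obs$phenophase[need]), names(floors))
    if (length(unstated)) {
      warning("no stated fallback floor for phenophase(s) ",
              paste0("'", unstated, "'", collapse = ", "),
              "; using DOY 100", call. = FALSE)
    }
    # species minimum assigned prior-visit day, per phenophase
    has_prior <- !is.na(obs$prior_visit)
    key_sp <- paste(obs$phenophase, obs$species)
    min_prior <- tapply(obs$prior_visit[has_prior], key_sp[has_prior], min)
    for (i in need) {
      ph <- obs$phenophase[i]
      floor_ph <- floors[ph]
      if (is.na(floor_ph)) floor_ph <- 100
      mp <- min_prior[paste(ph, obs$species[i])]
      bound <- if (is.na(mp)) floor_ph else {
        max(mp - config$fallback_weeks_days, floor_ph)
      }
      # the bound must stay a strict lower bound for this event
      obs$prior_visit[i] <- min(bound, obs$doy[i] - 1L)
      obs$fallback_bound[i] <- TRUE
    }
  }
  obs
}

#' Missing-data filter
#'
#' Discards any species x subsite x year cell of the green up or leaf
#' senescence phenophases in which more than `max_missing_frac` of the
#' observations are missing; other phenophases pass through. Rows that are
#' individually missing (no recorded day) are then removed everywhere, since
#' they carry no interval.
#'
#' @param observations observation table with an `is_missing` column.
#' @param config a [prep_config()].
#' @return List with `observations` (filtered) and `ledger`.
#' @export
apply_missingness_filter <- function(observations, config = prep_config()) {
  obs <- observations
  n0 <- nrow(obs)
  key <- cell_key(obs)
  subject <- obs$phenophase %in% c("green_up", "leaf_senescence")
  frac <- tapply(obs$is_missing, key, mean)
  drop_cell <- subject & frac[key] > config$max_missing_frac
  obs <- obs[!drop_cell, , drop = FALSE]
  n_cell <- n0 - nrow(obs)
  n1 <- nrow(obs)
  obs <- obs[!obs$is_missing, , drop = FALSE]
  ledger <- new_ledger(
    c("missingness_cell", "missing_row"),
    c(n_cell, n1 - nrow(obs)),
    c(n1, nrow(obs))
  )
  rownames(obs) <- NULL
  list(observations = obs, ledger = ledger)
}

#' Minimum-replication filter
#'
#' Removes every species x subsite x year cell that does not have at least
#' `min_obs_per_treatment` observations in both the OTC and CTL treatments.
#'
#' @inheritParams apply_missingness_filter
#' @return List with `observations` and `ledger`.
#' @export
filter_min_observations <- function(observations, config = prep_config()) {
  obs <- observations
  n0 <- nrow(obs)
  if (n0 == 0L) {
    return(list(observations = obs,
                ledger = new_ledger("min_observations", 0L, 0L)))
  }
  key <- cell_key(obs)
  n_otc <- tapply(obs$treatment == "OTC", key, sum)
  n_ctl <- tapply(obs$treatment == "CTL", key, sum)
  ok <- n_otc[key] >= config$min_obs_per_treatment &
    n_ctl[key] >= config$min_obs_per_treatment
  obs <- obs[ok, , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs,
       ledger = new_ledger("min_observations", n0 - nrow(obs), nrow(obs)))
}

#' Per-cell warmed-minus-control midpoint differences
#'
#' For each species x subsite x year cell of each phenophase, the mean
#' interval midpoint in OTC plots minus the mean in CTL plots (days).
#'
#' @inheritParams apply_missingness_filter
#' @return Data frame `phenophase`, `species`, `subsite`, `year`, `diff`.
#' @export
replicate_differences <- function(observations) {
  obs <- observations
  obs$midpoint <- (obs$prior_visit + obs$doy) / 2
  ag <- aggregate(midpoint ~ phenophase + species + subsite + year + treatment,
                  data = obs, FUN = mean)
  w <- ag[ag$treatment == "OTC", ]
  c_ <- ag[ag$treatment == "CTL", ]
  key_w <- paste(w$phenophase, w$species, w$subsite, w$year, sep = "|")
  key_c <- paste(c_$phenophase, c_$species, c_$subsite, c_$year, sep = "|")
  idx <- match(key_w, key_c)
  out <- w[!is.na(idx), c("phenophase", "species", "subsite", "year")]
  out$diff <- w$midpoint[!is.na(idx)] - c_$midpoint[idx[!is.na(idx)]]
  rownames(out) <- NULL
  out
}

#' Outlier filter on treatment-control differences
#'
#' Computes per-cell warmed-minus-control midpoint differences and removes
#' cells whose difference lies more than `outlier_sd` standard deviations
#' from the phenophase mean difference. With fewer than 3 cells in a
#' phenophase the SD is unstable and nothing is removed.
#'
#' @inheritParams apply_missingness_filter
#' @return List with `observations`, `ledger` and the `differences` table.
#' @export
remove_outliers <- function(observations, config = prep_config()) {
  obs <- observations
  n0 <- nrow(obs)
  diffs <- replicate_differences(obs)
  drop_keys <- character(0)
  for (ph in unique(diffs$phenophase)) {
    d <- diffs[diffs$phenophase == ph, ]
    if (nrow(d) < 3L) next
    s <- sd(d$diff)
    if (s == 0) next
    out <- abs(d$diff - mean(d$diff)) > config$outlier_sd * s
    drop_keys <- c(drop_keys,
                   paste(d$phenophase, d$species, d$subsite, d$year,
                         sep = "|")[out])
  }
  obs <- obs[!(cell_key(obs) %in% drop_keys), , drop = FALSE]
  rownames(obs) <- NULL
  list(observations = obs,
       ledger = new_ledger("outlier_4sd", n0 - nrow(obs), nrow(obs)),
       differences = diffs)
}

#' Standardize intervals per phenophase
#'
#' Computes the interval midpoint of each observation and, per phenophase,
#' centers and scales both interval bounds by the mean and SD of the
#' midpoints. The same affine map is applied to the lower and upper bounds so
#' interval-censored fitting can proceed on the standardized scale; the
#' scaling record allows back-transformation of effects to days.
#'
#' @param observations observation table with complete `prior_visit` bounds.
#' @return List with `intervals` (observations plus `midpoint`, `lower_std`,
#'   `upper_std`, `midpoint_std`) and `scaling` (data frame `phenophase`,
#'   `center`, `scale`).
#' @export
standardize <- function(observations) {
  obs <- observations
  if (any(is.na(obs$prior_visit) | is.na(obs$doy))) {
    stop("standardize() requires complete interval bounds")
  }
  if (any(obs$prior_visit >= obs$doy)) {
    stop("prior visit must precede the recorded day")
  }
  obs$midpoint <- (obs$prior_visit + obs$doy) / 2
  center <- tapply(obs$midpoint, obs$phenophase, mean)
  scale <- tapply(obs$midpoint, obs$phenophase, sd)
  if (any(is.na(scale) | scale == 0)) {
    stop("midpoint SD is zero (or undefined) for phenophase(s): ",
         paste(names(scale)[is.na(scale) | scale == 0], collapse = ", "))
  }
  obs$lower_std <- as.numeric((obs$prior_visit - center[obs$phenophase]) /
                                scale[obs$phenophase])
  obs$upper_std <- as.numeric((obs$doy - center[obs$phenophase]) /
                                scale[obs$phenophase])
  obs$midpoint_std <- as.numeric((obs$midpoint - center[obs$phenophase]) /
                                   scale[obs$phenophase])
  scaling <- data.frame(phenophase = names(center),
                        center = as.numeric(center),
                        scale = as.numeric(scale), stringsAsFactors = FALSE)
  rownames(scaling) <- NULL
  list(intervals = obs, scaling = scaling)
}

#' Full preparation pipeline
#'
#' Applies, in order: prior-visit assignment (with fallback bounds), the
#' missingness filter, the minimum-replication filter, the outlier filter,
#' and per-phenophase standardization. The combined ledger reconciles row
#' counts across every rule.
#'
#' @param observations raw observation table (as emitted by
#'   [censor_by_census()] or read from CSV with the same columns).
#' @param visit_history optional visit table for prior-visit recomputation.
#' @param config a [prep_config()].
#' @return List of class `prep_result`: `intervals`, `scaling`, `ledger`,
#'   `differences`.
#' @export
prep_observations <- function(observations, visit_history = NULL,
                              config = prep_config()) {
  obs <- assign_prior_visits(observations, visit_history, config)
  m <- apply_missingness_filter(obs, config)
  f <- filter_min_observations(m$observations, config)
  o <- remove_outliers(f$observations, config)
  s <- standardize(o$observations)
  ledger <- rbind(m$ledger, f$ledger, o$ledger)
  structure(list(intervals = s$intervals, scaling = s$scaling,
                 ledger = ledger, differences = o$differences),
            class = "prep_result")
}
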
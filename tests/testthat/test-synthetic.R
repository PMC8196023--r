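# Synthetic-data generator: design structure, generative model limits,
# census censoring semantics, determinism.

test_that("design dimensions follow the requested counts", {
  d <- generate_design(2, 2, 3, 2, 5, seed = 1, vary_years = FALSE)
  expect_equal(length(unique(d$subsite)), 4L)
  expect_equal(length(unique(d$plot)), 40L)
  expect_setequal(unique(d$treatment), c("OTC", "CTL"))
  expect_true(all(d$phenophase %in% phenophase_levels()))

  dmin <- generate_design(1, 1, 1, 1, 1, seed = 0)
  expect_equal(length(unique(dmin$plot)), 2L)
  expect_setequal(unique(dmin$treatment), c("OTC", "CTL"))

  expect_error(generate_design(0, 1, 1, 1, 1), "positive")
})

test_that("each subsite belongs to one site and plots to one treatment", {
  d <- generate_design(3, 2, 6, 2, 3, seed = 4)
  expect_true(all(tapply(d$site, d$subsite,
                         function(x) length(unique(x))) == 1L))
  expect_true(all(tapply(d$treatment, d$plot,
                         function(x) length(unique(x))) == 1L))
  # species at a random subset of sites: coverage is incomplete by default
  d2 <- generate_design(6, 1, 30, 1, 1, seed = 2, species_site_prob = 0.3)
  spp_sites <- tapply(d2$site, d2$species, function(x) length(unique(x)))
  expect_true(any(spp_sites < 6))
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_design(2, 2, 4, 2, 3, seed = 9)
  d2 <- generate_design(2, 2, 4, 2, 3, seed = 9)
  expect_identical(d1, d2)
  s1 <- simulate_phenology(n_sites = 2, n_subsites_per_site = 1,
                           n_species = 2, n_years = 1,
                           n_plots_per_treatment = 2, seed = 5)
  s2 <- simulate_phenology(n_sites = 2, n_subsites_per_site = 1,
                           n_species = 2, n_years = 1,
                           n_plots_per_treatment = 2, seed = 5)
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$climate$series, s2$climate$series)
})

test_that("noise-free limit reproduces intercept and treatment effect", {
  d <- generate_design(2, 1, 2, 1, 2, seed = 3, vary_years = FALSE,
                       phenophases = "flowering", species_site_prob = 1)
  truth <- make_truth(intercept = c(flowering = 180),
                      trt_effect = c(flowering = -2.4),
                      sd_species = c(0, 0), sd_site = c(0, 0),
                      sd_site_year = c(0, 0), sd_site_subsite = c(0, 0),
                      sigma_resid = 1e-9)
  ev <- simulate_events(d, truth, seed = 1)
  expect_equal(ev$true_doy[ev$treatment == "CTL"],
               rep(180, sum(ev$treatment == "CTL")), tolerance = 1e-6)
  expect_equal(ev$true_doy[ev$treatment == "OTC"],
               rep(177.6, sum(ev$treatment == "OTC")), tolerance = 1e-6)

  truth0 <- make_truth(intercept = c(flowering = 180),
                       trt_effect = c(flowering = 0),
                       sd_species = c(0, 0), sd_site = c(0, 0),
                       sd_site_year = c(0, 0), sd_site_subsite = c(0, 0),
                       sigma_resid = 1e-9)
  ev0 <- simulate_events(d, truth0, seed = 1)
  expect_equal(unique(round(ev0$true_doy, 6)), 180)
})

test_that("species-level SD is recovered across many species", {
  # Monte-Carlo check of the generative SD: one observation per species,
  # negligible residual, all other group SDs zero
  d <- generate_design(1, 1, 500, 1, 1, seed = 8, vary_years = FALSE,
                       phenophases = "flowering", species_site_prob = 1)
  d <- d[d$treatment == "CTL", ]
  truth <- make_truth(intercept = c(flowering = 180),
                      trt_effect = c(flowering = 0),
                      sd_species = c(3, 0), sd_site = c(0, 0),
                      sd_site_year = c(0, 0), sd_site_subsite = c(0, 0),
                      sigma_resid = 1e-9)
  ev <- simulate_events(d, truth, seed = 21)
  sp_means <- tapply(ev$true_doy, ev$species, mean)
  expect_equal(sd(sp_means), 3, tolerance = 0.2)
})

test_that("simulate_events validates truth against the design", {
  d <- generate_design(1, 1, 1, 1, 1, seed = 1, phenophases = "flowering")
  truth <- make_truth(intercept = c(green_up = 160),
                      trt_effect = c(green_up = 0))
  expect_error(simulate_events(d, truth, seed = 1), "lacks parameters")
})

test_that("census censoring maps true days to bounding visits", {
  ev <- toy_obs(doy = NA)
  ev$true_doy <- 163
  sched <- data.frame(site = "s1", subsite = "s1_ss1", plot = "p1",
                      year = 2001L, doy = c(150L, 157L, 164L))
  cfg <- census_config(random_missing_prob = 0)
  out <- censor_by_census(ev, sched, cfg, seed = 1)
  expect_equal(out$doy, 164L)
  expect_equal(out$prior_visit, 157L)
  expect_false(out$is_missing)

  # event before the first visit: recorded at first visit, no prior
  ev$true_doy <- 149
  out2 <- censor_by_census(ev, sched[sched$doy != 164, ], cfg, seed = 1)
  expect_equal(out2$doy, 150L)
  expect_true(is.na(out2$prior_visit))

  # event after the last visit is missing
  ev$true_doy <- 170
  out3 <- censor_by_census(ev, sched, cfg, seed = 1)
  expect_true(out3$is_missing)

  expect_error(censor_by_census(ev, sched[0, ], cfg), "empty")
})

test_that("daily censusing gives unit-width intervals at ceil(true day)", {
  ev <- do.call(rbind, lapply(1:20, function(i) {
    o <- toy_obs(doy = NA, plot = "p1")
    o$true_doy <- 150 + i * 0.7
    o
  }))
  sched <- data.frame(site = "s1", subsite = "s1_ss1", plot = "p1",
                      year = 2001L, doy = 140:200)
  out <- censor_by_census(ev, sched, census_config(random_missing_prob = 0),
                          seed = 1)
  expect_equal(out$doy, as.integer(ceiling(ev$true_doy)))
  expect_equal(out$doy - out$prior_visit, rep(1L, nrow(out)))
})

test_that("schedules are shared within subsite, increasing, in season", {
  d <- generate_design(2, 2, 2, 2, 3, seed = 6, vary_years = FALSE)
  cfg <- census_config(p_late_start = 0)
  sch <- make_census_schedules(d, cfg, seed = 2)
  by_plot <- split(sch$doy, paste(sch$plot, sch$year))
  expect_true(all(vapply(by_plot, function(v) all(diff(v) > 0), logical(1))))
  gaps <- unlist(lapply(by_plot, diff))
  expect_true(all(gaps >= cfg$interval_min & gaps <= cfg$interval_max))
  expect_true(all(sch$doy <= cfg$season_end))
  # all plots of a subsite-year share one visit sequence
  one <- sch[sch$year == sch$year[1] & sch$subsite == sch$subsite[1], ]
  seqs <- unique(lapply(split(one$doy, one$plot), sort))
  expect_length(seqs, 1L)
})

test_that("climate simulation honors its configuration", {
  d <- generate_design(2, 1, 2, 3, 2, seed = 3, vary_years = FALSE)
  c0 <- simulate_climate(d, climate_config(missing_prob = 0), seed = 1)
  expect_false(any(c0$series$is_missing))
  expect_false(anyNA(c0$series$tmean))

  # zero anomaly SD and zero noise: yearly curves identical
  cfg <- climate_config(anomaly_sd = 0, noise_sd = 0, missing_prob = 0)
  c1 <- simulate_climate(d, cfg, seed = 1)
  s <- c1$series[c1$series$site == "site01", ]
  by_year <- split(s$tmean, s$year)
  expect_equal(by_year[[1]], by_year[[2]])

  # injected +2 degC year shows up in the window mean
  sy <- unique(d[c("site", "year")])
  sy$anomaly <- ifelse(sy$year == 2002, 2, 0)
  c2 <- simulate_climate(d, climate_config(anomaly_sd = 0, noise_sd = 0.3,
                                           missing_prob = 0),
                         seed = 2, anomalies = sy)
  s2 <- c2$series[c2$series$site == "site01" & c2$series$doy %in% 150:180, ]
  ym <- tapply(s2$tmean, s2$year, mean)
  expect_equal(unname(ym["2002"] - mean(ym[c("2001", "2003")])), 2,
               tolerance = 0.15)
})

test_that("snowmelt advance applies only to warmed year-round plots", {
  n <- 4000
  design <- data.frame(
    site = rep(c("sA", "sB"), each = n),
    subsite = rep(c("sA_1", "sB_1"), each = n),
    plot = paste0("p", seq_len(2 * n)),
    year = 2001L,
    treatment = rep(c("OTC", "CTL"), n),
    deployment = rep(c("year_round", "summer_only"), each = n),
    stringsAsFactors = FALSE
  )
  set.seed(13)
  sm <- phenowarm:::simulate_snowmelt(design, make_truth())
  diff_by <- function(dep) {
    x <- sm[sm$deployment == dep, ]
    mean(x$snowmelt_doy[x$treatment == "OTC"]) -
      mean(x$snowmelt_doy[x$treatment == "CTL"])
  }
  expect_equal(diff_by("year_round"), -1.02, tolerance = 0.3)
  expect_equal(diff_by("summer_only"), 0, tolerance = 0.3)
})
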
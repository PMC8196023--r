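# Shared fixture builders. All fixtures are generated in code.

# minimal observation table; vectors recycle to the longest
toy_obs <- function(doy, prior = NA_integer_, treatment = "CTL",
                    species = "sp1", subsite = "s1_ss1", site = "s1",
                    plot = "p1", year = 2001L, phenophase = "flowering",
                    is_missing = FALSE) {
  data.frame(site = site, subsite = subsite, plot = plot, year = year,
             treatment = treatment, species = species,
             phenophase = phenophase, doy = as.integer(doy),
             prior_visit = as.integer(prior), is_missing = is_missing,
             stringsAsFactors = FALSE)
}

# small full simulation used by several integration tests
small_sim <- function(seed = 11, phenophases = "flowering",
                      trt_effect = NULL, n_sites = 3, n_species = 5,
                      n_years = 2, sigma_resid = 5) {
  if (is.null(trt_effect)) {
    trt_effect <- setNames(rep(-2, length(phenophases)), phenophases)
  }
  intercepts <- setNames(
    c(green_up = 160, flowering = 175, end_of_flowering = 193,
      fruiting = 200, seed_dispersal = 220,
      leaf_senescence = 240)[phenophases], phenophases)
  truth <- make_truth(intercept = intercepts, trt_effect = trt_effect,
                      sd_species = c(2, 1), sd_site = c(2, 1),
                      sd_site_year = c(2, 0.75), sd_site_subsite = c(1, 0.5),
                      sigma_resid = sigma_resid)
  simulate_phenology(n_sites = n_sites, n_subsites_per_site = 2,
                     n_species = n_species, n_years = n_years,
                     n_plots_per_treatment = 3, seed = seed,
                     vary_years = FALSE, species_site_prob = 1,
                     phenophases = phenophases, truth = truth)
}

# fabricate a posterior_fit with given draws (for summary/contrast tests)
fake_fit <- function(beta_draws, alpha_draws = rep(0, length(beta_draws)),
                     phenophase = "flowering", center = 175, scale = 10) {
  structure(list(
    phenophase = phenophase, model = "treatment", predictor = NULL,
    draws = cbind(alpha = alpha_draws, beta = beta_draws),
    rhat = c(alpha = 1, beta = 1), converged = TRUE,
    scaling = data.frame(phenophase = phenophase, center = center,
                         scale = scale, stringsAsFactors = FALSE)
  ), class = "posterior_fit")
}

# fabricate replicate estimates directly (bypassing stage 1)
fake_replicates <- function(n_species = 6, n_sites = 3, n_subsites = 2,
                            n_years = 2, beta = -0.25, se = 0.2,
                            sd_noise = 0, seed = 1,
                            phenophase = "flowering") {
  set.seed(seed)
  g <- expand.grid(species = sprintf("sp%02d", seq_len(n_species)),
                   site = sprintf("k%02d", seq_len(n_sites)),
                   ss = seq_len(n_subsites), year = seq_len(n_years) + 2000L,
                   treatment = c("OTC", "CTL"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$subsite <- paste0(g$site, "_ss", g$ss)
  g$ss <- NULL
  g$phenophase <- phenophase
  trt <- as.numeric(g$treatment == "OTC")
  g$se_mu <- rep(se, nrow(g))
  g$mu <- beta * trt + rnorm(nrow(g), 0, sd_noise) +
    rnorm(nrow(g), 0, g$se_mu)
  g$n_obs <- 4L
  g$method <- "mle"
  g$converged <- TRUE
  attr(g, "scaling") <- data.frame(phenophase = phenophase, center = 175,
                                   scale = 10, stringsAsFactors = FALSE)
  class(g) <- c("replicate_estimates", "data.frame")
  g
}

# small sampler settings for test fits
test_spec <- function(seed = 1, iter = 1200, warmup = 600) {
  model_spec(chains = 2, iter = iter, warmup = warmup, seed = seed)
}

# Stage-2 responses simulated from the hierarchical model itself, with the
# nuisance parameters (group SDs, intercept-slope correlations, residual SD)
# drawn from the model's own priors and the warming effect fixed at 0.
# Under this joint draw the posterior 90% ETI for beta has exactly nominal
# coverage of 0 (up to the near-flat beta prior), which makes it the
# appropriate null stream for interval-calibration checks.
prior_draw_replicates <- function(seed, n_species = 6, n_sites = 4,
                                  n_subsites = 2, n_years = 2) {
  set.seed(seed)
  half_t <- function(n, df = 3, scale = 10) abs(scale * rt(n, df))
  g <- expand.grid(species = sprintf("sp%d", seq_len(n_species)),
                   site = sprintf("k%d", seq_len(n_sites)),
                   ss = seq_len(n_subsites), year = seq_len(n_years) + 2000L,
                   treatment = c("OTC", "CTL"), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g$subsite <- paste0(g$site, "_", g$ss)
  g$ss <- NULL
  g$phenophase <- "flowering"
  sds <- matrix(half_t(8), 4, 2)
  rho <- 2 * rbeta(4, 1, 1) - 1
  sigr <- half_t(1)
  alpha <- rnorm(1, 0, 100)
  mk <- function(key, i) {
    u <- unique(key)
    z1 <- rnorm(length(u))
    z2 <- rnorm(length(u))
    a <- sds[i, 1] * z1
    b <- sds[i, 2] * (rho[i] * z1 + sqrt(1 - rho[i]^2) * z2)
    cbind(a[match(key, u)], b[match(key, u)])
  }
  D <- mk(g$species, 1) + mk(g$site, 2) + mk(paste(g$site, g$year), 3) +
    mk(g$subsite, 4)
  trt <- as.numeric(g$treatment == "OTC")
  g$se_mu <- runif(nrow(g), 0.05, 0.3)
  g$mu <- alpha + D[, 1] + D[, 2] * trt +
    rnorm(nrow(g), 0, sqrt(sigr^2 + g$se_mu^2))
  g$n_obs <- 4L
  g$method <- "mle"
  g$converged <- TRUE
  attr(g, "scaling") <- data.frame(phenophase = "flowering", center = 175,
                                   scale = 10, stringsAsFactors = FALSE)
  class(g) <- c("replicate_estimates", "data.frame")
  g
}
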
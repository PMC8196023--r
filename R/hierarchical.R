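# Stage 2: Bayesian hierarchical measurement-error models of the warming
# effect, fit with JAGS. The replicate means from stage 1 are the response,
# observed with known standard error; the warming effect carries correlated
# intercept-slope deviations for species, site, site:year and site:subsite.
#
#   mu_r ~ N(alpha + a_s + a_k + a_y + a_j + (beta + b_s + b_k + b_y + b_j)
#            * Trt_r [+ b2*St + b3*Trt*St],  sigma_r^2 + se_r^2)
#
# Priors: near-flat normals on alpha/beta (SD 100 on the standardized
# scale), half-Student-t(df 3, scale 10) on all SDs, and an LKJ(zeta)
# correlation prior per grouping factor, realized exactly for the 2x2 case
# as rho = 2B - 1 with B ~ Beta(zeta, zeta).

#' Sampler and prior settings for the hierarchical models
#'
#' Defaults mirror the analysis this package implements: two chains of
#' 10,000 iterations with 5,000 warmup and no thinning, half-Student-t(3,
#' scale 10) priors on all SDs, and LKJ(1) (uniform) priors on the
#' intercept-slope correlations. Observation-level dispersion combines the
#' residual SD with the known replicate SE in quadrature by default; the
#' literal sum is available for sensitivity analysis.
#'
#' @param chains number of MCMC chains (>= 2 for convergence diagnostics).
#' @param iter total iterations per chain (including warmup).
#' @param warmup warmup iterations per chain (adaptation + burn-in).
#' @param seed integer seed for the chains' RNG streams.
#' @param prior_sd_df,prior_sd_scale half-Student-t parameters for SD priors.
#' @param lkj_zeta LKJ shape for the 2x2 group correlation matrices (1 =
#'   uniform correlation).
#' @param error_combine `"quadrature"` (`sigma_r^2 + se^2`) or `"sum"`
#'   (`(sigma_r + se)^2`).
#' @param monitor_deviations include group-level deviation draws in the
#'   output (needed for group-level effect tables; adds memory).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(chains = 2, iter = 10000, warmup = 5000, seed = 1,
                       prior_sd_df = 3, prior_sd_scale = 10, lkj_zeta = 1,
                       error_combine = c("quadrature", "sum"),
                       monitor_deviations = FALSE) {
  error_combine <- match.arg(error_combine)
  stopifnot(chains >= 1, iter > warmup, warmup >= 200, lkj_zeta > 0)
  structure(list(chains = chains, iter = iter, warmup = warmup, seed = seed,
                 prior_sd_df = prior_sd_df, prior_sd_scale = prior_sd_scale,
                 lkj_zeta = lkj_zeta, error_combine = error_combine,
                 monitor_deviations = monitor_deviations),
            class = "model_spec")
}

# strip coda attributes from an mcmc chain, keeping the plain matrix
chain_matrix <- function(ch) {
  m <- unclass(ch)
  attr(m, "mcpar") <- NULL
  m
}

# grouping factors: JAGS suffix -> replicate-table key
group_factors <- function() {
  c(sp = "species", k = "site", sy = "site_year", ss = "site_subsite")
}

# internal: JAGS model code for the treatment / interaction model
jags_model_code <- function(spec, n_st = 0) {
  prec_expr <- if (spec$error_combine == "quadrature") {
    "1 / (sigma_r^2 + se[i]^2)"
  } else {
    "1 / pow(sigma_r + se[i], 2)"
  }
  st_eta <- if (n_st > 0) " + inprod(St[i,], b2) + trt[i]*inprod(St[i,], b3)"
            else ""
  g <- names(group_factors())
  dev_terms_a <- paste(sprintf("u_%s[%s[i],1]", g, g), collapse = " + ")
  dev_terms_b <- paste(sprintf("u_%s[%s[i],2]", g, g), collapse = " + ")
  group_blocks <- paste(vapply(g, function(s) sprintf(
    "  for (j in 1:J_%s) { u_%s[j,1:2] ~ dmnorm(zero2, Om_%s) }
  Om_%s <- inverse(S_%s)
  S_%s[1,1] <- sd_a_%s^2
  S_%s[2,2] <- sd_b_%s^2
  S_%s[1,2] <- rho_%s * sd_a_%s * sd_b_%s
  S_%s[2,1] <- S_%s[1,2]
  sd_a_%s ~ dt(0, prec_sd, df_sd) T(0,)
  sd_b_%s ~ dt(0, prec_sd, df_sd) T(0,)
  rb_%s ~ dbeta(zeta, zeta)
  rho_%s <- 2 * rb_%s - 1",
    s, s, s, s, s, s, s, s, s, s, s, s, s, s, s, s, s, s, s, s),
    character(1)), collapse = "\n")
  st_prior <- if (n_st > 0) {
    "  for (p in 1:P) { b2[p] ~ dnorm(0, 1e-4)\n    b3[p] ~ dnorm(0, 1e-4) }\n"
  } else ""
  sprintf("model {
  for (i in 1:N) {
    y[i] ~ dnorm(eta[i], prec[i])
    eta[i] <- alpha + %s + (beta + %s) * trt[i]%s
    prec[i] <- %s
  }
%s
%s  alpha ~ dnorm(0, 1e-4)
  beta ~ dnorm(0, 1e-4)
  sigma_r ~ dt(0, prec_sd, df_sd) T(0,)
}", dev_terms_a, dev_terms_b, st_eta, prec_expr, group_blocks, st_prior)
}

# internal: shared fitting engine
jags_hierarchical_fit <- function(replicates, spec, St = NULL,
                                  st_names = NULL, model = "treatment",
                                  predictor = NULL) {
  rep_df <- as.data.frame(replicates)
  phases <- unique(rep_df$phenophase)
  if (length(phases) != 1L) {
    stop("fit one phenophase at a time (found: ",
         paste(phases, collapse = ", "), ")")
  }
  rep_df$site_year <- paste(rep_df$site, rep_df$year, sep = ":")
  rep_df$site_subsite <- rep_df$subsite
  # sorted-key ordering makes fits invariant to input row permutation
  ord <- order(rep_df$species, rep_df$site, rep_df$subsite, rep_df$year,
               rep_df$treatment)
  rep_df <- rep_df[ord, ]
  if (!is.null(St)) St <- St[ord, , drop = FALSE]

  keep <- is.finite(rep_df$mu) & is.finite(rep_df$se_mu)
  if (!is.null(St)) keep <- keep & apply(is.finite(St), 1, all)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " replicate(s) dropped from this fit (missing response, ",
            "SE or predictor)")
    rep_df <- rep_df[keep, , drop = FALSE]
    if (!is.null(St)) St <- St[keep, , drop = FALSE]
  }
  if (nrow(rep_df) < 4L) stop("too few replicates to fit")

  gf <- group_factors()
  data <- list(y = rep_df$mu, se = rep_df$se_mu,
               trt = as.numeric(rep_df$treatment == "OTC"),
               N = nrow(rep_df), zero2 = c(0, 0),
               df_sd = spec$prior_sd_df,
               prec_sd = 1 / spec$prior_sd_scale^2,
               zeta = spec$lkj_zeta)
  levels_by_group <- list()
  for (s in names(gf)) {
    f <- factor(rep_df[[gf[s]]], levels = sort(unique(rep_df[[gf[s]]])))
    data[[s]] <- as.integer(f)
    data[[paste0("J_", s)]] <- nlevels(f)
    levels_by_group[[gf[[s]]]] <- levels(f)
  }
  n_st <- 0L
  if (!is.null(St)) {
    n_st <- ncol(St)
    data$St <- St
    data$P <- n_st
  }

  code <- jags_model_code(spec, n_st)
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(alpha = mean(data$y), beta = 0,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = spec$seed * 100L + ch)
  })
  monitor <- c("alpha", "beta", "sigma_r",
               paste0("sd_a_", names(gf)), paste0("sd_b_", names(gf)),
               paste0("rho_", names(gf)))
  if (n_st > 0) monitor <- c(monitor, "b2", "b3")
  if (spec$monitor_deviations) monitor <- c(monitor, paste0("u_", names(gf)))

  rjags::load.module("glm", quiet = TRUE)
  n_adapt <- min(1000L, max(200L, floor(spec$warmup / 2)))
  jm <- rjags::jags.model(textConnection(code), data = data,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  burn <- spec$warmup - n_adapt
  if (burn > 0) update(jm, burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitor, spec$iter - spec$warmup,
                                 progress.bar = "none")

  rhat <- gelman_rubin(samples)
  converged <- all(rhat < 1.1, na.rm = TRUE)
  if (!converged) {
    warning("split R-hat > 1.1 for: ",
            paste(names(rhat)[which(rhat >= 1.1)], collapse = ", "),
            "; fit flagged non-converged", call. = FALSE)
  }
  draws <- do.call(rbind, lapply(samples, chain_matrix))
  if (n_st > 0 && !is.null(st_names)) {
    # JAGS names a length-1 monitored vector without the index
    old <- if (n_st == 1L) c("b2", "b3") else
      c(sprintf("b2[%d]", seq_len(n_st)), sprintf("b3[%d]", seq_len(n_st)))
    new <- c(paste0("b2_", st_names), paste0("b3_", st_names))
    rename <- function(x) {
      i <- match(x, old)
      ifelse(is.na(i), x, new[i])
    }
    colnames(draws) <- rename(colnames(draws))
    names(rhat) <- rename(names(rhat))
  }

  structure(list(
    phenophase = phases, model = model, predictor = predictor,
    st_names = st_names, samples = samples, draws = draws, rhat = rhat,
    converged = converged, spec = spec,
    n_replicates = nrow(rep_df), n_dropped = n_drop,
    levels = levels_by_group,
    scaling = attr(replicates, "scaling")
  ), class = "posterior_fit")
}

#' Fit the treatment-only hierarchical model
#'
#' Estimates the overall warming effect `beta` for one phenophase from
#' replicate-level means and standard errors, with correlated
#' intercept-slope deviations grouped by species, site, year within site,
#' and subsite within site.
#'
#' @param replicates a `replicate_estimates` table (one phenophase), as from
#'   [estimate_replicates()] (subset to a phenophase) — columns `mu`,
#'   `se_mu`, `treatment`, `species`, `site`, `subsite`, `year`.
#' @param spec a [model_spec()].
#' @return An object of class `posterior_fit`: posterior `draws` (matrix),
#'   per-chain `samples` (coda), split R-hat per monitored parameter,
#'   `converged` flag, and the phenophase scaling record for day-units
#'   back-transformation.
#' @export
fit_treatment_model <- function(replicates, spec = model_spec()) {
  jags_hierarchical_fit(replicates, spec, model = "treatment")
}

# internal: build the spatiotemporal predictor matrix
build_st_matrix <- function(replicates, predictor) {
  rep_df <- as.data.frame(replicates)
  St <- switch(predictor,
    years = {
      yw <- rep_df$years_of_warming
      if (is.null(yw)) stop("replicates lack 'years_of_warming'")
      cbind(years_of_warming = yw - mean(yw))
    },
    latitude = {
      lat <- rep_df$latitude
      if (is.null(lat)) stop("replicates lack 'latitude'")
      cbind(latitude = lat - mean(tapply(lat, rep_df$site, "[", 1)))
    },
    moisture = cbind(moisture_moist = as.numeric(rep_df$moisture == "moist"),
                     moisture_wet = as.numeric(rep_df$moisture == "wet")),
    deployment = cbind(deployment_summer_only =
                         as.numeric(rep_df$deployment == "summer_only")),
    climate = {
      if (is.null(rep_df$site_temp)) {
        stop("replicates lack climate predictors; run group_means_center()")
      }
      cbind(site_temp = rep_df$site_temp, temp_anomaly = rep_df$temp_anomaly)
    },
    stop("unknown predictor '", predictor, "'")
  )
  const <- apply(St, 2, function(x) var(x[is.finite(x)]) == 0)
  if (any(const)) {
    message("predictor column(s) constant across replicates, dropped: ",
            paste(colnames(St)[const], collapse = ", "))
    St <- St[, !const, drop = FALSE]
  }
  St
}

#' Fit a treatment-by-predictor interaction model
#'
#' Extends the treatment-only model with fixed main and interaction terms
#' for one spatiotemporal predictor: years of warming (replicate level),
#' latitude (site), soil moisture (subsite; indicator coding, reference
#' "dry"), chamber deployment period (site; reference "year_round"), or
#' `"climate"`, which enters the two group-means-centered temperature
#' predictors (between-site mean and within-site anomaly) together.
#'
#' @inheritParams fit_treatment_model
#' @param predictor one of `"years"`, `"latitude"`, `"moisture"`,
#'   `"deployment"`, `"climate"`.
#' @return A `posterior_fit` with additional `b2_*` (main) and `b3_*`
#'   (interaction) parameters.
#' @export
fit_interaction_model <- function(replicates, predictor,
                                  spec = model_spec()) {
  St <- build_st_matrix(replicates, predictor)
  if (ncol(St) == 0L) {
    message("no varying predictor column left; ",
            "falling back to the treatment-only model")
    fit <- jags_hierarchical_fit(replicates, spec, model = "treatment")
    fit$predictor <- predictor
    return(fit)
  }
  jags_hierarchical_fit(replicates, spec, St = St,
                        st_names = colnames(St), model = "interaction",
                        predictor = predictor)
}

#' Equal-tailed credible interval
#'
#' Empirical `((1-level)/2, 1-(1-level)/2)` quantiles of posterior draws.
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param level interval mass, e.g. 0.90 or 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
#' @examples
#' compute_eti(rnorm(1e4), 0.90)
compute_eti <- function(draws, level = 0.90) {
  stopifnot(length(draws) >= 2, level > 0, level < 1)
  a <- (1 - level) / 2
  q <- quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic. Values near 1
#' indicate convergence; fits are flagged when any parameter exceeds 1.1.
#'
#' @param chains a `coda::mcmc.list`, or a list of equal-length numeric
#'   matrices (iterations x parameters), or a list of numeric vectors for a
#'   single parameter.
#' @return Named numeric vector of R-hat per parameter (NaN for parameters
#'   with zero variance in all chains).
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    mats <- lapply(chains, chain_matrix)
  } else if (is.list(chains)) {
    mats <- lapply(chains, function(ch) {
      if (is.null(dim(ch))) matrix(ch, ncol = 1,
                                   dimnames = list(NULL, "par")) else ch
    })
  } else {
    stop("chains must be an mcmc.list or a list of chains")
  }
  if (length(mats) < 2L) stop("need at least 2 chains")
  len <- unique(vapply(mats, nrow, integer(1)))
  if (length(len) != 1L) stop("chains must have equal length")
  half <- floor(len / 2)
  split_mats <- unlist(lapply(mats, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[seq.int(len - half + 1L, len), , drop = FALSE])
  }), recursive = FALSE)
  m <- length(split_mats)
  n <- half
  means <- vapply(split_mats, colMeans, numeric(ncol(mats[[1]])))
  vars <- vapply(split_mats, function(x) apply(x, 2, var),
                 numeric(ncol(mats[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)
  var_plus <- (n - 1) / n * W + B_over_n
  rhat <- sqrt(var_plus / W)
  setNames(rhat, colnames(mats[[1]]))
}

#' Summarize fixed effects in days
#'
#' Back-transforms the fixed-effect draws of a fit to day units by
#' multiplying by the phenophase midpoint SD, and reports posterior mean,
#' SD, 90/95% equal-tailed intervals and zero-exclusion flags — the layout
#' of a treatment-effects table.
#'
#' @param fit a `posterior_fit`.
#' @param scaling optional scaling record (data frame `phenophase`,
#'   `center`, `scale`); defaults to the one carried by the fit.
#' @return Data frame: `phenophase`, `parameter`, `estimate` (days),
#'   `std_error`, `eti90_low/high`, `eti95_low/high`, `effect_90`,
#'   `effect_95`.
#' @export
summarize_effects <- function(fit, scaling = NULL) {
  stopifnot(inherits(fit, "posterior_fit"))
  if (is.null(scaling)) scaling <- fit$scaling
  if (is.null(scaling)) stop("no scaling record available; supply `scaling`")
  sc <- scaling$scale[match(fit$phenophase, scaling$phenophase)]
  if (is.na(sc)) stop("scaling record lacks phenophase ", fit$phenophase)
  pars <- c("beta", grep("^b[23]_", colnames(fit$draws), value = TRUE))
  rows <- lapply(pars, function(p) {
    d <- fit$draws[, p] * sc
    e90 <- compute_eti(d, 0.90)
    e95 <- compute_eti(d, 0.95)
    data.frame(
      phenophase = fit$phenophase,
      parameter = if (p == "beta") "OTC" else sub("^b3_", "OTC x ",
                                                  sub("^b2_", "", p)),
      estimate = mean(d), std_error = sd(d),
      eti90_low = e90[1], eti90_high = e90[2],
      eti95_low = e95[1], eti95_high = e95[2],
      effect_90 = unname(e90[1] > 0 | e90[2] < 0),
      effect_95 = unname(e95[1] > 0 | e95[2] < 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat("Hierarchical", x$model, "model fit:", x$phenophase, "\n")
  if (!is.null(x$predictor)) cat("  predictor:", x$predictor, "\n")
  cat("  replicates:", x$n_replicates,
      " chains:", x$spec$chains,
      " kept iterations/chain:", x$spec$iter - x$spec$warmup, "\n")
  cat("  max split R-hat:", round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  beta <- x$draws[, "beta"]
  cat("  beta (standardized): ", round(mean(beta), 4), " +/- ",
      round(sd(beta), 4), "\n", sep = "")
  invisible(x)
}
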
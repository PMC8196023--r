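# Preparation rules: prior-visit assignment with fallback bounds, the three
# filters, standardization, ledger conservation and idempotence.

test_that("prior visits are recomputed from the visit history", {
  obs <- toy_obs(doy = 164, prior = NA)
  hist <- data.frame(plot = "p1", year = 2001L, doy = c(150L, 157L, 164L))
  out <- assign_prior_visits(obs, hist)
  expect_equal(out$prior_visit, 157L)
  expect_false(out$fallback_bound)
})

test_that("fallback bounds use species minimum prior visit minus 21, floored", {
  # green up: min prior 140 -> 140 - 21 = 119 >= floor 100
  obs <- rbind(
    toy_obs(doy = 150, prior = 140, phenophase = "green_up", plot = "p1"),
    toy_obs(doy = 145, prior = NA, phenophase = "green_up", plot = "p2")
  )
  out <- assign_prior_visits(obs)
  expect_equal(out$prior_visit[2], 119L)
  expect_true(out$fallback_bound[2])

  # flowering: min prior 130 -> max(109, 120) = 120 (floor binds)
  obs2 <- rbind(
    toy_obs(doy = 150, prior = 130, phenophase = "flowering", plot = "p1"),
    toy_obs(doy = 145, prior = NA, phenophase = "flowering", plot = "p2")
  )
  out2 <- assign_prior_visits(obs2)
  expect_equal(out2$prior_visit[2], 120L)

  # phenophase without a stated floor warns and uses 100
  obs3 <- toy_obs(doy = 150, prior = NA, phenophase = "fruiting")
  expect_warning(out3 <- assign_prior_visits(obs3), "floor")
  expect_equal(out3$prior_visit, 100L)
})

test_that("fallback bound stays a strict lower bound for early events", {
  obs <- rbind(
    toy_obs(doy = 150, prior = 145, phenophase = "green_up", plot = "p1"),
    toy_obs(doy = 118, prior = NA, phenophase = "green_up", plot = "p2")
  )
  out <- assign_prior_visits(obs)
  expect_lt(out$prior_visit[2], out$doy[2])
})

test_that("missingness filter drops only green up / senescence cells over 20%", {
  mk_cell <- function(ph, n_miss, n_tot, subsite) {
    o <- toy_obs(doy = c(rep(150L, n_tot - n_miss), rep(NA, n_miss)),
                 prior = 143, phenophase = ph, subsite = subsite,
                 plot = paste0("p", seq_len(n_tot)))
    o$is_missing <- is.na(o$doy)
    o
  }
  obs <- rbind(mk_cell("green_up", 5, 20, "ssA"),   # 25% -> dropped
               mk_cell("green_up", 3, 20, "ssB"),   # 15% -> kept
               mk_cell("flowering", 10, 20, "ssC")) # 50% but exempt -> kept
  res <- apply_missingness_filter(obs)
  kept <- res$observations
  expect_false(any(kept$subsite == "ssA"))
  expect_equal(sum(kept$subsite == "ssB"), 17L)  # missing rows also removed
  expect_equal(sum(kept$subsite == "ssC"), 10L)
  expect_equal(sum(res$ledger$dropped) + nrow(kept), nrow(obs))
})

test_that("minimum-replication filter needs 2 observations per treatment", {
  cell <- function(n_otc, n_ctl, subsite) {
    rbind(
      toy_obs(doy = 150, prior = 143, treatment = "OTC", subsite = subsite,
              plot = paste0(subsite, "_w", seq_len(n_otc))),
      toy_obs(doy = 152, prior = 143, treatment = "CTL", subsite = subsite,
              plot = paste0(subsite, "_c", seq_len(n_ctl)))
    )
  }
  obs <- rbind(cell(1, 3, "ssA"),  # dropped: 1 warmed
               cell(2, 2, "ssB"))  # kept: boundary
  res <- filter_min_observations(obs)
  expect_setequal(unique(res$observations$subsite), "ssB")
  expect_equal(res$ledger$dropped, 4L)

  empty <- filter_min_observations(obs[0, ])
  expect_equal(nrow(empty$observations), 0L)
  expect_equal(empty$ledger$dropped, 0L)
})

test_that("outlier filter removes cells beyond 4 SD of the phenophase mean", {
  # build cells whose OTC-CTL midpoint differences are known exactly
  mk_cell <- function(diff, subsite) {
    rbind(
      toy_obs(doy = 150L + diff, prior = 140L + diff, treatment = "OTC",
              subsite = subsite, plot = paste0(subsite, "_w", 1:2)),
      toy_obs(doy = 150, prior = 140, treatment = "CTL", subsite = subsite,
              plot = paste0(subsite, "_c", 1:2))
    )
  }
  diffs <- c(-2, -1, 0, 1, 2, 9)  # mean 1.5, sd ~3.9 -> 9 is within 4 SD
  obs <- do.call(rbind, Map(mk_cell, diffs, paste0("ss", seq_along(diffs))))
  got <- replicate_differences(obs)
  expect_equal(sort(got$diff), sort(diffs))

  # a lone extreme cell against 30 tight reference cells is removed
  # (the 4-SD rule needs n > 17 before any single cell can exceed it,
  # since max |z| = (n-1)/sqrt(n))
  diffs2 <- c(rep(c(-1, 0, 1), 10), 60)
  obs2 <- do.call(rbind, Map(mk_cell, diffs2, paste0("ss", seq_along(diffs2))))
  res <- remove_outliers(obs2)
  expect_equal(res$ledger$dropped, 4L)  # one 4-row cell
  expect_false(any(res$observations$subsite == "ss31"))
  # every retained cell is within the limit recomputed from the rule
  d <- res$differences
  lim <- mean(d$diff) + 4 * sd(d$diff)
  kept_diffs <- d$diff[d$subsite %in% res$observations$subsite]
  expect_true(all(kept_diffs < lim))

  # degenerate: all equal differences, SD 0 -> nothing removed
  obs3 <- do.call(rbind, Map(mk_cell, rep(2, 4), paste0("ss", 1:4)))
  expect_equal(remove_outliers(obs3)$ledger$dropped, 0L)

  # fewer than 3 cells: no removal
  obs4 <- do.call(rbind, Map(mk_cell, c(0, 50), c("ssA", "ssB")))
  expect_equal(remove_outliers(obs4)$ledger$dropped, 0L)
})

test_that("standardization centers and scales midpoints per phenophase", {
  obs <- toy_obs(doy = c(155L, 165L, 175L), prior = c(145L, 155L, 165L),
                 plot = paste0("p", 1:3))
  s <- standardize(obs)
  expect_equal(s$intervals$midpoint_std, c(-1, 0, 1))
  expect_equal(s$scaling$center, 160)
  expect_equal(s$scaling$scale, 10)
  # both bounds share the affine map
  expect_equal(s$intervals$upper_std - s$intervals$lower_std,
               rep(10 / 10, 3))

  # affine invariance: shifting all days leaves standardized values unchanged
  obs5 <- obs
  obs5$doy <- obs5$doy + 5L
  obs5$prior_visit <- obs5$prior_visit + 5L
  s5 <- standardize(obs5)
  expect_equal(s5$intervals$midpoint_std, s$intervals$midpoint_std)

  # back-transform of a standardized effect
  expect_equal(0.24 * s$scaling$scale, 2.4)

  # zero SD aborts
  obs0 <- toy_obs(doy = c(150L, 150L), prior = c(143L, 143L),
                  plot = c("p1", "p2"))
  expect_error(standardize(obs0), "SD is zero")
  # monotone: order of midpoints preserved
  expect_equal(order(s$intervals$midpoint), order(s$intervals$midpoint_std))
})

test_that("filters are idempotent and ledgers reconcile", {
  sim <- small_sim(seed = 17, phenophases = c("green_up", "flowering"))
  obs <- assign_prior_visits(sim$observations, sim$schedules)
  m1 <- apply_missingness_filter(obs)
  m2 <- apply_missingness_filter(m1$observations)
  expect_equal(nrow(m2$observations), nrow(m1$observations))

  f1 <- filter_min_observations(m1$observations)
  f2 <- filter_min_observations(f1$observations)
  expect_equal(f2$observations, f1$observations)

  o1 <- remove_outliers(f1$observations)
  o2 <- remove_outliers(o1$observations)
  expect_equal(nrow(o2$observations), nrow(o1$observations))

  # full pipeline ledger conserves rows rule by rule
  prep <- prep_observations(sim$observations, sim$schedules)
  led <- prep$ledger
  expect_equal(led$retained[1] - led$dropped[2], led$retained[2])
  expect_equal(led$retained[2] - led$dropped[3], led$retained[3])
  expect_equal(led$retained[3] - led$dropped[4], led$retained[4])
  expect_equal(nrow(prep$intervals), led$retained[4])
})
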
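# Small-cohort smoke and contract tests for the hierarchical fits; the
# full-scale parameter-recovery checks live in test-acceptance.R.

quiet_fit_rl <- function(...) suppressWarnings(fit_rl(...))
quiet_fit_ddm <- function(...) suppressWarnings(fit_ddm(...))

test_that("the RL fit returns a complete, reproducible posterior", {
  co <- make_learning_cohort(5, truth_seed = 7, sched_seed = 50,
                             sim_seed = 60)
  cfg <- mcmc_config(120, 120, 2, seed = 3)
  fit <- quiet_fit_rl(co$trials, cfg)
  expect_s3_class(fit, "rl_fit")
  s <- summary(fit)
  expect_true(all(c("parameter", "mean", "mode", "ci_lower", "ci_upper",
                    "rhat", "level") %in% names(s)))
  expect_true(all(s$ci_lower <= s$ci_upper))
  # split R-hat can dip below 1 by at most its finite-sample floor
  # sqrt(1 - 1/half) when the between-half variance is tiny
  floor_rhat <- sqrt(1 - 1 / (cfg$iterations %/% 2))
  expect_true(all(s$rhat >= floor_rhat - 1e-8, na.rm = TRUE))
  # six group-level natural-scale rows: both rates, both temperatures, and
  # the two within-group contrasts
  expect_setequal(s$parameter[s$level == "group"],
                  c("eta_r", "eta_p", "tau_r", "tau_p", "eta_diff",
                    "tau_diff"))
  expect_equal(nrow(coef(fit)), 5L)
  expect_true(all(coef(fit)[, c("eta_r", "eta_p")] > 0 &
                    coef(fit)[, c("eta_r", "eta_p")] < 1))

  # identical config and seed reproduce identical summaries
  fit2 <- quiet_fit_rl(co$trials, cfg)
  expect_identical(fit$summary, fit2$summary)

  expect_error(fit_rl(co$trials[co$trials$participant_id == 1, ], cfg),
               "2 participants")
})

test_that("degenerate all-target choices do not crash the RL fit", {
  co <- make_learning_cohort(3, truth_seed = 8, sched_seed = 70,
                             sim_seed = 80)
  co$trials$chose_target <- 1L
  fit <- quiet_fit_rl(co$trials, mcmc_config(80, 80, 2, seed = 5))
  expect_s3_class(fit, "rl_fit")
  expect_true(all(is.finite(summary(fit)$mean)))
})

test_that("the DDM fit returns a complete posterior and never samples z", {
  co <- make_search_cohort(4, truth_seed = 9, sched_seed = 90,
                           sim_seed = 95, dt = 1e-3)
  stp <- co$trials[co$trials$target_present == 1, ]
  cfg <- mcmc_config(100, 100, 2, seed = 4)
  fit <- quiet_fit_ddm(stp, cfg)
  expect_s3_class(fit, "ddm_fit")
  s <- summary(fit)
  expect_false(any(grepl("^z", s$parameter)))
  expect_true(all(s$ci_lower <= s$ci_upper))
  expect_true("t0" %in% s$parameter)
  # the population t0 honours its (0, min rt) support
  expect_lt(s$mean[s$parameter == "t0"], min(stp$rt_sec))
  expect_gt(s$mean[s$parameter == "t0"], 0)
  expect_equal(dim(coef(fit)), c(4L, 6L))

  fit2 <- quiet_fit_ddm(stp, cfg)
  expect_identical(fit$summary, fit2$summary)

  expect_error(fit_ddm(co$trials, cfg), "target-present")
})

test_that("posterior predictive checks recover their own statistics", {
  co <- make_learning_cohort(5, truth_seed = 7, sched_seed = 50,
                             sim_seed = 60)
  fit <- quiet_fit_rl(co$trials, mcmc_config(150, 150, 2, seed = 3))
  ppc <- posterior_predictive(fit, co$trials, ndraws = 60, seed = 2,
                              block_size = 20)
  expect_s3_class(ppc, "ppc")
  expect_true(all(ppc$pred_lower <= ppc$pred_upper))
  # data simulated from the fitted posterior itself: observed curves fall
  # inside the 95% bands in at least 90% of bins
  expect_gte(attr(ppc, "coverage"), 0.9)
})

test_that("DDM predictive quantiles are monotone and calibrated", {
  co <- make_search_cohort(4, truth_seed = 9, sched_seed = 90,
                           sim_seed = 95, dt = 1e-3)
  stp <- co$trials[co$trials$target_present == 1, ]
  fit <- quiet_fit_ddm(stp, mcmc_config(120, 120, 2, seed = 4))
  ppc <- posterior_predictive(fit, stp, ndraws = 40, seed = 3)
  expect_s3_class(ppc, "ppc")
  for (cc in unique(ppc$condition)) {
    expect_true(all(diff(ppc$pred_mean[ppc$condition == cc]) > 0))
    expect_true(all(diff(ppc$observed[ppc$condition == cc]) >= 0))
  }
  expect_gte(attr(ppc, "coverage"), 0.8)

  # an empty posterior is rejected
  broken <- fit
  broken$draws <- lapply(broken$draws, function(d) d[0, , drop = FALSE])
  expect_error(posterior_predictive(broken, stp, ndraws = 10), "no posterior")
})

test_that("group-level credible intervals cover the generating locations", {
  # 30 independent small replicates; each fitted group location's 95% CI
  # should contain the generating value in >= 80% of replicates
  hy <- population_hyper("young")
  truth_mu <- c(eta_r = qlogis(hy$eta_r), eta_p = qlogis(hy$eta_p),
                tau_r = log(hy$tau_r), tau_p = log(hy$tau_p))
  hits <- matrix(NA, 30, 4, dimnames = list(NULL, names(truth_mu)))
  for (r in 1:30) {
    co <- make_learning_cohort(8, truth_seed = 100 + r,
                               sched_seed = 3000 + 10 * r,
                               sim_seed = 4000 + 10 * r)
    fit <- quiet_fit_rl(co$trials, mcmc_config(250, 250, 2, seed = 10 + r))
    s <- summary(fit)
    for (p in names(truth_mu)) {
      row <- s[s$parameter == paste0("mu_", p), ]
      hits[r, p] <- truth_mu[p] >= row$ci_lower & truth_mu[p] <= row$ci_upper
    }
  }
  expect_true(all(colMeans(hits) >= 0.8))
})

test_that("rank of truth under the posterior is uniform (reduced SBC)", {
  # simulation-based calibration at reduced scale on the individual-level
  # reward model: draw (eta, tau) from the prior, simulate 100 reward
  # trials, compute the posterior rank of the true learning rate by grid
  # integration with the same prior; ranks must be uniform
  set.seed(71)
  n_rep <- 50
  m_e <- qlogis(0.1); s_e <- 1
  m_t <- log(6); s_t <- 0.4
  ge <- seq(m_e - 3.5 * s_e, m_e + 3.5 * s_e, length.out = 41)
  gt <- seq(m_t - 3.5 * s_t, m_t + 3.5 * s_t, length.out = 31)
  G <- expand.grid(e = ge, tt = gt)
  lprior <- dnorm(G$e, m_e, s_e, log = TRUE) + dnorm(G$tt, m_t, s_t,
                                                     log = TRUE)
  sched <- data.frame(block = 1L, trial = 1:100, pair_id = 1L,
                      condition = "reward", arrangement = 0L,
                      practice = FALSE)
  ranks <- vapply(seq_len(n_rep), function(r) {
    e_true <- rnorm(1, m_e, s_e)
    t_true <- rnorm(1, m_t, s_t)
    p <- data.frame(participant_id = 1L, group = "g",
                    eta_r = plogis(e_true), eta_p = 0.1,
                    tau_r = exp(t_true), tau_p = 1)
    tr <- simulate_learning_agent(p, sched, seed = 7000 + r)
    ll <- vapply(seq_len(nrow(G)), function(k) {
      rl_loglik(list(eta_r = plogis(G$e[k]), eta_p = 0.1,
                     tau_r = exp(G$tt[k]), tau_p = 1), tr)
    }, 0)
    w <- exp(ll + lprior - max(ll + lprior))
    w <- w / sum(w)
    marg <- rowSums(matrix(w, nrow = length(ge)))  # e varies fastest
    # posterior CDF at the true value, jittered within its grid cell
    cdf_below <- sum(marg[ge < e_true])
    cell <- sum(marg[which.min(abs(ge - e_true))])
    cdf_below + runif(1) * cell
  }, 0)
  expect_gt(ks.test(ranks, "punif")$p.value, 0.01)
})
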
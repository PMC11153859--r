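test_that("population sampling respects sizes, supports and seeds", {
  hy <- population_hyper("young")
  ho <- population_hyper("old")
  young <- sample_population(hy, 29, seed = 1)
  old <- sample_population(ho, 32, seed = 2, id_offset = 29)
  both <- rbind(young, old)
  expect_equal(nrow(both), 61L)
  expect_equal(both$participant_id, 1:61)
  expect_true(all(both$eta_r > 0 & both$eta_r < 1))
  expect_true(all(both$eta_p > 0 & both$eta_p < 1))
  expect_true(all(both$tau_r > 0 & both$tau_p > 0))
  expect_true(all(both[paste0("alpha_", c("reward", "punishment", "zero"))] > 0))
  expect_true(all(both$t0 > 0))
  expect_identical(young, sample_population(hy, 29, seed = 1))

  # degenerate scale limit: everyone collapses onto the group location
  tight <- population_hyper("young", eta_sd = 1e-8, tau_sd = 1e-8)
  pop <- sample_population(tight, 10, seed = 3)
  expect_equal(pop$eta_r, rep(0.05, 10), tolerance = 1e-6)
  expect_equal(pop$tau_r, rep(7.98, 10), tolerance = 1e-6)

  expect_error(population_hyper("young", eta_sd = -1), "scale")
  expect_error(population_hyper("young", eta_r = 1.4), "learning-rate")
})

test_that("hyper presets centre the two groups on distinct regimes", {
  hy <- population_hyper("young")
  ho <- population_hyper("old")
  expect_gt(hy$eta_r, ho$eta_r)
  expect_gt(hy$eta_p, ho$eta_p)
  expect_lt(hy$t0, ho$t0)
  expect_true(all(hy$nu > ho$nu))
})

test_that("simulated outcomes honour the feedback contingency", {
  hy <- population_hyper("young", eta_r = 0.2, tau_r = 8)
  p <- sample_population(hy, 1, seed = 4)
  sched <- data.frame(block = 1L, trial = seq_len(20000),
                      pair_id = 1L, condition = "reward",
                      arrangement = 0L, practice = FALSE)
  tr <- simulate_learning_agent(p, sched, contingency = 0.8, seed = 6)
  tgt <- tr[tr$chose_target == 1, ]
  expect_gt(nrow(tgt), 10000)
  expect_equal(mean(tgt$outcome == 1), 0.8, tolerance = 0.01 / 0.8)
  # nontarget choices carry the reversed probability; the learned agent
  # rarely picks the nontarget, so allow Monte-Carlo slack for the small
  # sample of such trials
  non <- tr[tr$chose_target == 0, ]
  expect_lt(abs(mean(non$outcome == 1) - 0.2),
            3 * sqrt(0.2 * 0.8 / nrow(non)))

  expect_error(simulate_learning_agent(p, sched, contingency = 1.2),
               "contingency")
})

test_that("zero-condition outcomes are always zero", {
  hy <- population_hyper("young")
  p <- sample_population(hy, 1, seed = 4)
  tr <- simulate_learning_agent(p, build_learning_schedule(9), seed = 10)
  expect_true(all(tr$outcome[tr$condition == "zero"] == 0))
  expect_equal(nrow(validate_trials(tr)), 0L)
})

test_that("strong learners approach ceiling choice in the reward condition", {
  hy <- population_hyper("young", eta_r = 0.5, tau_r = 30,
                         eta_sd = 1e-6, tau_sd = 1e-6)
  p <- sample_population(hy, 1, seed = 4)
  tr <- simulate_learning_agent(p, build_learning_schedule(12), seed = 13)
  rew <- tr[tr$condition == "reward", ]
  last_block <- rew[rew$block == 10, ]
  expect_gt(mean(last_block$chose_target), 0.9)
})

test_that("average learning curves rise under positive learning rates", {
  hy <- population_hyper("young", eta_r = 0.15, tau_r = 6)
  agents <- sample_population(hy, 200, seed = 5)
  sched <- build_learning_schedule(77)
  props <- sapply(1:200, function(i) {
    tr <- simulate_learning_agent(agents[i, ], sched, seed = 500 + i)
    rew <- tr[tr$condition == "reward", ]
    half <- nrow(rew) %/% 2
    c(mean(rew$chose_target[seq_len(half)]),
      mean(rew$chose_target[(half + 1):nrow(rew)]))
  })
  expect_gt(mean(props[2, ]), mean(props[1, ]))
})

test_that("exact block balance schedules the stated number of payouts", {
  hy <- population_hyper("young")
  p <- sample_population(hy, 1, seed = 4)
  sched <- build_learning_schedule(21)
  tr <- simulate_learning_agent(p, sched, seed = 22,
                                exact_block_balance = TRUE)
  # flags are exactly 8 of 10 per (pair, block); a trial delivers its outcome
  # to the choice the flag points at, so delivered payouts per block stay
  # within the schedule extremes whatever the agent chooses
  rew <- tr[tr$condition == "reward", ]
  delivered <- tapply(rew$outcome != 0, rew$block, sum)
  # with mixed choices the count stays between the two schedule extremes
  expect_true(all(delivered >= 0 & delivered <= 10))
  expect_equal(nrow(validate_trials(tr)), 0L)
})

test_that("search simulation respects the non-decision floor and drift sign", {
  hy <- population_hyper("young")
  p <- sample_population(hy, 1, seed = 8)
  sched <- build_search_schedule(30)
  tr <- simulate_search_participant(p, sched, seed = 31, dt = 5e-4)
  expect_true(all(tr$rt_sec > p$t0))
  expect_equal(nrow(validate_trials(tr)), 0L)
  # extreme positive drift: target-present responses all "present"
  fast <- p
  for (cc in c("reward", "punishment", "zero")) fast[[paste0("nu_", cc)]] <- 40
  tr <- simulate_search_participant(fast, sched, seed = 32, dt = 5e-4)
  pres <- tr[tr$target_present == 1, ]
  expect_true(all(pres$response == "present"))
})

test_that("search choice rates and quantiles match the density oracle", {
  set.seed(41)
  sim <- simulate_ddm(20000, alpha = 1.7, nu = 1.1, t0 = 0.35, dt = 2e-4)
  expect_equal(mean(sim$upper), boundary_prob(1.7, 1.1), tolerance = 0.01)
  tt <- seq(0.3501, 15, length.out = 4096)
  dens <- wfpt_density(tt, 1.7, 1.1, 0.35, boundary = "upper")
  cdf <- cumsum(dens) * (tt[2] - tt[1])
  cdf <- cdf / cdf[length(cdf)]
  qs <- approx(cdf, tt, xout = c(0.25, 0.5, 0.75), ties = "ordered")$y
  expect_equal(unname(quantile(sim$rt[sim$upper == 1], c(0.25, 0.5, 0.75))),
               qs, tolerance = 0.02)
})

test_that("generative model and likelihood are self-consistent", {
  co <- make_learning_cohort(10, truth_seed = 14, sched_seed = 300,
                             sim_seed = 400)
  ll_at <- function(scale) {
    sum(vapply(seq_len(10), function(i) {
      tr <- co$trials[co$trials$participant_id == i, ]
      p <- co$truth[i, ]
      rl_loglik(list(eta_r = min(p$eta_r * scale, 0.99),
                     eta_p = min(p$eta_p * scale, 0.99),
                     tau_r = p$tau_r * scale, tau_p = p$tau_p * scale), tr)
    }, 0))
  }
  expect_gt(ll_at(1), ll_at(2))
  expect_gt(ll_at(1), ll_at(0.5))
})

test_that("a full study is emitted with matching truth and reproducibly", {
  cfg <- study_config(n_young = 2L, n_old = 2L, dt = 1e-3)
  out <- generate_study(cfg, seed = 9)
  expect_equal(nrow(out$learning), 4L * 300L)
  expect_equal(nrow(out$search), 4L * 192L)
  expect_equal(nrow(out$truth), 4L)
  expect_equal(unique(out$learning$group), c("young", "old"))
  out2 <- generate_study(cfg, seed = 9)
  expect_identical(out, out2)

  dir <- tempfile()
  generate_study(cfg, seed = 9, outdir = dir)
  expect_true(all(file.exists(file.path(dir, c("learning_trials.csv",
                                               "search_trials.csv",
                                               "truth.csv")))))
  lt <- read.csv(file.path(dir, "learning_trials.csv"))
  expect_equal(nrow(lt), 1200L)
  expect_equal(nrow(validate_trials(lt)), 0L)
})
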
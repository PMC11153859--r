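#' Group-level hyperparameters for synthetic cohorts
#'
#' Describes the population distributions that synthetic participants are
#' drawn from: learning rates on the logit scale, inverse temperatures and
#' boundary separations on the log scale, drift rates on the natural scale,
#' and a within-condition correlation between log boundary separation and
#' drift. The `"young"` and `"old"` presets centre the learning-model
#' locations on posterior group means typical of young and older adults in
#' value-learning studies (eta_r = 0.05 / 0.01, eta_p = 0.12 / 0.02,
#' tau_r = 7.98 / 11.70, tau_p = 4.50 / 3.95) and give the older group a
#' larger boundary separation, lower drift and longer non-decision time; they
#' are generator defaults, not empirical claims.
#'
#' @param group `"young"` or `"old"` selects a preset; other labels require
#'   all locations explicitly.
#' @param ... named overrides of any field (see Details).
#' @return object of class `population_hyper`: a list with fields `group`,
#'   `eta_r`, `eta_p`, `tau_r`, `tau_p` (locations, natural scale), `eta_sd`
#'   (logit-scale SD), `tau_sd` (log-scale SD), `alpha`, `nu` (length-3
#'   vectors, reward/punishment/zero), `alpha_sd` (log-scale SD), `nu_sd`,
#'   `t0`, `t0_sd` (log-scale SD), `rho` (within-condition cor(log alpha,
#'   nu)), `alpha_absent`, `nu_absent` (target-absent generation extras).
#' @export
population_hyper <- function(group = c("young", "old"), ...) {
  if (is.character(group) && group[1L] %in% c("young", "old")) {
    group <- match.arg(group)
    preset <- if (group == "young") {
      list(eta_r = 0.05, eta_p = 0.12, tau_r = 7.98, tau_p = 4.50,
           alpha = c(reward = 1.60, punishment = 1.60, zero = 1.60),
           nu = c(reward = 1.42, punishment = 1.42, zero = 1.30),
           t0 = 0.36)
    } else {
      list(eta_r = 0.01, eta_p = 0.02, tau_r = 11.70, tau_p = 3.95,
           alpha = c(reward = 1.74, punishment = 1.75, zero = 1.77),
           nu = c(reward = 1.07, punishment = 0.93, zero = 0.98),
           t0 = 0.50)
    }
  } else {
    preset <- list()
  }
  h <- modifyList(c(preset,
                    list(group = if (is.character(group)) group[1L] else "custom",
                         eta_sd = 1.0, tau_sd = 0.3,
                         alpha_sd = 0.15, nu_sd = 0.4, t0_sd = 0.05,
                         rho = 0.3,
                         alpha_absent = 1.85, nu_absent = -1.2)),
                  list(...))
  for (f in c("eta_r", "eta_p", "tau_r", "tau_p", "alpha", "nu", "t0")) {
    if (is.null(h[[f]])) stop("hyperparameter '", f, "' missing")
  }
  if (any(c(h$eta_sd, h$tau_sd, h$alpha_sd, h$nu_sd, h$t0_sd) <= 0)) {
    stop("all scale hyperparameters must be > 0")
  }
  if (h$eta_r <= 0 || h$eta_r >= 1 || h$eta_p <= 0 || h$eta_p >= 1) {
    stop("learning-rate locations must lie in (0, 1)")
  }
  if (any(c(h$tau_r, h$tau_p, h$alpha, h$t0) <= 0)) {
    stop("tau, alpha and t0 locations must be > 0")
  }
  if (abs(h$rho) >= 1) stop("rho must lie in (-1, 1)")
  structure(h, class = "population_hyper")
}

#' Draw synthetic participants from a population
#'
#' Samples individual RL and DDM parameters from the group distributions:
#' logit learning rates and log inverse temperatures are normal around the
#' logit/log of the group locations; per condition, (log alpha, nu) is
#' bivariate normal with correlation `rho`; t0 is log-normal around the group
#' location.
#'
#' @param hyper a [population_hyper()] object.
#' @param n number of participants, >= 1.
#' @param seed integer seed.
#' @param id_offset participant ids are `id_offset + 1 .. id_offset + n`.
#' @return data.frame with one row per participant: `participant_id`,
#'   `group`, `eta_r`, `eta_p`, `tau_r`, `tau_p`,
#'   `alpha_reward/punishment/zero`, `nu_reward/punishment/zero`, `t0`,
#'   `alpha_absent`, `nu_absent`.
#' @export
sample_population <- function(hyper, n, seed, id_offset = 0L) {
  stopifnot(inherits(hyper, "population_hyper"), n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  out <- data.frame(
    participant_id = id_offset + seq_len(n),
    group = hyper$group,
    eta_r = plogis(rnorm(n, qlogis(hyper$eta_r), hyper$eta_sd)),
    eta_p = plogis(rnorm(n, qlogis(hyper$eta_p), hyper$eta_sd)),
    tau_r = exp(rnorm(n, log(hyper$tau_r), hyper$tau_sd)),
    tau_p = exp(rnorm(n, log(hyper$tau_p), hyper$tau_sd)),
    stringsAsFactors = FALSE
  )
  for (cond in LEARN_CONDITIONS) {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    out[[paste0("alpha_", cond)]] <-
      exp(log(hyper$alpha[[cond]]) + hyper$alpha_sd * z1)
    out[[paste0("nu_", cond)]] <-
      hyper$nu[[cond]] + hyper$nu_sd * (hyper$rho * z1 +
                                          sqrt(1 - hyper$rho^2) * z2)
  }
  out$t0 <- exp(rnorm(n, log(hyper$t0), hyper$t0_sd))
  out$alpha_absent <- exp(rnorm(n, log(hyper$alpha_absent), hyper$alpha_sd))
  out$nu_absent <- hyper$nu_absent + hyper$nu_sd * rnorm(n)
  out
}

#' Simulate one participant's associative learning session
#'
#' Walks the learning schedule with the dual-rate RW/softmax generative
#' model: choices from the softmax over current expected values, outcomes
#' from the feedback contingency (target choice in the reward condition earns
#' +1 with probability `contingency`, else 0; punishment mirrors with -1; the
#' nontarget carries the reversed probability; zero-condition outcomes are
#' always 0). With `exact_block_balance = TRUE` the feedback flags are
#' pre-scheduled per pair and block (exactly `contingency * 10` of the 10
#' presentations deliver the contingent outcome) instead of drawn per trial.
#'
#' @param participant one row of [sample_population()] output.
#' @param schedule output of [build_learning_schedule()].
#' @param contingency probability that the scheduled outcome is delivered for
#'   a target choice; in \[0, 1\].
#' @param seed integer seed.
#' @param exact_block_balance logical; see Description.
#' @return data.frame of learning trials: `participant_id`, `group`, `block`,
#'   `trial`, `condition`, `chose_target`, `outcome`.
#' @export
simulate_learning_agent <- function(participant, schedule, contingency = 0.8,
                                    seed = 1L, exact_block_balance = FALSE) {
  if (contingency < 0 || contingency > 1) stop("contingency must be in [0, 1]")
  sched <- schedule[!schedule$practice, ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  cond_i <- condition_code(sched$condition, "rl")
  if (!exact_block_balance) {
    sim <- rl_sim_cpp(cond_i, participant$eta_r, participant$eta_p,
                      participant$tau_r, participant$tau_p, contingency)
  } else {
    sim <- rl_sim_balanced(sched, cond_i, participant, contingency)
  }
  data.frame(participant_id = participant$participant_id,
             group = participant$group,
             block = sched$block, trial = sched$trial,
             condition = sched$condition,
             chose_target = as.integer(sim$chose_target),
             outcome = sim$outcome,
             stringsAsFactors = FALSE)
}

# Pre-scheduled feedback variant: per (pair, block), exactly
# round(contingency * k) of the k presentations carry the contingent flag;
# a flagged trial delivers the condition's outcome to a target choice (and 0
# to a nontarget choice), an unflagged trial the reverse.
rl_sim_balanced <- function(sched, cond_i, participant, contingency) {
  n <- nrow(sched)
  flag <- logical(n)
  for (b in unique(sched$block)) {
    for (p in unique(sched$pair_id)) {
      idx <- which(sched$block == b & sched$pair_id == p)
      k <- length(idx)
      n_on <- round(contingency * k)
      flag[idx] <- sample(rep(c(TRUE, FALSE), c(n_on, k - n_on)))
    }
  }
  ev <- matrix(0, 2, 2)  # [condition, option]: 1 = target, 2 = nontarget
  chose <- integer(n)
  outcome <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cond_i[i]
    if (ci == 0L) {
      chose[i] <- as.integer(runif(1) < 0.5)
      next
    }
    tau <- if (ci == 1L) participant$tau_r else participant$tau_p
    eta <- if (ci == 1L) participant$eta_r else participant$eta_p
    pt <- choice_prob(ev[ci, 1], ev[ci, 2], tau)
    ch <- if (runif(1) < pt) 1L else 2L
    chose[i] <- as.integer(ch == 1L)
    val <- if (ci == 1L) 1 else -1
    delivered <- if (ch == 1L) flag[i] else !flag[i]
    outcome[i] <- if (delivered) val else 0
    ev[ci, ch] <- update_value(ev[ci, ch], outcome[i], eta)
  }
  data.frame(chose_target = chose, outcome = outcome)
}

#' Simulate one participant's visual search session
#'
#' Target-present trials are drawn from the Wiener process with the
#' participant's condition-specific boundary separation and drift, shared
#' non-decision time and unbiased start point; target-absent trials use the
#' participant's absent-condition parameters (negative drift toward the
#' "absent" boundary). The "present" response maps to the upper boundary.
#'
#' @param participant one row of [sample_population()] output.
#' @param schedule output of [build_search_schedule()].
#' @param seed integer seed.
#' @param dt Euler-Maruyama step (seconds).
#' @return data.frame of search trials: `participant_id`, `group`, `block`,
#'   `trial`, `condition`, `target_present`, `response`, `rt_sec`.
#' @export
simulate_search_participant <- function(participant, schedule, seed = 1L,
                                        dt = 1e-4) {
  sched <- schedule[!schedule$practice, ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rt <- numeric(nrow(sched))
  resp <- character(nrow(sched))
  for (cond in SEARCH_CONDITIONS) {
    idx <- which(sched$condition == cond)
    if (!length(idx)) next
    if (cond == "absent") {
      a <- participant$alpha_absent
      v <- participant$nu_absent
    } else {
      a <- participant[[paste0("alpha_", cond)]]
      v <- participant[[paste0("nu_", cond)]]
    }
    sim <- simulate_ddm(length(idx), alpha = a, nu = v,
                        t0 = participant$t0, z = 0.5, dt = dt)
    rt[idx] <- sim$rt
    resp[idx] <- ifelse(sim$upper == 1, "present", "absent")
  }
  data.frame(participant_id = participant$participant_id,
             group = participant$group,
             block = sched$block, trial = sched$trial,
             condition = sched$condition,
             target_present = as.integer(sched$condition != "absent"),
             response = resp, rt_sec = rt,
             stringsAsFactors = FALSE)
}

#' Default synthetic-study configuration
#'
#' @param ... named overrides.
#' @return list with `n_young`, `n_old`, `hyper_young`, `hyper_old`,
#'   `contingency`, `dt`, `exact_block_balance`, `practice`.
#' @export
study_config <- function(...) {
  modifyList(list(n_young = 29L, n_old = 32L,
                  hyper_young = population_hyper("young"),
                  hyper_old = population_hyper("old"),
                  contingency = 0.8, dt = 1e-4,
                  exact_block_balance = FALSE, practice = FALSE),
             list(...))
}

#' Generate a complete synthetic study
#'
#' Samples participants from the young and old populations, builds each
#' participant their own pseudo-randomized learning and search schedules, and
#' simulates both sessions. The ground-truth parameter table enables
#' parameter-recovery scoring of downstream fits.
#'
#' @param config a [study_config()] list.
#' @param seed master integer seed; all per-participant seeds derive from it.
#' @param outdir optional directory; when given, writes `learning_trials.csv`,
#'   `search_trials.csv` and `truth.csv` (UTF-8, headers, RT in seconds).
#' @return (invisibly when writing) list with data.frames `learning`,
#'   `search`, `truth`.
#' @export
generate_study <- function(config = study_config(), seed = 1L, outdir = NULL) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  truth <- rbind(
    sample_population(config$hyper_young, config$n_young, seeds[1L]),
    sample_population(config$hyper_old, config$n_old, seeds[2L],
                      id_offset = config$n_young)
  )
  set.seed(seeds[3L])
  pseeds <- matrix(sample.int(.Machine$integer.max - 1L,
                              3L * nrow(truth)), ncol = 3L)
  learning <- vector("list", nrow(truth))
  search <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    lsched <- build_learning_schedule(pseeds[i, 1L], practice = config$practice)
    ssched <- build_search_schedule(pseeds[i, 1L], practice = config$practice)
    learning[[i]] <- simulate_learning_agent(
      truth[i, ], lsched, contingency = config$contingency,
      seed = pseeds[i, 2L], exact_block_balance = config$exact_block_balance)
    search[[i]] <- simulate_search_participant(
      truth[i, ], ssched, seed = pseeds[i, 3L], dt = config$dt)
  }
  out <- list(learning = do.call(rbind, learning),
              search = do.call(rbind, search),
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$learning, file.path(outdir, "learning_trials.csv"),
              row.names = FALSE)
    write.csv(out$search, file.path(outdir, "search_trials.csv"),
              row.names = FALSE)
    write.csv(out$truth, file.path(outdir, "truth.csv"), row.names = FALSE)
    return(invisible(out))
  }
  out
}
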
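# Shared fixture builders: small synthetic cohorts generated in code.

make_learning_cohort <- function(n, hyper = population_hyper("young"),
                                 truth_seed = 42, sched_seed = 1000,
                                 sim_seed = 2000) {
  truth <- sample_population(hyper, n, seed = truth_seed)
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_learning_agent(truth[i, ],
                            build_learning_schedule(sched_seed + i),
                            seed = sim_seed + i)
  }))
  list(truth = truth, trials = trials)
}

make_search_cohort <- function(n, hyper = population_hyper("young"),
                               truth_seed = 99, sched_seed = 500,
                               sim_seed = 700, dt = 1e-4) {
  truth <- sample_population(hyper, n, seed = truth_seed)
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_search_participant(truth[i, ],
                                build_search_schedule(sched_seed + i),
                                seed = sim_seed + i, dt = dt)
  }))
  list(truth = truth, trials = trials)
}

# Four-trial toy sequence with hand-traceable values.
toy_trials <- function() {
  data.frame(
    participant_id = 1L,
    condition = c("reward", "reward", "punishment", "reward"),
    chose_target = c(1L, 0L, 1L, 1L),
    outcome = c(1, 0, -1, 1),
    trial = 1:4
  )
}
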
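test_that("posterior mode finds the KDE peak", {
  expect_equal(posterior_mode(rep(3.2, 500)), 3.2)
  set.seed(81)
  # KDE argmax of a standard normal sample: sampling SD of the mode is
  # ~0.06 at this n, so a 2-SD band is the right check
  expect_equal(posterior_mode(rnorm(10000)), 0, tolerance = 0.12)

  # refinement oracle: coarse-grid argmax within one step of a fine grid
  x <- rlnorm(5000, 0, 0.5)
  m512 <- posterior_mode(x, n_grid = 512L)
  d <- density(x, bw = "nrd0", n = 2048L, from = min(x), to = max(x))
  m2048 <- d$x[which.max(d$y)]
  step <- (max(x) - min(x)) / 511
  expect_lt(abs(m512 - m2048), step)
})

test_that("spearman matches rank-based oracles and handles ties", {
  expect_equal(spearman(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman(1:10, -(1:10))$r, -1)

  set.seed(82)
  x <- sample(1:5, 40, replace = TRUE)  # heavy ties
  y <- x + rnorm(40)
  s <- spearman(x, y)
  expect_equal(s$r, cor(rank(x), rank(y)))           # definitional oracle
  expect_equal(s$r, cor(x, y, method = "spearman"))  # independent library

  # large-sample t approximation for the p-value
  r <- s$r
  tstat <- r * sqrt((40 - 2) / (1 - r^2))
  expect_equal(s$p, 2 * pt(-abs(tstat), 38))

  expect_warning(s0 <- spearman(rep(1, 10), 1:10), "variance")
  expect_true(is.na(s0$r))
  expect_error(spearman(1:3, 1:3), "at least 4")
  expect_error(spearman(1:5, 1:4), "equal length")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(83)
  for (i in 1:20) {
    x <- rnorm(25)
    y <- rnorm(25)
    base <- spearman(x, y)$r
    expect_equal(spearman(exp(x), y)$r, base)
    expect_equal(spearman(x, qlogis(plogis(y)^3))$r, base, tolerance = 1e-12)
    expect_equal(spearman(-x, y)$r, -base)
  }
})

test_that("the correlation table has the stated shape and flags", {
  set.seed(84)
  n <- 29
  base <- rnorm(n)
  rl <- data.frame(eta_r = plogis(base), eta_p = plogis(base + 1),
                   tau_r = exp(base), tau_p = exp(0.5 * base))
  ddm <- data.frame(alpha_reward = exp(base), alpha_punishment = base^3 + base,
                    alpha_zero = plogis(base), nu_reward = 2 * base,
                    nu_punishment = base + 5, nu_zero = -exp(-base))
  rownames(rl) <- rownames(ddm) <- paste0("p", 1:n)
  ct <- correlation_table(rl, ddm)
  expect_equal(nrow(ct), 24L)
  expect_equal(length(unique(ct$ddm_parameter)), 6L)
  expect_equal(length(unique(ct$rl_parameter)), 4L)
  # every ddm column is a monotone transform of the single latent driving
  # all rl columns, so |r| = 1 everywhere and every cell is flagged
  expect_equal(abs(ct$r), rep(1, 24L), tolerance = 1e-9)
  expect_true(all(ct$flag_conservative))

  # independent modes: flags should be rare and median |r| small
  rl2 <- as.data.frame(matrix(rnorm(n * 4), n,
                              dimnames = list(paste0("p", 1:n),
                                              names(rl))))
  ddm2 <- as.data.frame(matrix(rnorm(n * 6), n,
                               dimnames = list(paste0("p", 1:n),
                                               names(ddm))))
  ct2 <- correlation_table(rl2, ddm2)
  expect_lt(median(abs(ct2$r)), 0.30)
  # null flag rate at n = 29: P(|r| > 0.30) ~ 11%, so well under half flagged
  expect_lt(mean(ct2$flag_conservative), 0.5)

  rownames(ddm2)[1] <- "zzz"
  expect_error(correlation_table(rl2, ddm2), "mismatch")
})

test_that("individual posterior modes line up with posterior means when
          posteriors are tight", {
  co <- make_learning_cohort(6, truth_seed = 19, sched_seed = 150,
                             sim_seed = 160)
  fit <- suppressWarnings(fit_rl(co$trials, mcmc_config(150, 150, 2,
                                                        seed = 6)))
  modes <- individual_modes(fit)
  means <- coef(fit)
  expect_equal(dim(modes), c(6L, 4L))
  # agreement within a modest band: posteriors are not razor-thin at this
  # trial count and chain length, so mode and mean track but do not coincide
  expect_gt(cor(as.vector(as.matrix(modes)), as.vector(means)), 0.95)
  expect_equal(as.vector(as.matrix(modes)), as.vector(means),
               tolerance = 0.25)
})

test_that("learning curves aggregate block-wise choice proportions", {
  tr <- data.frame(
    participant_id = rep(1:2, each = 20),
    condition = "reward",
    chose_target = c(rep(1L, 20), rep(c(1L, 0L), 10)),
    trial = rep(1:20, 2)
  )
  tr_all <- tr
  tr_all$chose_target <- 1L  # every participant always picks the target
  lc <- learning_curves(tr_all, block_size = 10L)
  expect_equal(lc$proportion, c(1, 1), ignore_attr = TRUE)
  expect_equal(lc$se, c(0, 0), ignore_attr = TRUE)
  expect_equal(nrow(lc), 2L)

  # alternating chooser alone: exact halves, zero SE across one participant
  lc2 <- learning_curves(tr[21:40, ], block_size = 10L)
  expect_equal(lc2$proportion, c(0.5, 0.5))

  # hand-counted toy: 7 of 10 target choices
  tr3 <- data.frame(participant_id = 1, condition = "punishment",
                    chose_target = c(1, 1, 1, 0, 1, 0, 1, 1, 0, 1),
                    trial = 1:10)
  lc3 <- learning_curves(tr3, block_size = 10L)
  expect_equal(lc3$proportion, 0.7)

  expect_error(learning_curves(tr, block_size = 3L), "divide")

  # SE definition: cross-participant standard error of per-bin proportions
  lc4 <- learning_curves(tr, block_size = 20L)
  props <- c(1, 0.5)
  expect_equal(lc4$proportion, mean(props))
  expect_equal(lc4$se, sd(props) / sqrt(2))
})
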
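test_that("first-passage density is zero below t0 and nonnegative", {
  expect_equal(wfpt_density(c(0.1, 0.2, 0.25), 1.5, 1, t0 = 0.25), c(0, 0, 0))
  tt <- seq(0.26, 5, by = 0.01)
  expect_true(all(wfpt_density(tt, 1.5, 1, t0 = 0.25) >= 0))
  expect_error(wfpt_density(1, -1, 0), "alpha")
})

test_that("zero drift with central start is boundary-symmetric", {
  tt <- seq(0.01, 6, by = 0.01)
  up <- wfpt_density(tt, 1.8, 0, boundary = "upper")
  lo <- wfpt_density(tt, 1.8, 0, boundary = "lower")
  expect_equal(up, lo, tolerance = 1e-12)
})

test_that("the two boundary densities integrate to 1", {
  for (par in list(c(1.2, 0.8, 0.2), c(2.2, -1.5, 0.4), c(0.8, 2.5, 0.1))) {
    f <- function(t) {
      wfpt_density(t, par[1], par[2], par[3], boundary = "upper") +
        wfpt_density(t, par[1], par[2], par[3], boundary = "lower")
    }
    mass <- integrate(f, par[3], Inf, rel.tol = 1e-8)$value
    expect_equal(mass, 1, tolerance = 1e-3)
  }
})

test_that("absorption probabilities match the closed form and the density", {
  expect_equal(boundary_prob(1.5, 0), 0.5)
  expect_equal(boundary_prob(1.5, 50), 1, tolerance = 1e-9)
  expect_equal(boundary_prob(1.5, 1, boundary = "upper") +
                 boundary_prob(1.5, 1, boundary = "lower"), 1)
  # quadrature oracle: integral of the per-boundary density
  for (nu in c(-1.2, 0.4, 2)) {
    q <- integrate(function(t) wfpt_density(t, 1.6, nu, boundary = "upper"),
                   0, Inf, rel.tol = 1e-8)$value
    expect_equal(boundary_prob(1.6, nu, boundary = "upper"), q,
                 tolerance = 1e-3)
  }
})

test_that("series density agrees with the Euler-Maruyama path simulator", {
  set.seed(31)
  sim <- simulate_ddm(20000, alpha = 1.6, nu = 1.2, t0 = 0.3, dt = 2e-4)
  # choice proportions
  expect_equal(mean(sim$upper), boundary_prob(1.6, 1.2), tolerance = 0.02)
  # upper-boundary RT distribution vs density-implied CDF
  rts <- sim$rt[sim$upper == 1]
  tt <- seq(0.3001, 12, length.out = 4096)
  dens <- wfpt_density(tt, 1.6, 1.2, 0.3, boundary = "upper")
  cdf <- cumsum(dens) * (tt[2] - tt[1])
  cdf <- cdf / cdf[length(cdf)]
  emp <- ecdf(rts)(tt)
  expect_lt(max(abs(emp - cdf)), 0.02)
  # RT quartiles
  qs <- approx(cdf, tt, xout = c(0.25, 0.5, 0.75), ties = "ordered")$y
  expect_equal(unname(quantile(rts, c(0.25, 0.5, 0.75))), qs,
               tolerance = 0.02)
})

test_that("mean decision time decreases with |drift| at fixed boundary", {
  mean_dt <- function(nu) {
    integrate(function(t) {
      t * (wfpt_density(t, 1.6, nu, boundary = "upper") +
             wfpt_density(t, 1.6, nu, boundary = "lower"))
    }, 0, Inf, rel.tol = 1e-8)$value
  }
  m <- vapply(c(0.2, 0.8, 1.5, 2.5, 4), mean_dt, 0)
  expect_true(all(diff(m) < 0))
})

test_that("rescaling boundary and drift shifts quantiles as simulated", {
  # scale property oracle: alpha * 2, nu / 2 slows decisions
  set.seed(17)
  a <- simulate_ddm(4000, 1.2, 1.6, 0, dt = 2e-4)
  b <- simulate_ddm(4000, 2.4, 0.8, 0, dt = 2e-4)
  expect_gt(median(b$rt), median(a$rt))
  # absorption probability is invariant under alpha*k, nu/k at z = 0.5
  expect_equal(boundary_prob(1.2, 1.6), boundary_prob(2.4, 0.8),
               tolerance = 1e-12)
})

test_that("diffusion log-likelihood handles coding, errors and empty input", {
  params <- list(alpha = c(reward = 1.5, punishment = 1.5, zero = 1.5),
                 nu = c(reward = 0, punishment = 0, zero = 0), t0 = 0.2)
  tr1 <- data.frame(condition = "reward", response = "present", rt_sec = 0.9)
  tr2 <- data.frame(condition = "reward", response = "absent", rt_sec = 0.9)
  # symmetric parameters: same density whichever response is recorded
  expect_equal(ddm_loglik(params, tr1), ddm_loglik(params, tr2))

  expect_identical(ddm_loglik(params, tr1[0, ]), 0)
  bad <- data.frame(condition = "reward", response = "present", rt_sec = 0.1)
  expect_error(ddm_loglik(params, bad), "t0")
  expect_error(ddm_loglik(params,
                          data.frame(condition = "absent",
                                     response = "absent", rt_sec = 1)),
               "target-present")

  # response coding flag flips the boundary mapping
  params$nu <- c(reward = 1.5, punishment = 1.5, zero = 1.5)
  expect_equal(ddm_loglik(params, tr1, present_boundary = "lower"),
               ddm_loglik(params, tr2, present_boundary = "upper"))
})

test_that("true parameters beat perturbed drift on simulated data", {
  set.seed(12)
  sim <- simulate_ddm(5000, 1.6, 1.2, 0.3, dt = 2e-4)
  tr <- data.frame(condition = "reward",
                   response = ifelse(sim$upper == 1, "present", "absent"),
                   rt_sec = sim$rt)
  pars <- function(nu) list(alpha = c(reward = 1.6, punishment = 1.6,
                                      zero = 1.6),
                            nu = c(reward = nu, punishment = 0, zero = 0),
                            t0 = 0.3)
  ll_true <- ddm_loglik(pars(1.2), tr)
  expect_gt(ll_true, ddm_loglik(pars(1.8), tr))
  expect_gt(ll_true, ddm_loglik(pars(0.6), tr))
})
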
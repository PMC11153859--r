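#' Fit the hierarchical Wiener diffusion model to target-present search trials
#'
#' Hierarchical Bayesian estimation of the response-coded drift-diffusion
#' model. Per participant and learning condition, (log boundary separation,
#' drift rate) follows a bivariate normal with condition-specific group
#' location, scales, and within-condition correlation — the correlation
#' carries the covariance between caution and evidence quality. The
#' non-decision time t0 is a single population-level parameter, mapped
#' through a scaled logit so it stays in (0, min observed RT); the start
#' point is fixed at z = 0.5 and never sampled. Priors: group locations
#' N(0, 1.5^2), scales half-N(0, 1), correlation LKJ-type with shape 2
#' (density proportional to 1 - rho^2), t0's logit N(0, 1.5^2).
#'
#' Sampling is Metropolis-within-Gibbs: each (participant, condition) block
#' moves by a mixture of covariance-adapted 2-d random walks and
#' independence proposals from the group distribution; group locations are
#' Gibbs-sampled; scales and correlations are slice-sampled; (location,
#' scale) pairs are additionally moved in the non-centered parameterization
#' (interweaving); the t0 logit moves by an adaptive random walk against the
#' full-data likelihood.
#'
#' @param trials data.frame of target-present search trials (columns
#'   `participant_id`, `condition` in reward/punishment/zero, `response` in
#'   present/absent, `rt_sec`); absent-condition rows are rejected.
#' @param config an [mcmc_config()].
#' @param present_boundary which boundary the "present" (dissimilar)
#'   response maps to; `"upper"` is the response-coded default.
#' @return object of class `ddm_fit` with elements `draws`, `summary`,
#'   `participants`, `config`, `converged`, `accept`, `rt_min`.
#' @export
fit_ddm <- function(trials, config = mcmc_config(),
                    present_boundary = c("upper", "lower")) {
  stopifnot(inherits(config, "mcmc_config"))
  present_boundary <- match.arg(present_boundary)
  if (any(trials$condition == "absent") ||
      ("target_present" %in% names(trials) &&
       any(!trials$target_present %in% c(1, TRUE)))) {
    stop("fit_ddm expects target-present trials only; filter first")
  }
  ids <- unique(trials$participant_id)
  if (length(ids) < 2L) stop("need >= 2 participants")
  if (any(trials$rt_sec <= 0)) stop("non-positive RTs present")
  rt_min <- min(trials$rt_sec)

  up_all <- as.integer(trials$response == "present")
  if (present_boundary == "lower") up_all <- 1L - up_all
  dat <- lapply(ids, function(id) {
    rows <- trials$participant_id == id
    lapply(LEARN_CONDITIONS, function(cc) {
      r <- rows & trials$condition == cc
      list(rt = as.numeric(trials$rt_sec[r]), up = up_all[r])
    })
  })

  chains <- vector("list", config$chains)
  accept <- numeric(config$chains)
  for (c in seq_len(config$chains)) {
    res <- run_ddm_chain(dat, length(ids), config$iterations, config$burn_in,
                         seed = config$seed + c - 1L, ids = ids,
                         rt_min = rt_min)
    chains[[c]] <- res$draws
    accept[c] <- res$accept
  }

  pars <- colnames(chains[[1L]])
  lvl <- ifelse(grepl("^(sigma_|rho_)", pars), "hyper",
                ifelse(grepl("\\[", pars), "individual", "group"))
  smry <- summarize_draws(chains)
  smry$level <- lvl
  converged <- all(smry$rhat <= 1.05, na.rm = TRUE)
  if (!converged) {
    warning("non-convergence: max split R-hat = ",
            round(max(smry$rhat, na.rm = TRUE), 3),
            " (> 1.05); summaries are flagged")
  }
  structure(list(draws = chains, summary = smry, participants = ids,
                 config = config, converged = converged,
                 accept = mean(accept), rt_min = rt_min),
            class = "ddm_fit")
}

# Bivariate normal log density with correlation rho; x is an n x 2 matrix.
ldmvn2 <- function(x, m, s1, s2, rho) {
  z1 <- (x[, 1L] - m[1L]) / s1
  z2 <- (x[, 2L] - m[2L]) / s2
  -log(2 * pi) - log(s1 * s2) - 0.5 * log1p(-rho^2) -
    (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2))
}

run_ddm_chain <- function(dat, J, n_iter, n_burn, seed, ids, rt_min,
                          tol = 1e-7) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  prior_loc_sd <- 1.5

  ll_jc <- function(j, cc, la, v, t0) {
    d <- dat[[j]][[cc]]
    wfpt_loglik_cpp(d$rt, d$up, exp(la), v, t0, 0.5, tol)
  }
  # concatenated per-condition arrays for batched whole-group evaluations
  cat_c <- lapply(1:3, function(cc) {
    parts <- lapply(dat, `[[`, cc)
    list(off = c(0L, cumsum(vapply(parts, function(p) length(p$rt), 0L))),
         rt = unlist(lapply(parts, `[[`, "rt")),
         up = unlist(lapply(parts, `[[`, "up")))
  })
  ll_batch <- function(cc, la_col, v_col, t0) {
    wfpt_loglik_batch_cpp(cat_c[[cc]]$off, cat_c[[cc]]$rt, cat_c[[cc]]$up,
                          exp(la_col), v_col, t0, 0.5, tol)
  }

  # state: x[j, c, 1:2] = (log alpha, nu); hypers per condition
  mu <- matrix(c(rnorm(3L, log(1.5), 0.25), rnorm(3L, 1, 0.4)), 3L, 2L)
  s1 <- exp(rnorm(3L, log(0.3), 0.2))   # sd of log alpha
  s2 <- exp(rnorm(3L, log(0.4), 0.2))   # sd of nu
  rho <- tanh(rnorm(3L, 0, 0.3))
  u <- rnorm(1L, 0.8, 0.3)              # t0 = rt_min * plogis(u)
  t0 <- rt_min * plogis(u)
  x <- array(0, c(J, 3L, 2L))
  for (cc in 1:3) {
    x[, cc, 1L] <- rnorm(J, mu[cc, 1L], 0.15)
    x[, cc, 2L] <- rnorm(J, mu[cc, 2L], 0.25)
  }
  ll <- matrix(0, J, 3L)
  for (j in seq_len(J)) for (cc in 1:3) {
    ll[j, cc] <- ll_jc(j, cc, x[j, cc, 1L], x[j, cc, 2L], t0)
  }

  ls_x <- matrix(log(0.15), J, 3L)
  ls_h <- matrix(log(0.3), 3L, 3L)  # per condition: s1, s2, rho proposals
  ls_u <- log(0.1)

  # running moments per participant block for covariance-adapted proposals
  run_n <- 0
  run_mean <- array(0, c(J, 3L, 2L))
  run_cov <- array(0, c(J, 3L, 2L, 2L))
  prop_chol <- array(NA_real_, c(J, 3L, 2L, 2L))
  adapt_start <- min(200L, n_burn %/% 2L)

  cn <- c(paste0("alpha_", LEARN_CONDITIONS), paste0("nu_", LEARN_CONDITIONS),
          "t0",
          paste0("sigma_log_alpha_", LEARN_CONDITIONS),
          paste0("sigma_nu_", LEARN_CONDITIONS),
          paste0("rho_", LEARN_CONDITIONS),
          as.vector(outer(ids, LEARN_CONDITIONS,
                          function(i, cc) paste0("alpha_", cc, "[", i, "]"))),
          as.vector(outer(ids, LEARN_CONDITIONS,
                          function(i, cc) paste0("nu_", cc, "[", i, "]"))))
  kept <- matrix(NA_real_, n_iter, length(cn))
  colnames(kept) <- cn

  acc_n <- 0L
  total <- n_burn + n_iter
  for (t in seq_len(total)) {
    gam <- adapt_gamma(t)
    # transition kernel: composition of two full update cycles
    for (cycle_ in 1:2) {
    for (rep_ in 1:3) for (j in seq_len(J)) {
      for (cc in 1:3) {
        if (runif(1L) < 0.25) {
          # independence proposal from the group distribution
          z1 <- rnorm(1L)
          z2 <- rnorm(1L)
          prop <- c(mu[cc, 1L] + s1[cc] * z1,
                    mu[cc, 2L] + s2[cc] * (rho[cc] * z1 +
                                             sqrt(1 - rho[cc]^2) * z2))
          llp <- ll_jc(j, cc, prop[1L], prop[2L], t0)
          lr <- llp - ll[j, cc]
          acc <- is.finite(lr) && log(runif(1)) < lr
          if (acc) {
            x[j, cc, ] <- prop
            ll[j, cc] <- llp
          }
          if (t > n_burn) acc_n <- acc_n + acc
          next
        }
        st <- exp(ls_x[j, cc])
        L <- prop_chol[j, cc, , ]
        prop <- if (is.na(L[1L])) x[j, cc, ] + st * c(0.5, 1) * rnorm(2L)
                else x[j, cc, ] + st * as.vector(L %*% rnorm(2L))
        llp <- ll_jc(j, cc, prop[1L], prop[2L], t0)
        lr <- llp - ll[j, cc] +
          ldmvn2(matrix(prop, 1L), mu[cc, ], s1[cc], s2[cc], rho[cc]) -
          ldmvn2(matrix(x[j, cc, ], 1L), mu[cc, ], s1[cc], s2[cc], rho[cc])
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) {
          x[j, cc, ] <- prop
          ll[j, cc] <- llp
        }
        if (t <= n_burn) ls_x[j, cc] <- ls_x[j, cc] + gam * ((acc) - 0.3)
        else acc_n <- acc_n + acc
      }
    }
    if (t <= n_burn) {
      run_n <- run_n + 1
      for (cc in 1:3) {
        X <- x[, cc, ]
        delta <- X - run_mean[, cc, ]
        run_mean[, cc, ] <- run_mean[, cc, ] + delta / run_n
        d2 <- X - run_mean[, cc, ]
        for (p in 1:2) for (q in 1:2) {
          run_cov[, cc, p, q] <- run_cov[, cc, p, q] + delta[, p] * d2[, q]
        }
      }
      if (t >= adapt_start && t %% 50L == 0L && run_n > 10L) {
        fresh <- is.na(prop_chol[1L, 1L, 1L, 1L])
        for (j in seq_len(J)) for (cc in 1:3) {
          C <- run_cov[j, cc, , ] / (run_n - 1) + diag(1e-5, 2L)
          prop_chol[j, cc, , ] <- t(chol(C))
          if (fresh) ls_x[j, cc] <- log(2.38 / sqrt(2))
        }
      }
    }
    for (cc in 1:3) {
      # conjugate Gibbs for the location given scales/correlation
      S <- matrix(c(s1[cc]^2, rho[cc] * s1[cc] * s2[cc],
                    rho[cc] * s1[cc] * s2[cc], s2[cc]^2), 2L)
      Sinv <- solve(S)
      P <- J * Sinv + diag(2L) / prior_loc_sd^2
      V <- solve(P)
      m <- V %*% (Sinv %*% colSums(x[, cc, , drop = FALSE])[1L, , drop = TRUE])
      L <- chol(V)
      mu[cc, ] <- as.vector(m + t(L) %*% rnorm(2L))

      xc <- x[, cc, ]
      # scales and correlation: slice sampling in the centered conditional
      s1[cc] <- exp(slice1(log(s1[cc]), function(ls) {
        s <- exp(ls)
        sum(ldmvn2(xc, mu[cc, ], s, s2[cc], rho[cc])) +
          dnorm(s, 0, 1, log = TRUE) + ls
      }, w = 0.3))
      s2[cc] <- exp(slice1(log(s2[cc]), function(ls) {
        s <- exp(ls)
        sum(ldmvn2(xc, mu[cc, ], s1[cc], s, rho[cc])) +
          dnorm(s, 0, 1, log = TRUE) + ls
      }, w = 0.3))
      # LKJ(2) prior on rho => density prop. to (1 - rho^2); plus the
      # Jacobian of the atanh transform
      rho[cc] <- tanh(slice1(atanh(rho[cc]), function(z) {
        r <- tanh(z)
        sum(ldmvn2(xc, mu[cc, ], s1[cc], s2[cc], r)) + 2 * log1p(-r^2)
      }, w = 0.3))

      # non-centered interweaving per coordinate: translate (location) and
      # rescale (scale) the individual effects jointly with the hyper
      for (k in 1:2) {
        sk <- if (k == 1L) s1[cc] else s2[cc]
        eps <- exp(ls_h[cc, k]) * rnorm(1L)
        xp <- xc
        xp[, k] <- xc[, k] + eps
        llp <- ll_batch(cc, xp[, 1L], xp[, 2L], t0)
        lr <- sum(llp) - sum(ll[, cc]) +
          dnorm(mu[cc, k] + eps, 0, prior_loc_sd, log = TRUE) -
          dnorm(mu[cc, k], 0, prior_loc_sd, log = TRUE)
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) {
          mu[cc, k] <- mu[cc, k] + eps
          x[, cc, k] <- xp[, k]
          xc <- xp
          ll[, cc] <- llp
        }
        if (t <= n_burn) ls_h[cc, k] <- ls_h[cc, k] + gam * ((acc) - 0.35)

        sfac <- exp(exp(ls_h[cc, 3L]) * rnorm(1L))
        sp <- sk * sfac
        xp <- xc
        xp[, k] <- mu[cc, k] + (xc[, k] - mu[cc, k]) * sfac
        llp <- ll_batch(cc, xp[, 1L], xp[, 2L], t0)
        news1 <- if (k == 1L) sp else s1[cc]
        news2 <- if (k == 2L) sp else s2[cc]
        lr <- sum(llp) - sum(ll[, cc]) +
          sum(ldmvn2(xp, mu[cc, ], news1, news2, rho[cc])) -
          sum(ldmvn2(xc, mu[cc, ], s1[cc], s2[cc], rho[cc])) +
          J * log(sfac) +  # Jacobian of rescaling the individual effects
          dnorm(sp, 0, 1, log = TRUE) - dnorm(sk, 0, 1, log = TRUE) +
          log(sfac)        # Jacobian of the log-scale walk
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) {
          if (k == 1L) s1[cc] <- sp else s2[cc] <- sp
          x[, cc, k] <- xp[, k]
          xc <- xp
          ll[, cc] <- llp
        }
        if (t <= n_burn) ls_h[cc, 3L] <- ls_h[cc, 3L] + gam * ((acc) - 0.35)
      }
    }
    # population t0 via its scaled logit
    up_ <- u + exp(ls_u) * rnorm(1L)
    t0p <- rt_min * plogis(up_)
    llp <- sapply(1:3, function(cc) ll_batch(cc, x[, cc, 1L], x[, cc, 2L], t0p))
    lr <- sum(llp) - sum(ll) +
      dnorm(up_, 0, prior_loc_sd, log = TRUE) -
      dnorm(u, 0, prior_loc_sd, log = TRUE)
    acc <- is.finite(lr) && log(runif(1)) < lr
    if (acc) {
      u <- up_
      t0 <- t0p
      ll <- llp
    }
    if (t <= n_burn) ls_u <- ls_u + gam * ((acc) - 0.35)
    }  # cycle_

    if (t > n_burn) {
      i <- t - n_burn
      kept[i, ] <- c(exp(mu[, 1L]), mu[, 2L], t0, s1, s2, rho,
                     as.vector(exp(x[, , 1L])), as.vector(x[, , 2L]))
    }
  }
  list(draws = kept, accept = acc_n / (n_iter * J * 18L))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Hierarchical Wiener diffusion model fit (z fixed at 0.5)\n")
  cat(sprintf("  participants: %d   chains: %d   kept iterations: %d\n",
              length(x$participants), x$config$chains, x$config$iterations))
  cat(sprintf("  convergence: %s (max split R-hat = %.3f)\n",
              if (x$converged) "all R-hat <= 1.05" else "NOT CONVERGED",
              max(x$summary$rhat, na.rm = TRUE)))
  cat("\nGroup-level posterior:\n")
  print(format_summary(x$summary[x$summary$level == "group", ]),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.ddm_fit <- function(object, level = NULL, ...) {
  s <- object$summary
  if (!is.null(level)) s <- s[s$level %in% level, ]
  s
}

#' Posterior means of individual-level diffusion parameters
#'
#' @param object a `ddm_fit`.
#' @param ... unused.
#' @return matrix (participants x 6): `alpha_*` and `nu_*` per condition.
#' @export
coef.ddm_fit <- function(object, ...) {
  pars <- c(paste0("alpha_", LEARN_CONDITIONS),
            paste0("nu_", LEARN_CONDITIONS))
  out <- sapply(pars, function(p) {
    vapply(object$participants, function(id) {
      mean(pooled_draws(object$draws, paste0(sub("_", "_", p), "[", id, "]")))
    }, 0)
  })
  rownames(out) <- object$participants
  out
}

#' @export
group_draws.ddm_fit <- function(fit, parameter) {
  ok <- c(paste0("alpha_", LEARN_CONDITIONS),
          paste0("nu_", LEARN_CONDITIONS), "t0",
          paste0("sigma_log_alpha_", LEARN_CONDITIONS),
          paste0("sigma_nu_", LEARN_CONDITIONS),
          paste0("rho_", LEARN_CONDITIONS))
  if (!parameter %in% ok) {
    stop("'", parameter, "' is not a group-level parameter of a ddm_fit")
  }
  pooled_draws(fit$draws, parameter)
}
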
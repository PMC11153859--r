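#' Fit the hierarchical dual-learning-rate RW model
#'
#' Hierarchical Bayesian estimation of the dual-rate Rescorla-Wagner/softmax
#' model. Each participant's four parameters are modelled on transformed
#' scales — logit learning rates, log inverse temperatures — as normal around
#' group-level locations with group-level scales. Priors: locations
#' N(0, 1.5^2), scales half-N(0, 1). Sampling is Metropolis-within-Gibbs:
#' each participant's per-condition (learning rate, inverse temperature)
#' block moves by a mixture of covariance-adapted random walks and
#' independence proposals from the group distribution; group locations are
#' Gibbs-sampled, group scales slice-sampled, and (location, scale) pairs
#' are additionally moved in the non-centered parameterization
#' (interweaving), which breaks the funnel coupling between scales and
#' individual effects. Proposal scales adapt during burn-in only.
#' Zero-condition trials carry no feedback and are excluded from the
#' likelihood.
#'
#' Group-level summaries are reported on the natural scale (inverse-logit /
#' exponential of the location draws), together with the within-group derived
#' contrasts `eta_diff = eta_r - eta_p` and `tau_diff = tau_r - tau_p`.
#'
#' @param trials data.frame of learning trials (columns `participant_id`,
#'   `condition`, `chose_target`, `outcome`, ordered by `trial` within
#'   participant); typically one age group at a time.
#' @param config an [mcmc_config()].
#' @return object of class `rl_fit` with elements `draws` (list of
#'   iterations x parameters matrices, one per chain), `summary` (data.frame
#'   of posterior summaries with split R-hat), `participants`, `config`,
#'   `converged` (all R-hat <= 1.05), `accept` (mean per-participant
#'   acceptance rates).
#' @seealso [posterior_predictive()], [group_contrast()],
#'   [individual_modes()]
#' @export
fit_rl <- function(trials, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  ids <- unique(trials$participant_id)
  if (length(ids) < 2L) stop("need >= 2 participants")
  if (!any(trials$condition %in% c("reward", "punishment"))) {
    stop("no reward/punishment trials present")
  }
  dat <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    if ("trial" %in% names(tr)) tr <- tr[order(tr$trial), ]
    list(cond = condition_code(as.character(tr$condition), "rl"),
         chose = as.integer(tr$chose_target),
         out = as.numeric(tr$outcome))
  })
  J <- length(ids)

  chains <- vector("list", config$chains)
  accept <- numeric(config$chains)
  for (c in seq_len(config$chains)) {
    res <- run_rl_chain(dat, J, config$iterations, config$burn_in,
                        seed = config$seed + c - 1L, ids = ids)
    chains[[c]] <- res$draws
    accept[c] <- res$accept
  }

  pars <- colnames(chains[[1L]])
  lvl <- ifelse(grepl("^(mu|sigma)_", pars), "hyper",
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
                 accept = mean(accept)),
            class = "rl_fit")
}

# One chain of the RL sampler. Parameter layout per participant:
# theta = (logit eta_r, logit eta_p, log tau_r, log tau_p). The likelihood
# separates by condition (columns 1,3 touch only reward trials; 2,4 only
# punishment trials), so participants are updated in two 2-d blocks with
# cached per-condition log-likelihoods. Group locations are Gibbs-sampled
# and (location, scale) pairs are additionally moved in the non-centered
# parameterization (interweaving), which breaks the funnel coupling between
# scales and individual effects.
run_rl_chain <- function(dat, J, n_iter, n_burn, seed, ids) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  prior_loc_sd <- 1.5

  # per-condition trial subsets (sequence order preserved; EVs do not
  # interact across conditions)
  sub <- lapply(dat, function(d) {
    lapply(c(1L, 2L), function(cc) {
      k <- d$cond == cc
      list(cond = d$cond[k], chose = d$chose[k], out = d$out[k])
    })
  })
  ll_cond <- function(j, cc, e, lt) {
    d <- sub[[j]][[cc]]
    rl_loglik_cpp(d$cond, d$chose, d$out,
                  if (cc == 1L) plogis(e) else 0.1,
                  if (cc == 2L) plogis(e) else 0.1,
                  if (cc == 1L) exp(lt) else 1,
                  if (cc == 2L) exp(lt) else 1)
  }
  # concatenated per-condition arrays for batched whole-group evaluations
  cat_c <- lapply(c(1L, 2L), function(cc) {
    parts <- lapply(sub, `[[`, cc)
    list(off = c(0L, cumsum(vapply(parts, function(p) length(p$chose), 0L))),
         chose = unlist(lapply(parts, `[[`, "chose")),
         out = unlist(lapply(parts, `[[`, "out")))
  })
  ll_batch <- function(cc, e_col, lt_col) {
    rl_loglik_batch_cpp(cat_c[[cc]]$off, cat_c[[cc]]$chose, cat_c[[cc]]$out,
                        plogis(e_col), exp(lt_col))
  }
  blk <- list(c(1L, 3L), c(2L, 4L))  # (eta, tau) columns per condition

  # dispersed initial values per chain
  mu <- rnorm(4L, c(-2.5, -2.5, 1.5, 1.5), 0.8)
  sigma <- exp(rnorm(4L, log(0.5), 0.3))
  theta <- t(vapply(seq_len(J), function(j) rnorm(4L, mu, 0.3),
                    numeric(4L)))
  ll <- sapply(c(1L, 2L), function(cc) {
    vapply(seq_len(J), function(j) {
      ll_cond(j, cc, theta[j, blk[[cc]][1L]], theta[j, blk[[cc]][2L]])
    }, 0)
  })
  step_dir <- c(1, 0.6)  # relative proposal SDs for (logit eta, log tau)
  ls_j <- matrix(log(0.3), J, 2L)
  ls_sig <- rep(log(0.4), 4L)
  ls_asis <- rep(log(0.15), 4L)

  # running moments of each participant block, for covariance-adapted
  # proposals once enough burn-in history has accumulated
  run_n <- 0
  run_mean <- array(0, c(J, 2L, 2L))          # [j, cc, par]
  run_cov <- array(0, c(J, 2L, 2L, 2L))       # [j, cc, par, par]
  prop_chol <- array(NA_real_, c(J, 2L, 2L, 2L))
  adapt_start <- min(200L, n_burn %/% 2L)

  kept <- matrix(NA_real_, n_iter, 8L + 4L * J)
  colnames(kept) <- c(paste0("mu_", RL_PARS), paste0("sigma_", RL_PARS),
                      as.vector(outer(ids, RL_PARS,
                                      function(i, p) paste0(p, "[", i, "]"))))
  acc_n <- 0L
  total <- n_burn + n_iter
  for (t in seq_len(total)) {
    gam <- adapt_gamma(t)
    # the transition kernel is the composition of two full update cycles;
    # kept iterations therefore decorrelate faster at fixed chain length
    for (cycle_ in 1:2) {
    for (rep_ in 1:2) for (j in seq_len(J)) {
      for (cc in c(1L, 2L)) {
        cols <- blk[[cc]]
        cur <- theta[j, cols]
        if (runif(1L) < 0.25) {
          # independence proposal from the group distribution; cancels the
          # prior terms and lets weakly identified participants jump across
          # likelihood ridges
          prop <- rnorm(2L, mu[cols], sigma[cols])
          llp <- ll_cond(j, cc, prop[1L], prop[2L])
          lr <- llp - ll[j, cc]
          acc <- is.finite(lr) && log(runif(1)) < lr
          if (acc) {
            theta[j, cols] <- prop
            ll[j, cc] <- llp
          }
          if (t > n_burn) acc_n <- acc_n + acc
          next
        }
        L <- prop_chol[j, cc, , ]
        prop <- if (is.na(L[1L])) cur + exp(ls_j[j, cc]) * step_dir * rnorm(2L)
                else cur + exp(ls_j[j, cc]) * as.vector(L %*% rnorm(2L))
        llp <- ll_cond(j, cc, prop[1L], prop[2L])
        lr <- llp - ll[j, cc] +
          sum(dnorm(prop, mu[cols], sigma[cols], log = TRUE)) -
          sum(dnorm(cur, mu[cols], sigma[cols], log = TRUE))
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) {
          theta[j, cols] <- prop
          ll[j, cc] <- llp
        }
        if (t <= n_burn) ls_j[j, cc] <- ls_j[j, cc] + gam * ((acc) - 0.3)
        else acc_n <- acc_n + acc
      }
    }
    if (t <= n_burn) {
      run_n <- run_n + 1
      for (cc in c(1L, 2L)) {
        X <- theta[, blk[[cc]], drop = FALSE]
        delta <- X - run_mean[, cc, ]
        run_mean[, cc, ] <- run_mean[, cc, ] + delta / run_n
        d2 <- X - run_mean[, cc, ]
        for (p in 1:2) for (q in 1:2) {
          run_cov[, cc, p, q] <- run_cov[, cc, p, q] + delta[, p] * d2[, q]
        }
      }
      if (t >= adapt_start && t %% 50L == 0L && run_n > 10L) {
        fresh <- is.na(prop_chol[1L, 1L, 1L, 1L])
        for (j in seq_len(J)) for (cc in c(1L, 2L)) {
          C <- run_cov[j, cc, , ] / (run_n - 1) + diag(1e-5, 2L)
          prop_chol[j, cc, , ] <- t(chol(C))
          if (fresh) ls_j[j, cc] <- log(2.38 / sqrt(2))
        }
      }
    }
    for (k in 1:4) {
      # centered: Gibbs for the location, slice sampling for the scale
      prec <- J / sigma[k]^2 + 1 / prior_loc_sd^2
      m <- sum(theta[, k]) / sigma[k]^2 / prec
      mu[k] <- rnorm(1L, m, sqrt(1 / prec))

      th_k <- theta[, k]
      mu_k <- mu[k]
      sigma[k] <- exp(slice1(log(sigma[k]), function(ls) {
        s <- exp(ls)
        sum(dnorm(th_k, mu_k, s, log = TRUE)) +
          dnorm(s, 0, 1, log = TRUE) + ls  # half-normal prior + Jacobian
      }, w = 0.3))

      # non-centered interweaving: hold raw effects fixed, move the location
      # (translation of all individual effects) and the scale (rescale about
      # the location) in separate scalar Metropolis moves
      cc <- if (k %in% c(1L, 3L)) 1L else 2L
      cols <- blk[[cc]]
      ll_with <- function(th_p) {
        e_col <- if (k == cols[1L]) th_p else theta[, cols[1L]]
        lt_col <- if (k == cols[2L]) th_p else theta[, cols[2L]]
        ll_batch(cc, e_col, lt_col)
      }
      for (r_ in 1:2) {
        # translation move
        eps <- exp(ls_asis[k]) * rnorm(1L)
        mu_p <- mu[k] + eps
        th_p <- theta[, k] + eps
        llp <- ll_with(th_p)
        lr <- sum(llp) - sum(ll[, cc]) +
          dnorm(mu_p, 0, prior_loc_sd, log = TRUE) -
          dnorm(mu[k], 0, prior_loc_sd, log = TRUE)
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) {
          mu[k] <- mu_p
          theta[, k] <- th_p
          ll[, cc] <- llp
        }
        if (t <= n_burn) ls_asis[k] <- ls_asis[k] + gam * ((acc) - 0.35)

        # rescale move
        s_ <- exp(ls_sig[k]) * rnorm(1L)
        sg_p <- sigma[k] * exp(s_)
        th_p <- mu[k] + (theta[, k] - mu[k]) * exp(s_)
        llp <- ll_with(th_p)
        lr <- sum(llp) - sum(ll[, cc]) +
          dnorm(sg_p, 0, 1, log = TRUE) - dnorm(sigma[k], 0, 1, log = TRUE) +
          log(sg_p) - log(sigma[k])  # Jacobian of the log-scale walk
        acc <- is.finite(lr) && log(runif(1)) < lr
        if (acc) {
          sigma[k] <- sg_p
          theta[, k] <- th_p
          ll[, cc] <- llp
        }
        if (t <= n_burn) ls_sig[k] <- ls_sig[k] + gam * ((acc) - 0.35)
      }
    }
    }  # cycle_
    if (t > n_burn) {
      i <- t - n_burn
      nat <- cbind(plogis(theta[, 1:2, drop = FALSE]),
                   exp(theta[, 3:4, drop = FALSE]))
      kept[i, ] <- c(mu, sigma, as.vector(nat))
    }
  }
  # append natural-scale group-level draws and the within-group contrasts
  g <- cbind(eta_r = plogis(kept[, "mu_eta_r"]),
             eta_p = plogis(kept[, "mu_eta_p"]),
             tau_r = exp(kept[, "mu_tau_r"]),
             tau_p = exp(kept[, "mu_tau_p"]))
  g <- cbind(g, eta_diff = g[, "eta_r"] - g[, "eta_p"],
             tau_diff = g[, "tau_r"] - g[, "tau_p"])
  list(draws = cbind(kept, g), accept = acc_n / (n_iter * J * 4L))
}

RL_PARS <- c("eta_r", "eta_p", "tau_r", "tau_p")

#' @export
print.rl_fit <- function(x, ...) {
  cat("Hierarchical dual-learning-rate RW model fit\n")
  cat(sprintf("  participants: %d   chains: %d   kept iterations: %d\n",
              length(x$participants), x$config$chains, x$config$iterations))
  cat(sprintf("  convergence: %s (max split R-hat = %.3f)\n",
              if (x$converged) "all R-hat <= 1.05" else "NOT CONVERGED",
              max(x$summary$rhat, na.rm = TRUE)))
  cat("\nGroup-level posterior (natural scale):\n")
  print(format_summary(x$summary[x$summary$level == "group", ]),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.rl_fit <- function(object, level = NULL, ...) {
  s <- object$summary
  if (!is.null(level)) s <- s[s$level %in% level, ]
  s
}

#' Posterior means of individual-level parameters
#'
#' @param object an `rl_fit`.
#' @param ... unused.
#' @return matrix (participants x parameters) of posterior means on the
#'   natural scale.
#' @export
coef.rl_fit <- function(object, ...) {
  out <- sapply(RL_PARS, function(p) {
    vapply(object$participants, function(id) {
      mean(pooled_draws(object$draws, paste0(p, "[", id, "]")))
    }, 0)
  })
  rownames(out) <- object$participants
  out
}

#' @export
group_draws.rl_fit <- function(fit, parameter) {
  ok <- c(RL_PARS, "eta_diff", "tau_diff",
          paste0("mu_", RL_PARS), paste0("sigma_", RL_PARS))
  if (!parameter %in% ok) {
    stop("'", parameter, "' is not a group-level parameter of an rl_fit")
  }
  pooled_draws(fit$draws, parameter)
}

format_summary <- function(s) {
  data.frame(parameter = s$parameter,
             mean = sprintf("%.3f", s$mean),
             mode = sprintf("%.3f", s$mode),
             `95% CI` = sprintf("[%.3f, %.3f]", s$ci_lower, s$ci_upper),
             rhat = sprintf("%.3f", s$rhat),
             check.names = FALSE)
}
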
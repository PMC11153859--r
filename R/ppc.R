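#' Draw response times from the Wiener density by inverse-CDF sampling
#'
#' Fast sampler used for posterior predictive simulation: the two boundary
#' densities are evaluated on a fine grid, turned into CDFs, and inverted.
#' Accuracy is set by the grid; the Euler-Maruyama path simulator
#' [simulate_ddm()] remains the oracle-grade generative route.
#'
#' @inheritParams wfpt_density
#' @param n number of trials.
#' @param t_max upper RT limit of the grid (seconds).
#' @param n_grid grid resolution.
#' @return data.frame with `rt` and `upper`.
#' @keywords internal
rwiener_icdf <- function(n, alpha, nu, t0 = 0, z = 0.5, t_max = 15,
                         n_grid = 2048L) {
  tt <- seq(t0 + 1e-4, t0 + t_max, length.out = n_grid)
  dt <- tt[2L] - tt[1L]
  fu <- wfpt_density(tt, alpha, nu, t0, z, "upper")
  fl <- wfpt_density(tt, alpha, nu, t0, z, "lower")
  cu <- cumsum(fu) * dt
  cl <- cumsum(fl) * dt
  p_up <- cu[n_grid] / (cu[n_grid] + cl[n_grid])
  up <- as.integer(runif(n) < p_up)
  rt <- numeric(n)
  for (b in 0:1) {
    idx <- which(up == b)
    if (!length(idx)) next
    cdf <- if (b == 1L) cu / cu[n_grid] else cl / cl[n_grid]
    keep <- c(TRUE, diff(cdf) > 0)
    rt[idx] <- approx(cdf[keep], tt[keep], xout = runif(length(idx)),
                      rule = 2)$y
  }
  data.frame(rt = rt, upper = up)
}

# Pick `ndraws` (chain, iteration) pairs from a fit's posterior.
draw_index <- function(fit, ndraws) {
  nc <- length(fit$draws)
  ni <- nrow(fit$draws[[1L]])
  if (is.null(ni) || ni < 1L) stop("fit holds no posterior draws")
  k <- sample.int(nc * ni, min(ndraws, nc * ni))
  cbind(chain = (k - 1L) %/% ni + 1L, iter = (k - 1L) %% ni + 1L)
}

#' Simulate replicate datasets from a fitted model's posterior
#'
#' Each replicate re-simulates the template trials with individual-level
#' parameters taken from one joint posterior draw: choices from the
#' RW/softmax generative model for `rl_fit` (outcomes re-drawn under
#' `contingency`), response/RT pairs from the Wiener process for `ddm_fit`.
#'
#' @param object fitted model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param trials template trial data.frame (the data that was fitted).
#' @param contingency feedback contingency for RL replicates.
#' @param ... unused.
#' @return list of data.frames shaped like `trials`.
#' @export
simulate.rl_fit <- function(object, nsim = 1, seed = NULL, trials,
                            contingency = 0.8, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- draw_index(object, nsim)
  lapply(seq_len(nrow(idx)), function(s) {
    dr <- object$draws[[idx[s, 1L]]][idx[s, 2L], ]
    out <- trials
    for (id in object$participants) {
      rows <- which(trials$participant_id == id)
      rows <- rows[order(trials$trial[rows])]
      cond <- condition_code(as.character(trials$condition[rows]), "rl")
      sim <- rl_sim_cpp(cond,
                        dr[paste0("eta_r[", id, "]")],
                        dr[paste0("eta_p[", id, "]")],
                        dr[paste0("tau_r[", id, "]")],
                        dr[paste0("tau_p[", id, "]")],
                        contingency)
      out$chose_target[rows] <- sim$chose_target
      out$outcome[rows] <- sim$outcome
    }
    out
  })
}

#' @rdname simulate.rl_fit
#' @export
simulate.ddm_fit <- function(object, nsim = 1, seed = NULL, trials, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- draw_index(object, nsim)
  lapply(seq_len(nrow(idx)), function(s) {
    dr <- object$draws[[idx[s, 1L]]][idx[s, 2L], ]
    out <- trials
    for (id in object$participants) {
      for (cc in LEARN_CONDITIONS) {
        rows <- which(trials$participant_id == id & trials$condition == cc)
        if (!length(rows)) next
        sim <- rwiener_icdf(length(rows),
                            alpha = dr[paste0("alpha_", cc, "[", id, "]")],
                            nu = dr[paste0("nu_", cc, "[", id, "]")],
                            t0 = dr["t0"])
        out$rt_sec[rows] <- sim$rt
        out$response[rows] <- ifelse(sim$upper == 1, "present", "absent")
      }
    }
    out
  })
}

#' Posterior predictive check
#'
#' Compares data simulated from the fitted posterior against the observed
#' data. For the learning model the discrepancy measure is the block-wise
#' cross-participant mean target-choice proportion per condition; for the
#' diffusion model it is the pooled RT quantiles (0.1/0.3/0.5/0.7/0.9) per
#' condition. Each observed statistic is checked against the central 95%
#' predictive band across replicates.
#'
#' @param fit fitted model (`rl_fit` or `ddm_fit`).
#' @param trials the observed trial data that was fitted.
#' @param ndraws number of posterior replicates.
#' @param seed integer seed.
#' @param ... passed to the class method (`block_size` for RL).
#' @return object of class `ppc`: data.frame of statistics with observed
#'   value, predictive band, and `inside` flag, plus attribute `coverage`
#'   (fraction of statistics inside their band).
#' @export
posterior_predictive <- function(fit, trials, ndraws = 100, seed = 1, ...) {
  UseMethod("posterior_predictive")
}

#' @export
posterior_predictive.rl_fit <- function(fit, trials, ndraws = 100, seed = 1,
                                        block_size = 10L, ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  obs <- learning_curves(trials, block_size)
  reps <- simulate(fit, nsim = ndraws, trials = trials)
  sim_props <- sapply(reps, function(r) {
    learning_curves(r, block_size)$proportion
  })
  lo <- apply(sim_props, 1L, quantile, probs = 0.025, names = FALSE)
  hi <- apply(sim_props, 1L, quantile, probs = 0.975, names = FALSE)
  out <- data.frame(statistic = paste0("prop[", obs$condition, ",bin",
                                       obs$bin, "]"),
                    condition = obs$condition, bin = obs$bin,
                    observed = obs$proportion,
                    pred_lower = lo, pred_upper = hi,
                    pred_mean = rowMeans(sim_props),
                    stringsAsFactors = FALSE)
  out$inside <- out$observed >= out$pred_lower & out$observed <= out$pred_upper
  structure(out, coverage = mean(out$inside), model = "rl",
            class = c("ppc", "data.frame"))
}

#' @export
posterior_predictive.ddm_fit <- function(fit, trials, ndraws = 50, seed = 1,
                                         probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                         ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  qtab <- function(d) {
    unlist(lapply(LEARN_CONDITIONS, function(cc) {
      quantile(d$rt_sec[d$condition == cc], probs, names = FALSE)
    }))
  }
  obs <- qtab(trials)
  reps <- simulate(fit, nsim = ndraws, trials = trials)
  sim_q <- sapply(reps, qtab)
  out <- data.frame(
    statistic = paste0("rt_q", rep(probs, times = length(LEARN_CONDITIONS)),
                       "[", rep(LEARN_CONDITIONS, each = length(probs)), "]"),
    condition = rep(LEARN_CONDITIONS, each = length(probs)),
    prob = rep(probs, times = length(LEARN_CONDITIONS)),
    observed = obs,
    pred_lower = apply(sim_q, 1L, quantile, probs = 0.025, names = FALSE),
    pred_upper = apply(sim_q, 1L, quantile, probs = 0.975, names = FALSE),
    pred_mean = rowMeans(sim_q),
    stringsAsFactors = FALSE)
  out$inside <- out$observed >= out$pred_lower & out$observed <= out$pred_upper
  structure(out, coverage = mean(out$inside), model = "ddm",
            class = c("ppc", "data.frame"))
}

#' @export
print.ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%s model): %.0f%% of %d statistics inside the 95%% predictive band\n",
              attr(x, "model"), 100 * attr(x, "coverage"), nrow(x)))
  invisible(x)
}

#' Plot a posterior predictive check
#'
#' @param x a `ppc` object.
#' @param ... passed to [plot()].
#' @export
plot.ppc <- function(x, ...) {
  n <- nrow(x)
  plot(seq_len(n), x$observed, ylim = range(x$pred_lower, x$pred_upper,
                                            x$observed),
       xlab = "statistic", ylab = "value", pch = 19, ...)
  arrows(seq_len(n), x$pred_lower, seq_len(n), x$pred_upper,
         angle = 90, code = 3, length = 0.02, col = "grey50")
  points(seq_len(n), x$observed, pch = 19)
  legend("topleft", legend = c("observed", "95% predictive band"),
         pch = c(19, NA), lty = c(NA, 1), col = c("black", "grey50"),
         bty = "n")
  invisible(x)
}
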
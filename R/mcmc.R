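#' MCMC configuration
#'
#' Settings for the hierarchical samplers. The desk-scale default (1,000
#' kept iterations, 1,000 burn-in, 4 chains) is sized for routine use and
#' testing; the heavier 5,000/5,000/4 schedule used for final inference is
#' available by overriding `iterations` and `burn_in`.
#'
#' @param iterations kept iterations per chain, >= 1.
#' @param burn_in discarded warm-up iterations per chain (adaptation of the
#'   random-walk proposal scales happens only here), >= 1.
#' @param chains number of chains, >= 2.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 1000L, burn_in = 1000L, chains = 4L,
                        seed = 1L) {
  stopifnot(iterations >= 1, burn_in >= 1, chains >= 2)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 chains = as.integer(chains),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Split R-hat convergence diagnostic
#'
#' The rank-free split-\eqn{\widehat{R}}: each chain is halved, and the
#' between- to within-half variance ratio is folded into
#' \eqn{\sqrt{((n-1)/n \, W + B/n) / W}}. Values near 1 indicate that the
#' chains have mixed; values above ~1.05 flag non-convergence.
#'
#' @param chains list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @return the split R-hat statistic (>= 1 up to floating-point error).
#' @export
#' @examples
#' set.seed(1)
#' rhat(replicate(4, rnorm(1000), simplify = FALSE))  # ~1.00
rhat <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(i) chains[, i])
  if (length(chains) < 2L) stop("rhat needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal lengths")
  half <- n %/% 2L
  splits <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[seq.int(n - half + 1L, n)])
  }), recursive = FALSE)
  means <- vapply(splits, mean, 0)
  vars <- vapply(splits, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-300) return(if (B < 1e-300) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Robbins-Monro step size for proposal-scale adaptation during burn-in.
adapt_gamma <- function(t) min(0.5, t^(-0.6))

# Univariate slice sampler (stepping out + shrinkage); used for conditionals
# that are cheap to evaluate, where it mixes without tuning.
slice1 <- function(x0, logf, w = 0.5, m = 20L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  y <- f0 - stats::rexp(1L)
  L <- x0 - runif(1L) * w
  R <- L + w
  j <- floor(runif(1L) * m)
  k <- m - 1L - j
  while (j > 0 && logf(L) > y) {
    L <- L - w
    j <- j - 1L
  }
  while (k > 0 && logf(R) > y) {
    R <- R + w
    k <- k - 1L
  }
  repeat {
    x1 <- runif(1L, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Summarise posterior draws: one row per parameter with mean, KDE mode,
# central 95% interval and split R-hat. `draws` is a list of chains, each an
# iterations x parameters matrix with identical column names.
summarize_draws <- function(draws, level = NULL) {
  pars <- colnames(draws[[1L]])
  all <- do.call(rbind, draws)
  out <- data.frame(
    parameter = pars,
    mean = colMeans(all),
    mode = vapply(pars, function(p) posterior_mode(all[, p]), 0),
    ci_lower = apply(all, 2L, quantile, probs = 0.025, names = FALSE),
    ci_upper = apply(all, 2L, quantile, probs = 0.975, names = FALSE),
    rhat = vapply(pars, function(p) {
      rhat(lapply(draws, function(d) d[, p]))
    }, 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(level)) out$level <- level
  rownames(out) <- NULL
  out
}

# Extract pooled draws (all chains concatenated) of one parameter.
pooled_draws <- function(draws, parameter) {
  if (!parameter %in% colnames(draws[[1L]])) {
    stop("parameter '", parameter, "' not found in posterior draws")
  }
  unlist(lapply(draws, function(d) d[, parameter]), use.names = FALSE)
}

#' Posterior contrast between two fitted groups
#'
#' Elementwise difference of the two fits' posterior draws for a group-level
#' parameter (fit_a minus fit_b), summarised as the posterior mean and
#' central 95% credible interval. If the fits hold different numbers of
#' draws, both are truncated to the common length with a warning.
#'
#' @param fit_a,fit_b fitted model objects (class `rl_fit` or `ddm_fit`).
#' @param parameter name of a group-level parameter present in both fits
#'   (e.g. `"eta_r"` for RL fits, `"nu_reward"` or `"t0"` for DDM fits).
#' @return data.frame (class `group_contrast`) with `parameter`,
#'   `mean_diff`, `ci_lower`, `ci_upper`.
#' @export
group_contrast <- function(fit_a, fit_b, parameter) {
  a <- group_draws(fit_a, parameter)
  b <- group_draws(fit_b, parameter)
  if (length(a) != length(b)) {
    warning("draw counts differ (", length(a), " vs ", length(b),
            "); truncating to common length")
    n <- min(length(a), length(b))
    a <- a[seq_len(n)]
    b <- b[seq_len(n)]
  }
  d <- a - b
  ci <- quantile(d, c(0.025, 0.975), names = FALSE)
  structure(data.frame(parameter = parameter, mean_diff = mean(d),
                       ci_lower = ci[1L], ci_upper = ci[2L],
                       stringsAsFactors = FALSE),
            class = c("group_contrast", "data.frame"))
}

#' Group-level posterior draws on the natural scale
#'
#' @param fit a fitted model object.
#' @param parameter group-level parameter name.
#' @return numeric vector of pooled draws.
#' @export
group_draws <- function(fit, parameter) UseMethod("group_draws")
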
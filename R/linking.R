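#' Posterior mode of a scalar parameter's draws
#'
#' The most probable value of a marginal posterior, located as the argmax of
#' a Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth)
#' evaluated on a regular grid spanning the sample range.
#'
#' @param samples numeric vector of posterior draws (>= 100 recommended;
#'   fewer are accepted with reduced stability).
#' @param n_grid number of grid points for the KDE argmax.
#' @return the estimated mode; constant samples return that constant.
#' @export
posterior_mode <- function(samples, n_grid = 512L) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("no finite draws")
  rng <- range(samples)
  if (rng[1L] == rng[2L]) return(rng[1L])
  d <- density(samples, bw = "nrd0", n = n_grid, from = rng[1L], to = rng[2L])
  d$x[which.max(d$y)]
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Pearson correlation of average (midrank) ranks, with the two-sided
#' p-value from the t approximation `t = r sqrt((n-2)/(1-r^2))` on n-2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `r` and `p`; a zero-variance input gives an `NA`
#'   correlation and a warning (the correlation is undefined).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero variance; Spearman correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- cor(rx, ry)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Cross-model Spearman correlation table
#'
#' Rank-correlates each participant's diffusion-model posterior modes
#' (boundary separation and drift per condition; 6 rows) against their
#' learning-model posterior modes (both learning rates and inverse
#' temperatures; 4 columns). Cells crossing the conservative criterion
#' |r| > 0.30 are flagged. p-values are reported per cell, uncorrected;
#' with 24 cells, a few moderate correlations are expected by chance.
#'
#' @param rl_modes data.frame/matrix with rownames = participant ids and
#'   columns `eta_r`, `eta_p`, `tau_r`, `tau_p` (e.g. posterior modes).
#' @param ddm_modes data.frame/matrix with the same rownames and columns
#'   `alpha_reward`, `alpha_punishment`, `alpha_zero`, `nu_reward`,
#'   `nu_punishment`, `nu_zero`.
#' @param criterion threshold on |r| for the conservative flag.
#' @return data.frame (class `correlation_table`) in long form with columns
#'   `ddm_parameter`, `rl_parameter`, `r`, `p`, `flag_conservative`
#'   (6 x 4 = 24 rows).
#' @export
correlation_table <- function(rl_modes, ddm_modes, criterion = 0.30) {
  rl_modes <- as.data.frame(rl_modes)
  ddm_modes <- as.data.frame(ddm_modes)
  if (!setequal(rownames(rl_modes), rownames(ddm_modes))) {
    only_rl <- setdiff(rownames(rl_modes), rownames(ddm_modes))
    only_dd <- setdiff(rownames(ddm_modes), rownames(rl_modes))
    stop("participant mismatch between models; only in RL: ",
         paste(only_rl, collapse = ", "), "; only in DDM: ",
         paste(only_dd, collapse = ", "))
  }
  ddm_modes <- ddm_modes[rownames(rl_modes), , drop = FALSE]
  ddm_pars <- c(paste0("alpha_", LEARN_CONDITIONS),
                paste0("nu_", LEARN_CONDITIONS))
  rl_pars <- RL_PARS
  out <- expand.grid(ddm_parameter = ddm_pars, rl_parameter = rl_pars,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(dp, rp) {
    s <- spearman(ddm_modes[[dp]], rl_modes[[rp]])
    c(s$r, s$p)
  }, out$ddm_parameter, out$rl_parameter)
  out$r <- res[1L, ]
  out$p <- res[2L, ]
  out$flag_conservative <- !is.na(out$r) & abs(out$r) > criterion
  structure(out, class = c("correlation_table", "data.frame"))
}

#' @export
print.correlation_table <- function(x, ...) {
  wide <- matrix(sprintf("%+.2f%s", x$r,
                         ifelse(x$flag_conservative, "*", " ")),
                 nrow = length(unique(x$ddm_parameter)),
                 dimnames = list(unique(x$ddm_parameter),
                                 unique(x$rl_parameter)))
  cat("Spearman rank correlations between posterior modes",
      "(* = |r| > 0.30):\n")
  print(wide, quote = FALSE)
  invisible(x)
}

#' Posterior modes of individual-level parameters from a fit
#'
#' @param fit an `rl_fit` or `ddm_fit`.
#' @return data.frame (participants x parameters) of marginal posterior
#'   modes, ready for [correlation_table()].
#' @export
individual_modes <- function(fit) {
  pars <- if (inherits(fit, "rl_fit")) RL_PARS else
    c(paste0("alpha_", LEARN_CONDITIONS), paste0("nu_", LEARN_CONDITIONS))
  out <- sapply(pars, function(p) {
    vapply(fit$participants, function(id) {
      posterior_mode(pooled_draws(fit$draws, paste0(p, "[", id, "]")))
    }, 0)
  })
  out <- as.data.frame(out)
  rownames(out) <- fit$participants
  out
}

#' Block-wise learning curves
#'
#' For each condition, trials are numbered within participant in
#' presentation order (1..100 per condition under the main design) and
#' grouped into consecutive bins of `block_size` trials; the curve is the
#' cross-participant mean (and standard error) of the per-bin target-choice
#' proportion. `block_size = 5` gives 20 fine-grained bins; `block_size =
#' 20` gives the five coarse bins often used for interval summaries.
#'
#' @param trials data.frame of learning trials with `participant_id`,
#'   `condition`, `chose_target`, `trial`.
#' @param block_size number of trials per bin; must divide the per-condition
#'   trial count of every participant.
#' @return data.frame with `condition`, `bin`, `proportion`, `se`,
#'   `n_participants`.
#' @export
learning_curves <- function(trials, block_size = 5L) {
  ids <- unique(trials$participant_id)
  per <- list()
  for (id in ids) {
    tr <- trials[trials$participant_id == id, ]
    tr <- tr[order(tr$trial), ]
    for (cond in unique(tr$condition)) {
      ch <- tr$chose_target[tr$condition == cond]
      if (length(ch) %% block_size != 0L) {
        stop("block_size ", block_size, " does not divide the ", cond,
             "-condition trial count (", length(ch), ") of participant ", id)
      }
      bins <- rep(seq_len(length(ch) %/% block_size), each = block_size)
      per[[length(per) + 1L]] <- data.frame(
        participant_id = id, condition = cond,
        bin = seq_len(max(bins)),
        prop = tapply(as.numeric(ch), bins, mean),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  agg <- aggregate(prop ~ condition + bin, per,
                   function(v) c(mean(v), sd(v) / sqrt(length(v)), length(v)))
  out <- data.frame(condition = agg$condition, bin = agg$bin,
                    proportion = agg$prop[, 1L], se = agg$prop[, 2L],
                    n_participants = agg$prop[, 3L],
                    stringsAsFactors = FALSE)
  out[order(out$condition, out$bin), ]
}
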
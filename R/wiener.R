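#' Wiener first-passage-time density
#'
#' Density of the time at which a unit-diffusion Wiener process with drift
#' `nu`, boundary separation `alpha` and relative start point `z` first hits
#' the named boundary, shifted by the non-decision time `t0`. Returns 0 for
#' `t <= t0`. Evaluated by the small-time / large-time series expansions with
#' adaptive switching; truncation error is bounded by `eps`.
#'
#' @param t vector of times (seconds).
#' @param alpha boundary separation, > 0.
#' @param nu drift rate (evidence units per second); positive drift favours
#'   the upper boundary.
#' @param t0 non-decision time in seconds, >= 0.
#' @param z relative start point in (0, 1); the response-coded model fixes
#'   `z = 0.5`.
#' @param boundary `"upper"` or `"lower"`.
#' @param eps series truncation tolerance.
#' @return vector of densities, >= 0.
#' @export
#' @examples
#' tt <- seq(0.3, 3, by = 0.01)
#' f <- wfpt_density(tt, alpha = 1.6, nu = 1.4, t0 = 0.25)
wfpt_density <- function(t, alpha, nu, t0 = 0, z = 0.5,
                         boundary = c("upper", "lower"), eps = 1e-7) {
  boundary <- match.arg(boundary)
  if (alpha <= 0) stop("alpha must be > 0")
  if (t0 < 0) stop("t0 must be >= 0")
  if (z <= 0 || z >= 1) stop("z must lie in (0, 1)")
  if (boundary == "lower") {
    wfpt_lower_cpp(as.numeric(t), alpha, nu, z, t0, eps)
  } else {
    wfpt_lower_cpp(as.numeric(t), alpha, -nu, 1 - z, t0, eps)
  }
}

#' Absorption probability at a boundary
#'
#' Closed-form probability that the diffusion is absorbed at the named
#' boundary: for drift `nu`, separation `alpha`, start `z * alpha`,
#' `P(upper) = (1 - exp(-2 nu z alpha)) / (1 - exp(-2 nu alpha))`, and
#' `P(upper) = z` when `nu = 0`.
#'
#' @inheritParams wfpt_density
#' @return probability in \[0, 1\].
#' @export
boundary_prob <- function(alpha, nu, z = 0.5, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  if (alpha <= 0) stop("alpha must be > 0")
  if (z <= 0 || z >= 1) stop("z must lie in (0, 1)")
  p_up <- if (abs(nu) < 1e-10) z else
    expm1(-2 * nu * z * alpha) / expm1(-2 * nu * alpha)
  if (boundary == "upper") p_up else 1 - p_up
}

#' Response-coded diffusion log-likelihood for target-present search trials
#'
#' Sums log Wiener first-passage densities over target-present trials, with
#' the "present"/"dissimilar" response mapped to the upper boundary and the
#' "absent"/"same" response to the lower boundary (configurable via
#' `present_boundary`). Boundary separation and drift are per learning
#' condition; `t0` is shared; the start point is fixed at `z`.
#'
#' @param params list with `alpha` and `nu` (named numeric vectors with
#'   entries `reward`, `punishment`, `zero`) and scalar `t0`; optionally `z`
#'   (default 0.5).
#' @param trials data.frame of search trials with columns `condition`
#'   (target-present conditions only), `response`, `rt_sec`.
#' @param present_boundary boundary the "present" response maps to.
#' @param eps series truncation tolerance.
#' @return summed log-likelihood (<= 0 whenever densities are <= 1).
#' @export
ddm_loglik <- function(params, trials,
                       present_boundary = c("upper", "lower"), eps = 1e-7) {
  present_boundary <- match.arg(present_boundary)
  if (nrow(trials) == 0L) return(0)
  if (any(trials$condition == "absent")) {
    stop("ddm_loglik is defined for target-present trials only")
  }
  t0 <- params$t0
  if (any(trials$rt_sec <= t0)) {
    bad <- which(trials$rt_sec <= t0)[1L]
    stop("rt <= t0 at trial row ", bad, " (rt = ", trials$rt_sec[bad],
         ", t0 = ", t0, "); trim trials or bound t0")
  }
  alpha <- params$alpha[LEARN_CONDITIONS]
  nu <- params$nu[LEARN_CONDITIONS]
  if (any(alpha <= 0)) stop("alpha must be > 0")
  z <- if (is.null(params$z)) 0.5 else params$z
  up <- as.integer(trials$response == "present")
  if (present_boundary == "lower") up <- 1L - up
  ddm_loglik_cpp(as.numeric(trials$rt_sec), up,
                 condition_code(as.character(trials$condition), "ddm"),
                 as.numeric(alpha), as.numeric(nu), t0, z, eps)
}

#' Simulate diffusion-process choices and response times
#'
#' Euler-Maruyama simulation of the unit-diffusion Wiener process with the
#' given parameters; the default step `dt = 1e-4` s gives oracle-grade
#' accuracy against the series density. Draws come from R's RNG stream, so
#' results are reproducible under `set.seed()`.
#'
#' @inheritParams wfpt_density
#' @param n number of trials.
#' @param dt Euler step in seconds.
#' @return data.frame with `rt` (seconds, includes `t0`) and `upper`
#'   (1 = upper boundary, 0 = lower).
#' @export
simulate_ddm <- function(n, alpha, nu, t0 = 0, z = 0.5, dt = 1e-4) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (t0 < 0) stop("t0 must be >= 0")
  ddm_sim_cpp(as.integer(n), alpha, nu, t0, z, dt)
}
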
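#' Rescorla-Wagner value update
#'
#' One step of the delta rule: `EV_new = EV_old + eta * (outcome - EV_old)`.
#' Only the chosen option's expected value is updated on any trial; callers
#' apply this to the chosen option's EV slot.
#'
#' @param ev current expected value.
#' @param outcome monetary outcome, one of -1, 0, +1.
#' @param eta learning rate in (0, 1); `eta = 0` is accepted as the degenerate
#'   no-learning limit used in tests.
#' @return updated expected value.
#' @export
#' @examples
#' update_value(0, 1, 0.05)  # 0.05
update_value <- function(ev, outcome, eta) {
  if (any(eta < 0 | eta >= 1)) stop("eta must lie in [0, 1)")
  if (any(!outcome %in% c(-1, 0, 1))) stop("outcome must be -1, 0 or +1")
  ev + eta * (outcome - ev)
}

#' Softmax choice probability
#'
#' Probability of choosing the option with expected value `ev_chosen` over the
#' alternative with `ev_other`, under inverse temperature `tau`:
#' `exp(tau * ev_chosen) / (exp(tau * ev_chosen) + exp(tau * ev_other))`.
#' Computed via max-subtraction so it is stable for `|tau * ev|` up to ~700.
#'
#' @param ev_chosen,ev_other expected values of the two options.
#' @param tau inverse temperature, `tau >= 0` (`tau = 0` gives random choice).
#' @return choice probability in (0, 1).
#' @export
choice_prob <- function(ev_chosen, ev_other, tau) {
  if (any(tau < 0)) stop("tau must be >= 0")
  a <- tau * ev_chosen
  b <- tau * ev_other
  m <- pmax(a, b)
  exp(a - m) / (exp(a - m) + exp(b - m))
}

#' Log-likelihood of a learning trial sequence under the dual-rate RW model
#'
#' Sequentially replays the participant's reward- and punishment-condition
#' trials: the log softmax probability of the recorded choice is evaluated at
#' the pre-update expected values, then the chosen option's EV is updated with
#' the condition's learning rate. Zero-outcome-condition trials carry no
#' feedback and are skipped entirely. EVs start at 0.
#'
#' @param params named list or vector with `eta_r`, `eta_p`, `tau_r`, `tau_p`.
#' @param trials data.frame with columns `condition`, `chose_target`,
#'   `outcome`, and `trial` (used to verify time ordering).
#' @return the summed log-likelihood (always <= 0).
#' @export
rl_loglik <- function(params, trials) {
  p <- as.list(params)
  stopifnot(all(c("eta_r", "eta_p", "tau_r", "tau_p") %in% names(p)))
  if (p$eta_r < 0 || p$eta_r >= 1 || p$eta_p < 0 || p$eta_p >= 1) {
    stop("learning rates must lie in [0, 1)")
  }
  if (p$tau_r < 0 || p$tau_p < 0) stop("inverse temperatures must be >= 0")
  if ("trial" %in% names(trials) && is.unsorted(trials$trial, strictly = TRUE)) {
    stop("trials must be in time order (column 'trial' strictly increasing)")
  }
  rl_loglik_cpp(condition_code(trials$condition, "rl"),
                as.integer(trials$chose_target),
                as.numeric(trials$outcome),
                p$eta_r, p$eta_p, p$tau_r, p$tau_p)
}

#' Simulate one softmax choice
#'
#' Bernoulli draw of a target choice given the current expected values.
#' Zero-condition choices are uniform (no values are learned there).
#'
#' @param ev_target,ev_nontarget current expected values.
#' @param tau inverse temperature.
#' @param condition condition label; `"zero"` forces a uniform draw.
#' @return logical: `TRUE` if the target was chosen.
#' @export
simulate_choice <- function(ev_target, ev_nontarget, tau, condition = "reward") {
  p <- if (condition == "zero") 0.5 else choice_prob(ev_target, ev_nontarget, tau)
  runif(1) < p
}
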
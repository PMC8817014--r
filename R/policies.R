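#' Assignment policies
#'
#' A policy is the unit the simulation engine runs: it exposes exactly two
#' methods, `propose(state, t, obs)` returning `list(arms, state)` and
#' `observe(state, t, arms, delta_y, G)` returning the updated state, plus an
#' `init(obs)` constructor for its state. Alternative policies are therefore
#' drop-in. Policies never see true effects or latent draws; only
#' group-aware policies (`uses_group = TRUE`) receive the observed group
#' vector `G`.
#'
#' In period 1 every policy assigns at random with probability 1/2 per arm
#' (an initial randomized trial); decision rules take effect from period 2.
#'
#' @param name Policy label (also the RNG sub-stream label, so two policies
#'   with the same name in one comparison draw identical streams).
#' @param init,propose,observe The three methods described above.
#' @param uses_group Whether the engine should pass the observed group `G`
#'   to `observe()`.
#' @return An object of class `rita_policy_def`.
#' @seealso [policy_rita()], [policy_rct()], [policy_moderator()]
#' @export
policy_def <- function(name, init, propose, observe, uses_group = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(init), is.function(propose), is.function(observe))
  structure(list(name = name, init = init, propose = propose,
                 observe = observe, uses_group = uses_group),
            class = "rita_policy_def")
}

#' @export
print.rita_policy_def <- function(x, ...) {
  cat(sprintf("<policy '%s'%s>\n", x$name,
              if (x$uses_group) ", group-aware" else ""))
  invisible(x)
}

#' The RITA policy
#'
#' Recurrent Individual Treatment Assignment: every period, each individual
#' is assigned probabilistically, responses are pooled and ranked, individual
#' mean ranks are updated for the assigned arm, and the assignment
#' probability is updated multiplicatively (individual rank times relative
#' rank to a learning exponent) and clamped into the exploration bounds. See
#' [rita_step()] for the update itself.
#'
#' @param config A [rita_config()].
#' @param keep_state If `TRUE`, the full per-period state dump is retained
#'   on the trajectory (see [simulate_policy()]).
#' @return A [policy_def()].
#' @export
policy_rita <- function(config = rita_config(), keep_state = FALSE) {
  policy_def(
    name = "rita",
    init = function(obs) init_states(obs),
    propose = function(state, t, obs) {
      list(arms = draw_assignments(state), state = state)
    },
    observe = function(state, t, arms, delta_y, G = NULL) {
      rita_step(state, arms, delta_y, config)
    },
    uses_group = FALSE
  ) -> p
  p$keep_state <- keep_state
  p$config <- config
  p
}

#' Estimate the average treatment effect by OLS
#'
#' Regresses the period-1 treatment response on an intercept and the arm-A
#' indicator. With no covariates the coefficient equals the difference of
#' arm means and its standard error the classical two-sample (pooled) one;
#' the p-value is the two-sided t-test for the arm coefficient.
#'
#' @param y Numeric response vector (one period's outcome change).
#' @param assigned_A Logical/0-1 vector, `TRUE` for arm A.
#' @return A list of class `ate_estimate`: `alpha_hat`, `se`, `p_value`, `n`.
#' @examples
#' estimate_ate_ols(c(1, 1, 0, 0), c(1, 1, 0, 0))$alpha_hat # 1
#' @export
estimate_ate_ols <- function(y, assigned_A) {
  assigned_A <- as.numeric(assigned_A)
  stopifnot(length(y) == length(assigned_A), length(y) >= 4,
            all(assigned_A %in% c(0, 1)))
  if (length(unique(assigned_A)) < 2L) {
    stop("both arms must be represented to estimate the ATE", call. = FALSE)
  }
  fit <- stats::lm(y ~ assigned_A)
  # noiseless inputs fit perfectly; the zero-residual warning is expected
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    alpha_hat = unname(cf["assigned_A", "Estimate"]),
    se = unname(cf["assigned_A", "Std. Error"]),
    p_value = unname(cf["assigned_A", "Pr(>|t|)"]),
    n = length(y)
  ), class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("ATE (A - B): %.4f (SE %.4f, p = %.3g, n = %d)\n",
              x$alpha_hat, x$se, x$p_value, x$n))
  invisible(x)
}

#' Deterministic assignment rule from an ATE estimate
#'
#' Assigns the coefficient-wise better arm: A if `alpha_hat > 0`, else B
#' (an exact zero goes to A). The significance threshold is recorded for
#' reporting only — assignment follows the coefficient's sign even when the
#' estimate is insignificant, since with equal ATEs either choice is equally
#' defensible but a rule must commit.
#'
#' @param est An [estimate_ate_ols()] result.
#' @param threshold Significance level recorded alongside the decision.
#' @return `"A"` or `"B"`, with attributes `significant` and `threshold`.
#' @export
baseline_rule <- function(est, threshold = 0.05) {
  arm <- if (est$alpha_hat >= 0) "A" else "B"
  structure(arm, significant = est$p_value < threshold, threshold = threshold)
}

#' The RCT baseline policy
#'
#' Period 1 is a conventional randomized trial (probability 1/2 per arm);
#' the ATE is then estimated once from the period-1 responses by OLS and
#' every individual is assigned the coefficient-wise better arm with
#' certainty for all remaining periods.
#'
#' @param threshold Significance level recorded with the estimate.
#' @param re_estimate If `TRUE`, the ATE is re-estimated each period from
#'   that period's responses (off by default: the baseline never revisits
#'   its period-1 decision, and with deterministic assignment there is no
#'   variation left to re-estimate from).
#' @return A [policy_def()].
#' @export
policy_rct <- function(threshold = 0.05, re_estimate = FALSE) {
  policy_def(
    name = "baseline",
    init = function(obs) list(chosen = NULL, estimate = NULL),
    propose = function(state, t, obs) {
      arms <- if (t == 1L || is.null(state$chosen)) {
        ifelse(stats::runif(obs) < 0.5, "A", "B")
      } else {
        rep(state$chosen, obs)
      }
      list(arms = arms, state = state)
    },
    observe = function(state, t, arms, delta_y, G = NULL) {
      if (is.null(state$estimate) || re_estimate) {
        both <- length(unique(arms)) == 2L
        if (both) {
          est <- estimate_ate_ols(delta_y, arms == "A")
          state$estimate <- est
          state$chosen <- as.character(baseline_rule(est, threshold))
        }
      }
      state
    },
    uses_group = FALSE
  )
}

#' Moderated ATE estimate
#'
#' Fits the period-1 responses with an arm-by-group interaction,
#' `y ~ G + I_A + I_A:G`, so the differential effect of A over B is
#' `alpha1` for `G = 0` and `alpha1 + alpha2` for `G = 1`.
#'
#' @param y Numeric response vector.
#' @param assigned_A Logical/0-1 arm-A indicator.
#' @param x1 Binary observed moderator.
#' @return A list of class `moderator_estimate`: `alpha1`, `alpha2`, `n`.
#' @export
estimate_moderator_ols <- function(y, assigned_A, x1) {
  assigned_A <- as.numeric(assigned_A)
  x1 <- as.numeric(x1)
  stopifnot(length(y) == length(assigned_A), length(y) == length(x1))
  if (length(unique(assigned_A)) < 2L) {
    stop("both arms must be represented", call. = FALSE)
  }
  fit <- stats::lm(y ~ x1 + assigned_A + assigned_A:x1)
  cf <- stats::coef(fit)
  structure(list(
    alpha1 = unname(cf["assigned_A"]),
    alpha2 = unname(cf["x1:assigned_A"]),
    n = length(y)
  ), class = "moderator_estimate")
}

#' Assignment rule from a moderated estimate
#'
#' Assigns arm A iff the estimated differential effect
#' `alpha1 + alpha2 * x1` is positive for the individual's moderator value.
#'
#' @param est An [estimate_moderator_ols()] result (or any list with
#'   `alpha1`, `alpha2`).
#' @param x1 Binary moderator value(s).
#' @return `"A"`/`"B"`, vectorized over `x1`.
#' @examples
#' est <- list(alpha1 = -0.2, alpha2 = 0.6)
#' moderator_rule(est, 1) # "A": differential effect 0.4
#' moderator_rule(est, 0) # "B": differential effect -0.2
#' @export
moderator_rule <- function(est, x1) {
  ifelse(est$alpha1 + est$alpha2 * as.numeric(x1) > 0, "A", "B")
}

#' The moderator baseline policy
#'
#' Like [policy_rct()], but the period-1 regression includes an interaction
#' with the observed group, and from period 2 each individual is assigned
#' deterministically to the arm the moderated estimate favors for their
#' group. This comparator captures all *observed* heterogeneity but none of
#' the latent heterogeneity.
#'
#' @return A [policy_def()] with `uses_group = TRUE`.
#' @export
policy_moderator <- function() {
  policy_def(
    name = "moderator",
    init = function(obs) list(chosen = NULL),
    propose = function(state, t, obs) {
      arms <- if (t == 1L || is.null(state$chosen)) {
        ifelse(stats::runif(obs) < 0.5, "A", "B")
      } else {
        state$chosen
      }
      list(arms = arms, state = state)
    },
    observe = function(state, t, arms, delta_y, G = NULL) {
      if (is.null(state$chosen)) {
        if (is.null(G)) stop("moderator policy needs the observed group",
                             call. = FALSE)
        est <- estimate_moderator_ols(delta_y, arms == "A", G)
        state$estimate <- est
        state$chosen <- moderator_rule(est, G)
      }
      state
    },
    uses_group = TRUE
  )
}

# Resolve a policy given by name or already constructed.
as_policy <- function(x, rita_cfg = rita_config()) {
  if (inherits(x, "rita_policy_def")) return(x)
  switch(as.character(x),
    rita = policy_rita(rita_cfg),
    baseline = ,
    rct = policy_rct(),
    moderator = policy_moderator(),
    stop("unknown policy: '", x, "'", call. = FALSE)
  )
}
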
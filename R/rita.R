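#' Tunables of the RITA assignment policy
#'
#' @param lambda_l,lambda_u Exploration bounds on the assignment
#'   probabilities: after every update, each arm's probability is clamped
#'   into `[lambda_l, lambda_u]`, so assignment never becomes deterministic.
#'   Defaults 0.05 and 0.95.
#' @param tie_rule How tied responses are ranked: `"random"` (seeded random
#'   tie-break, the default — ranks are always an exact permutation of
#'   `1..obs`) or `"average"` (average ranks re-indexed to a permutation in
#'   id order).
#' @param eq10_literal Logical. The update for an individual assigned to arm
#'   B admits two readings; the default (`FALSE`) is the symmetric mirror of
#'   the arm-A update, `tau_B = (rank/obs) * (rank/IMR_A)^(count_B - 1)`,
#'   which reinforces B when B ranks well. `TRUE` switches to the literal
#'   alternative form `1 - tau_A = (1 - rank/obs) * (IMR_A/rank)^(count_B-1)`,
#'   kept for comparison.
#' @return An object of class `rita_config`.
#' @examples
#' rita_config()
#' rita_config(lambda_l = 0.1, lambda_u = 0.9)
#' @export
rita_config <- function(lambda_l = 0.05, lambda_u = 0.95,
                        tie_rule = c("random", "average"),
                        eq10_literal = FALSE) {
  stopifnot(lambda_l > 0, lambda_u < 1, lambda_l < lambda_u,
            is.logical(eq10_literal), length(eq10_literal) == 1L)
  structure(list(
    lambda_l = lambda_l,
    lambda_u = lambda_u,
    tie_rule = match.arg(tie_rule),
    eq10_literal = eq10_literal
  ), class = "rita_config")
}

#' Initialize RITA per-individual state
#'
#' Before any evidence, every individual is assigned to A with probability
#' 1/2 and both individual mean ranks (IMRs) start at the mid-rank
#' `obs / 2`; assignment counts and rank sums start at zero.
#'
#' @param obs Number of individuals (>= 2).
#' @return A `data.frame` of class `rita_state` with one row per individual:
#'   `tau_A` (assignment probability to A), `imr_A`, `imr_B` (individual
#'   mean ranks), `count_A`, `count_B` (cumulative assignment counts),
#'   `rank_sum_A`, `rank_sum_B` (running rank totals), and
#'   `tau_A_unclamped` (last pre-clamp update, diagnostic).
#' @examples
#' st <- init_states(1000)
#' st$imr_A[1] # 500
#' @export
init_states <- function(obs) {
  stopifnot(obs >= 2)
  obs <- as.integer(obs)
  st <- data.frame(
    tau_A = rep(0.5, obs),
    imr_A = rep(obs / 2, obs),
    imr_B = rep(obs / 2, obs),
    count_A = integer(obs),
    count_B = integer(obs),
    rank_sum_A = numeric(obs),
    rank_sum_B = numeric(obs),
    tau_A_unclamped = rep(0.5, obs)
  )
  attr(st, "obs") <- obs
  class(st) <- c("rita_state", "data.frame")
  st
}

#' Draw arm assignments from the current probabilities
#'
#' Each individual independently receives A with probability `tau_A`, else B.
#' Uses the current global RNG state (callers seed a named sub-stream).
#'
#' @param states A [init_states()] state frame.
#' @return Character vector of `"A"`/`"B"`.
#' @export
draw_assignments <- function(states) {
  ifelse(stats::runif(nrow(states)) < states$tau_A, "A", "B")
}

#' Rank pooled treatment responses
#'
#' Ranks the period's outcome changes across the whole population, pooled
#' over both arms: rank 1 for the smallest change, `obs` for the largest.
#' The result is always an exact permutation of `1..obs` (required because
#' the probability update rescales ranks by `obs`).
#'
#' @param delta_y Numeric vector of per-period outcome changes, one per
#'   individual; must be finite.
#' @param tie_rule `"random"` (seeded random tie-break) or `"average"`
#'   (average ranks re-indexed to a permutation in id order).
#' @return Integer vector of ranks, a permutation of `1..length(delta_y)`.
#' @examples
#' rank_responses(c(0.1, 0.5, 0.3)) # 1 3 2
#' @export
rank_responses <- function(delta_y, tie_rule = c("random", "average")) {
  tie_rule <- match.arg(tie_rule)
  if (any(!is.finite(delta_y))) {
    stop("non-finite treatment responses cannot be ranked", call. = FALSE)
  }
  if (tie_rule == "random") {
    as.integer(rank(delta_y, ties.method = "random"))
  } else {
    # average ranks, then re-indexed to an exact permutation (ties resolved
    # in id order)
    as.integer(rank(rank(delta_y, ties.method = "average"),
                    ties.method = "first"))
  }
}

#' Update individual mean ranks after one period
#'
#' For each individual, the assigned arm's cumulative count and rank sum are
#' incremented and its IMR recomputed as `rank_sum / count`; the other arm's
#' IMR is untouched.
#'
#' @param states A [init_states()] state frame.
#' @param arms Character vector of `"A"`/`"B"`, the period's assignments.
#' @param ranks Integer ranks from [rank_responses()].
#' @return The updated state frame.
#' @export
update_imr <- function(states, arms, ranks) {
  obs <- nrow(states)
  stopifnot(length(arms) == obs, length(ranks) == obs,
            all(arms %in% c("A", "B")), all(ranks >= 1), all(ranks <= obs))
  a <- arms == "A"
  states$count_A[a] <- states$count_A[a] + 1L
  states$rank_sum_A[a] <- states$rank_sum_A[a] + ranks[a]
  states$imr_A[a] <- states$rank_sum_A[a] / states$count_A[a]
  b <- !a
  states$count_B[b] <- states$count_B[b] + 1L
  states$rank_sum_B[b] <- states$rank_sum_B[b] + ranks[b]
  states$imr_B[b] <- states$rank_sum_B[b] / states$count_B[b]
  states
}

#' Probability update (pre-clamp)
#'
#' Computes next-period assignment probabilities from this period's pooled
#' ranks. For an individual assigned to A,
#' \deqn{\tau_A = \frac{rank}{obs} \cdot
#'   \left(\frac{rank}{IMR_B}\right)^{count_A - 1},}
#' i.e. an individual-rank factor times a relative-rank factor raised to a
#' learning exponent that grows with the number of times the arm has been
#' assigned; the exponent is 0 on the first assignment, so the first update
#' uses the individual rank alone. For an individual assigned to B the
#' default is the symmetric mirror, `tau_B = (rank/obs) *
#' (rank/IMR_A)^(count_B - 1)` with `tau_A = 1 - tau_B` (see
#' [rita_config()]'s `eq10_literal` for the alternative printed form).
#'
#' Must be called after [update_imr()] for the same period (counts include
#' the current assignment). The result can fall outside `[0, 1]`; apply
#' [clamp_probability()].
#'
#' @inheritParams update_imr
#' @param config A [rita_config()].
#' @return Numeric vector of unclamped `tau_A` values.
#' @examples
#' st <- init_states(1000)
#' st <- update_imr(st, rep("A", 1000), seq_len(1000))
#' # individual ranked 600 on the first A assignment:
#' update_probability(st, rep("A", 1000), seq_len(1000))[600] # 0.6
#' @export
update_probability <- function(states, arms, ranks, config = rita_config()) {
  obs <- nrow(states)
  stopifnot(length(arms) == obs, length(ranks) == obs)
  a <- arms == "A"
  cnt <- ifelse(a, states$count_A, states$count_B)
  if (any(cnt == 0)) {
    stop("update_imr must be applied before update_probability ",
         "(assigned-arm count is zero)", call. = FALSE)
  }
  r <- as.numeric(ranks)
  imr_opp <- ifelse(a, states$imr_B, states$imr_A)

  tau_A <- numeric(obs)
  # assigned A: tau_A directly
  tau_A[a] <- (r[a] / obs) * (r[a] / imr_opp[a])^(cnt[a] - 1)
  # assigned B
  if (config$eq10_literal) {
    tau_A[!a] <- 1 - (1 - r[!a] / obs) * (imr_opp[!a] / r[!a])^(cnt[!a] - 1)
  } else {
    tau_B <- (r[!a] / obs) * (r[!a] / imr_opp[!a])^(cnt[!a] - 1)
    tau_A[!a] <- 1 - tau_B
  }
  # overflow of the learning factor means full certainty; the clamp bounds it
  tau_A[a][is.nan(tau_A[a]) | tau_A[a] > .Machine$double.xmax] <- Inf
  tau_A
}

#' Clamp assignment probabilities to the exploration bounds
#'
#' Bounds both arms' probabilities into `[lambda_l, lambda_u]`: `tau_A` is
#' clamped to `[max(lambda_l, 1 - lambda_u), min(lambda_u, 1 - lambda_l)]`,
#' which with the default symmetric bounds reduces to `[0.05, 0.95]`.
#'
#' @param tau Numeric vector of (possibly out-of-range) `tau_A` values.
#' @param config A [rita_config()].
#' @return Clamped probabilities.
#' @examples
#' clamp_probability(c(1.2, 0.01, 0.6)) # 0.95 0.05 0.60
#' @export
clamp_probability <- function(tau, config = rita_config()) {
  lo <- max(config$lambda_l, 1 - config$lambda_u)
  hi <- min(config$lambda_u, 1 - config$lambda_l)
  pmin(pmax(tau, lo), hi)
}

#' One full RITA update for a period
#'
#' Composition of the per-period steps: pooled ranking of the responses,
#' IMR bookkeeping for the assigned arms, the probability update, and the
#' exploration clamp. Pure in its inputs: returns a new state frame. Random
#' tie-breaking uses the current global RNG state.
#'
#' @inheritParams update_imr
#' @param delta_y Numeric vector of per-period outcome changes.
#' @param config A [rita_config()].
#' @return The updated state frame; the period's ranks are attached as
#'   attribute `"ranks"`.
#' @export
rita_step <- function(states, arms, delta_y, config = rita_config()) {
  obs <- nrow(states)
  stopifnot(length(arms) == obs, length(delta_y) == obs)
  ranks <- rank_responses(delta_y, config$tie_rule)
  states <- update_imr(states, arms, ranks)
  tau_raw <- update_probability(states, arms, ranks, config)
  states$tau_A_unclamped <- tau_raw
  states$tau_A <- clamp_probability(tau_raw, config)
  attr(states, "ranks") <- ranks
  states
}
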
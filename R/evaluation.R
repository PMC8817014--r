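#' Proportion assigned to an arm in a period
#'
#' @param traj A [simulate_policy()] trajectory.
#' @param arm `"A"` or `"B"`.
#' @param period Period in `1..periods`.
#' @return Fraction of individuals assigned `arm` in that period.
#' @export
assignment_proportion <- function(traj, arm = "A", period) {
  stopifnot(period >= 1, period <= traj$periods)
  mean(traj$arms[, period] == arm)
}

#' Per-period assignment-proportion curve
#'
#' @inheritParams assignment_proportion
#' @return Numeric vector of length `periods`: fraction assigned `arm` in
#'   each period.
#' @export
assignment_proportions <- function(traj, arm = "A") {
  colMeans(traj$arms == arm)
}

#' Average cumulative outcome gain
#'
#' Mean over individuals of `y_period - y_0`. Gains rather than raw
#' outcomes: the baseline score `y0 ~ N(10, 1)` is policy-independent, so
#' curves start at 0 and paired differences are unaffected by the choice.
#'
#' @param traj A trajectory.
#' @param period Period in `0..periods` (`0` gives 0 by definition).
#' @return Mean cumulative gain in outcome units.
#' @export
average_cumulative_gain <- function(traj, period = traj$periods) {
  stopifnot(period >= 0, period <= traj$periods)
  if (period == 0) return(0)
  mean(traj$y_mat[, period] - traj$population$y0)
}

#' Paired per-individual gain difference between two policies
#'
#' `(y_T - y_0)` under `traj_a` minus under `traj_b`, per individual. The
#' two trajectories must come from the same comparison (identical
#' population), so the differences isolate assignment decisions.
#'
#' @param traj_a,traj_b Trajectories sharing a population (see
#'   [run_comparison()]).
#' @return Numeric vector, one difference per individual.
#' @export
gain_difference <- function(traj_a, traj_b) {
  pa <- traj_a$population
  pb <- traj_b$population
  if (!isTRUE(all.equal(pa$id, pb$id)) ||
      !isTRUE(all.equal(pa$y0, pb$y0)) ||
      !isTRUE(all.equal(pa$effect_A, pb$effect_A)) ||
      !isTRUE(all.equal(pa$effect_B, pb$effect_B))) {
    stop("trajectories were not run on the same population", call. = FALSE)
  }
  traj_a$gain - traj_b$gain
}

#' Order individuals by final outcome under a trajectory
#'
#' The "RITA rank" display ordering: ids sorted ascending by final
#' cumulative outcome (rank 1 = lowest final outcome); ties broken by id.
#'
#' @param traj A trajectory (conventionally the RITA one).
#' @return Integer vector of ids, a permutation.
#' @export
rita_rank_order <- function(traj) {
  traj$population$id[order(traj$final_y, traj$population$id)]
}

#' Subgroup medians of paired gain differences
#'
#' Splits the per-individual paired differences by each individual's
#' ground-truth optimal arm ([optimal_arm()], evaluation-only) and returns
#' the subgroup medians and counts. Medians use the standard midpoint
#' convention for even counts.
#'
#' @param diffs Per-individual differences from [gain_difference()].
#' @param pop The shared population.
#' @return A list: `median_overall`, `median_A_optimal`, `median_B_optimal`,
#'   `n_A_optimal`, `n_B_optimal`.
#' @export
subgroup_medians <- function(diffs, pop) {
  stopifnot(length(diffs) == nrow(pop))
  opt <- optimal_arm(pop)
  list(
    median_overall = stats::median(diffs),
    median_A_optimal = if (any(opt == "A"))
      stats::median(diffs[opt == "A"]) else NA_real_,
    median_B_optimal = if (any(opt == "B"))
      stats::median(diffs[opt == "B"]) else NA_real_,
    n_A_optimal = sum(opt == "A"),
    n_B_optimal = sum(opt == "B")
  )
}

#' Fraction of individuals on their individually optimal arm
#'
#' @param traj A trajectory.
#' @param period Period to evaluate (default the final one).
#' @return Fraction in `[0, 1]`.
#' @export
optimal_assignment_fraction <- function(traj, period = traj$periods) {
  mean(traj$arms[, period] == optimal_arm(traj$population))
}

#' Summarize a two-policy comparison
#'
#' Computes the headline comparison metrics for a paired run: mean and SD of
#' the per-individual cumulative-gain differences at the final period,
#' overall and subgroup medians (split by ground-truth optimal arm), and the
#' per-period assignment-proportion curves.
#'
#' @param cmp A [run_comparison()] result.
#' @param policy,reference Names of the compared and reference policies in
#'   `cmp` (differences are `policy - reference`).
#' @return A list of class `comparison_summary`.
#' @export
comparison_summary <- function(cmp, policy = "rita", reference = "baseline") {
  stopifnot(inherits(cmp, "rita_comparison"),
            policy %in% names(cmp), reference %in% names(cmp))
  pop <- attr(cmp, "population")
  d <- gain_difference(cmp[[policy]], cmp[[reference]])
  med <- subgroup_medians(d, pop)
  structure(c(list(
    world_id = attr(cmp, "world_id"),
    seed = attr(cmp, "seed"),
    policy = policy,
    reference = reference,
    mean_gain_diff = mean(d),
    sd_gain_diff = stats::sd(d)
  ), med, list(
    optimal_fraction = vapply(cmp, optimal_assignment_fraction, 0.0),
    assignment_prop_A = lapply(cmp, assignment_proportions)
  )), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat(sprintf("<comparison on %s (seed %d): %s - %s>\n",
              x$world_id, x$seed, x$policy, x$reference))
  cat(sprintf("  mean gain difference : %8.2f (SD %.2f)\n",
              x$mean_gain_diff, x$sd_gain_diff))
  cat(sprintf("  median difference    : %8.2f overall\n", x$median_overall))
  cat(sprintf("    A-optimal (n = %3d): %8.2f\n",
              x$n_A_optimal, x$median_A_optimal))
  cat(sprintf("    B-optimal (n = %3d): %8.2f\n",
              x$n_B_optimal, x$median_B_optimal))
  cat(sprintf("  fraction on optimal arm at T: %s\n",
              paste(sprintf("%s %.2f", names(x$optimal_fraction),
                            x$optimal_fraction), collapse = ", ")))
  invisible(x)
}

#' One-row data frame of a comparison summary
#'
#' @param x A [comparison_summary()].
#' @param ... Unused.
#' @return A one-row `data.frame` suitable for stacking across worlds/seeds.
#' @export
as.data.frame.comparison_summary <- function(x, ...) {
  data.frame(
    world = x$world_id, seed = x$seed,
    policy = x$policy, reference = x$reference,
    mean_gain_diff = x$mean_gain_diff, sd_gain_diff = x$sd_gain_diff,
    median_overall = x$median_overall,
    median_A_optimal = x$median_A_optimal,
    median_B_optimal = x$median_B_optimal,
    n_A_optimal = x$n_A_optimal, n_B_optimal = x$n_B_optimal,
    optimal_fraction_policy = unname(x$optimal_fraction[x$policy]),
    optimal_fraction_reference = unname(x$optimal_fraction[x$reference])
  )
}

#' Replicate a paired comparison over many seeds
#'
#' Runs [run_comparison()] for each seed and stacks the one-row summaries,
#' adding the baseline's realized post-trial arm (`baseline_arm`) and the
#' subgroup medians re-keyed to it: `median_fav` is the median difference
#' among individuals whose optimal arm matches the baseline's chosen arm
#' (the subgroup the baseline serves perfectly), `median_other` the rest.
#' In label-symmetric settings (equal overall ATEs) the baseline's arm
#' choice is a coin flip across seeds, so the raw A/B-optimal medians are
#' bimodal while the re-keyed ones are stable.
#'
#' @param world World preset name or [world_spec()].
#' @param seeds Integer vector of master seeds.
#' @param obs,periods,noise_sd As in [run_comparison()].
#' @param rita_cfg A [rita_config()].
#' @return A `data.frame`, one row per seed.
#' @export
replicate_comparison <- function(world, seeds, obs = 1000, periods = 60,
                                 noise_sd = 0.1, rita_cfg = rita_config()) {
  rows <- lapply(seeds, function(s) {
    cmp <- run_comparison(world, list(policy_rct(), policy_rita(rita_cfg)),
                          obs = obs, periods = periods, seed = s,
                          noise_sd = noise_sd)
    sm <- comparison_summary(cmp)
    row <- as.data.frame(sm)
    base_arm <- cmp$baseline$state$chosen
    if (is.null(base_arm)) base_arm <- NA_character_
    row$baseline_arm <- base_arm
    if (identical(base_arm, "B")) {
      row$median_fav <- sm$median_B_optimal
      row$median_other <- sm$median_A_optimal
    } else {
      row$median_fav <- sm$median_A_optimal
      row$median_other <- sm$median_B_optimal
    }
    row
  })
  do.call(rbind, rows)
}
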
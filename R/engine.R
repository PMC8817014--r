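#' Simulate one policy on one world
#'
#' Runs the longitudinal loop for `periods` periods on a population of `obs`
#' individuals: each period the policy proposes assignments, the outcome
#' change is the assigned arm's individual effect plus iid noise
#' `N(0, noise_sd)`, outcomes accumulate, and the (assignments, responses)
#' pair is fed back to the policy. Policies never observe effects or latent
#' draws; group-aware policies additionally receive `G`.
#'
#' All randomness derives from `seed` via named sub-streams
#' ([substream_seed()]): `"population"`, `"noise"`, and
#' `"policy/<name>/<period>"`, so the same seed gives a bit-identical
#' trajectory and different policies on the same seed face the identical
#' population and (by default) identical noise.
#'
#' @param world A [world_spec()], or a preset name like `"world4"`.
#' @param policy A [policy_def()] (or `"rita"`, `"baseline"`,
#'   `"moderator"`).
#' @param obs Population size (default 1000).
#' @param periods Number of periods (default 60).
#' @param seed Integer master seed.
#' @param noise_sd Outcome-noise standard deviation (default 0.1).
#' @param population Optionally a pre-built [make_population()] frame
#'   (overrides `world`/`obs` draws; used for paired comparisons).
#' @param noise Optionally a pre-drawn `obs x periods` noise matrix.
#' @param keep_state For state-dumping policies (RITA), retain the
#'   per-period state panel.
#' @return An object of class `rita_trajectory`: a list with the long-format
#'   `records` data frame (`period, id, arm, delta_y, y`), the `population`,
#'   per-individual final `gain` (`y_T - y_0`), and run metadata.
#' @examples
#' tr <- simulate_policy("world1", "baseline", obs = 20, periods = 3, seed = 1)
#' head(tr$records)
#' @export
simulate_policy <- function(world, policy, obs = 1000, periods = 60, seed = 1,
                            noise_sd = 0.1, population = NULL, noise = NULL,
                            keep_state = FALSE) {
  if (is.character(world)) world <- world_spec(world)
  policy <- as_policy(policy)
  stopifnot(periods >= 1)
  periods <- as.integer(periods)

  if (is.null(population)) {
    population <- make_population(world, obs, substream_seed(seed, "population"))
  }
  obs <- nrow(population)
  if (is.null(noise)) {
    noise <- with_stream(substream_seed(seed, "noise"),
                         matrix(stats::rnorm(obs * periods, 0, noise_sd),
                                obs, periods))
  }
  stopifnot(nrow(noise) == obs, ncol(noise) == periods)

  keep_state <- keep_state || isTRUE(policy$keep_state)
  state <- policy$init(obs)
  arms_m <- matrix(NA_character_, obs, periods)
  dy_m <- matrix(NA_real_, obs, periods)
  y <- population$y0
  y_m <- matrix(NA_real_, obs, periods)
  state_dump <- if (keep_state) vector("list", periods) else NULL

  for (t in seq_len(periods)) {
    with_stream(substream_seed(seed, sprintf("policy/%s/%d", policy$name, t)), {
      prop <- policy$propose(state, t, obs)
      state <- prop$state
      arms <- prop$arms
      if (!all(arms %in% c("A", "B")) || length(arms) != obs) {
        stop("policy '", policy$name, "' proposed invalid assignments",
             call. = FALSE)
      }
      dy <- ifelse(arms == "A", population$effect_A, population$effect_B) +
        noise[, t]
      y <- y + dy
      state <- policy$observe(state, t, arms, dy,
                              G = if (policy$uses_group) population$G else NULL)
    })
    arms_m[, t] <- arms
    dy_m[, t] <- dy
    y_m[, t] <- y
    if (keep_state && is.data.frame(state)) {
      state_dump[[t]] <- cbind(period = t, id = population$id,
                               arm = arms, delta_y = dy, rank =
                                 as.integer(attr(state, "ranks")),
                               as.data.frame(state))
    }
  }

  records <- data.frame(
    period = rep(seq_len(periods), each = obs),
    id = rep(population$id, periods),
    arm = as.vector(arms_m),
    delta_y = as.vector(dy_m),
    y = as.vector(y_m)
  )

  structure(list(
    records = records,
    population = population,
    world_id = world$world_id,
    policy_name = policy$name,
    seed = seed,
    obs = obs,
    periods = periods,
    noise_sd = noise_sd,
    gain = y - population$y0,
    final_y = y,
    arms = arms_m,
    y_mat = y_m,
    state = state,
    state_dump = if (keep_state) do.call(rbind, state_dump) else NULL
  ), class = "rita_trajectory")
}

#' @export
print.rita_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: policy '%s' on %s, obs = %d, periods = %d, seed = %d>\n",
              x$policy_name, x$world_id, x$obs, x$periods, x$seed))
  cat(sprintf("  mean cumulative gain at T: %.3f\n", mean(x$gain)))
  invisible(x)
}

#' Run several policies on one shared world draw
#'
#' Head-to-head comparison with common random numbers: every policy faces
#' the identical population (same latent draws and baselines) and, by
#' default, the identical outcome-noise stream per (individual, period), so
#' per-individual gain differences isolate the assignment decisions.
#' Policy-internal randomness (assignment draws, tie-breaks) uses
#' independent per-policy sub-streams, so the policy list order is
#' irrelevant.
#'
#' @inheritParams simulate_policy
#' @param policies List of [policy_def()]s or policy names (>= 2).
#' @param independent_noise If `TRUE`, each policy draws its own noise
#'   stream instead of the shared one.
#' @return A named list of `rita_trajectory` objects (one per policy), of
#'   class `rita_comparison`, with the shared population attached.
#' @examples
#' cmp <- run_comparison("world1", list("baseline", "rita"),
#'                       obs = 30, periods = 5, seed = 1)
#' names(cmp)
#' @export
run_comparison <- function(world, policies = list("baseline", "rita"),
                           obs = 1000, periods = 60, seed = 1,
                           noise_sd = 0.1, independent_noise = FALSE,
                           keep_state = FALSE) {
  if (is.character(world)) world <- world_spec(world)
  stopifnot(length(policies) >= 2)
  policies <- lapply(policies, as_policy)

  population <- make_population(world, obs, substream_seed(seed, "population"))
  shared_noise <- with_stream(substream_seed(seed, "noise"),
                              matrix(stats::rnorm(obs * periods, 0, noise_sd),
                                     obs, periods))

  out <- lapply(policies, function(p) {
    noise <- if (independent_noise) {
      with_stream(substream_seed(seed, paste0("noise/", p$name)),
                  matrix(stats::rnorm(obs * periods, 0, noise_sd),
                         obs, periods))
    } else {
      shared_noise
    }
    simulate_policy(world, p, obs = obs, periods = periods, seed = seed,
                    noise_sd = noise_sd, population = population,
                    noise = noise, keep_state = keep_state)
  })
  names(out) <- vapply(policies, `[[`, "", "name")
  structure(out, class = "rita_comparison", population = population,
            world_id = world$world_id, seed = seed)
}

#' Write a trajectory as long-format delimited text
#'
#' @param traj A [simulate_policy()] trajectory.
#' @param path Output file (tab-separated); a YAML sidecar
#'   `<path>.meta.yaml` records world, policy, seed, sizes, and noise sd.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  rec <- traj$records
  rec$policy <- traj$policy_name
  utils::write.table(rec[, c("period", "id", "policy", "arm", "delta_y", "y")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(world = traj$world_id, policy = traj$policy_name,
                        seed = traj$seed, obs = traj$obs,
                        periods = traj$periods, noise_sd = traj$noise_sd),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}
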
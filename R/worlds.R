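#' Specify a simulation world
#'
#' A world defines how per-individual, per-period treatment effects for two
#' competing interventions A and B are generated. Each arm's individual
#' effect is a latent draw `e_L` scaled by an optional observed-group
#' interaction:
#'
#' \deqn{effect = e_L \cdot (1 + ind_G / scale)}
#'
#' where `e_L ~ N(latent_mean, latent_sd)` (degenerate at the mean when
#' `latent_sd = 0`), `ind_G` is `G` for arm A and `1 - G` for arm B, and
#' `scale` is the interaction divisor (`0` disables the interaction). The
#' heterogeneity is thus multiplicative in the latent draw, `h = u + u * o`,
#' with an unobserved component `u` and an observed component `o` keyed to a
#' binary group `G` that the assignment policies never see (only the optional
#' moderator comparator observes `G`).
#'
#' Four named presets span the heterogeneity regimes studied in the package:
#'
#' * `world1` — constant effects 0.8 (A) vs 0.6 (B): no heterogeneity.
#' * `world2` — latent-only heterogeneity, `N(0.8, 0.4)` vs `N(0.6, 0.3)`,
#'   same ATEs as world 1 (coefficient of variation 0.5).
#' * `world3` — latent `N(0.7, 0.35)` (A, boosted for `G = 1` via divisor
#'   3.5) vs `N(0.5, 0.25)` (B, boosted for `G = 0` via divisor 2.5):
#'   subgroup ATEs 0.9/0.7 (A) and 0.5/0.7 (B), overall 0.8 vs 0.6.
#' * `world4` — both arms latent `N(0.7, 0.35)` with divisor 3.5, A keyed to
#'   `G = 1` and B to `G = 0`: equal overall ATEs of 0.8 but opposite
#'   subgroup profiles, so the population ATE carries no information about
#'   individual assignment.
#'
#' @param world_id `"world1"`..`"world4"` (or integers 1..4) for a preset, or
#'   `"custom"` together with the remaining arguments.
#' @param mean_effect_A,mean_effect_B Implied population-average effects,
#'   outcome units per period (informational for custom worlds; presets set
#'   them consistently).
#' @param latent_A,latent_B Length-2 numeric `c(mean, sd)` of the latent
#'   effect distribution per arm; `sd = 0` gives a degenerate (constant)
#'   effect.
#' @param interaction_scale_A,interaction_scale_B Positive divisors of the
#'   observed-group interaction (arm A interacts with `G = 1`, arm B with
#'   `G = 0`); `0` means no interaction.
#' @param group_fraction Fraction of the population with `G = 1`.
#' @return An object of class `world_spec`.
#' @examples
#' world_spec("world3")
#' world_spec("custom", latent_A = c(1, 0.2), latent_B = c(1, 0.2))
#' @seealso [make_population()], [world_ate()]
#' @export
world_spec <- function(world_id = c("world1", "world2", "world3", "world4",
                                    "custom"),
                       mean_effect_A = NULL, mean_effect_B = NULL,
                       latent_A = NULL, latent_B = NULL,
                       interaction_scale_A = 0, interaction_scale_B = 0,
                       group_fraction = 0.5) {
  if (is.numeric(world_id)) {
    if (!world_id %in% 1:4) {
      stop("unknown world_id: ", world_id, call. = FALSE)
    }
    world_id <- paste0("world", world_id)
  }
  world_id <- match.arg(world_id)

  presets <- list(
    world1 = list(latent_A = c(0.8, 0),    latent_B = c(0.6, 0),
                  scale_A = 0,   scale_B = 0),
    world2 = list(latent_A = c(0.8, 0.4),  latent_B = c(0.6, 0.3),
                  scale_A = 0,   scale_B = 0),
    world3 = list(latent_A = c(0.7, 0.35), latent_B = c(0.5, 0.25),
                  scale_A = 3.5, scale_B = 2.5),
    world4 = list(latent_A = c(0.7, 0.35), latent_B = c(0.7, 0.35),
                  scale_A = 3.5, scale_B = 3.5)
  )

  if (world_id != "custom") {
    p <- presets[[world_id]]
    latent_A <- p$latent_A
    latent_B <- p$latent_B
    interaction_scale_A <- p$scale_A
    interaction_scale_B <- p$scale_B
  } else {
    if (is.null(latent_A) || is.null(latent_B)) {
      stop("custom worlds need latent_A and latent_B as c(mean, sd)",
           call. = FALSE)
    }
  }
  stopifnot(length(latent_A) == 2L, length(latent_B) == 2L,
            latent_A[2] >= 0, latent_B[2] >= 0,
            interaction_scale_A >= 0, interaction_scale_B >= 0,
            group_fraction >= 0, group_fraction <= 1)

  spec <- structure(list(
    world_id = world_id,
    latent_A = as.numeric(latent_A),
    latent_B = as.numeric(latent_B),
    interaction_scale_A = as.numeric(interaction_scale_A),
    interaction_scale_B = as.numeric(interaction_scale_B),
    group_fraction = as.numeric(group_fraction)
  ), class = "world_spec")
  spec$mean_effect_A <- if (is.null(mean_effect_A)) {
    world_ate(spec, "A")
  } else {
    as.numeric(mean_effect_A)
  }
  spec$mean_effect_B <- if (is.null(mean_effect_B)) {
    world_ate(spec, "B")
  } else {
    as.numeric(mean_effect_B)
  }
  spec
}

#' @export
print.world_spec <- function(x, ...) {
  cat(sprintf("<world_spec '%s'>\n", x$world_id))
  fmt <- function(arm, lat, sc, g) {
    if (lat[2] == 0) {
      dist <- sprintf("constant %.2f", lat[1])
    } else {
      dist <- sprintf("N(%.2f, %.2f)", lat[1], lat[2])
    }
    inter <- if (sc > 0) sprintf(", x (1 + %s/%.1f)", g, sc) else ""
    cat(sprintf("  arm %s: e_L ~ %s%s   (ATE %.3f)\n",
                arm, dist, inter, world_ate(x, arm)))
  }
  fmt("A", x$latent_A, x$interaction_scale_A, "G")
  fmt("B", x$latent_B, x$interaction_scale_B, "(1-G)")
  cat(sprintf("  group fraction P(G = 1) = %.2f\n", x$group_fraction))
  invisible(x)
}

# Interaction indicator per arm: A is keyed to G = 1, B to G = 0.
arm_indicator <- function(arm, G) {
  if (arm == "A") G else 1 - G
}

#' Closed-form expected treatment effect of a world
#'
#' The expected per-period effect of one arm, either within an observed group
#' or marginally over the group mix. Since the heterogeneity is
#' multiplicative in the latent draw, the subgroup mean is
#' `latent_mean * (1 + ind_G / scale)` and the marginal mean is the
#' `group_fraction`-weighted mixture.
#'
#' @param spec A [world_spec()].
#' @param arm `"A"` or `"B"`.
#' @param group `0`, `1`, or `NULL` (marginal over groups).
#' @return The expected effect in outcome units per period.
#' @examples
#' world_ate(world_spec("world3"), "A", group = 1) # 0.9
#' world_ate(world_spec("world3"), "B")            # 0.6
#' @export
world_ate <- function(spec, arm = c("A", "B"), group = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  arm <- match.arg(arm)
  lat <- if (arm == "A") spec$latent_A else spec$latent_B
  sc <- if (arm == "A") spec$interaction_scale_A else spec$interaction_scale_B
  mult <- function(G) {
    if (sc > 0) 1 + arm_indicator(arm, G) / sc else 1
  }
  if (is.null(group)) {
    f <- spec$group_fraction
    lat[1] * (f * mult(1) + (1 - f) * mult(0))
  } else {
    stopifnot(group %in% c(0, 1))
    lat[1] * mult(group)
  }
}

#' Generate a population for a world
#'
#' Draws `obs` individuals: a binary observed group `G`, a baseline outcome
#' `y0 ~ N(10, 1)`, one latent effect draw per arm (fixed for all periods),
#' and the implied per-period effects `effect_A`, `effect_B`. Treatment-effect
#' heterogeneity is constant within an individual over time.
#'
#' By default `G` is an exact `group_fraction` split (rounded), shuffled by
#' the seed, so a 0.5 fraction is realized exactly; `group_assign =
#' "bernoulli"` draws `G` iid instead.
#'
#' @param spec A [world_spec()].
#' @param obs Number of individuals (>= 2).
#' @param seed Integer seed; identical seeds give bit-identical populations.
#' @param group_assign `"exact"` (default) or `"bernoulli"`.
#' @return A `data.frame` of class `rita_population` with columns
#'   `id, G, e_LA, e_LB, effect_A, effect_B, y0` and the spec attached as
#'   attribute `"spec"`.
#' @examples
#' pop <- make_population(world_spec("world1"), obs = 10, seed = 1)
#' all(pop$effect_A == 0.8)
#' @export
make_population <- function(spec, obs, seed,
                            group_assign = c("exact", "bernoulli")) {
  stopifnot(inherits(spec, "world_spec"), obs >= 2)
  group_assign <- match.arg(group_assign)
  obs <- as.integer(obs)

  with_stream(seed, {
    if (group_assign == "exact") {
      n1 <- round(spec$group_fraction * obs)
      G <- sample(rep(c(1L, 0L), c(n1, obs - n1)))
    } else {
      G <- as.integer(stats::runif(obs) < spec$group_fraction)
    }
    y0 <- stats::rnorm(obs, 10, 1)
    e_LA <- stats::rnorm(obs, spec$latent_A[1], spec$latent_A[2])
    e_LB <- stats::rnorm(obs, spec$latent_B[1], spec$latent_B[2])

    mult_A <- if (spec$interaction_scale_A > 0) {
      1 + G / spec$interaction_scale_A
    } else {
      rep(1, obs)
    }
    mult_B <- if (spec$interaction_scale_B > 0) {
      1 + (1 - G) / spec$interaction_scale_B
    } else {
      rep(1, obs)
    }

    pop <- data.frame(
      id = seq_len(obs),
      G = G,
      e_LA = e_LA,
      e_LB = e_LB,
      effect_A = e_LA * mult_A,
      effect_B = e_LB * mult_B,
      y0 = y0
    )
    attr(pop, "spec") <- spec
    class(pop) <- c("rita_population", "data.frame")
    pop
  })
}

#' Individually optimal arm (ground truth)
#'
#' Which arm has the larger per-period effect for each individual. This is
#' generator-side ground truth used only by evaluation code; no assignment
#' policy ever observes it. Exact ties go to A.
#'
#' @param pop A [make_population()] data frame (or any data frame with
#'   `effect_A` and `effect_B` columns).
#' @return Character vector of `"A"`/`"B"`, one per individual.
#' @export
optimal_arm <- function(pop) {
  stopifnot(all(c("effect_A", "effect_B") %in% names(pop)))
  ifelse(pop$effect_A >= pop$effect_B, "A", "B")
}

#' Write a population as delimited text
#'
#' @param pop A [make_population()] data frame.
#' @param path Output file path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.table(as.data.frame(pop), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a world specification from a YAML config file
#'
#' The file either names a preset (`world: world3`) or spells out a custom
#' world under the same field names as [world_spec()], with `latent_A` /
#' `latent_B` as two-element `[mean, sd]` lists.
#'
#' @param path Path to a YAML file.
#' @return A [world_spec()].
#' @export
read_world_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  world_spec_from_list(cfg)
}

world_spec_from_list <- function(cfg) {
  if (!is.null(cfg$world) && is.null(cfg$latent_A)) {
    return(world_spec(cfg$world))
  }
  world_spec(
    world_id = if (is.null(cfg$world)) "custom" else cfg$world,
    latent_A = unlist(cfg$latent_A),
    latent_B = unlist(cfg$latent_B),
    interaction_scale_A = if (is.null(cfg$interaction_scale_A)) 0 else
      cfg$interaction_scale_A,
    interaction_scale_B = if (is.null(cfg$interaction_scale_B)) 0 else
      cfg$interaction_scale_B,
    group_fraction = if (is.null(cfg$group_fraction)) 0.5 else
      cfg$group_fraction
  )
}
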
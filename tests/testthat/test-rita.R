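# The worked single-individual examples use an obs = 1000 panel in which
# individual 1 plays the role of the person being tracked; the other 999
# individuals fill out the rank permutation.
arms_with <- function(arm1, obs = 1000) c(arm1, rep("B", obs - 1))
ranks_with <- function(rank1, obs = 1000) {
  c(rank1, setdiff(seq_len(obs), rank1))
}

test_that("initial states are uninformative", {
  st <- init_states(1000)
  expect_equal(st$tau_A, rep(0.5, 1000))
  expect_equal(st$imr_A[1], 500)
  expect_equal(st$imr_B[1], 500)
  expect_equal(st$count_A, integer(1000))
  expect_equal(init_states(4)$imr_A[1], 2)
  expect_error(init_states(1))
})

test_that("assignment draws follow tau_A", {
  st <- init_states(10)
  st$tau_A <- rep(1, 10) # unclamped test state
  expect_equal(draw_assignments(st), rep("A", 10))
  st$tau_A <- rep(0, 10)
  expect_equal(draw_assignments(st), rep("B", 10))

  st <- init_states(1e5)
  set.seed(1)
  frac <- mean(draw_assignments(st) == "A")
  se <- sqrt(0.25 / 1e5) # binomial SE at p = 0.5
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("pooled ranks are a permutation increasing in the response", {
  expect_equal(rank_responses(c(0.1, 0.5, 0.3)), c(1L, 3L, 2L))
  set.seed(2)
  expect_true(all(sort(rank_responses(c(0.2, 0.2))) == 1:2))
  expect_error(rank_responses(c(1, NA)), "non-finite")
  expect_error(rank_responses(c(1, Inf)), "non-finite")

  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    x <- sample(round(stats::rnorm(n), 1), n) # generates ties
    for (rule in c("random", "average")) {
      r <- rank_responses(x, rule)
      expect_identical(sort(r), seq_len(n)) # permutation identity
      # strictly smaller response implies strictly smaller rank
      expect_true(all(outer(r, r, `<`)[outer(x, x, `<`)]))
    }
  }
  # average rule resolves ties in id order
  expect_equal(rank_responses(c(0.5, 0.2, 0.5), "average"), c(2L, 1L, 3L))
})

test_that("IMR bookkeeping updates only the assigned arm", {
  st <- init_states(1000)
  st <- update_imr(st, arms_with("A"), ranks_with(600))
  expect_equal(st$imr_A[1], 600)
  expect_equal(st$imr_B[1], 500)
  expect_equal(st$count_A[1], 1L)

  st2 <- update_imr(st, arms_with("A"), ranks_with(400))
  expect_equal(st2$imr_A[1], 500) # mean of 600, 400
  expect_equal(st2$count_A[1], 2L)

  stb <- update_imr(init_states(1000), c("B", rep("A", 999)), ranks_with(250))
  expect_equal(stb$imr_B[1], 250)
  expect_equal(stb$imr_A[1], 500)
})

test_that("probability update reproduces the worked example", {
  # first A assignment, rank 600: exponent 0, tau = individual rank = 0.6
  st <- update_imr(init_states(1000), arms_with("A"), ranks_with(600))
  tau1 <- update_probability(st, arms_with("A"), ranks_with(600))
  expect_equal(tau1[1], 0.6)
  expect_equal(st$imr_A[1] / st$imr_B[1], 1.2) # relative rank 600/500

  # second A assignment, rank 600 again: 0.6 * 1.2^1 = 0.72
  st <- update_imr(st, arms_with("A"), ranks_with(600))
  tau2 <- update_probability(st, arms_with("A"), ranks_with(600))
  expect_equal(tau2[1], 0.72)

  # both factors unity
  st3 <- init_states(1000)
  st3$count_A <- rep(5L, 1000)
  st3$count_B <- rep(5L, 1000)
  st3$imr_B <- rep(1000, 1000)
  tau3 <- update_probability(st3, arms_with("A"), ranks_with(1000))
  expect_equal(tau3[1], 1.0)

  expect_error(update_probability(init_states(10), rep("A", 10), 1:10),
               "update_imr")
})

test_that("mirror update for arm B complements the arm-A form", {
  # fresh state, assigned B with rank r: tau_B = r/obs, so tau_A = 1 - r/obs
  obs <- 1000
  arms <- c("B", rep("A", obs - 1))
  st <- update_imr(init_states(obs), arms, ranks_with(250))
  expect_equal(update_probability(st, arms, ranks_with(250))[1], 0.75)

  # literal printed branch instead gives tau_A = rank/obs
  lit <- rita_config(eq10_literal = TRUE)
  expect_equal(update_probability(st, arms, ranks_with(250), lit)[1], 0.25)
})

test_that("exploration clamp bounds both arms", {
  expect_equal(clamp_probability(1.2), 0.95)
  expect_equal(clamp_probability(0.01), 0.05)
  expect_equal(clamp_probability(0.6), 0.6)
  expect_equal(clamp_probability(c(-3, 2)), c(0.05, 0.95))
  # asymmetric bounds: tau_A is clamped so that tau_B also respects them
  cfg <- rita_config(lambda_l = 0.2, lambda_u = 0.9)
  expect_equal(clamp_probability(0.95, cfg), 0.8) # 1 - tau_A >= 0.2
  expect_equal(clamp_probability(0.05, cfg), 0.2)
})

test_that("reinforcement is monotone in the assignment count until clamped", {
  obs <- 1000
  tau_at_count <- function(r, imr_opp, k) {
    st <- init_states(obs)
    st$count_A <- rep(k, obs)
    st$imr_B <- rep(imr_opp, obs)
    update_probability(st, rep("A", obs), ranks_with(r))[1]
  }
  above <- vapply(1:6, function(k) tau_at_count(600, 500, k), 0.0)
  expect_true(all(diff(above) > 0)) # r > imr_opp: growing pull towards A
  below <- vapply(1:6, function(k) tau_at_count(400, 500, k), 0.0)
  expect_true(all(diff(below) < 0)) # r < imr_opp: shrinking
})

test_that("one step is invariant under relabelling the arms", {
  obs <- 50
  set.seed(9)
  dy <- stats::rnorm(obs)
  arms <- sample(c("A", "B"), obs, replace = TRUE)
  cfg <- rita_config()

  set.seed(1); s1 <- rita_step(init_states(obs), arms, dy, cfg)
  set.seed(1); s2 <- rita_step(init_states(obs), flip_arms(arms), dy, cfg)
  expect_equal(s2$tau_A, 1 - s1$tau_A)
  expect_equal(s2$imr_A, s1$imr_B)
  expect_equal(s2$count_B, s1$count_A)
  expect_equal(mirror_states(s1)$rank_sum_A, s2$rank_sum_A)
})

test_that("persistent top ranks drive tau to the upper clamp", {
  obs <- 100
  st <- init_states(obs)
  arms <- c("A", rep("B", obs - 1))
  for (k in 1:2) {
    dy <- c(10, stats::runif(obs - 1)) # individual 1 always ranks obs
    st <- rita_step(st, arms, dy)
  }
  expect_equal(st$tau_A[1], 0.95)
  expect_gt(st$tau_A_unclamped[1], 1) # (1) * (obs/imr_B)^1 >= 1
})

test_that("identical responses give a permutation-invariant tau set", {
  # all on one arm with tied responses: the random tie-break permutes who
  # gets which rank, but the multiset of updated probabilities is fixed
  obs <- 20
  set.seed(4)
  s1 <- rita_step(init_states(obs), rep("A", obs), rep(1, obs))
  s2 <- rita_step(init_states(obs), rep("A", obs), rep(1, obs))
  want <- clamp_probability(seq_len(obs) / obs)
  expect_equal(sort(s1$tau_A), want)
  expect_equal(sort(s2$tau_A), want)
  expect_false(identical(s1$tau_A, s2$tau_A)) # but assigned to different ids
})

test_that("full small-panel trajectories equal the brute-force oracle", {
  for (case in list(list(obs = 4, periods = 3, seed = 5, world = "world2"),
                    list(obs = 6, periods = 3, seed = 8, world = "world4"))) {
    tr <- simulate_policy(case$world, policy_rita(keep_state = TRUE),
                          obs = case$obs, periods = case$periods,
                          seed = case$seed)
    pop <- tr$population
    noise <- with(case, {
      n <- rita::substream_seed(seed, "noise")
      set.seed(n)
      matrix(stats::rnorm(obs * periods, 0, 0.1), obs, periods)
    })
    orc <- oracle_rita_run(pop, noise, case$seed)
    got <- tr$state_dump
    for (col in c("arm", "delta_y", "rank", "imr_A", "imr_B",
                  "count_A", "count_B", "tau_A")) {
      expect_equal(got[[col]], orc[[col]], tolerance = 1e-12,
                   label = sprintf("%s obs=%d col %s",
                                   case$world, case$obs, col))
    }
  }
})
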
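# Minimal hand-built trajectory for arithmetic checks.
toy_trajectory <- function(dy, y0 = rep(10, nrow(dy)),
                           arms = matrix("A", nrow(dy), ncol(dy))) {
  obs <- nrow(dy)
  y <- y0 + t(apply(dy, 1, cumsum))
  if (ncol(dy) == 1) y <- matrix(y, ncol = 1)
  pop <- data.frame(id = seq_len(obs), G = rep(0L, obs),
                    e_LA = 0, e_LB = 0,
                    effect_A = rep(1, obs), effect_B = rep(0, obs), y0 = y0)
  structure(list(population = pop, obs = obs, periods = ncol(dy),
                 arms = arms, y_mat = y, gain = y[, ncol(dy)] - y0,
                 final_y = y[, ncol(dy)], seed = 0, world_id = "toy",
                 policy_name = "toy"),
            class = "rita_trajectory")
}

test_that("assignment proportions count the assigned arm per period", {
  tr <- simulate_policy("world1", "baseline", obs = 1000, periods = 3,
                        seed = 2)
  expect_equal(assignment_proportion(tr, "A", 2), 1) # deterministic from t=2
  expect_equal(assignment_proportion(tr, "A", 3), 1)
  p1 <- assignment_proportion(tr, "A", 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 1000))
  expect_equal(assignment_proportion(tr, "B", 2), 0)
  expect_equal(assignment_proportions(tr, "A")[2:3], c(1, 1))
  expect_error(assignment_proportion(tr, "A", 4))
})

test_that("average cumulative gain is the mean of y_t - y0", {
  tr <- toy_trajectory(matrix(1, 2, 3)) # two individuals, dy = (1,1,1) each
  expect_equal(average_cumulative_gain(tr, 0), 0)
  expect_equal(average_cumulative_gain(tr, 3), 3)

  # world-1 baseline expectation at T = 60: 0.7 + 59 * 0.8 = 47.9
  full <- simulate_policy("world1", "baseline", obs = 1000, periods = 60,
                          seed = 14)
  expect_lt(abs(average_cumulative_gain(full) - 47.9), 0.12)
})

test_that("gain differences are paired and guard against mixed populations", {
  cmp <- run_comparison("world1", list("baseline", "rita"), obs = 20,
                        periods = 4, seed = 3)
  expect_equal(gain_difference(cmp$rita, cmp$rita), rep(0, 20))

  other <- simulate_policy("world1", "rita", obs = 20, periods = 4, seed = 99)
  expect_error(gain_difference(cmp$rita, other), "same population")

  # hand computation on a 2-individual panel
  ta <- toy_trajectory(matrix(c(1, 2, 3, 4), 2, 2))
  tb <- toy_trajectory(matrix(c(0, 1, 1, 1), 2, 2))
  expect_equal(gain_difference(ta, tb), c(3, 4))
})

test_that("subgroup medians split by ground-truth optimal arm", {
  pop <- data.frame(effect_A = c(1, 1, 1), effect_B = c(0, 0, 0))
  m <- subgroup_medians(c(1, 2, 3), pop)
  expect_equal(m$median_A_optimal, 2)
  expect_equal(m$n_B_optimal, 0)
  expect_true(is.na(m$median_B_optimal))

  pop2 <- data.frame(effect_A = c(1, 0), effect_B = c(0, 1))
  m2 <- subgroup_medians(c(-4, 4), pop2)
  expect_equal(m2$median_A_optimal, -4)
  expect_equal(m2$median_B_optimal, 4)
  expect_equal(m2$n_A_optimal + m2$n_B_optimal, 2)
  expect_equal(m2$median_overall, 0) # midpoint convention
})

test_that("final-outcome rank ordering sorts ascending with id tie-break", {
  tr <- toy_trajectory(matrix(c(5, 2, 9), 3, 1))
  expect_equal(rita_rank_order(tr), c(2L, 1L, 3L))
  tied <- toy_trajectory(matrix(c(1, 1, 1), 3, 1))
  expect_equal(rita_rank_order(tied), 1:3)

  set.seed(8)
  rnd <- toy_trajectory(matrix(stats::rnorm(15), 5, 3))
  expect_equal(rnd$final_y[match(rita_rank_order(rnd), rnd$population$id)],
               sort(rnd$final_y)) # independent sort oracle
})

test_that("exploration can only cost in the homogeneous world", {
  meds <- vapply(1:4, function(s) {
    cmp <- run_comparison("world1", list("baseline", "rita"), obs = 300,
                          periods = 30, seed = s)
    stats::median(gain_difference(cmp$rita, cmp$baseline))
  }, 0.0)
  expect_true(all(meds <= 0))
})

test_that("comparison summaries aggregate the paired metrics consistently", {
  cmp <- run_comparison("world4", list("baseline", "rita"), obs = 100,
                        periods = 10, seed = 12)
  sm <- comparison_summary(cmp)
  d <- gain_difference(cmp$rita, cmp$baseline)
  expect_equal(sm$mean_gain_diff, mean(d))
  expect_equal(sm$median_overall, stats::median(d))
  expect_equal(sm$n_A_optimal + sm$n_B_optimal, 100)
  df <- as.data.frame(sm)
  expect_equal(nrow(df), 1)
  expect_equal(df$mean_gain_diff, mean(d))

  rep <- replicate_comparison("world4", seeds = 1:2, obs = 100, periods = 10)
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$baseline_arm %in% c("A", "B")))
  expect_equal(rep$median_fav,
               ifelse(rep$baseline_arm == "B", rep$median_B_optimal,
                      rep$median_A_optimal))
})

test_that("plot builders return ggplot objects", {
  cmp <- run_comparison("world2", list("baseline", "rita"), obs = 40,
                        periods = 5, seed = 1)
  expect_s3_class(plot_assignment_proportions(cmp), "ggplot")
  expect_s3_class(plot_average_gains(cmp), "ggplot")
  expect_s3_class(plot_ranked_gains(cmp, bin = 5), "ggplot")
})
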
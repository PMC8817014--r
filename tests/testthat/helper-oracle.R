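# Independent brute-force transcription of the RITA update equations,
# written with explicit per-individual scalar loops and no shared code with
# the package's vectorized implementation. Used to verify full state
# trajectories on small panels.
#
# Population and noise are inputs (generated with the package's generators);
# the algorithm itself is re-derived here from the per-period steps:
#   tau_A  assignment probability, initialized 1/2
#   IMR_Z  mean pooled rank over periods assigned to Z, initialized obs/2
#   assigned A: tau_A' = (rank/obs) * (rank/IMR_B)^(nA - 1)
#   assigned B: tau_B' = (rank/obs) * (rank/IMR_A)^(nB - 1), tau_A' = 1 - tau_B'
#   clamp tau_A' into [lambda_l, lambda_u]
oracle_rita_run <- function(pop, noise, seed, lambda_l = 0.05,
                            lambda_u = 0.95) {
  obs <- nrow(pop)
  periods <- ncol(noise)
  tau <- rep(0.5, obs)
  imr_A <- rep(obs / 2, obs)
  imr_B <- rep(obs / 2, obs)
  n_A <- integer(obs)
  n_B <- integer(obs)
  ranks_A <- vector("list", obs) # per-individual rank history per arm
  ranks_B <- vector("list", obs)
  y <- pop$y0

  hist <- list()
  for (t in seq_len(periods)) {
    set.seed(substream_seed(seed, sprintf("policy/rita/%d", t)))
    u <- stats::runif(obs)
    arms <- character(obs)
    dy <- numeric(obs)
    for (i in seq_len(obs)) {
      arms[i] <- if (u[i] < tau[i]) "A" else "B"
      dy[i] <- if (arms[i] == "A") pop$effect_A[i] else pop$effect_B[i]
      dy[i] <- dy[i] + noise[i, t]
    }
    y <- y + dy
    # pooled rank: 1 = smallest response, obs = largest (responses are
    # continuous, so ties have probability zero)
    r <- integer(obs)
    r[order(dy)] <- seq_len(obs)

    for (i in seq_len(obs)) {
      if (arms[i] == "A") {
        ranks_A[[i]] <- c(ranks_A[[i]], r[i])
        n_A[i] <- n_A[i] + 1L
        imr_A[i] <- sum(ranks_A[[i]]) / n_A[i]
        tau_raw <- (r[i] / obs) * (r[i] / imr_B[i])^(n_A[i] - 1)
      } else {
        ranks_B[[i]] <- c(ranks_B[[i]], r[i])
        n_B[i] <- n_B[i] + 1L
        imr_B[i] <- sum(ranks_B[[i]]) / n_B[i]
        tau_B_raw <- (r[i] / obs) * (r[i] / imr_A[i])^(n_B[i] - 1)
        tau_raw <- 1 - tau_B_raw
      }
      tau[i] <- min(max(tau_raw, lambda_l), lambda_u)
    }
    hist[[t]] <- data.frame(period = t, id = pop$id, arm = arms,
                            delta_y = dy, rank = r, imr_A = imr_A,
                            imr_B = imr_B, count_A = n_A, count_B = n_B,
                            tau_A = tau, y = y)
  }
  do.call(rbind, hist)
}

# Mirror a state frame under the arm relabelling A <-> B.
mirror_states <- function(st) {
  sw <- st
  sw$tau_A <- 1 - st$tau_A
  sw$tau_A_unclamped <- 1 - st$tau_A_unclamped
  sw$imr_A <- st$imr_B
  sw$imr_B <- st$imr_A
  sw$count_A <- st$count_B
  sw$count_B <- st$count_A
  sw$rank_sum_A <- st$rank_sum_B
  sw$rank_sum_B <- st$rank_sum_A
  sw
}

flip_arms <- function(arms) ifelse(arms == "A", "B", "A")
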
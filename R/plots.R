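#' Plot assignment proportions over time
#'
#' One line per policy: the fraction of the population assigned to `arm` in
#' each period.
#'
#' @param cmp A [run_comparison()] result.
#' @param arm Arm whose proportion is shown (default `"A"`).
#' @return A ggplot object.
#' @export
plot_assignment_proportions <- function(cmp, arm = "A") {
  df <- do.call(rbind, lapply(names(cmp), function(p) {
    data.frame(policy = p,
               period = seq_len(cmp[[p]]$periods),
               prop = assignment_proportions(cmp[[p]], arm))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$prop,
                                   colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Period", y = sprintf("Proportion assigned to %s", arm),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot average cumulative outcome gains over time
#'
#' @param cmp A [run_comparison()] result.
#' @return A ggplot object.
#' @export
plot_average_gains <- function(cmp) {
  df <- do.call(rbind, lapply(names(cmp), function(p) {
    tr <- cmp[[p]]
    data.frame(policy = p,
               period = seq_len(tr$periods),
               gain = vapply(seq_len(tr$periods),
                             function(t) average_cumulative_gain(tr, t), 0.0))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$gain,
                                   colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Period", y = "Average cumulative gain", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-individual cumulative gains ordered by final-outcome rank
#'
#' Individuals are ordered by their final cumulative outcome under `policy`
#' (the "RITA rank" when that policy is RITA), binned, and each policy's
#' mean within-bin cumulative gain is drawn. Bin width is cosmetic only.
#'
#' @param cmp A [run_comparison()] result.
#' @param policy Policy whose final outcomes define the ordering.
#' @param bin Number of individuals per bin (default 10).
#' @return A ggplot object.
#' @export
plot_ranked_gains <- function(cmp, policy = "rita", bin = 10) {
  ord <- rita_rank_order(cmp[[policy]])
  idx <- match(ord, cmp[[policy]]$population$id)
  n <- length(idx)
  bins <- ceiling(seq_len(n) / bin)
  df <- do.call(rbind, lapply(names(cmp), function(p) {
    g <- cmp[[p]]$gain[idx]
    data.frame(policy = p,
               bin = unique(bins) * bin,
               gain = as.numeric(tapply(g, bins, mean)))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$gain,
                                   colour = .data$policy)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("Rank under '%s' (binned)", policy),
                  y = "Cumulative gain", colour = NULL) +
    ggplot2::theme_minimal()
}
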
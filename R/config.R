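#' Assemble a run configuration
#'
#' The full recipe for one reproducible run: world, sizes, policies, policy
#' tunables, noise, and master seed. Defaults reproduce the benchmark setup
#' (obs = 1000, 60 periods, noise sd 0.1, exploration bounds 0.05/0.95,
#' baseline-vs-RITA comparison).
#'
#' @param world Preset name (`"world1"`..`"world4"`) or a [world_spec()].
#' @param obs Population size.
#' @param periods Number of periods.
#' @param policies Character vector of policy names (`"baseline"`, `"rita"`,
#'   `"moderator"`).
#' @param noise_sd Outcome-noise SD.
#' @param seed Master seed.
#' @param lambda_l,lambda_u RITA exploration bounds.
#' @param tie_rule,eq10_literal Passed to [rita_config()].
#' @param keep_state Retain RITA's per-period state dump (off by default;
#'   at obs x periods above 1e5 records the dump is sizeable).
#' @param out_dir Output directory for [run_bundle()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(world = "world4", obs = 1000, periods = 60,
                       policies = c("baseline", "rita"), noise_sd = 0.1,
                       seed = 1, lambda_l = 0.05, lambda_u = 0.95,
                       tie_rule = "random", eq10_literal = FALSE,
                       keep_state = obs * periods <= 1e5,
                       out_dir = "rita-run") {
  structure(list(
    world = if (inherits(world, "world_spec")) world$world_id else world,
    world_spec = if (inherits(world, "world_spec")) unclass(world) else NULL,
    obs = as.integer(obs), periods = as.integer(periods),
    policies = policies, noise_sd = noise_sd, seed = as.integer(seed),
    lambda_l = lambda_l, lambda_u = lambda_u, tie_rule = tie_rule,
    eq10_literal = eq10_literal, keep_state = keep_state,
    out_dir = out_dir
  ), class = "run_config")
}

#' Read / write run configurations as YAML
#'
#' Round-trips losslessly: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  known <- names(cfg)
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(raw)] <- raw
  cfg$obs <- as.integer(cfg$obs)
  cfg$periods <- as.integer(cfg$periods)
  cfg$seed <- as.integer(cfg$seed)
  cfg$policies <- as.character(unlist(cfg$policies))
  cfg
}

resolve_world <- function(cfg) {
  if (!is.null(cfg$world_spec)) {
    world_spec_from_list(c(list(world = "custom"), cfg$world_spec))
  } else {
    if (!cfg$world %in% paste0("world", 1:4)) {
      stop("unknown world: '", cfg$world, "'", call. = FALSE)
    }
    world_spec(cfg$world)
  }
}

#' Execute a run configuration and write an artifact bundle
#'
#' Runs all configured policies on the configured world with common random
#' numbers, then writes to `cfg$out_dir`: each policy's trajectory
#' (`trajectory_<policy>.tsv` + YAML sidecar), the population
#' (`population.tsv`), RITA's per-period state dump when retained
#' (`states_rita.tsv`), a one-row comparison summary (`summary.tsv`, when
#' both `"rita"` and `"baseline"` ran), figures (`assignment.png`,
#' `gains.png`, `ranked_gains.png`), and the resolved configuration
#' (`manifest.yaml`) from which the bundle can be regenerated bit-for-bit.
#'
#' @param cfg A [run_config()] (or path to a YAML config).
#' @return The comparison object, invisibly; side effect: files under
#'   `cfg$out_dir`.
#' @export
run_bundle <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  world <- resolve_world(cfg)
  rcfg <- rita_config(cfg$lambda_l, cfg$lambda_u, cfg$tie_rule,
                      cfg$eq10_literal)
  policies <- lapply(cfg$policies, as_policy, rita_cfg = rcfg)

  cmp <- run_comparison(world, policies, obs = cfg$obs,
                        periods = cfg$periods, seed = cfg$seed,
                        noise_sd = cfg$noise_sd, keep_state = cfg$keep_state)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_population(attr(cmp, "population"), out("population.tsv"))
  for (p in names(cmp)) {
    write_trajectory(cmp[[p]], out(sprintf("trajectory_%s.tsv", p)))
    if (!is.null(cmp[[p]]$state_dump)) {
      utils::write.table(cmp[[p]]$state_dump,
                         out(sprintf("states_%s.tsv", p)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (all(c("rita", "baseline") %in% names(cmp))) {
    sm <- comparison_summary(cmp)
    utils::write.table(as.data.frame(sm), out("summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  save_plot <- function(plot, f) {
    grDevices::png(out(f), width = 900, height = 600, res = 120)
    print(plot)
    grDevices::dev.off()
  }
  save_plot(plot_assignment_proportions(cmp), "assignment.png")
  save_plot(plot_average_gains(cmp), "gains.png")
  if ("rita" %in% names(cmp)) {
    save_plot(plot_ranked_gains(cmp), "ranked_gains.png")
  }
  write_run_config(cfg, out("manifest.yaml"))
  invisible(cmp)
}

#' Replicate the benchmark comparison across worlds and seeds
#'
#' For each world and each master seed, runs the paired baseline-vs-RITA
#' comparison at the benchmark settings and returns the per-seed summary
#' rows plus across-seed aggregates (mean, SD, and 2.5%/97.5% replication
#' quantiles of each headline metric).
#'
#' @param seeds Integer vector of master seeds (a single seed flags the
#'   aggregates as single-replication).
#' @param worlds Character vector of world presets.
#' @param obs,periods,noise_sd Benchmark settings.
#' @param rita_cfg A [rita_config()].
#' @return A list of class `replication_report`: `per_seed` (data frame) and
#'   `aggregate` (data frame, one row per world x metric).
#' @export
replication_report <- function(seeds, worlds = paste0("world", 1:4),
                               obs = 1000, periods = 60, noise_sd = 0.1,
                               rita_cfg = rita_config()) {
  per_seed <- do.call(rbind, lapply(worlds, function(w) {
    replicate_comparison(w, seeds, obs = obs, periods = periods,
                         noise_sd = noise_sd, rita_cfg = rita_cfg)
  }))
  metrics <- c("mean_gain_diff", "sd_gain_diff", "median_overall",
               "median_A_optimal", "median_B_optimal",
               "median_fav", "median_other",
               "optimal_fraction_policy", "optimal_fraction_reference")
  aggregate <- do.call(rbind, lapply(split(per_seed, per_seed$world),
    function(df) {
      do.call(rbind, lapply(metrics, function(m) {
        v <- df[[m]] # subgroup medians can be NA when a subgroup is empty
        data.frame(world = df$world[1], metric = m,
                   mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
                   q025 = if (all(is.na(v))) NA_real_ else
                     unname(stats::quantile(v, 0.025, na.rm = TRUE)),
                   q975 = if (all(is.na(v))) NA_real_ else
                     unname(stats::quantile(v, 0.975, na.rm = TRUE)),
                   n_seeds = length(v))
      }))
    }))
  rownames(aggregate) <- NULL
  structure(list(per_seed = per_seed, aggregate = aggregate,
                 single_replication = length(seeds) == 1L),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication report: %d seed(s)%s>\n",
              length(unique(x$per_seed$seed)),
              if (x$single_replication) " [single replication]" else ""))
  print(x$aggregate, digits = 3)
  invisible(x)
}
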
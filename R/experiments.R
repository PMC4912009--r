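# Replicated experiment designs: profiling replicates with distinct seeds,
# Boltzmann-constant (K) scaling sweeps, and the initial-temperature
# benchmark with a fixed proposal budget under geometric cooling.

.result_row <- function(experiment, alignment, replicate, arm, trace,
                        report, profile) {
  tc <- cmax <- npk <- NA_real_
  if (!is.null(report)) {
    npk <- report$n_peaks
    if (report$n_peaks >= 1L) {
      tc <- report$peaks$temperature[1]
      cmax <- report$peaks$C[1]
    }
  }
  data.frame(experiment = experiment, alignment = alignment,
             replicate = replicate, arm = as.character(arm),
             T_c = tc, C_max = cmax, n_peaks = npk,
             best_length = if (is.null(trace)) NA_real_ else trace$best_length,
             best_hi = if (is.null(trace)) NA_real_ else trace$best_hi,
             proposed = if (is.null(trace)) NA_real_ else trace$total_proposed,
             termination = if (is.null(trace)) "error" else trace$termination,
             stringsAsFactors = FALSE)
}

#' Replicated annealing runs with distinct seeds
#'
#' Runs `n_replicates` independent annealing searches (seeds
#' `base_seed + 1, ..., base_seed + n_replicates`, all distinct), computes
#' each run's specific-heat profile and peak report, and collects one
#' long-format result row per run. A failing replicate is recorded with
#' `termination = "error"` rather than aborting the batch.
#'
#' @param ctx scoring context.
#' @param cfg an [sa_config()]; its `seed` field is overridden per
#'   replicate.
#' @param n_replicates number of runs (default 20).
#' @param base_seed integer base seed.
#' @param experiment,arm labels written into the result rows.
#' @param keep_traces,keep_profiles retain the per-run traces / profiles
#'   and peak reports (memory permitting).
#' @param smooth_window,prominence_frac passed to [detect_peaks()].
#' @return A list of class `"sa_experiment"`: `table` (result rows),
#'   `reports`, and optionally `traces` and `profiles`.
#' @export
run_replicates <- function(ctx, cfg, n_replicates = 20L, base_seed = 1L,
                           experiment = "replicates", arm = "1",
                           keep_traces = FALSE, keep_profiles = FALSE,
                           smooth_window = 5L, prominence_frac = 0.25) {
  rows <- vector("list", n_replicates)
  traces <- if (keep_traces) vector("list", n_replicates) else NULL
  profiles <- if (keep_profiles) vector("list", n_replicates) else NULL
  reports <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed) + r
    row <- tryCatch({
      tr <- anneal(ctx, cfg_r)
      pr <- heat_profile(tr)
      rep_r <- detect_peaks(pr, smooth_window, prominence_frac)
      reports[[r]] <- rep_r
      if (keep_traces) traces[[r]] <- tr
      if (keep_profiles) profiles[[r]] <- pr
      .result_row(experiment, ctx$id, r, arm, tr, rep_r, pr)
    }, error = function(e) {
      .result_row(experiment, ctx$id, r, arm, NULL, NULL, NULL)
    })
    rows[[r]] <- row
  }
  structure(list(table = do.call(rbind, rows), reports = reports,
                 traces = traces, profiles = profiles),
            class = "sa_experiment")
}

#' @export
print.sa_experiment <- function(x, ...) {
  cat(sprintf("Annealing experiment: %d run(s)\n", nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Boltzmann-constant scaling sweep
#'
#' Repeats the replicate design with the effective Boltzmann constant set
#' to `factor * K` for each factor, scaling the initial temperature, the
#' decrement and the floor by the same factor so the peak stays on the
#' sampled temperature range. Seeds are shared across factor arms, so a
#' factor-1 arm reproduces [run_replicates()] exactly, and (by the
#' invariance of the acceptance rule under joint scaling of K and T)
#' corresponding runs at factors related by exact powers of two make
#' identical acceptance decisions.
#'
#' @param ctx scoring context (its own `c` is ignored; each arm sets it).
#' @param cfg base [sa_config()] whose schedule is scaled per arm.
#' @param factors positive multipliers of K (default the study values
#'   0.1, 0.5, 2, 10).
#' @param n_replicates replicates per factor (default 20).
#' @param base_seed shared base seed.
#' @param ... passed to [run_replicates()].
#' @return An `"sa_experiment"` whose table has one arm per factor, plus a
#'   `summary` data.frame of per-arm mean critical temperature and peak
#'   magnitude.
#' @export
k_scaling_experiment <- function(ctx, cfg, factors = c(0.1, 0.5, 2, 10),
                                 n_replicates = 20L, base_seed = 1L, ...) {
  stopifnot(all(factors > 0))
  parts <- vector("list", length(factors))
  reports <- list()
  for (i in seq_along(factors)) {
    f <- factors[i]
    ctx_f <- set_boltzmann(ctx, f)
    cfg_f <- cfg
    cfg_f$schedule$t0 <- cfg$schedule$t0 * f
    cfg_f$schedule$m <- cfg$schedule$m * f
    cfg_f$schedule$t_floor <- cfg$schedule$t_floor * f
    ex <- run_replicates(ctx_f, cfg_f, n_replicates, base_seed,
                         experiment = "k_scaling", arm = format(f), ...)
    parts[[i]] <- ex$table
    reports[[format(f)]] <- ex$reports
  }
  tab <- do.call(rbind, parts)
  summ <- do.call(rbind, lapply(split(tab, tab$arm), function(d)
    data.frame(arm = d$arm[1], factor = as.numeric(d$arm[1]),
               mean_T_c = mean(d$T_c, na.rm = TRUE),
               mean_C_max = mean(d$C_max, na.rm = TRUE),
               stringsAsFactors = FALSE)))
  summ <- summ[order(summ$factor), ]
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, reports = reports,
                 traces = NULL, profiles = NULL),
            class = "sa_experiment")
}

#' Initial-temperature benchmark under a fixed move budget
#'
#' Compares three starting temperatures `T1 < T2 < T3` with `T2` the
#' critical temperature (estimated beforehand from a profiling batch) and
#' `T3 = 2 T2 - T1`, under geometric cooling with an identical total
#' proposal budget in every arm. When no budget is supplied it is estimated
#' as the mean number of proposals of `n_prelim` preliminary runs started
#' from `T3` that terminate by freezing or the floor, mirroring how the
#' budget is calibrated in practice.
#'
#' @param ctx scoring context.
#' @param t2 critical temperature (see [critical_temperature()]).
#' @param t1 low starting temperature (default `1e-4`).
#' @param budget total proposals per run; estimated when `NULL`.
#' @param alpha geometric cooling ratio (default 0.99).
#' @param n,l,freeze_window run parameters as in [sa_config()].
#' @param n_replicates runs per arm (default 20).
#' @param n_prelim preliminary runs for budget estimation (default 20).
#' @param base_seed base seed; arms use disjoint seed blocks.
#' @return An `"sa_experiment"` with arms `"T1"`, `"T2"`, `"T3"`, the `t0`
#'   of each run in column `t0`, and the estimated `budget` attached.
#' @export
benchmark_initial_temperatures <- function(ctx, t2, t1 = 1e-4, budget = NULL,
                                           alpha = 0.99, n = 2000L, l = 10L,
                                           freeze_window = 50L,
                                           n_replicates = 20L,
                                           n_prelim = 20L, base_seed = 1L) {
  stopifnot(t1 > 0, t2 > t1)
  t3 <- 2 * t2 - t1
  floor_t <- t1 / 1000
  if (is.null(budget)) {
    used <- numeric(n_prelim)
    for (r in seq_len(n_prelim)) {
      cfg_p <- sa_config(sa_schedule("geometric", t0 = t3, alpha = alpha,
                                     t_floor = floor_t),
                         n = n, l = l, freeze_window = freeze_window,
                         seed = as.integer(base_seed) + 9000L + r)
      used[r] <- anneal(ctx, cfg_p)$total_proposed
    }
    budget <- round(mean(used))
  }
  # flag a budget that cannot carry the T3 arm out of its high-temperature
  # phase (final temperature would still exceed t2)
  if (t3 * alpha^(budget / n) > t2)
    warning("move budget too small for the T3 arm to cool below T2")
  # the benchmark arms terminate on the shared budget alone: freezing is
  # disabled and the floor sits far below T1 so every arm consumes the same
  # number of proposals
  arms <- c(T1 = t1, T2 = t2, T3 = t3)
  parts <- vector("list", 3L)
  for (i in seq_along(arms)) {
    cfg_a <- sa_config(sa_schedule("geometric", t0 = arms[i], alpha = alpha,
                                   t_floor = t1 * 1e-9),
                       n = n, l = l, freeze_window = 1000000000L,
                       total_move_budget = budget)
    ex <- run_replicates(ctx, cfg_a, n_replicates,
                         base_seed = as.integer(base_seed) + (i - 1L) * n_replicates,
                         experiment = "benchmark", arm = names(arms)[i])
    ex$table$t0 <- unname(arms[i])
    parts[[i]] <- ex$table
  }
  tab <- do.call(rbind, parts)
  structure(list(table = tab, budget = budget,
                 temperatures = c(arms, use.names = TRUE),
                 reports = NULL, traces = NULL, profiles = NULL),
            class = "sa_experiment")
}
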
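# The canonical simulated annealing engine: Metropolis acceptance on the
# homoplasy index, n moves per temperature for equilibration, linear or
# geometric cooling, freezing after a window of unimproved temperature
# decrements, and per-temperature trace recording. There is deliberately no
# final hill-climbing refinement and no archive of equally parsimonious
# trees: the engine is the canonical form of the algorithm.

#' Define a cooling schedule
#'
#' Linear schedules decrease the temperature by a constant `m` each block
#' and stop below `t_floor` (default `m`). Geometric schedules multiply by
#' `alpha` each block and stop below `t_floor` (default `t0/1000`). A
#' constant schedule holds `t0` forever and requires a move budget to
#' terminate.
#'
#' @param kind `"linear"`, `"geometric"` or `"constant"`.
#' @param t0 initial temperature (> 0).
#' @param m linear decrement (> 0; default `1e-7`).
#' @param alpha geometric ratio in (0, 1) (default 0.99).
#' @param t_floor stopping temperature.
#' @return An object of class `"sa_schedule"`.
#' @export
sa_schedule <- function(kind = c("linear", "geometric", "constant"), t0,
                        m = 1e-7, alpha = 0.99, t_floor = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t0), t0 > 0)
  if (kind == "linear") {
    stopifnot(is.numeric(m), m > 0)
    t_floor <- t_floor %||% m
  } else if (kind == "geometric") {
    stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
    t_floor <- t_floor %||% (t0 / 1000)
  } else {
    t_floor <- 0
  }
  structure(list(kind = kind, t0 = t0, m = m, alpha = alpha,
                 t_floor = t_floor),
            class = "sa_schedule")
}

#' Configure an annealing run
#'
#' @param schedule an [sa_schedule()].
#' @param n moves attempted per temperature before the decrement
#'   (default 2000).
#' @param l HI-sampling interval in moves (default 10); must divide `n`.
#' @param l_tree topology-sampling interval in moves (default 100); must
#'   divide `n`. Topologies are only recorded at the designated temperatures
#'   (see `tree_sample_levels`).
#' @param freeze_window number of consecutive temperature decrements without
#'   a new best HI that terminates the run (default 50).
#' @param total_move_budget optional cap on the total number of proposals.
#' @param seed RNG seed applied at the start of the run (optional; the
#'   caller may manage the RNG instead).
#' @param tree_sample_levels if > 0, topologies are sampled at this many
#'   linearly spaced temperatures between `t0` and the schedule floor, fixed
#'   before the run starts (default 0 = no topology sampling).
#' @param nni_only propose only NNI moves (a switch used for Metropolis
#'   sanity checks with a symmetric kernel); the production default is
#'   strict NNI/SPR alternation.
#' @param record_decisions keep the per-proposal acceptance decision
#'   sequence in the trace.
#' @return An object of class `"sa_config"`.
#' @export
sa_config <- function(schedule, n = 2000L, l = 10L, l_tree = 100L,
                      freeze_window = 50L, total_move_budget = NULL,
                      seed = NULL, tree_sample_levels = 0L, nni_only = FALSE,
                      record_decisions = FALSE) {
  stopifnot(inherits(schedule, "sa_schedule"))
  n <- as.integer(n); l <- as.integer(l); l_tree <- as.integer(l_tree)
  freeze_window <- as.integer(freeze_window)
  if (n < 1L || l < 1L || freeze_window < 1L)
    amp_stop("n, l and freeze_window must be positive", "config_error")
  if (n %% l != 0L)
    amp_stop("l must divide n", "config_error")
  if (n %% l_tree != 0L)
    amp_stop("l_tree must divide n", "config_error")
  if (schedule$kind == "constant" && is.null(total_move_budget))
    amp_stop("a constant schedule requires total_move_budget", "config_error")
  structure(list(schedule = schedule, n = n, l = l, l_tree = l_tree,
                 freeze_window = freeze_window,
                 total_move_budget = total_move_budget,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 tree_sample_levels = as.integer(tree_sample_levels),
                 nni_only = isTRUE(nni_only),
                 record_decisions = isTRUE(record_decisions)),
            class = "sa_config")
}

#' Metropolis acceptance probability on the homoplasy index
#'
#' `min(1, exp(-delta_hi / temperature))` for positive temperatures; at
#' `temperature = 0` the rule degenerates to a step function (1 for strictly
#' downhill, 0 otherwise). With HI as cost, `delta_hi = c K (1/L_current -
#' 1/L_candidate)`, so the data minimum K plays the role of the Boltzmann
#' constant.
#'
#' @param delta_hi signed cost change (vectorised).
#' @param temperature a single temperature >= 0.
#' @return Probabilities in `[0, 1]`.
#' @export
acceptance_probability <- function(delta_hi, temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature >= 0)
  if (temperature == 0) return(as.numeric(delta_hi < 0))
  pmin(1, exp(-delta_hi / temperature))
}

# Blocks at which topologies are sampled: the blocks whose temperatures are
# nearest to n_levels linearly spaced values between t0 and the schedule
# floor, fixed prospectively (before the run).
tree_sample_blocks <- function(schedule, n_levels) {
  if (n_levels <= 0L) return(integer(0))
  temps <- seq(schedule$t0, schedule$t_floor, length.out = n_levels)
  blocks <- switch(schedule$kind,
    linear = round((schedule$t0 - temps) / schedule$m) + 1,
    geometric = round(log(pmax(temps, schedule$t_floor) / schedule$t0) /
                        log(schedule$alpha)) + 1,
    constant = seq_len(n_levels))
  sort(unique(as.integer(pmax(1, blocks))))
}

#' Run a simulated annealing search
#'
#' At each temperature, `cfg$n` candidate topologies are proposed by strict
#' NNI/SPR alternation (starting with NNI), accepted or rejected by
#' [acceptance_probability()] on the change in homoplasy index, and the
#' working HI is recorded every `cfg$l` moves. The temperature then
#' decreases per the schedule. The run terminates when the schedule reaches
#' its floor, when `freeze_window` consecutive decrements bring no new best
#' HI (frozen), or when the move budget is exhausted.
#'
#' @param ctx a [build_context()] scoring context.
#' @param cfg an [sa_config()].
#' @param start optional starting [topology()]; by default a random topology
#'   is drawn (after seeding, so the whole run is reproducible from
#'   `cfg$seed`).
#' @return An object of class `"sa_trace"`: per-block summaries (`blocks`),
#'   the HI samples in long form (`hi`), optional topology samples
#'   (`tree_samples`), the initial/final/best topologies and scores, the
#'   acceptance-decision sequence when requested, and the termination
#'   reason (`"floor"`, `"frozen"` or `"budget"`).
#' @examples
#' sim <- evolve_alignment(8, 100, p = 0.05, seed = 1)
#' ctx <- build_context(sim$alignment)
#' cfg <- sa_config(sa_schedule("linear", t0 = 2e-3, m = 1e-4), n = 200,
#'                  l = 10, freeze_window = 10, seed = 1)
#' tr <- anneal(ctx, cfg)
#' tr$best_length
#' @export
anneal <- function(ctx, cfg, start = NULL) {
  stopifnot(inherits(ctx, "scoring_context"), inherits(cfg, "sa_config"))
  if (ctx$n_taxa < 4L)
    amp_stop("annealing needs at least 4 taxa", "config_error")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(start)) start <- random_topology(ctx$n_taxa)
  stopifnot(inherits(start, "topology"))
  if (start$n_taxa != ctx$n_taxa)
    amp_stop("starting topology does not match the alignment", "config_error")
  sch <- cfg$schedule
  kind_int <- match(sch$kind, c("linear", "geometric", "constant")) - 1L
  blocks_designated <- tree_sample_blocks(sch, cfg$tree_sample_levels)
  res <- cpp_anneal(start$edge, ctx$n_taxa, ctx$pat, ctx$weights, ctx$K_eff,
                    kind_int, sch$t0, sch$m, sch$alpha, sch$t_floor,
                    cfg$n, cfg$l, cfg$l_tree, cfg$freeze_window,
                    as.numeric(cfg$total_move_budget %||% -1),
                    blocks_designated, cfg$nni_only, cfg$record_decisions)
  nb <- length(res$block_T)
  blocks <- data.frame(block = seq_len(nb), temperature = res$block_T,
                       proposed = res$block_proposed,
                       accepted = res$block_accepted,
                       nni = res$block_nni, spr = res$block_spr,
                       n_samples = res$block_nsamples)
  hi <- data.frame(block = rep.int(seq_len(nb), res$block_nsamples),
                   sample_index = sequence(res$block_nsamples),
                   hi = res$hi)
  tree_samples <- NULL
  if (length(res$snap_block) > 0L) {
    tree_samples <- list(
      block = res$snap_block, move = res$snap_move,
      trees = lapply(res$snap_trees, topology, n_taxa = ctx$n_taxa,
                     validate = FALSE))
  }
  structure(list(
    alignment_id = ctx$id, config = cfg, n_taxa = ctx$n_taxa,
    initial = start, blocks = blocks, hi = hi, tree_samples = tree_samples,
    designated_blocks = blocks_designated,
    final = topology(res$final_edge, ctx$n_taxa, validate = FALSE),
    final_length = res$final_L, final_hi = res$final_HI,
    best = topology(res$best_edge, ctx$n_taxa, validate = FALSE),
    best_length = res$best_L, best_hi = res$best_HI,
    total_proposed = res$total_proposed, termination = res$termination,
    decisions = if (cfg$record_decisions) as.logical(res$decisions) else NULL),
    class = "sa_trace")
}

#' @export
print.sa_trace <- function(x, ...) {
  cat(sprintf(
    "Annealing trace '%s': %d temperature blocks, %g proposals, %s\n",
    x$alignment_id, nrow(x$blocks), x$total_proposed, x$termination))
  cat(sprintf("  best length %g (HI %.4g), final length %g\n",
              x$best_length, x$best_hi, x$final_length))
  invisible(x)
}

#' Mean acceptance probability as a function of temperature
#'
#' Monte-Carlo diagnostic: proposes moves from the given fixed topologies
#' (alternating NNI/SPR), records the HI changes once, and evaluates the
#' mean Metropolis acceptance probability at each requested temperature. By
#' construction the curve is non-decreasing in temperature.
#'
#' @param ctx scoring context.
#' @param topologies a [topology()] or list of topologies acting as fixed
#'   states.
#' @param temperatures numeric vector of temperatures (>= 0).
#' @param n_proposals proposals drawn per topology (default 200).
#' @return `data.frame` with columns `temperature` and `rate`.
#' @export
acceptance_rate_curve <- function(ctx, topologies, temperatures,
                                  n_proposals = 200L) {
  if (inherits(topologies, "topology")) topologies <- list(topologies)
  deltas <- numeric(0)
  for (t in topologies) {
    L0 <- fitch_length(t, ctx)
    h0 <- homoplasy_index(L0, ctx)
    for (i in seq_len(n_proposals)) {
      prop <- alternating_proposer(t, i - 1L)
      Lc <- fitch_length(prop$topology, ctx)
      deltas <- c(deltas, homoplasy_index(Lc, ctx) - h0)
    }
  }
  data.frame(temperature = temperatures,
             rate = vapply(temperatures,
                           function(T) mean(acceptance_probability(deltas, T)),
                           numeric(1)))
}
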
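# Plain-text serialisation of run artefacts: CSV for samples/profiles/
# series/result tables, JSON for configuration headers and peak reports,
# newick for sampled topologies.

#' Write an annealing trace to disk
#'
#' Produces `<prefix>_trace.csv` (block, temperature, sample_index, hi),
#' `<prefix>_run.json` (configuration, seed, termination, best scores) and,
#' when topologies were sampled, `<prefix>_trees.csv` with one newick string
#' per sampled topology.
#'
#' @param trace an [anneal()] trace.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default the alignment identifier).
#' @return Invisibly, the paths written.
#' @export
write_trace <- function(trace, dir, prefix = trace$alignment_id) {
  stopifnot(inherits(trace, "sa_trace"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p1 <- file.path(dir, paste0(prefix, "_trace.csv"))
  hi <- trace$hi
  hi$temperature <- trace$blocks$temperature[hi$block]
  write.csv(hi[, c("block", "temperature", "sample_index", "hi")], p1,
            row.names = FALSE)
  paths <- c(paths, p1)
  cfg <- trace$config
  hdr <- list(alignment = trace$alignment_id, n_taxa = trace$n_taxa,
              schedule = unclass(cfg$schedule),
              n = cfg$n, l = cfg$l, l_tree = cfg$l_tree,
              freeze_window = cfg$freeze_window, seed = cfg$seed,
              total_move_budget = cfg$total_move_budget,
              nni_only = cfg$nni_only,
              termination = trace$termination,
              total_proposed = trace$total_proposed,
              best_length = trace$best_length, best_hi = trace$best_hi,
              final_length = trace$final_length)
  p2 <- file.path(dir, paste0(prefix, "_run.json"))
  jsonlite::write_json(hdr, p2, auto_unbox = TRUE, null = "null", digits = NA)
  paths <- c(paths, p2)
  if (!is.null(trace$tree_samples)) {
    ts <- trace$tree_samples
    p3 <- file.path(dir, paste0(prefix, "_trees.csv"))
    write.csv(data.frame(block = ts$block, move = ts$move,
                         newick = vapply(ts$trees, write_newick,
                                         character(1))),
              p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Write a specific-heat profile as CSV
#' @param profile a [heat_profile()].
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "heat_profile"))
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a peak report as JSON
#' @param report a [detect_peaks()] report.
#' @param path output file.
#' @export
write_peaks <- function(report, path) {
  stopifnot(inherits(report, "peak_report"))
  jsonlite::write_json(list(classification = report$classification,
                            n_peaks = report$n_peaks,
                            smooth_window = report$smooth_window,
                            prominence_frac = report$prominence_frac,
                            peaks = report$peaks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a consensus series as CSV
#' @param series a [consensus_series()].
#' @param path output file.
#' @export
write_consensus_series <- function(series, path) {
  stopifnot(inherits(series, "consensus_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment result table as CSV
#' @param x an `"sa_experiment"` or its `table`.
#' @param path output file.
#' @export
write_result_table <- function(x, path) {
  tab <- if (inherits(x, "sa_experiment")) x$table else x
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
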
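# Temperature-stratified strict consensus trees: the strict consensus of
# the topologies sampled at a temperature shows how much structure is
# shared by the states the search visits there; its resolution rising as
# the temperature falls below the critical temperature is the signature of
# the search becoming trapped in one region of tree space.

#' Strict consensus of a set of topologies
#'
#' The consensus tree contains exactly the splits present in every input
#' tree (computed via `ape::consensus` with p = 1; split bookkeeping and
#' resolution use the package's canonical split representation).
#'
#' @param trees a list of [topology()] objects over the same leaf set.
#' @return An object of class `"consensus_tree"`: fields `n_taxa`, `splits`
#'   (named list of canonical splits), and `phylo` (multifurcating `ape`
#'   tree for display).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "topology")) trees <- list(trees)
  if (length(trees) == 0L)
    amp_stop("strict consensus of an empty tree list", "consensus_error")
  n <- trees[[1]]$n_taxa
  if (!all(vapply(trees, function(t) t$n_taxa, integer(1)) == n))
    amp_stop("trees have different leaf sets", "consensus_error")
  labels <- paste0("t", seq_len(n))
  splitsets <- lapply(trees, function(t) names(splits(t)))
  common <- Reduce(intersect, splitsets)
  phys <- lapply(trees, as_phylo, taxa = labels)
  cphy <- if (length(trees) == 1L) phys[[1]] else {
    class(phys) <- "multiPhylo"
    ape::consensus(phys, p = 1, rooted = FALSE)
  }
  keep <- splits(trees[[1]])[common]
  structure(list(n_taxa = n, splits = keep, phylo = cphy),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("Strict consensus: %d taxa, %d of %d splits (resolution %.2f)\n",
              x$n_taxa, length(x$splits), x$n_taxa - 3L, resolution(x)))
  invisible(x)
}

#' Resolution of a (consensus) tree
#'
#' Fraction of the n-3 possible internal splits that are present: 1 for a
#' fully binary tree, 0 for a star.
#'
#' @param ct a `consensus_tree` or a binary [topology()].
#' @return Fraction in `[0, 1]`.
#' @export
resolution <- function(ct) {
  if (inherits(ct, "topology")) return(1)
  stopifnot(inherits(ct, "consensus_tree"))
  if (ct$n_taxa < 4L)
    amp_stop("resolution undefined below 4 taxa", "consensus_error")
  length(ct$splits) / (ct$n_taxa - 3L)
}

# mean pairwise Robinson-Foulds distance of a list of topologies
.mean_pairwise_rf <- function(trees) {
  k <- length(trees)
  if (k < 2L) return(0)
  keys <- lapply(trees, function(t) names(splits(t)))
  tot <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tot <- tot + length(setdiff(keys[[i]], keys[[j]])) +
        length(setdiff(keys[[j]], keys[[i]]))
    }
  }
  tot / (k * (k - 1L) / 2L)
}

#' Consensus series across sampled temperatures
#'
#' For every temperature block at which the trace recorded topology
#' samples, computes the strict consensus, its resolution, and the mean
#' pairwise Robinson-Foulds distance of the sampled trees, in cooling
#' order.
#'
#' @param trace an [anneal()] trace run with `tree_sample_levels > 0`.
#' @return A `data.frame` of class `"consensus_series"` with columns
#'   `block`, `temperature`, `n_trees`, `resolution`, `mean_rf`; the
#'   consensus trees themselves are kept in attribute `"consensus"`.
#' @export
consensus_series <- function(trace) {
  stopifnot(inherits(trace, "sa_trace"))
  ts <- trace$tree_samples
  if (is.null(ts))
    amp_stop("trace holds no topology samples (set tree_sample_levels)",
             "consensus_error")
  blocks <- sort(unique(ts$block))
  rows <- vector("list", length(blocks))
  cons <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    trees <- ts$trees[ts$block == b]
    ct <- strict_consensus(trees)
    cons[[i]] <- ct
    rows[[i]] <- data.frame(
      block = b,
      temperature = trace$blocks$temperature[match(b, trace$blocks$block)],
      n_trees = length(trees), resolution = resolution(ct),
      mean_rf = .mean_pairwise_rf(trees))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("consensus_series", "data.frame")
  attr(out, "consensus") <- cons
  out
}

#' Root a tree for display
#'
#' Produces a rooted newick string for figures; rooting is display-only and
#' never used in scoring. If the outgroup is monophyletic (one side of an
#' edge) the tree is rooted on that edge; otherwise the fallback roots on
#' the edge separating the maximum number of outgroup taxa, preferring the
#' smallest such side and breaking remaining ties by the lexicographically
#' lowest canonical split.
#'
#' @param t a [topology()] or `consensus_tree`.
#' @param outgroup taxon indices (or labels, when `taxa` is given) forming
#'   the outgroup; a non-empty proper subset of the taxa.
#' @param taxa optional leaf labels.
#' @return A rooted newick string.
#' @export
root_for_display <- function(t, outgroup, taxa = NULL) {
  if (inherits(t, "consensus_tree")) {
    phy <- t$phylo
    n <- t$n_taxa
    sides <- unname(t$splits)
  } else {
    stopifnot(inherits(t, "topology"))
    n <- t$n_taxa
    taxa <- taxa %||% attr(t, "taxa")
    phy <- as_phylo(t, taxa)
    sides <- unname(splits(t))
  }
  labels <- phy$tip.label
  if (is.character(outgroup)) {
    og <- match(outgroup, labels)
    if (anyNA(og))
      amp_stop("unknown outgroup label", "consensus_error")
  } else {
    og <- as.integer(outgroup)
  }
  if (length(og) == 0L || length(og) >= n || any(og < 1L | og > n))
    amp_stop("outgroup must be a non-empty proper subset of the taxa",
             "consensus_error")
  # candidate sides: every edge of the tree, i.e. each split side and its
  # complement, plus the trivial pendant-edge sides
  all_ix <- seq_len(n)
  cand <- c(lapply(all_ix, function(i) i),
            sides, lapply(sides, function(s) setdiff(all_ix, s)))
  score <- vapply(cand, function(s) length(intersect(s, og)), numeric(1))
  size <- lengths(cand)
  key <- vapply(cand, function(s) paste(sort(s), collapse = ","),
                character(1))
  o <- order(-score, size, key)
  best <- cand[[o[1]]]
  rooted <- ape::root(phy, outgroup = labels[best], resolve.root = TRUE)
  ape::write.tree(rooted)
}
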
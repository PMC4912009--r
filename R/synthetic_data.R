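# Synthetic alignments with controlled tree signal and homoplasy, so every
# pipeline stage is testable without external data. Sequences evolve on a
# known topology under an equal-rates process: along each branch every site
# substitutes with probability p to a uniformly chosen different base.
# Raising p raises the homoplasy level (lowers the CI of the optimal tree).

#' Evolve a nucleotide alignment on a tree
#'
#' The root sequence is drawn from `base_comp`; each of the 2n-3 branches
#' then applies the single-parameter substitution process independently.
#' `p` must stay below 0.75, the saturation fixed point of the equal-rates
#' model.
#'
#' @param n_taxa number of taxa (>= 4); ignored when `tree` is given.
#' @param n_sites number of sites (>= 1).
#' @param p per-branch, per-site substitution probability in `[0, 0.75)`.
#' @param tree optional generating [topology()]; by default a random
#'   topology is drawn by stepwise addition.
#' @param base_comp base composition of the root sequence (A, C, G, T);
#'   default uniform.
#' @param seed optional RNG seed (the draw is fully reproducible from it).
#' @return A list of class `"sim_alignment"`: `alignment` (taxa named
#'   `t1..tn`), `tree` (the generating topology) and `params`.
#' @examples
#' sim <- evolve_alignment(8, 200, p = 0.05, seed = 42)
#' sim$alignment
#' @export
evolve_alignment <- function(n_taxa, n_sites, p, tree = NULL,
                             base_comp = rep(0.25, 4), seed = NULL) {
  if (!is.numeric(p) || p < 0 || p >= 0.75)
    amp_stop("substitution probability p must lie in [0, 0.75)", "sim_error")
  stopifnot(n_sites >= 1, length(base_comp) == 4, all(base_comp >= 0),
            sum(base_comp) > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- random_topology(n_taxa)
  stopifnot(inherits(tree, "topology"))
  n <- tree$n_taxa
  adj <- .adjacency(tree)
  root <- n + 1L
  nv <- 2L * n - 2L
  seqs <- vector("list", nv)
  seqs[[root]] <- sample.int(4L, n_sites, replace = TRUE,
                             prob = base_comp / sum(base_comp))
  # depth-first over branches from the root internal vertex
  stack_v <- root
  stack_p <- 0L
  while (length(stack_v)) {
    v <- stack_v[length(stack_v)]
    pa <- stack_p[length(stack_p)]
    stack_v <- stack_v[-length(stack_v)]
    stack_p <- stack_p[-length(stack_p)]
    for (u in adj[[v]]) {
      if (u == pa) next
      s <- seqs[[v]]
      mut <- runif(n_sites) < p
      nmut <- sum(mut)
      if (nmut > 0L) {
        s[mut] <- ((s[mut] - 1L + sample.int(3L, nmut, replace = TRUE)) %% 4L) + 1L
      }
      seqs[[u]] <- s
      if (u > n) {
        stack_v <- c(stack_v, u)
        stack_p <- c(stack_p, v)
      }
    }
  }
  bases <- c("A", "C", "G", "T")
  leaf_seqs <- vapply(seq_len(n),
                      function(i) paste(bases[seqs[[i]]], collapse = ""),
                      character(1))
  aln <- alignment(paste0("t", seq_len(n)), leaf_seqs)
  structure(list(alignment = aln, tree = tree,
                 params = list(n_taxa = n, n_sites = n_sites, p = p,
                               base_comp = base_comp, seed = seed)),
            class = "sim_alignment")
}

#' Hand-checkable toy alignments with exhaustive certificates
#'
#' Three small fixtures whose optima are certified by [exhaustive_search()]
#' at call time (never hard-coded):
#' \describe{
#'   \item{quartet_informative}{4 taxa, 3 identical informative columns:
#'     K = 3, a unique optimal quartet of length 3 pairing the agreeing
#'     taxa.}
#'   \item{hexad_clean}{6 taxa, homoplasy-free: two columns support each
#'     internal split of the generating tree, so the optimal length equals
#'     K exactly.}
#'   \item{hexad_conflict}{6 taxa with two equally weighted conflicting
#'     grouping signals, giving at least two equally parsimonious
#'     topologies.}
#' }
#'
#' @return Named list; each entry holds `alignment`, `K`, `optimal_length`,
#'   `optimal_topologies`, `n_optimal` and `n_topologies`.
#' @export
toy_fixtures <- function() {
  fixture <- function(taxa, cols) {
    seqs <- apply(do.call(rbind, cols), 2L, paste, collapse = "")
    a <- alignment(taxa, seqs)
    ctx <- build_context(a)
    ex <- exhaustive_search(ctx)
    list(alignment = a, K = ctx$K, optimal_length = ex$optimal_length,
         optimal_topologies = ex$topologies,
         n_optimal = length(ex$topologies),
         n_topologies = ex$n_topologies)
  }
  t4 <- paste0("t", 1:4)
  t6 <- paste0("t", 1:6)
  split_col <- function(n, side) {
    x <- rep("A", n)
    x[side] <- "C"
    x
  }
  list(
    quartet_informative = fixture(t4, list(
      c("A", "A", "C", "C"), c("A", "A", "C", "C"), c("A", "A", "C", "C"))),
    # generating tree ((t1,t2),((t3,t4),(t5,t6))): splits {3,4}, {5,6},
    # {3,4,5,6}; two clean columns per split
    hexad_clean = fixture(t6, list(
      split_col(6, c(3, 4)), split_col(6, c(3, 4)),
      split_col(6, c(5, 6)), split_col(6, c(5, 6)),
      split_col(6, c(3, 4, 5, 6)), split_col(6, c(3, 4, 5, 6)))),
    # equal support for the incompatible groupings {1,2} and {2,3}
    hexad_conflict = fixture(t6, list(
      split_col(6, c(1, 2)), split_col(6, c(1, 2)),
      split_col(6, c(2, 3)), split_col(6, c(2, 3)))))
}
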
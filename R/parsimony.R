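# Parsimony scoring: Fitch tree length over compressed site patterns, the
# data-determined minimum change count K, and the consistency/homoplasy
# index normalisation CI = K/L, HI = 1 - CI.

.popcount4 <- c(1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

.encode_matrix <- function(a) {
  # n_taxa x n_sites matrix of 4-bit base masks
  chars <- strsplit(a$seqs, "", fixed = TRUE)
  m <- matrix(0L, nrow = a$n_taxa, ncol = a$n_sites)
  for (i in seq_len(a$n_taxa)) m[i, ] <- .iupac[chars[[i]]]
  m
}

#' Tree-independent minimum changes for one alignment column
#'
#' The minimum number of substitutions any tree must spend on a column,
#' minimised over all resolutions of ambiguity: the size of the smallest set
#' of bases intersecting every taxon's state-set, minus one. Fully ambiguous
#' taxa (`-`, `?`, `N`) therefore contribute nothing.
#'
#' @param column either a character vector of IUPAC codes or an integer
#'   vector of 4-bit base masks (A=1, C=2, G=4, T=8).
#' @return Non-negative integer.
#' @examples
#' min_changes_column(c("A", "A", "C", "C"))  # 1
#' min_changes_column(c("A", "A", "N", "-"))  # 0
#' @export
min_changes_column <- function(column) {
  if (length(column) == 0L)
    amp_stop("empty column", "parsimony_error")
  if (is.character(column)) {
    m <- .iupac[toupper(column)]
    if (anyNA(m))
      amp_stop("unrecognised state code in column", "aln_char_error")
  } else {
    m <- as.integer(column)
    if (any(m < 1L | m > 15L))
      amp_stop("state masks must lie in 1..15", "parsimony_error")
  }
  best <- 4L
  for (s in 1:15) {
    if (.popcount4[s] < best && all(bitwAnd(m, s) > 0L))
      best <- .popcount4[s]
  }
  best - 1L
}

# vectorised over sites: minimum hitting-set size per column, minus one
.min_changes_all <- function(m) {
  n_sites <- ncol(m)
  best <- rep.int(4L, n_sites)
  for (s in order(.popcount4)) {
    todo <- .popcount4[s] < best
    if (!any(todo)) next
    cov <- .colSums(bitwAnd(m[, todo, drop = FALSE], s) > 0L,
                    nrow(m), sum(todo)) == nrow(m)
    best[todo][cov] <- .popcount4[s]
  }
  best - 1L
}

#' Build a scoring context from an alignment
#'
#' Encodes IUPAC codes as base sets ('-' and '?' map to full ambiguity),
#' collapses identical site patterns with multiplicities, and computes K,
#' the sum over columns of the tree-independent minimum change count
#' ([min_changes_column()]). K acts as the Boltzmann constant of the
#' annealing acceptance rule; `c` is a multiplier on that constant
#' (`K_eff = c * K`), used in Boltzmann-scaling experiments, and leaves the
#' stored K itself unchanged.
#'
#' @param a an [alignment()].
#' @param c positive Boltzmann multiplier (default 1).
#' @param id identifier carried into run traces.
#' @return An object of class `"scoring_context"`.
#' @export
build_context <- function(a, c = 1, id = "aln") {
  stopifnot(inherits(a, "aln"))
  if (a$n_sites < 1L)
    amp_stop("alignment has zero sites", "aln_dim_error")
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    amp_stop("boltzmann multiplier c must be a positive number",
             "parsimony_error")
  m <- .encode_matrix(a)
  keys <- apply(m, 2L, paste, collapse = ",")
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  w <- as.numeric(tabulate(idx, nbins = sum(first)))
  pat <- t(m[, first, drop = FALSE])  # P x n_taxa, one column per taxon
  storage.mode(pat) <- "integer"
  K <- sum(.min_changes_all(m))
  structure(list(taxa = a$taxa, n_taxa = a$n_taxa, n_sites = a$n_sites,
                 pat = pat, weights = w, K = as.integer(K), c = as.numeric(c),
                 K_eff = as.numeric(c) * K, id = id),
            class = "scoring_context")
}

#' @export
print.scoring_context <- function(x, ...) {
  cat(sprintf(
    "Scoring context '%s': %d taxa, %d sites (%d patterns), K = %d, c = %g\n",
    x$id, x$n_taxa, x$n_sites, nrow(x$pat), x$K, x$c))
  invisible(x)
}

#' Set the Boltzmann multiplier of a scoring context
#'
#' @param ctx a scoring context.
#' @param c positive multiplier; `K_eff` becomes `c * K`.
#' @return The updated context.
#' @export
set_boltzmann <- function(ctx, c) {
  stopifnot(inherits(ctx, "scoring_context"), is.numeric(c), c > 0)
  ctx$c <- as.numeric(c)
  ctx$K_eff <- ctx$c * ctx$K
  ctx
}

#' Fitch tree length
#'
#' Minimum number of substitutions needed to explain the alignment on the
#' given topology, from the standard post-order intersection/union pass
#' (rooted on the edge incident to taxon 1; the count is independent of that
#' choice), summed over compressed patterns with multiplicities.
#'
#' @param t a [topology()].
#' @param ctx a [build_context()] scoring context over the same taxa.
#' @return Tree length (numeric, integer-valued).
#' @export
fitch_length <- function(t, ctx) {
  stopifnot(inherits(t, "topology"), inherits(ctx, "scoring_context"))
  if (t$n_taxa != ctx$n_taxa)
    amp_stop(sprintf("topology has %d leaves but context has %d taxa",
                     t$n_taxa, ctx$n_taxa), "parsimony_error")
  cpp_fitch_length(t$edge, t$n_taxa, ctx$pat, ctx$weights)
}

#' Homoplasy index of a tree length
#'
#' `HI = 1 - CI` with `CI = (c K) / L`. For the degenerate case `L = 0`
#' (which forces `K = 0`) the convention is `CI = 1`, `HI = 0`. A length
#' below K is impossible by theory and signals a scoring bug.
#'
#' @param L tree length.
#' @param ctx scoring context supplying `K` and the multiplier `c`.
#' @return HI value (in `[0, 1)` for `c = 1`).
#' @export
homoplasy_index <- function(L, ctx) {
  stopifnot(inherits(ctx, "scoring_context"))
  if (any(L < ctx$K - 1e-9))
    amp_stop(sprintf("tree length %g below theoretical minimum K = %d",
                     min(L), ctx$K), "parsimony_bug")
  ifelse(L <= 0, 0, 1 - ctx$K_eff / L)
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates all (2n-5)!! unrooted binary topologies by recursive edge
#' addition and scores each with [fitch_length()]. Only feasible for small
#' n; refused above 9 taxa (135,135 topologies). Used as the certification
#' oracle for fixtures and heuristic-search tests.
#'
#' @param x an [alignment()] or a [build_context()] context.
#' @return List with `optimal_length`, `n_topologies` (count enumerated) and
#'   `topologies` (all optimal [topology()] objects).
#' @export
exhaustive_search <- function(x) {
  ctx <- if (inherits(x, "aln")) build_context(x) else x
  stopifnot(inherits(ctx, "scoring_context"))
  if (ctx$n_taxa < 4L)
    amp_stop("need at least 4 taxa", "parsimony_error")
  if (ctx$n_taxa > 9L)
    amp_stop("exhaustive search refused above 9 taxa", "parsimony_error")
  res <- cpp_exhaustive(ctx$n_taxa, ctx$pat, ctx$weights)
  list(optimal_length = res$best_length,
       n_topologies = res$n_topologies,
       topologies = lapply(res$best_edges, topology, n_taxa = ctx$n_taxa,
                           validate = FALSE))
}
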
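# Unrooted binary tree topologies over taxon indices.
#
# Vertices are 1-based: leaves 1..n are the taxa, internal vertices occupy
# n+1..2n-2, and the 2n-3 edges are held as a two-column integer matrix.
# Trees are topology-only (no branch lengths): the parsimony criterion and
# all annealing diagnostics depend on topology alone. Labels attach only at
# the I/O boundary (newick, display).

#' Construct a topology from an edge matrix
#'
#' @param edge integer matrix with 2n-3 rows and 2 columns; leaves are
#'   vertices `1..n_taxa`, internal vertices `n_taxa+1..2*n_taxa-2`.
#' @param n_taxa number of leaves (>= 4).
#' @param validate check the tree invariants (degree-3 internals, degree-1
#'   leaves, connectedness). Skipping is for internal hot paths.
#' @return An object of class `"topology"`.
#' @export
topology <- function(edge, n_taxa, validate = TRUE) {
  edge <- matrix(as.integer(edge), ncol = 2L)
  t <- structure(list(n_taxa = as.integer(n_taxa), edge = edge),
                 class = "topology")
  if (validate) validate_topology(t)
  t
}

#' Check the structural invariants of a topology
#'
#' An n-leaf unrooted binary tree must have exactly n-2 internal vertices of
#' degree 3, n leaves of degree 1, 2n-3 edges, and be connected (which,
#' given the degree sequence and edge count, rules out cycles).
#'
#' @param t a [topology()].
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_topology <- function(t) {
  stopifnot(inherits(t, "topology"))
  n <- t$n_taxa
  if (n < 4L) amp_stop("need at least 4 taxa", "topology_error")
  nv <- 2L * n - 2L
  ne <- 2L * n - 3L
  if (nrow(t$edge) != ne)
    amp_stop(sprintf("expected %d edges, found %d", ne, nrow(t$edge)),
             "topology_error")
  if (any(t$edge < 1L) || any(t$edge > nv))
    amp_stop("edge endpoint outside vertex range", "topology_error")
  deg <- tabulate(t$edge, nbins = nv)
  if (!all(deg[seq_len(n)] == 1L))
    amp_stop("every leaf must have degree 1", "topology_error")
  if (!all(deg[(n + 1L):nv] == 3L))
    amp_stop("every internal vertex must have degree 3", "topology_error")
  # connectivity by breadth-first search from leaf 1
  adj <- .adjacency(t)
  seen <- logical(nv)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen))
    amp_stop("topology is not connected", "topology_error")
  invisible(TRUE)
}

.adjacency <- function(t) {
  nv <- 2L * t$n_taxa - 2L
  adj <- vector("list", nv)
  for (i in seq_len(nrow(t$edge))) {
    a <- t$edge[i, 1L]
    b <- t$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Unrooted binary topology: %d taxa, %d edges\n", x$n_taxa,
              nrow(x$edge)))
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

#' Random topology by stepwise addition
#'
#' Starts from the 3-leaf star and attaches each remaining taxon to a
#' uniformly chosen existing edge. This is the usual "random topology"
#' starting point for heuristic searches; it is uniform over topologies for
#' n = 4 but not for larger n. Randomness comes from R's RNG, so
#' `set.seed()` makes draws reproducible.
#'
#' @param n_taxa number of leaves (>= 4).
#' @return A [topology()].
#' @examples
#' set.seed(1)
#' random_topology(6)
#' @export
random_topology <- function(n_taxa) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 4L) amp_stop("need at least 4 taxa", "topology_error")
  n <- n_taxa
  edge <- matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2L,
                 byrow = TRUE)
  for (k in seq_len(n)[-(1:3)]) {
    ei <- sample.int(nrow(edge), 1L)
    w <- n + k - 2L
    b <- edge[ei, 2L]
    edge[ei, 2L] <- w
    edge <- rbind(edge, c(w, b), c(w, k))
  }
  topology(edge, n, validate = FALSE)
}

#' Non-trivial splits (bipartitions) of a topology
#'
#' Each of the n-3 internal edges induces a bipartition of the taxa. Splits
#' are stored canonically as the side that excludes taxon 1, sorted
#' ascending; the list names are the comma-separated canonical keys, so two
#' topologies are isomorphic iff their name sets are equal.
#'
#' @param t a [topology()].
#' @return Named list of integer vectors (one per internal edge).
#' @export
splits <- function(t) {
  stopifnot(inherits(t, "topology"))
  n <- t$n_taxa
  adj <- .adjacency(t)
  r <- adj[[1L]][1L]  # internal vertex adjacent to leaf 1
  # preorder from r, then accumulate leaf-descendant sets in reverse
  nv <- 2L * n - 2L
  parent <- integer(nv)
  order <- integer(0)
  stack <- r
  parent[r] <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) {
      if (u != parent[v] && u > n) {
        parent[u] <- v
        stack <- c(stack, u)
      }
    }
  }
  below <- vector("list", nv)
  for (v in rev(order)) {
    leaves <- integer(0)
    for (u in adj[[v]]) {
      if (u == parent[v]) next
      leaves <- c(leaves, if (u <= n) u else below[[u]])
    }
    below[[v]] <- leaves
  }
  out <- list()
  for (v in order) {
    if (v == r) next            # edge (r, leaf 1) is the pendant edge of taxon 1
    side <- sort(below[[v]])
    if (length(side) >= 2L && length(side) <= n - 2L)
      out[[paste(side, collapse = ",")]] <- side
  }
  out
}

#' Robinson-Foulds distance between two topologies
#'
#' Size of the symmetric difference of the non-trivial split sets; 0 iff the
#' topologies are identical.
#'
#' @param t1,t2 topologies over the same leaf set.
#' @return Non-negative integer count.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "topology"), inherits(t2, "topology"))
  if (t1$n_taxa != t2$n_taxa)
    amp_stop("topologies have different leaf sets", "topology_error")
  s1 <- names(splits(t1))
  s2 <- names(splits(t2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# ---------------------------------------------------------------------------
# newick I/O via ape. The topology is written rooted at the internal vertex
# adjacent to leaf 1, which produces the basal trifurcation form customary
# for unrooted trees; branch lengths are never written.
# ---------------------------------------------------------------------------

#' Convert a topology to an ape "phylo" object
#'
#' @param t a [topology()].
#' @param taxa optional character labels for leaves 1..n; defaults to
#'   `t1, t2, ...`.
#' @return An unrooted `phylo` with a basal trifurcation.
#' @export
as_phylo <- function(t, taxa = NULL) {
  stopifnot(inherits(t, "topology"))
  n <- t$n_taxa
  taxa <- taxa %||% paste0("t", seq_len(n))
  if (length(taxa) != n) amp_stop("need one label per taxon", "topology_error")
  adj <- .adjacency(t)
  r <- adj[[1L]][1L]
  nv <- 2L * n - 2L
  newid <- integer(nv)
  newid[r] <- n + 1L
  nxt <- n + 1L
  out <- matrix(0L, nrow = 2L * n - 3L, ncol = 2L)
  k <- 0L
  # iterative preorder emitting parent -> child rows (cladewise order)
  stack_v <- r
  stack_p <- 0L
  while (length(stack_v)) {
    v <- stack_v[length(stack_v)]
    p <- stack_p[length(stack_v)]
    stack_v <- stack_v[-length(stack_v)]
    stack_p <- stack_p[-length(stack_p)]
    for (u in adj[[v]]) {
      if (u == p) next
      k <- k + 1L
      if (u <= n) {
        out[k, ] <- c(newid[v], u)
      } else {
        nxt <- nxt + 1L
        newid[u] <- nxt
        out[k, ] <- c(newid[v], nxt)
        stack_v <- c(stack_v, u)
        stack_p <- c(stack_p, v)
      }
    }
  }
  phy <- structure(list(edge = out, Nnode = n - 2L,
                        tip.label = as.character(taxa)),
                   class = "phylo")
  attr(phy, "order") <- "cladewise"
  phy
}

#' Convert an ape "phylo" object to a topology
#'
#' The tree is unrooted first; it must be binary. Tips are mapped to taxon
#' indices by position in `taxa` when given; otherwise labels of the form
#' `t<k>` map to index `k`, and any other label set maps alphabetically.
#'
#' @param phy a `phylo`.
#' @param taxa optional character vector fixing which label is taxon 1, 2, ...
#' @return A [topology()]; the labels used are attached as attribute `taxa`.
#' @export
as_topology <- function(phy, taxa = NULL) {
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::collapse.singles(ape::unroot(phy))
  n <- length(phy$tip.label)
  if (n < 4L) amp_stop("need at least 4 taxa", "topology_error")
  if (phy$Nnode != n - 2L)
    amp_stop("tree is not an unrooted binary topology", "topology_error")
  if (is.null(taxa)) {
    # default mapping: the package's own labels t<k> map back to index k;
    # any other label set is mapped in alphabetical order
    if (all(grepl("^t[0-9]+$", phy$tip.label))) {
      taxa <- paste0("t", seq_len(n))
    } else {
      taxa <- sort(phy$tip.label)
    }
  }
  {
    tipmap <- match(phy$tip.label, taxa)
    if (anyNA(tipmap))
      amp_stop(sprintf("unknown taxon label(s): %s",
                       paste(phy$tip.label[is.na(tipmap)], collapse = ", ")),
               "topology_error")
  }
  old_int <- sort(unique(as.vector(phy$edge[phy$edge > n])))
  edge <- phy$edge
  edge[] <- ifelse(phy$edge <= n, tipmap[pmin(phy$edge, n)],
                   n + match(phy$edge, old_int))
  t <- topology(edge, n)
  attr(t, "taxa") <- as.character(taxa)
  t
}

#' Parse a newick string into a topology
#'
#' Accepts both fully binary rooted form (the root dichotomy is collapsed by
#' unrooting) and the basal-trifurcation form; branch lengths, if present,
#' are discarded.
#'
#' @param text a newick string.
#' @param taxa optional label order defining taxon indices.
#' @return A [topology()].
#' @examples
#' parse_newick("((A,B),(C,D));")
#' @export
parse_newick <- function(text, taxa = NULL) {
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy))
    amp_stop(sprintf("malformed newick: %s", text), "newick_error")
  as_topology(phy, taxa)
}

#' Write a topology as a newick string
#'
#' Output is stable for a fixed topology and taxon order (deterministic
#' traversal), with the unrooted tree written as a basal trifurcation and no
#' branch lengths.
#'
#' @param t a [topology()].
#' @param taxa optional leaf labels.
#' @return A newick string.
#' @export
write_newick <- function(t, taxa = NULL) {
  taxa <- taxa %||% attr(t, "taxa")
  ape::write.tree(as_phylo(t, taxa))
}
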
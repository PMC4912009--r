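# Candidate-solution proposals: nearest neighbour interchange (NNI) and
# subtree pruning-regrafting (SPR), proposed in strict alternation starting
# with NNI. Every decision point (edge, side, arrangement, destination) is a
# uniform draw from R's RNG; SPR destinations that would recreate the source
# topology are ineligible, so every proposal is a genuine perturbation.

.proposal <- function(kind, t, edited) {
  structure(list(kind = kind, topology = t, edited = edited),
            class = "move_proposal")
}

#' @export
print.move_proposal <- function(x, ...) {
  cat(sprintf("%s proposal (edited edges: %s)\n", x$kind,
              paste(x$edited, collapse = ", ")))
  print(x$topology)
  invisible(x)
}

#' Propose a random NNI neighbour
#'
#' Picks a uniform random internal edge and one of its two alternative
#' subtree arrangements uniformly.
#'
#' @param t a [topology()] with at least 4 taxa.
#' @return A `move_proposal`: list with `kind`, the rearranged `topology`,
#'   and the indices of the `edited` edges.
#' @export
nni_neighbor <- function(t) {
  stopifnot(inherits(t, "topology"))
  res <- cpp_nni(t$edge, t$n_taxa)
  .proposal("NNI", topology(res$edge, t$n_taxa, validate = FALSE),
            res$edited)
}

#' Apply a specific NNI deterministically
#'
#' `internal_edge` is the row index of an internal edge in the topology's
#' edge matrix; `arrangement` selects one of the two alternative exchanges
#' across that edge. Applying the same (edge, arrangement) twice returns the
#' original topology.
#'
#' @param t a [topology()].
#' @param internal_edge edge-matrix row index of an internal edge.
#' @param arrangement 1 or 2.
#' @return The rearranged [topology()].
#' @export
nni_apply <- function(t, internal_edge, arrangement) {
  stopifnot(inherits(t, "topology"), arrangement %in% 1:2)
  topology(cpp_nni_apply(t$edge, t$n_taxa, as.integer(internal_edge),
                         as.integer(arrangement)),
           t$n_taxa, validate = FALSE)
}

#' Enumerate the full NNI neighbourhood
#'
#' All `2 * (n_taxa - 3)` topologies one NNI move away from `t` (some may be
#' isomorphic to each other for symmetric sources, but each edge/arrangement
#' pair is returned once).
#'
#' @param t a [topology()].
#' @return List of topologies.
#' @export
nni_neighborhood <- function(t) {
  internal <- which(t$edge[, 1L] > t$n_taxa & t$edge[, 2L] > t$n_taxa)
  out <- vector("list", 2L * length(internal))
  k <- 0L
  for (e in internal) {
    for (arr in 1:2) {
      k <- k + 1L
      out[[k]] <- nni_apply(t, e, arr)
    }
  }
  out
}

#' Propose a random SPR neighbour
#'
#' Cuts a uniform random edge on a uniformly chosen side, suppresses the
#' degree-2 vertex left in the remainder, and regrafts the pruned subtree
#' onto a uniformly chosen eligible edge. The merged edge at the old
#' attachment point is ineligible (regrafting there recreates the source);
#' draws with no eligible destination are redrawn.
#'
#' @param t a [topology()] with at least 4 taxa.
#' @return A `move_proposal`.
#' @export
spr_neighbor <- function(t) {
  stopifnot(inherits(t, "topology"))
  res <- cpp_spr(t$edge, t$n_taxa)
  .proposal("SPR", topology(res$edge, t$n_taxa, validate = FALSE),
            res$edited)
}

#' Alternating NNI/SPR proposer
#'
#' Even move indices (0, 2, 4, ...) propose NNI, odd indices SPR — strict
#' alternation starting with NNI.
#'
#' @param t a [topology()].
#' @param move_index 0-based move counter.
#' @return A `move_proposal`.
#' @export
alternating_proposer <- function(t, move_index) {
  if (as.integer(move_index) %% 2L == 0L) nni_neighbor(t) else spr_neighbor(t)
}
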
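# Independent oracles used across the suite. These deliberately avoid the
# package's own Fitch/split machinery wherever they are used to check it.

# Minimum-mutation count by exhaustive enumeration of ancestral labelings:
# every assignment of one base to each internal vertex is scored by counting
# mismatched edges (a leaf edge mismatches when the parent base is outside
# the leaf's state set), minimised per site pattern. Feasible for n <= 7.
brute_force_length <- function(t, ctx) {
  n <- t$n_taxa
  k <- n - 2L
  A <- as.matrix(expand.grid(rep(list(1:4), k)))
  Amask <- matrix(bitwShiftL(1L, A - 1L), nrow(A), k)
  total <- 0
  for (p in seq_len(nrow(ctx$pat))) {
    cost <- numeric(nrow(A))
    for (e in seq_len(nrow(t$edge))) {
      u <- t$edge[e, 1L]
      v <- t$edge[e, 2L]
      if (u > n && v > n) {
        cost <- cost + (A[, u - n] != A[, v - n])
      } else {
        leaf <- min(u, v)
        int <- max(u, v)
        cost <- cost + (bitwAnd(Amask[, int - n], ctx$pat[p, leaf]) == 0L)
      }
    }
    total <- total + ctx$weights[p] * min(cost)
  }
  total
}

# All unrooted binary topologies on n leaves by recursive edge addition
# (independent of the package's C++ enumerator).
enumerate_topologies <- function(n) {
  out <- list()
  grow <- function(edge, k) {
    if (k > n) {
      out[[length(out) + 1L]] <<- topology(edge, n, validate = FALSE)
      return(invisible())
    }
    for (ei in seq_len(nrow(edge))) {
      e2 <- edge
      w <- n + k - 2L
      b <- e2[ei, 2L]
      e2[ei, 2L] <- w
      grow(rbind(e2, c(w, b), c(w, k)), k + 1L)
    }
  }
  grow(matrix(c(1L, n + 1L, 2L, n + 1L, 3L, n + 1L), ncol = 2L, byrow = TRUE),
       4L)
  out
}

# canonical identity key of a topology (split keys in sorted order, so the
# key is representation-independent)
topo_key <- function(t) paste(sort(names(splits(t))), collapse = "|")

# splits of a (possibly multifurcating) phylo with labels t1..tn, canonical
# side excluding taxon 1 -- the ape-based route used to cross-check the
# package's split bookkeeping
phylo_splits <- function(phy, n) {
  pp <- ape::prop.part(phy)
  ix <- match(attr(pp, "labels"), paste0("t", seq_len(n)))
  keys <- character(0)
  for (cl in pp) {
    side <- sort(ix[cl])
    if (length(side) >= 2L && length(side) <= n - 2L) {
      if (1L %in% side) side <- sort(setdiff(seq_len(n), side))
      keys <- c(keys, paste(side, collapse = ","))
    }
  }
  unique(keys)
}

# random alignment with arbitrary IUPAC content (for parser round-trips)
random_iupac_alignment <- function(n_taxa, n_sites) {
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
             "H", "V", "N", "-", "?")
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste(sample(codes, n_sites, replace = TRUE,
                 prob = c(rep(0.22, 4), rep(0.12 / 13, 13))),
          collapse = ""), character(1))
  alignment(paste0("tax", seq_len(n_taxa)), seqs)
}
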
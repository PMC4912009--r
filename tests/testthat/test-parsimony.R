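test_that("column minimum changes count unavoidable states only", {
  expect_equal(min_changes_column(c("A", "A", "C", "C")), 1L)
  expect_equal(min_changes_column(c("A", "C", "G", "T")), 3L)
  # ambiguity can always match A here
  expect_equal(min_changes_column(c("A", "A", "N", "-")), 0L)
  expect_equal(min_changes_column(c("A", "A", "A")), 0L)
  # partial ambiguity that cannot join the fixed states still costs:
  # {C},{T},{A,G} needs three distinct bases
  expect_equal(min_changes_column(c("C", "T", "R")), 2L)
  # but {C},{T},{C,T} resolves onto the fixed states
  expect_equal(min_changes_column(c("C", "T", "Y")), 1L)
  # matches the brute-force minimum over all resolutions
  set.seed(31)
  codes <- names(annealMP:::.iupac)
  for (i in 1:50) {
    col <- sample(codes, 6, replace = TRUE)
    masks <- annealMP:::.iupac[col]
    combos <- expand.grid(lapply(masks, function(m)
      which(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)))
    oracle <- min(apply(combos, 1, function(x) length(unique(x)))) - 1L
    expect_equal(min_changes_column(col), oracle)
  }
})

test_that("the scoring context compresses patterns and sums K over columns", {
  a <- alignment(paste0("t", 1:4),
                 c("AAAACCAA", "AAAACCAA", "CCAAGGCC", "CCAACCCC"))
  ctx <- build_context(a)
  expect_equal(nrow(ctx$pat), 3L)      # 3 distinct columns
  expect_equal(sum(ctx$weights), 8)    # multiplicities cover all sites
  expect_equal(ctx$K, sum(vapply(1:8, function(j)
    min_changes_column(substring(a$seqs, j, j)), integer(1))))
  # constant data: K = 0
  expect_equal(build_context(alignment(paste0("t", 1:4), rep("AAAA", 4)))$K, 0L)
  # the multiplier scales K_eff but never K itself
  ctx2 <- build_context(a, c = 2)
  expect_equal(ctx2$K, ctx$K)
  expect_equal(ctx2$K_eff, 2 * ctx$K)
  expect_error(build_context(a, c = 0), class = "parsimony_error")
})

test_that("Fitch lengths match hand-executable cases", {
  a <- alignment(paste0("t", 1:4), c("A", "A", "C", "C"))
  ctx <- build_context(a)
  expect_equal(fitch_length(parse_newick("((t1,t2),(t3,t4));"), ctx), 1)
  expect_equal(fitch_length(parse_newick("((t1,t3),(t2,t4));"), ctx), 2)
  b <- alignment(paste0("t", 1:4), c("A", "C", "G", "T"))
  ctxb <- build_context(b)
  for (t in enumerate_topologies(4)) expect_equal(fitch_length(t, ctxb), 3)
  const <- build_context(alignment(paste0("t", 1:4), rep("AAAA", 4)))
  expect_equal(fitch_length(random_topology(4), const), 0)
  expect_error(fitch_length(random_topology(5), ctx), class = "parsimony_error")
})

test_that("Fitch equals the exhaustive ancestral-labeling minimum and phangorn", {
  set.seed(32)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    sim <- evolve_alignment(n, sample(5:15, 1), p = runif(1, 0, 0.5))
    ctx <- build_context(sim$alignment)
    t <- random_topology(n)
    L <- fitch_length(t, ctx)
    expect_equal(L, brute_force_length(t, ctx))
    expect_gte(L, ctx$K)
  }
  skip_if_not_installed("phangorn")
  for (i in 1:10) {
    sim <- evolve_alignment(8, 40, p = 0.3)
    ctx <- build_context(sim$alignment)
    t <- random_topology(8)
    chars <- strsplit(sim$alignment$seqs, "")
    names(chars) <- sim$alignment$taxa
    pd <- phangorn::phyDat(do.call(rbind, chars), type = "DNA")
    expect_equal(fitch_length(t, ctx),
                 as.numeric(phangorn::fitch(as_phylo(t, sim$alignment$taxa),
                                            pd)))
  }
})

test_that("pattern compression and vertex relabeling leave scores unchanged", {
  set.seed(33)
  sim <- evolve_alignment(8, 60, p = 0.3)
  ctx <- build_context(sim$alignment)
  # uncompressed context: every site its own pattern
  ctx_unc <- ctx
  ctx_unc$pat <- t(annealMP:::.encode_matrix(sim$alignment))
  storage.mode(ctx_unc$pat) <- "integer"
  ctx_unc$weights <- rep(1, sim$alignment$n_sites)
  for (i in 1:10) {
    t <- random_topology(8)
    L <- fitch_length(t, ctx)
    expect_equal(L, fitch_length(t, ctx_unc))
    # relabel internal vertices and shuffle edge order: same unrooted tree
    perm <- c(seq_len(8), 8L + sample(6))
    edge2 <- matrix(perm[t$edge], ncol = 2)[sample(nrow(t$edge)), ]
    expect_equal(fitch_length(topology(edge2, 8), ctx), L)
  }
})

test_that("homoplasy index follows CI = cK/L with the stated conventions", {
  a <- alignment(paste0("t", 1:4), c("AACC", "AACC", "CCAA", "CCAA"))
  ctx <- build_context(a)   # K = 4
  expect_equal(homoplasy_index(4, ctx), 0)        # CI = 1
  expect_equal(homoplasy_index(8, ctx), 0.5)      # CI = 0.5
  const <- build_context(alignment(paste0("t", 1:4), rep("AA", 4)))
  expect_equal(homoplasy_index(0, const), 0)      # L = 0 convention
  expect_error(homoplasy_index(3, ctx), class = "parsimony_bug")
  ctx2 <- build_context(a, c = 2)
  expect_equal(homoplasy_index(16, ctx2), 0.5)    # effective K doubles
})

test_that("exhaustive search enumerates (2n-5)!! topologies and certifies optima", {
  fx <- toy_fixtures()$quartet_informative
  ex <- exhaustive_search(fx$alignment)
  expect_equal(ex$n_topologies, 3)
  ex6 <- exhaustive_search(toy_fixtures()$hexad_clean$alignment)
  expect_equal(ex6$n_topologies, 105)
  expect_error(exhaustive_search(build_context(
    evolve_alignment(10, 10, p = 0.1, seed = 1)$alignment)),
    class = "parsimony_error")
  # homoplasy-free 7-taxon data: optimum attains K and includes the
  # generating topology
  set.seed(34)
  gen <- random_topology(7)
  cols <- lapply(splits(gen), function(s) {
    x <- rep("A", 7); x[s] <- "C"; x
  })
  a <- alignment(paste0("t", 1:7),
                 apply(do.call(rbind, cols), 2, paste, collapse = ""))
  ctx <- build_context(a)
  ex7 <- exhaustive_search(ctx)
  expect_equal(ex7$optimal_length, ctx$K)
  expect_true(topo_key(gen) %in%
                vapply(ex7$topologies, topo_key, character(1)))
})
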
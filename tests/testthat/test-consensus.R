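test_that("strict consensus keeps exactly the shared splits", {
  # identical inputs: the tree itself, fully resolved
  set.seed(61)
  t <- random_topology(8)
  ct <- strict_consensus(rep(list(t), 20))
  expect_setequal(names(ct$splits), names(splits(t)))
  expect_equal(resolution(ct), 1)
  # the three quartets share nothing: star tree
  quartets <- list(parse_newick("((t1,t2),(t3,t4));"),
                   parse_newick("((t1,t3),(t2,t4));"),
                   parse_newick("((t1,t4),(t2,t3));"))
  star <- strict_consensus(quartets)
  expect_length(star$splits, 0L)
  expect_equal(resolution(star), 0)
  # two 6-taxon trees sharing exactly one split
  t1 <- parse_newick("(((t1,t2),(t3,t4)),(t5,t6));")
  t2 <- parse_newick("(((t1,t3),(t2,t4)),(t5,t6));")
  shared <- intersect(names(splits(t1)), names(splits(t2)))
  expect_length(shared, 1L)
  both <- strict_consensus(list(t1, t2))
  expect_setequal(names(both$splits), shared)
  expect_error(strict_consensus(list()), class = "consensus_error")
  expect_error(strict_consensus(list(t1, random_topology(5))),
               class = "consensus_error")
})

test_that("consensus splits agree with the ape consensus tree", {
  set.seed(62)
  for (i in 1:8) {
    trees <- lapply(1:5, function(j) random_topology(8))
    ct <- strict_consensus(trees)
    expect_setequal(names(ct$splits), phylo_splits(ct$phylo, 8))
  }
})

test_that("consensus is idempotent and anti-monotone in its input set", {
  set.seed(63)
  trees <- lapply(1:4, function(j) random_topology(7))
  c1 <- strict_consensus(trees)
  c2 <- strict_consensus(trees)
  expect_identical(names(c1$splits), names(c2$splits))
  # adding a tree can only shrink (or keep) the split set
  for (i in 1:10) {
    base <- lapply(1:3, function(j) random_topology(7))
    more <- c(base, list(random_topology(7)))
    expect_true(all(names(strict_consensus(more)$splits) %in%
                      names(strict_consensus(base)$splits)))
  }
})

test_that("resolution counts splits out of n-3", {
  t1 <- parse_newick("(((t1,t2),(t3,t4)),(t5,t6));")
  expect_equal(resolution(strict_consensus(list(t1))), 1)
  t2 <- parse_newick("(((t1,t3),(t2,t4)),(t5,t6));")
  expect_equal(resolution(strict_consensus(list(t1, t2))), 1 / 3)
})

test_that("the consensus series tracks sampled temperatures in cooling order", {
  sim <- evolve_alignment(8, 120, p = 0.05, seed = 64)
  ctx <- build_context(sim$alignment, id = "series")
  cfg <- sa_config(sa_schedule("linear", t0 = 2e-3, m = 2e-5), n = 500,
                   l = 10, l_tree = 50, freeze_window = 1000, seed = 2,
                   tree_sample_levels = 8)
  tr <- anneal(ctx, cfg)
  cs <- consensus_series(tr)
  expect_s3_class(cs, "consensus_series")
  expect_equal(nrow(cs), length(unique(tr$tree_samples$block)))
  expect_true(all(diff(cs$temperature) < 0))
  expect_true(all(cs$n_trees == 10L))
  expect_true(all(cs$resolution >= 0 & cs$resolution <= 1))
  # the coldest sampled temperature is at least as resolved as the hottest
  expect_gte(cs$resolution[nrow(cs)], cs$resolution[1])
  # a temperature where all samples agree is fully resolved with zero RF
  agree <- which(cs$mean_rf == 0)
  if (length(agree)) expect_true(all(cs$resolution[agree] == 1))
  # traces without samples are refused
  cfg0 <- sa_config(sa_schedule("linear", t0 = 2e-3, m = 2e-5), n = 500,
                    l = 10, freeze_window = 1000, seed = 2)
  expect_error(consensus_series(anneal(ctx, cfg0)), class = "consensus_error")
})

test_that("display rooting honours monophyletic outgroups and is deterministic", {
  q <- parse_newick("((t1,t2),(t3,t4));")
  r1 <- ape::read.tree(text = root_for_display(q, outgroup = 1))
  expect_true(ape::is.rooted(r1))
  # taxon t1 sits alone on one side of the root
  root_children <- r1$edge[r1$edge[, 1] == length(r1$tip.label) + 1L, 2]
  expect_true(any(root_children <= 4 &
                    r1$tip.label[pmin(root_children, 4)] == "t1"))
  # an outgroup equal to one side of an existing split roots on that edge
  r2 <- ape::read.tree(text = root_for_display(q, outgroup = c("t3", "t4")))
  expect_true(ape::is.monophyletic(r2, c("t3", "t4")))
  # non-monophyletic outgroup: deterministic fallback
  t6 <- parse_newick("((t1,t2),(t3,t4),(t5,t6));")
  expect_identical(root_for_display(t6, outgroup = c(2, 5)),
                   root_for_display(t6, outgroup = c(2, 5)))
  expect_error(root_for_display(q, outgroup = 1:4),
               class = "consensus_error")
})
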
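test_that("acceptance probability follows the Metropolis closed forms", {
  expect_equal(acceptance_probability(0, 0.01), 1)
  expect_equal(acceptance_probability(-0.05, 1e-6), 1)
  expect_equal(acceptance_probability(0.01, 0.01), exp(-1))
  # zero-temperature step function
  expect_equal(acceptance_probability(c(-1, 0, 1), 0), c(1, 0, 0))
  # vectorised and monotone in temperature
  d <- 0.02
  expect_lt(acceptance_probability(d, 0.005), acceptance_probability(d, 0.01))
})

test_that("configuration contracts are enforced", {
  sch <- sa_schedule("linear", t0 = 2e-3, m = 1e-5)
  expect_error(sa_config(sch, n = 2000, l = 3), class = "config_error")
  expect_error(sa_config(sch, n = 2000, l_tree = 300), class = "config_error")
  expect_error(sa_config(sch, n = 0), class = "config_error")
  expect_error(sa_config(sa_schedule("constant", t0 = 1e-3), n = 100, l = 10),
               class = "config_error")
  expect_error(sa_schedule("geometric", t0 = 1e-2, alpha = 1.2))
})

test_that("block structure follows the schedule arithmetic", {
  sim <- evolve_alignment(12, 100, p = 0.05, seed = 51)
  ctx <- build_context(sim$alignment, id = "arith")
  cfg <- sa_config(sa_schedule("linear", t0 = 2e-3, m = 1e-5), n = 2000,
                   l = 10, freeze_window = 1000, seed = 1)
  tr <- anneal(ctx, cfg)
  expect_lte(nrow(tr$blocks), 200L)
  expect_true(all(tr$blocks$n_samples == 200L))
  expect_true(all(tr$blocks$proposed == 2000L))
  # strict alternation: exactly half NNI, half SPR in every block
  expect_true(all(tr$blocks$nni == 1000L))
  expect_true(all(tr$blocks$spr == 1000L))
  expect_true(all(diff(tr$blocks$temperature) < 0))
  expect_equal(tr$blocks$temperature[1], 2e-3)
  expect_equal(tr$termination, "floor")
})

test_that("identical seeds give identical traces", {
  sim <- evolve_alignment(8, 80, p = 0.1, seed = 52)
  ctx <- build_context(sim$alignment, id = "det")
  cfg <- sa_config(sa_schedule("linear", t0 = 1e-3, m = 2e-5), n = 500,
                   l = 10, seed = 7, tree_sample_levels = 5)
  tr1 <- anneal(ctx, cfg)
  tr2 <- anneal(ctx, cfg)
  expect_identical(tr1, tr2)
})

test_that("near-zero temperature behaves as pure descent", {
  sim <- evolve_alignment(10, 120, p = 0.1, seed = 53)
  ctx <- build_context(sim$alignment, id = "descent")
  cfg <- sa_config(sa_schedule("constant", t0 = 1e-9), n = 500, l = 10,
                   total_move_budget = 10000, freeze_window = 1000, seed = 3)
  tr <- anneal(ctx, cfg)
  expect_true(all(diff(tr$hi$hi) <= 1e-12))
  expect_equal(tr$termination, "budget")
  expect_equal(tr$total_proposed, 10000)
})

test_that("slow cooling recovers the exhaustive optimum on clean data", {
  fx <- toy_fixtures()$hexad_clean
  ctx <- build_context(fx$alignment, id = "clean6")
  hits <- 0L
  for (s in 1:5) {
    cfg <- sa_config(sa_schedule("linear", t0 = 2e-3, m = 1e-5), n = 2000,
                     l = 10, seed = s)
    tr <- anneal(ctx, cfg)
    if (tr$best_length == fx$optimal_length) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("freezing terminates after the configured unimproved window", {
  fx <- toy_fixtures()$hexad_clean
  ctx <- build_context(fx$alignment, id = "freeze")
  cfg <- sa_config(sa_schedule("linear", t0 = 2e-3, m = 1e-6), n = 200,
                   l = 10, freeze_window = 20, seed = 2)
  tr <- anneal(ctx, cfg)
  expect_equal(tr$termination, "frozen")
  # no new best in the final freeze_window blocks
  expect_lte(nrow(tr$blocks), 2000L)
})

test_that("geometric cooling multiplies the temperature by alpha", {
  sim <- evolve_alignment(8, 60, p = 0.1, seed = 54)
  ctx <- build_context(sim$alignment, id = "geo")
  cfg <- sa_config(sa_schedule("geometric", t0 = 1e-3, alpha = 0.9,
                               t_floor = 1e-4),
                   n = 200, l = 10, freeze_window = 1000, seed = 1)
  tr <- anneal(ctx, cfg)
  ratios <- tr$blocks$temperature[-1] / tr$blocks$temperature[-nrow(tr$blocks)]
  expect_equal(ratios, rep(0.9, nrow(tr$blocks) - 1L))
  expect_true(all(tr$blocks$temperature >= 1e-4))
})

test_that("NNI-only sampling at fixed temperature approaches the Boltzmann law", {
  # symmetric kernel: the stationary distribution over the 15 five-taxon
  # topologies should track exp(-HI/T); a rank-correlation sanity check
  topos <- enumerate_topologies(5)
  sim <- evolve_alignment(5, 40, p = 0.3, seed = 13)
  ctx <- build_context(sim$alignment, id = "metro")
  his <- vapply(topos, function(t) homoplasy_index(fitch_length(t, ctx), ctx),
                numeric(1))
  temp <- 0.02
  cfg <- sa_config(sa_schedule("constant", t0 = temp), n = 2000, l = 10,
                   l_tree = 10, total_move_budget = 2e5,
                   freeze_window = 10^9, tree_sample_levels = 100,
                   nni_only = TRUE, seed = 2)
  tr <- anneal(ctx, cfg)
  keys <- vapply(tr$tree_samples$trees, topo_key, character(1))
  freq <- table(factor(keys, levels = vapply(topos, topo_key, character(1))))
  expect_gt(stats::cor(as.numeric(freq), exp(-his / temp),
                       method = "spearman"), 0.8)
})

test_that("the acceptance-rate curve is monotone and saturates", {
  sim <- evolve_alignment(8, 60, p = 0.2, seed = 55)
  ctx <- build_context(sim$alignment, id = "rate")
  set.seed(4)
  states <- list(random_topology(8), random_topology(8))
  curve <- acceptance_rate_curve(ctx, states, c(0, 1e-4, 1e-3, 1e-2, 1e3),
                                 n_proposals = 100)
  expect_true(all(diff(curve$rate) >= 0))
  expect_gt(curve$rate[nrow(curve)], 0.999)
  # at T = 0 only the strictly-downhill fraction passes
  expect_lt(curve$rate[1], 1)
})

test_that("traces serialise to CSV/JSON and round-trip key quantities", {
  sim <- evolve_alignment(6, 50, p = 0.1, seed = 56)
  ctx <- build_context(sim$alignment, id = "ser")
  cfg <- sa_config(sa_schedule("linear", t0 = 5e-4, m = 5e-5), n = 100,
                   l = 10, l_tree = 50, freeze_window = 1000, seed = 1,
                   tree_sample_levels = 3)
  tr <- anneal(ctx, cfg)
  dir <- withr::local_tempdir()
  paths <- write_trace(tr, dir)
  expect_true(all(file.exists(paths)))
  csv <- utils::read.csv(paths[1])
  expect_equal(nrow(csv), nrow(tr$hi))
  hdr <- jsonlite::read_json(paths[2])
  expect_equal(hdr$termination, tr$termination)
  expect_equal(hdr$best_length, tr$best_length)
  trees <- utils::read.csv(paths[3])
  expect_equal(nrow(trees), length(tr$tree_samples$block))
})
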
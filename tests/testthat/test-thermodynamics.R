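# helper: fabricate a minimal trace with prescribed per-block HI samples
fake_trace <- function(temps, sample_list, n = NULL, l = 1L) {
  stopifnot(length(temps) == length(sample_list))
  n <- n %||% length(sample_list[[1]])
  cfg <- sa_config(sa_schedule("linear", t0 = max(temps), m = 1e-5),
                   n = n, l = l, l_tree = l, freeze_window = 10L)
  nb <- length(temps)
  ns <- lengths(sample_list)
  structure(list(
    alignment_id = "fake", config = cfg, n_taxa = 8L,
    blocks = data.frame(block = seq_len(nb), temperature = temps,
                        proposed = n, accepted = 0L, nni = 0L, spr = 0L,
                        n_samples = ns),
    hi = data.frame(block = rep.int(seq_len(nb), ns),
                    sample_index = sequence(ns),
                    hi = unlist(sample_list)),
    tree_samples = NULL, termination = "floor"),
    class = "sa_trace")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("specific heat follows C = var/T^2 exactly", {
  expect_equal(specific_heat(c(0.4, 0.6), 0.5), 0.08)  # var 0.02, T^2 0.25
  expect_equal(specific_heat(rep(0.3, 50), 0.01), 0)
  # doubling deviations quadruples C at fixed T
  x <- c(0.40, 0.44, 0.38, 0.42)
  x2 <- 0.41 + 2 * (x - 0.41)
  expect_equal(specific_heat(x2, 0.2), 4 * specific_heat(x, 0.2))
  expect_error(specific_heat(0.5, 0.1), class = "thermo_error")
  expect_error(specific_heat(c(0.4, 0.6), 0), class = "thermo_error")
})

test_that("profiles hold one point per completed block", {
  temps <- seq(1e-3, 1e-4, length.out = 10)
  tr <- fake_trace(temps, replicate(10, rnorm(20, 0.4, 0.01),
                                    simplify = FALSE), n = 20L)
  p <- heat_profile(tr)
  expect_s3_class(p, "heat_profile")
  expect_equal(nrow(p), 10L)
  expect_equal(p$temperature, temps)
  # a truncated final block is dropped
  sam <- replicate(10, rnorm(20, 0.4, 0.01), simplify = FALSE)
  sam[[10]] <- sam[[10]][1:7]
  expect_equal(nrow(heat_profile(fake_trace(temps, sam, n = 20L))), 9L)
  expect_error(heat_profile(fake_trace(temps[1:2], sam[1:2], n = 20L)),
               class = "thermo_error")
})

test_that("forced constant variance gives C proportional to 1/T^2", {
  temps <- seq(2e-3, 2e-4, length.out = 15)
  # two samples m +/- s have variance exactly 2 s^2
  s <- 0.01
  tr <- fake_trace(temps, replicate(15, 0.4 + c(-s, s), simplify = FALSE),
                   n = 2L)
  p <- heat_profile(tr)
  expect_equal(p$C, 2 * s^2 / temps^2)
  expect_true(all(diff(p$C) > 0))  # strictly increasing as T falls
})

test_that("peak detection recovers constructed unimodal and bimodal profiles", {
  temps <- seq(1e-3, 1e-5, length.out = 61)
  gauss <- function(mu, sd, h) h * exp(-(temps - mu)^2 / (2 * sd^2))
  as_profile <- function(C) {
    p <- data.frame(block = seq_along(temps), temperature = temps, C = C)
    class(p) <- c("heat_profile", "data.frame")
    p
  }
  step <- diff(range(temps)) / 60
  uni <- as_profile(gauss(5e-4, 1e-4, 3) + 0.05)
  rep_u <- detect_peaks(uni)
  expect_equal(rep_u$classification, "single")
  expect_lt(abs(rep_u$peaks$temperature[1] - 5e-4), step)
  bi <- as_profile(gauss(8e-4, 6e-5, 3) + gauss(2e-4, 6e-5, 2.4))
  rep_b <- detect_peaks(bi)
  expect_equal(rep_b$classification, "double")
  expect_lt(max(abs(sort(rep_b$peaks$temperature[1:2]) - c(2e-4, 8e-4))),
            2 * step)
  flat <- as_profile(rep(1.7, 61))
  rep_f <- detect_peaks(flat)
  expect_equal(rep_f$classification, "none")
  expect_equal(rep_f$n_peaks, 0L)
})

test_that("critical temperature averages the largest peak across replicates", {
  mk <- function(tc) {
    structure(list(peaks = data.frame(index = 1L, temperature = tc,
                                      C = 1, prominence = 1),
                   n_peaks = 1L, classification = "single"),
              class = "peak_report")
  }
  expect_equal(critical_temperature(list(mk(4e-4), mk(5e-4), mk(6e-4))), 5e-4)
  expect_equal(critical_temperature(mk(3e-4)), 3e-4)
  peakless <- structure(list(peaks = data.frame(), n_peaks = 0L,
                             classification = "none"),
                        class = "peak_report")
  expect_equal(critical_temperature(list(mk(2e-4), peakless)), 2e-4)
  expect_error(critical_temperature(list(peakless)), class = "thermo_error")
})
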
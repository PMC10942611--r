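make_calls <- function(n_src, n_presyn, barcode = "BC1", prefix = "c") {
  data.table(
    cell_id = sprintf("%s%03d", prefix, seq_len(n_src + n_presyn)),
    barcode = barcode, count = 10L,
    role = rep(c("source", "presynaptic"), c(n_src, n_presyn)))
}

test_that("build_networks classifies by source count and size boundary", {
  calls <- rbind(make_calls(1, 5, "BC1", "a"),   # single source
                 make_calls(2, 3, "BC2", "b"),   # multi source
                 make_calls(0, 4, "BC3", "d"),   # 0 sources, 4 cells
                 make_calls(0, 5, "BC4", "e"))   # 0 sources, 5 cells
  nets <- build_networks(calls)
  cl <- setNames(nets$network_class, nets$barcode)
  expect_equal(unname(cl[c("BC1", "BC2", "BC3", "BC4")]),
               c("single_source", "multi_source", "no_source", "lost_source"))
  ## classes partition the barcodes
  expect_equal(sort(nets$barcode), sort(unique(calls$barcode)))
  ## excluded cells are dropped before grouping
  calls2 <- rbind(make_calls(0, 4, "BC5", "f"),
                  data.table(cell_id = "f999", barcode = "BC5", count = 5L,
                             role = "excluded"))
  net5 <- build_networks(calls2)
  expect_equal(net5$n_cells, 4L)
  expect_equal(net5$network_class, "no_source")
})

test_that("multiplicity_prob reproduces the published worked examples", {
  expect_equal(round(multiplicity_prob(0.001, 1000, 2), 2), 0.26)
  expect_equal(signif(multiplicity_prob(0.001, 1000, 7), 1), 8e-5)
  expect_equal(multiplicity_prob(0.42, 100, 0), 1)
  expect_equal(multiplicity_prob(0, 100, 2), 0)
})

test_that("multiplicity_prob converges to the Poisson tail as f -> 0", {
  f <- 1e-4
  n <- 20000  # n * f = 2
  for (m in 2:8) {
    b <- multiplicity_prob(f, n, m)
    p <- ppois(m - 1, n * f, lower.tail = FALSE)
    expect_lt(abs(b - p) / p, 0.01)
  }
})

test_that("infection_posterior handles degenerate supports", {
  ## huge uniform library: collisions essentially impossible, M = C
  lib <- sample_library(10000, 0, seed = 1)
  post <- infection_posterior(10, 10, lib, mc_reps = 200, seed = 2)
  expect_equal(post$support, 10L)
  expect_equal(post$mass, 1)
  expect_equal(post$mode, 10L)
  expect_equal(post$ci95, c(10L, 10L))

  two <- toy_library(c("ACGTACGTACGTACGTACGT", "TGCAACGTACGTACGTACGT"),
                     frequency = c(0.5, 0.5))
  post <- infection_posterior(2, 2, two, seed = 3)
  expect_equal(post$mode, 2L)
  expect_equal(post$mass, 1)
  expect_true(post$exact)  # small library uses exact enumeration
})

test_that("exact occupancy enumeration matches brute-force simulation", {
  freqs <- c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  lib <- toy_library(rand_bc(6), frequency = freqs)
  ## brute-force oracle: direct simulation of P(M distinct | N draws)
  set.seed(7)
  N <- 8L
  sim_distinct <- replicate(200000, length(unique(
    sample.int(6, N, replace = TRUE, prob = freqs))))
  post <- infection_posterior(4, 10, lib, seed = 8)  # exact path
  p_sim <- mean(sim_distinct == 4L)
  ## recover the exact likelihood at N = 8 from the normalized posterior
  ## by recomputing it directly through the exported interface:
  ## compare full posteriors computed exactly vs by Monte Carlo instead
  post_mc <- infection_posterior(4, 10, lib, mc_reps = 50000, seed = 9,
                                 exact_max = 0L)
  expect_false(post_mc$exact)
  expect_equal(post$mass, post_mc$mass, tolerance = 0.02)
  expect_equal(post$mode, post_mc$mode)
  ## and anchor one support point against the independent simulation:
  ## P(M=4 | N=8) appears in both up to normalization, so compare ratios
  i8 <- which(post$support == 8L)
  i5 <- which(post$support == 5L)
  set.seed(10)
  sim5 <- replicate(200000, length(unique(
    sample.int(6, 5L, replace = TRUE, prob = freqs))))
  ratio_sim <- p_sim / mean(sim5 == 4L)
  ratio_exact <- post$mass[i8] / post$mass[i5]
  expect_equal(ratio_exact, ratio_sim, tolerance = 0.05)
})

test_that("infection_posterior errors usefully on impossible inputs", {
  ## a steeply skewed 13-barcode library (too big for the exact path)
  ## essentially never yields 13 distinct barcodes in 13-15 draws, so a
  ## tiny Monte-Carlo run sees zero successes across the whole support
  skew <- 2^-(1:13); skew <- skew / sum(skew)
  set.seed(101)
  lib13 <- toy_library(rand_bc(13), frequency = skew)
  expect_error(infection_posterior(13, 15, lib13, mc_reps = 5, seed = 4),
               "mc_reps")
  lib <- sample_library(10000, 0, seed = 1)
  expect_error(infection_posterior(10, 5, lib), "c_combinations")
})

test_that("decompose_ledger reproduces the published arithmetic", {
  post <- list(mode = 76L, c_combinations = 126L)
  led <- decompose_ledger(43L, post)
  expect_equal(led$est_double_labeled_pairs, 33L)
  expect_equal(led$est_connected_pairs, 50L)
  ## conservation: singles + double + connected = C
  expect_equal(led$singles + led$est_double_labeled_pairs +
               led$est_connected_pairs, led$c_combinations)

  expect_equal(decompose_ledger(43L, list(mode = 126L, c_combinations = 126L))$
               est_connected_pairs, 0L)
  expect_equal(decompose_ledger(43L, list(mode = 43L, c_combinations = 126L))$
               est_double_labeled_pairs, 0L)
  expect_error(decompose_ledger(80L, post), "inconsistency")
})

test_that("decompose_ledger consumes network tables", {
  calls <- rbind(make_calls(1, 3, "BC1", "a"), make_calls(1, 2, "BC2", "b"),
                 make_calls(2, 2, "BC3", "d"))
  nets <- build_networks(calls)
  led <- decompose_ledger(nets, list(mode = 3L, c_combinations = 4L))
  expect_equal(led$singles, 2L)
  expect_equal(led$est_double_labeled_pairs, 1L)
  expect_equal(led$est_connected_pairs, 1L)
})

test_that("source_detection_fraction brackets the survival rate", {
  ## constructed world: 40 qualifying barcodes, 60% with a surviving
  ## source cell at deep reads
  set.seed(71)
  rows <- list(); cells <- list()
  for (b in 1:40) {
    ids <- sprintf("b%02d_c%02d", b, 1:13)
    has_src <- b <= 24
    rows[[b]] <- data.table(cell_id = ids, barcode = sprintf("BC%02d", b),
                            count = 12L)
    cells[[b]] <- toy_cells(ids, g_count = c(if (has_src) 5L else 0L,
                                             rep(0L, 12)))
  }
  reads <- rbindlist(rows); cells <- rbindlist(cells)
  fr <- source_detection_fraction(reads, cells)
  expect_equal(unname(fr), c(0.6, 0.6))

  ## all sources present and deep -> (1, 1); no sources -> (0, 0)
  cells_all <- copy(cells)[, g_count := rep(c(5L, rep(0L, 12)), 40)]
  expect_equal(unname(source_detection_fraction(reads, cells_all)), c(1, 1))
  cells_none <- copy(cells)[, g_count := 0L]
  expect_equal(unname(source_detection_fraction(reads, cells_none)), c(0, 0))
  expect_error(source_detection_fraction(reads[count < 0], cells),
               "no qualifying")
})

test_that("source_detection_fraction on simulated data tracks 1 - death rate", {
  lib <- sample_library(5000, 0, seed = 81)
  cfg <- sim_config(seed = 82, n_library_barcodes = 5000L, n_tva_cells = 400L,
                    n_bystander_cells = 20000L, n_infections = 400L,
                    p_direct_infection = 0, p_source_death = 0.4,
                    p_intersource_connection = 0, per_base_error = 0,
                    g_count_leak_mean = 0, reads_per_barcode_mean = 30)
  sim <- simulate_transsynaptic(cfg, lib)
  fr <- source_detection_fraction(sim$reads, sim$cells)
  n_qual <- sum(table(sim$reads$barcode) >= 12)
  se <- sqrt(0.6 * 0.4 / n_qual)
  expect_lt(abs(fr[["lower"]] - 0.6), 4 * se)
  expect_lt(abs(fr[["upper"]] - 0.6), 4 * se)
})

test_that("single_infection_threshold: trivial cases and determinism", {
  lib <- sample_library(1000, 1, seed = 91)
  one <- single_infection_threshold(lib, 1, reps = 50, seed = 92)
  expect_equal(one$n_infections, 1)
  expect_equal(one$freq_threshold, 1)

  a <- single_infection_threshold(lib, 50, reps = 100, seed = 93)
  b <- single_infection_threshold(lib, 50, reps = 100, seed = 93)
  expect_identical(a, b)
  expect_error(single_infection_threshold(lib, 2000), "smaller")
})

test_that("single_infection_threshold matches the coupon-collector closed form", {
  lib <- sample_library(1000, 0, seed = 94)
  res <- single_infection_threshold(lib, 100, reps = 400, seed = 95)
  ## uniform library: E[draws to reach 100 distinct] = sum_{i=0}^{99} 1000/(1000-i)
  expected_draws <- sum(1000 / (1000 - 0:99))
  expect_lt(abs(res$n_infections - expected_draws), 4)
  ## analytic f-solve at the expected draw count
  N <- round(expected_draws)
  crit <- function(fv) {
    p1 <- pbinom(0, N, fv, lower.tail = FALSE)
    pbinom(1, N, fv, lower.tail = FALSE) / p1
  }
  f_analytic <- uniroot(function(fv) crit(fv) - 0.05, c(1e-10, 0.5),
                        tol = 1e-12)$root
  expect_equal(res$freq_threshold, f_analytic, tolerance = 0.05)
})
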
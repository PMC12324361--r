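test_that("rate matrix reduces to the pure power-law background", {
  cfg <- sim_config(n_bins = 40, bin_size = 1e4, alpha = 1, s0 = 0,
                    gamma = 0, tau = 0,
                    loops = tibble::tibble(a1 = integer(), a2 = integer(),
                                           amplitude = numeric(), sigma = numeric()))
  r <- build_rate_matrix(cfg)
  d <- abs(outer(0:39, 0:39, "-"))
  off <- d > 0
  expect_equal(r[off] * (d[off] * 1e4), rep(1, sum(off)), tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_true(all(r >= 0))
})

test_that("a single Gaussian loop dot adds 1 + A at its centre on a flat background", {
  cfg <- sim_config(n_bins = 60, bin_size = 1e4, alpha = 0, s0 = 0,
                    gamma = 0, tau = 0,
                    loops = tibble::tibble(a1 = 10L, a2 = 40L,
                                           amplitude = 3, sigma = 1))
  r <- build_rate_matrix(cfg)
  expect_equal(r[11, 41], 4, tolerance = 1e-10)
  expect_equal(r[41, 11], 4, tolerance = 1e-10)   # symmetric mirror term
})

test_that("cohesin depletion equals the tau = 0, amplitude = 0 model elementwise", {
  base_args <- list(n_bins = 80, bin_size = 1e4, seed = 5, tau = 0.5,
                    loops = tibble::tibble(a1 = c(10L, 30L), a2 = c(25L, 60L),
                                           amplitude = 4, sigma = 1))
  dep <- do.call(sim_config, c(base_args, perturbation = "cohesin_depleted"))
  null <- sim_config(n_bins = 80, bin_size = 1e4, seed = 5, tau = 0,
                     loops = tibble::tibble(a1 = c(10L, 30L), a2 = c(25L, 60L),
                                            amplitude = 0, sigma = 1))
  expect_equal(build_rate_matrix(dep), build_rate_matrix(null))
})

test_that("TSA changes loop-centre rates only by the background factor", {
  loops <- tibble::tibble(a1 = 20L, a2 = 50L, amplitude = 5, sigma = 1)
  mk <- function(pert) sim_config(n_bins = 100, bin_size = 1e4, tau = 0,
                                  gamma = 0, loops = loops, perturbation = pert)
  r0 <- build_rate_matrix(mk("none"))
  r1 <- build_rate_matrix(mk("tsa"))
  bg <- tsa_background_profile()(30 * 1e4)
  expect_equal(r1[21, 51] / r0[21, 51], bg, tolerance = 1e-10)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_bins = 50, tad_boundaries = c(0, 20, 20, 50)),
               "strictly increasing")
  expect_error(sim_config(n_bins = 50,
                          loops = tibble::tibble(a1 = 10L, a2 = 60L,
                                                 amplitude = 1, sigma = 1)),
               "outside matrix")
  expect_error(sim_config(n_bins = 50,
                          loops = tibble::tibble(a1 = 10L, a2 = 5L,
                                                 amplitude = 1, sigma = 1)),
               "a1 < a2")
  r <- build_rate_matrix(sim_config(n_bins = 20, tau = 0, gamma = 0))
  expect_error(sample_counts(r, depth = 0, seed = 1, bin_size = 1e4),
               "depth")
})

test_that("sampling is deterministic under a fixed seed", {
  cfg <- sim_config(n_bins = 60, depth = 1e5, seed = 42)
  m1 <- simulate_map(cfg)
  m2 <- simulate_map(cfg)
  expect_identical(m1$counts, m2$counts)
  cfg2 <- sim_config(n_bins = 60, depth = 1e5, seed = 43)
  expect_false(identical(simulate_map(cfg2)$counts, m1$counts))
})

test_that("sampled counts match Poisson moments at high depth", {
  cfg <- sim_config(n_bins = 30, bin_size = 1e4, gamma = 0, tau = 0.5,
                    depth = 5e6, seed = 7,
                    loops = tibble::tibble(a1 = integer(), a2 = integer(),
                                           amplitude = numeric(), sigma = numeric()))
  rate <- build_rate_matrix(cfg)
  m <- sample_counts(rate, depth = cfg$depth, seed = 7, bin_size = 1e4)
  ut <- upper.tri(rate, diag = TRUE)
  lambda <- rate[ut] * cfg$depth / sum(rate[ut])
  z <- (m$counts[ut] - lambda) / sqrt(lambda)
  # mean of standardized residuals ~ N(0, 1/sqrt(k))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
})

test_that("log-log slope of sampled counts recovers the decay exponent", {
  cfg <- sim_config(n_bins = 500, bin_size = 1e4, alpha = 1, gamma = 0,
                    tau = 0, depth = 1e7, seed = 11,
                    loops = tibble::tibble(a1 = integer(), a2 = integer(),
                                           amplitude = numeric(), sigma = numeric()))
  m <- simulate_map(cfg)
  # mean count per diagonal, 2..150 bins
  d <- 2:150
  mc <- vapply(d, function(dd) {
    i <- seq_len(500 - dd)
    mean(m$counts[cbind(i, i + dd)])
  }, numeric(1))
  fit <- stats::lm(log10(mc) ~ log10(d))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.05)
})

test_that("ground truth serializes loop size classes and boundary files", {
  loops <- tibble::tibble(a1 = c(10L, 20L, 30L), a2 = c(40L, 170L, 39L),
                          amplitude = 2, sigma = 1)
  cfg <- sim_config(n_bins = 200, bin_size = 1e4, loops = loops, seed = 2)
  gt <- emit_ground_truth(cfg)
  expect_equal(gt$loops$size, c(3e5, 1.5e6, 9e4))
  expect_equal(gt$loops$size_class, c("100kb-500kb", ">1Mb", NA))
  expect_equal(gt$enrichment$tau_effective,
               c(cfg$tau, cfg$tau * cfg$tsa_tad_retention, 0, 0))

  dir <- tempfile("gt")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  empty_cfg <- sim_config(n_bins = 200, bin_size = 1e4, seed = 2,
                          loops = tibble::tibble(a1 = integer(), a2 = integer(),
                                                 amplitude = numeric(),
                                                 sigma = numeric()))
  gt2 <- emit_ground_truth(empty_cfg, dir = dir)
  bedpe_lines <- readLines(file.path(dir, "loops_truth.bedpe"))
  expect_true(all(grepl("^#", bedpe_lines)))   # header only for empty loop list
  bnd <- readLines(file.path(dir, "boundaries_truth.bed"))
  expect_gt(length(bnd), 1)
  expect_match(bnd[1], "seed=2")
})
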
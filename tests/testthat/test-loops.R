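test_that("loop pileup centre recovers 1 + A on noise-free rates", {
  cfg <- sim_config(n_bins = 120, bin_size = 2e4, alpha = 0, s0 = 0,
                    gamma = 0, tau = 0,
                    loops = tibble::tibble(a1 = 40L, a2 = 80L,
                                           amplitude = 3, sigma = 1))
  r <- build_rate_matrix(cfg)
  oe <- fake_oe(r, bin_size = 2e4)
  lp <- loops_from_bins(40, 80, 2e4)
  pile <- loop_pileup(oe, lp, w_bins = 10)
  expect_equal(pile$pileup[11, 11], 4, tolerance = 1e-6)
})

test_that("pileups equal the brute-force window mean", {
  set.seed(61)
  vals <- matrix(stats::rlnorm(150 * 150, 0, 0.5), 150, 150)
  vals[sample(150 * 150, 400)] <- NA
  oe <- fake_oe(vals, bin_size = 2e4)
  b1 <- c(20L, 40L, 90L); b2 <- c(50L, 95L, 130L)
  lp <- loops_from_bins(b1, b2, 2e4)
  pile <- loop_pileup(oe, lp, w_bins = 6)
  expect_equal(pile$pileup, oracle_window_mean(vals, cbind(b1, b2), 6),
               tolerance = 1e-12)

  # two identical windows -> the pileup equals either window
  vals2 <- matrix(1, 100, 100)
  vals2[21:31, 61:71] <- 5
  vals2[41:51, 81:91] <- 5
  oe2 <- fake_oe(vals2, bin_size = 2e4)
  pile2 <- loop_pileup(oe2, loops_from_bins(c(25L, 45L), c(65L, 85L), 2e4),
                       w_bins = 5)
  expect_equal(pile2$pileup, vals2[21:31, 61:71])

  # out-of-range windows are dropped and counted; all-dropped errors
  pile3 <- loop_pileup(oe2, loops_from_bins(c(25L, 2L), c(65L, 98L), 2e4),
                       w_bins = 5)
  expect_equal(pile3$n_dropped, 1)
  expect_error(loop_pileup(oe2, loops_from_bins(1L, 99L, 2e4), w_bins = 5),
               "zero retained")
})

test_that("loop-line extraction and comparison identities", {
  set.seed(62)
  g <- exp(-outer((-5:5)^2, rep(1, 11)) / 8 - outer(rep(1, 11), (-5:5)^2) / 8)
  pile <- structure(list(pileup = 1 + 2 * g, n_loops = 10L, n_dropped = 0L,
                         w_bins = 5L, bin_size = 2e4), class = "loop_pileup")
  ln <- loop_line(pile)
  expect_equal(nrow(ln), 11)
  expect_equal(ln$value[6], pile$pileup[6, 6])       # centre = loop pixel
  expect_equal(which.max(ln$value), 6L)              # maximal at k = 0

  # transpose-symmetric pileup: loop-line invariant under transposition
  pile_t <- pile; pile_t$pileup <- t(pile$pileup)
  expect_equal(loop_line(pile_t)$value, ln$value)

  expect_true(all(loopline_ratio(ln, ln)$ratio == 1))
  expect_true(all(loopline_difference(ln, ln)$diff == 0))
  short <- ln[1:5, ]; class(short) <- class(ln)
  expect_error(loopline_ratio(short, ln), "mismatch")

  # near-zero reference values are masked in the ratio
  ln_low <- ln; ln_low$value <- c(1e-6, ln$value[-1])
  r <- loopline_ratio(ln, ln_low)
  expect_true(is.na(r$ratio[1]))
})

test_that("size stratification is a partition with the stated strata", {
  lp <- loops_from_bins(c(0L, 0L, 0L, 0L), c(15L, 25L, 50L, 4L), 2e4)
  # sizes: 300 kb, 500 kb, 1 Mb, 80 kb
  expect_equal(lp$size_class,
               c("100kb-500kb", "500kb-1Mb", ">1Mb", NA))
  st <- stratify_by_size(lp)
  expect_equal(attr(st, "n_excluded"), 1L)
  expect_equal(sum(attr(st, "class_counts")) + attr(st, "n_excluded"), nrow(lp))
  expect_equal(as.integer(attr(st, "class_counts")), c(1L, 1L, 1L))
})

test_that("covariate ranking recovers a null and a true association", {
  set.seed(63)
  n <- 800
  n_loops <- 500
  b1 <- sample(10:(n - 60), n_loops)
  b2 <- b1 + sample(10:45, n_loops, replace = TRUE)
  ref_vals <- matrix(stats::rlnorm(n * n, 0, 0.05), n, n)
  ref_vals[cbind(b1 + 1, b2 + 1)] <- 2
  # treated: per-loop attenuation of the loop pixel
  atten <- stats::runif(n_loops, 0, 0.6)
  tr_vals <- matrix(stats::rlnorm(n * n, 0, 0.05), n, n)
  tr_vals[cbind(b1 + 1, b2 + 1)] <- 2 * (1 - atten)
  oe_ref <- fake_oe(ref_vals, bin_size = 2e4)
  oe_tr <- fake_oe(tr_vals, bin_size = 2e4)

  # covariate independent of the attenuation: null trend
  lp_null <- loops_from_bins(b1, b2, 2e4, covariate = stats::rlnorm(n_loops))
  rk <- rank_loops_by_covariate(oe_tr, oe_ref, lp_null, n_groups = 5, w_bins = 4)
  expect_lt(abs(rk$trend$rho), 0.1)

  # covariate equal to the true amplitude change: strong negative trend
  lp_true <- loops_from_bins(b1, b2, 2e4, covariate = atten)
  rk2 <- rank_loops_by_covariate(oe_tr, oe_ref, lp_true, n_groups = 5, w_bins = 4)
  expect_lt(rk2$trend$rho, -0.5)
  expect_lt(rk2$trend$p_value, 1e-6)

  # single group reduces to a plain comparison
  rk1 <- rank_loops_by_covariate(oe_tr, oe_ref, lp_null, n_groups = 1, w_bins = 4)
  expect_equal(unique(rk1$per_loop$group), 1L)

  # missing covariates are dropped and counted
  cv <- stats::rlnorm(n_loops); cv[1:7] <- NA
  lp_na <- loops_from_bins(b1, b2, 2e4, covariate = cv)
  rk3 <- rank_loops_by_covariate(oe_tr, oe_ref, lp_na, n_groups = 5, w_bins = 4)
  expect_gte(rk3$n_dropped, 7)
})

test_that("anchor signal summaries average the track around anchors", {
  lp <- loops_from_bins(c(10L, 30L), c(40L, 90L), 2e4)
  const <- rep(3.5, 120)
  s <- anchor_signal_summary(const, lp, flank_bp = 4e4, bin_size = 2e4)
  expect_equal(s$per_loop$anchor_mean, c(3.5, 3.5))

  set.seed(64)
  track <- stats::rnorm(120)
  s2 <- anchor_signal_summary(track, lp, flank_bp = 4e4, bin_size = 2e4)
  expect_equal(s2$per_loop$anchor1_mean[1], mean(track[(10 - 2):(10 + 2) + 1]))
  expect_equal(s2$per_loop$anchor2_mean[2], mean(track[(90 - 2):(90 + 2) + 1]))

  empty <- loop_set(tibble::tibble(chrom1 = character(), start1 = numeric(),
                                   end1 = numeric(), chrom2 = character(),
                                   start2 = numeric(), end2 = numeric()))
  s3 <- anchor_signal_summary(const, empty, flank_bp = 4e4, bin_size = 2e4)
  expect_equal(nrow(s3$per_loop), 0)
})

test_that("anchor midpoints on a bin edge resolve toward the lower bin", {
  ls <- loop_set(tibble::tibble(chrom1 = "c", start1 = 1e4, end1 = 3e4,
                                chrom2 = "c", start2 = 9e4, end2 = 11e4))
  lb <- loops_to_bins(ls, 2e4)   # midpoints 20 kb and 100 kb, both on edges
  expect_equal(lb$bin1, 0L)
  expect_equal(lb$bin2, 4L)
})
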
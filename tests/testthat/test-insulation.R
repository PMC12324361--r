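balanced_unit <- function(vals, bin_size = 1e4, ignore_diags = 0L) {
  contact_matrix(vals, bin_size = bin_size, weights = rep(1, nrow(vals)),
                 ignore_diags = ignore_diags)
}

test_that("insulation is zero on a uniform map and minimal at a block junction", {
  m <- balanced_unit(matrix(4, 60, 60))
  tr <- insulation(m, 1e5)
  expect_true(all(abs(tr$score[!is.na(tr$score)]) < 1e-12))

  # two blocks with no inter-block signal
  v <- matrix(0, 60, 60)
  v[1:30, 1:30] <- 2
  v[31:60, 31:60] <- 2
  v <- v + diag(60) * 0.1
  tr2 <- insulation(balanced_unit(v), 1e5)
  # the empty-diamond plateau spans the two bins flanking the junction
  expect_true(tr2$bin[which.min(tr2$score)] %in% c(29L, 30L))
})

test_that("insulation equals the nested-loop diamond oracle", {
  for (seed in 1:3) {
    vals <- random_symmetric_counts(40, lambda = 15, seed = seed)
    m <- balanced_unit(vals)
    w <- 5L
    tr <- insulation(m, w * 1e4)
    for (i0 in c(5L, 12L, 20L, 34L)) {
      expect_equal(tr$diamond[i0 + 1], oracle_diamond(vals, i0, w),
                   tolerance = 1e-12)
    }
    # with the short-range exclusion active
    m2 <- balanced_unit(vals, ignore_diags = 2L)
    tr2 <- insulation(m2, w * 1e4)
    for (i0 in c(6L, 15L, 28L)) {
      expect_equal(tr2$diamond[i0 + 1],
                   oracle_diamond(vals, i0, w, ignore = 2), tolerance = 1e-12)
    }
  }
  expect_error(insulation(balanced_unit(matrix(1, 30, 30)), 2e4),
               "at least 3 bins")
  expect_error(insulation(balanced_unit(matrix(1, 30, 30)), 2.5e4),
               "multiple")
})

test_that("Li threshold separates a bimodal strength distribution", {
  set.seed(41)
  weak <- stats::rlnorm(200, log(0.05), 0.3)
  strong <- stats::rlnorm(40, log(1.2), 0.2)
  x <- c(weak, strong)
  thr <- li_threshold(x)
  expect_gt(thr, max(weak))
  expect_lt(thr, min(strong))
  # the exhaustive minimum cross-entropy scan lands in the same gap and
  # classifies every observation identically
  scan <- oracle_li_scan(x)
  expect_gt(scan, max(weak))
  expect_lt(scan, min(strong))
  expect_equal(x > thr, x > scan)
})

test_that("boundary calling recovers simulated TAD boundaries", {
  cfg <- sim_config(n_bins = 600, bin_size = 1e4, depth = 3e6, seed = 17,
                    tad_boundaries = seq(0L, 600L, by = 50L),
                    loops = tibble::tibble(a1 = integer(), a2 = integer(),
                                           amplitude = numeric(), sigma = numeric()))
  m <- balance_matrix(simulate_map(cfg))
  bd <- call_boundaries(insulation(m, 1e5))
  truth <- setdiff(seq(0L, 600L, by = 50L), c(0L, 600L))
  recall <- mean(vapply(truth, function(b) any(abs(bd$bin - b) <= 1), logical(1)))
  spurious <- mean(vapply(bd$bin, function(b) !any(abs(truth - b) <= 1), logical(1)))
  expect_gte(recall, 0.9)
  expect_lte(spurious, 0.1)
})

test_that("a monotone insulation track yields no boundaries", {
  tr <- tibble::tibble(bin = 0:49, start = (0:49) * 1e4, end = (1:50) * 1e4,
                       score = seq(-1, 1, length.out = 50),
                       diamond = 1, n_valid = 25L)
  attr(tr, "window_bp") <- 5e4
  attr(tr, "bin_size") <- 1e4
  attr(tr, "chrom") <- "chrS"
  class(tr) <- c("insulation_track", class(tr))
  expect_warning(b <- call_boundaries(tr), "no local minima")
  expect_equal(nrow(b), 0)
})

test_that("boundary pileups average windows correctly", {
  # identical surroundings: the pileup equals any single window
  n <- 90
  base <- matrix(1, n, n)
  for (b in c(20L, 50L, 80L)) {
    idx <- (b - 5):(b + 5)
    base[idx, idx] <- base[idx, idx] + outer(1:11, 1:11) / 20
  }
  oe <- fake_oe(base, bin_size = 2e4)
  bp <- boundary_pileup(oe, c(20L, 50L), flank_bp = 1e5)
  w1 <- base[(20 - 5):(20 + 5) + 1, (20 - 5):(20 + 5) + 1]
  expect_equal(bp$pileup, w1, tolerance = 1e-12)
  expect_equal(bp$valley$value, diag(w1))

  # 600 kb flank at 20 kb bins: 61 x 61 window
  oe2 <- fake_oe(matrix(1, 200, 200), bin_size = 2e4)
  bp2 <- boundary_pileup(oe2, c(50L, 100L, 198L), flank_bp = 6e5)
  expect_equal(dim(bp2$pileup), c(61, 61))
  expect_equal(bp2$n_used, 2)      # window at bin 198 is incomplete
  expect_equal(bp2$n_dropped, 1)

  # random boundary set matches the brute-force window-mean oracle
  set.seed(6)
  vals <- matrix(stats::rlnorm(90 * 90, 0, 0.3), 90, 90)
  vals[sample(90 * 90, 200)] <- NA
  oe3 <- fake_oe(vals, bin_size = 2e4)
  bs <- c(15L, 30L, 61L)
  bp3 <- boundary_pileup(oe3, bs, flank_bp = 2e5)
  expect_equal(bp3$pileup, oracle_window_mean(vals, cbind(bs, bs), 10),
               tolerance = 1e-12)

  expect_error(boundary_pileup(oe2, c(2L), flank_bp = 6e5), "zero complete")
})

test_that("TAD intervals exclude boundary bins and never overlap", {
  tads <- tads_from_boundaries(c(10L, 30L, 55L), bin_size = 1e4)
  expect_equal(tads$start_bin, c(11L, 31L))
  expect_equal(tads$end_bin, c(29L, 54L))
  expect_equal(tads$start, c(11, 31) * 1e4)
  expect_equal(tads$end, c(30, 55) * 1e4)
  expect_true(all(tads$start_bin[-1] > tads$end_bin[-nrow(tads)]))
})
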
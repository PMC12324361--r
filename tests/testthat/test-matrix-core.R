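test_that("triplet files round-trip counts exactly and weights to 1e-12", {
  counts <- random_symmetric_counts(25, seed = 3)
  m <- contact_matrix(counts, bin_size = 1e4, chrom = "chrT")
  bal <- balance_matrix(m)
  path <- tempfile(fileext = ".tsv")
  write_contact_matrix(bal, path, seed = 3)
  back <- read_contact_matrix(path)
  expect_identical(back$counts, bal$counts)
  expect_equal(back$bin_size, 1e4)
  expect_identical(back$chrom, "chrT")
  expect_identical(back$mask, bal$mask)
  expect_equal(back$weights, bal$weights, tolerance = 1e-12)
  unlink(path)
})

test_that("mirrored duplicates collapse to one entry; conflicts are rejected with a line number", {
  p <- tempfile()
  writeLines(c("0\t1\t5", "1\t0\t5"), p)
  m <- read_contact_matrix(p, n_bins = 3, bin_size = 1e4)
  expect_equal(m$counts[1, 2], 5)
  expect_equal(m$counts[2, 1], 5)

  writeLines(c("0\t1\t5", "0\t1\t2"), p)   # same orientation: summed
  expect_equal(read_contact_matrix(p, n_bins = 3, bin_size = 1e4)$counts[1, 2], 7)

  writeLines(c("0\t1\t5", "1\t0\t7"), p)
  expect_error(read_contact_matrix(p, n_bins = 3, bin_size = 1e4),
               "line 2.*conflicting")

  writeLines("0\t1\t-2", p)
  expect_error(read_contact_matrix(p, n_bins = 3, bin_size = 1e4),
               "line 1.*negative")

  writeLines("0\t5\t2", p)
  expect_error(read_contact_matrix(p, n_bins = 3, bin_size = 1e4),
               "line 1.*out of range")

  writeLines(character(), p)
  m0 <- read_contact_matrix(p, n_bins = 4, bin_size = 1e4)
  expect_equal(m0$counts, matrix(0, 4, 4))
  unlink(p)
})

test_that("MAD-max masks zero/low-coverage bins and matches the stated rule", {
  n <- 30
  counts <- matrix(5, n, n)
  m <- contact_matrix(counts, bin_size = 1e4)
  expect_false(any(madmax_filter(m)))   # uniform coverage: nothing masked

  counts2 <- counts
  counts2[4, ] <- 0; counts2[, 4] <- 0
  m2 <- contact_matrix(counts2, bin_size = 1e4)
  msk <- madmax_filter(m2)
  expect_true(msk[4])
  expect_equal(sum(msk), 1)

  for (seed in 1:5) {
    counts3 <- random_symmetric_counts(50, lambda = 8, seed = seed)
    counts3[seed, ] <- counts3[seed, ] %/% 50   # one starved bin
    counts3[, seed] <- t(counts3)[, seed]
    m3 <- contact_matrix(counts3, bin_size = 1e4)
    expect_identical(madmax_filter(m3, madmax = 3),
                     oracle_madmax(m3$counts, 3))
  }
})

test_that("ICE balancing matches Sinkhorn and honours its contracts", {
  # fixed point: already balanced matrix gets equal weights
  n <- 12
  flat <- matrix(1, n, n)
  m <- contact_matrix(flat, bin_size = 1e4, ignore_diags = 0L)
  bal <- ice_balance(m, ignore_diags = 0)
  expect_equal(bal$weights, rep(1, n), tolerance = 1e-6)

  # random positive 6x6, no diagonal exclusion: matches brute-force Sinkhorn
  set.seed(8)
  x <- matrix(runif(36, 1, 10), 6, 6)
  x <- (x + t(x)) / 2
  mb <- ice_balance(contact_matrix(x, bin_size = 1e4, ignore_diags = 0L),
                    ignore_diags = 0, tol = 1e-12, max_iter = 10000)
  ours <- balanced_values(mb)
  ours <- ours / mean(rowSums(ours))          # scale to row sums 1
  expect_equal(ours, oracle_sinkhorn(x), tolerance = 1e-8)

  # masked bin: weight is NA, never 0
  counts <- random_symmetric_counts(20, seed = 2)
  mm <- apply_mask(contact_matrix(counts, bin_size = 1e4), seq_len(20) == 7)
  bb <- ice_balance(mm)
  expect_true(is.na(bb$weights[7]))
  expect_false(any(bb$weights[!bb$mask] == 0))

  # marginal CV < tol on every accepted run
  for (seed in 1:5) {
    cm <- ice_balance(contact_matrix(random_symmetric_counts(40, seed = seed),
                                     bin_size = 1e4))
    b <- balanced_values(cm)
    b[is.na(b)] <- 0
    d <- abs(outer(1:40, 1:40, "-"))
    b[d < cm$ignore_diags] <- 0
    marg <- rowSums(b)[!cm$mask]
    expect_lt(stats::sd(marg) / mean(marg), 1e-5)
  }

  # non-convergence is an error reporting the final CV
  expect_error(ice_balance(contact_matrix(random_symmetric_counts(30, seed = 1),
                                          bin_size = 1e4), max_iter = 1),
               "did not converge.*CV")
})

test_that("expected profile and O/E match the nested-loop oracle", {
  counts <- random_symmetric_counts(8, seed = 4)
  m <- balance_matrix(contact_matrix(counts, bin_size = 1e4))
  e <- expected_cis(m)
  expect_equal(e$expected,
               oracle_expected(balanced_values(m), m$mask, m$ignore_diags))

  # constant per diagonal => expected recovers it and O/E is identically 1
  n <- 10
  cvals <- 100 / (1 + abs(outer(1:n, 1:n, "-")))
  mc <- contact_matrix(cvals, bin_size = 1e4,
                       weights = rep(1, n), ignore_diags = 2L)
  ec <- expected_cis(mc)
  expect_equal(ec$expected[3:n], 100 / (1 + 2:(n - 1)))
  oe <- oe_transform(mc)
  defined <- !is.na(oe$oe)
  expect_equal(unique(round(oe$oe[defined], 12)), 1)

  # fully masked diagonal region: expected is NA, not 0
  msk <- rep(FALSE, 8); msk[c(1, 5)] <- TRUE
  m2 <- balance_matrix(apply_mask(contact_matrix(counts, bin_size = 1e4), msk))
  e2 <- expected_cis(m2)
  expect_true(all(is.na(e2$expected[1:2])))    # ignored diagonals stay NA
  expect_equal(e2$expected,
               oracle_expected(balanced_values(m2), m2$mask, m2$ignore_diags))
})

test_that("coarsening sums counts into blocks", {
  counts <- random_symmetric_counts(10, seed = 9)
  m <- contact_matrix(counts, bin_size = 1e4)
  cm <- coarsen_matrix(m, 5)
  expect_equal(dim(cm$counts), c(2, 2))
  expect_equal(cm$counts[1, 2], sum(counts[1:5, 6:10]))
  expect_equal(cm$bin_size, 5e4)
})
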
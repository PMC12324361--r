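# Independent brute-force oracles used to pin the vectorized implementations.
# All are deliberately written as plain nested loops over the definitions.

random_symmetric_counts <- function(n, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# per-diagonal mean of a (possibly NA-holding) matrix over unmasked pairs
oracle_expected <- function(vals, mask, ignore_diags) {
  n <- nrow(vals)
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    acc <- c()
    for (i in 1:(n - d)) {
      j <- i + d
      if (!mask[i] && !mask[j] && !is.na(vals[i, j])) acc <- c(acc, vals[i, j])
    }
    if (d >= ignore_diags && length(acc) > 0) out[d + 1] <- mean(acc)
  }
  out
}

# diamond sum at 0-based bin i0: rows (i0-w+1..i0) x cols (i0+1..i0+w),
# excluding pairs at separation < ignore
oracle_diamond <- function(vals, i0, w, ignore = 0) {
  s <- 0
  for (r in (i0 - w + 1):i0) {
    for (cc in (i0 + 1):(i0 + w)) {
      if (cc - r < ignore) next
      v <- vals[r + 1, cc + 1]
      if (!is.na(v)) s <- s + v
    }
  }
  s
}

# saddle aggregation: mean O/E per rank-group pair
oracle_saddle <- function(oe_vals, groups, n_groups) {
  S <- matrix(NA_real_, n_groups, n_groups)
  for (g1 in 1:n_groups) {
    for (g2 in 1:n_groups) {
      acc <- c()
      for (i in which(groups == g1)) {
        for (j in which(groups == g2)) {
          v <- oe_vals[i, j]
          if (!is.na(v)) acc <- c(acc, v)
        }
      }
      if (length(acc) > 0) S[g1, g2] <- mean(acc)
    }
  }
  S
}

# pixelwise mean of windows centred at 0-based (r, c) pairs
oracle_window_mean <- function(vals, centres, w) {
  side <- 2 * w + 1
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  for (k in seq_len(nrow(centres))) {
    for (a in -w:w) {
      for (b in -w:w) {
        v <- vals[centres[k, 1] + a + 1, centres[k, 2] + b + 1]
        if (!is.na(v)) {
          acc[a + w + 1, b + w + 1] <- acc[a + w + 1, b + w + 1] + v
          cnt[a + w + 1, b + w + 1] <- cnt[a + w + 1, b + w + 1] + 1
        }
      }
    }
  }
  ifelse(cnt > 0, acc / cnt, NA_real_)
}

# exhaustive two-sided permutation rank-sum test (no-tie data)
oracle_wilcox <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # W for the first group
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  list(statistic = w_obs, p_value = p)
}

# plain symmetric Sinkhorn iteration on a positive matrix (no diagonal
# exclusion): converges to the doubly stochastic scaling (row sums 1)
oracle_sinkhorn <- function(x, iters = 10000) {
  T <- x
  for (k in seq_len(iters)) {
    m <- rowSums(T)
    T <- T / sqrt(outer(m, m))
  }
  T
}

# MAD-max rule spelled out
oracle_madmax <- function(counts, p) {
  cov <- rowSums(counts)
  lc <- log(cov[cov > 0])
  thr <- median(lc) - p * mad(lc)
  cov == 0 | (cov > 0 & log(cov) < thr)
}

# exhaustive Li minimum-cross-entropy threshold search
oracle_li_scan <- function(x) {
  x <- sort(x[x > 0])
  cand <- (x[-1] + x[-length(x)]) / 2
  ce <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) return(Inf)
    -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
  }, numeric(1))
  cand[which.min(ce)]
}

# geometric distance binning of per-diagonal means, spelled out
oracle_ps_bins <- function(vals, bin_size, bins_per_decade, ignore_diags = 2) {
  n <- nrow(vals)
  e <- oracle_expected(vals, rep(FALSE, n), ignore_diags)
  nv <- sapply(0:(n - 1), function(d) n - d)
  s <- (0:(n - 1)) * bin_size
  ok <- !is.na(e) & s > 0
  s <- s[ok]; e <- e[ok]; nv <- nv[ok]
  lo <- log10(min(s)); hi <- log10(max(s))
  edges <- 10^seq(lo, hi + 1 / bins_per_decade, by = 1 / bins_per_decade)
  grp <- findInterval(s, edges, rightmost.closed = TRUE)
  p <- tapply(seq_along(s), grp, function(i) {
    pos <- e[i] > 0
    if (!any(pos)) return(0)
    exp(sum(log(e[i][pos]) * nv[i][pos]) / sum(nv[i][pos]))
  })
  sb <- tapply(seq_along(s), grp, function(i) exp(sum(log(s[i]) * nv[i]) / sum(nv[i])))
  ord <- order(as.numeric(sb))
  list(s_bp = as.numeric(sb)[ord], p = as.numeric(p)[ord])
}

# ideal two-corner checkerboard O/E field
checkerboard_oe <- function(e, aa = 2, ab = 0.5) {
  n <- length(e)
  v <- matrix(ab, n, n)
  v[outer(e, e) > 0] <- aa
  v
}

# wrap a plain matrix as an oe_matrix for unit tests
fake_oe <- function(vals, bin_size = 2e4, mask = NULL, chrom = "chrS") {
  structure(list(oe = vals, bin_size = bin_size, chrom = chrom,
                 n_bins = nrow(vals),
                 mask = if (is.null(mask)) rep(FALSE, nrow(vals)) else mask),
            class = "oe_matrix")
}

# build an eigen_track from raw values
fake_e1 <- function(values, bin_size = 1e5, chrom = "chrS") {
  n <- length(values)
  out <- tibble::tibble(bin = 0:(n - 1), start = (0:(n - 1)) * bin_size,
                        end = (1:n) * bin_size, e1 = values,
                        masked = is.na(values))
  attr(out, "bin_size") <- bin_size
  attr(out, "chrom") <- chrom
  attr(out, "method") <- "cor"
  class(out) <- c("eigen_track", class(out))
  out
}

# minimal loop_set straight from bin indices
loops_from_bins <- function(bin1, bin2, bin_size, ...) {
  ls <- loop_set(tibble::tibble(
    chrom1 = "chrS", start1 = bin1 * bin_size, end1 = (bin1 + 1) * bin_size,
    chrom2 = "chrS", start2 = bin2 * bin_size, end2 = (bin2 + 1) * bin_size,
    ...))
  loops_to_bins(ls, bin_size)
}
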
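#' Contact probability versus genomic separation, P(s)
#'
#' Averages the (balanced) signal over log-spaced distance bins. For a
#' `contact_matrix` the balanced signal is used and the first `ignore_diags`
#' diagonals are excluded; a plain matrix (e.g. a noise-free generator rate
#' matrix) is averaged as-is.
#'
#' Within each distance bin the per-diagonal means are combined by a
#' pair-weighted geometric mean (with the bin centre at the pair-weighted
#' geometric mean separation), which reproduces any power-law decay exactly
#' and therefore keeps the log-derivative free of within-bin binning bias;
#' all-zero diagonals are excluded from the geometric average.
#'
#' Normalization modes: `"ref"` scales the curve to unit value at `s_ref`
#' (log-log interpolated), `"area"` to unit sum, `"none"` leaves the
#' balanced scale. When comparing treatment conditions whose decay differs
#' at short range, anchor the curves at an unaffected separation (large
#' `s_ref`) so differences remain interpretable.
#'
#' @param x A `contact_matrix` or a plain symmetric matrix.
#' @param bins_per_decade Number of geometric distance bins per decade.
#' @param normalize One of `"ref"`, `"area"`, `"none"`.
#' @param s_ref Reference separation (bp) for `normalize = "ref"`.
#' @param ... Method arguments.
#' @return A tibble of class `ps_curve` with columns `s_bp`, `p`, `n_pairs`.
#' @export
ps_curve <- function(x, ...) UseMethod("ps_curve")

#' @rdname ps_curve
#' @export
ps_curve.contact_matrix <- function(x, bins_per_decade = 8,
                                    normalize = c("ref", "area", "none"),
                                    s_ref = 1e5, ...) {
  prof <- expected_cis(x)
  ps_from_profile(prof$s_bp, prof$expected, prof$n_valid,
                  bins_per_decade, match.arg(normalize), s_ref)
}

#' @rdname ps_curve
#' @param bin_size Bin width in bp (plain-matrix method).
#' @param ignore_diags Diagonals to exclude (plain-matrix method; default 2).
#' @export
ps_curve.matrix <- function(x, bin_size, bins_per_decade = 8,
                            normalize = c("ref", "area", "none"),
                            s_ref = 1e5, ignore_diags = 2L, ...) {
  n <- nrow(x)
  expected <- rep(NA_real_, n)
  n_valid <- integer(n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    v <- x[cbind(i, i + d)]
    ok <- !is.na(v)
    n_valid[d + 1L] <- sum(ok)
    if (d >= ignore_diags && any(ok)) expected[d + 1L] <- mean(v[ok])
  }
  ps_from_profile((0:(n - 1L)) * bin_size, expected, n_valid,
                  bins_per_decade, match.arg(normalize), s_ref)
}

ps_from_profile <- function(s_bp, expected, n_valid, bins_per_decade,
                            normalize, s_ref) {
  ok <- !is.na(expected) & n_valid > 0 & s_bp > 0
  if (sum(ok) < 3) stop("fewer than 3 diagonals with valid pairs")
  s <- s_bp[ok]; p <- expected[ok]; w <- n_valid[ok]
  lo <- log10(min(s)); hi <- log10(max(s))
  edges <- 10^seq(lo, hi + 1 / bins_per_decade, by = 1 / bins_per_decade)
  grp <- findInterval(s, edges, rightmost.closed = TRUE)
  agg <- function(f) as.numeric(tapply(seq_along(s), grp, f))
  # pair-weighted geometric averaging within each distance bin: exact on
  # power-law decays, so log-derivatives carry no within-bin binning bias
  p_bin <- agg(function(i) {
    pos <- p[i] > 0
    if (!any(pos)) return(0)
    exp(sum(log(p[i][pos]) * w[i][pos]) / sum(w[i][pos]))
  })
  s_bin <- agg(function(i) exp(sum(log(s[i]) * w[i]) / sum(w[i])))
  n_bin <- agg(function(i) sum(w[i]))
  keep <- !is.na(p_bin)
  out <- tibble::tibble(s_bp = s_bin[keep], p = p_bin[keep],
                        n_pairs = n_bin[keep])
  out <- out[order(out$s_bp), ]
  if (nrow(out) < 3) stop("fewer than 3 nonempty distance bins")
  if (all(out$p == 0)) stop("no nonzero signal in any distance bin")
  if (normalize == "ref") {
    ref_val <- exp(stats::approx(log(out$s_bp), log(pmax(out$p, .Machine$double.xmin)),
                                 xout = log(s_ref), rule = 2)$y)
    out$p <- out$p / ref_val
  } else if (normalize == "area") {
    out$p <- out$p / sum(out$p)
  }
  attr(out, "normalization") <- normalize
  attr(out, "s_ref") <- if (normalize == "ref") s_ref else NA_real_
  class(out) <- c("ps_curve", class(out))
  out
}

#' Log-derivative of a P(s) curve
#'
#' Central finite differences of `log10 P` with respect to `log10 s`,
#' followed by an optional centered moving-average smoothing of the slope
#' series (`smoothing_window` bins; 1 disables smoothing; edge windows are
#' truncated). Smoothing after differentiation keeps an exact power law's
#' derivative exact even though the log-spaced grid is uneven. Defined on
#' interior points only.
#'
#' @param curve A `ps_curve`.
#' @param smoothing_window Odd window length in curve bins (default 3).
#' @return A tibble of class `derivative_curve` with columns `s_bp`, `slope`.
#' @export
ps_derivative <- function(curve, smoothing_window = 3) {
  stopifnot(inherits(curve, "ps_curve"), smoothing_window >= 1,
            smoothing_window %% 2 == 1)
  keep <- curve$p > 0
  s <- curve$s_bp[keep]; p <- curve$p[keep]
  if (length(s) < 5) stop("need at least 5 positive points to differentiate")
  x <- log10(s); y <- log10(p)
  n <- length(x)
  i <- 2:(n - 1)
  slope <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  h <- (smoothing_window - 1) / 2
  if (h > 0) {
    m <- length(slope)
    slope <- vapply(seq_len(m),
                    function(k) mean(slope[max(1, k - h):min(m, k + h)]),
                    numeric(1))
  }
  out <- tibble::tibble(s_bp = s[i], slope = slope)
  attr(out, "smoothing_window") <- smoothing_window
  class(out) <- c("derivative_curve", class(out))
  out
}

#' Differential P(s) decomposition across cohesin states
#'
#' Computes, per separation, the treatment-induced P(s) difference in
#' cohesin-depleted cells divided by the difference in cohesin-intact cells:
#' `ratio(s) = [P_ctrl_depleted(s) - P_treated_depleted(s)] /
#' [P_ctrl_intact(s) - P_treated_intact(s)]`. The ratio isolates the
#' cohesin-independent share of the treatment effect; `1 - ratio(s)` is the
#' cohesin-attributable share. Values where the denominator magnitude falls
#' below `epsilon_frac` of its maximum are masked (the denominator is
#' reported for diagnostics).
#'
#' Curves on different distance grids are resampled onto the first curve's
#' grid (linear interpolation of P in log s, restricted to the overlap).
#' All four curves must share a normalization anchored at separations the
#' treatment does not affect.
#'
#' @param ps_ctrl_intact,ps_treated_intact P(s) with cohesin present.
#' @param ps_ctrl_depleted,ps_treated_depleted P(s) with cohesin depleted.
#' @param epsilon_frac Masking threshold as a fraction of the maximum
#'   absolute denominator (default 0.01).
#' @return A tibble of class `delta_ratio_curve` with columns `s_bp`,
#'   `ratio`, `delta_intact`, `delta_depleted`, `masked`.
#' @export
delta_ratio <- function(ps_ctrl_intact, ps_treated_intact,
                        ps_ctrl_depleted, ps_treated_depleted,
                        epsilon_frac = 0.01) {
  curves <- list(ps_ctrl_intact, ps_treated_intact,
                 ps_ctrl_depleted, ps_treated_depleted)
  stopifnot(all(vapply(curves, inherits, logical(1), "ps_curve")))
  grid <- curves[[1]]$s_bp
  same <- vapply(curves, function(cv)
    length(cv$s_bp) == length(grid) && all(cv$s_bp == grid), logical(1))
  if (!all(same)) {
    lo <- max(vapply(curves, function(cv) min(cv$s_bp), numeric(1)))
    hi <- min(vapply(curves, function(cv) max(cv$s_bp), numeric(1)))
    grid <- grid[grid >= lo & grid <= hi]
    if (length(grid) < 3) stop("distance grids do not overlap after resampling")
    curves <- lapply(curves, function(cv) {
      p <- stats::approx(log(cv$s_bp), cv$p, xout = log(grid))$y
      tibble::tibble(s_bp = grid, p = p)
    })
  }
  p <- lapply(curves, `[[`, "p")
  den <- p[[1]] - p[[2]]
  num <- p[[3]] - p[[4]]
  eps <- epsilon_frac * max(abs(den), 0, na.rm = TRUE)
  masked <- is.na(den) | abs(den) <= eps | den == 0
  ratio <- ifelse(masked, NA_real_, num / den)
  out <- tibble::tibble(s_bp = grid, ratio = ratio, delta_intact = den,
                        delta_depleted = num, masked = masked)
  attr(out, "epsilon") <- eps
  class(out) <- c("delta_ratio_curve", class(out))
  out
}
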
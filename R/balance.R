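#' MAD-max coverage filter
#'
#' Flags low-coverage bins the way the MAD-max filter does: a bin is masked
#' when its marginal coverage falls below
#' `median * exp(-madmax * MAD)` computed in log-coverage space (MAD with the
#' usual 1.4826 normal-consistency constant). Zero-coverage bins are always
#' masked.
#'
#' @param mat A `contact_matrix`.
#' @param madmax Filter constant in log-coverage MAD units (default 5).
#' @return Logical vector, `TRUE` for masked bins.
#' @export
madmax_filter <- function(mat, madmax = 5) {
  stopifnot(inherits(mat, "contact_matrix"))
  cov <- rowSums(mat$counts)
  if (all(cov == 0)) stop("all bins have zero coverage; increase depth")
  lc <- log(cov[cov > 0])
  thr <- stats::median(lc) - madmax * stats::mad(lc)
  mask <- cov == 0 | (cov > 0 & log(pmax(cov, .Machine$double.xmin)) < thr)
  if (all(mask))
    stop("MAD-max filter masked every bin; increase sequencing depth")
  mask
}

#' Apply a bin mask to a contact matrix
#'
#' Returns a copy of the matrix with the given bins excluded (existing mask
#' is OR-ed in) and any stale balancing weights dropped.
#'
#' @param mat A `contact_matrix`.
#' @param mask Logical vector of length `n_bins`.
#' @return A `contact_matrix`.
#' @export
apply_mask <- function(mat, mask) {
  stopifnot(inherits(mat, "contact_matrix"), length(mask) == mat$n_bins)
  contact_matrix(mat$counts, bin_size = mat$bin_size, chrom = mat$chrom,
                 mask = mat$mask | mask, ignore_diags = mat$ignore_diags)
}

#' Iterative correction (ICE) balancing
#'
#' Iteratively equalizes the marginals of the unmasked submatrix, excluding
#' the first `ignore_diags` diagonals (short-range ligation artefacts).
#' Convergence is declared when the coefficient of variation of the balanced
#' marginals drops below `tol`; the per-bin weights are then rescaled so
#' their mean over unmasked bins is 1. Unmasked bins with zero marginal on
#' the reduced matrix are added to the mask (they cannot be balanced).
#'
#' @param mat A `contact_matrix` (mask already applied, e.g. via
#'   [madmax_filter()] and [apply_mask()]).
#' @param ignore_diags Diagonals to exclude (default: the matrix's setting,
#'   normally 2).
#' @param tol Convergence tolerance on the marginal CV.
#' @param max_iter Maximum iterations; non-convergence is an error reporting
#'   the final CV.
#' @return A `contact_matrix` with `weights` filled in (`NA` on masked bins,
#'   never 0).
#' @export
ice_balance <- function(mat, ignore_diags = NULL, tol = 1e-5, max_iter = 200) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (is.null(ignore_diags)) ignore_diags <- mat$ignore_diags
  ignore_diags <- as.integer(ignore_diags)
  n <- mat$n_bins
  x <- mat$counts
  if (ignore_diags > 0) {
    for (d in 0:(ignore_diags - 1L)) {
      i <- seq_len(n - d)
      x[cbind(i, i + d)] <- 0
      x[cbind(i + d, i)] <- 0
    }
  }
  mask <- mat$mask
  x[mask, ] <- 0
  x[, mask] <- 0
  mask <- mask | rowSums(x) == 0   # unbalanceable bins
  x[mask, ] <- 0
  x[, mask] <- 0
  active <- !mask
  if (!any(active)) stop("no balanceable bins left after masking")

  b <- rep(1, n)
  cv <- Inf
  for (it in seq_len(max_iter)) {
    invb <- 1 / b
    m <- as.vector(x %*% invb) * invb
    ma <- m[active]
    cv <- stats::sd(ma) / mean(ma)
    if (is.finite(cv) && cv < tol) break
    b[active] <- b[active] * ma / mean(ma)
  }
  if (!is.finite(cv) || cv >= tol)
    stop(sprintf("ICE did not converge in %d iterations (final marginal CV = %.3g)",
                 max_iter, cv))
  w <- 1 / b
  w <- w / mean(w[active])
  w[!active] <- NA_real_
  contact_matrix(mat$counts, bin_size = mat$bin_size, chrom = mat$chrom,
                 weights = w, mask = mask, ignore_diags = ignore_diags)
}

#' Distance-decay expected profile
#'
#' Per-diagonal mean of the balanced signal over pairs of unmasked bins.
#' Diagonals below `ignore_diags` and diagonals with no valid pair are
#' reported as `NA` (missing, never 0).
#'
#' @param mat A balanced `contact_matrix`.
#' @return A tibble of class `expected_profile` with columns `diag`, `s_bp`,
#'   `expected`, `n_valid`.
#' @export
expected_cis <- function(mat) {
  stopifnot(inherits(mat, "contact_matrix"))
  b <- balanced_values(mat)
  n <- mat$n_bins
  expected <- rep(NA_real_, n)
  n_valid <- integer(n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    v <- b[cbind(i, i + d)]
    ok <- !is.na(v)
    n_valid[d + 1L] <- sum(ok)
    if (d >= mat$ignore_diags && any(ok)) expected[d + 1L] <- mean(v[ok])
  }
  out <- tibble::tibble(diag = 0:(n - 1L), s_bp = (0:(n - 1L)) * mat$bin_size,
                        expected = expected, n_valid = n_valid)
  attr(out, "bin_size") <- mat$bin_size
  attr(out, "ignore_diags") <- mat$ignore_diags
  attr(out, "chrom") <- mat$chrom
  class(out) <- c("expected_profile", class(out))
  out
}

#' Observed/expected transform
#'
#' Divides each balanced entry by the expected value at its genomic
#' separation. Entries on masked bins or on diagonals without a defined
#' expected are `NA`.
#'
#' @param mat A balanced `contact_matrix`.
#' @param expected An `expected_profile`; computed from `mat` when `NULL`.
#' @param scale Optional multiplier applied to the balanced signal before
#'   division (used when normalizing against another condition's expected).
#' @return An `oe_matrix` object wrapping the dense O/E matrix.
#' @export
oe_transform <- function(mat, expected = NULL, scale = 1) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (is.null(expected)) expected <- expected_cis(mat)
  n <- mat$n_bins
  if (nrow(expected) != n) stop("expected profile does not match matrix size")
  b <- balanced_values(mat) * scale
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e_lookup <- expected$expected
  e_lookup[!is.na(e_lookup) & e_lookup == 0] <- NA_real_
  emat <- matrix(e_lookup[d + 1L], n, n)
  oe <- b / emat
  structure(list(oe = oe, bin_size = mat$bin_size, chrom = mat$chrom,
                 n_bins = n, mask = mat$mask),
            class = "oe_matrix")
}

#' @export
print.oe_matrix <- function(x, ...) {
  cat(sprintf("<oe_matrix> %s: %d bins x %s bp\n", x$chrom, x$n_bins,
              format(x$bin_size, big.mark = ",")))
  invisible(x)
}

#' @export
as.matrix.oe_matrix <- function(x, ...) x$oe

#' Observed/expected against a reference condition
#'
#' For cross-condition comparisons of absolute contact levels (e.g. the
#' intra-TAD intensity decomposition), each condition is divided by the
#' *reference* condition's expected profile rather than its own, after
#' rescaling the balanced signal so that the two conditions agree at large
#' separations (where treatment effects on the decay vanish). A purely
#' distance-dependent treatment effect cancels in a per-sample O/E and would
#' be invisible; anchoring to a shared expected preserves it while removing
#' the arbitrary overall depth scale.
#'
#' @param mat A balanced `contact_matrix` for the condition of interest.
#' @param ref_expected The reference condition's [expected_cis()] profile.
#' @param anchor_bp Length-2 range of separations (bp) used to compute the
#'   rescaling factor; default `c(4e6, Inf)`, past the transition range of short-range treatment effects.
#' @return An `oe_matrix` with attribute `"scale"` recording the factor used.
#' @export
oe_vs_reference <- function(mat, ref_expected, anchor_bp = c(4e6, Inf)) {
  stopifnot(inherits(mat, "contact_matrix"),
            inherits(ref_expected, "expected_profile"))
  own <- expected_cis(mat)
  sel <- own$s_bp >= anchor_bp[1] & own$s_bp <= anchor_bp[2] &
    !is.na(own$expected) & !is.na(ref_expected$expected)
  if (!any(sel))
    stop("no diagonals with defined expected in the anchor range")
  w <- pmin(own$n_valid[sel], ref_expected$n_valid[sel])
  k <- sum(ref_expected$expected[sel] * w) / sum(own$expected[sel] * w)
  out <- oe_transform(mat, expected = ref_expected, scale = k)
  attr(out, "scale") <- k
  out
}
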
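#' Binned cis contact matrix
#'
#' The central container of the package: a symmetric matrix of contact counts
#' between fixed-size genomic bins on one chromosome, together with per-bin
#' balancing weights and a bin mask. Bins are 0-based and intervals are
#' half-open `[start, end)`; a genomic position maps to bin
#' `floor(pos / bin_size)`.
#'
#' @param counts Symmetric numeric matrix of non-negative counts.
#' @param bin_size Bin width in bp (> 0).
#' @param chrom Chromosome label.
#' @param weights Optional per-bin balancing weights (`NA` where masked).
#' @param mask Optional logical vector, `TRUE` for excluded bins.
#' @param ignore_diags Number of diagonals (starting at the main diagonal)
#'   excluded from balancing and expected profiles.
#'
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chrS",
                           weights = NULL, mask = NULL, ignore_diags = 2L) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  n <- nrow(counts)
  if (ncol(counts) != n) stop("`counts` must be square")
  if (any(counts < 0, na.rm = TRUE)) stop("`counts` must be non-negative")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8 * max(1, max(abs(counts))))
    stop("`counts` must be symmetric")
  if (!is.numeric(bin_size) || bin_size <= 0) stop("`bin_size` must be > 0")
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  if (!is.null(weights)) {
    stopifnot(length(weights) == n)
    if (any(!is.na(weights[mask])))
      stop("weights must be NA on masked bins")
  }
  structure(
    list(counts = counts, bin_size = as.numeric(bin_size), chrom = chrom,
         n_bins = n, weights = weights, mask = mask,
         ignore_diags = as.integer(ignore_diags)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins x %s bp (%s masked, %s)\n",
              x$chrom, x$n_bins, format(x$bin_size, big.mark = ","),
              sum(x$mask),
              if (is.null(x$weights)) "unbalanced" else "balanced"))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Balanced contact values
#'
#' Applies the ICE weights elementwise: `balanced[i, j] = counts[i, j] *
#' w[i] * w[j]`. Masked rows/columns are `NA`. Errors if the matrix has not
#' been balanced yet.
#'
#' @param mat A `contact_matrix` with weights (see [ice_balance()]).
#' @return A dense numeric matrix.
#' @export
balanced_values <- function(mat) {
  stopifnot(inherits(mat, "contact_matrix"))
  if (is.null(mat$weights))
    stop("matrix has no balancing weights; run ice_balance() first")
  w <- mat$weights
  b <- mat$counts * outer(w, w)
  b[mat$mask, ] <- NA_real_
  b[, mat$mask] <- NA_real_
  b
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums counts over `factor` x `factor` blocks of bins, e.g. to derive a
#' 100-kb matrix from a 10-kb one before compartment analysis. Weights and
#' mask are dropped; re-run filtering and balancing at the new resolution.
#'
#' @param mat A `contact_matrix`.
#' @param factor Integer aggregation factor (>= 2).
#' @return A `contact_matrix` at `bin_size * factor`.
#' @export
coarsen_matrix <- function(mat, factor) {
  stopifnot(inherits(mat, "contact_matrix"), factor >= 2)
  factor <- as.integer(factor)
  n <- mat$n_bins
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  m <- max(grp)
  agg <- rowsum(mat$counts, grp)            # collapse rows
  agg <- t(rowsum(t(agg), grp))             # collapse columns
  contact_matrix(agg, bin_size = mat$bin_size * factor, chrom = mat$chrom,
                 ignore_diags = mat$ignore_diags)
}
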
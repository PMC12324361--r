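#' Compartment eigenvector (E1)
#'
#' Leading eigenvector of the correlation structure of the O/E matrix over
#' unmasked bins, oriented so that its correlation with a per-bin covariate
#' (typically gene density, higher in active A compartments) is
#' non-negative. `method = "cor"` (default, the common toolchain convention)
#' decomposes the Pearson correlation matrix of O/E columns; `method = "oe"`
#' decomposes the centred O/E matrix directly. Undefined O/E entries inside
#' the unmasked submatrix (the ignored short-range diagonals) are treated as
#' neutral (1).
#'
#' @param oe An `oe_matrix`, typically at 100-kb resolution.
#' @param covariate Per-bin orientation covariate (length `n_bins`).
#' @param method `"cor"` or `"oe"`.
#' @return A tibble of class `eigen_track` with columns `bin`, `start`,
#'   `end`, `e1` (`NA` on masked bins), `masked`.
#' @export
compute_e1 <- function(oe, covariate, method = c("cor", "oe")) {
  stopifnot(inherits(oe, "oe_matrix"), length(covariate) == oe$n_bins)
  method <- match.arg(method)
  n <- oe$n_bins
  has_data <- colSums(!is.na(oe$oe)) > 0
  um <- which(!oe$mask & has_data)
  if (length(um) < 3) stop("degenerate matrix: fewer than 3 unmasked bins")
  M <- oe$oe[um, um, drop = FALSE]
  M[is.na(M)] <- 1
  if (method == "cor") {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0))
      stop("degenerate matrix: zero-variance O/E columns on unmasked bins")
    ev <- eigen(stats::cor(M), symmetric = TRUE)
  } else {
    ev <- eigen(M - mean(M), symmetric = TRUE)
  }
  v <- ev$vectors[, 1] * sqrt(max(ev$values[1], 0))
  cc <- suppressWarnings(stats::cor(v, covariate[um]))
  if (!is.na(cc) && cc < 0) v <- -v
  e1 <- rep(NA_real_, n)
  e1[um] <- v
  out <- tibble::tibble(bin = 0:(n - 1L),
                        start = (0:(n - 1L)) * oe$bin_size,
                        end = (1:n) * oe$bin_size,
                        e1 = e1, masked = is.na(e1))
  attr(out, "bin_size") <- oe$bin_size
  attr(out, "chrom") <- oe$chrom
  attr(out, "method") <- method
  class(out) <- c("eigen_track", class(out))
  out
}

#' Compartment boundaries from E1 sign changes
#'
#' Boundaries are placed at sign changes of E1 along each contiguous run of
#' defined bins. Any sign change lying within `min_separation` of another
#' sign change is removed, together with its close partner (both members of
#' each close pair are dropped), in a deterministic left-to-right scan over
#' the original change positions. Zero E1 values are treated as positive.
#'
#' @param track An `eigen_track`.
#' @param min_separation Minimum separation (bp) between retained sign
#'   changes; default 400 kb.
#' @return A tibble with columns `chrom`, `pos_bp`, `left_bin`, `right_bin`.
#' @export
call_compartment_boundaries <- function(track, min_separation = 4e5) {
  stopifnot(inherits(track, "eigen_track"))
  bs <- attr(track, "bin_size")
  chrom <- attr(track, "chrom")
  def <- which(!is.na(track$e1))
  changes <- integer(0)  # bin index of the left bin of each change
  if (length(def) >= 2) {
    runs <- split(def, cumsum(c(1L, diff(def) != 1L)))
    for (r in runs) {
      if (length(r) < 2) next
      sgn <- ifelse(track$e1[r] >= 0, 1L, -1L)
      flip <- which(sgn[-1] != sgn[-length(sgn)])
      changes <- c(changes, track$bin[r[flip]])
    }
  }
  if (length(changes) == 0)
    return(tibble::tibble(chrom = character(), pos_bp = numeric(),
                          left_bin = integer(), right_bin = integer()))
  changes <- sort(changes)
  pos <- (changes + 1) * bs
  close_prev <- c(FALSE, diff(pos) < min_separation)
  close_next <- c(diff(pos) < min_separation, FALSE)
  keep <- !(close_prev | close_next)
  tibble::tibble(chrom = chrom, pos_bp = pos[keep],
                 left_bin = as.integer(changes[keep]),
                 right_bin = as.integer(changes[keep]) + 1L)
}

#' Summaries of an E1 track
#'
#' Counts A bins (`e1 > 0`) and B bins (`e1 < 0`) among defined bins, and
#' histograms the E1 values (bin edges configurable and recorded).
#'
#' @param track An `eigen_track`.
#' @param breaks Histogram break points; default 25 equal bins spanning the
#'   observed range.
#' @return A list of class `e1_summary` with tibbles `summary`
#'   (`n_a`, `n_b`, `frac_a`) and `histogram` (`lower`, `upper`, `count`).
#' @export
e1_summary <- function(track, breaks = NULL) {
  stopifnot(inherits(track, "eigen_track"))
  v <- track$e1[!is.na(track$e1)]
  if (length(v) == 0) {
    warning("all bins masked; A and B counts are zero")
    return(structure(list(
      summary = tibble::tibble(n_a = 0L, n_b = 0L, frac_a = NA_real_),
      histogram = tibble::tibble(lower = numeric(), upper = numeric(),
                                 count = integer())),
      class = "e1_summary"))
  }
  if (is.null(breaks)) breaks <- seq(min(v), max(v), length.out = 26)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(
    summary = tibble::tibble(n_a = sum(v > 0), n_b = sum(v < 0),
                             frac_a = sum(v > 0) / sum(v != 0)),
    histogram = tibble::tibble(lower = h$breaks[-length(h$breaks)],
                               upper = h$breaks[-1], count = h$counts)),
    class = "e1_summary")
}

#' Saddle plot and compartmentalization strength
#'
#' Orders unmasked bins by a *reference* E1 ranking (always from a declared
#' reference condition, never recomputed per condition), groups them into
#' `n_groups` equal-occupancy rank bins, aggregates the O/E matrix over all
#' group pairs, and summarizes the `corner` x `corner` corner means:
#' strength of A-A interactions as AA/AB, of B-B as BB/BA, and combined
#' compartmentalization strength as (AA + BB)/(AB + BA). The result is
#' invariant under strictly monotone transforms of the ranking values.
#'
#' @param oe An `oe_matrix`.
#' @param reference_track An `eigen_track` from the reference condition.
#' @param n_groups Number of rank bins (default 50).
#' @param corner Corner size in rank bins (default 10).
#' @return A list of class `saddle_result`: `saddle` (ordered B-to-A
#'   aggregated matrix), `corners` and `strength` tibbles.
#' @export
saddle_strength <- function(oe, reference_track, n_groups = 50, corner = 10) {
  stopifnot(inherits(oe, "oe_matrix"), inherits(reference_track, "eigen_track"),
            nrow(reference_track) == oe$n_bins, corner < n_groups)
  has_data <- colSums(!is.na(oe$oe)) > 0
  valid <- which(!oe$mask & has_data & !is.na(reference_track$e1))
  if (length(valid) < n_groups)
    stop(sprintf("only %d usable bins for %d rank groups; use coarser binning",
                 length(valid), n_groups))
  g <- dplyr::ntile(reference_track$e1[valid], n_groups)
  P <- matrix(0, length(valid), n_groups)
  P[cbind(seq_along(valid), g)] <- 1
  O <- oe$oe[valid, valid, drop = FALSE]
  W <- !is.na(O)
  O[!W] <- 0
  S_sum <- t(P) %*% O %*% P
  S_n <- t(P) %*% W %*% P
  S <- ifelse(S_n > 0, S_sum / S_n, NA_real_)
  lo <- seq_len(corner)
  hi <- (n_groups - corner + 1L):n_groups
  BB <- mean(S[lo, lo], na.rm = TRUE); AA <- mean(S[hi, hi], na.rm = TRUE)
  AB <- mean(S[lo, hi], na.rm = TRUE); BA <- mean(S[hi, lo], na.rm = TRUE)
  structure(list(
    saddle = S,
    corners = tibble::tibble(corner = c("AA", "BB", "AB", "BA"),
                             mean_oe = c(AA, BB, AB, BA)),
    strength = tibble::tibble(aa_strength = AA / AB, bb_strength = BB / BA,
                              combined = (AA + BB) / (AB + BA)),
    n_groups = n_groups, corner_size = corner),
    class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat(sprintf("<saddle_result> %dx%d rank bins, %d-bin corners | AA/AB=%.3f BB/BA=%.3f combined=%.3f\n",
              x$n_groups, x$n_groups, x$corner_size,
              x$strength$aa_strength, x$strength$bb_strength,
              x$strength$combined))
  invisible(x)
}
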
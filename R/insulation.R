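#' Diamond insulation score
#'
#' For each bin `i`, sums the balanced signal over the `w` x `w`
#' off-diagonal diamond of pairs between bins `[i - w + 1, i]` and
#' `[i + 1, i + w]` (`w = window_bp / bin_size`), excluding pairs closer
#' than the matrix's `ignore_diags` separation. The score is `log2` of each
#' diamond sum relative to the chromosome mean diamond sum. Diamonds with
#' fewer than half their entries defined (masked bins) are `NA`, as are
#' bins within `w` of a chromosome end; partially masked diamonds are
#' rescaled to the full-diamond entry count.
#'
#' @param mat A balanced `contact_matrix`.
#' @param window_bp Diamond half-width in bp; must be a multiple of the bin
#'   size and at least 3 bins.
#' @return A tibble of class `insulation_track` with columns `bin`, `start`,
#'   `end`, `score`, `diamond`, `n_valid`.
#' @export
insulation <- function(mat, window_bp) {
  stopifnot(inherits(mat, "contact_matrix"))
  bs <- mat$bin_size
  if (abs(window_bp / bs - round(window_bp / bs)) > 1e-9)
    stop("`window_bp` must be a multiple of the bin size")
  w <- as.integer(round(window_bp / bs))
  if (w < 3) stop("insulation window must span at least 3 bins")
  n <- mat$n_bins
  b <- balanced_values(mat)
  val <- b; val[is.na(val)] <- 0
  def <- !is.na(b) * 1
  # summed-area tables for O(1) rectangle sums
  sat <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative
    t(cs)
  }
  Sv <- sat(val); Sd <- sat(def)
  rect <- function(S, r1, r2, c1, c2) {
    S[r2, c2] -
      (if (r1 > 1) S[r1 - 1, c2] else 0) -
      (if (c1 > 1) S[r2, c1 - 1] else 0) +
      (if (r1 > 1 && c1 > 1) S[r1 - 1, c1 - 1] else 0)
  }
  g <- mat$ignore_diags
  full <- w * w - max(0L, (g * (g - 1L)) %/% 2L)   # entries after short-range exclusion
  diamond <- rep(NA_real_, n)
  n_valid <- rep(NA_integer_, n)
  for (i0 in (w - 1L):(n - 1L - w)) {    # 0-based bin index
    r1 <- i0 - w + 2L; r2 <- i0 + 1L     # 1-based rows (i0-w+1..i0)+1
    c1 <- i0 + 2L; c2 <- i0 + 1L + w     # 1-based cols (i0+1..i0+w)+1
    nv <- rect(Sd, r1, r2, c1, c2)
    s <- rect(Sv, r1, r2, c1, c2)
    if (g > 1) {
      for (dd in 1:(g - 1L)) {           # drop pairs at separation < ignore_diags
        for (c0 in (i0 + 1L):(i0 + dd)) {
          rr <- c0 - dd + 1L; cc <- c0 + 1L
          nv <- nv - def[rr, cc]
          s <- s - val[rr, cc]
        }
      }
    }
    n_valid[i0 + 1L] <- nv
    if (nv >= full / 2) diamond[i0 + 1L] <- s * (full / nv)
  }
  mu <- mean(diamond, na.rm = TRUE)
  if (!is.finite(mu) || mu <= 0) stop("no valid insulation diamonds")
  out <- tibble::tibble(bin = 0:(n - 1L), start = (0:(n - 1L)) * bs,
                        end = (1:n) * bs, score = log2(diamond / mu),
                        diamond = diamond, n_valid = n_valid)
  attr(out, "window_bp") <- window_bp
  attr(out, "bin_size") <- bs
  attr(out, "chrom") <- mat$chrom
  class(out) <- c("insulation_track", class(out))
  out
}

#' Li minimum cross-entropy threshold
#'
#' Iterative minimum cross-entropy thresholding on a sample of positive
#' values: starting from the mean, alternately computes the below/above
#' means `m_b`, `m_f` and updates the threshold to
#' `(m_b - m_f) / (log m_b - log m_f)` until convergence.
#'
#' @param x Positive numeric values (non-positive values are dropped).
#' @param tol Convergence tolerance.
#' @return The threshold (scalar).
#' @export
li_threshold <- function(x, tol = 1e-8) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 2) return(if (length(x)) x / 2 else NA_real_)
  if (max(x) - min(x) < tol) return(mean(x))
  t_cur <- mean(x)
  for (it in 1:200) {
    below <- x[x <= t_cur]; above <- x[x > t_cur]
    if (length(below) == 0 || length(above) == 0) break
    mb <- mean(below); mf <- mean(above)
    t_new <- (mb - mf) / (log(mb) - log(mf))
    if (!is.finite(t_new)) break
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur
}

#' TAD boundary calling from an insulation track
#'
#' Boundaries are local minima of the insulation score. The diamond at bin
#' `i` measures contact flow between `[i - w + 1, i]` and `[i + 1, i + w]`,
#' so a minimum at `i` places the barrier between bins `i` and `i + 1`; the
#' reported boundary bin is `i + 1`, the first bin of the downstream TAD.
#' Each minimum's strength is its valley prominence: `min(left peak, right
#' peak) - valley`, where the peaks are the maximum scores within
#' `search_bins` on each side. Minima whose strength exceeds the Li minimum
#' cross-entropy threshold of the strength distribution are retained.
#'
#' Minima separated by fewer than `merge_bins` bins are treated as one
#' valley (a sharp junction produces a flat-bottomed valley two to three
#' bins wide whose bottom noise would otherwise split into twin calls);
#' only the deepest minimum of each such cluster is kept.
#'
#' @param track An `insulation_track`.
#' @param search_bins Peak search half-window in bins; defaults to the
#'   insulation window.
#' @param merge_bins Minima closer than this many bins are merged, keeping
#'   the deepest (default 3).
#' @return A tibble of class `boundary_set` with columns `bin`, `start`,
#'   `end`, `score`, `strength`; attribute `"threshold"` records the Li
#'   threshold.
#' @export
call_boundaries <- function(track, search_bins = NULL, merge_bins = 3L) {
  stopifnot(inherits(track, "insulation_track"))
  bs <- attr(track, "bin_size")
  if (is.null(search_bins))
    search_bins <- as.integer(round(attr(track, "window_bp") / bs))
  sc <- track$score
  n <- length(sc)
  def <- which(!is.na(sc))
  is_min <- rep(FALSE, n)
  for (j in def) {
    l <- if (j > 1) sc[j - 1] else NA
    r <- if (j < n) sc[j + 1] else NA
    if (!is.na(l) && !is.na(r) && sc[j] < l && sc[j] <= r) is_min[j] <- TRUE
  }
  mins <- which(is_min)
  if (length(mins) > 1 && merge_bins > 0) {
    cl <- cumsum(c(1L, diff(mins) >= merge_bins))
    mins <- vapply(split(mins, cl), function(g) g[which.min(sc[g])],
                   integer(1))
    mins <- unname(sort(mins))
  }
  if (length(mins) == 0) {
    warning("no local minima in insulation track; empty boundary set")
    out <- tibble::tibble(bin = integer(), start = numeric(), end = numeric(),
                          score = numeric(), strength = numeric())
    attr(out, "threshold") <- NA_real_
    class(out) <- c("boundary_set", class(out))
    return(out)
  }
  strength <- vapply(mins, function(j) {
    left <- sc[max(1, j - search_bins):(j - 1)]
    right <- sc[(j + 1):min(n, j + search_bins)]
    lmax <- suppressWarnings(max(left, na.rm = TRUE))
    rmax <- suppressWarnings(max(right, na.rm = TRUE))
    if (!is.finite(lmax) || !is.finite(rmax)) return(NA_real_)
    min(lmax, rmax) - sc[j]
  }, numeric(1))
  ok <- !is.na(strength)
  mins <- mins[ok]; strength <- strength[ok]
  thr <- li_threshold(strength)
  keep <- !is.na(thr) & strength > thr
  kept <- mins[keep]
  out <- tibble::tibble(bin = track$bin[kept] + 1L,
                        start = track$end[kept],
                        end = track$end[kept] + bs,
                        score = sc[kept],
                        strength = strength[keep])
  attr(out, "threshold") <- thr
  attr(out, "chrom") <- attr(track, "chrom")
  attr(out, "bin_size") <- bs
  class(out) <- c("boundary_set", class(out))
  out
}

#' Aggregate O/E windows at TAD boundaries
#'
#' Stacks `(2f + 1)` x `(2f + 1)` O/E windows centred on each boundary bin
#' (`f = flank_bp / bin_size`) from a *designated reference condition's*
#' boundary set, averages them pixel-wise (NA-aware), and extracts the
#' diagonal valley profile through the window centre. Windows extending past
#' the matrix are dropped and counted.
#'
#' @param oe An `oe_matrix`.
#' @param boundaries A `boundary_set` or integer vector of boundary bins
#'   (0-based).
#' @param flank_bp Flank on each side in bp (default 600 kb).
#' @return A list of class `boundary_pileup`: `pileup` matrix, `valley`
#'   tibble (`offset_bp`, `value`), `n_used`, `n_dropped`.
#' @export
boundary_pileup <- function(oe, boundaries, flank_bp = 6e5) {
  stopifnot(inherits(oe, "oe_matrix"))
  bins <- if (inherits(boundaries, "boundary_set")) boundaries$bin else as.integer(boundaries)
  f <- as.integer(round(flank_bp / oe$bin_size))
  n <- oe$n_bins
  complete <- bins - f >= 0L & bins + f <= n - 1L
  use <- bins[complete]
  if (length(use) == 0) stop("zero complete boundary windows")
  side <- 2L * f + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  for (b in use) {
    idx <- (b - f):(b + f) + 1L
    wdw <- oe$oe[idx, idx]
    ok <- !is.na(wdw)
    acc[ok] <- acc[ok] + wdw[ok]
    cnt <- cnt + ok
  }
  pile <- ifelse(cnt > 0, acc / cnt, NA_real_)
  valley <- tibble::tibble(offset_bp = ((-f):f) * oe$bin_size,
                           value = diag(pile))
  structure(list(pileup = pile, valley = valley,
                 n_used = length(use), n_dropped = sum(!complete),
                 flank_bp = flank_bp, bin_size = oe$bin_size),
            class = "boundary_pileup")
}

#' Coerce a data frame of TAD intervals to a `tad_set`
#'
#' Accepts any tibble with `start_bin` / `end_bin` (inclusive, 0-based)
#' columns, e.g. the ground-truth TAD table of [emit_ground_truth()].
#'
#' @param x A data frame with columns `start_bin`, `end_bin` and optionally
#'   `tad_id`, `chrom`, `start`, `end`.
#' @param bin_size Bin width in bp.
#' @return A `tad_set` tibble.
#' @export
as_tad_set <- function(x, bin_size) {
  stopifnot(all(c("start_bin", "end_bin") %in% names(x)))
  out <- tibble::tibble(
    tad_id = if ("tad_id" %in% names(x)) x$tad_id else seq_len(nrow(x)),
    chrom = if ("chrom" %in% names(x)) x$chrom else "chrS",
    start = x$start_bin * bin_size,
    end = (x$end_bin + 1) * bin_size,
    start_bin = as.integer(x$start_bin),
    end_bin = as.integer(x$end_bin))
  attr(out, "bin_size") <- bin_size
  class(out) <- c("tad_set", class(out))
  out
}

#' TAD intervals between consecutive boundaries
#'
#' Each TAD runs from the end of one boundary bin to the start of the next
#' (half-open, boundary bins excluded), so consecutive TADs never overlap.
#'
#' @param boundaries A `boundary_set` or integer vector of boundary bins
#'   (0-based), sorted.
#' @param bin_size Bin width in bp (taken from a `boundary_set` when absent).
#' @param chrom Chromosome label.
#' @param min_bins TADs narrower than this many interior bins are dropped.
#' @return A tibble of class `tad_set` with columns `tad_id`, `chrom`,
#'   `start`, `end`, `start_bin`, `end_bin` (inclusive interior bins).
#' @export
tads_from_boundaries <- function(boundaries, bin_size = NULL, chrom = NULL,
                                 min_bins = 1L) {
  if (inherits(boundaries, "boundary_set")) {
    if (is.null(bin_size)) bin_size <- attr(boundaries, "bin_size")
    if (is.null(chrom)) chrom <- attr(boundaries, "chrom")
    bins <- boundaries$bin
  } else bins <- as.integer(boundaries)
  if (is.null(chrom)) chrom <- "chrS"
  stopifnot(!is.null(bin_size))
  bins <- sort(unique(bins))
  if (length(bins) < 2) {
    out <- tibble::tibble(tad_id = integer(), chrom = character(),
                          start = numeric(), end = numeric(),
                          start_bin = integer(), end_bin = integer())
  } else {
    start_bin <- bins[-length(bins)] + 1L
    end_bin <- bins[-1] - 1L
    keep <- end_bin - start_bin + 1L >= min_bins
    out <- tibble::tibble(tad_id = seq_len(sum(keep)), chrom = chrom,
                          start = start_bin[keep] * bin_size,
                          end = (end_bin[keep] + 1L) * bin_size,
                          start_bin = start_bin[keep], end_bin = end_bin[keep])
  }
  attr(out, "bin_size") <- bin_size
  class(out) <- c("tad_set", class(out))
  out
}
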
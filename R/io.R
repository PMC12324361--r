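#' Read a sparse triplet contact matrix
#'
#' Reads `bin1<TAB>bin2<TAB>count` text (0-based bin indices). Lines starting
#' with `#` are header/provenance comments; headers written by
#' [write_contact_matrix()] carry `chrom`, `bin_size` and `n_bins`, which are
#' used when the corresponding arguments are missing. Duplicate records with
#' the same orientation are summed; a pair present in both orientations must
#' carry the same total on each side (mirrored storage of one symmetric
#' entry), otherwise the read is rejected naming the offending line.
#'
#' @param path File path.
#' @param n_bins,bin_size,chrom Matrix dimensions/metadata; required unless
#'   present in the file header.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, n_bins = NULL, bin_size = NULL,
                                chrom = NULL) {
  lines <- readr::read_lines(path)
  is_comment <- grepl("^#", lines)
  w_lines <- grep("^#w\t", lines, value = TRUE)
  m_lines <- grep("^#mask\t", lines, value = TRUE)
  for (h in setdiff(lines[is_comment], c(w_lines, m_lines))) {
    kv <- regmatches(h, gregexpr("[a-z_]+=[^ \t]+", h))[[1]]
    for (item in kv) {
      key <- sub("=.*", "", item); val <- sub(".*=", "", item)
      if (key == "n_bins" && is.null(n_bins)) n_bins <- as.integer(val)
      if (key == "bin_size" && is.null(bin_size)) bin_size <- as.numeric(val)
      if (key == "chrom" && is.null(chrom)) chrom <- val
    }
  }
  if (is.null(n_bins) || is.null(bin_size))
    stop("`n_bins` and `bin_size` must be given or present in the file header")
  if (is.null(chrom)) chrom <- "chrS"

  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  n <- as.integer(n_bins)
  counts <- matrix(0, n, n)
  if (length(body_idx) > 0) {
    fields <- strsplit(trimws(lines[body_idx]), "[ \t]+")
    bad_len <- lengths(fields) != 3L
    if (any(bad_len))
      stop(sprintf("line %d: expected 3 fields", body_idx[which(bad_len)[1]]))
    rec <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(rec))
      stop(sprintf("line %d: non-numeric field",
                   body_idx[which(rowSums(is.na(rec)) > 0)[1]]))
    bad_bin <- rec[, 1] < 0 | rec[, 2] < 0 | rec[, 1] >= n | rec[, 2] >= n
    if (any(bad_bin))
      stop(sprintf("line %d: bin index out of range [0, %d)",
                   body_idx[which(bad_bin)[1]], n))
    bad_cnt <- rec[, 3] < 0
    if (any(bad_cnt))
      stop(sprintf("line %d: negative count", body_idx[which(bad_cnt)[1]]))

    i <- as.integer(rec[, 1]); j <- as.integer(rec[, 2]); v <- rec[, 3]
    # accumulate per written orientation, then reconcile mirrored storage
    up <- i <= j
    key_as_written <- paste(i, j)
    upper_tot <- tapply(v[up], key_as_written[up], sum)
    lower_tot <- tapply(v[!up], paste(j[!up], i[!up]), sum)
    both <- intersect(names(upper_tot), names(lower_tot))
    conflict <- both[abs(upper_tot[both] - lower_tot[both]) > 1e-9]
    if (length(conflict) > 0) {
      ij <- as.integer(strsplit(conflict[1], " ")[[1]])
      bad_line <- body_idx[which(i == ij[2] & j == ij[1])[1]]
      stop(sprintf("line %d: asymmetric duplicate for bins (%d, %d) with conflicting values",
                   bad_line, ij[1], ij[2]))
    }
    vals <- c(upper_tot, lower_tot[setdiff(names(lower_tot), both)])
    ij <- do.call(rbind, strsplit(names(vals), " "))
    bi <- as.integer(ij[, 1]); bj <- as.integer(ij[, 2])
    counts[cbind(bi + 1L, bj + 1L)] <- vals
    counts[cbind(bj + 1L, bi + 1L)] <- vals
  }
  mask <- rep(FALSE, n)
  if (length(m_lines) > 0) {
    mb <- as.integer(vapply(strsplit(m_lines, "\t"), `[[`, "", 2))
    mask[mb + 1L] <- TRUE
  }
  weights <- NULL
  if (length(w_lines) > 0) {
    wf <- do.call(rbind, strsplit(w_lines, "\t"))
    weights <- rep(NA_real_, n)
    weights[as.integer(wf[, 2]) + 1L] <- as.numeric(wf[, 3])
  }
  contact_matrix(counts, bin_size = bin_size, chrom = chrom,
                 weights = weights, mask = mask)
}

#' Write a contact matrix as sparse triplet text
#'
#' Writes the non-zero upper triangle (including the diagonal) as
#' `bin1<TAB>bin2<TAB>count`, preceded by a provenance header with chromosome,
#' bin size, bin count and an optional seed / configuration hash. Balancing
#' weights and the bin mask, when present, are serialized as `#w` / `#mask`
#' comment records at full precision so balanced matrices round-trip.
#'
#' @param mat A `contact_matrix`.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields recorded in the header.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path, seed = NULL, config_hash = NULL) {
  stopifnot(inherits(mat, "contact_matrix"))
  hdr <- sprintf("# hicsig matrix chrom=%s bin_size=%s n_bins=%d%s%s",
                 mat$chrom, format(mat$bin_size, scientific = FALSE),
                 mat$n_bins,
                 if (is.null(seed)) "" else sprintf(" seed=%d", seed),
                 if (is.null(config_hash)) "" else sprintf(" config_hash=%s", config_hash))
  extra <- character()
  if (any(mat$mask))
    extra <- c(extra, sprintf("#mask\t%d", which(mat$mask) - 1L))
  if (!is.null(mat$weights)) {
    wi <- which(!is.na(mat$weights))
    extra <- c(extra, sprintf("#w\t%d\t%.17g", wi - 1L, mat$weights[wi]))
  }
  hdr <- c(hdr, extra)
  ut <- which(upper.tri(mat$counts, diag = TRUE) & mat$counts != 0,
              arr.ind = TRUE)
  body <- if (nrow(ut) > 0) {
    ord <- order(ut[, 1], ut[, 2])
    ut <- ut[ord, , drop = FALSE]
    sprintf("%d\t%d\t%s", ut[, 1] - 1L, ut[, 2] - 1L,
            format(mat$counts[ut], scientific = FALSE, trim = TRUE))
  } else character()
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

provenance_header <- function(what, seed = NULL, config_hash = NULL) {
  sprintf("# hicsig %s%s%s", what,
          if (is.null(seed)) "" else sprintf(" seed=%d", seed),
          if (is.null(config_hash)) "" else sprintf(" config_hash=%s", config_hash))
}

#' Interval and track writers (BED / BEDPE / bedGraph)
#'
#' Thin writers for the plain-text genomic formats the pipeline exchanges:
#' 0-based half-open intervals throughout. Each writer emits one provenance
#' comment line before the records.
#'
#' @param x A tibble with the columns named below.
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields.
#' @return `path`, invisibly.
#' @name interval_io
NULL

#' @rdname interval_io
#' @details `write_bed()` expects `chrom`, `start`, `end` and optionally
#'   `name` and `score`.
#' @export
write_bed <- function(x, path, seed = NULL, config_hash = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  stopifnot(all(c("chrom", "start", "end") %in% cols))
  lines <- do.call(paste, c(lapply(x[cols], format_plain), sep = "\t"))
  readr::write_lines(c(provenance_header("bed", seed, config_hash), lines), path)
  invisible(path)
}

#' @rdname interval_io
#' @details `write_bedpe()` expects `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`; remaining columns are appended in order.
#' @export
write_bedpe <- function(x, path, seed = NULL, config_hash = NULL) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  stopifnot(all(req %in% names(x)))
  cols <- c(req, setdiff(names(x), req))
  hdr <- c(provenance_header("bedpe", seed, config_hash),
           paste0("#", paste(cols, collapse = "\t")))
  lines <- if (nrow(x) > 0)
    do.call(paste, c(lapply(x[cols], format_plain), sep = "\t")) else character()
  readr::write_lines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname interval_io
#' @details `write_bedgraph()` expects `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(x, path, seed = NULL, config_hash = NULL) {
  req <- c("chrom", "start", "end", "value")
  stopifnot(all(req %in% names(x)))
  lines <- do.call(paste, c(lapply(x[req], format_plain), sep = "\t"))
  readr::write_lines(c(provenance_header("bedgraph", seed, config_hash), lines),
                     path)
  invisible(path)
}

#' @rdname interval_io
#' @param ... Passed on to [readr::read_tsv()].
#' @export
read_bedpe <- function(path, ...) {
  first <- readr::read_lines(path, n_max = 10)
  col_line <- grep("^#chrom1\t", first, value = TRUE)
  cols <- if (length(col_line) > 0) {
    strsplit(sub("^#", "", col_line[1]), "\t")[[1]]
  } else {
    c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  }
  x <- readr::read_tsv(path, comment = "#", col_names = cols,
                       show_col_types = FALSE, ...)
  x
}

#' @rdname interval_io
#' @export
read_bedgraph <- function(path, ...) {
  readr::read_tsv(path, comment = "#",
                  col_names = c("chrom", "start", "end", "value"),
                  show_col_types = FALSE, ...)
}

format_plain <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else as.character(v)
}
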
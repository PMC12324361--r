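#' Simulation configuration for synthetic contact maps
#'
#' Builds and validates the full parameter set of the synthetic Hi-C
#' generator. The generated rate matrix is a product of four components:
#' a power-law distance decay `B(s) = (s + s0)^(-alpha)`, a compartment
#' checkerboard `C(i,j) = max(0, 1 + gamma * e_i * e_j)`, a multiplicative
#' TAD factor `T(i,j) = 1 + tau` for bin pairs within the same TAD tile
#' (tiles `[b_k, b_{k+1})` between consecutive boundaries), and focal
#' Gaussian loop dots `L(i,j) = 1 + sum_k A_k * [g_k(i,a1) g_k(j,a2)
#' + g_k(i,a2) g_k(j,a1)]`. Three perturbations emulate the treatments the
#' package is designed to compare:
#'
#' * `"tsa"` (histone hyperacetylation): the intra-TAD cohesin component is
#'   retained at a fraction `tsa_tad_retention`, the short-range background
#'   is apodized by `tsa_background_scale(s)` (default 0.8 below 2 Mb,
#'   smoothly returning to 1), and loop amplitudes are multiplied by each
#'   loop's `tsa_amp_retention` (default 1: CTCF-CTCF dots preserved).
#' * `"cohesin_depleted"`: `tau = 0` and all loop amplitudes zero.
#' * `"tsa_and_depleted"`: both, i.e. `tau = 0`, amplitudes zero, and the
#'   background apodization applied.
#'
#' @param n_bins Number of bins on the simulated chromosome.
#' @param bin_size Bin width in bp.
#' @param alpha Power-law decay exponent (> 0).
#' @param s0 Decay offset in bp (>= 0).
#' @param compartment_profile Per-bin compartment value (typically in
#'   `{-1, +1}`); default: alternating 1-Mb blocks starting with A (+1).
#' @param gamma Compartment contrast (>= 0; < 1 recommended so the
#'   checkerboard never clips at zero).
#' @param tad_boundaries Strictly increasing bin indices in `[0, n_bins]`
#'   tiling the chromosome into TADs; default: consecutive domain sizes
#'   cycling through 150-400 kb.
#' @param tau Intra-TAD cohesin enrichment (>= 0). The default 4 yields an
#'   apparent intra-TAD O/E enrichment of roughly 1.5-2x after the expected
#'   profile absorbs part of the shared short-range signal, in line with
#'   typical mammalian Hi-C maps.
#' @param loops Tibble with columns `a1`, `a2` (anchor bins, `a1 < a2`),
#'   `amplitude`, `sigma` (bins), and optionally `covariate` and
#'   `tsa_amp_retention`; default: `default_loops()`.
#' @param depth Expected total read pairs when sampling counts.
#' @param seed Integer seed controlling sampling and the simulated covariate.
#' @param perturbation One of `"none"`, `"tsa"`, `"cohesin_depleted"`,
#'   `"tsa_and_depleted"`.
#' @param tsa_tad_retention Fraction of `tau` retained under TSA, in `[0, 1]`.
#' @param tsa_background_scale Function of distance (bp) returning a
#'   multiplier <= 1 at short range; default [tsa_background_profile()].
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_bins, bin_size = 1e4, alpha = 1, s0 = 1e4,
                       compartment_profile = NULL, gamma = 0.3,
                       tad_boundaries = NULL, tau = 4, loops = NULL,
                       depth = 1e7, seed = 1L,
                       perturbation = c("none", "tsa", "cohesin_depleted",
                                        "tsa_and_depleted"),
                       tsa_tad_retention = 0.8,
                       tsa_background_scale = tsa_background_profile()) {
  perturbation <- match.arg(perturbation)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 4, bin_size > 0, alpha >= 0, s0 >= 0, gamma >= 0,
            tau >= 0, depth >= 0,
            tsa_tad_retention >= 0, tsa_tad_retention <= 1)
  if (is.null(compartment_profile))
    compartment_profile <- default_compartments(n_bins, bin_size)
  stopifnot(length(compartment_profile) == n_bins,
            all(is.finite(compartment_profile)))
  if (is.null(tad_boundaries))
    tad_boundaries <- default_tad_boundaries(n_bins, bin_size)
  tad_boundaries <- as.integer(tad_boundaries)
  if (any(diff(tad_boundaries) <= 0))
    stop("`tad_boundaries` must be strictly increasing (overlapping TADs rejected)")
  if (any(tad_boundaries < 0) || any(tad_boundaries > n_bins))
    stop("`tad_boundaries` must lie within [0, n_bins]")
  if (is.null(loops)) loops <- default_loops(n_bins, bin_size, seed = seed)
  loops <- tibble::as_tibble(loops)
  if (nrow(loops) > 0) {
    stopifnot(all(c("a1", "a2", "amplitude", "sigma") %in% names(loops)))
    if (any(loops$a1 >= loops$a2)) stop("loop anchors must satisfy a1 < a2")
    if (any(loops$a1 < 0 | loops$a2 >= n_bins))
      stop("loop anchor outside matrix")
    if (any(loops$amplitude < 0) || any(loops$sigma <= 0))
      stop("loop amplitude must be >= 0 and sigma > 0")
  }
  if (!"tsa_amp_retention" %in% names(loops) && nrow(loops) > 0)
    loops$tsa_amp_retention <- 1
  if (!is.function(tsa_background_scale))
    stop("`tsa_background_scale` must be a function of distance in bp")
  structure(
    list(n_bins = n_bins, bin_size = as.numeric(bin_size), alpha = alpha,
         s0 = s0, compartment_profile = as.numeric(compartment_profile),
         gamma = gamma, tad_boundaries = tad_boundaries, tau = tau,
         loops = loops, depth = depth, seed = as.integer(seed),
         perturbation = perturbation, tsa_tad_retention = tsa_tad_retention,
         tsa_background_scale = tsa_background_scale),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d bins x %s bp | alpha=%.2f gamma=%.2f tau=%.2f | %d TADs, %d loops | %s\n",
    x$n_bins, format(x$bin_size, big.mark = ","), x$alpha, x$gamma, x$tau,
    max(0L, length(x$tad_boundaries) - 1L), nrow(x$loops), x$perturbation))
  invisible(x)
}

#' Smooth short-range background apodization profile
#'
#' Returns a function of genomic distance (bp) equal to `short_scale` well
#' below `s_mid`, rising smoothly (logistic, width `width`) to 1 beyond it.
#' This is the generator's model of a chromatin-decompaction effect that
#' reduces short-range (< 2 Mb) contact frequency uniformly along the genome.
#' `short_scale = 1` disables the effect.
#'
#' @param short_scale Multiplier at short range (<= 1).
#' @param s_mid Transition midpoint in bp.
#' @param width Logistic transition width in bp.
#' @return A vectorized function `f(s_bp)`.
#' @export
tsa_background_profile <- function(short_scale = 0.8, s_mid = 2e6,
                                   width = 2.5e5) {
  stopifnot(short_scale <= 1, short_scale > 0, s_mid > 0, width > 0)
  function(s_bp) short_scale + (1 - short_scale) * stats::plogis((s_bp - s_mid) / width)
}

default_compartments <- function(n_bins, bin_size, block_bp = 1e6) {
  block <- max(1L, as.integer(round(block_bp / bin_size)))
  e <- rep(c(1, -1), length.out = ceiling(n_bins / block))
  rep(e, each = block)[seq_len(n_bins)]
}

default_tad_boundaries <- function(n_bins, bin_size,
                                   sizes_bp = c(2.5e5, 1.5e5, 3e5, 2e5, 4e5, 3.5e5)) {
  sizes <- pmax(3L, as.integer(round(sizes_bp / bin_size)))
  b <- 0L
  repeat {
    nxt <- b[length(b)] + sizes[(length(b) - 1L) %% length(sizes) + 1L]
    if (nxt >= n_bins) break
    b <- c(b, nxt)
  }
  c(b, n_bins)
}

#' Default synthetic loop list
#'
#' Draws loop anchor pairs with log-uniform separations between 100 kb and
#' 1.5 Mb, constant amplitude and width, plus a log-normal per-loop covariate
#' emulating an anchor acetylation change that is independent of any
#' loop-strength change.
#'
#' @param n_bins,bin_size Chromosome geometry.
#' @param n_loops Number of loops.
#' @param amplitude,sigma Dot amplitude and Gaussian width (bins).
#' @param seed Seed for anchor placement and the covariate.
#' @return A loop tibble suitable for [sim_config()].
#' @export
default_loops <- function(n_bins, bin_size, n_loops = 40, amplitude = 6,
                          sigma = 1, seed = 1L) {
  set.seed(seed + 9173L)
  min_sep <- max(3L, as.integer(ceiling(1e5 / bin_size)))
  max_sep <- min(n_bins - 2L, as.integer(floor(1.5e6 / bin_size)))
  sep <- as.integer(round(exp(stats::runif(n_loops, log(min_sep), log(max_sep)))))
  a1 <- as.integer(floor(stats::runif(n_loops, 1, n_bins - sep - 1)))
  tibble::tibble(
    a1 = a1, a2 = a1 + sep, amplitude = amplitude, sigma = sigma,
    covariate = stats::rlnorm(n_loops, meanlog = 0, sdlog = 0.5),
    tsa_amp_retention = 1
  )
}

#' Build the noise-free contact rate matrix
#'
#' Evaluates the generator model (see [sim_config()]) including the
#' configured perturbation, returning the dense symmetric non-negative rate
#' matrix that [sample_counts()] draws Poisson counts from.
#'
#' @param config A `sim_config`.
#' @return A dense `n_bins` x `n_bins` numeric matrix.
#' @export
build_rate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_bins
  idx <- seq_len(n) - 1L
  d <- abs(outer(idx, idx, "-"))
  s_bp <- d * config$bin_size

  tsa_on <- config$perturbation %in% c("tsa", "tsa_and_depleted")
  depleted <- config$perturbation %in% c("cohesin_depleted", "tsa_and_depleted")
  tau_eff <- effective_tau(config)

  B <- (s_bp + config$s0)^(-config$alpha)
  if (config$s0 == 0) B[d == 0] <- config$bin_size^(-config$alpha)
  if (tsa_on) B <- B * config$tsa_background_scale(s_bp)

  e <- config$compartment_profile
  C <- pmax(0, 1 + config$gamma * outer(e, e))

  rate <- B * C
  if (tau_eff > 0) {
    tb <- config$tad_boundaries
    # TADs tile the chromosome: tile k covers bins [tb[k], tb[k+1]) so every
    # bin belongs to exactly one TAD and coverage has no dead boundary bins
    for (k in seq_len(length(tb) - 1L)) {
      ii <- (tb[k]:(tb[k + 1L] - 1L)) + 1L
      rate[ii, ii] <- rate[ii, ii] * (1 + tau_eff)
    }
  }
  if (!depleted && nrow(config$loops) > 0) {
    L <- matrix(0, n, n)
    for (k in seq_len(nrow(config$loops))) {
      lp <- config$loops[k, ]
      amp <- lp$amplitude * if (tsa_on) lp$tsa_amp_retention else 1
      if (amp <= 0) next
      g1 <- exp(-(idx - lp$a1)^2 / (2 * lp$sigma^2))
      g2 <- exp(-(idx - lp$a2)^2 / (2 * lp$sigma^2))
      L <- L + amp * (outer(g1, g2) + outer(g2, g1))
    }
    rate <- rate * (1 + L)
  }
  stopifnot(all(is.finite(rate)), all(rate >= 0))
  rate
}

effective_tau <- function(config) {
  switch(config$perturbation,
         none = config$tau,
         tsa = config$tau * config$tsa_tad_retention,
         cohesin_depleted = 0,
         tsa_and_depleted = 0)
}

#' Sample Poisson counts from a rate matrix
#'
#' Upper-triangle entries (diagonal included) are drawn independently from
#' Poisson distributions with means proportional to the rates, scaled so the
#' expected total count equals `depth`; the matrix is stored symmetrically.
#' Fixed `seed` gives identical matrices.
#'
#' @param rate Dense symmetric non-negative rate matrix.
#' @param depth Expected total read pairs (> 0).
#' @param seed Integer seed.
#' @param bin_size Bin width in bp for the resulting [contact_matrix()].
#' @param chrom Chromosome label.
#' @return A `contact_matrix` of sampled counts.
#' @export
sample_counts <- function(rate, depth, seed, bin_size, chrom = "chrS") {
  if (!is.numeric(depth) || depth <= 0) stop("`depth` must be > 0")
  n <- nrow(rate)
  ut <- upper.tri(rate, diag = TRUE)
  lambda <- rate[ut] * (depth / sum(rate[ut]))
  set.seed(as.integer(seed))
  draws <- stats::rpois(length(lambda), lambda)
  counts <- matrix(0, n, n)
  counts[ut] <- draws
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, bin_size = bin_size, chrom = chrom)
}

#' Simulate a contact map from a configuration
#'
#' Convenience wrapper: builds the rate matrix for `config` and samples
#' counts at `config$depth` with `config$seed`.
#'
#' @param config A `sim_config`.
#' @param chrom Chromosome label for the result.
#' @return A `contact_matrix`.
#' @export
simulate_map <- function(config, chrom = "chrS") {
  sample_counts(build_rate_matrix(config), depth = config$depth,
                seed = config$seed, bin_size = config$bin_size, chrom = chrom)
}

#' Ground truth annotations for a simulated chromosome
#'
#' Derives, deterministically from the configuration, everything the
#' parameter-recovery tests compare against: the true compartment profile,
#' TAD boundary and interval lists, the loop list with size class and the
#' simulated per-loop covariate, and the effective intra-TAD enrichment per
#' perturbation. Optionally serializes BED / BEDPE / bedGraph files with a
#' provenance header.
#'
#' @param config A `sim_config`.
#' @param dir Optional output directory; created if missing.
#' @param chrom Chromosome label used in the files.
#' @return A list of class `ground_truth` with elements `config`,
#'   `e1_truth`, `boundaries`, `tads`, `loops`, `enrichment`.
#' @export
emit_ground_truth <- function(config, dir = NULL, chrom = "chrS") {
  stopifnot(inherits(config, "sim_config"))
  bs <- config$bin_size
  n <- config$n_bins
  e1_truth <- tibble::tibble(
    chrom = chrom, start = (seq_len(n) - 1) * bs, end = seq_len(n) * bs,
    value = config$compartment_profile)
  tb <- config$tad_boundaries
  interior <- tb[tb > 0 & tb < n]
  boundaries <- tibble::tibble(
    chrom = chrom, start = interior * bs, end = (interior + 1) * bs,
    bin = interior)
  tads <- tibble::tibble(
    tad_id = seq_len(length(tb) - 1L),
    chrom = chrom,
    start = tb[-length(tb)] * bs,
    end = tb[-1] * bs,
    start_bin = tb[-length(tb)],
    end_bin = tb[-1] - 1L)
  loops <- config$loops
  loops_out <- if (nrow(loops) > 0) {
    sz <- (loops$a2 - loops$a1) * bs
    tibble::tibble(
      chrom1 = chrom, start1 = loops$a1 * bs, end1 = (loops$a1 + 1) * bs,
      chrom2 = chrom, start2 = loops$a2 * bs, end2 = (loops$a2 + 1) * bs,
      size = sz, size_class = loop_size_class(sz),
      amplitude = loops$amplitude,
      covariate = if ("covariate" %in% names(loops)) loops$covariate else NA_real_,
      tsa_amp_retention = loops$tsa_amp_retention)
  } else {
    tibble::tibble(chrom1 = character(), start1 = numeric(), end1 = numeric(),
                   chrom2 = character(), start2 = numeric(), end2 = numeric(),
                   size = numeric(), size_class = character(),
                   amplitude = numeric(), covariate = numeric(),
                   tsa_amp_retention = numeric())
  }
  enrichment <- tibble::tibble(
    perturbation = c("none", "tsa", "cohesin_depleted", "tsa_and_depleted"),
    tau_effective = c(config$tau, config$tau * config$tsa_tad_retention, 0, 0))
  gt <- structure(
    list(config = config, e1_truth = e1_truth, boundaries = boundaries,
         tads = tads, loops = loops_out, enrichment = enrichment),
    class = "ground_truth")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    h <- rlang::hash(config[setdiff(names(config), "tsa_background_scale")])
    write_bed(boundaries, file.path(dir, "boundaries_truth.bed"),
              seed = config$seed, config_hash = h)
    write_bedpe(loops_out, file.path(dir, "loops_truth.bedpe"),
                seed = config$seed, config_hash = h)
    write_bedgraph(e1_truth, file.path(dir, "e1_truth.bedgraph"),
                   seed = config$seed, config_hash = h)
    readr::write_tsv(enrichment, file.path(dir, "enrichment_truth.tsv"))
  }
  gt
}
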
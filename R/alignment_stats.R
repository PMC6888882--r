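#' Binary substitution/persistence sequence
#'
#' A pairwise alignment reduced to symbols over {0, 1}: 0 where the paired
#' residues are identical (a persistence), 1 where they differ (a
#' substitution). Identity is the fraction of 0s.
#'
#' @param symbols integer/numeric vector of 0s and 1s.
#' @param identity optional identity; computed as `1 - mean(symbols)` when
#'   missing.
#' @param source optional tag describing the origin of the alignment.
#' @export
binary_alignment <- function(symbols, identity = NULL, source = NA_character_) {
  symbols <- as.integer(symbols)
  if (any(is.na(symbols)) || !all(symbols %in% c(0L, 1L)))
    stop("symbols must be 0/1")
  if (is.null(identity)) identity <- 1 - mean(symbols)
  structure(list(symbols = symbols, identity = identity, source = source),
            class = "binary_alignment")
}

#' @export
print.binary_alignment <- function(x, ...) {
  cat(sprintf("binary_alignment: %d positions, identity %.4f\n",
              length(x$symbols), x$identity))
  invisible(x)
}

#' Translate a pairwise residue alignment to a binary sequence
#'
#' Only ungapped blocks are accepted; gaps must be removed (or filtered
#' upstream, e.g. keeping ungapped stretches of at least 80 residues) before
#' calling.
#'
#' @param seqA,seqB residue strings of equal length, no gap characters.
#' @return a [binary_alignment()].
#' @examples
#' binarize_alignment("ACDE", "ACDG") # 0 0 0 1, identity 0.75
#' @export
binarize_alignment <- function(seqA, seqB) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (any(c(a, b) %in% c("-", ".")))
    stop("gap characters are not allowed; pass ungapped blocks only")
  binary_alignment(as.integer(a != b))
}

#' Along-chain conditional substitution profile
#'
#' For every substitution (symbol 1) inside the trimmed region of each
#' alignment and every along-chain offset +/- d with the partner position also
#' inside the trimmed region, the partner's symbol increments N1(d) or N0(d).
#' The profile P(d) = N1 / (N0 + N1) is the conditional probability of
#' observing a substitution d sites away from another substitution, pooled
#' over all alignments. Ordered pairs are counted in both directions; P(d) is
#' invariant under that convention. Distances with no conditioning pairs have
#' `P = NaN` (flagged, never silently 0).
#'
#' @param alignments a [binary_alignment()] or list of them (0/1 vectors are
#'   also accepted).
#' @param d_max largest along-chain distance (default 30, the fitting range).
#' @param trim number of residues excluded at each end to reduce boundary
#'   effects (default 5).
#' @return object of class `conditional_profile`: a data frame with columns
#'   `d`, `N1`, `N0`, `P`.
#' @export
conditional_profile <- function(alignments, d_max = 30, trim = 5) {
  if (inherits(alignments, "binary_alignment")) alignments <- list(alignments)
  if (!is.list(alignments)) alignments <- list(alignments)
  if (d_max < 1) stop("d_max must be >= 1")
  symb <- lapply(alignments, function(a)
    if (inherits(a, "binary_alignment")) a$symbols else as.integer(a))
  usable <- vapply(symb, length, numeric(1)) > 2 * trim + 1
  if (!any(usable))
    stop("no alignment longer than the trimmed minimum 2*trim + 1")
  N1 <- N0 <- numeric(d_max)
  for (x in symb[usable]) {
    lo <- trim + 1L
    hi <- length(x) - trim
    for (d in seq_len(min(d_max, hi - lo))) {
      cs <- lo:(hi - d)
      centers <- cs[x[cs] == 1L]          # direction +d
      if (length(centers)) {
        hits <- sum(x[centers + d])
        N1[d] <- N1[d] + hits
        N0[d] <- N0[d] + length(centers) - hits
      }
      cs <- (lo + d):hi
      centers <- cs[x[cs] == 1L]          # direction -d
      if (length(centers)) {
        hits <- sum(x[centers - d])
        N1[d] <- N1[d] + hits
        N0[d] <- N0[d] + length(centers) - hits
      }
    }
  }
  out <- data.frame(d = seq_len(d_max), N1 = N1, N0 = N0,
                    P = ifelse(N1 + N0 > 0, N1 / (N1 + N0), NaN))
  attr(out, "trim") <- trim
  attr(out, "n_alignments") <- sum(usable)
  class(out) <- c("conditional_profile", "data.frame")
  out
}

#' Histogram of the number of substitutions per site
#'
#' @param counts non-negative integer per-site substitution counts (pool the
#'   two branches' sites by concatenating their count vectors).
#' @return object of class `substitution_histogram`: list with `k` (0..max),
#'   `counts` (n_k), `freq` (normalized), `mean_k`, `n_sites`.
#' @export
substitution_histogram <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("empty input")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  kmax <- max(counts)
  k <- 0:kmax
  n_k <- vapply(k, function(kk) sum(counts == kk), numeric(1))
  structure(list(k = k, counts = n_k, freq = n_k / sum(n_k),
                 mean_k = mean(counts), n_sites = length(counts)),
            class = "substitution_histogram")
}

#' @export
print.substitution_histogram <- function(x, ...) {
  cat(sprintf("substitution_histogram: %d sites, mean k = %.4f, k up to %d\n",
              x$n_sites, x$mean_k, max(x$k)))
  invisible(x)
}

#' Negative binomial probability of k substitutions at a site
#'
#' Parameterized by the shape `alpha` and the mean `mean_k`:
#' `p(k) = Gamma(alpha + k) / (Gamma(alpha) k!) *
#'   (mean_k / (mean_k + alpha))^k * (alpha / (mean_k + alpha))^alpha`,
#' the count distribution of a Poisson mixture with Gamma-distributed rates of
#' shape `alpha`. Evaluated through `stats::dnbinom(size = alpha, mu =
#' mean_k)`, which computes it in log-space. `alpha -> Inf` recovers
#' Poisson(mean_k).
#'
#' @param k non-negative integer(s).
#' @param alpha shape parameter (> 0).
#' @param mean_k mean number of substitutions per site (>= 0).
#' @export
negbinom_pmf <- function(k, alpha, mean_k) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive number")
  if (!is.numeric(mean_k) || length(mean_k) != 1 || mean_k < 0)
    stop("mean_k must be >= 0")
  if (mean_k == 0) return(as.numeric(k == 0))
  stats::dnbinom(k, size = alpha, mu = mean_k)
}

#' Fit the negative-binomial shape parameter alpha
#'
#' Weighted least-squares fit of the normalized histogram frequencies to
#' [negbinom_pmf()] with the mean constrained to the data mean, so only alpha
#' is optimized (mirroring a gnuplot weighted fit with Poisson errors on the
#' counts). Bin k gets standard deviation `sqrt(n_k)/N`; empty bins inside
#' the fitted range get one pseudo-count, `1/N`. The optimization is a
#' bounded 1-D search on log(alpha) over [1e-3, 1e6], robust to the flat
#' Poisson plateau at large alpha.
#'
#' @param x a [substitution_histogram()] or a vector of per-site counts.
#' @param mean_k mean constraint; defaults to the histogram mean.
#' @param alpha_bounds search interval for alpha.
#' @return object of class `negbinom_fit`: list with `alpha`, `mean_k`,
#'   `rms_residual` (unweighted rms of observed minus fitted frequencies over
#'   the fitted bins), `n_sites`.
#' @export
fit_alpha <- function(x, mean_k = NULL, alpha_bounds = c(1e-3, 1e6)) {
  if (!inherits(x, "substitution_histogram")) x <- substitution_histogram(x)
  if (sum(x$counts > 0) < 2)
    stop("histogram needs at least 2 occupied bins to fit alpha")
  if (is.null(mean_k)) mean_k <- x$mean_k
  if (mean_k <= 0) stop("mean_k must be > 0")
  N <- sum(x$counts)
  sd_k <- ifelse(x$counts > 0, sqrt(x$counts) / N, 1 / N)
  w <- 1 / sd_k^2
  obj <- function(la) {
    p <- negbinom_pmf(x$k, exp(la), mean_k)
    sum(w * (x$freq - p)^2)
  }
  opt <- stats::optimise(obj, interval = log(alpha_bounds), tol = 1e-7)
  alpha <- exp(opt$minimum)
  resid <- x$freq - negbinom_pmf(x$k, alpha, mean_k)
  structure(list(alpha = alpha, mean_k = mean_k,
                 rms_residual = sqrt(mean(resid^2)),
                 n_sites = x$n_sites, objective = opt$objective),
            class = "negbinom_fit")
}

#' @export
print.negbinom_fit <- function(x, ...) {
  cat(sprintf("negbinom_fit: alpha = %.4g (mean k = %.4g, %d sites, rms resid %.3g)\n",
              x$alpha, x$mean_k, x$n_sites, x$rms_residual))
  invisible(x)
}

#' Overlap ratio
#'
#' The number of sites substituted more than once divided by the number of
#' sites substituted at least once; a classic measure of substitution-rate
#' heterogeneity (molecular-clock overdispersion).
#'
#' @param counts per-site substitution counts.
#' @export
overlap_ratio <- function(counts) {
  counts <- as.numeric(counts)
  n1 <- sum(counts >= 1)
  if (n1 == 0) stop("overlap ratio undefined: no site substituted")
  sum(counts >= 2) / n1
}
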
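#' Simulate two branches diverging from a common equilibrated ancestor
#'
#' Both branches start from one equilibrated state (identical last-substitution
#' times) and evolve independently after the split -- no cross-branch rate
#' coupling. Sequence identity of the measured window is the fraction of
#' window sites never substituted in either branch, a lower bound on the true
#' identity since back and convergent substitutions are ignored; it is
#' non-increasing in time. The simulation stops at the first step where the
#' window identity falls to or below `target_identity`, or at
#' `config$max_time` (flagged, not an error).
#'
#' @param map a [contact_map()].
#' @param params [model_params()] or [two_class_params()].
#' @param config a [sim_config()].
#' @param target_identity stopping identity, in (0, 1).
#' @param window `c(start, length)`: the portion of the protein on which
#'   identity is measured (the whole map evolves). Default: the whole chain.
#' @param classes [site_classes()] for two-class parameters.
#' @param ancestor optional pre-equilibrated [chain_state()]; computed with
#'   [equilibrate()] when missing.
#' @param record_identities optional identity levels in (0, 1) at which a
#'   snapshot of the state (per-branch counts and the window substitution
#'   indicator) is recorded as the trajectory first crosses them.
#' @return an object of class `divergence_result`: list with `events` (data
#'   frame branch/site/time), `counts` (L x 2 matrix, branches A and B),
#'   `window`, `window_subs` (0/1 per window site: substituted in at least one
#'   branch), `identity`, `time`, `steps`, `multi_joint_steps` (steps with
#'   >= 2 substitutions summed over both branches), `multi_branch_steps`
#'   (steps where a single branch had >= 2), `reached_target`, and `snapshots`
#'   (one per recorded identity, `NULL` if never reached).
#' @export
simulate_divergence <- function(map, params, config, target_identity,
                                window = NULL, classes = NULL,
                                ancestor = NULL, record_identities = NULL) {
  stopifnot(inherits(map, "contact_map"), inherits(config, "sim_config"))
  if (target_identity <= 0 || target_identity >= 1)
    stop("target_identity must be in (0, 1)")
  if (is.null(window)) window <- c(1L, map$L)
  wstart <- as.integer(window[1]); wlen <- as.integer(window[2])
  if (wstart < 1 || wlen < 1 || wstart + wlen - 1 > map$L)
    stop("window out of range")
  thresholds <- sort(unique(c(record_identities, target_identity)),
                     decreasing = TRUE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("identity levels must be in (0, 1)")
  if (min(thresholds) < target_identity)
    stop("record_identities below target_identity would never be reached")
  if (is.null(ancestor)) ancestor <- equilibrate(map, params, config, classes)
  stopifnot(inherits(ancestor, "chain_state"), ancestor$L == map$L)
  base <- base_rates(params, map$L, classes)
  res <- cpp_simulate_pair(neighbor_list(map), base, params$J, config$dt,
                           ancestor$t_last, as.integer(ancestor$mutated),
                           wstart - 1L, wlen, thresholds, config$max_time)
  snaps <- res$snapshots
  names(snaps) <- formatC(thresholds, format = "f", digits = 4)
  structure(list(
    events = data.frame(branch = c("A", "B")[res$event_branch],
                        site = res$event_site, time = res$event_time),
    counts = cbind(A = res$counts_a, B = res$counts_b),
    window = c(start = wstart, length = wlen),
    window_subs = res$window_subs,
    identity = res$identity,
    time = res$time,
    steps = res$steps,
    multi_joint_steps = res$multi_joint_steps,
    multi_branch_steps = res$multi_branch_steps,
    reached_target = res$reached_target,
    snapshots = snaps,
    target_identity = target_identity,
    map_L = map$L), class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(paste0(
    "divergence_result: L = %d, window [%d, %d], identity %.4f",
    " (target %.4f%s)\n  %d events over %.1f time units (%g steps),",
    " multi-substitution steps: %.3g%%\n"),
    x$map_L, x$window[1], x$window[1] + x$window[2] - 1, x$identity,
    x$target_identity, if (x$reached_target) "" else ", max_time hit",
    nrow(x$events), x$time, x$steps,
    if (x$steps > 0) 100 * x$multi_joint_steps / x$steps else 0))
  invisible(x)
}

#' Run an ensemble of divergence simulations binned by sequence identity
#'
#' For each replicate a window length is sampled from `lengths`, a map at
#' least that long is sampled from `map_source`, a window is placed uniformly
#' at random, the chain is equilibrated and the two branches are evolved past
#' the lowest identity bin. As the trajectory first crosses each bin's
#' midpoint (the stand-in for the mean identity of a matching alignment set),
#' the window substitution pattern and the per-branch substitution counts are
#' recorded. Replicate r uses RNG seed `seed + r`, so results are reproducible
#' and independent of scheduling.
#'
#' @param map_source list of `list(map =, classes =)` entries (as returned by
#'   [synthetic_contact_map()]), or a single such entry.
#' @param lengths candidate window lengths (sampled uniformly unless
#'   `length_weights` is given). The default used by the fitting helpers is a
#'   uniform stand-in over 80-300.
#' @param params,config,classes as in [simulate_divergence()]; classes are
#'   taken per map from `map_source`.
#' @param bins two-column matrix (or list of `c(lo, hi)`) of non-overlapping
#'   identity bins, e.g. `rbind(c(.90,.92), c(.80,.82), c(.70,.72), c(.60,.62))`.
#' @param n_reps number of replicates.
#' @param seed integer base seed.
#' @param length_weights optional sampling weights for `lengths`.
#' @return object of class `divergence_ensemble`: per-bin lists of binary
#'   alignments (window substitution patterns) and pooled per-site
#'   substitution counts (both branches pooled as separate realizations).
#' @export
run_ensemble <- function(map_source, lengths, params, config, bins,
                         n_reps, seed = 1, length_weights = NULL) {
  if (!is.null(map_source$map)) map_source <- list(map_source)
  bins <- as_bins(bins)
  mids <- rowMeans(bins)
  ord <- order(mids, decreasing = TRUE)
  bins <- bins[ord, , drop = FALSE]
  mids <- mids[ord]
  map_L <- vapply(map_source, function(m) m$map$L, numeric(1))
  out <- lapply(seq_along(mids), function(i)
    list(alignments = list(), counts = integer(0), times = numeric(0)))
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    len <- if (length(lengths) == 1) lengths else
      sample(lengths, 1, prob = length_weights)
    cand <- which(map_L >= len)
    if (!length(cand)) {
      warning(sprintf("replicate %d skipped: no map of length >= %d", r, len))
      skipped <- skipped + 1L
      next
    }
    src <- map_source[[if (length(cand) == 1) cand else sample(cand, 1)]]
    wstart <- sample.int(src$map$L - len + 1L, 1)
    res <- simulate_divergence(src$map, params, config,
                               target_identity = min(mids),
                               window = c(wstart, len),
                               classes = src$classes,
                               record_identities = mids)
    widx <- wstart:(wstart + len - 1L)
    for (i in seq_along(mids)) {
      sn <- res$snapshots[[i]]
      if (is.null(sn)) next
      aln <- binary_alignment(sn$window_subs, source = sprintf("rep%d", r))
      out[[i]]$alignments <- c(out[[i]]$alignments, list(aln))
      out[[i]]$counts <- c(out[[i]]$counts,
                           sn$counts_a[widx], sn$counts_b[widx])
      out[[i]]$times <- c(out[[i]]$times, sn$time)
    }
  }
  structure(list(bins = bins, midpoints = mids, results = out,
                 n_reps = n_reps, skipped = skipped, seed = seed),
            class = "divergence_ensemble")
}

as_bins <- function(bins) {
  if (is.list(bins)) bins <- do.call(rbind, bins)
  bins <- as.matrix(bins)
  if (ncol(bins) != 2 || any(bins[, 1] >= bins[, 2]))
    stop("bins must be rows c(lo, hi) with lo < hi")
  o <- order(bins[, 1])
  if (any(bins[o, 1][-1] < bins[o, 2][-nrow(bins)]))
    stop("identity bins must not overlap")
  bins
}

#' @export
print.divergence_ensemble <- function(x, ...) {
  cat(sprintf("divergence_ensemble: %d replicates (%d skipped), %d bins\n",
              x$n_reps, x$skipped, nrow(x$bins)))
  for (i in seq_len(nrow(x$bins)))
    cat(sprintf("  bin [%.2f, %.2f]: %d alignments, %d pooled sites\n",
                x$bins[i, 1], x$bins[i, 2],
                length(x$results[[i]]$alignments),
                length(x$results[[i]]$counts)))
  invisible(x)
}

#' Conditional substitution profiles of an ensemble, one per identity bin
#'
#' @param ens a [run_ensemble()] result.
#' @param d_max,trim passed to [conditional_profile()].
#' @return named list of `conditional_profile` objects (names = bin midpoints).
#' @export
ensemble_profiles <- function(ens, d_max = 30, trim = 5) {
  stopifnot(inherits(ens, "divergence_ensemble"))
  prof <- lapply(ens$results, function(b) {
    if (!length(b$alignments)) return(NULL)
    conditional_profile(b$alignments, d_max = d_max, trim = trim)
  })
  names(prof) <- formatC(ens$midpoints, format = "f", digits = 4)
  prof
}

#' Per-bin summary statistics of an ensemble
#'
#' Fits the negative-binomial shape parameter alpha to the pooled
#' substitutions-per-site histogram of each bin and computes the overlap
#' ratio (sites substituted more than once over sites substituted at least
#' once), both on counts pooling the two branches as separate realizations.
#'
#' @param ens a [run_ensemble()] result.
#' @return data frame with one row per identity bin.
#' @export
ensemble_summary <- function(ens) {
  stopifnot(inherits(ens, "divergence_ensemble"))
  rows <- lapply(seq_along(ens$midpoints), function(i) {
    b <- ens$results[[i]]
    alpha <- mean_k <- ovl <- NA_real_
    if (length(b$counts) && any(b$counts >= 1)) {
      h <- substitution_histogram(b$counts)
      mean_k <- h$mean_k
      fit <- tryCatch(fit_alpha(h), error = function(e) NULL)
      if (!is.null(fit)) alpha <- fit$alpha
      ovl <- overlap_ratio(b$counts)
    }
    data.frame(bin_low = ens$bins[i, 1], bin_high = ens$bins[i, 2],
               midpoint = ens$midpoints[i],
               n_alignments = length(b$alignments),
               n_sites = length(b$counts), mean_k = mean_k,
               alpha = alpha, overlap_ratio = ovl)
  })
  do.call(rbind, rows)
}
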
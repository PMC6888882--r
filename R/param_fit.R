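#' RMSD between conditional profiles
#'
#' Root mean square displacement between model and reference P(d) over all
#' (bin, d) pairs with d = 1 .. d_max - 1, the objective minimized when
#' fitting (J, r0). Only distances shorter than `d_max` enter.
#'
#' @param model,reference single `conditional_profile` objects or named lists
#'   of them (one per identity bin; names must match).
#' @param d_max distances d < d_max are compared (default 30).
#' @export
profile_rmsd <- function(model, reference, d_max = 30) {
  as_list <- function(p) if (inherits(p, "conditional_profile")) list(p) else p
  model <- as_list(model); reference <- as_list(reference)
  if (length(model) != length(reference))
    stop("model and reference must have the same number of bins")
  dd <- seq_len(d_max - 1)
  pull <- function(p) {
    if (is.null(p)) stop("missing profile for a bin")
    v <- p$P[match(dd, p$d)]
    if (any(!is.finite(v)))
      stop("P(d) undefined for some required distance; cannot compute RMSD")
    v
  }
  sq <- mapply(function(m, r) (pull(m) - pull(r))^2, model, reference)
  sqrt(mean(unlist(sq)))
}

#' Objective specification for parameter fitting
#'
#' Bundles the reference profiles, identity bins and ensemble settings against
#' which (J, r0) are optimized.
#'
#' @param bins identity bins as in [run_ensemble()].
#' @param reference named list of reference `conditional_profile` objects, one
#'   per bin (ordered/named by bin midpoint as in [ensemble_profiles()]).
#' @param map_source,lengths,config,n_reps as in [run_ensemble()].
#' @param d_max,trim profile settings; d < d_max enters the RMSD.
#' @param seed base seed used for every objective evaluation (common random
#'   numbers: each parameter point is evaluated on the same replicate seeds,
#'   which is essential to tame Monte-Carlo noise in the objective).
#' @export
fit_objective_spec <- function(bins, reference, map_source, lengths,
                               config = sim_config(), n_reps = 8,
                               d_max = 30, trim = 5, seed = 1) {
  bins <- as_bins(bins)
  if (length(reference) != nrow(bins))
    stop("one reference profile per bin is required")
  structure(list(bins = bins, reference = reference, map_source = map_source,
                 lengths = lengths, config = config, n_reps = n_reps,
                 d_max = d_max, trim = trim, seed = seed),
            class = "fit_objective_spec")
}

#' Optimize the model parameters against reference profiles
#'
#' Coarse log-spaced grid search over (J, r0) followed by Nelder-Mead
#' refinement on log10 parameters. Every objective evaluation reruns the
#' divergence ensemble with the objective's fixed seed policy (common random
#' numbers), computes the per-bin conditional profiles and returns their
#' [profile_rmsd()] to the reference. For the two-class family the optimized
#' baseline is the unstructured one (structured sites keep r0 = 0).
#'
#' @param spec a [fit_objective_spec()].
#' @param model_family `"one-class"` or `"two-class"`.
#' @param grid_J,grid_r0 grid values (defaults: 5 log-spaced points over
#'   [1e-3, 1] and [1e-5, 1e-1]).
#' @param simplex_maxit Nelder-Mead iteration budget (0 skips refinement).
#' @param start optional `c(J, r0)` start point; when given the grid stage is
#'   skipped.
#' @return list with `params` (fitted parameter object), `J`, `r0`,
#'   `objective`, and `trace` (data frame of all evaluations).
#' @export
optimize_params <- function(spec, model_family = c("one-class", "two-class"),
                            grid_J = 10^seq(-3, 0, length.out = 5),
                            grid_r0 = 10^seq(-5, -1, length.out = 5),
                            simplex_maxit = 25, start = NULL) {
  stopifnot(inherits(spec, "fit_objective_spec"))
  model_family <- match.arg(model_family)
  trace <- list()
  n_eval <- 0L
  make_params <- function(J, r0) {
    if (model_family == "one-class") model_params(r0 = r0, J = J)
    else two_class_params(r0_unstructured = r0, J = J)
  }
  objective <- function(J, r0, stage) {
    val <- tryCatch({
      ens <- run_ensemble(spec$map_source, spec$lengths, make_params(J, r0),
                          spec$config, spec$bins, spec$n_reps, seed = spec$seed)
      prof <- ensemble_profiles(ens, d_max = spec$d_max, trim = spec$trim)
      profile_rmsd(prof, spec$reference, d_max = spec$d_max)
    }, error = function(e) 1e6)
    n_eval <<- n_eval + 1L
    trace[[n_eval]] <<- data.frame(J = J, r0 = r0, objective = val,
                                   stage = stage)
    val
  }
  if (is.null(start)) {
    pts <- expand.grid(J = grid_J, r0 = grid_r0)
  } else {
    pts <- data.frame(J = start[1], r0 = start[2])
  }
  vals <- mapply(function(J, r0) objective(J, r0, "grid"), pts$J, pts$r0)
  best <- which.min(vals)
  bJ <- pts$J[best]; br0 <- pts$r0[best]; bval <- vals[best]
  if (simplex_maxit > 0) {
    fn <- function(lp) objective(10^lp[1], 10^lp[2], "simplex")
    opt <- stats::optim(log10(c(bJ, br0)), fn, method = "Nelder-Mead",
                        control = list(maxit = simplex_maxit))
    if (opt$value < bval) {
      bJ <- 10^opt$par[1]; br0 <- 10^opt$par[2]; bval <- opt$value
    }
  }
  if (all(vapply(trace, function(t) t$objective >= 1e6, logical(1))))
    stop("fit failure: no valid objective evaluation in the budget")
  list(params = make_params(bJ, br0), J = bJ, r0 = br0, objective = bval,
       trace = do.call(rbind, trace), model_family = model_family)
}
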
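#' Parameters of the uniform (one-class) rate model
#'
#' The substitution rate of site i at time t is
#' `r_i(t) = r0 + J * sum_k C[i,k] * exp(-(t - t_k))`,
#' where `t_k` is the time of the last substitution at site k and sites that
#' never substituted contribute exactly 0. Rates are per site per memory-time
#' unit; the kernel decay time defines the (dimensionless) unit of time.
#'
#' Defaults are the values obtained by jointly fitting the along-chain
#' conditional substitution profiles over the 60-90% sequence-identity range.
#'
#' @param r0 baseline substitution rate (>= 0).
#' @param J coupling amplitude per contacting recent substitution (>= 0).
#' @export
model_params <- function(r0 = 4e-4, J = 0.02) {
  if (!is.numeric(r0) || length(r0) != 1 || r0 < 0) stop("r0 must be >= 0")
  if (!is.numeric(J) || length(J) != 1 || J < 0) stop("J must be >= 0")
  structure(list(r0 = r0, J = J), class = "model_params")
}

#' Parameters of the two-class rate model
#'
#' Variant in which structured residues (class `"S"`) have zero baseline rate
#' and substitute only through the coupling term, while unstructured residues
#' (`"U"`) keep a positive baseline. Both classes share the same coupling `J`.
#' Defaults are the fitted two-class values.
#'
#' @param r0_unstructured baseline rate of unstructured sites.
#' @param J shared coupling amplitude.
#' @param r0_structured baseline rate of structured sites (0 by default).
#' @export
two_class_params <- function(r0_unstructured = 0.01, J = 0.021,
                             r0_structured = 0) {
  if (any(c(r0_unstructured, J, r0_structured) < 0))
    stop("all rates must be >= 0")
  structure(list(r0_unstructured = r0_unstructured,
                 r0_structured = r0_structured, J = J),
            class = "two_class_params")
}

#' Simulation configuration
#'
#' @param dt time step in memory-time units. The default 0.01 keeps the
#'   fraction of steps with two or more simultaneous substitutions well below
#'   1% at the fitted parameters (the validation used to justify the explicit
#'   scheme).
#' @param equilibration_time duration of the pre-split dynamics bringing the
#'   last-substitution lags to stationarity (memory-time units).
#' @param max_time safety cap on the post-split simulation time.
#' @export
sim_config <- function(dt = 0.01, equilibration_time = 50, max_time = 5000) {
  if (dt <= 0) stop("dt must be > 0")
  if (equilibration_time < 0) stop("equilibration_time must be >= 0")
  if (max_time <= 0) stop("max_time must be > 0")
  structure(list(dt = dt, equilibration_time = equilibration_time,
                 max_time = max_time), class = "sim_config")
}

# per-site baseline rate vector; two-class params require class labels
base_rates <- function(params, L, classes = NULL) {
  if (inherits(params, "two_class_params")) {
    if (is.null(classes)) stop("two-class parameters require site classes")
    classes <- site_classes(classes)
    if (length(classes) != L) stop("classes length must match map length")
    ifelse(unclass(classes) == "S", params$r0_structured, params$r0_unstructured)
  } else if (inherits(params, "model_params")) {
    rep(params$r0, L)
  } else stop("params must be model_params or two_class_params")
}

#' Dynamical state of a chain
#'
#' Holds the current clock, the per-site time of the most recent substitution
#' (`NA` for sites that never substituted, which contribute exactly 0 to the
#' rate), and per-site substitution counts.
#'
#' @param L number of sites.
#' @export
chain_state <- function(L) {
  structure(list(L = as.integer(L), time = 0,
                 t_last = rep(NA_real_, L),
                 mutated = rep(FALSE, L),
                 counts = integer(L)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("chain_state: %d sites, t = %.3f, %d sites ever substituted, %d substitutions\n",
              x$L, x$time, sum(x$mutated), sum(x$counts)))
  invisible(x)
}

#' Instantaneous substitution rates
#'
#' Reference (pure R) evaluation of the memory-kernel rate: baseline plus
#' `J * exp(-lag)` summed over contacting sites that substituted no longer
#' than 40 memory-time units ago (older contributions are below
#' double-precision relevance and treated as exactly 0).
#'
#' @param state a [chain_state()].
#' @param map a [contact_map()].
#' @param params [model_params()] or [two_class_params()].
#' @param classes [site_classes()], required for two-class parameters.
#' @return numeric vector of per-site rates.
#' @export
site_rates <- function(state, map, params, classes = NULL) {
  stopifnot(inherits(state, "chain_state"), inherits(map, "contact_map"))
  if (state$L != map$L) stop("state and map have different lengths")
  rate <- base_rates(params, map$L, classes)
  lag <- state$time - state$t_last
  active <- which(state$mutated & lag <= 40)
  for (k in active) {
    nb <- which(map$adj[k, ])
    rate[nb] <- rate[nb] + params$J * exp(-lag[k])
  }
  rate
}

#' @rdname site_rates
#' @param site single site index.
#' @export
site_rate <- function(state, map, params, site, classes = NULL) {
  if (length(site) != 1 || site < 1 || site > map$L) stop("site out of range")
  site_rates(state, map, params, classes)[site]
}

#' Advance a chain by one discrete time step (reference implementation)
#'
#' Explicit scheme: substitution probabilities `p_i = r_i * dt` are computed
#' from the state at the start of the step; every site substitutes
#' independently; substituted sites get their last-substitution time set to
#' the end-of-step clock, so the kernel is at lag 0 when rates are next
#' evaluated. The heavily used simulators ([evolve_chain()],
#' [simulate_divergence()]) run the same scheme in compiled code and are
#' bit-identical to iterating this function under a shared RNG stream.
#'
#' @inheritParams site_rates
#' @param config a [sim_config()].
#' @return list with the updated `state` and `substituted` (site indices).
#' @export
step <- function(state, map, params, config, classes = NULL) {
  rate <- site_rates(state, map, params, classes)
  p <- rate * config$dt
  if (any(p > 1)) stop("substitution probability r*dt > 1; decrease dt")
  u <- stats::runif(state$L)
  subs <- which(u < p)
  tn <- state$time + config$dt
  if (length(subs)) {
    state$mutated[subs] <- TRUE
    state$t_last[subs] <- tn
    state$counts[subs] <- state$counts[subs] + 1L
  }
  state$time <- tn
  list(state = state, substituted = subs)
}

#' Evolve a chain for a fixed duration (compiled stepper)
#'
#' @inheritParams step
#' @param duration time to simulate, rounded up to whole steps.
#' @return list with `state` (updated [chain_state()]), `events` (data frame
#'   of site/time), `steps`, `multi_steps` (steps with >= 2 substitutions),
#'   and the mean total rate over each half of the run (a stationarity
#'   diagnostic).
#' @export
evolve_chain <- function(state, map, params, config, duration, classes = NULL) {
  stopifnot(inherits(state, "chain_state"), inherits(map, "contact_map"),
            inherits(config, "sim_config"))
  if (state$L != map$L) stop("state and map have different lengths")
  base <- base_rates(params, map$L, classes)
  res <- cpp_evolve(neighbor_list(map), base, params$J, config$dt,
                    state$t_last, as.integer(state$mutated),
                    state$counts, state$time, duration)
  new <- state
  new$time <- res$time
  new$mutated <- res$mutated > 0
  new$t_last <- ifelse(new$mutated, res$t_last, NA_real_)
  new$counts <- res$counts
  list(state = new,
       events = data.frame(site = res$event_site, time = res$event_time),
       steps = res$steps, multi_steps = res$multi_steps,
       mean_rate_first_half = res$mean_rate_first_half,
       mean_rate_second_half = res$mean_rate_second_half)
}

#' Equilibrate a chain before the two-branch split
#'
#' Runs the step dynamics from the all-never-substituted state for
#' `equilibration_time`, then resets the clock to 0 (shifting the
#' last-substitution times so the lags t - t_k are preserved) and zeroes the
#' substitution counts: pre-split history shapes the rates but does not count
#' as divergence.
#'
#' @inheritParams step
#' @return an equilibrated [chain_state()] with `time = 0`.
#' @export
equilibrate <- function(map, params, config, classes = NULL) {
  st <- chain_state(map$L)
  if (config$equilibration_time > 0) {
    st <- evolve_chain(st, map, params, config,
                       config$equilibration_time, classes)$state
  }
  st$t_last <- st$t_last - st$time
  st$time <- 0
  st$counts <- integer(map$L)
  st
}
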
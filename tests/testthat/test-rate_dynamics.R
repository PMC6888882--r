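test_that("site rates follow the memory kernel", {
  m <- band_map(10)
  p <- model_params(r0 = 4e-4, J = 0.02)
  st <- chain_state(10)

  # empty history: rate is the baseline everywhere
  expect_equal(site_rates(st, m, p), rep(4e-4, 10))

  # one contacting neighbor at lag 0 contributes exactly J
  st$mutated[4] <- TRUE; st$t_last[4] <- 0; st$time <- 0
  expect_equal(site_rate(st, m, p, 5), 4e-4 + 0.02)
  # lag 1 is damped by exp(-1)
  st$time <- 1
  expect_equal(site_rate(st, m, p, 5), 4e-4 + 0.02 * exp(-1))
  # site 8 is not in contact with site 4
  expect_equal(site_rate(st, m, p, 8), 4e-4)
  # lags beyond 40 memory-time units contribute exactly 0
  st$time <- 41
  expect_equal(site_rate(st, m, p, 5), 4e-4)
})

test_that("site rates equal a naive full-sum evaluation on random states", {
  set.seed(11)
  for (rep in 1:5) {
    syn <- synthetic_contact_map(25, helix_spans = list(c(3, 14)),
                                 long_range_per_site = 2, seed = rep)
    st <- chain_state(25)
    st$time <- 10
    mut <- sample(25, 12)
    st$mutated[mut] <- TRUE
    st$t_last[mut] <- runif(12, -40, 10)
    p <- model_params(r0 = 0.01, J = 0.3)
    expect_equal(site_rates(st, syn$map, p),
                 oracle_site_rates(st, syn$map, rep(0.01, 25), 0.3))
    tc <- two_class_params(r0_unstructured = 0.05, J = 0.3)
    expect_equal(site_rates(st, syn$map, tc, classes = syn$classes),
                 oracle_site_rates(st, syn$map,
                                   ifelse(unclass(syn$classes) == "S", 0, 0.05),
                                   0.3))
  }
})

test_that("step implements independent Bernoulli substitutions at r*dt", {
  m <- band_map(10)
  cfg <- sim_config(dt = 0.1, equilibration_time = 0)

  # zero rates: nothing ever substitutes
  st <- chain_state(10)
  set.seed(1)
  for (i in 1:50) st <- step(st, m, model_params(r0 = 0, J = 0), cfg)$state
  expect_equal(sum(st$counts), 0L)
  expect_equal(st$time, 5)

  # single isolated site: frequency of substitution per step is r0*dt
  one <- contact_map(matrix(0, 1, 1))
  set.seed(2)
  ev <- evolve_chain(chain_state(1), one, model_params(r0 = 0.5, J = 0), cfg,
                     duration = 1e4)
  freq <- nrow(ev$events) / ev$steps
  se <- sqrt(0.05 * 0.95 / ev$steps)
  expect_lt(abs(freq - 0.05), 3 * se)

  # after a substitution at i, a contacting j has p = (r0 + J)*dt next step
  st <- chain_state(10)
  st$mutated[4] <- TRUE; st$t_last[4] <- 0.1; st$time <- 0.1
  p <- model_params(r0 = 0.1, J = 0.5)
  expect_equal(site_rate(st, m, p, 5) * cfg$dt, (0.1 + 0.5) * 0.1)

  # dt too large for the rates is a configuration error
  expect_error(step(chain_state(10), m, model_params(r0 = 20, J = 0), cfg),
               "decrease dt")
})

test_that("compiled stepper reproduces the R reference bit-for-bit", {
  for (s in 1:3) {
    syn <- synthetic_contact_map(15, helix_spans = list(c(2, 11)),
                                 long_range_per_site = 1.5, seed = s)
    p <- model_params(r0 = 0.05, J = 0.4)
    cfg <- sim_config(dt = 0.05, equilibration_time = 0)
    set.seed(100 + s)
    st <- chain_state(15)
    for (i in 1:300) st <- step(st, syn$map, p, cfg)$state
    set.seed(100 + s)
    fast <- evolve_chain(chain_state(15), syn$map, p, cfg, duration = 15)
    expect_identical(st$counts, fast$state$counts)
    expect_identical(st$t_last, fast$state$t_last)
    expect_identical(st$time, fast$state$time)
  }
})

test_that("equilibration reaches the stationary lag distribution", {
  # zero duration leaves the chain untouched
  m <- band_map(12)
  cfg0 <- sim_config(equilibration_time = 0)
  st <- equilibrate(m, model_params(), cfg0)
  expect_equal(sum(st$mutated), 0L)
  expect_equal(sum(st$counts), 0L)
  expect_equal(st$time, 0)

  # J = 0: fraction of sites with lag < 1 matches the exponential waiting law
  big <- contact_map(matrix(0, 2000, 2000))
  cfg <- sim_config(dt = 0.01, equilibration_time = 30)
  set.seed(5)
  st <- equilibrate(big, model_params(r0 = 0.5, J = 0), cfg)
  frac <- mean(st$mutated & (-st$t_last) < 1)
  expected <- 1 - exp(-0.5)
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(frac - expected), 3 * se)
  # counts are reset: pre-split history never counts as divergence
  expect_equal(sum(st$counts), 0L)

  # total rate is stationary: first and second half of a long run agree
  syn <- synthetic_contact_map(60, helix_spans = list(c(11, 40)),
                               long_range_per_site = 1, seed = 9)
  pp <- model_params(r0 = 0.05, J = 0.1)
  cfg2 <- sim_config(dt = 0.02, equilibration_time = 40)
  diffs <- vapply(1:25, function(s) {
    set.seed(s)
    st0 <- equilibrate(syn$map, pp, cfg2)
    ev <- evolve_chain(st0, syn$map, pp, cfg2, duration = 80)
    ev$mean_rate_second_half - ev$mean_rate_first_half
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("J = 0 chains are Poisson: dispersion of counts is 1", {
  nochange <- contact_map(matrix(0, 1500, 1500))
  set.seed(21)
  ev <- evolve_chain(chain_state(1500), nochange, model_params(r0 = 0.02, J = 0),
                     sim_config(dt = 0.1), duration = 100)
  k <- ev$state$counts
  vm <- var(k) / mean(k)
  expect_lt(abs(vm - 1), 3 * sqrt(2 / length(k)))
})
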
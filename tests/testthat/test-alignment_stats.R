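test_that("residue alignments binarize position-wise", {
  a <- binarize_alignment("ACDE", "ACDE")
  expect_equal(a$symbols, c(0L, 0L, 0L, 0L))
  expect_equal(a$identity, 1)
  b <- binarize_alignment("ACDE", "ACDG")
  expect_equal(b$symbols, c(0L, 0L, 0L, 1L))
  expect_equal(b$identity, 0.75)
  expect_error(binarize_alignment("AC-E", "ACDE"), "gap")
  expect_error(binarize_alignment("ACD", "ACDE"), "length")
})

test_that("conditional profile matches hand-derived counts on a small string", {
  # x = 0110100000; ordered (center, partner) pairs counted in both directions
  x <- as.integer(strsplit("0110100000", "")[[1]])
  prof <- conditional_profile(list(x), d_max = 3, trim = 0)
  expect_equal(prof$N1, c(2, 2, 2))
  expect_equal(prof$N0, c(4, 3, 2))
  expect_equal(prof$P, c(1 / 3, 2 / 5, 1 / 2))
})

test_that("degenerate alignments give flagged or certain profiles", {
  zeros <- binary_alignment(rep(0L, 30))
  p0 <- conditional_profile(zeros, d_max = 5, trim = 5)
  expect_equal(p0$N1 + p0$N0, rep(0, 5))
  expect_true(all(is.nan(p0$P)))

  ones <- binary_alignment(rep(1L, 30))
  p1 <- conditional_profile(ones, d_max = 5, trim = 5)
  expect_true(all(p1$P == 1))

  expect_error(conditional_profile(binary_alignment(rep(0L, 8)), trim = 5),
               "trimmed minimum")
})

test_that("conditional profile equals the brute-force oracle on random strings", {
  set.seed(33)
  for (rep in 1:30) {
    n <- sample(15:60, 1)
    x <- list(rbinom(n, 1, runif(1, 0.1, 0.6)),
              rbinom(n, 1, runif(1, 0.1, 0.6)))
    trim <- sample(0:3, 1)
    d_max <- sample(3:12, 1)
    prof <- conditional_profile(x, d_max = d_max, trim = trim)
    ora <- oracle_profile(x, d_max, trim)
    expect_equal(prof$N1, ora$N1)
    expect_equal(prof$N0, ora$N0)
  }
})

test_that("substitution histograms tally, normalize and add", {
  h <- substitution_histogram(c(0, 0, 1, 2))
  expect_equal(h$counts, c(2, 1, 1))
  expect_equal(sum(h$freq), 1)
  expect_equal(h$mean_k, 0.75)
  h2 <- substitution_histogram(c(0, 2, 2, 5))
  pooled <- substitution_histogram(c(0, 0, 1, 2, 0, 2, 2, 5))
  padded <- c(h$counts, rep(0, 3))
  expect_equal(pooled$counts, padded + h2$counts)
  expect_error(substitution_histogram(numeric(0)), "empty")
  expect_error(substitution_histogram(c(1, -1)), "non-negative")
})

test_that("negative binomial pmf matches closed forms and the Poisson limit", {
  expect_equal(negbinom_pmf(0, 2.5, 1.7), (2.5 / (1.7 + 2.5))^2.5)
  # alpha = 1, mean 1 is geometric with ratio 1/2
  expect_equal(negbinom_pmf(0:10, 1, 1), 0.5^(1:11))
  # large-alpha limit is Poisson
  k <- 0:30
  expect_lt(max(abs(negbinom_pmf(k, 1e6, 3) - dpois(k, 3))), 1e-4)
  # normalization with negligible tail
  expect_lt(abs(1 - sum(negbinom_pmf(0:500, 0.7, 2.3))), 1e-10)
  # log-space hand evaluation agrees
  set.seed(4)
  for (rep in 1:10) {
    al <- runif(1, 0.1, 20); mk <- runif(1, 0.1, 5)
    expect_equal(negbinom_pmf(0:40, al, mk), oracle_negbinom(0:40, al, mk),
                 tolerance = 1e-12)
  }
  expect_error(negbinom_pmf(1, -1, 2), "positive")
})

test_that("alpha fitting recovers exact and sampled negative binomials", {
  # histogram exactly on the pmf: zero-residual fixed point
  k <- 0:60
  exact <- structure(list(k = k, counts = negbinom_pmf(k, 1.3, 1) * 1e7,
                          freq = NULL, mean_k = 1, n_sites = 1e7),
                     class = "substitution_histogram")
  exact$freq <- exact$counts / sum(exact$counts)
  fit <- fit_alpha(exact, mean_k = 1)
  expect_equal(fit$alpha, 1.3, tolerance = 1e-4)
  expect_lt(fit$rms_residual, 1e-8)

  # parameter recovery from sampled data
  set.seed(8)
  ks <- rnbinom(1e5, size = 0.5, mu = 2)
  fit <- fit_alpha(substitution_histogram(ks))
  expect_lt(abs(fit$alpha - 0.5) / 0.5, 0.10)

  # Poisson data sit on the large-alpha plateau
  set.seed(9)
  fitp <- fit_alpha(substitution_histogram(rpois(1e4, 2)))
  expect_gte(fitp$alpha, 50)

  expect_error(fit_alpha(substitution_histogram(rep(2, 50))), "occupied")
})

test_that("overlap ratio counts repeated substitutions", {
  expect_equal(overlap_ratio(c(2, 1, 0, 3)), 2 / 3)
  expect_equal(overlap_ratio(c(0, 1, 1, 0)), 0)
  expect_equal(overlap_ratio(c(2, 5, 3)), 1)
  expect_error(overlap_ratio(c(0, 0)), "undefined")
})
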
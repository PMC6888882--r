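test_that("contact maps from coordinates use a strict distance threshold", {
  two <- function(d) contact_map_from_coordinates(rbind(c(0, 0, 0), c(d, 0, 0)),
                                                  threshold = 10)
  expect_equal(as.matrix(two(9))[1, 2], 1)
  expect_equal(as.matrix(two(12))[1, 2], 0)
  expect_equal(as.matrix(two(10))[1, 2], 0) # boundary: strictly nearer than
  coll <- contact_map_from_coordinates(rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0)),
                                       threshold = 10)
  expect_equal(as.matrix(coll),
               rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
})

test_that("degenerate coordinate inputs are rejected", {
  expect_error(contact_map_from_coordinates(matrix(numeric(0), 0, 3)), "empty")
  expect_error(contact_map_from_coordinates(rbind(c(0, 0, NA), c(1, 1, 1))),
               "finite")
  expect_error(contact_map_from_coordinates(rbind(c(0, 0, 0)), threshold = -1),
               "positive")
})

test_that("contact maps are invariant under rigid motions of the coordinates", {
  set.seed(42)
  for (rep in 1:5) {
    xyz <- matrix(rnorm(30 * 3, sd = 8), ncol = 3)
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    moved <- xyz %*% rot + matrix(rnorm(3), nrow(xyz), 3, byrow = TRUE) * 5
    expect_equal(as.matrix(contact_map_from_coordinates(xyz)),
                 as.matrix(contact_map_from_coordinates(moved)))
  }
})

test_that("synthetic maps contain exactly the stated deterministic contacts", {
  syn <- synthetic_contact_map(20, long_range_per_site = 0, backbone_width = 2,
                               seed = 1)
  band <- abs(outer(1:20, 1:20, "-"))
  expect_equal(as.matrix(syn$map), (band >= 1 & band <= 2) * 1)
  expect_equal(unclass(syn$classes), rep("U", 20))

  helix <- synthetic_contact_map(20, helix_spans = list(c(6, 15)),
                                 long_range_per_site = 0, backbone_width = 2,
                                 seed = 1)
  expected <- (band >= 1 & band <= 2)
  for (i in 6:15) for (w in 3:4)
    if (i + w <= 15) expected[i, i + w] <- expected[i + w, i] <- TRUE
  expect_equal(as.matrix(helix$map), expected * 1)
  expect_equal(unclass(helix$classes), ifelse(1:20 %in% 6:15, "S", "U"))
  expect_error(synthetic_contact_map(20, helix_spans = list(c(1, 8), c(5, 12))),
               "overlap")
})

test_that("long-range contact density matches its Poisson mean", {
  deg <- vapply(1:50, function(s) {
    syn <- synthetic_contact_map(200, long_range_per_site = 1,
                                 backbone_width = 2, seed = 1000 + s)
    # long-range degree = total degree minus the deterministic band
    mean(contact_degree(syn$map)) - mean(rowSums(
      (abs(outer(1:200, 1:200, "-")) >= 1) & (abs(outer(1:200, 1:200, "-")) <= 2)))
  }, numeric(1))
  se <- sd(deg) / sqrt(length(deg))
  expect_lt(abs(mean(deg) - 1), 3 * se + 1e-12)
})

test_that("every constructor yields a symmetric zero-diagonal map", {
  maps <- list(
    synthetic_contact_map(30, helix_spans = list(c(5, 20)), seed = 3)$map,
    contact_map_from_coordinates(matrix(rnorm(60, sd = 6), ncol = 3)),
    contact_map(rbind(c(1, 5), c(2, 9)), L = 10),
    pad_unmapped_sites(band_map(15), c(1, 8)))
  for (m in maps) {
    a <- as.matrix(m)
    expect_equal(a, t(a))
    expect_equal(diag(a), rep(0, nrow(a)))
  }
  expect_error(contact_map(rbind(c(1, 1)), L = 5), "self")
  expect_error(contact_map(rbind(c(1, 9)), L = 5), "range")
})

test_that("submap restricts the parent adjacency and composes", {
  b <- band_map(30)
  s <- submap(b, 5, 10)
  expect_equal(as.matrix(s$map), as.matrix(band_map(10)))
  expect_equal(s$parent_index, 5:14)

  whole <- submap(b, 1, 30)
  expect_equal(as.matrix(whole$map), as.matrix(b))

  set.seed(7)
  rnd <- synthetic_contact_map(40, long_range_per_site = 2, seed = 7)$map
  w <- submap(rnd, 4, 5)
  expect_equal(as.matrix(w$map), as.matrix(rnd)[4:8, 4:8])

  inner <- submap(submap(rnd, 6, 20)$map, 3, 8)$map
  direct <- submap(rnd, 8, 8)$map
  expect_equal(as.matrix(inner), as.matrix(direct))
  expect_error(submap(rnd, 35, 10), "range")
})
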
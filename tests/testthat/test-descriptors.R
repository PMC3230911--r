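test_that("zones are placed by the fixed-length rules around the peaks", {
  # peaks at 1-based indices 24 and 38 on a 61-px profile
  z <- locate_zones(rep(1, 61), peaks = c(24, 38))
  expect_identical(z$z1, c(29L, 33L))
  expect_identical(z$z2a, c(22L, 26L))
  expect_identical(z$z2b, c(36L, 40L))
  expect_identical(z$z3a, c(17L, 21L))
  expect_identical(z$z3b, c(41L, 45L))
  expect_identical(z$z4a, c(7L, 16L))
  expect_identical(z$z4b, c(46L, 55L))
  expect_identical(z$z5, c(24L, 38L))
  expect_identical(z$z6a, c(1L, 23L))
  expect_identical(z$z6b, c(39L, 61L))
  expect_false(z$truncated)
  span <- function(r) r[2] - r[1] + 1L
  expect_identical(span(z$z1), 5L)
  expect_identical(span(z$z2a), 5L)
  expect_identical(span(z$z3a), 5L)
  expect_identical(span(z$z4a), 10L)
})

test_that("symmetric peaks give a zone model symmetric about the midpoint", {
  z <- locate_zones(rep(1, 61), peaks = c(25, 37))
  expect_identical(z$z1, c(29L, 33L))
  expect_identical(62L - rev(z$z2b), z$z2a)
  expect_identical(62L - rev(z$z4b), z$z4a)
  expect_identical(62L - rev(z$z6b), z$z6a)
})

test_that("zones near the boundary are truncated and flagged", {
  z <- locate_zones(rep(1, 61), peaks = c(10, 24))
  expect_true(z$truncated)
  expect_identical(z$z4a[1], 1L)
})

test_that("a uniform functional profile yields the closed-form internalization degree", {
  z <- locate_zones(rep(1, 61), peaks = c(24, 38))
  d <- compute_descriptors(rep(1, 61), z)
  expect_equal(d$F, 15 / 61)
  expect_equal(d$sum5, 15)
  expect_equal(d$sum5 + d$sum6, 61)
  # D from stated sums: sum2 = 10 px, sum4 = 20 px of a uniform profile
  expect_equal(d$D, 10 / 20)
})

test_that("descriptor D follows its defining ratio", {
  z <- locate_zones(rep(1, 61), peaks = c(24, 38))
  f <- rep(0, 61)
  f[c(z$z2a[1]:z$z2a[2], z$z2b[1]:z$z2b[2])] <- 20   # sum2 = 200
  f[c(z$z4a[1]:z$z4a[2], z$z4b[1]:z$z4b[2])] <- 5    # sum4 = 100
  expect_equal(compute_descriptors(f, z)$D, 2)
})

test_that("signal confined between the peaks gives missing outer ratios and F = 1", {
  z <- locate_zones(rep(1, 61), peaks = c(24, 38))
  f <- rep(0, 61)
  f[29:33] <- 10          # zone 1 only
  d <- compute_descriptors(f, z)
  expect_true(is.na(d$C) && is.na(d$D) && is.na(d$E))
  expect_equal(d$F, 1)
})

test_that("positional variance matches its closed forms", {
  v <- rep(0, 61); v[31] <- 42
  expect_equal(profile_variance(v), 0)
  expect_equal(profile_variance(rep(3, 61)), 1 / 12, tolerance = 1e-3)
  expect_equal(profile_variance(c(1, 1)), 0.0625)
  expect_true(is.na(profile_variance(rep(0, 10))))
})

test_that("all ratio descriptors are invariant to positive scaling of the functional channel", {
  z <- locate_zones(rep(1, 61), peaks = c(24, 38))
  set.seed(5)
  f <- runif(61, 1, 50)
  d1 <- compute_descriptors(f, z)
  d2 <- compute_descriptors(f * 7.3, z)
  for (v in c("X", "Y", "Z", "A", "B", "C", "D", "E", "F", "variance"))
    expect_equal(d1[[v]], d2[[v]], tolerance = 1e-12)
})

test_that("moving signal from the membrane zones to the deep cytoplasm lowers C, D and E", {
  z <- locate_zones(rep(1, 61), peaks = c(24, 38))
  f <- rep(1, 61)
  f[c(22:26, 36:40)] <- 20
  f[c(7:16, 46:55)] <- 2
  before <- compute_descriptors(f, z)
  g <- f
  g[c(22:26, 36:40)] <- 10                    # take 100 from zone 2
  g[c(7:16, 46:55)] <- 2 + 100 / 20           # give it to zone 4
  after <- compute_descriptors(g, z)
  expect_equal(sum(g), sum(f))
  expect_lt(after$D, before$D)
  expect_lt(after$E, before$E)
  expect_lte(after$C, before$C)
})

test_that("mean internalization degree decreases with decreasing membrane fraction", {
  mean_F <- vapply(c(1.0, 0.8, 0.6, 0.4), function(mf) {
    gi <- straight_image(noise = 0, mf = mf, seed = 17)
    anchors <- centerline_anchors(gi$truth)
    anchors <- anchors[seq(1, nrow(anchors), by = 5), , drop = FALSE]
    Fs <- vapply(seq_len(nrow(anchors)), function(i) {
      p <- extract_profile(gi$image, c(anchors[i, 2], anchors[i, 1]), c(1, 0))
      ctr <- p
      ctr$structural <- p$structural[11:71]
      ctr$functional <- p$functional[11:71]
      z <- locate_zones(ctr$structural)
      compute_descriptors(ctr$functional, z)$F
    }, 0)
    mean(Fs)
  }, 0)
  expect_true(all(diff(mean_F) < 0))
})
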
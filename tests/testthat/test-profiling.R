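skeleton_from_pixels <- function(rows, cols, nr = 40, nc = 40) {
  m <- matrix(0L, nr, nc)
  m[cbind(rows, cols)] <- 1L
  canaliq:::new_skeleton(m)
}

test_that("fit_tangent recovers segment orientation", {
  s <- skeleton_from_pixels(rep(20, 15), 10:24)
  expect_equal(fit_tangent(s, c(20, 17)), c(1, 0), tolerance = 1e-12)
  d <- skeleton_from_pixels(10:24, 10:24)
  expect_equal(fit_tangent(d, c(17, 17)), c(sqrt(2) / 2, sqrt(2) / 2),
               tolerance = 1e-9)
  # noisy near-vertical: within 5 degrees of vertical, matching a TLS oracle
  set.seed(2)
  rows <- 5:35
  cols <- round(20 + rnorm(length(rows), 0, 0.6))
  cols <- Reduce(function(a, b) c(a, a[length(a)] + max(-1, min(1, b - a[length(a)]))),
                 cols[-1], cols[1])          # keep the chain 8-connected
  sn <- skeleton_from_pixels(rows, cols)
  anchor <- c(rows[15], cols[15])
  v <- fit_tangent(sn, anchor, half_window = 5)
  expect_lt(abs(atan2(v[1], v[2])) * 180 / pi, 5)
  # oracle: total least squares via SVD on the same window
  sel <- abs(sn$pixels$row - anchor[1]) <= 5 & abs(sn$pixels$col - anchor[2]) <= 5
  M <- cbind(sn$pixels$col[sel], sn$pixels$row[sel])
  M <- sweep(M, 2, colMeans(M))
  u <- svd(M)$v[, 1]
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  expect_equal(v, unname(u), tolerance = 1e-9)
})

test_that("profiles extracted from a constant image are constant", {
  img <- two_channel_image(matrix(3, 160, 160), matrix(8, 160, 160))
  p <- extract_profile(img, c(80, 80), c(1, 0))
  expect_equal(p$structural, rep(3, 81))
  expect_equal(p$functional, rep(8, 81))
})

test_that("a centerline profile of a straight canaliculus is symmetric with peaks at half separation", {
  gi <- straight_image(noise = 0, mf = 1, vesicles = 0)
  p <- extract_profile(gi$image, c(80, 80), c(1, 0))
  expect_equal(p$structural[1:40], rev(p$structural[42:81]), tolerance = 1e-9)
  pk <- which(p$structural == max(p$structural))
  expect_setequal(pk, c(41 - 6, 41 + 6))
  # widening is a no-op along a translation-invariant ridge
  p1 <- extract_profile(gi$image, c(80, 80), c(1, 0), width_lines = 1L)
  expect_equal(p$structural, p1$structural, tolerance = 1e-9)
})

test_that("out-of-bounds profiles are skipped", {
  img <- two_channel_image(matrix(1, 160, 160), matrix(1, 160, 160))
  expect_null(extract_profile(img, c(10, 80), c(1, 0)))
})

test_that("selection criteria accept and reject the documented profile shapes", {
  thr <- selection_thresholds()
  others <- list(list(pos = 10, h = 20), list(pos = 62, h = 20),
                 list(pos = 70, h = 20))
  good <- synthetic_profile(30, 100, 45, 95, valley = 10, others = others)
  m <- select_profile(good, thr)
  expect_true(m$accepted)
  expect_equal(m$maxValue1, 100)
  expect_equal(m$maxValue2, 95)
  expect_equal(abs(m$positionMax1 - m$positionMax2), 15)
  expect_equal(m$minValue, 10)
  expect_equal(m$p60_local_maxima, 20)
  expect_equal(m$r1, 5 / 95)
  expect_equal(m$r2, 10 / 95)
  # peaks 120 vs 100: relative difference 0.20 >= 0.15
  bad1 <- select_profile(synthetic_profile(30, 120, 45, 100, valley = 10), thr)
  expect_false(bad1$accepted)
  expect_identical(bad1$reason, "peak_difference")
  # peak distance exactly 26 fails the strict upper bound
  bad2 <- select_profile(synthetic_profile(25, 100, 51, 95, valley = 10), thr)
  expect_false(bad2$accepted)
  expect_identical(bad2$reason, "peak_distance")
  # shallow valley
  bad3 <- select_profile(synthetic_profile(30, 100, 45, 95, valley = 30), thr)
  expect_false(bad3$accepted)
  expect_identical(bad3$reason, "valley")
  # noisy tails: secondary maxima at ~60% of the peaks
  noisy <- synthetic_profile(30, 100, 45, 95, valley = 10,
                             others = list(list(pos = 10, h = 60),
                                           list(pos = 64, h = 60),
                                           list(pos = 72, h = 60)))
  bad4 <- select_profile(noisy, thr)
  expect_false(bad4$accepted)
  expect_identical(bad4$reason, "noisy")
  # flat profile: no peaks
  flat <- select_profile(rep(5, 81), thr)
  expect_false(flat$accepted)
  expect_identical(flat$reason, "fewer_than_two_peaks")
})

test_that("selection is monotone in the peak-difference and valley thresholds", {
  set.seed(11)
  profs <- lapply(1:60, function(i)
    synthetic_profile(30, 100, 45, runif(1, 60, 100),
                      valley = runif(1, 5, 45)))
  grid1 <- c(0.05, 0.15, 0.25, 0.35)
  grid2 <- c(0.1, 0.2, 0.3, 0.4)
  counts <- matrix(0L, length(grid1), length(grid2))
  for (i in seq_along(grid1)) for (j in seq_along(grid2)) {
    thr <- selection_thresholds(peak_diff = grid1[i], valley = grid2[j])
    counts[i, j] <- sum(vapply(profs, function(p)
      select_profile(p, thr)$accepted, TRUE))
  }
  expect_true(all(apply(counts, 2, diff) >= 0))
  expect_true(all(apply(counts, 1, diff) >= 0))
})

test_that("ranking follows the unweighted combination of rank positions", {
  mk <- function(r1, r2, x) structure(
    list(anchor = c(1L, as.integer(x)), direction = c(1, 0),
         structural = rep(1, 81),
         functional = rep(1, 81), metrics = list(r1 = r1, r2 = r2,
                                                 accepted = TRUE),
         rank = NA_integer_), class = "profile_pair")
  one <- suppressWarnings(rank_profiles(list(mk(0.1, 0.1, 1)), top_n = 5))
  expect_identical(one[[1]]$rank, 1L)
  # dominator on both criteria ranks first
  two <- suppressWarnings(
    rank_profiles(list(mk(0.10, 0.10, 1), mk(0.05, 0.05, 2)), top_n = 5))
  expect_identical(two[[1]]$anchor[2], 2L)
  # five fabricated metric sets vs exhaustive rank-sum oracle
  r1 <- c(0.02, 0.10, 0.05, 0.14, 0.08)
  r2 <- c(0.15, 0.02, 0.10, 0.05, 0.01)
  ranked <- rank_profiles(lapply(1:5, function(i) mk(r1[i], r2[i], i)),
                          top_n = 5)
  got <- vapply(ranked, function(p) p$anchor[2], 0L)
  oracle <- order(rank(r1) + rank(r2), r1)
  expect_identical(got, as.integer(oracle))
  expect_warning(rank_profiles(list(mk(0.1, 0.1, 1)), top_n = 3), "accepted")
})

test_that("the model profile is the centred truncated average", {
  base <- synthetic_profile(35, 100, 47, 100, valley = 10)
  m <- build_model_profile(rbind(base, base))
  expect_length(m$values, 61)
  expect_identical(m$midpoint, 31L)
  expect_equal(m$values, base[11:71])
  # uniformly shifted profiles keep peaks symmetric about the midpoint
  sh <- c(base[3:81], 5, 5)
  m2 <- build_model_profile(rbind(sh, sh))
  expect_equal(sort(abs(m2$peaks - 31)), c(6, 6))
  expect_error(build_model_profile(rbind(rep(1, 81))), "two peaks")
})

test_that("centering finds and undoes integer translations and shifts both channels", {
  base <- synthetic_profile(35, 100, 47, 100, valley = 10)
  model <- build_model_profile(rbind(base))
  mk <- function(s, f) structure(
    list(anchor = c(1L, 1L), direction = c(1, 0), structural = s,
         functional = f, metrics = NULL, rank = NA_integer_,
         shift = NA_integer_), class = "profile_pair")
  c0 <- center_profile(mk(base, base), model)
  expect_identical(c0$shift, 0L)
  expect_equal(c0$structural, model$values)
  # translate by +5: content moves right, optimal shift is -5
  tr <- c(rep(5, 5), base[1:76])
  c5 <- center_profile(mk(tr, tr), model)
  expect_identical(c5$shift, -5L)
  expect_equal(c5$structural, c0$structural)
  expect_equal(c5$functional, c0$functional)
  # the functional channel gets exactly the structural shift
  funky <- sin(seq_len(81))^2
  cf <- center_profile(mk(tr, funky), model)
  expect_identical(cf$shift, -5L)
  expect_equal(cf$functional, funky[(41 + 5 - 30):(41 + 5 + 30)])
})

test_that("all centerline profiles of a symmetric canaliculus pass selection; strong asymmetry fails all", {
  gi <- straight_image(noise = 0, asym = 1)
  anchors <- centerline_anchors(gi$truth)
  ok <- vapply(seq_len(nrow(anchors)), function(i) {
    p <- extract_profile(gi$image, c(anchors[i, 2], anchors[i, 1]), c(1, 0))
    select_profile(p$structural)$accepted
  }, TRUE)
  expect_true(all(ok))
  # 25% peak discrepancy: every profile rejected
  ga <- straight_image(noise = 0, asym = 0.8)
  bad <- vapply(seq_len(nrow(anchors)), function(i) {
    p <- extract_profile(ga$image, c(anchors[i, 2], anchors[i, 1]), c(1, 0))
    select_profile(p$structural)$accepted
  }, TRUE)
  expect_false(any(bad))
})

test_that("profile CSV round-trips through write_profiles/read_profiles", {
  gi <- straight_image(noise = 0)
  p <- extract_profile(gi$image, c(80, 80), c(1, 0))
  p$metrics <- select_profile(p$structural)
  p$rank <- 1L
  path <- tempfile(fileext = ".csv")
  write_profiles(list(p), path, image_id = 3L)
  back <- read_profiles(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$structural, p$structural)
  expect_equal(back[[1]]$functional, p$functional)
  expect_equal(back[[1]]$anchor, p$anchor)
  expect_true(back[[1]]$metrics$accepted)
  unlink(path)
})
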
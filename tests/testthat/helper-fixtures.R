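# Shared fixtures: small synthetic images and independent oracles.

# One straight horizontal canaliculus centred at row `row`, spanning the
# whole image width.
straight_spec <- function(shape = c(160, 160), row = 80, sep = 1200,
                          asym = 1, noise = 0, mf = 0.9, vesicles = 0.5,
                          sigma = 200) {
  canaliculus_spec(path = rbind(c(-10, row), c(shape[2] + 10, row)),
                   ridge_separation = sep, ridge_sigma = sigma,
                   zo1_asymmetry = asym, membrane_fraction = mf,
                   vesicle_density = vesicles, noise_sigma = noise)
}

straight_image <- function(..., shape = c(160, 160), seed = 1) {
  generate_image(straight_spec(shape = shape, ...), shape = shape,
                 seed = seed)
}

# Centerline anchors of a ground truth, away from the image borders.
centerline_anchors <- function(truth, margin = 45, shape = c(160, 160)) {
  ctr <- do.call(rbind, lapply(truth$canaliculi, function(cn) cn$centerline))
  keep <- ctr[, 1] > margin & ctr[, 1] < shape[2] - margin &
    ctr[, 2] > margin & ctr[, 2] < shape[1] - margin
  ctr[keep, , drop = FALSE] # columns: x, y
}

# Independent 8-connected component labelling oracle (breadth-first
# search in plain R), used to check the compiled labelling and the
# component-preserving property of the thinning.
oracle_label <- function(m, connectivity = 8) {
  m <- (m != 0)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- integer(sum(m))
    queue[1] <- start
    head <- 1L; tail <- 1L
    lab[start] <- cur
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nbrs))) {
        rr <- r + nbrs$dr[k]; cc <- c + nbrs$dc[k]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          tail <- tail + 1L
          queue[tail] <- q
        }
      }
    }
  }
  lab
}

oracle_n_components <- function(m, connectivity = 8) {
  max(oracle_label(m, connectivity))
}

# Random blob masks for topology properties: thresholded smoothed noise.
random_mask <- function(n = 64, p = 0.5, seed = 1) {
  set.seed(seed)
  raw <- matrix(runif(n * n), n, n)
  sm <- canaliq:::box_mean(raw, 5L)
  (sm < quantile(sm, p)) * 1L
}

# A synthetic 81-px structural profile with controlled peak structure:
# two triangular principal peaks plus optional secondary maxima of given
# heights, on a low baseline.
synthetic_profile <- function(pos1 = 30, h1 = 100, pos2 = 45, h2 = 95,
                              valley = 10, others = NULL, baseline = 5,
                              n = 81) {
  v <- rep(baseline, n)
  lo <- min(pos1, pos2); hi <- max(pos1, pos2)
  v[(lo + 2):(hi - 2)] <- valley
  put_peak <- function(v, pos, h) {
    v[pos] <- h
    v[pos - 1] <- max(v[pos - 1], h / 2)
    v[pos + 1] <- max(v[pos + 1], h / 2)
    v
  }
  v <- put_peak(v, pos1, h1)
  v <- put_peak(v, pos2, h2)
  if (!is.null(others))
    for (i in seq_along(others))
      v <- put_peak(v, others[[i]]$pos, others[[i]]$h)
  v
}
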
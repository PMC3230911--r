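# Internal helpers shared across modules.

# Run code with a temporary RNG state; the caller's stream is untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Mirror-pad a matrix by k rows/columns on each side (edge-inclusive
# reflection, the border convention used for texture features).
reflect_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(k < nr, k < nc)
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# Moving-window mean over a w x w box, borders by reflection; uses an
# integral image so cost is independent of w.
box_mean <- function(m, w) {
  k <- (w - 1L) %/% 2L
  p <- reflect_pad(m, k)
  s <- apply(apply(p, 2, cumsum), 1, cumsum) # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  nr <- nrow(m); nc <- ncol(m)
  i1 <- 1:nr; i2 <- i1 + 2L * k
  j1 <- 1:nc; j2 <- j1 + 2L * k
  (s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
      s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (w * w)
}

# Bilinear interpolation of matrix values at continuous coordinates
# (x = column, y = row, both 1-based). Returns NA outside [1, nc] x [1, nr].
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), nc - 1L); y0 <- pmin(floor(ys), nr - 1L)
  fx <- xs - x0; fy <- ys - y0
  v00 <- m[cbind(y0, x0)]
  v01 <- m[cbind(y0, x0 + 1L)]
  v10 <- m[cbind(y0 + 1L, x0)]
  v11 <- m[cbind(y0 + 1L, x0 + 1L)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

# Number of foreground 8-neighbours for every pixel of a logical matrix.
neighbor_counts <- function(m) {
  m <- (m != 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[2:(nr + 1L) + dr, 2:(nc + 1L) + dc, drop = FALSE]
  }
  out
}

# Coerce mask-like input (logical/numeric matrix or foreground_mask) to a
# binary integer matrix.
as_binary_matrix <- function(x) {
  if (inherits(x, "foreground_mask")) x <- x$mask
  if (inherits(x, "skeleton")) x <- x$mask
  stopifnot(is.matrix(x))
  (x != 0) * 1L
}

# Moving average with edge replication, used only for peak *detection*.
moving_average <- function(v, w = 3L) {
  if (w <= 1L) return(v)
  k <- (w - 1L) %/% 2L
  n <- length(v)
  p <- c(rep(v[1], k), v, rep(v[n], k))
  as.numeric(stats::filter(p, rep(1 / w, w), sides = 2))[(k + 1L):(k + n)]
}

# Indices of interior local maxima of a vector. Runs of equal values are
# compressed so a plateau counts once, at its centre pixel (floor of the
# run midpoint). Profile endpoints are never maxima.
local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  is_max <- c(FALSE, vals[2:(k - 1)] > vals[1:(k - 2)] &
                vals[2:(k - 1)] > vals[3:k], FALSE)
  idx <- which(is_max)
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}
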
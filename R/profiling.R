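# Orthogonal intensity profile extraction, selection, ranking, centering.

#' Selection thresholds for structural profiles
#'
#' The four empirical acceptance conditions on a structural-marker profile:
#' relative peak-height difference below `peak_diff`; peak distance
#' strictly between `dist_min` and `dist_max` pixels; valley-to-peak ratio
#' below `valley`; 60th percentile of the remaining local maxima relative
#' to the second peak below `noise`. The distance bounds are defined at a
#' 100 nm pixel size and rescaled by `100 / pixel_size` for other
#' resolutions.
#'
#' @param peak_diff maximum relative difference between the two peak
#'   heights (default 0.15).
#' @param dist_min,dist_max exclusive bounds on the peak distance in
#'   pixels at 100 nm pixel size (defaults 7 and 26, i.e. the canalicular
#'   diameter range 0.8-2.5 um).
#' @param valley maximum ratio of the inter-peak minimum to the second
#'   peak (default 0.2).
#' @param noise maximum ratio of the 60th percentile of the other local
#'   maxima to the second peak (default 0.4).
#' @param pixel_size pixel size in nm used to rescale the distance bounds.
#' @return object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(peak_diff = 0.15, dist_min = 7,
                                 dist_max = 26, valley = 0.2, noise = 0.4,
                                 pixel_size = 100) {
  s <- 100 / pixel_size
  structure(list(peak_diff = peak_diff, dist_min = dist_min * s,
                 dist_max = dist_max * s, valley = valley, noise = noise),
            class = "selection_thresholds")
}

#' Local tangent direction of a skeleton fragment
#'
#' Fits an orthogonal-regression (total least squares) line through the
#' skeleton pixels of the anchor's fragment within a Chebyshev window
#' around the anchor, and returns its unit direction. Sign convention:
#' positive x component; if the direction is vertical, positive y.
#'
#' @param skel a `skeleton`.
#' @param anchor length-2 vector `c(row, col)` of a skeleton pixel.
#' @param half_window Chebyshev radius of the fitting window (default 5).
#' @return unit vector `c(dx, dy)` (x = column, y = row), or `NULL` when
#'   fewer than 3 fragment pixels fall inside the window.
#' @export
fit_tangent <- function(skel, anchor, half_window = 5L) {
  px <- skel$pixels
  at <- px$row == anchor[1] & px$col == anchor[2]
  if (!any(at)) stop("anchor is not a skeleton pixel")
  frag <- px$fragment[which(at)[1]]
  sel <- px$fragment == frag &
    abs(px$row - anchor[1]) <= half_window &
    abs(px$col - anchor[2]) <= half_window
  if (sum(sel) < 3L) return(NULL)
  x <- px$col[sel]; y <- px$row[sel]
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (ev[1] < 0 || (ev[1] == 0 && ev[2] < 0)) ev <- -ev
  ev / sqrt(sum(ev^2))
}

#' Extract a co-located profile pair orthogonal to the membrane
#'
#' Samples both channels at 1-pixel steps along the line through the
#' anchor orthogonal to the local tangent `direction`, centred on the
#' anchor. The profile is widened by averaging `width_lines` parallel
#' lines offset along the tangent at 1-pixel spacing (3 lines = 0.3 um at
#' 100 nm pixels). Sub-pixel positions are sampled by bilinear
#' interpolation; if any sample falls outside the image the profile is
#' skipped.
#'
#' @param image a [two_channel_image()].
#' @param anchor `c(row, col)` anchor pixel.
#' @param direction unit tangent `c(dx, dy)` from [fit_tangent()].
#' @param length odd profile length in pixels (default 81, i.e. 8 um at
#'   100 nm).
#' @param width_lines number of averaged parallel lines (default 3).
#' @return a `profile_pair` (anchor, direction, structural and functional
#'   intensity vectors, pixel size), or `NULL` if out of bounds.
#' @export
extract_profile <- function(image, anchor, direction, length = 81L,
                            width_lines = 3L) {
  stopifnot(length %% 2L == 1L)
  half <- (length - 1L) / 2L
  lat <- (-half):half
  n <- c(-direction[2], direction[1])        # orthogonal to the tangent
  offs <- seq_len(width_lines) - (width_lines + 1) / 2
  xs <- outer(lat * n[1], offs * direction[1], "+") + anchor[2]
  ys <- outer(lat * n[2], offs * direction[2], "+") + anchor[1]
  sv <- bilinear_sample(image$structural, as.vector(xs), as.vector(ys))
  if (anyNA(sv)) return(NULL)
  fv <- bilinear_sample(image$functional, as.vector(xs), as.vector(ys))
  structure(list(anchor = as.integer(anchor), direction = direction,
                 structural = rowMeans(matrix(sv, length, width_lines)),
                 functional = rowMeans(matrix(fv, length, width_lines)),
                 pixel_size = image$pixel_size,
                 metrics = NULL, rank = NA_integer_, shift = NA_integer_),
            class = "profile_pair")
}

#' Evaluate the four selection criteria on a structural profile
#'
#' Local maxima are detected on a lightly smoothed copy (moving average,
#' window 3) of the profile; all criterion values are computed from the
#' unsmoothed intensities at the detected positions. The two highest local
#' maxima are the candidate peaks; the profile is accepted iff the
#' relative peak difference, peak distance, valley depth and residual
#' local-maxima criteria all hold. All metric values are stored regardless
#' of the outcome.
#'
#' @param structural numeric profile vector (raw, usually 81 px).
#' @param thresholds a [selection_thresholds()] object.
#' @return object of class `selection_metrics`: `maxValue1`, `maxValue2`,
#'   `positionMax1`, `positionMax2`, `minValue`, `p60_local_maxima`, the
#'   ranking criteria `r1` and `r2`, `accepted`, and a `reason` code when
#'   rejected.
#' @export
select_profile <- function(structural, thresholds = selection_thresholds()) {
  sm <- moving_average(structural, 3L)
  peaks <- local_maxima(sm)
  if (length(peaks) < 2L) {
    return(structure(list(maxValue1 = NA_real_, maxValue2 = NA_real_,
                          positionMax1 = NA_integer_,
                          positionMax2 = NA_integer_, minValue = NA_real_,
                          p60_local_maxima = NA_real_, r1 = NA_real_,
                          r2 = NA_real_, accepted = FALSE,
                          reason = "fewer_than_two_peaks"),
                     class = "selection_metrics"))
  }
  h <- structural[peaks]
  ord <- order(h, decreasing = TRUE)
  i1 <- peaks[ord[1]]; i2 <- peaks[ord[2]]
  mv1 <- structural[i1]; mv2 <- structural[i2]
  between <- structural[min(i1, i2):max(i1, i2)]
  minv <- min(between)
  others <- h[-ord[1:2]]
  p60 <- if (length(others)) unname(quantile(others, 0.6)) else 0
  r1 <- (mv1 - mv2) / mv2
  r2 <- minv / mv2
  d <- abs(i1 - i2)
  ok4 <- r1 < thresholds$peak_diff
  ok5 <- d > thresholds$dist_min && d < thresholds$dist_max
  ok6 <- r2 < thresholds$valley
  ok7 <- p60 / mv2 < thresholds$noise
  reason <- if (!ok4) "peak_difference" else if (!ok5) "peak_distance"
  else if (!ok6) "valley" else if (!ok7) "noisy" else NA_character_
  structure(list(maxValue1 = mv1, maxValue2 = mv2,
                 positionMax1 = as.integer(i1), positionMax2 = as.integer(i2),
                 minValue = minv, p60_local_maxima = p60,
                 r1 = r1, r2 = r2,
                 accepted = ok4 && ok5 && ok6 && ok7, reason = reason),
            class = "selection_metrics")
}

#' Rank accepted profiles and keep the best
#'
#' Each accepted profile is ranked on two criteria: `r1`, the relative
#' peak-height difference, and `r2`, the valley-to-peak ratio (smaller is
#' better for both). The final order is the unweighted combination of the
#' two per-criterion rank positions (sum of integer ranks, ties by `r1`
#' then anchor coordinates), and the best `top_n` profiles are returned
#' with their `rank` field set.
#'
#' @param accepted list of `profile_pair`s with populated metrics.
#' @param top_n number of profiles to keep (default 20).
#' @return list of at most `top_n` profiles, in rank order.
#' @export
rank_profiles <- function(accepted, top_n = 20L) {
  if (!length(accepted)) return(accepted)
  r1 <- vapply(accepted, function(p) p$metrics$r1, 0)
  r2 <- vapply(accepted, function(p) p$metrics$r2, 0)
  ax <- vapply(accepted, function(p) p$anchor[2], 0L)
  ay <- vapply(accepted, function(p) p$anchor[1], 0L)
  total <- rank(r1, ties.method = "min") + rank(r2, ties.method = "min")
  ord <- order(total, r1, ax, ay)
  if (length(ord) < top_n)
    warning(sprintf("only %d accepted profiles (requested top %d)",
                    length(ord), top_n))
  keep <- ord[seq_len(min(top_n, length(ord)))]
  out <- accepted[keep]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Build the model (average) structural profile
#'
#' Averages the accepted structural profiles, locates the two peaks of the
#' average, sets their midpoint as the null point, and cuts the model to
#' `out_length` pixels centred on it.
#'
#' @param profiles list of accepted `profile_pair`s, or a matrix with one
#'   raw structural profile per row.
#' @param out_length model length (default 61).
#' @return object of class `model_profile`: `values` (length 61), `peaks`
#'   (indices on the model), `midpoint` (its centre index).
#' @export
build_model_profile <- function(profiles, out_length = 61L) {
  mat <- if (is.matrix(profiles)) profiles
  else do.call(rbind, lapply(profiles, function(p) p$structural))
  if (is.null(mat) || nrow(mat) < 1L) stop("no accepted profiles")
  avg <- colMeans(mat)
  peaks <- local_maxima(moving_average(avg, 3L))
  if (length(peaks) < 2L)
    stop("average profile has fewer than two peaks; dataset unusable")
  h <- avg[peaks]
  top <- sort(peaks[order(h, decreasing = TRUE)][1:2])
  mid <- as.integer(round(mean(top)))
  half <- (out_length - 1L) %/% 2L
  idx <- (mid - half):(mid + half)
  if (idx[1] < 1L || idx[length(idx)] > length(avg))
    stop("model midpoint too close to the profile end")
  structure(list(values = avg[idx], peaks = top - (mid - half) + 1L,
                 midpoint = half + 1L),
            class = "model_profile")
}

#' Center a profile pair against the model profile
#'
#' Evaluates the dot product between the raw structural profile and the
#' model profile at every integer shift in `[-max_shift, +max_shift]`, and
#' applies the argmax shift to both channels; ties are resolved by the
#' smallest absolute shift (negative first). Both channels are then cut to
#' the model length, centred on the model midpoint.
#'
#' @param pair a raw `profile_pair` (length 81).
#' @param model a [build_model_profile()] result (length 61).
#' @param max_shift maximum allowed shift in pixels (default 10).
#' @return the centred `profile_pair` (61 px channels, `shift` recorded).
#' @export
center_profile <- function(pair, model, max_shift = 10L) {
  L <- length(pair$structural)
  M <- length(model$values)
  half <- (M - 1L) / 2L
  ctr <- (L + 1L) / 2L
  shifts <- (-max_shift):max_shift
  shifts <- shifts[order(abs(shifts), shifts)]
  dots <- vapply(shifts, function(s) {
    sum(pair$structural[(ctr - s - half):(ctr - s + half)] * model$values)
  }, 0)
  s <- shifts[which.max(dots)]
  idx <- (ctr - s - half):(ctr - s + half)
  pair$structural <- pair$structural[idx]
  pair$functional <- pair$functional[idx]
  pair$shift <- as.integer(s)
  pair
}

#' Extract, select and rank all profiles of one image
#'
#' Runs the profiling stage over every pruned-skeleton pixel: tangent fit,
#' orthogonal profile extraction, the four selection criteria, ranking,
#' model-profile construction from the accepted profiles and centering of
#' both channels.
#'
#' @param image a [two_channel_image()].
#' @param skel a pruned `skeleton`.
#' @param thresholds a [selection_thresholds()].
#' @param length,width_lines profile geometry, see [extract_profile()].
#' @param top_n profiles kept by ranking (default 20).
#' @param max_shift centering search radius (default 10).
#' @param stride anchor stride along the skeleton (default 1 = every
#'   pixel).
#' @return list with `accepted` (centred accepted profiles, rank set on
#'   the top ones), `model` (the model profile or NULL), and `log` (counts:
#'   extracted, skipped out-of-bounds, accepted).
#' @export
extract_image_profiles <- function(image, skel,
                                   thresholds = selection_thresholds(),
                                   length = 81L, width_lines = 3L,
                                   top_n = 20L, max_shift = 10L,
                                   stride = 1L) {
  px <- skel$pixels
  if (nrow(px) == 0L)
    return(list(accepted = list(), model = NULL,
                log = list(extracted = 0L, skipped = 0L, accepted = 0L)))
  anchors <- px[seq(1L, nrow(px), by = stride), , drop = FALSE]
  accepted <- list()
  n_extracted <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(anchors))) {
    a <- c(anchors$row[i], anchors$col[i])
    dir <- fit_tangent(skel, a)
    if (is.null(dir)) next
    pp <- extract_profile(image, a, dir, length = length,
                          width_lines = width_lines)
    if (is.null(pp)) { n_skipped <- n_skipped + 1L; next }
    n_extracted <- n_extracted + 1L
    pp$metrics <- select_profile(pp$structural, thresholds)
    if (pp$metrics$accepted) accepted[[base::length(accepted) + 1L]] <- pp
  }
  model <- NULL
  if (base::length(accepted)) {
    ranked <- rank_profiles(accepted, top_n = min(top_n, base::length(accepted)))
    rank_map <- stats::setNames(
      vapply(ranked, function(p) p$rank, 0L),
      vapply(ranked, function(p) paste(p$anchor, collapse = ","), ""))
    model <- tryCatch(build_model_profile(accepted), error = function(e) NULL)
    if (!is.null(model)) {
      accepted <- lapply(accepted, function(p) {
        key <- paste(p$anchor, collapse = ",")
        if (!is.na(rank_map[key])) p$rank <- unname(rank_map[key])
        center_profile(p, model, max_shift = max_shift)
      })
    }
  }
  list(accepted = accepted, model = model,
       log = list(extracted = n_extracted, skipped = n_skipped,
                  accepted = base::length(accepted)))
}
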
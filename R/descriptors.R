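# Zone model and densitometric descriptors of centred profiles.
#
# A centred 61-px profile is partitioned around its two structural peaks:
# zone 1 (5 px) at the inter-peak midpoint, zones 2a/2b (5 px) on the
# peaks (canalicular membrane), zones 3a/3b (5 px) just outside them
# (peri-membrane cytoplasm), zones 4a/4b (10 px) further out (deep
# cytoplasm), zone 5 peak-to-peak (canalicular interior, peak pixels
# included) and zones 6a/6b from one pixel outside each peak to the
# profile ends. Zones 3 and 4 abut their inner neighbours with no gaps.

#' Place the zone model on a centred structural profile
#'
#' @param structural centred structural profile (61 px) — used to detect
#'   the peaks when `peaks` is not given.
#' @param peaks optional integer vector of the two peak indices (1-based).
#' @param zone_lengths named lengths in pixels for zones 1, 2, 3 (odd) and
#'   4; defaults 5, 5, 5, 10.
#' @return object of class `zone_model`: list of inclusive index ranges
#'   (`z1`, `z2a`, ..., `z6b`), the peak indices and a `truncated` flag set
#'   when a zone had to be clipped at the profile ends.
#' @export
locate_zones <- function(structural, peaks = NULL,
                         zone_lengths = c(z1 = 5L, z2 = 5L, z3 = 5L,
                                          z4 = 10L)) {
  n <- length(structural)
  if (is.null(peaks)) {
    idx <- local_maxima(moving_average(structural, 3L))
    if (length(idx) < 2L) stop("profile has fewer than two peaks")
    h <- structural[idx]
    peaks <- sort(idx[order(h, decreasing = TRUE)][1:2])
  }
  peaks <- sort(as.integer(peaks))
  p1 <- peaks[1]; p2 <- peaks[2]
  h1 <- (zone_lengths[["z1"]] - 1L) %/% 2L
  h2 <- (zone_lengths[["z2"]] - 1L) %/% 2L
  l3 <- zone_lengths[["z3"]]; l4 <- zone_lengths[["z4"]]
  mid <- as.integer(round((p1 + p2) / 2))
  z <- list(
    z1 = c(mid - h1, mid + h1),
    z2a = c(p1 - h2, p1 + h2), z2b = c(p2 - h2, p2 + h2),
    z3a = c(p1 - h2 - l3, p1 - h2 - 1L), z3b = c(p2 + h2 + 1L, p2 + h2 + l3),
    z4a = c(p1 - h2 - l3 - l4, p1 - h2 - l3 - 1L),
    z4b = c(p2 + h2 + l3 + 1L, p2 + h2 + l3 + l4),
    z5 = c(p1, p2),
    z6a = c(1L, p1 - 1L), z6b = c(p2 + 1L, n))
  truncated <- FALSE
  for (nm in names(z)) {
    r <- z[[nm]]
    if (r[1] < 1L || r[2] > n) truncated <- TRUE
    z[[nm]] <- c(max(r[1], 1L), min(r[2], n))
    if (z[[nm]][1] > z[[nm]][2]) z[[nm]] <- NULL
  }
  structure(c(z, list(peaks = c(p1, p2), truncated = truncated)),
            class = "zone_model")
}

zone_sum <- function(v, range) {
  if (is.null(range)) return(0)
  sum(v[range[1]:range[2]])
}

#' Zone descriptors of a functional profile
#'
#' Sums the functional intensities over the zone groups and forms the nine
#' unitless ratio descriptors plus the legacy profile variance:
#' `X = sum1/sum2`, `Y = sum1/sum3`, `Z = sum1/sum4`,
#' `A = sum1/(sum2+sum3)`, `B = sum1/(sum3+sum4)`, `C = sum2/sum3`,
#' `D = sum2/sum4`, `E = sum2/(sum3+sum4)` and the internalization degree
#' `F = sum5/(sum5+sum6)`. A zero denominator yields `NA`, never an error.
#'
#' @param functional centred functional profile (same length as the
#'   profile the zones were placed on).
#' @param zones a [locate_zones()] result.
#' @return object of class `descriptor_set`: one-row data frame with
#'   `sum1`..`sum6`, `X`..`F` and `variance`.
#' @export
compute_descriptors <- function(functional, zones) {
  s1 <- zone_sum(functional, zones$z1)
  s2 <- zone_sum(functional, zones$z2a) + zone_sum(functional, zones$z2b)
  s3 <- zone_sum(functional, zones$z3a) + zone_sum(functional, zones$z3b)
  s4 <- zone_sum(functional, zones$z4a) + zone_sum(functional, zones$z4b)
  s5 <- zone_sum(functional, zones$z5)
  s6 <- zone_sum(functional, zones$z6a) + zone_sum(functional, zones$z6b)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  out <- data.frame(
    sum1 = s1, sum2 = s2, sum3 = s3, sum4 = s4, sum5 = s5, sum6 = s6,
    X = rat(s1, s2), Y = rat(s1, s3), Z = rat(s1, s4),
    A = rat(s1, s2 + s3), B = rat(s1, s3 + s4),
    C = rat(s2, s3), D = rat(s2, s4), E = rat(s2, s3 + s4),
    F = rat(s5, s5 + s6),
    variance = profile_variance(functional))
  class(out) <- c("descriptor_set", "data.frame")
  out
}

#' Positional variance of an intensity profile
#'
#' The lateral position is treated as a random variable with density
#' proportional to the intensity; positions are the pixel bin centres
#' rescaled to the unit interval, `(i - 0.5) / n`. The variance of that
#' distribution is the legacy translocation descriptor: broader
#' functional-marker distributions give larger values, and it is invariant
#' to scaling of the intensities.
#'
#' @param functional intensity profile (nonnegative).
#' @return unitless variance, or `NA` for a zero-total profile.
#' @export
profile_variance <- function(functional) {
  tot <- sum(functional)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  n <- length(functional)
  x <- (seq_len(n) - 0.5) / n
  w <- functional / tot
  mu <- sum(w * x)
  sum(w * (x - mu)^2)
}
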
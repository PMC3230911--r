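# Statistical comparison of descriptor distributions.

#' Unpaired Wilcoxon rank-sum test
#'
#' Two-sided p-value of the Wilcoxon-Mann-Whitney rank-sum statistic.
#' For combined sample sizes up to 20 without ties the exact null
#' distribution is used; otherwise the tie-corrected normal approximation
#' with continuity correction. Missing values are dropped.
#'
#' @param a,b numeric samples (nonempty after removing `NA`).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return p-value in (0, 1].
#' @export
rank_sum_test <- function(a, b, alternative = "two.sided") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("a sample is empty after dropping NAs")
  exact <- (length(a) + length(b) <= 20L) && !any(duplicated(c(a, b)))
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
  min(p, 1)
}

#' Repeated-subsampling rank-sum comparison of two datasets
#'
#' Emulates the equal-sample-size protocol: per repetition, `n` values are
#' drawn without replacement from each dataset and compared with
#' [rank_sum_test()]; the per-descriptor median p-value over `reps`
#' repetitions is reported. Two conditions are called significantly
#' distinct for a descriptor when its median p-value is below 0.05.
#'
#' @param dsA,dsB data frames of descriptor values (columns = descriptors,
#'   rows = profiles) or plain numeric vectors.
#' @param n subsample size per dataset (default 100); lowered, with a
#'   message, when a dataset has fewer rows.
#' @param reps number of repetitions (default 100).
#' @param seed integer seed; identical seeds give identical results.
#' @return object of class `comparison_result`: `median_p` (named),
#'   `p_values` (reps x descriptors matrix), `significant`, `n_used`,
#'   `reps`, `seed`.
#' @export
subsample_compare <- function(dsA, dsB, n = 100L, reps = 100L, seed = 1L) {
  as_df <- function(x) if (is.data.frame(x)) x else data.frame(value = x)
  dsA <- as_df(dsA); dsB <- as_df(dsB)
  vars <- intersect(names(dsA), names(dsB))
  vars <- vars[vapply(vars, function(v) is.numeric(dsA[[v]]), TRUE)]
  if (!length(vars)) stop("no common numeric descriptor columns")
  n_used <- min(n, nrow(dsA), nrow(dsB))
  if (n_used < n)
    message(sprintf("subsample size lowered to %d (datasets have %d and %d rows)",
                    n_used, nrow(dsA), nrow(dsB)))
  pv <- local_seed(seed, {
    m <- matrix(NA_real_, reps, length(vars),
                dimnames = list(NULL, vars))
    for (r in seq_len(reps)) {
      ia <- sample.int(nrow(dsA), n_used)
      ib <- sample.int(nrow(dsB), n_used)
      for (v in vars)
        m[r, v] <- tryCatch(rank_sum_test(dsA[[v]][ia], dsB[[v]][ib]),
                            error = function(e) NA_real_)
    }
    m
  })
  med <- apply(pv, 2, median, na.rm = TRUE)
  structure(list(median_p = med, p_values = pv,
                 significant = med < 0.05, n_used = n_used,
                 reps = reps, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d x %d subsampling, %d repetitions\n",
              x$n_used, x$n_used, x$reps))
  print(signif(x$median_p, 3))
  invisible(x)
}

#' Density-crossing discrimination threshold
#'
#' Kernel density estimates (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of both samples are intersected between the two sample
#' medians; the crossing point is the discrimination threshold. When
#' several crossings exist, the one minimising the training error is
#' chosen; when none lies between the medians (or a sample is degenerate)
#' the midpoint of the medians is returned and flagged.
#'
#' @param valuesA,valuesB numeric samples (>= 20 values each).
#' @param min_n minimum sample size (default 20).
#' @return list with `threshold`, `flagged` (TRUE when the fallback was
#'   used), and `bandwidths`.
#' @export
density_crossing_threshold <- function(valuesA, valuesB, min_n = 20L) {
  a <- valuesA[!is.na(valuesA)]; b <- valuesB[!is.na(valuesB)]
  if (length(a) < min_n || length(b) < min_n)
    stop("both samples need at least ", min_n, " values")
  mA <- median(a); mB <- median(b)
  lo <- min(mA, mB); hi <- max(mA, mB)
  if (sd(a) == 0 || sd(b) == 0 || lo == hi)
    return(list(threshold = (mA + mB) / 2, flagged = TRUE,
                bandwidths = c(NA_real_, NA_real_)))
  dA <- density(a, from = lo, to = hi, n = 512)
  dB <- density(b, from = lo, to = hi, n = 512)
  grid <- dA$x
  fA <- dA$y; fB <- dB$y
  dd <- fA - fB
  cross <- which(dd[-1] * dd[-length(dd)] < 0)
  if (!length(cross)) {
    # no sign change: for strongly separated samples both densities vanish
    # between the medians; take the centre of that empty region
    tiny <- pmax(fA, fB) <= 1e-12 * max(fA, fB)
    if (any(tiny))
      return(list(threshold = median(grid[tiny]), flagged = FALSE,
                  bandwidths = c(dA$bw, dB$bw)))
    return(list(threshold = (mA + mB) / 2, flagged = TRUE,
                bandwidths = c(dA$bw, dB$bw)))
  }
  cand <- vapply(cross, function(i) {
    grid[i] + (grid[i + 1] - grid[i]) * dd[i] / (dd[i] - dd[i + 1])
  }, 0)
  if (length(cand) > 1L) {
    # A predicts on its median's side of the threshold; count errors
    err <- vapply(cand, function(t) {
      if (mA < mB) sum(a >= t) + sum(b < t) else sum(a < t) + sum(b >= t)
    }, 0)
    cand <- cand[which.min(err)]
  }
  list(threshold = cand[1], flagged = FALSE, bandwidths = c(dA$bw, dB$bw))
}

#' Evaluate the simple threshold classifier
#'
#' Predicts the class of each value by thresholding and reports precision,
#' recall and F-score of the positive class, in percent. The positive
#' class is predicted on the side given by `positive_side` (for the
#' membrane-concentration descriptors the internalized condition lies on
#' the lower side).
#'
#' @param values numeric descriptor values.
#' @param labels factor or character vector of true classes, same length.
#' @param threshold discrimination threshold.
#' @param positive label of the positive class.
#' @param positive_side `"below"` (predict positive when value <
#'   threshold) or `"above"`.
#' @return object of class `classifier_eval`: `precision`, `recall`,
#'   `f_score` (percent; `NA` when undefined), counts, `threshold` and
#'   orientation.
#' @export
evaluate_classifier <- function(values, labels, threshold, positive,
                                positive_side = c("below", "above")) {
  positive_side <- match.arg(positive_side)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels)[ok]
  if (length(unique(labels)) < 2L) stop("two classes are required")
  pred_pos <- if (positive_side == "below") values < threshold
  else values > threshold
  is_pos <- labels == positive
  tp <- sum(pred_pos & is_pos)
  fp <- sum(pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision, recall = recall, f_score = f,
                 tp = tp, fp = fp, fn = fn, threshold = threshold,
                 positive = positive, positive_side = positive_side),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval> precision %.2f%%, recall %.2f%%, F %.2f%% (threshold %.4g, positive '%s' %s)\n",
              x$precision, x$recall, x$f_score, x$threshold, x$positive,
              x$positive_side))
  invisible(x)
}
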
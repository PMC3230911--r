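# Supervised texture segmentation of the structural channel.
#
# The membrane foreground is bright, thin and high-contrast against a flat
# noisy background, so per-window intensity statistics plus gradient and
# ordinal contrast measures separate the two classes well. The texture
# feature list is fixed and documented; the classifier is a
# ridge-regularised logistic regression behind a train/predict contract,
# recorded in the mask provenance.

TEXTURE_FEATURES <- c("mean", "sd", "skewness", "grad_mean", "grad_sd",
                      "center_contrast", "contrast_h", "contrast_v")

#' Per-pixel texture features
#'
#' Computes, for every pixel, a fixed-length feature vector from the square
#' window centred on it: window mean, standard deviation and skewness of
#' intensity; mean and standard deviation of the central-difference
#' gradient magnitude; the centre pixel's intensity minus the window mean;
#' and the window means of the absolute horizontal and vertical
#' neighbour-to-neighbour intensity differences (ordinal contrast). Borders
#' are handled by mirror reflection.
#'
#' @param channel intensity matrix.
#' @param window odd window edge length in pixels (>= 3, default 15).
#' @return numeric array `nrow x ncol x 8` with feature names in the third
#'   dimension; attribute `window` records the window used.
#' @export
extract_texture_features <- function(channel, window = 15L) {
  stopifnot(is.matrix(channel), window >= 3L, window %% 2L == 1L)
  if (window > min(dim(channel)))
    stop("texture window larger than the image")
  I <- channel
  mu <- box_mean(I, window)
  m2 <- box_mean(I^2, window)
  v <- pmax(m2 - mu^2, 0)
  sdv <- sqrt(v)
  m3 <- box_mean(I^3, window)
  skew <- m3 - 3 * mu * m2 + 2 * mu^3
  skew <- ifelse(sdv > 1e-12, skew / sdv^3, 0)
  p <- reflect_pad(I, 1L)
  nr <- nrow(I); nc <- ncol(I)
  gx <- (p[2:(nr + 1), 3:(nc + 2)] - p[2:(nr + 1), 1:nc]) / 2
  gy <- (p[3:(nr + 2), 2:(nc + 1)] - p[1:nr, 2:(nc + 1)]) / 2
  g <- sqrt(gx^2 + gy^2)
  gmu <- box_mean(g, window)
  gsd <- sqrt(pmax(box_mean(g^2, window) - gmu^2, 0))
  dh <- abs(p[2:(nr + 1), 2:(nc + 1)] - p[2:(nr + 1), 1:nc])
  dv <- abs(p[2:(nr + 1), 2:(nc + 1)] - p[1:nr, 2:(nc + 1)])
  out <- array(c(mu, sdv, skew, gmu, gsd, I - mu,
                 box_mean(dh, window), box_mean(dv, window)),
               dim = c(nr, nc, length(TEXTURE_FEATURES)),
               dimnames = list(NULL, NULL, TEXTURE_FEATURES))
  attr(out, "window") <- as.integer(window)
  out
}

#' Labeled example regions for foreground training
#'
#' @param foreground,background logical masks (same dimension as the image)
#'   or two-column (row, col) index matrices marking example pixels of each
#'   class. The sets must be disjoint and nonempty.
#' @return object of class `labeled_regions`.
#' @export
labeled_regions <- function(foreground, background) {
  to_idx <- function(x) {
    if (is.matrix(x) && ncol(x) == 2 && !is.logical(x)) {
      cbind(as.integer(x[, 1]), as.integer(x[, 2]))
    } else which(x != 0, arr.ind = TRUE)
  }
  fg <- to_idx(foreground); bg <- to_idx(background)
  if (nrow(fg) == 0 || nrow(bg) == 0)
    stop("both foreground and background examples are required")
  key <- function(i) paste(i[, 1], i[, 2])
  if (length(intersect(key(fg), key(bg))))
    stop("foreground and background examples overlap")
  structure(list(foreground = fg, background = bg),
            class = "labeled_regions")
}

feature_matrix <- function(features, idx = NULL) {
  d <- dim(features)
  X <- matrix(features, d[1] * d[2], d[3])
  colnames(X) <- dimnames(features)[[3]]
  if (!is.null(idx)) X <- X[(idx[, 2] - 1L) * d[1] + idx[, 1], , drop = FALSE]
  X
}

#' Train the foreground classification model
#'
#' Fits a ridge-regularised logistic regression (deterministic coordinate
#' descent) on the texture features of the labeled example pixels. Classes
#' are balanced by down-sampling to at most `max_per_class` pixels per
#' class (deterministic under `seed`).
#'
#' @param features output of [extract_texture_features()].
#' @param labels a [labeled_regions()] object.
#' @param lambda ridge penalty used for prediction.
#' @param max_per_class training-set cap per class.
#' @param seed seed for the down-sampling draw.
#' @return object of class `foreground_model` with the fitted classifier,
#'   the feature window, and provenance.
#' @export
train_foreground_model <- function(features, labels, lambda = 1e-4,
                                   max_per_class = 4000L, seed = 1L) {
  stopifnot(inherits(labels, "labeled_regions"))
  sub <- function(idx) {
    if (nrow(idx) > max_per_class)
      idx[sort(sample.int(nrow(idx), max_per_class)), , drop = FALSE]
    else idx
  }
  picked <- local_seed(seed, list(fg = sub(labels$foreground),
                                  bg = sub(labels$background)))
  X <- rbind(feature_matrix(features, picked$fg),
             feature_matrix(features, picked$bg))
  y <- c(rep(1L, nrow(picked$fg)), rep(0L, nrow(picked$bg)))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = c(1, 0.1, 0.01, lambda))
  structure(list(fit = fit, lambda = lambda,
                 window = attr(features, "window"),
                 features = colnames(X),
                 provenance = list(classifier = "ridge logistic (glmnet)",
                                   lambda = lambda,
                                   n_train = length(y))),
            class = "foreground_model")
}

predict_foreground_prob <- function(model, features) {
  X <- feature_matrix(features)
  p <- stats::predict(model$fit, newx = X, s = model$lambda,
                      type = "response")
  matrix(p, dim(features)[1], dim(features)[2])
}

#' Classify image pixels as membrane foreground
#'
#' Applies a trained [train_foreground_model()] to an intensity channel
#' (features are recomputed with the model's window) and thresholds the
#' foreground probability at 0.5.
#'
#' @param channel intensity matrix, or a precomputed feature array.
#' @param model a `foreground_model`.
#' @return object of class `foreground_mask`: logical `mask` plus
#'   `provenance` (classifier, window, threshold).
#' @export
classify_foreground <- function(channel, model) {
  features <- if (is.array(channel) && length(dim(channel)) == 3) channel
  else extract_texture_features(channel, model$window)
  prob <- predict_foreground_prob(model, features)
  structure(list(mask = prob > 0.5,
                 provenance = c(model$provenance,
                                list(window = model$window, threshold = 0.5))),
            class = "foreground_mask")
}

#' @export
print.foreground_mask <- function(x, ...) {
  cat(sprintf("<foreground_mask> %d x %d, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Morphological cleaning of a foreground mask
#'
#' Applies, in order: morphological opening with a 3 x 3 box (deletes tiny
#' objects), removal of connected components (8-connectivity) smaller than
#' the first area threshold, morphological closing with the same element
#' (bridges gaps the opening may have introduced), and removal of
#' components smaller than the second, larger area threshold — larger
#' because closing may have merged fragments. The default thresholds
#' (125 and 250 px) refer to a 300 nm pixel size and are rescaled by
#' `(300 / pixel_size)^2` for other resolutions.
#'
#' @param mask a `foreground_mask` or binary matrix.
#' @param pixel_size pixel size in nm (default 300, the calibration
#'   resolution of the thresholds).
#' @param area_threshold_1,area_threshold_2 component-area thresholds in
#'   pixels at 300 nm pixel size.
#' @param element_size edge of the square structuring element (default 3).
#' @return cleaned `foreground_mask` with the applied thresholds recorded
#'   in its provenance.
#' @export
clean_mask <- function(mask, pixel_size = 300, area_threshold_1 = 125,
                       area_threshold_2 = 250, element_size = 3L) {
  m <- as_binary_matrix(mask)
  scale <- (300 / pixel_size)^2
  a1 <- area_threshold_1 * scale
  a2 <- area_threshold_2 * scale
  brush <- EBImage::makeBrush(element_size, shape = "box")
  m <- EBImage::opening(m, brush)
  m <- drop_small_components(m, a1)
  m <- EBImage::closing(m, brush)
  m <- drop_small_components(m, a2)
  prov <- if (inherits(mask, "foreground_mask")) mask$provenance else list()
  structure(list(mask = m == 1,
                 provenance = c(prov, list(
                   cleaning = sprintf(
                     "open %dx%d, area >= %g, close, area >= %g",
                     element_size, element_size, a1, a2)))),
            class = "foreground_mask")
}

drop_small_components <- function(m, min_area) {
  m <- (as.matrix(m) != 0) * 1L
  lab <- cpp_label(m, 8L)
  if (max(lab) == 0L) return(m)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_area)
  if (length(drop)) m[lab %in% drop] <- 0L
  m
}
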
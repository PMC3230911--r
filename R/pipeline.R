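# End-to-end workflow: segmentation -> skeleton -> profiling -> descriptors
# per image, and dataset-level statistical comparison.

#' Workflow configuration
#'
#' Collects every tunable of the pipeline with defaults matching the
#' published protocol: 15-px texture window, 3 x 3 structuring element,
#' area thresholds 125/250 px (at 300 nm pixels), 7-px minimum skeleton
#' fragment, 81-px profiles widened to 0.3 um, selection thresholds
#' 15% / (7, 26) px / 0.2 / 0.4, top 20 ranked profiles, +/- 10 px
#' centering shift, zone lengths 5/5/5/10 px, and 100 x 100 subsampling
#' with 100 repetitions.
#'
#' @param pixel_size pixel size of the images, nm.
#' @param texture_window texture feature window, px.
#' @param element_size structuring element edge, px.
#' @param area_threshold_1,area_threshold_2 mask cleaning area thresholds
#'   at 300 nm pixel size.
#' @param min_fragment minimum skeleton fragment, px.
#' @param profile_length raw profile length, px (odd).
#' @param profile_width_um averaged profile width, um.
#' @param peak_diff,dist_min,dist_max,valley,noise selection thresholds,
#'   see [selection_thresholds()].
#' @param top_n ranked profiles kept per image.
#' @param max_shift centering search radius, px.
#' @param zone_lengths zone lengths (z1, z2, z3, z4), px.
#' @param subsample_n,subsample_reps comparison subsampling parameters.
#' @param stride skeleton anchor stride.
#' @param seed default seed for stochastic stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(pixel_size = 100, texture_window = 15L,
                       element_size = 3L, area_threshold_1 = 125,
                       area_threshold_2 = 250, min_fragment = 7L,
                       profile_length = 81L, profile_width_um = 0.3,
                       peak_diff = 0.15, dist_min = 7, dist_max = 26,
                       valley = 0.2, noise = 0.4, top_n = 20L,
                       max_shift = 10L,
                       zone_lengths = c(z1 = 5L, z2 = 5L, z3 = 5L, z4 = 10L),
                       subsample_n = 100L, subsample_reps = 100L,
                       stride = 1L, seed = 1L) {
  cfg <- list(pixel_size = pixel_size, texture_window = texture_window,
              element_size = element_size,
              area_threshold_1 = area_threshold_1,
              area_threshold_2 = area_threshold_2,
              min_fragment = min_fragment, profile_length = profile_length,
              profile_width_um = profile_width_um, peak_diff = peak_diff,
              dist_min = dist_min, dist_max = dist_max, valley = valley,
              noise = noise, top_n = top_n, max_shift = max_shift,
              zone_lengths = zone_lengths, subsample_n = subsample_n,
              subsample_reps = subsample_reps, stride = stride, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

config_thresholds <- function(config) {
  selection_thresholds(peak_diff = config$peak_diff,
                       dist_min = config$dist_min,
                       dist_max = config$dist_max,
                       valley = config$valley, noise = config$noise,
                       pixel_size = config$pixel_size)
}

config_width_lines <- function(config) {
  max(1L, as.integer(round(config$profile_width_um * 1000 /
                             config$pixel_size)))
}

# Training labels from the synthetic ground truth of one image: the ridge
# band (within 2 ridge sigma of the true ridges) is foreground and
# everything else background. Labelling the background right up to the
# band keeps the decision boundary at the band edge instead of letting it
# smear outward by the texture window.
labels_from_truth <- function(truth, shape) {
  band <- matrix(FALSE, shape[1], shape[2])
  for (cn in truth$canaliculi) band <- band | cn$band
  labeled_regions(band, !band)
}

#' Run the extraction workflow over a dataset of images
#'
#' Per image: texture classification of the structural channel, mask
#' cleaning, skeletonization and pruning, orthogonal profile extraction
#' with selection, ranking and centering, and zone-descriptor computation
#' for every accepted profile. The foreground model is trained once on the
#' first image (from `labels`, or automatically from synthetic ground
#' truth) and applied to the whole dataset.
#'
#' @param images list of [two_channel_image()] objects, of
#'   `list(image, truth)` pairs as returned by [generate_image()], or a
#'   character vector of TIFF paths (read with [read_two_channel_tiff()]).
#' @param config a [run_config()].
#' @param model optional pre-trained [train_foreground_model()] model.
#' @param labels optional [labeled_regions()] for training on the first
#'   image.
#' @param out_dir optional directory: writes `profiles.csv`,
#'   `descriptors.csv` and `manifest.json`.
#' @return object of class `dataset_result`: per-image entries (counts,
#'   accepted profiles, descriptor rows), pooled `descriptors` data frame
#'   (with `image` and `rank` columns), the `model`, `config` and
#'   aggregate medians.
#' @export
run_extraction <- function(images, config = run_config(), model = NULL,
                           labels = NULL, out_dir = NULL) {
  if (is.character(images))
    images <- lapply(images, read_two_channel_tiff,
                     pixel_size = config$pixel_size)
  if (!length(images)) stop("empty image dataset")
  norm <- lapply(images, function(x) {
    if (inherits(x, "two_channel_image")) list(image = x, truth = NULL)
    else x
  })
  if (is.null(model)) {
    if (is.null(labels)) {
      tr <- norm[[1]]$truth
      if (is.null(tr))
        stop("provide a trained model or labeled regions for training")
      labels <- labels_from_truth(tr, dim(norm[[1]]$image$structural))
    }
    feats <- extract_texture_features(norm[[1]]$image$structural,
                                      config$texture_window)
    model <- train_foreground_model(feats, labels, seed = config$seed)
  }
  thr <- config_thresholds(config)
  wl <- config_width_lines(config)
  per_image <- vector("list", length(norm))
  desc_all <- NULL
  for (i in seq_along(norm)) {
    img <- norm[[i]]$image
    fg <- classify_foreground(img$structural, model)
    cl <- clean_mask(fg, pixel_size = config$pixel_size,
                     area_threshold_1 = config$area_threshold_1,
                     area_threshold_2 = config$area_threshold_2,
                     element_size = config$element_size)
    sk <- prune(skeletonize(cl), min_fragment = config$min_fragment)
    pr <- extract_image_profiles(img, sk, thresholds = thr,
                                 length = config$profile_length,
                                 width_lines = wl, top_n = config$top_n,
                                 max_shift = config$max_shift,
                                 stride = config$stride)
    desc <- profile_descriptors(pr$accepted, config$zone_lengths, image = i)
    flagged <- length(pr$accepted) == 0L
    per_image[[i]] <- list(counts = c(extracted = pr$log$extracted,
                                      skipped = pr$log$skipped,
                                      accepted = pr$log$accepted,
                                      ranked = sum(!is.na(desc$rank))),
                           profiles = pr$accepted, model_profile = pr$model,
                           descriptors = desc, flagged = flagged)
    desc_all <- rbind(desc_all, desc)
  }
  res <- structure(list(images = per_image, descriptors = desc_all,
                        model = model, config = config,
                        aggregates = if (!is.null(desc_all) && nrow(desc_all))
                          vapply(desc_all[descriptor_names()], median,
                                 0, na.rm = TRUE) else NULL),
                   class = "dataset_result")
  if (!is.null(out_dir)) write_dataset_result(res, out_dir)
  res
}

descriptor_names <- function() c("X", "Y", "Z", "A", "B", "C", "D", "E",
                                 "F", "variance")

# Descriptor rows for a list of centred accepted profiles.
profile_descriptors <- function(accepted, zone_lengths, image = NA) {
  rows <- lapply(accepted, function(p) {
    zones <- tryCatch(locate_zones(p$structural, zone_lengths = zone_lengths),
                      error = function(e) NULL)
    if (is.null(zones)) return(NULL)
    d <- compute_descriptors(p$functional, zones)
    cbind(data.frame(image = image, anchor_row = p$anchor[1],
                     anchor_col = p$anchor[2], rank = p$rank,
                     shift = p$shift, truncated = zones$truncated), d)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(image = integer(0), anchor_row = integer(0),
                      anchor_col = integer(0), rank = integer(0),
                      shift = integer(0), truncated = logical(0))
    for (v in c("sum1", "sum2", "sum3", "sum4", "sum5", "sum6",
                descriptor_names())) out[[v]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.dataset_result <- function(x, ...) {
  counts <- t(vapply(x$images, function(im) im$counts, numeric(4)))
  cat(sprintf("<dataset_result> %d image(s); profiles extracted %d, accepted %d\n",
              length(x$images), sum(counts[, "extracted"]),
              sum(counts[, "accepted"])))
  if (!is.null(x$aggregates)) {
    cat("median descriptors:\n")
    print(signif(x$aggregates, 3))
  }
  invisible(x)
}

# Pool descriptor values of a dataset_result; mode "top" keeps the ranked
# best profiles per image, "all" every accepted profile.
pool_descriptors <- function(result, mode = c("top", "all"), top_n = NULL) {
  mode <- match.arg(mode)
  d <- result$descriptors
  if (mode == "top") {
    n <- if (is.null(top_n)) result$config$top_n else top_n
    d <- d[!is.na(d$rank) & d$rank <= n, , drop = FALSE]
  }
  d
}

#' Compare two extracted datasets
#'
#' Pools the descriptor values of each dataset (top-ranked profiles per
#' image by default, mirroring the ranked evaluation modes), runs the
#' repeated-subsampling rank-sum comparison for every descriptor, and
#' fits/evaluates the density-crossing threshold classifier for one chosen
#' descriptor. The positive (internalized) class is taken as the dataset
#' with the lower median of that descriptor, predicted on the lower side
#' of the threshold.
#'
#' @param result_a,result_b [run_extraction()] results.
#' @param config a [run_config()]; defaults to `result_a`'s.
#' @param mode `"top"` (default; ranked best `top_n` per image) or
#'   `"all"` accepted profiles.
#' @param top_n ranked profiles per image used when `mode = "top"`.
#' @param descriptor descriptor for the classifier (default `"D"`).
#' @param seed subsampling seed (default from config).
#' @return list with `comparison` (a `comparison_result`), `classifier`
#'   (a `classifier_eval`), `threshold` info, pooled sizes and the mode.
#' @export
run_comparison <- function(result_a, result_b, config = NULL,
                           mode = c("top", "all"), top_n = NULL,
                           descriptor = "D", seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(config)) config <- result_a$config
  if (is.null(seed)) seed <- config$seed
  da <- pool_descriptors(result_a, mode, top_n)
  db <- pool_descriptors(result_b, mode, top_n)
  if (!nrow(da) || !nrow(db)) stop("a dataset has no accepted profiles")
  vars <- descriptor_names()
  cmp <- subsample_compare(da[vars], db[vars], n = config$subsample_n,
                           reps = config$subsample_reps, seed = seed)
  va <- da[[descriptor]][!is.na(da[[descriptor]])]
  vb <- db[[descriptor]][!is.na(db[[descriptor]])]
  thr <- density_crossing_threshold(va, vb)
  positive <- if (median(va) <= median(vb)) "A" else "B"
  ev <- evaluate_classifier(c(va, vb),
                            rep(c("A", "B"), c(length(va), length(vb))),
                            thr$threshold, positive = positive,
                            positive_side = "below")
  list(comparison = cmp, classifier = ev, threshold = thr,
       n_pooled = c(A = nrow(da), B = nrow(db)), mode = mode,
       descriptor = descriptor)
}
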
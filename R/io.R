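# File interfaces: TIFF images, profile/descriptor CSV, ground-truth JSON,
# YAML configuration, JSON run manifests.

#' Write a two-channel image as a multi-page 16-bit TIFF
#'
#' Page 1 holds the structural channel, page 2 the functional channel.
#' Intensities are clipped to `[0, max_value]` and quantized to 16 bit.
#'
#' @param image a [two_channel_image()].
#' @param path output file path.
#' @param max_value intensity mapped to the 16-bit maximum (default
#'   65535, i.e. intensities are stored as-is).
#' @export
write_two_channel_tiff <- function(image, path, max_value = 65535) {
  q <- function(m) pmin(pmax(m / max_value, 0), 1)
  tiff::writeTIFF(list(q(image$structural), q(image$functional)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel image from TIFF
#'
#' Accepts a single multi-page TIFF (structural first) or a pair of
#' single-channel files.
#'
#' @param path one (multi-page) or two (per-channel) file paths.
#' @param pixel_size pixel size in nm to attach to the image.
#' @param max_value intensity scale of the 16-bit data (default 65535).
#' @return a [two_channel_image()].
#' @export
read_two_channel_tiff <- function(path, pixel_size = 100,
                                  max_value = 65535) {
  to_mat <- function(x) {
    m <- as.matrix(x)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * max_value
  }
  if (length(path) == 2L) {
    s <- to_mat(tiff::readTIFF(path[1]))
    f <- to_mat(tiff::readTIFF(path[2]))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) < 2L) stop("expected a two-page TIFF: ", path)
    s <- to_mat(pages[[1]]); f <- to_mat(pages[[2]])
  }
  two_channel_image(s, f, pixel_size)
}

#' Write ground truth as a JSON sidecar
#'
#' Serializes centerline pixels, true ridge polylines, ridge separation
#' and membrane fraction per canaliculus (the in-memory band masks are
#' not written).
#'
#' @param truth a `ground_truth` from [generate_image()].
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(pixel_size = truth$pixel_size,
              canaliculi = lapply(truth$canaliculi, function(cn) {
                list(centerline = unname(as.matrix(cn$centerline)),
                     ridges = lapply(cn$ridges, function(r)
                       unname(round(as.matrix(r), 3))),
                     membrane_fraction = cn$membrane_fraction,
                     ridge_separation = cn$ridge_separation)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write or read a workflow configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals$zone_lengths <- as.list(vals$zone_lengths) # keep the zone names
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$zone_lengths))
    vals$zone_lengths <- unlist(vals$zone_lengths)
  do.call(run_config, vals)
}

#' Export profiles to CSV
#'
#' One row per profile: metadata (image id, anchor, direction, rank,
#' accepted flag, the ranking criteria r1/r2, centering shift) followed by
#' the structural and functional intensity columns (`s_1...`, `f_1...`).
#' The same layout is the ingestion path for manually extracted profiles.
#'
#' @param profiles list of `profile_pair`s.
#' @param path CSV output path.
#' @param image_id identifier stored in the `image` column.
#' @export
write_profiles <- function(profiles, path, image_id = 1L) {
  rows <- lapply(profiles, function(p) {
    meta <- data.frame(image = image_id, anchor_row = p$anchor[1],
                       anchor_col = p$anchor[2],
                       dir_x = p$direction[1], dir_y = p$direction[2],
                       rank = p$rank, shift = p$shift,
                       accepted = isTRUE(p$metrics$accepted),
                       r1 = if (is.null(p$metrics)) NA_real_ else p$metrics$r1,
                       r2 = if (is.null(p$metrics)) NA_real_ else p$metrics$r2)
    s <- as.data.frame(t(p$structural))
    names(s) <- paste0("s_", seq_along(p$structural))
    f <- as.data.frame(t(p$functional))
    names(f) <- paste0("f_", seq_along(p$functional))
    cbind(meta, s, f)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read profiles from CSV
#'
#' Reads the layout written by [write_profiles()] (or produced by a manual
#' profile-extraction tool following it) back into `profile_pair`s.
#'
#' @param path CSV path.
#' @param pixel_size pixel size in nm to attach.
#' @return list of `profile_pair`s.
#' @export
read_profiles <- function(path, pixel_size = 100) {
  d <- read.csv(path)
  scols <- grep("^s_", names(d)); fcols <- grep("^f_", names(d))
  lapply(seq_len(nrow(d)), function(i) {
    structure(list(anchor = c(d$anchor_row[i], d$anchor_col[i]),
                   direction = c(d$dir_x[i], d$dir_y[i]),
                   structural = as.numeric(d[i, scols]),
                   functional = as.numeric(d[i, fcols]),
                   pixel_size = pixel_size,
                   metrics = list(accepted = as.logical(d$accepted[i]),
                                  r1 = d$r1[i], r2 = d$r2[i]),
                   rank = d$rank[i], shift = d$shift[i]),
              class = "profile_pair")
  })
}

# Write the CSV/JSON outputs of a dataset_result under out_dir.
write_dataset_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_prof <- NULL
  for (i in seq_along(result$images)) {
    ps <- result$images[[i]]$profiles
    if (length(ps)) {
      tmp <- tempfile(fileext = ".csv")
      write_profiles(ps, tmp, image_id = i)
      all_prof <- rbind(all_prof, read.csv(tmp))
      unlink(tmp)
    }
  }
  if (!is.null(all_prof))
    write.csv(all_prof, file.path(out_dir, "profiles.csv"),
              row.names = FALSE)
  write.csv(result$descriptors, file.path(out_dir, "descriptors.csv"),
            row.names = FALSE)
  manifest <- list(package = "canaliq",
                   version = as.character(utils::packageVersion("canaliq")),
                   config = unclass(result$config),
                   n_images = length(result$images))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
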
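# Synthetic two-channel canaliculus images with ground truth.
#
# A canaliculus is modelled as a smooth path flanked by two parallel bright
# ridges in the structural channel (the tight-junction lines), with
# Gaussian cross-sections. The functional channel carries a
# membrane-bound component on the ridges, scaled by membrane_fraction, and
# a cytoplasmic component of Gaussian puncta ("immunoreactive vesicles")
# scaled by 1 - membrane_fraction; the total functional signal is
# independent of membrane_fraction, so internalization redistributes
# signal rather than destroying it.

#' Specification of one synthetic canaliculus
#'
#' @param path numeric matrix with columns (x, y): control points of the
#'   centerline polyline, in pixel coordinates (x = column, y = row).
#' @param ridge_separation distance between the two structural ridges
#'   (canalicular width), nm. Must lie within `separation_range`.
#' @param ridge_sigma Gaussian line spread of each ridge, nm.
#' @param zo1_amplitude peak intensity of the structural ridges.
#' @param zo1_asymmetry amplitude ratio of the second ridge to the first;
#'   1 emulates a canaliculus lying in the image plane, values away from 1
#'   a tilted one whose profile peaks differ in height.
#' @param membrane_fraction fraction (0..1) of functional-marker signal on
#'   the membrane ridges; the remainder goes into cytoplasmic puncta.
#' @param bsep_amplitude peak intensity of the membrane-bound functional
#'   signal when `membrane_fraction = 1`.
#' @param vesicle_density cytoplasmic puncta per square micrometre of the
#'   peri-canalicular band.
#' @param vesicle_sigma Gaussian radius of a punctum, nm.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param background constant background intensity.
#' @param separation_range allowed range for `ridge_separation`, nm;
#'   default 800-2500 nm, the empirical range of canalicular diameters.
#' @return object of class `canaliculus_spec`.
#' @export
canaliculus_spec <- function(path,
                             ridge_separation = 1200,
                             ridge_sigma = 200,
                             zo1_amplitude = 200,
                             zo1_asymmetry = 1,
                             membrane_fraction = 0.9,
                             bsep_amplitude = 150,
                             vesicle_density = 0.5,
                             vesicle_sigma = 200,
                             noise_sigma = 5,
                             background = 10,
                             separation_range = c(800, 2500)) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 2, nrow(path) >= 2)
  if (ridge_separation < separation_range[1] ||
      ridge_separation > separation_range[2])
    stop("ridge_separation outside the allowed range [",
         separation_range[1], ", ", separation_range[2], "] nm")
  if (membrane_fraction < 0 || membrane_fraction > 1)
    stop("membrane_fraction must lie in [0, 1]")
  structure(list(path = path, ridge_separation = ridge_separation,
                 ridge_sigma = ridge_sigma, zo1_amplitude = zo1_amplitude,
                 zo1_asymmetry = zo1_asymmetry,
                 membrane_fraction = membrane_fraction,
                 bsep_amplitude = bsep_amplitude,
                 vesicle_density = vesicle_density,
                 vesicle_sigma = vesicle_sigma,
                 noise_sigma = noise_sigma, background = background),
            class = "canaliculus_spec")
}

#' Two-channel image container
#'
#' Registered structural and functional intensity grids with a common pixel
#' size. Intensities are nonnegative real values; quantization to 16 bit
#' happens only on TIFF export.
#'
#' @param structural,functional numeric matrices of equal dimension.
#' @param pixel_size pixel edge length, nm.
#' @return object of class `two_channel_image`.
#' @export
two_channel_image <- function(structural, functional, pixel_size = 100) {
  stopifnot(is.matrix(structural), is.matrix(functional),
            all(dim(structural) == dim(functional)), pixel_size > 0)
  structure(list(structural = structural, functional = functional,
                 pixel_size = pixel_size),
            class = "two_channel_image")
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, pixel size %g nm\n",
              nrow(x$structural), ncol(x$structural), x$pixel_size))
  invisible(x)
}

# Signed lateral distance of every pixel to a polyline, plus arc-length
# parameters and whether the orthogonal projection falls inside the path
# extent. Vectorised over pixels, looped over segments (few of them).
polyline_field <- function(path, shape) {
  nr <- shape[1]; nc <- shape[2]
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), nc), nr, nc)
  n <- nrow(path)
  best <- matrix(Inf, nr, nc)     # unsigned distance
  sgn <- matrix(1, nr, nc)
  interior <- matrix(FALSE, nr, nc)
  for (i in seq_len(n - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2]) / len2
    tc <- pmin(pmax(t, 0), 1)
    px <- a[1] + tc * ab[1]
    py <- a[2] + tc * ab[2]
    d <- sqrt((X - px)^2 + (Y - py)^2)
    cross <- ab[1] * (Y - a[2]) - ab[2] * (X - a[1])
    upd <- d < best
    best[upd] <- d[upd]
    sgn[upd] <- sign(cross[upd] + (cross[upd] == 0))
    interior <- interior | (t >= 0 & t <= 1)
  }
  list(dist = best * sgn, interior = interior)
}

# Evenly spaced points (and unit normals) along a polyline, step in pixels.
polyline_points <- function(path, step = 0.5) {
  pts <- NULL; nrm <- NULL
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    L <- sqrt(sum((b - a)^2))
    if (L == 0) next
    t <- seq(0, 1, by = step / L)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    u <- (b - a) / L
    pts <- rbind(pts, seg)
    nrm <- rbind(nrm, matrix(c(-u[2], u[1]), nrow(seg), 2, byrow = TRUE))
  }
  list(points = pts, normals = nrm)
}

render_canaliculus <- function(spec, shape, pixel_size) {
  s2 <- spec$ridge_separation / (2 * pixel_size)
  sig <- spec$ridge_sigma / pixel_size
  fld <- polyline_field(spec$path, shape)
  d <- fld$dist
  gate <- fld$interior
  r1 <- exp(-(d - s2)^2 / (2 * sig^2))
  r2 <- exp(-(d + s2)^2 / (2 * sig^2))
  structural <- spec$zo1_amplitude * (r1 + spec$zo1_asymmetry * r2)
  structural[!gate] <- 0
  membrane <- r1 + r2                       # unit-amplitude symmetric band
  # membrane-bound functional signal is strictly confined to a 3-sigma
  # band around the ridges
  membrane[!gate | pmin(abs(abs(d) - s2), abs(abs(d) + s2)) > 3 * sig] <- 0
  list(structural = structural, membrane = membrane, dist = d, gate = gate,
       half_sep = s2, sigma = sig)
}

# Gaussian puncta in the peri-canalicular cytoplasm band; returns the
# rendered (unit-amplitude) punctum image. Band: lateral distance from the
# centerline between half_sep + 3 sigma and that plus band_width_nm.
render_puncta <- function(spec, shape, pixel_size, band_width_nm = 1500) {
  pp <- polyline_points(spec$path, step = 0.5)
  if (is.null(pp$points)) return(matrix(0, shape[1], shape[2]))
  arc_len_um <- nrow(pp$points) * 0.5 * pixel_size / 1000
  band_um <- band_width_nm / 1000
  n_puncta <- round(spec$vesicle_density * arc_len_um * 2 * band_um)
  img <- matrix(0, shape[1], shape[2])
  if (n_puncta < 1) return(img)
  lo <- spec$ridge_separation / 2 + 3 * spec$ridge_sigma
  k <- sample.int(nrow(pp$points), n_puncta, replace = TRUE)
  side <- sample(c(-1, 1), n_puncta, replace = TRUE)
  off <- runif(n_puncta, lo, lo + band_width_nm) / pixel_size
  ctr <- pp$points[k, , drop = FALSE] + side * off * pp$normals[k, , drop = FALSE]
  sv <- spec$vesicle_sigma / pixel_size
  w <- ceiling(4 * sv)
  for (i in seq_len(n_puncta)) {
    cx <- ctr[i, 1]; cy <- ctr[i, 2]
    if (cx < 1 || cx > shape[2] || cy < 1 || cy > shape[1]) next
    cc <- max(1L, floor(cx - w)):min(shape[2], ceiling(cx + w))
    rr <- max(1L, floor(cy - w)):min(shape[1], ceiling(cy + w))
    gx <- exp(-(cc - cx)^2 / (2 * sv^2))
    gy <- exp(-(rr - cy)^2 / (2 * sv^2))
    img[rr, cc] <- img[rr, cc] + outer(gy, gx)
  }
  img
}

#' Generate a synthetic two-channel image
#'
#' Renders each canaliculus as two Gaussian-cross-section ridges flanking
#' its path at half the ridge separation in the structural channel. The
#' functional channel receives the symmetric ridge band scaled by
#' `membrane_fraction` plus cytoplasmic puncta scaled so that the total
#' functional signal (background excluded) is independent of
#' `membrane_fraction`. Additive Gaussian noise (clipped at zero) or,
#' optionally, Poisson noise is applied per channel.
#'
#' @param specs list of [canaliculus_spec()] objects; an empty list yields
#'   a background-only image (using defaults for background/noise).
#' @param shape image dimensions `c(rows, cols)`, at least 128 x 128.
#' @param pixel_size pixel edge length, nm (> 0). Default 100 nm.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @return list with `image` (a [two_channel_image()]) and `truth` (a
#'   `ground_truth` object: per-canaliculus centerline pixels, true ridge
#'   positions, membrane fraction, and an in-memory band mask).
#' @export
generate_image <- function(specs, shape = c(160, 160), pixel_size = 100,
                           seed = NULL,
                           noise_model = c("gaussian", "poisson")) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(shape) == 2, all(shape >= 128), pixel_size > 0)
  if (inherits(specs, "canaliculus_spec")) specs <- list(specs)
  local_seed(seed, {
    background <- if (length(specs)) specs[[1]]$background else 10
    noise_sigma <- if (length(specs)) specs[[1]]$noise_sigma else 5
    structural <- matrix(background, shape[1], shape[2])
    functional <- matrix(background, shape[1], shape[2])
    truth <- list()
    bands <- matrix(0L, shape[1], shape[2])
    for (spec in specs) {
      rc <- render_canaliculus(spec, shape, pixel_size)
      structural <- structural + rc$structural
      mem_total <- sum(rc$membrane)
      target_total <- spec$bsep_amplitude * mem_total
      functional <- functional +
        spec$membrane_fraction * spec$bsep_amplitude * rc$membrane
      cyto_target <- (1 - spec$membrane_fraction) * target_total
      if (cyto_target > 0 && spec$vesicle_density > 0) {
        p <- render_puncta(spec, shape, pixel_size)
        sp <- sum(p)
        if (sp > 0) functional <- functional + (cyto_target / sp) * p
      }
      band <- abs(rc$dist) <= rc$half_sep + 2 * rc$sigma & rc$gate
      bands <- bands + band
      pp <- polyline_points(spec$path, step = 0.5)
      ctr <- unique(round(pp$points))
      ctr <- ctr[ctr[, 1] >= 1 & ctr[, 1] <= shape[2] &
                   ctr[, 2] >= 1 & ctr[, 2] <= shape[1], , drop = FALSE]
      ridges <- list(pp$points + rc$half_sep * pp$normals,
                     pp$points - rc$half_sep * pp$normals)
      truth[[length(truth) + 1L]] <- list(
        centerline = ctr, ridges = ridges,
        membrane_fraction = spec$membrane_fraction,
        ridge_separation = spec$ridge_separation,
        band = band)
    }
    if (any(bands > 1L))
      warning("overlapping canaliculi specs")
    if (noise_model == "gaussian") {
      if (noise_sigma > 0) {
        structural <- structural + rnorm(length(structural), 0, noise_sigma)
        functional <- functional + rnorm(length(functional), 0, noise_sigma)
      }
    } else {
      structural <- matrix(rpois(length(structural), pmax(structural, 0)),
                           shape[1], shape[2])
      functional <- matrix(rpois(length(functional), pmax(functional, 0)),
                           shape[1], shape[2])
    }
    structural[structural < 0] <- 0
    functional[functional < 0] <- 0
    img <- two_channel_image(structural, functional, pixel_size)
    list(image = img,
         truth = structure(list(canaliculi = truth, pixel_size = pixel_size),
                           class = "ground_truth"))
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Emulates a standard acquisition of several images from different tissue
#' regions of one biological condition: per image, the number of canaliculi,
#' their orientation, lateral placement, curvature and ridge separation are
#' jittered, while the condition-defining `membrane_fraction` (and the other
#' intensity parameters) of the template are kept.
#'
#' @param template a [canaliculus_spec()] whose intensity parameters and
#'   `membrane_fraction` define the condition; its `path` is ignored.
#' @param n_images number of images (>= 1).
#' @param seed integer seed controlling the whole dataset.
#' @param shape,pixel_size image geometry, as in [generate_image()].
#' @param n_canaliculi range (min, max) of canaliculi per image.
#' @return list of length `n_images`; each element is a list with `image`
#'   and `truth` as returned by [generate_image()].
#' @export
generate_dataset <- function(template, n_images, seed = 1,
                             shape = c(160, 160), pixel_size = 100,
                             n_canaliculi = c(1, 2)) {
  stopifnot(n_images >= 1)
  # Lateral spacing between canaliculi exceeds the raw profile half-length
  # (40 px), so one canaliculus never appears in a neighbour's profile.
  spacing <- 52
  params <- local_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      k <- sample(n_canaliculi[1]:n_canaliculi[2], 1)
      theta <- runif(1, 0, pi)
      list(k = k, theta = theta,
           dtheta = runif(k, -1.5, 1.5) * pi / 180,
           offsets = (seq_len(k) - (k + 1) / 2) * spacing + runif(k, -2, 2),
           sag = rnorm(k, 0, 1.5),
           sep = template$ridge_separation * runif(k, 0.9, 1.1),
           img_seed = sample.int(.Machine$integer.max - 1L, 1))
    })
  })
  lapply(params, function(p) {
    cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
    L <- max(shape) # long enough to leave the image on both sides
    specs <- lapply(seq_len(p$k), function(j) {
      th <- p$theta + p$dtheta[j]
      u <- c(cos(th), sin(th)); nrm <- c(-u[2], u[1])
      ctr <- c(cx, cy) + p$offsets[j] * nrm
      pa <- rbind(ctr - L * u,
                  ctr - 0.5 * L * u + p$sag[j] * nrm,
                  ctr + 0.5 * L * u + p$sag[j] * nrm,
                  ctr + L * u)
      sp <- template
      sp$path <- pa
      sp$ridge_separation <- max(800, min(2500, p$sep[j]))
      sp
    })
    generate_image(specs, shape = shape, pixel_size = pixel_size,
                   seed = p$img_seed)
  })
}
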
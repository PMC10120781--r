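# Fibrillar-collagen architecture metrics for SHG-like grayscale images.
#
# Conventions used throughout: images are numeric matrices indexed
# [row, col] with the origin top-left; x = column, y = row. Angles are in
# degrees in [-90, 90), 0 = image x-axis, positive counter-clockwise in
# the conventional (y-up) view.

#' Otsu threshold of positive pixel intensities
#'
#' Wraps `EBImage::otsu` over the nonzero pixels of the image (zero
#' background, e.g. after autofluorescence subtraction, would otherwise
#' dominate the histogram).
#'
#' @param image Numeric matrix.
#' @return Threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image) {
  v <- as.vector(as_image_matrix(image))
  v <- v[v > 0]
  if (!length(v)) return(0)
  rg <- range(v)
  if (rg[1] == rg[2]) return(rg[1] / 2)
  EBImage::otsu(EBImage::Image(matrix(v, nrow = 1)), range = rg, levels = 256L)
}

#' Subtract an autofluorescence channel from an SHG image
#'
#' Pixelwise `max(shg - autofluor, 0)`: the autofluorescence estimate is
#' removed and negative residuals clamp to zero.
#'
#' @param shg,autofluor Numeric matrices of identical shape.
#' @return The corrected image matrix.
#' @export
subtract_autofluorescence <- function(shg, autofluor) {
  shg <- as_image_matrix(shg, "shg")
  autofluor <- as_image_matrix(autofluor, "autofluor")
  if (!identical(dim(shg), dim(autofluor))) {
    abort("`shg` and `autofluor` must have the same shape.")
  }
  pmax(shg - autofluor, 0)
}

#' Integrated density of foreground collagen signal
#'
#' Sum of pixel intensities over the foreground (above-threshold) pixels,
#' the ImageJ-style "integrated density" readout of total fibrillar
#' collagen per field, plus the foreground area fraction.
#'
#' @param image Numeric matrix.
#' @param threshold Foreground threshold; default Otsu over nonzero
#'   pixels. Use 0 to integrate every positive pixel.
#' @return One-row tibble: `integrated_density`, `area_fraction`,
#'   `threshold`.
#' @export
integrated_density <- function(image, threshold = NULL) {
  image <- as_image_matrix(image)
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  if (threshold < 0) abort("`threshold` must be >= 0.")
  fg <- image > threshold
  tibble(
    integrated_density = sum(image[fg]),
    area_fraction = mean(fg),
    threshold = threshold
  )
}

hann_window <- function(n) {
  if (n == 1) return(1)
  k <- seq_len(n) - 1
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' FFT spectral anisotropy (alignment aspect ratio)
#'
#' Fiber alignment is read off the 2-D power spectrum: aligned fibers
#' concentrate spectral power along the line through the origin
#' perpendicular to the fiber direction, while an isotropic field spreads
#' it evenly. The image is mean-subtracted and Hann-windowed, the power
#' spectrum's second-central-moment tensor about the DC origin is formed,
#' and the statistic is `sqrt(lambda_max / lambda_min)` of its
#' eigenvalues: 1 for isotropy, larger for stronger alignment. Invariant
#' to intensity scaling and (up to interpolation) to rotation.
#'
#' @param image Numeric, non-constant matrix.
#' @return Aspect ratio (>= 1).
#' @export
fft_alignment <- function(image) {
  image <- as_image_matrix(image)
  if (max(image) == min(image)) abort("image is constant; alignment undefined.")
  nr <- nrow(image); nc <- ncol(image)
  w <- outer(hann_window(nr), hann_window(nc))
  x <- (image - mean(image)) * w
  P <- Mod(stats::fft(x))^2

  # centered frequency index along each axis (DC at index 1)
  freq_idx <- function(n) {
    k <- seq_len(n) - 1
    ifelse(k > n / 2, k - n, k)
  }
  fy <- freq_idx(nr) / nr # row frequency
  fx <- freq_idx(nc) / nc # col frequency
  # drop the unpaired Nyquist bins so the spectrum support is symmetric
  # (makes the statistic exactly invariant under 90-degree rotation)
  fy[abs(fy) >= 0.5 - 1e-12] <- NA
  fx[abs(fx) >= 0.5 - 1e-12] <- NA
  Fy <- matrix(fy, nr, nc)
  Fx <- matrix(fx, nr, nc, byrow = TRUE)
  P[is.na(Fy) | is.na(Fx)] <- 0
  Fy[is.na(Fy)] <- 0
  Fx[is.na(Fx)] <- 0
  W <- sum(P)
  if (W == 0) abort("image has no spectral power.")
  mxx <- sum(P * Fx^2) / W
  myy <- sum(P * Fy^2) / W
  mxy <- sum(P * Fx * Fy) / W
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2, 2), symmetric = TRUE)$values
  sqrt(max(ev) / max(min(ev), .Machine$double.eps))
}

gaussian_kernel_1d <- function(sigma, derivative = FALSE) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (derivative) -x / sigma^2 * g else g
}

#' Structure-tensor orientation histogram of an image
#'
#' Per-pixel orientation from the smoothed structure tensor (Gaussian
#' gradients, Gaussian tensor smoothing), accumulated over foreground
#' pixels into a gradient-energy-weighted histogram over \[-90, 90)
#' degrees. The histogram mode (center of the heaviest bin) is the
#' field-level fiber angle readout.
#'
#' @param image Numeric matrix.
#' @param bin_deg Bin width in degrees; must divide 180.
#' @param sigma_gradient,sigma_tensor Gaussian scales (px) for the
#'   gradient and the tensor smoothing.
#' @param threshold Foreground threshold (default Otsu over nonzero
#'   pixels).
#' @return List with `histogram` (tibble `bin_center`, `weight`) and
#'   `mode_deg`.
#' @export
orientation_histogram <- function(image, bin_deg = 2,
                                  sigma_gradient = 1, sigma_tensor = 2,
                                  threshold = NULL) {
  image <- as_image_matrix(image)
  if (180 %% bin_deg != 0) abort("`bin_deg` must divide 180.")
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  fg <- image > threshold
  if (!any(fg)) abort("no foreground pixels above threshold.")

  g <- gaussian_kernel_1d(sigma_gradient)
  dg <- gaussian_kernel_1d(sigma_gradient, derivative = TRUE)
  kx <- outer(g, dg)  # derivative along columns (x)
  ky <- outer(dg, g)  # derivative along rows
  gx <- EBImage::filter2(image, kx)
  gy <- -EBImage::filter2(image, ky) # flip: rows grow downward, y grows up

  gs <- gaussian_kernel_1d(sigma_tensor)
  ks <- outer(gs, gs)
  jxx <- EBImage::filter2(gx * gx, ks)
  jyy <- EBImage::filter2(gy * gy, ks)
  jxy <- EBImage::filter2(gx * gy, ks)

  # gradient direction + 90 deg = structure direction
  theta <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90
  theta <- wrap_angle_deg(theta)
  energy <- jxx + jyy

  th <- theta[fg]
  wt <- energy[fg]
  breaks <- seq(-90, 90, by = bin_deg)
  bin <- findInterval(th, breaks, rightmost.closed = FALSE, left.open = FALSE)
  bin[bin > length(breaks) - 1] <- length(breaks) - 1
  weight <- vapply(seq_len(length(breaks) - 1),
                   function(b) sum(wt[bin == b]), numeric(1))
  centers <- breaks[-length(breaks)] + bin_deg / 2
  list(
    histogram = tibble(bin_center = centers, weight = weight),
    mode_deg = centers[which.max(weight)]
  )
}

# label 8-connected components of a sparse logical matrix; returns an
# integer matrix of labels (0 = background)
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  offsets <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      for (o in offsets) {
        q <- p + o
        if (q < 1L || q > nr * nc) next
        qr <- (q - 1L) %% nr + 1L
        if (abs(qr - r) > 1L) next # column wrap guard
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# order the pixels of a degree-<=2 component into a path, starting at an
# endpoint; returns matrix of (row, col) or NULL for loops
trace_path <- function(pix_rc, sk_dim) {
  n <- nrow(pix_rc)
  if (n == 1) return(pix_rc)
  key <- (pix_rc[, 2] - 1) * sk_dim[1] + pix_rc[, 1]
  keyset <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = keyset)
  adj <- function(i) {
    r <- pix_rc[i, 1]; c <- pix_rc[i, 2]
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      k <- as.character((c + dc - 1) * sk_dim[1] + (r + dr))
      j <- keyset[[k]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(seq_len(n), function(i) length(adj(i)), integer(1))
  ends <- which(deg <= 1)
  start <- if (length(ends)) ends[1] else return(NULL) # loop: skip
  path <- integer(n)
  visited <- logical(n)
  path[1] <- start
  visited[start] <- TRUE
  len <- 1L
  repeat {
    nxt <- adj(path[len])
    nxt <- nxt[!visited[nxt]]
    if (!length(nxt)) break
    len <- len + 1L
    path[len] <- nxt[1]
    visited[nxt[1]] <- TRUE
  }
  pix_rc[path[seq_len(len)], , drop = FALSE]
}

# moving-average smoothing of an ordered (row, col) pixel chain; window
# must be small relative to any real curvature wavelength
smooth_path <- function(path, window = 5L) {
  n <- nrow(path)
  if (n <= window) return(path)
  half <- window %/% 2L
  sm <- path
  for (j in 1:2) {
    cs <- cumsum(c(0, path[, j]))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    sm[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  sm
}

#' Trace individual fibers in an SHG-like image
#'
#' A simplified centerline tracer: Otsu foreground threshold,
#' morphological skeletonization, removal of branch-point pixels, then
#' ordering of each remaining simple path. Per fiber it reports arc
#' length (diagonal steps weighted sqrt(2)), chord length (endpoint
#' distance), straightness (chord/arc), mean width (twice the mean
#' distance-transform value of the mask along the path) and chord angle.
#'
#' @param image Numeric matrix.
#' @param min_length_px Minimum arc length (px) for a fiber to be kept.
#' @param threshold Foreground threshold (default Otsu over nonzero
#'   pixels).
#' @return Tibble: `fiber_id`, `n_points`, `length_px`, `chord_px`,
#'   `width_px`, `straightness`, `angle_deg`, and a `path` list-column of
#'   (row, col) matrices. Empty image gives an empty tibble.
#' @export
trace_fibers <- function(image, min_length_px = 30, threshold = NULL) {
  image <- as_image_matrix(image)
  if (min_length_px < 2) abort("`min_length_px` must be >= 2.")
  empty <- tibble(fiber_id = integer(), n_points = integer(),
                  length_px = numeric(), chord_px = numeric(),
                  width_px = numeric(), straightness = numeric(),
                  angle_deg = numeric(), path = list())
  if (all(image <= 0)) return(empty)
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  mask <- image > threshold
  if (!any(mask)) return(empty)

  sk <- skeletonize(mask)
  if (!any(sk)) return(empty)
  cn <- crossing_number(sk)
  junction <- sk & cn > 2
  # cut one pixel around each junction too, so arms of crossing fibers
  # cannot stay 8-connected through the junction's shoulder pixels
  near_junction <- Reduce(`|`, lapply(zs_neighbors(matrix(as.integer(junction),
                                                          nrow(junction))),
                                      function(x) x == 1L))
  sk_paths <- sk & !junction & !near_junction
  lab <- label8(sk_paths)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty)

  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))

  rows <- list()
  id <- 0L
  for (cc in seq_len(n_comp)) {
    pix <- which(lab == cc)
    rc <- cbind((pix - 1L) %% nrow(sk) + 1L, (pix - 1L) %/% nrow(sk) + 1L)
    path <- trace_path(rc, dim(sk))
    if (is.null(path) || nrow(path) < 2) next
    # smooth the staircased pixel chain before measuring: raw chain-code
    # arc length overestimates oblique segments by up to ~8%
    sm <- smooth_path(path)
    steps <- sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2)
    arc <- sum(steps)
    if (arc < min_length_px) next
    chord <- sqrt((sm[nrow(sm), 1] - sm[1, 1])^2 +
                    (sm[nrow(sm), 2] - sm[1, 2])^2)
    # distmap measures center-to-center; the mask edge sits half a pixel
    # beyond the last foreground center
    width <- 2 * (mean(dm[path]) - 0.5)
    # chord angle in the x-right / y-up convention
    ang <- wrap_angle_deg(atan2(-(sm[nrow(sm), 1] - sm[1, 1]),
                                sm[nrow(sm), 2] - sm[1, 2]) * 180 / pi)
    id <- id + 1L
    rows[[id]] <- tibble(fiber_id = id, n_points = nrow(path),
                         length_px = arc, chord_px = chord,
                         width_px = width,
                         straightness = min(chord / arc, 1),
                         angle_deg = ang, path = list(path))
  }
  if (!length(rows)) return(empty)
  list_rbind(rows)
}

#' Percentage of straight fibers
#'
#' A fiber is straight when its straightness (chord/arc) strictly exceeds
#' [straight_threshold] (= 1/1.08): a fiber at exactly the threshold is
#' not straight.
#'
#' @param fibers Tibble from [trace_fibers()] (nonempty).
#' @return Percentage in \[0, 100\].
#' @export
straight_fraction <- function(fibers) {
  if (!nrow(fibers)) abort("no fibers to classify.")
  100 * mean(fibers$straightness > straight_threshold)
}

#' All fiber-architecture metrics for one image
#'
#' Runs autofluorescence subtraction (when given), integrated density,
#' FFT alignment, the orientation histogram and the fiber tracer, and
#' returns the image-level summary row.
#'
#' @param shg SHG image matrix.
#' @param autofluor Optional autofluorescence image to subtract.
#' @param min_length_px Passed to [trace_fibers()].
#' @param bin_deg Passed to [orientation_histogram()].
#' @param threshold Foreground threshold (default Otsu).
#' @return One-row tibble: `integrated_density`, `area_fraction`,
#'   `alignment_aspect_ratio`, `orientation_mode_deg`, `n_fibers`,
#'   `mean_length_px`, `mean_width_px`, `pct_straight`,
#'   `straight_threshold`.
#' @export
summarize_image <- function(shg, autofluor = NULL, min_length_px = 30,
                            bin_deg = 2, threshold = NULL) {
  img <- as_image_matrix(shg, "shg")
  if (any(dim(img) < 64)) abort("image must be at least 64 x 64 pixels.")
  if (!is.null(autofluor)) img <- subtract_autofluorescence(img, autofluor)
  dens <- integrated_density(img, threshold = threshold)
  orient <- orientation_histogram(img, bin_deg = bin_deg, threshold = threshold)
  fibers <- trace_fibers(img, min_length_px = min_length_px,
                         threshold = threshold)
  tibble(
    integrated_density = dens$integrated_density,
    area_fraction = dens$area_fraction,
    alignment_aspect_ratio = fft_alignment(img),
    orientation_mode_deg = orient$mode_deg,
    n_fibers = nrow(fibers),
    mean_length_px = if (nrow(fibers)) mean(fibers$length_px) else NA_real_,
    mean_width_px = if (nrow(fibers)) mean(fibers$width_px) else NA_real_,
    pct_straight = if (nrow(fibers)) straight_fraction(fibers) else NA_real_,
    straight_threshold = straight_threshold
  )
}

#' Read a grayscale (optionally multi-page) TIFF as an image matrix
#'
#' Multi-page stacks are reduced by max-intensity projection; RGB pages
#' are averaged to grayscale.
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_fiber_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- map(pages, function(pg) {
    if (length(dim(pg)) == 3) apply(pg, c(1, 2), mean) else pg
  })
  Reduce(pmax, pages)
}

#' Batch fiber metrics over a set of TIFF files
#'
#' @param files Character vector of TIFF paths (processed in filename
#'   order for stable output).
#' @param ... Passed to [summarize_image()].
#' @return Tibble with one row per image, first column `file`.
#' @export
summarize_images <- function(files, ...) {
  files <- sort(files)
  rows <- map(files, function(f) {
    dplyr::bind_cols(tibble(file = basename(f)),
                     summarize_image(read_fiber_image(f), ...))
  })
  list_rbind(rows)
}
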
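# Cell and nucleus morphometry from two-channel fluorescence images
# (nuclear stain + cytoskeleton stain), with the scalar index formulas.

# Minimum cross-entropy (Li) threshold, iterative form: alternate between
# class means below/above t and t = (m_f - m_b) / (log m_f - log m_b).
li_threshold <- function(image, tol = 1e-4, max_iter = 100L) {
  v <- as.vector(image)
  v <- v[is.finite(v)]
  eps <- max(v) * 1e-6 + 1e-12
  v <- pmax(v, eps)
  t <- mean(v)
  for (i in seq_len(max_iter)) {
    mb <- mean(v[v <= t])
    mf <- mean(v[v > t])
    if (!is.finite(mb) || !is.finite(mf) || mb == mf) break
    t_new <- (mf - mb) / (log(mf) - log(mb))
    if (abs(t_new - t) < tol * t) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Tiled adaptive Otsu thresholding (per-tile threshold, falling back to
#' the global Otsu value in flat tiles), connected-component labeling,
#' and exclusion of objects whose equivalent diameter
#' `2 * sqrt(area / pi)` is below `min_diameter_px` (default 15 px, the
#' conventional small-debris cutoff).
#'
#' @param image Numeric matrix (nuclear channel).
#' @param min_diameter_px Minimum object equivalent diameter in pixels.
#' @param tile_size Side of the adaptive-threshold tiles.
#' @return Integer label matrix (0 = background), labels sequential.
#' @export
segment_nuclei <- function(image, min_diameter_px = 15, tile_size = 64) {
  image <- as_image_matrix(image)
  if (max(image) == min(image)) {
    return(matrix(0L, nrow(image), ncol(image)))
  }
  global_t <- otsu_threshold(image)
  nr <- nrow(image); nc <- ncol(image)
  thmap <- matrix(global_t, nr, nc)
  r_starts <- seq(1, nr, by = tile_size)
  c_starts <- seq(1, nc, by = tile_size)
  for (r0 in r_starts) for (c0 in c_starts) {
    rr <- r0:min(r0 + tile_size - 1, nr)
    cc <- c0:min(c0 + tile_size - 1, nc)
    tile <- image[rr, cc]
    # only trust a local threshold when the tile clearly has both classes
    if (sd(tile) > 0.1 * sd(image) && any(tile > 0)) {
      thmap[rr, cc] <- otsu_threshold(tile)
    }
  }
  mask <- image > thmap
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  keep <- which(tabulate(lab[lab > 0]) >= pi * (min_diameter_px / 2)^2)
  out <- matrix(0L, nr, nc)
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Segment cell bodies from a cytoskeleton channel, seeded at nuclei
#'
#' The cytoskeleton channel is thresholded with the minimum-cross-entropy
#' (Li) method and cell territories are grown from the nucleus seeds with
#' `EBImage::propagate` (the propagation segmentation family used by
#' CellProfiler-style pipelines). Every cell inherits its nucleus label
#' and contains at least the nucleus footprint.
#'
#' @param image Numeric matrix (cytoskeleton channel).
#' @param nuclei Integer label matrix from [segment_nuclei()].
#' @return Integer cell label matrix aligned with the nucleus labels.
#' @export
segment_cells <- function(image, nuclei) {
  image <- as_image_matrix(image)
  if (!identical(dim(image), dim(nuclei))) abort("channel shapes differ.")
  if (!any(nuclei > 0)) abort("no nuclei seeds; segment nuclei first.")
  t <- li_threshold(image)
  mask <- image > t | nuclei > 0
  seg <- EBImage::propagate(EBImage::Image(image),
                            seeds = EBImage::Image(nuclei),
                            mask = EBImage::Image(mask), lambda = 1e-4)
  out <- EBImage::imageData(seg)
  storage.mode(out) <- "integer"
  out
}

# Moore-neighbor outer contour trace; returns ordered boundary (row,col).
moore_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  # start at the first foreground pixel in column-major scan
  start <- which(padded)[1]
  sr <- (start - 1) %% (nr + 2) + 1
  sc <- (start - 1) %/% (nr + 2) + 1
  # Moore neighborhood, clockwise starting west
  drs <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dcs <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  path <- matrix(0L, nrow = 4 * (nr * nc), ncol = 2)
  path[1, ] <- c(sr, sc)
  len <- 1L
  cur <- c(sr, sc)
  backtrack <- 1L # direction index pointing to previous (background) pixel
  repeat {
    found <- FALSE
    k <- backtrack
    for (step in 1:8) {
      k <- (k %% 8) + 1L
      r2 <- cur[1] + drs[k]; c2 <- cur[2] + dcs[k]
      if (padded[r2, c2]) {
        # new backtrack: the neighbor just before the hit, seen from the new pixel
        prev_k <- if (k == 1) 8L else k - 1L
        br <- cur[1] + drs[prev_k]; bc <- cur[2] + dcs[prev_k]
        cur <- c(r2, c2)
        backtrack <- which(drs == br - r2 & dcs == bc - c2)
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (cur[1] == sr && cur[2] == sc) break
    len <- len + 1L
    path[len, ] <- cur
    if (len >= nrow(path)) break
  }
  path[seq_len(len), , drop = FALSE] - 1L # remove padding offset
}

# Closed-contour length from the chain code with the
# Vossepoel-Smeulders corner correction: plain 1/sqrt(2) step weights
# overestimate smooth digital boundaries by ~5%, which doubles in the
# squared compactness; the corrected estimator is <1% off on circles.
contour_perimeter <- function(contour) {
  if (nrow(contour) < 2) return(4) # single pixel: unit square
  closed <- rbind(contour, contour[1, ])
  d <- cbind(diff(closed[, 1]), diff(closed[, 2]))
  diag_step <- d[, 1] != 0 & d[, 2] != 0
  n_even <- sum(!diag_step)
  n_odd <- sum(diag_step)
  code <- atan2(d[, 1], d[, 2])
  n_corner <- sum(code != c(code[-1], code[1]))
  0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner
}

#' Per-cell morphometric parameters
#'
#' For each labeled cell (with its matching-label nucleus) computes pixel
#' areas, outer-contour perimeter (Moore trace, diagonal steps weighted
#' sqrt(2)), compactness `perimeter^2 / (4 * pi * area)` (1 for a perfect
#' circle, larger for irregular shapes), orientation of the cell's
#' principal axis from second central moments (degrees in \[-90, 90),
#' x-axis = 0, counter-clockwise positive), and the nuclear fraction
#' (nuclear area / cell area), a morphometric aggressiveness indicator.
#'
#' @param cell_mask Integer cell label matrix.
#' @param nucleus_mask Integer nucleus label matrix with matching labels.
#' @return Tibble: `cell_id`, `cell_area`, `nuclear_area`, `perimeter`,
#'   `compactness`, `orientation_deg`, `nuclear_fraction`.
#' @export
cell_morphometrics <- function(cell_mask, nucleus_mask) {
  if (!identical(dim(cell_mask), dim(nucleus_mask))) abort("mask shapes differ.")
  ids <- sort(setdiff(unique(as.vector(cell_mask)), 0))
  if (!length(ids)) abort("no cells in mask.")
  rows <- map(ids, function(id) {
    cell <- cell_mask == id
    nuc <- nucleus_mask == id
    if (!any(nuc)) abort(sprintf("cell %d has no nucleus with matching label.", id))
    if (any(nuc & !cell)) abort(sprintf("nucleus %d extends outside its cell.", id))
    ca <- sum(cell)
    na_ <- sum(nuc)
    per <- contour_perimeter(moore_contour(cell))
    # second central moments in x = col, y = -row (counter-clockwise angles)
    idx <- which(cell, arr.ind = TRUE)
    x <- idx[, 2]; y <- -idx[, 1]
    mu20 <- mean((x - mean(x))^2)
    mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    orient <- wrap_angle_deg(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
    tibble(cell_id = id, cell_area = ca, nuclear_area = na_,
           perimeter = per,
           compactness = per^2 / (4 * pi * ca),
           orientation_deg = orient,
           nuclear_fraction = na_ / ca)
  })
  list_rbind(rows)
}

#' Correlate cell orientation angles with the field's fiber angle
#'
#' Plain Pearson correlation and linear regression between paired angle
#' lists on \[-90, 90), as commonly reported for cell-matrix co-alignment.
#' Note the circularity caveat: angles near +/-90 wrap, so the linear
#' correlation understates co-alignment for fields oriented near the
#' wrap-around.
#'
#' @param cell_angles_deg,fiber_angles_deg Paired angle vectors (degrees).
#' @return One-row tibble: `r`, `p`, `slope`, `intercept`, `n`.
#' @export
orientation_correlation <- function(cell_angles_deg, fiber_angles_deg) {
  if (length(cell_angles_deg) != length(fiber_angles_deg)) {
    abort("angle vectors must be paired (equal length).")
  }
  if (length(cell_angles_deg) < 3) abort("need at least 3 angle pairs.")
  a <- wrap_angle_deg(cell_angles_deg)
  b <- wrap_angle_deg(fiber_angles_deg)
  ct <- cor.test(b, a, method = "pearson")
  fit <- lm(a ~ b)
  tibble(r = unname(ct$estimate), p = ct$p.value,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n = length(a))
}

#' Percentage of marker-positive nuclei
#'
#' The proliferative (Ki-67) or apoptotic (cleaved caspase-3) index:
#' `100 * n_positive / n_total`.
#'
#' @param n_positive,n_total Nonnegative counts, `n_total > 0`,
#'   `n_positive <= n_total`. Vectorized.
#' @return Percentage(s) in \[0, 100\].
#' @export
positive_fraction <- function(n_positive, n_total) {
  if (any(n_total <= 0)) abort("`n_total` must be positive.")
  if (any(n_positive < 0 | n_positive > n_total)) {
    abort("`n_positive` must lie in [0, n_total].")
  }
  100 * n_positive / n_total
}

#' Caliper tumor volume
#'
#' The standard ellipsoid approximation `V = L * W^2 / 2` with axes
#' normalized so that `L >= W` (swapped with a message when given the
#' other way round). Vectorized.
#'
#' @param L Longest caliper dimension (mm).
#' @param W Perpendicular width (mm).
#' @return Tibble: `L`, `W` (normalized), `volume` (mm^3), `swapped`.
#' @export
tumor_volume <- function(L, W) {
  if (any(!is.finite(L)) || any(!is.finite(W)) || any(L <= 0) || any(W <= 0)) {
    abort("`L` and `W` must be positive.")
  }
  swapped <- W > L
  if (any(swapped)) {
    inform(sprintf("%d measurement(s) had W > L; axes swapped.", sum(swapped)))
  }
  Lz <- pmax(L, W)
  Wz <- pmin(L, W)
  tibble(L = Lz, W = Wz, volume = Lz * Wz^2 / 2, swapped = swapped)
}
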
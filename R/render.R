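# Synthetic fiber-field and cell-fixture renderers with exact ground
# truth, so every image metric has a recovery test.

# von Mises sampler (Best-Fisher rejection scheme); no installed package
# provides one. kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
    }
  }
  out
}

#' Parameters for the synthetic fiber-field renderer
#'
#' Fibers are Gaussian-profile tubes along sinusoidally perturbed lines.
#' Orientations are axial von Mises: an angle `phi` is drawn from a von
#' Mises distribution centered at `2 * mean_angle` with concentration
#' `kappa` and halved, so `kappa = 0` gives an isotropic field and larger
#' `kappa` concentrates fibers around `mean_angle_deg`. Waviness is a
#' single-frequency sinusoidal perpendicular offset (two full periods per
#' fiber, random phase) whose relative amplitude fixes the arc/chord
#' ratio exactly, giving closed-form straightness ground truth.
#'
#' @param image_size Image side in pixels (square).
#' @param n_fibers Number of fibers.
#' @param kappa Orientation concentration (>= 0; 0 = isotropic).
#' @param mean_angle_deg Mean fiber angle, degrees in \[-90, 90).
#' @param length_mean,length_sd Fiber chord length distribution (px).
#' @param width_mean,width_sd Fiber width (FWHM of the tube profile, px).
#' @param waviness_amp Relative sinusoidal amplitude (amplitude /
#'   wavelength); 0 = straight fibers.
#' @param waviness_spread Per-fiber relative jitter of the waviness
#'   amplitude: each fiber's amplitude is `waviness_amp *
#'   Unif(1 - spread, 1 + spread)`. 0 (default) gives every fiber the
#'   same exact arc/chord ratio.
#' @param noise_sd Additive Gaussian intensity noise (image max is ~1).
#' @param seed RNG seed; fixed seed reproduces image and table exactly.
#' @return List of class `"fiber_field_params"`.
#' @export
fiber_field_params <- function(image_size = 256, n_fibers = 30,
                               kappa = 2, mean_angle_deg = 0,
                               length_mean = 120, length_sd = 20,
                               width_mean = 4, width_sd = 0.5,
                               waviness_amp = 0, waviness_spread = 0,
                               noise_sd = 0.01, seed = 1L) {
  if (kappa < 0) abort("`kappa` must be >= 0.")
  if (width_mean <= 0) abort("`width_mean` must be positive.")
  if (length_mean <= 0) abort("`length_mean` must be positive.")
  if (waviness_amp < 0) abort("`waviness_amp` must be >= 0.")
  if (waviness_spread < 0 || waviness_spread > 1) {
    abort("`waviness_spread` must lie in [0, 1].")
  }
  if (n_fibers < 0) abort("`n_fibers` must be >= 0.")
  if (image_size < 64) abort("`image_size` must be >= 64.")
  structure(list(
    image_size = as.integer(image_size), n_fibers = as.integer(n_fibers),
    kappa = kappa, mean_angle_deg = wrap_angle_deg(mean_angle_deg),
    length_mean = length_mean, length_sd = length_sd,
    width_mean = width_mean, width_sd = width_sd,
    waviness_amp = waviness_amp, waviness_spread = waviness_spread,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "fiber_field_params")
}

# arc/chord ratio of y = A sin(2 pi t / lambda) over whole periods,
# as a function of relative amplitude a_rel = A / lambda
sinuosity_of_amplitude <- function(a_rel) {
  s <- 2 * pi * a_rel
  f <- function(u) sqrt(1 + s^2 * cos(u)^2)
  integrate(f, 0, 2 * pi, rel.tol = 1e-10)$value / (2 * pi)
}

#' Relative waviness amplitude giving a target arc/chord ratio
#'
#' Inverts the sinusoid arc-length quadrature: returns the
#' `waviness_amp` for which every rendered fiber has
#' `arc / chord = sinuosity` exactly (hence straightness
#' `1 / sinuosity`).
#'
#' @param sinuosity Target arc/chord ratio (>= 1).
#' @return Relative amplitude (amplitude / wavelength).
#' @export
waviness_for_sinuosity <- function(sinuosity) {
  if (sinuosity < 1) abort("`sinuosity` must be >= 1.")
  if (sinuosity == 1) return(0)
  uniroot(function(a) sinuosity_of_amplitude(a) - sinuosity,
          c(1e-9, 2), tol = 1e-10)$root
}

#' Render a synthetic fiber field with ground truth
#'
#' @param params A [fiber_field_params()] object.
#' @return List with `image` (numeric matrix, intensities ~\[0, 1+noise\])
#'   and `fibers`, a tibble of per-fiber ground truth: `fiber_id`,
#'   `angle_deg` (chord angle), `chord_px`, `arc_px`, `width_px`,
#'   `straightness`.
#' @export
render_fiber_field <- function(params = fiber_field_params()) {
  if (!inherits(params, "fiber_field_params")) {
    abort("`params` must come from fiber_field_params().")
  }
  p <- params
  size <- p$image_size
  diag_len <- sqrt(2) * size
  if (p$length_mean > diag_len) {
    abort("mean fiber length exceeds the image diagonal.")
  }

  with_seed(p$seed, {
    img <- matrix(0, size, size)
    truth <- list()
    if (p$n_fibers > 0) {
      mu2 <- 2 * p$mean_angle_deg * pi / 180
      angles <- wrap_angle_deg(rvonmises(p$n_fibers, mu2, p$kappa) / 2 * 180 / pi)
      lens <- pmin(pmax(rnorm(p$n_fibers, p$length_mean, p$length_sd), 10),
                   diag_len - 2)
      widths <- pmax(rnorm(p$n_fibers, p$width_mean, p$width_sd), 1)
      phases <- runif(p$n_fibers, 0, 2 * pi)
      amp_rels <- p$waviness_amp *
        runif(p$n_fibers, 1 - p$waviness_spread, 1 + p$waviness_spread)
      sinus <- vapply(amp_rels, sinuosity_of_amplitude, numeric(1))

      for (i in seq_len(p$n_fibers)) {
        len <- lens[i]
        margin <- min(len / 2, size / 2 - 1)
        r0 <- runif(1, 1 + margin, size - margin)
        c0 <- runif(1, 1 + margin, size - margin)
        th <- angles[i] * pi / 180
        lambda <- len / 2 # two full periods per fiber
        amp <- amp_rels[i] * lambda

        t <- seq(-len / 2, len / 2, by = 0.5)
        # offsets over whole periods; phase shifts the pattern only
        off <- amp * sin(2 * pi * t / lambda + phases[i]) -
          amp * 0 # mean handled by symmetry over full periods
        # direction (cos th, sin th) in x-right / y-up; row = -y
        rr <- r0 - t * sin(th) - off * cos(th)
        cc <- c0 + t * cos(th) - off * sin(th)

        sigma <- widths[i] / (2 * sqrt(2 * log(2))) # FWHM -> sigma
        rad <- max(2L, ceiling(2.5 * sigma))
        for (k in seq_along(t)) {
          ri <- round(rr[k]); ci <- round(cc[k])
          rs <- max(1, ri - rad):min(size, ri + rad)
          cs <- max(1, ci - rad):min(size, ci + rad)
          if (!length(rs) || !length(cs)) next
          d2 <- outer((rs - rr[k])^2, (cs - cc[k])^2, `+`)
          img[rs, cs] <- pmax(img[rs, cs], exp(-d2 / (2 * sigma^2)))
        }

        truth[[i]] <- tibble(
          fiber_id = i, angle_deg = angles[i],
          chord_px = len, arc_px = len * sinus[i],
          width_px = widths[i], straightness = 1 / sinus[i]
        )
      }
    }
    if (p$noise_sd > 0) {
      img <- img + matrix(rnorm(size * size, 0, p$noise_sd), size, size)
      img <- pmax(img, 0)
    }
    fibers <- if (length(truth)) list_rbind(truth) else
      tibble(fiber_id = integer(), angle_deg = numeric(),
             chord_px = numeric(), arc_px = numeric(),
             width_px = numeric(), straightness = numeric())
    list(image = img, fibers = fibers, params = p)
  })
}

ellipse_mask <- function(size, x, y, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  rowv <- seq_len(size)
  dy <- -(matrix(rowv, size, size) - y) # y-up
  dx <- matrix(rowv, size, size, byrow = TRUE) - x
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a two-channel cell/nucleus fixture with truth masks
#'
#' Draws elliptical cells with elliptical nuclei at given positions,
#' producing a nuclear-stain channel, a cytoskeleton channel, and the
#' ground-truth label masks for segmentation scoring.
#'
#' @param cells Tibble with one row per cell: `x`, `y` (center, pixels;
#'   `x` = column, `y` = row), `nucleus_r` (nucleus radius), `cell_a`,
#'   `cell_b` (cell semi-axes), `angle_deg` (cell orientation). Circles
#'   can be given via `cell_r` instead of `cell_a`/`cell_b`.
#' @param image_size Square image side (px).
#' @param noise_sd Additive Gaussian noise on both channels.
#' @param seed RNG seed (used only for the noise).
#' @return List: `nuclear_image`, `cyto_image`, `nucleus_truth`,
#'   `cell_truth` (integer label masks; cell i has label i).
#' @export
render_cell_fixture <- function(cells, image_size = 256, noise_sd = 0,
                                seed = 1L) {
  if (!all(c("x", "y", "nucleus_r") %in% names(cells))) {
    abort("`cells` needs x, y and nucleus_r columns.")
  }
  if (!"cell_a" %in% names(cells)) {
    if (!"cell_r" %in% names(cells)) abort("`cells` needs cell_a/cell_b or cell_r.")
    cells$cell_a <- cells$cell_r
    cells$cell_b <- cells$cell_r
  }
  if (!"angle_deg" %in% names(cells)) cells$angle_deg <- 0
  size <- image_size
  lim <- function(x, a) x - a < 1 | x + a > size
  if (any(lim(cells$x, cells$cell_a) | lim(cells$y, cells$cell_a))) {
    abort("a cell extends outside the image bounds.")
  }

  nuc_truth <- matrix(0L, size, size)
  cell_truth <- matrix(0L, size, size)
  for (i in seq_len(nrow(cells))) {
    nm <- ellipse_mask(size, cells$x[i], cells$y[i],
                       cells$nucleus_r[i], cells$nucleus_r[i], 0)
    if (any(nuc_truth[nm] != 0L)) abort("nucleus centers/radii overlap.")
    cm <- ellipse_mask(size, cells$x[i], cells$y[i],
                       cells$cell_a[i], cells$cell_b[i], cells$angle_deg[i])
    nuc_truth[nm] <- i
    cell_truth[cm & cell_truth == 0L] <- i
  }

  with_seed(seed, {
    nuclear <- (nuc_truth > 0) * 1
    cyto <- (cell_truth > 0) * 0.8 + (nuc_truth > 0) * 0.2
    if (noise_sd > 0) {
      nuclear <- pmax(nuclear + matrix(rnorm(size^2, 0, noise_sd), size, size), 0)
      cyto <- pmax(cyto + matrix(rnorm(size^2, 0, noise_sd), size, size), 0)
    }
    list(nuclear_image = nuclear, cyto_image = cyto,
         nucleus_truth = nuc_truth, cell_truth = cell_truth)
  })
}

#' Write a fiber field (or any image matrix) to a grayscale TIFF
#'
#' @param image Numeric matrix; values are rescaled to \[0, 1\].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_image_tiff <- function(image, path) {
  image <- as_image_matrix(image)
  rng <- range(image)
  scaled <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
  tiff::writeTIFF(scaled, path)
  invisible(path)
}
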
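# Synthetic histology phantoms: oriented test textures, a curved
# white-matter tract with locally parallel ridge texture, and planted NSC
# clusters with controllable alignment to the tract.  These stand in for
# stained sections (which are not publicly deposited) and provide ground
# truth for every downstream module.

#' Sinusoidal stripe test image
#'
#' Grating `0.5 + 0.5 cos(2 pi (x sin a - y cos a) / period)` whose
#' stripes run along the axial angle `angle_deg` (measured from the
#' positive x axis).  The cosine form makes the 90-degree image the exact
#' transpose of the 0-degree image.
#'
#' @param size image size, one or two positive integers (nrow, ncol).
#' @param period_px stripe period in pixels (>= 2).
#' @param angle_deg stripe orientation in degrees, \[0, 180).
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity fraction); the image is clipped back to \[0, 1\].
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return numeric matrix with values in \[0, 1\].
#' @export
make_stripe_image <- function(size, period_px, angle_deg, noise_sd = 0,
                              seed = 1L) {
  size <- check_size(size)
  check_number(period_px, "period_px", positive = TRUE)
  if (period_px < 2) stop_invalid("`period_px` must be >= 2")
  check_number(angle_deg, "angle_deg")
  if (angle_deg < 0 || angle_deg >= 180)
    stop_invalid("`angle_deg` must be in [0, 180)")
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  n <- size[1L]; m <- size[2L]
  x <- matrix(seq_len(m), n, m, byrow = TRUE)
  y <- matrix(seq_len(n), n, m)
  a <- angle_deg * pi / 180
  img <- 0.5 + 0.5 * cos(2 * pi * (x * sin(a) - y * cos(a)) / period_px)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
  }
  pmin(pmax(img, 0), 1)
}

#' Isotropic crosshatch test image
#'
#' Sum of two equal-amplitude orthogonal sinusoids,
#' `0.5 + 0.25 (sin(2 pi x / p) + sin(2 pi y / p))`.  Windowed over a full
#' period the gradient energy is identical along both axes, so the
#' structure-tensor coherence is ~0: the isotropic reference texture.
#'
#' @inheritParams make_stripe_image
#' @return numeric matrix with values in \[0, 1\].
#' @export
make_isotropic_crosshatch <- function(size, period_px) {
  size <- check_size(size)
  check_number(period_px, "period_px", positive = TRUE)
  if (period_px < 2) stop_invalid("`period_px` must be >= 2")
  n <- size[1L]; m <- size[2L]
  x <- matrix(seq_len(m), n, m, byrow = TRUE)
  y <- matrix(seq_len(n), n, m)
  0.5 + 0.25 * (sin(2 * pi * x / period_px) + sin(2 * pi * y / period_px))
}

# Evaluate a polynomial (coefficients in increasing power) and its
# derivative at x.
poly_eval <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}
poly_deriv_eval <- function(coefs, x) {
  if (length(coefs) < 2L) return(rep(0, length(x)))
  d <- coefs[-1L] * seq_len(length(coefs) - 1L)
  poly_eval(d, x)
}

#' Curved white-matter tract phantom
#'
#' Builds a two-channel phantom: a myelin-like (`dii_image`) channel with
#' a band of oriented ridge texture around a polynomial centreline
#' `y = f(x)` (the white-matter tract), embedded in a low-amplitude
#' isotropic noise background (grey matter), plus the matching tissue
#' masks.  The texture phase is the vertical offset from the centreline,
#' so its level sets run parallel to the local centreline tangent and the
#' analytic tangent angle `atan(f'(x))` is the per-pixel ground-truth
#' orientation.
#'
#' @param size image size (nrow, ncol).
#' @param tract numeric vector of polynomial coefficients (increasing
#'   power, pixel units) defining the centreline `y = f(x)`, or a list
#'   with element `coefs`.  Default: horizontal line through the middle.
#' @param tract_halfwidth_px half-width of the white-matter band,
#'   measured vertically, in pixels.
#' @param texture_period_px ridge period of the tract texture.
#' @param seed RNG seed for the background texture.
#' @param pixel_scale_um physical pixel size in micrometres.
#' @return an object of class `phantom`: `dii_image`, `nsc_image` (zeros
#'   until [plant_clusters()] is called), `masks` (a [tissue_masks()]
#'   object), `tract` (coefficients), `tract_centerline` (x, y matrix),
#'   `injection_site`, `pixel_scale_um`, `truth_cluster_angles` (empty),
#'   `clusters` (`NULL`).
#' @export
make_tract_phantom <- function(size = c(256L, 384L), tract = NULL,
                               tract_halfwidth_px = 28,
                               texture_period_px = 8, seed = 1L,
                               pixel_scale_um = 1.444) {
  size <- check_size(size)
  n <- size[1L]; m <- size[2L]
  check_number(tract_halfwidth_px, "tract_halfwidth_px", positive = TRUE)
  check_number(texture_period_px, "texture_period_px", positive = TRUE)
  check_number(pixel_scale_um, "pixel_scale_um", positive = TRUE)
  if (is.list(tract)) tract <- tract$coefs
  if (is.null(tract)) tract <- n / 2
  if (!is.numeric(tract) || length(tract) < 1L)
    stop_invalid("`tract` must be a numeric coefficient vector")
  xs <- seq_len(m)
  cy <- poly_eval(tract, xs)
  if (any(cy < 1 + tract_halfwidth_px) || any(cy > n - tract_halfwidth_px))
    stop_invalid("tract centreline leaves the image (margin < halfwidth)")
  x <- matrix(xs, n, m, byrow = TRUE)
  y <- matrix(seq_len(n), n, m)
  offset <- y - matrix(cy, n, m, byrow = TRUE)
  wm <- abs(offset) <= tract_halfwidth_px
  set.seed(seed)
  background <- gaussian_smooth(matrix(stats::runif(n * m), n, m), 1)
  background <- 0.15 * (background - min(background)) /
    max(max(background) - min(background), 1e-12)
  dii <- 0.6 + 0.35 * cos(2 * pi * offset / texture_period_px)
  dii[!wm] <- background[!wm]
  masks <- tissue_masks(wm = wm, gm = !wm,
                        background = matrix(FALSE, n, m),
                        pixel_scale_um = pixel_scale_um)
  inj_x <- max(2, round(0.1 * m))
  injection_site <- c(x = inj_x, y = round(poly_eval(tract, inj_x)))
  structure(list(dii_image = dii,
                 nsc_image = matrix(0, n, m),
                 masks = masks,
                 tract = tract,
                 tract_centerline = cbind(x = xs, y = cy),
                 injection_site = injection_site,
                 pixel_scale_um = pixel_scale_um,
                 truth_cluster_angles = numeric(0),
                 clusters = NULL,
                 seed = seed),
            class = "phantom")
}

#' Tangent angle of the phantom tract
#'
#' @param phantom a `phantom`.
#' @param x abscissa position(s) in pixels.
#' @return axial tangent angle(s) of the centreline in degrees.
#' @export
tract_tangent_angle <- function(phantom, x) {
  axial_mod(atan(poly_deriv_eval(phantom$tract, x)) * 180 / pi)
}

# Render one elongated super-Gaussian blob into img (max-combined).  The
# quartic falloff exp(-q^4/2) gives a sharp stain-like edge, so the
# thresholded footprint area is ~size_px over a wide threshold range.
# Long axis at `angle_deg`, aspect ratio 2.
draw_blob <- function(img, cx, cy, size_px, angle_deg, aspect = 2) {
  # half-maximum ellipse area pi*su*sv*sqrt(2 log 2) ~ size_px
  sig_prod <- size_px / (pi * sqrt(2 * log(2)))
  su <- sqrt(sig_prod * aspect)
  sv <- sqrt(sig_prod / aspect)
  r <- ceiling(2.2 * su)
  n <- nrow(img); m <- ncol(img)
  rows <- max(1L, round(cy) - r):min(n, round(cy) + r)
  cols <- max(1L, round(cx) - r):min(m, round(cx) + r)
  xx <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  yy <- matrix(rows, length(rows), length(cols)) - cy
  a <- angle_deg * pi / 180
  u <- xx * cos(a) + yy * sin(a)
  v <- -xx * sin(a) + yy * cos(a)
  q2 <- u^2 / su^2 + v^2 / sv^2
  blob <- exp(-q2^2 / 2)
  img[rows, cols] <- pmax(img[rows, cols], blob)
  img
}

#' Plant NSC clusters into a phantom
#'
#' Places `n_clusters` elongated cluster blobs at positions spread along
#' the tract centreline.  Each planting unit (a single cluster when
#' `chain_size = 1`, otherwise a short chain of `chain_size` clusters laid
#' out along a common direction) gets a ground-truth axial angle equal to
#' the local tract tangent plus angular noise drawn uniformly from
#' `(1 - alignment) * c(-90, 90)` degrees: `alignment = 1` reproduces the
#' tangent exactly, `alignment = 0` gives uniform axial angles.  Chains
#' (`chain_size > 1`) arrange clusters *spatially* along the truth
#' direction, so that coalesced-region tangents can recover it; this is
#' what the orientation-regression validation uses.
#'
#' @param phantom a `phantom` from [make_tract_phantom()].
#' @param n_clusters number of clusters (>= 1).
#' @param alignment fraction in \[0, 1\]: 1 = blobs aligned with the local
#'   tract tangent, 0 = uniform random axial angles.
#' @param center_jitter_px uniform-disk jitter radius applied to each
#'   planting-unit centre.
#' @param sizes per-cluster target areas in pixels (length `n_clusters`).
#' @param seed RNG seed.
#' @param chain_size clusters per chain (1 = independent clusters).
#' @param chain_spacing_px centre-to-centre spacing inside a chain.
#' @param retry_cap resampling attempts for jittered centres falling
#'   outside the brain mask before an error is raised.
#' @return the phantom with `nsc_image`, `truth_cluster_angles` and
#'   `clusters` (an `nsc_clusters` table of the *planted* truth centres,
#'   sizes and chain ids) filled in.
#' @export
plant_clusters <- function(phantom, n_clusters, alignment,
                           center_jitter_px = 0,
                           sizes = rep(40, n_clusters), seed = 1L,
                           chain_size = 1L, chain_spacing_px = 14,
                           retry_cap = 25L) {
  if (!inherits(phantom, "phantom")) stop_invalid("`phantom` required")
  check_number(n_clusters, "n_clusters", positive = TRUE, integerish = TRUE)
  check_number(alignment, "alignment")
  if (alignment < 0 || alignment > 1)
    stop_invalid("`alignment` must be in [0, 1]")
  check_number(center_jitter_px, "center_jitter_px", nonneg = TRUE)
  if (length(sizes) != n_clusters || any(sizes <= 0))
    stop_invalid("`sizes` must hold one positive area per cluster")
  check_number(chain_size, "chain_size", positive = TRUE, integerish = TRUE)
  set.seed(seed)
  n <- nrow(phantom$dii_image); m <- ncol(phantom$dii_image)
  brain <- phantom$masks$wm | phantom$masks$gm
  n_units <- ceiling(n_clusters / chain_size)
  # anchor abscissae spread along the tract, clear of the borders
  margin <- 0.08 * m
  ax <- seq(margin, m - margin, length.out = n_units + 2L)[-c(1L, n_units + 2L)]
  if (n_units == 1L) ax <- m / 2
  cx <- numeric(n_clusters); cy <- numeric(n_clusters)
  angles <- numeric(n_clusters)
  unit_of <- rep(seq_len(n_units), each = chain_size)[seq_len(n_clusters)]
  for (u in seq_len(n_units)) {
    members <- which(unit_of == u)
    tangent <- tract_tangent_angle(phantom, ax[u])
    noise <- (1 - alignment) * stats::runif(1L, -90, 90)
    ang <- axial_mod(tangent + noise)
    base <- c(ax[u], poly_eval(phantom$tract, ax[u]))
    ok <- FALSE
    for (try in seq_len(retry_cap)) {
      if (center_jitter_px > 0) {
        rr <- center_jitter_px * sqrt(stats::runif(1L))
        ph <- stats::runif(1L, 0, 2 * pi)
        centre <- base + rr * c(cos(ph), sin(ph))
      } else centre <- base
      offs <- (seq_along(members) - (length(members) + 1) / 2) *
        chain_spacing_px
      px <- centre[1L] + offs * cos(ang * pi / 180)
      py <- centre[2L] + offs * sin(ang * pi / 180)
      ix <- round(px); iy <- round(py)
      inside <- ix >= 1 & ix <= m & iy >= 1 & iy <= n
      if (all(inside) && all(brain[cbind(iy, ix)])) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_invalid("cluster placement failed: centres fall outside the ",
                   "brain mask after ", retry_cap, " retries")
    cx[members] <- px; cy[members] <- py
    angles[members] <- ang
  }
  img <- phantom$nsc_image
  for (i in seq_len(n_clusters))
    img <- draw_blob(img, cx[i], cy[i], sizes[i], angles[i])
  phantom$nsc_image <- img
  phantom$truth_cluster_angles <- angles
  phantom$clusters <- nsc_clusters(
    x = cx, y = cy, size = as.numeric(sizes),
    tissue_class = ifelse(phantom$masks$wm[cbind(pmin(pmax(round(cy), 1), n),
                                                 pmin(pmax(round(cx), 1), m))],
                          "WM", "GM"),
    region_id = unit_of)
  phantom
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, pixel scale %.4g um/px\n",
              nrow(x$dii_image), ncol(x$dii_image), x$pixel_scale_um))
  cat(sprintf("  tract poly degree %d, WM fraction %.2f\n",
              length(x$tract) - 1L, mean(x$masks$wm)))
  cat(sprintf("  planted clusters: %d\n",
              length(x$truth_cluster_angles)))
  invisible(x)
}
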
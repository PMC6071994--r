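# Internal helpers: argument checking, axial-angle arithmetic, Gaussian
# smoothing and histogram thresholding shared across modules.

stop_invalid <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0)
    stop_invalid(sprintf("`%s` must be >= 0", name))
  if (integerish && abs(x - round(x)) > 1e-8)
    stop_invalid(sprintf("`%s` must be an integer", name))
  invisible(x)
}

check_image <- function(img, name = "image", min_dim = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid(sprintf("`%s` must be a numeric matrix", name))
  if (any(!is.finite(img)))
    stop_invalid(sprintf("`%s` contains non-finite pixels", name))
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop_invalid(sprintf("`%s` must be at least %dx%d", name, min_dim, min_dim))
  invisible(img)
}

# Canonical size argument: length-1 (square) or c(nrow, ncol).
check_size <- function(size) {
  if (!is.numeric(size) || !length(size) %in% c(1L, 2L) ||
      any(!is.finite(size)) || any(size < 1) ||
      any(abs(size - round(size)) > 1e-8))
    stop_invalid("`size` must be one or two positive integers (nrow, ncol)")
  size <- as.integer(round(size))
  if (length(size) == 1L) size <- c(size, size)
  size
}

#' Reduce angles to the axial interval \[0, 180)
#'
#' Axial (head-less) angles such as fibre or cluster orientations are
#' equivalent modulo 180 degrees.
#'
#' @param theta_deg numeric vector of angles in degrees.
#' @return angles folded into \[0, 180).
#' @export
axial_mod <- function(theta_deg) ((theta_deg %% 180) + 180) %% 180

#' Signed axial difference between two angles
#'
#' @param a,b angles in degrees (axial).
#' @return signed difference `a - b` folded into (-90, 90\].
#' @export
axial_diff <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

# Mirror ("symmetric") boundary index: 1,2,...,n reflected without repeating
# beyond one period; valid for arbitrarily large pad widths.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j[j < 0L] <- j[j < 0L] + 2L * n
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  as.integer(j + 1L)
}

gaussian_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Smooth each column of `m` with kernel `k` using mirror boundaries.
smooth_columns <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- reflect_index(seq.int(1L - r, n + r), n)
  padded <- m[idx, , drop = FALSE]
  out <- stats::filter(padded, k, method = "convolution", sides = 2L)
  matrix(out[(r + 1L):(r + n), ], nrow = n)
}

#' Separable Gaussian smoothing of an image
#'
#' Mirror (reflective) boundary handling; kernel truncated at 4 sigma.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma = 0` returns
#'   the input unchanged.
#' @return smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(img, sigma) {
  check_image(img)
  check_number(sigma, "sigma", nonneg = TRUE)
  if (sigma == 0) return(img)
  k <- gaussian_kernel1d(sigma)
  t(smooth_columns(t(smooth_columns(img, k)), k))
}

#' Otsu threshold of an intensity image
#'
#' Maximises the between-class variance of a 256-bin histogram; returns an
#' intensity cut so that `img > threshold` is foreground.
#'
#' @param img numeric matrix or vector of finite intensities.
#' @param n_bins number of histogram bins.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  if (any(!is.finite(v))) stop_invalid("image contains non-finite pixels")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  edges[which.max(between) + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
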
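# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the code under test.

# Eigenvalues of a symmetric 2x2 tensor via the characteristic polynomial
# (polyroot), eigenvector of the larger root from the null space.
brute_eigen2 <- function(jxx, jxy, jyy) {
  tr <- jxx + jyy
  dt <- jxx * jyy - jxy^2
  roots <- sort(Re(polyroot(c(dt, -tr, 1))), decreasing = TRUE)
  lmax <- roots[1L]
  v <- if (abs(jxy) > 1e-14) c(jxy, lmax - jxx) else
    if (jxx >= jyy) c(1, 0) else c(0, 1)
  theta <- nscmigration::axial_mod(atan2(v[2L], v[1L]) * 180 / pi)
  list(lambda_max = roots[1L], lambda_min = roots[2L], theta = theta)
}

# Distance transform by exhaustive nearest-TRUE-pixel search.
brute_distance_transform <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      out[i, j] <- sqrt(min((pts[, 1L] - i)^2 + (pts[, 2L] - j)^2))
  out
}

# Weighted median by direct accumulation over the sorted values.
brute_weighted_median <- function(v, w) {
  o <- order(v)
  cw <- cumsum(w[o]) / sum(w)
  v[o][which(cw >= 0.5)[1L]]
}

# Weighted simple-regression coefficients from the normal equations.
brute_wls <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = beta[1L], slope = beta[2L])
}
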
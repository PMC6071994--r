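# Correlating NSC cluster orientation (theta_NSC) with local white-matter
# orientation (theta_WM): neighbourhood sampling of the orientation field,
# axial wraparound alignment of angle pairs, and cluster-weighted least
# squares.

#' Local white-matter orientation around a point
#'
#' Coherence-weighted mean axial orientation over valid pixels within
#' `radius_px` of `center` whose coherence is at least `coherence_min`.
#'
#' @param field an [orientation_field()].
#' @param center numeric `(x, y)` in pixels, inside the image.
#' @param radius_px sampling radius (default 25 px).
#' @param coherence_min minimum coherence of contributing pixels.
#' @return mean axial orientation in degrees, or `NA` (with a message)
#'   when no pixel qualifies.
#' @export
local_wm_orientation <- function(field, center, radius_px = 25,
                                 coherence_min = 0.2) {
  if (!inherits(field, "orientation_field"))
    stop_invalid("`field` must be an orientation_field")
  check_number(radius_px, "radius_px", positive = TRUE)
  n <- nrow(field$theta); m <- ncol(field$theta)
  cx <- center[1L]; cy <- center[2L]
  if (cx < 1 || cx > m || cy < 1 || cy > n)
    stop_invalid("`center` outside the image")
  rows <- max(1L, floor(cy - radius_px)):min(n, ceiling(cy + radius_px))
  cols <- max(1L, floor(cx - radius_px)):min(m, ceiling(cx + radius_px))
  xx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  yy <- matrix(rows, length(rows), length(cols))
  inside <- (xx - cx)^2 + (yy - cy)^2 <= radius_px^2
  keep <- inside & field$valid[rows, cols] &
    field$coherence[rows, cols] >= coherence_min
  if (!any(keep)) {
    message("local_wm_orientation: no valid pixel in neighbourhood")
    return(NA_real_)
  }
  mean_axial_orientation(field$theta[rows, cols][keep],
                         field$coherence[rows, cols][keep])
}

#' Align an axial angle pair across the 0/180 wrap
#'
#' Replaces `theta_nsc` by `theta_nsc + k * 180` (k in -1, 0, 1) so that
#' the difference to `theta_wm` has magnitude <= 90 degrees.  Without
#' this step a naive linear regression of axial angles is discontinuous
#' at the wrap.
#'
#' @param theta_wm,theta_nsc angles in degrees on \[0, 180) (vectorised).
#' @return matrix with columns `theta_wm`, `theta_nsc` (aligned).
#' @export
axial_pair_alignment <- function(theta_wm, theta_nsc) {
  d <- theta_nsc - theta_wm
  adj <- d - 180 * round(d / 180)
  cbind(theta_wm = theta_wm, theta_nsc = theta_wm + adj)
}

#' Weighted least-squares regression of angle pairs
#'
#' Ordinary weighted least squares of `y` on `x`;
#' `r^2 = 1 - weighted RSS / weighted TSS`.  Slope, intercept and `r^2`
#' are invariant to a common rescaling of the weights.
#'
#' @param pairs two-column matrix or data frame `(x, y)` in degrees.
#' @param weights positive weights, one per pair.
#' @return object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`, `weights_used`, `pairs`.
#' @export
weighted_regression <- function(pairs, weights = NULL) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 2L)
    stop_invalid("`pairs` must be an (n >= 2) x 2 matrix")
  x <- pairs[, 1L]; y <- pairs[, 2L]
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights <= 0))
    stop_invalid("`weights` must be positive, one per pair")
  if (length(unique(x)) < 2L)
    stop_invalid("all x identical: slope undefined")
  fit <- stats::lm(y ~ x, weights = weights)
  co <- stats::coef(fit)
  mu <- sum(weights * y) / sum(weights)
  tss <- sum(weights * (y - mu)^2)
  rss <- sum(weights * stats::residuals(fit)^2)
  r2 <- if (tss <= 0) 0 else max(0, min(1, 1 - rss / tss))
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2, n_points = length(x),
                 weights_used = weights, pairs = pairs),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> slope %.3f, intercept %.2f deg, r^2 %.3f, n %d\n",
    x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' theta_NSC vs theta_WM regression, overall and per tissue class
#'
#' For every cluster carrying a `theta_nsc`, the local white-matter
#' orientation is sampled around its centre, the pair is aligned across
#' the axial wrap, and weighted regressions are run for all clusters and
#' for the WM-only / GM-only subsets.  Following the weighting used for
#' such analyses, each pair's weight is the total number of clusters in
#' its coalesced region (`weight_mode = "cluster_count"`); the cluster
#' pixel size is available as an alternative.
#'
#' @param clusters annotated [nsc_clusters()] table (needs `theta_nsc`,
#'   `tissue_class`, `region_id`).
#' @param regions list of coalesced regions (used for region totals).
#' @param field an [orientation_field()].
#' @param masks a [tissue_masks()] object (tissue classes are derived
#'   from it when missing).
#' @param radius_px,coherence_min passed to [local_wm_orientation()].
#' @param weight_mode `"cluster_count"` (region totals) or `"size"`.
#' @param wrap axial wraparound handling before regression.
#'   `"common_window"` (default) folds both angles of every pair into the
#'   single 180-degree window centred on the weighted axial mean of
#'   theta_WM, which leaves independent angles uncorrelated;
#'   `"pairwise"` applies [axial_pair_alignment()] per pair, which
#'   minimises each pair's difference but biases the fitted slope towards
#'   1 when the angles are unrelated (the expected theta_NSC given
#'   theta_WM is then theta_WM itself).  Both break down when the true
#'   angle spread approaches the full 180-degree range.
#' @return list with elements `all`, `wm`, `gm`: each a
#'   `regression_result` or `NULL` when fewer than 2 usable points, plus
#'   a `scatter` data frame (theta_wm, theta_nsc aligned, weight,
#'   tissue_class, region_id).
#' @export
correlate_by_tissue <- function(clusters, regions, field, masks,
                                radius_px = 25, coherence_min = 0.2,
                                weight_mode = c("cluster_count", "size"),
                                wrap = c("common_window", "pairwise")) {
  weight_mode <- match.arg(weight_mode)
  wrap <- match.arg(wrap)
  if (all(is.na(clusters$tissue_class)) && !is.null(masks))
    clusters <- classify_clusters(clusters, masks)
  usable <- which(!is.na(clusters$theta_nsc) & !clusters$excluded)
  theta_wm <- rep(NA_real_, length(usable))
  for (k in seq_along(usable)) {
    i <- usable[k]
    theta_wm[k] <- suppressMessages(
      local_wm_orientation(field, c(clusters$x[i], clusters$y[i]),
                           radius_px, coherence_min))
  }
  keep <- !is.na(theta_wm)
  usable <- usable[keep]
  theta_wm <- theta_wm[keep]
  if (!length(usable))
    return(list(all = NULL, wm = NULL, gm = NULL,
                scatter = data.frame()))
  region_tot <- table(clusters$region_id[!is.na(clusters$region_id)])
  w <- switch(weight_mode,
              cluster_count = as.numeric(
                region_tot[as.character(clusters$region_id[usable])]),
              size = clusters$size[usable])
  aligned <- if (wrap == "pairwise") {
    axial_pair_alignment(theta_wm, clusters$theta_nsc[usable])
  } else {
    centre <- mean_axial_orientation(theta_wm, w)
    cbind(theta_wm = centre + axial_diff(theta_wm, centre),
          theta_nsc = centre + axial_diff(clusters$theta_nsc[usable],
                                          centre))
  }
  scatter <- data.frame(theta_wm = aligned[, 1L],
                        theta_nsc = aligned[, 2L],
                        weight = w,
                        tissue_class = clusters$tissue_class[usable],
                        region_id = clusters$region_id[usable])
  fit_subset <- function(rows) {
    if (length(rows) < 2L ||
        length(unique(scatter$theta_wm[rows])) < 2L) return(NULL)
    weighted_regression(as.matrix(scatter[rows, c("theta_wm",
                                                  "theta_nsc")]),
                        scatter$weight[rows])
  }
  list(all = fit_subset(seq_len(nrow(scatter))),
       wm = fit_subset(which(scatter$tissue_class %in% "WM")),
       gm = fit_subset(which(scatter$tissue_class %in% "GM")),
       scatter = scatter)
}
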
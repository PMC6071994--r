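# Tissue masks and cluster-size-weighted distance statistics: distances
# from the injection site (with an exclusion radius), distances to the
# nearest white/grey matter interface, weighted cumulative probability
# distributions (CPDs) with medians, and the percentage of NSC signal in
# white matter.

#' Tissue mask container
#'
#' White matter, grey matter and background must be mutually exclusive
#' and jointly exhaustive.  Interface pixels are the WM pixels with a GM
#' 8-neighbour plus the GM pixels with a WM 8-neighbour.
#'
#' @param wm,gm,background logical matrices of equal shape.
#' @param pixel_scale_um physical pixel size in micrometres.
#' @return object of class `tissue_masks` with the three masks,
#'   `interface` (logical matrix), `interface_xy` (matrix of interface
#'   pixel coordinates) and `pixel_scale_um`.
#' @export
tissue_masks <- function(wm, gm, background = NULL,
                         pixel_scale_um = 1.444) {
  if (!is.matrix(wm) || !is.matrix(gm) || !is.logical(wm) ||
      !is.logical(gm) || !all(dim(wm) == dim(gm)))
    stop_invalid("`wm` and `gm` must be logical matrices of equal shape")
  if (is.null(background)) background <- !(wm | gm)
  if (!all(dim(background) == dim(wm)))
    stop_invalid("`background` shape mismatch")
  if (any(wm & gm) || any(wm & background) || any(gm & background))
    stop_invalid("wm, gm and background must be mutually exclusive")
  if (!all(wm | gm | background))
    stop_invalid("wm, gm and background must cover every pixel")
  check_number(pixel_scale_um, "pixel_scale_um", positive = TRUE)
  iface <- (wm & has_neighbor(gm)) | (gm & has_neighbor(wm))
  xy <- which(iface, arr.ind = TRUE)
  structure(list(wm = wm, gm = gm, background = background,
                 interface = iface,
                 interface_xy = cbind(x = xy[, 2L], y = xy[, 1L]),
                 pixel_scale_um = pixel_scale_um),
            class = "tissue_masks")
}

# TRUE where any 8-neighbour of `mask` is TRUE.
has_neighbor <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(FALSE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rs <- seq_len(n) + dr
    cs <- seq_len(m) + dc
    vr <- rs >= 1L & rs <= n
    vc <- cs >= 1L & cs <= m
    out[vr, vc] <- out[vr, vc] | mask[rs[vr], cs[vc]]
  }
  out
}

#' @export
print.tissue_masks <- function(x, ...) {
  cat(sprintf(
    "<tissue_masks> %d x %d px: WM %.1f%%, GM %.1f%%, background %.1f%%, %d interface px\n",
    nrow(x$wm), ncol(x$wm), 100 * mean(x$wm), 100 * mean(x$gm),
    100 * mean(x$background), nrow(x$interface_xy)))
  invisible(x)
}

#' Segment white matter from a myelin-stain image
#'
#' Smooths the DiI-like channel (suppressing the fibre-scale texture so
#' the stain *envelope*, not individual fibres, is segmented), thresholds
#' it (fixed cut or Otsu), removes components smaller than
#' `min_component_px`, and builds the tissue masks with GM = brain minus
#' WM.
#'
#' @param dii_image numeric intensity matrix.
#' @param threshold numeric cut or `"otsu"`.
#' @param min_component_px minimum WM component area kept.
#' @param smooth_sigma_px Gaussian pre-smoothing; choose about half the
#'   myelin texture period (0 disables).
#' @param brain_mask logical matrix of in-brain pixels; default whole
#'   frame.
#' @param pixel_scale_um micrometres per pixel.
#' @return a [tissue_masks()] object.
#' @export
wm_mask_from_dii <- function(dii_image, threshold = "otsu",
                             min_component_px = 25L, smooth_sigma_px = 4,
                             brain_mask = NULL, pixel_scale_um = 1.444) {
  check_image(dii_image)
  check_number(smooth_sigma_px, "smooth_sigma_px", nonneg = TRUE)
  smoothed <- gaussian_smooth(dii_image, smooth_sigma_px)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(smoothed)
         else check_number(threshold, "threshold")
  wm <- smoothed > thr
  if (is.null(brain_mask))
    brain_mask <- matrix(TRUE, nrow(dii_image), ncol(dii_image))
  wm <- wm & brain_mask
  if (any(wm) && min_component_px > 1L) {
    lab <- label_components(wm)
    area <- tabulate(lab[lab > 0L])
    wm[lab > 0L & area[pmax(lab, 1L)] < min_component_px] <- FALSE
  }
  if (!any(wm))
    stop_invalid("no white matter found above threshold; ",
                 "review the threshold or the image")
  gm <- brain_mask & !wm
  if (!any(gm))
    warning("white matter covers the whole brain mask; GM empty, ",
            "no WM/GM interface")
  tissue_masks(wm = wm, gm = gm, background = !brain_mask,
               pixel_scale_um = pixel_scale_um)
}

#' Cluster distances from the injection site
#'
#' 2-D Euclidean distances scaled to micrometres.  Clusters at or inside
#' the exclusion radius (default 1000 px, i.e. 1444 um at the default
#' pixel scale) are flagged excluded; only strictly farther clusters
#' enter the distance distributions.
#'
#' @param clusters an [nsc_clusters()] table.
#' @param injection_site numeric `(x, y)` in pixels.
#' @param exclusion_radius_px exclusion radius in pixels.
#' @param pixel_scale_um micrometres per pixel.
#' @param image_shape optional `(nrow, ncol)`; when given, an injection
#'   site outside the image raises an error.
#' @return data frame with `distance_um` and logical `excluded`.
#' @export
distances_from_injection <- function(clusters, injection_site,
                                     exclusion_radius_px = 1000,
                                     pixel_scale_um = 1.444,
                                     image_shape = NULL) {
  if (length(injection_site) != 2L || any(!is.finite(injection_site)))
    stop_invalid("`injection_site` must be finite (x, y)")
  check_number(exclusion_radius_px, "exclusion_radius_px", nonneg = TRUE)
  check_number(pixel_scale_um, "pixel_scale_um", positive = TRUE)
  if (!is.null(image_shape)) {
    image_shape <- check_size(image_shape)
    if (injection_site[1L] < 1 || injection_site[1L] > image_shape[2L] ||
        injection_site[2L] < 1 || injection_site[2L] > image_shape[1L])
      stop_invalid("`injection_site` lies outside the image")
  }
  d_px <- sqrt((clusters$x - injection_site[1L])^2 +
                 (clusters$y - injection_site[2L])^2)
  data.frame(distance_um = d_px * pixel_scale_um,
             excluded = d_px <= exclusion_radius_px)
}

#' Weighted cumulative probability distribution
#'
#' Empirical weighted CDF of the supplied values; the weighted median is
#' the smallest value whose cumulative weight reaches one half.
#'
#' @param values_um numeric values (micrometres in the migration
#'   analyses).
#' @param weights positive weights, recycled to the value length when
#'   scalar.
#' @return object of class `cpd`: list with sorted `distances_um`,
#'   `cum_prob`, `weights` (sorted order), `median_um` and `n`.
#' @export
weighted_cpd <- function(values_um, weights = NULL) {
  if (!length(values_um)) stop_invalid("no values supplied")
  if (any(!is.finite(values_um))) stop_invalid("non-finite values")
  if (is.null(weights)) weights <- rep(1, length(values_um))
  if (length(weights) == 1L) weights <- rep(weights, length(values_um))
  if (length(weights) != length(values_um) || any(weights <= 0))
    stop_invalid("`weights` must be positive and match `values_um`")
  o <- order(values_um)
  v <- values_um[o]
  w <- weights[o]
  cp <- cumsum(w) / sum(w)
  cp[length(cp)] <- 1  # guard roundoff
  structure(list(distances_um = v, cum_prob = cp, weights = w,
                 median_um = v[which(cp >= 0.5)[1L]],
                 n = length(v)),
            class = "cpd")
}

#' @export
print.cpd <- function(x, ...) {
  cat(sprintf("<cpd> n = %d, median = %.4g um, range [%.4g, %.4g] um\n",
              x$n, x$median_um, min(x$distances_um), max(x$distances_um)))
  invisible(x)
}

#' @export
plot.cpd <- function(x, ..., xlab = "distance (um)",
                     ylab = "cumulative probability") {
  graphics::plot(x$distances_um, x$cum_prob, type = "s", xlab = xlab,
                 ylab = ylab, ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Weighted fraction of NSC signal in white matter
#'
#' @param clusters a classified [nsc_clusters()] table (see
#'   [classify_clusters()]).
#' @param masks optional [tissue_masks()]; when given, classification is
#'   (re)derived from the masks.
#' @return list with `wm_percent`, `gm_percent`, `unclassified_percent`
#'   (each of the total cluster weight; they sum to 100) and the weight
#'   totals.
#' @export
wm_fraction <- function(clusters, masks = NULL) {
  if (!is.null(masks)) clusters <- classify_clusters(clusters, masks)
  if (!nrow(clusters)) stop_invalid("no clusters")
  total <- sum(clusters$size)
  wmw <- sum(clusters$size[clusters$tissue_class %in% "WM"])
  gmw <- sum(clusters$size[clusters$tissue_class %in% "GM"])
  list(wm_percent = 100 * wmw / total,
       gm_percent = 100 * gmw / total,
       unclassified_percent = 100 * (total - wmw - gmw) / total,
       total_weight = total)
}

#' Cluster distances to the nearest WM/GM interface
#'
#' Exact Euclidean distance transform of the interface pixel set, sampled
#' at the (pixel-rounded) cluster centres and scaled to micrometres.
#'
#' @param clusters an [nsc_clusters()] table.
#' @param masks a [tissue_masks()] object with a non-empty interface.
#' @param pixel_scale_um micrometres per pixel; defaults to the masks'.
#' @return numeric vector of distances in micrometres, one per cluster.
#' @export
interface_distances <- function(clusters, masks,
                                pixel_scale_um = masks$pixel_scale_um) {
  if (!inherits(masks, "tissue_masks")) stop_invalid("`masks` required")
  if (!any(masks$interface))
    stop_invalid("empty WM/GM interface")
  check_number(pixel_scale_um, "pixel_scale_um", positive = TRUE)
  if (!nrow(clusters)) return(numeric(0))
  dt <- distance_transform(masks$interface)
  n <- nrow(masks$wm); m <- ncol(masks$wm)
  iy <- pmin(pmax(round(clusters$y), 1), n)
  ix <- pmin(pmax(round(clusters$x), 1), m)
  dt[cbind(iy, ix)] * pixel_scale_um
}
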
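# NSC cluster detection and geometry: intensity thresholding into
# connected components, disk dilate/erode coalescing of cluster centres,
# circularity filtering, principal-frame quadratic fits and per-cluster
# tangent angles (theta_NSC).

#' NSC cluster table constructor
#'
#' A thin S3 wrapper around a data frame with one row per detected (or
#' planted) cluster: centre coordinates `x`, `y` (pixels), positive weight
#' `size`, `tissue_class` (`"WM"`, `"GM"` or `NA`), coalesced `region_id`
#' (`NA` until [coalesce()]), tangent orientation `theta_nsc` (degrees,
#' `NA` until extracted) and logical `excluded`.
#'
#' @param x,y cluster centre coordinates in pixels.
#' @param size positive per-cluster weights (pixel area or cell count).
#' @param tissue_class,region_id,theta_nsc,excluded optional columns.
#' @return object of classes `nsc_clusters` and `data.frame`.
#' @export
nsc_clusters <- function(x = numeric(0), y = numeric(0),
                         size = numeric(0), tissue_class = NA_character_,
                         region_id = NA_integer_, theta_nsc = NA_real_,
                         excluded = FALSE) {
  if (length(x) != length(y) || length(x) != length(size))
    stop_invalid("x, y and size must have equal length")
  if (length(size) && any(size <= 0))
    stop_invalid("cluster sizes must be positive")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   size = as.numeric(size),
                   tissue_class = rep_len(tissue_class, length(x)),
                   region_id = rep_len(region_id, length(x)),
                   theta_nsc = rep_len(theta_nsc, length(x)),
                   excluded = rep_len(excluded, length(x)),
                   stringsAsFactors = FALSE)
  class(df) <- c("nsc_clusters", "data.frame")
  df
}

#' Detect NSC clusters in a stain channel
#'
#' Thresholds the image (fixed cut or Otsu), labels 8-connected
#' components, and keeps those with at least `min_size_px` pixels.  The
#' centre is the intensity-weighted centroid; the size is the component
#' pixel area.
#'
#' @param nsc_image numeric intensity matrix.
#' @param threshold numeric cut (foreground is `> threshold`) or
#'   `"otsu"`.
#' @param min_size_px minimum component area in pixels.
#' @return an [nsc_clusters()] table (possibly empty).
#' @export
detect_clusters <- function(nsc_image, threshold = "otsu",
                            min_size_px = 5L) {
  check_image(nsc_image)
  check_number(min_size_px, "min_size_px", positive = TRUE,
               integerish = TRUE)
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(nsc_image)
  } else {
    check_number(threshold, "threshold")
    if (threshold < min(nsc_image) || threshold > max(nsc_image))
      stop_invalid("`threshold` outside image intensity range")
    threshold
  }
  fg <- nsc_image > thr
  if (!any(fg)) {
    message("detect_clusters: no pixels above threshold")
    return(nsc_clusters())
  }
  lab <- label_components(fg, connectivity = 8L)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  area <- tabulate(labs)
  keep <- which(area >= min_size_px)
  if (!length(keep)) {
    message("detect_clusters: no component reaches min_size_px")
    return(nsc_clusters())
  }
  rc <- arrayInd(idx, dim(nsc_image))
  w <- nsc_image[idx]
  sx <- rowsum(w * rc[, 2L], labs)[, 1L]
  sy <- rowsum(w * rc[, 1L], labs)[, 1L]
  sw <- rowsum(w, labs)[, 1L]
  nsc_clusters(x = (sx / sw)[keep], y = (sy / sw)[keep],
               size = area[keep])
}

#' Assign a tissue class to each cluster
#'
#' Class is read from the mask value at the (rounded) cluster centre.
#' Clusters landing on background are flagged with `NA` and a warning.
#'
#' @param clusters an [nsc_clusters()] table.
#' @param masks a [tissue_masks()] object.
#' @return the cluster table with `tissue_class` filled.
#' @export
classify_clusters <- function(clusters, masks) {
  if (!nrow(clusters)) return(clusters)
  n <- nrow(masks$wm); m <- ncol(masks$wm)
  iy <- pmin(pmax(round(clusters$y), 1), n)
  ix <- pmin(pmax(round(clusters$x), 1), m)
  at <- cbind(iy, ix)
  cls <- ifelse(masks$wm[at], "WM", ifelse(masks$gm[at], "GM",
                                           NA_character_))
  if (anyNA(cls))
    warning(sum(is.na(cls)), " cluster(s) fall on background tissue")
  clusters$tissue_class <- cls
  clusters
}

#' Coalesce cluster centres into regions by disk dilation and erosion
#'
#' The binary map of cluster centres is dilated by `dilate_px` and eroded
#' by `erode_px` with Euclidean disk structuring elements (the defaults,
#' 200 and 100 px, merge centres closer than about twice the net radius).
#' Connected components of the result are the coalesced regions; every
#' cluster is assigned the label of the region containing its centre.
#' Region circularity `4 pi A / P^2` is computed immediately and regions
#' above `circularity_max` are flagged excluded from orientation fitting.
#'
#' @param clusters an [nsc_clusters()] table.
#' @param image_shape integer vector (nrow, ncol) of the source image.
#' @param dilate_px,erode_px disk radii, `dilate_px > erode_px >= 0`.
#' @param circularity_max exclusion threshold on circularity.
#' @return list with `clusters` (region ids and exclusion flags filled)
#'   and `regions`, a list of `coalesced_region` objects (fields `label`,
#'   `pixel_idx`, `dim`, `area_px`, `perimeter_px`, `circularity`,
#'   `excluded`, `member_clusters`; fit fields added by
#'   [fit_region_polynomial()]).
#' @export
coalesce <- function(clusters, image_shape, dilate_px = 200,
                     erode_px = 100, circularity_max = 0.7) {
  check_number(dilate_px, "dilate_px", positive = TRUE)
  check_number(erode_px, "erode_px", nonneg = TRUE)
  if (dilate_px <= erode_px)
    stop_invalid("`dilate_px` must exceed `erode_px`")
  image_shape <- check_size(image_shape)
  if (!nrow(clusters))
    return(list(clusters = clusters, regions = list()))
  n <- image_shape[1L]; m <- image_shape[2L]
  iy <- pmin(pmax(round(clusters$y), 1), n)
  ix <- pmin(pmax(round(clusters$x), 1), m)
  map <- coalesce_map(iy, ix, c(n, m), dilate_px, erode_px)
  lab <- label_components(map, connectivity = 8L)
  clusters$region_id <- lab[cbind(iy, ix)]
  clusters$region_id[clusters$region_id == 0L] <- NA_integer_
  regions <- lapply(seq_len(max(lab)), function(l) {
    mask <- lab == l
    area <- sum(mask)
    perim <- trace_perimeter(mask)
    circ <- if (perim < 1) 1 else 4 * pi * area / perim^2
    structure(list(label = l,
                   pixel_idx = which(mask),
                   dim = dim(mask),
                   area_px = area,
                   perimeter_px = perim,
                   circularity = circ,
                   excluded = circ > circularity_max,
                   member_clusters = which(!is.na(clusters$region_id) &
                                             clusters$region_id == l),
                   poly_coeffs = NULL,
                   principal_frame = NULL,
                   fit_degree = NA_integer_),
              class = "coalesced_region")
  })
  for (r in regions)
    clusters$excluded[r$member_clusters] <- r$excluded
  list(clusters = clusters, regions = regions)
}

# Dilate point centres by a disk and erode back, equivalently to
# binary_erode_disk(binary_dilate_disk(centres, dilate), erode) but
# exploiting sparsity: disks are painted directly and the erosion
# distance transform runs on the padded bounding box of the dilated set
# (everything beyond the box is background at distance > erode_px, and
# pixels outside the image never erode the set, matching the generic
# operators' border convention).
coalesce_map <- function(iy, ix, shape, dilate_px, erode_px) {
  n <- shape[1L]; m <- shape[2L]
  dil <- matrix(FALSE, n, m)
  r <- dilate_px
  ri <- floor(r)
  for (k in seq_along(iy)) {
    rows <- max(1L, iy[k] - ri):min(n, iy[k] + ri)
    cols <- max(1L, ix[k] - ri):min(m, ix[k] + ri)
    dy <- rows - iy[k]
    dx <- cols - ix[k]
    patch <- outer(dy^2, dx^2, `+`) <= r^2 + 1e-9
    dil[rows, cols] <- dil[rows, cols] | patch
  }
  if (erode_px == 0) return(dil)
  pad <- ceiling(erode_px) + 2L
  rr <- range(which(rowSums(dil) > 0))
  cr <- range(which(colSums(dil) > 0))
  rows <- max(1L, rr[1L] - pad):min(n, rr[2L] + pad)
  cols <- max(1L, cr[1L] - pad):min(m, cr[2L] + pad)
  crop <- dil[rows, cols, drop = FALSE]
  out <- matrix(FALSE, n, m)
  out[rows, cols] <- if (any(!crop)) {
    distance_transform(!crop) > erode_px + 1e-9
  } else crop
  out
}

region_mask <- function(region) {
  mask <- matrix(FALSE, region$dim[1L], region$dim[2L])
  mask[region$pixel_idx] <- TRUE
  mask
}

#' Circularity of a coalesced region
#'
#' `4 pi area / perimeter^2` with the perimeter measured by tracing the
#' outer 8-connected boundary contour (diagonal steps count sqrt(2)), so
#' a disk scores close to 1 (discretisation may push it slightly above)
#' and elongated shapes score low.
#'
#' @param region a `coalesced_region`.
#' @return circularity value.
#' @export
region_circularity <- function(region) {
  if (!inherits(region, "coalesced_region"))
    stop_invalid("`region` must be a coalesced_region")
  region$circularity
}

#' Principal-frame quadratic fit of a region
#'
#' Region pixels are rotated about their centroid so that the principal
#' (long) axis becomes the abscissa `u`, then `v = a u^2 + b u + c` is fit
#' by least squares.  Fitting in the principal frame keeps the
#' function-graph parameterisation well defined for any region
#' orientation.  A rank-deficient quadratic falls back to a flagged
#' degree-1 fit.
#'
#' @param region a `coalesced_region` with at least 6 pixels, not
#'   excluded by circularity.
#' @return the region with `poly_coeffs` (`c(a, b, c)`),
#'   `principal_frame` (list `angle_deg`, `centroid`) and `fit_degree`
#'   filled.
#' @export
fit_region_polynomial <- function(region) {
  if (!inherits(region, "coalesced_region"))
    stop_invalid("`region` must be a coalesced_region")
  if (isTRUE(region$excluded))
    stop_invalid("region excluded by circularity; no fit")
  if (region$area_px < 6L)
    stop_invalid("region too small to fit (needs >= 6 pixels)")
  rc <- arrayInd(region$pixel_idx, region$dim)
  xy <- cbind(x = rc[, 2L], y = rc[, 1L])
  centroid <- colMeans(xy)
  cc <- sweep(xy, 2L, centroid)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  major <- ev$vectors[, 1L]
  angle <- atan2(major[2L], major[1L])
  u <- cc[, 1L] * cos(angle) + cc[, 2L] * sin(angle)
  v <- -cc[, 1L] * sin(angle) + cc[, 2L] * cos(angle)
  degree <- 2L
  fit <- tryCatch(stats::lm(v ~ u + I(u^2)), error = function(e) NULL)
  co <- if (!is.null(fit)) stats::coef(fit) else rep(NA_real_, 3L)
  if (is.null(fit) || anyNA(co)) {
    degree <- 1L
    fit <- stats::lm(v ~ u)
    co <- c(stats::coef(fit), 0)[c(3L, 2L, 1L)]  # a = 0
    poly_coeffs <- c(a = 0, b = unname(stats::coef(fit)[2L]),
                     c = unname(stats::coef(fit)[1L]))
  } else {
    poly_coeffs <- c(a = unname(co[3L]), b = unname(co[2L]),
                     c = unname(co[1L]))
  }
  region$poly_coeffs <- poly_coeffs
  region$principal_frame <- list(angle_deg = angle * 180 / pi,
                                 centroid = centroid)
  region$fit_degree <- degree
  region$u_range <- range(u)
  region
}

#' Tangent angle of the region polynomial nearest a cluster centre
#'
#' The point on the fitted curve closest to the cluster centre is found by
#' dense 1-px sampling of `u` over the fitted range (extended by 10%)
#' followed by golden-section refinement; the tangent slope `2 a u + b`
#' there is rotated back to the image frame and reduced to \[0, 180).
#'
#' @param region a fitted `coalesced_region`.
#' @param center numeric `(x, y)` cluster centre in image coordinates.
#' @return list with `theta_deg` (axial tangent angle), `u_star` (curve
#'   parameter of the nearest point) and logical `extrapolated` (nearest
#'   point beyond the fitted `u` range).
#' @export
cluster_tangent_angle <- function(region, center) {
  if (is.null(region$poly_coeffs))
    stop_invalid("region has no polynomial fit")
  a <- region$poly_coeffs[["a"]]
  b <- region$poly_coeffs[["b"]]
  c_ <- region$poly_coeffs[["c"]]
  frame <- region$principal_frame
  ang <- frame$angle_deg * pi / 180
  p <- c(center[1L] - frame$centroid[1L], center[2L] - frame$centroid[2L])
  pu <- p[1L] * cos(ang) + p[2L] * sin(ang)
  pv <- -p[1L] * sin(ang) + p[2L] * cos(ang)
  ur <- region$u_range
  pad <- 0.1 * max(diff(ur), 1)
  grid <- seq(ur[1L] - pad, ur[2L] + pad, by = 1)
  d2 <- function(u) (u - pu)^2 + (a * u^2 + b * u + c_ - pv)^2
  vals <- d2(grid)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  u_star <- if (hi > lo) stats::optimize(d2, c(lo, hi))$minimum else grid[i]
  slope <- 2 * a * u_star + b
  # tangent direction (1, slope) in the principal frame, back to image frame
  dirx <- cos(ang) * 1 - sin(ang) * slope
  diry <- sin(ang) * 1 + cos(ang) * slope
  theta <- axial_mod(atan2(diry, dirx) * 180 / pi)
  list(theta_deg = theta, u_star = u_star,
       extrapolated = u_star < ur[1L] || u_star > ur[2L])
}

#' Full cluster-orientation extraction
#'
#' Convenience wrapper chaining [coalesce()], [fit_region_polynomial()]
#' and [cluster_tangent_angle()]: every cluster belonging to a retained
#' (circularity <= `circularity_max`) region with a valid fit receives a
#' `theta_nsc`.
#'
#' @inheritParams coalesce
#' @return list with the annotated `clusters` table and the fitted
#'   `regions` list.
#' @export
extract_cluster_orientations <- function(clusters, image_shape,
                                         dilate_px = 200, erode_px = 100,
                                         circularity_max = 0.7) {
  co <- coalesce(clusters, image_shape, dilate_px, erode_px,
                 circularity_max)
  clusters <- co$clusters
  regions <- co$regions
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    if (r$excluded || r$area_px < 6L || !length(r$member_clusters)) next
    r <- fit_region_polynomial(r)
    r$theta_nsc_per_cluster <- vapply(r$member_clusters, function(i) {
      cluster_tangent_angle(r, c(clusters$x[i], clusters$y[i]))$theta_deg
    }, numeric(1))
    clusters$theta_nsc[r$member_clusters] <- r$theta_nsc_per_cluster
    regions[[k]] <- r
  }
  list(clusters = clusters, regions = regions)
}
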
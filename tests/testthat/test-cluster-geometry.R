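# Cluster detection, coalescing, circularity filtering, polynomial fits
# and tangent angles.

test_that("detect_clusters finds blobs with correct sizes and centres", {
  img <- matrix(0, 60, 80)
  img[10:14, 10:19] <- 1   # 50 px
  img[40:47, 50:59] <- 1   # 80 px
  cl <- detect_clusters(img, threshold = 0.5, min_size_px = 5)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$size, c(50, 80))
  i <- which(cl$size == 50)
  expect_equal(cl$x[i], 14.5)
  expect_equal(cl$y[i], 12)
  expect_message(empty <- detect_clusters(matrix(0, 20, 20) + 0.01),
                 "no pixels|no component")
  expect_equal(nrow(empty), 0L)
  expect_error(detect_clusters(img, threshold = 7), "range")
})

test_that("planted clusters are recovered within 2 px", {
  ph <- make_tract_phantom(size = c(128, 500), tract = 64,
                           tract_halfwidth_px = 24)
  ph <- plant_clusters(ph, 10, alignment = 1, center_jitter_px = 0,
                       sizes = rep(50, 10), seed = 2, chain_size = 1L)
  cl <- detect_clusters(ph$nsc_image)
  expect_equal(nrow(cl), 10L)
  d <- sapply(seq_len(nrow(cl)), function(i)
    min(sqrt((ph$clusters$x - cl$x[i])^2 + (ph$clusters$y - cl$y[i])^2)))
  expect_lt(max(d), 2)
})

test_that("coalescing merges nearby centres and separates distant ones", {
  near <- nsc_clusters(x = c(150, 300), y = c(200, 200), size = c(1, 1))
  res <- coalesce(near, c(400L, 450L), dilate_px = 200, erode_px = 100)
  expect_equal(length(res$regions), 1L)
  expect_equal(res$clusters$region_id, c(1L, 1L))
  far <- nsc_clusters(x = c(250, 850), y = c(200, 200), size = c(1, 1))
  res2 <- coalesce(far, c(400L, 1100L), dilate_px = 200, erode_px = 100)
  expect_equal(length(res2$regions), 2L)
  expect_equal(res2$clusters$region_id, c(1L, 2L))
  # single centre: net disk of radius ~dilate - erode, circularity ~1
  one <- nsc_clusters(x = 200, y = 200, size = 1)
  res3 <- coalesce(one, c(400L, 400L), dilate_px = 200, erode_px = 100)
  r <- res3$regions[[1L]]
  expect_lt(abs(r$area_px - pi * 100^2) / (pi * 100^2), 0.03)
  expect_gt(r$circularity, 0.95)
  expect_lt(r$circularity, 1.1)
  expect_true(r$excluded)
  expect_error(coalesce(one, c(400L, 400L), 100, 100), "exceed")
})

test_that("circularity decreases with elongation at fixed area", {
  circ_of_rect <- function(h, w) {
    m <- matrix(FALSE, h + 20L, w + 20L)
    m[11:(10 + h), 11:(10 + w)] <- TRUE
    4 * pi * sum(m) / nscmigration:::trace_perimeter(m)^2
  }
  # fixed area 3600, growing aspect ratio
  vals <- c(circ_of_rect(60, 60), circ_of_rect(40, 90),
            circ_of_rect(24, 150), circ_of_rect(12, 300))
  expect_true(all(diff(vals) < 0))
})

test_that("polynomial fit works in the principal frame", {
  # pixels from a thick parabolic band v = 0.01 u^2, rotated by 40 deg
  mk_region <- function(rot_deg) {
    u <- rep(seq(-60, 60, by = 1), each = 5)
    v <- 0.01 * u^2 + rep(-2:2, times = 121)
    a <- rot_deg * pi / 180
    x <- round(250 + u * cos(a) - v * sin(a))
    y <- round(150 + u * sin(a) + v * cos(a))
    mask <- matrix(FALSE, 300, 500)
    mask[cbind(y, x)] <- TRUE
    structure(list(label = 1L, pixel_idx = which(mask), dim = dim(mask),
                   area_px = sum(mask), perimeter_px = 100,
                   circularity = 0.2, excluded = FALSE,
                   member_clusters = integer(0)),
              class = "coalesced_region")
  }
  # the principal frame is defined up to axis sign, so compare |a|
  f0 <- fit_region_polynomial(mk_region(0))
  expect_equal(abs(unname(f0$poly_coeffs[["a"]])), 0.01, tolerance = 0.1)
  f40 <- fit_region_polynomial(mk_region(40))
  expect_equal(abs(unname(f40$poly_coeffs[["a"]])),
               abs(unname(f0$poly_coeffs[["a"]])), tolerance = 0.02)
  # straight horizontal segment: all coefficients ~0 in frame
  seg <- matrix(FALSE, 50, 200)
  seg[24:26, 20:180] <- TRUE
  rs <- structure(list(label = 1L, pixel_idx = which(seg), dim = dim(seg),
                       area_px = sum(seg), perimeter_px = 10,
                       circularity = 0.2, excluded = FALSE,
                       member_clusters = integer(0)),
                  class = "coalesced_region")
  fs <- fit_region_polynomial(rs)
  expect_lt(max(abs(fs$poly_coeffs)), 1e-6)
  tiny <- rs; tiny$area_px <- 4L
  expect_error(fit_region_polynomial(tiny), ">= 6")
})

test_that("tangent angles follow the fitted curve", {
  seg <- matrix(FALSE, 50, 200)
  seg[24:26, 20:180] <- TRUE
  rs <- structure(list(label = 1L, pixel_idx = which(seg), dim = dim(seg),
                       area_px = sum(seg), perimeter_px = 10,
                       circularity = 0.2, excluded = FALSE,
                       member_clusters = integer(0)),
                  class = "coalesced_region")
  fs <- fit_region_polynomial(rs)
  t1 <- cluster_tangent_angle(fs, c(100, 30))
  expect_lt(abs(axial_diff(t1$theta_deg, 0)), 0.5)
  # synthetic fit: parabola v = 0.01 u^2 in an axis-aligned frame
  par <- fs
  par$poly_coeffs <- c(a = 0.01, b = 0, c = 0)
  par$principal_frame <- list(angle_deg = 0, centroid = c(100, 25))
  par$u_range <- c(-80, 80)
  vertex <- cluster_tangent_angle(par, c(100, 25))
  expect_lt(abs(axial_diff(vertex$theta_deg, 0)), 0.5)
  # at u ~ 50 the tangent slope is 2 * 0.01 * 50 = 1 -> 45 degrees
  off <- cluster_tangent_angle(par, c(150, 25 + 0.01 * 50^2))
  expect_lt(abs(axial_diff(off$theta_deg, 45)), 1.5)
  beyond <- cluster_tangent_angle(par, c(100 + 200, 25 + 100))
  expect_true(beyond$extrapolated)
})

test_that("theta_NSC is rotation equivariant", {
  base_angle <- function(phi) {
    # thick bar through the centre at angle phi
    u <- rep(seq(-70, 70, by = 1), each = 7)
    v <- rep(-3:3, times = 141)
    a <- phi * pi / 180
    x <- round(150 + u * cos(a) - v * sin(a))
    y <- round(150 + u * sin(a) + v * cos(a))
    mask <- matrix(FALSE, 300, 300)
    mask[cbind(y, x)] <- TRUE
    cl <- nsc_clusters(x = 150 + 30 * cos(a), y = 150 + 30 * sin(a),
                       size = 10)
    reg <- structure(list(label = 1L, pixel_idx = which(mask),
                          dim = dim(mask), area_px = sum(mask),
                          perimeter_px = 10, circularity = 0.2,
                          excluded = FALSE, member_clusters = 1L),
                     class = "coalesced_region")
    fit <- fit_region_polynomial(reg)
    cluster_tangent_angle(fit, c(cl$x, cl$y))$theta_deg
  }
  t0 <- base_angle(0)
  for (phi in c(15, 40, 77))
    expect_lt(abs(axial_diff(base_angle(phi), t0 + phi)), 2)
})

test_that("full orientation extraction recovers planted truth", {
  ph <- make_tract_phantom(size = c(128, 500), tract = 64,
                           tract_halfwidth_px = 24)
  ph <- plant_clusters(ph, 16, alignment = 1, center_jitter_px = 2,
                       seed = 5, chain_size = 4L)
  cl <- detect_clusters(ph$nsc_image)
  ext <- extract_cluster_orientations(cl, dim(ph$nsc_image),
                                      dilate_px = 16, erode_px = 8)
  got <- ext$clusters$theta_nsc
  expect_gt(sum(!is.na(got)), 8)
  err <- abs(axial_diff(got[!is.na(got)], 0))  # truth = 0 (horizontal)
  expect_lt(stats::median(err), 10)
})
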
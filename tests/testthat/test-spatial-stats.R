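# Tissue masks, injection/interface distances, weighted CPDs and WM
# fractions.

test_that("tissue mask constructor enforces the partition", {
  wm <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  gm <- !wm
  m <- tissue_masks(wm, gm)
  expect_s3_class(m, "tissue_masks")
  expect_error(tissue_masks(wm, wm), "exclusive")
  expect_error(tissue_masks(wm, matrix(FALSE, 2, 2),
                            matrix(FALSE, 2, 2)), "cover")
})

test_that("white-matter segmentation recovers the phantom band", {
  ph <- make_tract_phantom(size = c(128, 300), tract = c(70, 0.02),
                           tract_halfwidth_px = 24, seed = 3)
  mk <- wm_mask_from_dii(ph$dii_image)
  jac <- sum(mk$wm & ph$masks$wm) / sum(mk$wm | ph$masks$wm)
  expect_gt(jac, 0.9)
  expect_error(wm_mask_from_dii(matrix(0, 30, 30)), "threshold")
  expect_warning(wm_mask_from_dii(matrix(1, 30, 30) +
                                    1e-6 * matrix(stats::rnorm(900), 30),
                                  threshold = 0.5),
                 "GM empty")
})

test_that("injection distances use the exclusion radius and pixel scale", {
  cl <- nsc_clusters(x = c(1001, 1, 301), y = c(1, 1, 401),
                     size = c(1, 1, 1))
  d <- distances_from_injection(cl, c(1, 1), exclusion_radius_px = 1000,
                                pixel_scale_um = 1.444)
  expect_equal(d$distance_um[1L], 1444)
  expect_true(d$excluded[1L])    # exactly at the boundary -> excluded
  expect_true(d$excluded[2L])    # at the site
  expect_equal(d$distance_um[2L], 0)
  d2 <- distances_from_injection(cl, c(1, 1), exclusion_radius_px = 100,
                                 pixel_scale_um = 1)
  expect_equal(d2$distance_um[3L], 500)  # 3-4-5 triangle
  expect_false(d2$excluded[3L])
  expect_error(distances_from_injection(cl, c(-5, 1), 10, 1,
                                        image_shape = c(100, 100)),
               "outside")
})

test_that("weighted CPD matches direct weighted-median computation", {
  c1 <- weighted_cpd(c(1, 2, 3))
  expect_equal(c1$median_um, 2)
  expect_equal(c1$cum_prob, c(1, 2, 3) / 3)
  c2 <- weighted_cpd(c(1, 10), c(9, 1))
  expect_equal(c2$median_um, 1)
  c3 <- weighted_cpd(5)
  expect_equal(c3$cum_prob, 1)
  expect_equal(c3$median_um, 5)
  # ordering and weight-scale invariance
  set.seed(8)
  for (rep in 1:5) {
    v <- stats::runif(31, 0, 500)
    w <- stats::runif(31, 0.1, 4)
    perm <- sample(31)
    a <- weighted_cpd(v, w)
    b <- weighted_cpd(v[perm], 10 * w[perm])
    expect_equal(a$median_um, b$median_um)
    expect_equal(a$cum_prob, b$cum_prob)
    expect_equal(a$median_um, brute_weighted_median(v, w))
    expect_true(all(diff(a$cum_prob) >= -1e-12))
    expect_equal(a$cum_prob[length(a$cum_prob)], 1)
  }
  expect_error(weighted_cpd(numeric(0)), "no values")
  expect_error(weighted_cpd(1, -1), "positive")
})

test_that("exclusion radius monotonicity: larger radius, larger median", {
  set.seed(11)
  cl <- nsc_clusters(x = stats::runif(60, 1, 900),
                     y = stats::runif(60, 1, 900),
                     size = stats::runif(60, 1, 5))
  meds <- sapply(c(0, 100, 250, 400), function(r) {
    d <- distances_from_injection(cl, c(450, 450), r, 1)
    if (!any(!d$excluded)) return(NA_real_)
    weighted_cpd(d$distance_um[!d$excluded],
                 cl$size[!d$excluded])$median_um
  })
  expect_true(all(diff(stats::na.omit(meds)) >= 0))
})

test_that("wm_fraction partitions weight exactly", {
  cl <- nsc_clusters(x = c(1, 2, 3), y = c(1, 1, 1), size = c(1, 1, 2),
                     tissue_class = c("WM", "GM", "WM"))
  fr <- wm_fraction(cl)
  expect_equal(fr$wm_percent, 75)
  expect_equal(fr$gm_percent, 25)
  expect_equal(fr$wm_percent + fr$gm_percent + fr$unclassified_percent,
               100)
  allwm <- nsc_clusters(x = 1:3, y = 1:3, size = rep(1, 3),
                        tissue_class = "WM")
  expect_equal(wm_fraction(allwm)$wm_percent, 100)
  # cluster on background triggers a warning and counts in neither
  wm <- matrix(FALSE, 10, 10); wm[1:5, ] <- TRUE
  gm <- matrix(FALSE, 10, 10); gm[6:9, ] <- TRUE
  masks <- tissue_masks(wm, gm, !(wm | gm))
  clb <- nsc_clusters(x = c(2, 2), y = c(2, 10), size = c(1, 1))
  expect_warning(fr2 <- wm_fraction(clb, masks), "background")
  expect_equal(fr2$wm_percent, 50)
  expect_equal(fr2$unclassified_percent, 50)
})

test_that("planted WM weight fraction is recovered from the phantom", {
  ph <- make_tract_phantom(size = c(192, 600), tract = 96,
                           tract_halfwidth_px = 30, seed = 9)
  # 7 clusters on the tract, 3 forced into GM by vertical offset
  set.seed(10)
  xs <- seq(60, 540, length.out = 10)
  ys <- c(rep(96, 7), rep(30, 3))
  img <- ph$nsc_image
  for (i in seq_along(xs))
    img <- nscmigration:::draw_blob(img, xs[i], ys[i], 40, 0)
  cl <- classify_clusters(detect_clusters(img), ph$masks)
  fr <- wm_fraction(cl)
  expect_equal(fr$wm_percent, 70, tolerance = 0.03)
})

test_that("interface distances equal brute-force nearest-pixel search", {
  # straight vertical interface at x = 100
  wm <- matrix(FALSE, 60, 200); wm[, 1:100] <- TRUE
  masks <- tissue_masks(wm, !wm)
  cl <- nsc_clusters(x = c(130, 100), y = c(30, 30), size = c(1, 1))
  d <- interface_distances(cl, masks, pixel_scale_um = 1)
  expect_equal(d[2L], 0)
  expect_equal(d[1L], 29)  # interface spans x = 100 and 101; nearest 101
  # random masks vs brute force
  for (seed in 1:3) {
    set.seed(seed)
    wm <- gaussian_smooth(matrix(stats::runif(128 * 128), 128), 6) > 0.5
    if (!any(wm) || all(wm)) next
    masks <- tissue_masks(wm, !wm)
    cl <- nsc_clusters(x = sample(5:124, 12), y = sample(5:124, 12),
                       size = rep(1, 12))
    d <- interface_distances(cl, masks, pixel_scale_um = 1)
    bdt <- brute_distance_transform(masks$interface)
    expect_equal(d, bdt[cbind(round(cl$y), round(cl$x))],
                 tolerance = 1e-6)
  }
  empty <- tissue_masks(matrix(TRUE, 5, 5), matrix(FALSE, 5, 5))
  expect_error(interface_distances(cl, empty), "interface")
})
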
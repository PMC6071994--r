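# Seeding, stepping rules, termination causes and path statistics.

test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_paths = 0, seed_center = c(1, 1)), "> 0")
  expect_error(sim_config(seed_center = c(1, NA)), "finite")
  expect_error(sim_config(seed_center = c(1, 1), step_px = 0), "> 0")
  cfg <- sim_config(seed_center = c(50, 50))
  expect_equal(cfg$n_paths, 500L)
  expect_equal(cfg$wm_kernel_sigma_px, 5)
})

test_that("seeds are uniform over the disk and reproducible", {
  cfg <- sim_config(n_paths = 10000L, seed_center = c(200, 200),
                    seed_radius_px = 50, rng_seed = 4)
  s1 <- draw_seeds(cfg, image_shape = c(400L, 400L))
  s2 <- draw_seeds(cfg, image_shape = c(400L, 400L))
  expect_identical(s1, s2)
  r <- sqrt((s1[, 1L] - 200)^2 + (s1[, 2L] - 200)^2)
  expect_true(all(r <= 50 + 1e-9))
  expect_equal(mean(r <= 25), 0.25, tolerance = 0.02)
  cfg0 <- sim_config(n_paths = 5L, seed_center = c(10, 10),
                     seed_radius_px = 0)
  expect_true(all(draw_seeds(cfg0) == c(10, 10, 10, 10, 10)))
  cfg_bad <- sim_config(seed_center = c(5, 5), seed_radius_px = 50)
  expect_error(draw_seeds(cfg_bad, image_shape = c(100L, 100L)),
               "outside")
})

test_that("white-matter rule follows the axis with sign persistence", {
  f <- uniform_field(20, 20, 0)
  masks <- all_wm_masks(20, 20)
  cfg <- sim_config(n_paths = 1L, seed_center = c(10, 10))
  fwd <- next_step(c(10, 10), c(1, 0), f, masks, cfg)
  expect_equal(fwd$direction, c(1, 0))
  expect_equal(fwd$tissue, "WM")
  bwd <- next_step(c(10, 10), c(-1, 0), f, masks, cfg)
  expect_equal(bwd$direction, c(-1, 0))
  gm <- all_gm_masks(20, 20)
  set.seed(1)
  st <- next_step(c(10, 10), c(1, 0), f, gm, cfg)
  expect_equal(st$tissue, "GM")
  expect_equal(sqrt(sum(st$direction^2)), 1)
  expect_error(next_step(c(10, 10), c(1, 0), f,
                         tissue_masks(matrix(FALSE, 20, 20),
                                      matrix(FALSE, 20, 20)), cfg),
               "outside")
})

test_that("grey-matter turning angles are uniform in magnitude", {
  set.seed(2)
  t_iso <- sample_gm_turns(100000)
  expect_lte(max(abs(t_iso)), 180)
  ks <- suppressWarnings(
    stats::ks.test(abs(t_iso), "punif", 0, 180)$statistic)
  expect_lt(ks, 0.01)
  # signs balanced
  expect_equal(mean(t_iso > 0), 0.5, tolerance = 0.01)
  t_signed <- sample_gm_turns(1000, "signed")
  expect_true(all(t_signed >= 0))
})

test_that("uniform white matter yields straight, exact-length paths", {
  f <- uniform_field(64, 220, 0)
  masks <- all_wm_masks(64, 220)
  cfg <- sim_config(n_paths = 6L, seed_center = c(110, 32),
                    seed_radius_px = 0, step_px = 1, max_steps = 100L,
                    rng_seed = 9)
  paths <- simulate_paths(f, masks, cfg)
  for (p in paths) {
    expect_equal(p$terminated_by, "max_steps")
    d <- sqrt(sum((p$points[nrow(p$points), ] - p$points[1L, ])^2))
    expect_equal(d, 100)
    steps <- sqrt(rowSums(diff(p$points)^2))
    expect_equal(steps, rep(1, 100), tolerance = 1e-9)
    expect_equal(abs(p$points[nrow(p$points), 2L] - p$points[1L, 2L]), 0)
  }
})

test_that("self-intersection truncates a path revisiting its own cell", {
  # a confined grey-matter walk revisits one of its occupancy cells
  gm <- all_gm_masks(60, 60)
  f <- uniform_field(60, 60, 0, coherence = 0, valid = FALSE)
  cfg <- sim_config(n_paths = 5L, seed_center = c(30, 30),
                    seed_radius_px = 0, max_steps = 2000L, rng_seed = 3)
  paths <- simulate_paths(f, gm, cfg)
  causes <- vapply(paths, function(p) p$terminated_by, character(1))
  expect_true(all(causes == "self_intersection"))
  for (p in paths) {
    cells <- paste(round(p$points[, 1L]), round(p$points[, 2L]))
    # the final cell was already visited earlier in the path
    expect_true(cells[length(cells)] %in%
                  cells[seq_len(length(cells) - 1L)])
  }
  # turning truncation off lets the same walk run its full budget
  cfg2 <- sim_config(n_paths = 5L, seed_center = c(30, 30),
                     seed_radius_px = 0, max_steps = 300L, rng_seed = 3,
                     truncate_self_intersection = FALSE)
  paths2 <- simulate_paths(f, gm, cfg2)
  expect_true(all(vapply(paths2, function(p) p$terminated_by,
                         character(1)) %in% c("max_steps", "boundary")))
})

test_that("paths terminate at the image boundary", {
  f <- uniform_field(30, 40, 0)
  masks <- all_wm_masks(30, 40)
  cfg <- sim_config(n_paths = 3L, seed_center = c(36, 15),
                    seed_radius_px = 0, max_steps = 100L, rng_seed = 2)
  paths <- simulate_paths(f, masks, cfg)
  expect_true(all(vapply(paths, function(p) p$terminated_by,
                         character(1)) == "boundary"))
})

test_that("simulations are bit-identical for a fixed configuration", {
  ph <- make_tract_phantom(size = c(96, 200), tract = 48,
                           tract_halfwidth_px = 18, seed = 1)
  f <- orientation_field(ph$dii_image, 5)
  cfg <- sim_config(n_paths = 40L, seed_center = c(40, 48),
                    seed_radius_px = 8, max_steps = 120L, rng_seed = 77)
  p1 <- simulate_paths(f, ph$masks, cfg)
  p2 <- simulate_paths(f, ph$masks, cfg)
  expect_identical(p1, p2)
})

test_that("grey-matter walks are diffusive; white matter is ballistic", {
  gm <- all_gm_masks(320, 320)
  f <- uniform_field(320, 320, 0, coherence = 0, valid = FALSE)
  steps <- c(25L, 50L, 100L, 200L)
  disp <- sapply(steps, function(ns) {
    cfg <- sim_config(n_paths = 300L, seed_center = c(160, 160),
                      seed_radius_px = 0, max_steps = ns, rng_seed = 13,
                      truncate_self_intersection = FALSE)
    ps <- simulate_paths(f, gm, cfg)
    mean(vapply(ps, function(p)
      sqrt(sum((p$points[nrow(p$points), ] - p$points[1L, ])^2)),
      numeric(1)))
  })
  expo <- stats::coef(stats::lm(log(disp) ~ log(steps)))[2L]
  expect_gt(expo, 0.4)
  expect_lt(expo, 0.6)
  # ballistic WM exceeds diffusive GM by > 5x at 200 steps
  wmf <- uniform_field(320, 820, 0)
  wmm <- all_wm_masks(320, 820)
  cfgw <- sim_config(n_paths = 50L, seed_center = c(310, 160),
                     seed_radius_px = 0, max_steps = 200L, rng_seed = 13)
  pw <- simulate_paths(wmf, wmm, cfgw)
  dw <- mean(vapply(pw, function(p)
    sqrt(sum((p$points[nrow(p$points), ] - p$points[1L, ])^2)),
    numeric(1)))
  expect_gt(dw / disp[4L], 5)
})

test_that("path statistics summarise displacement and tissue occupancy", {
  pts <- cbind(seq(0, 100), 50)
  p <- structure(list(points = pts, terminated_by = "max_steps",
                      steps_in_wm = 100L, steps_in_gm = 0L),
                 class = "migration_path")
  st <- path_statistics(list(p), pixel_scale_um = 1.444)
  expect_equal(st$mean_net_displacement_um, 144.4)
  expect_equal(st$pct_steps_in_wm, 100)
  # pooled stats invariant to ordering
  q <- structure(list(points = pts[1:51, ], terminated_by = "boundary",
                      steps_in_wm = 20L, steps_in_gm = 30L),
                 class = "migration_path")
  s1 <- path_statistics(list(p, q))
  s2 <- path_statistics(list(q, p))
  expect_equal(s1$mean_net_displacement_um, s2$mean_net_displacement_um)
  expect_equal(s1$pct_steps_in_wm, s2$pct_steps_in_wm)
  expect_equal(s1$pct_steps_in_wm, 100 * 120 / 150)
})
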
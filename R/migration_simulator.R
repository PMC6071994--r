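# Stochastic NSC migration model: paths seeded uniformly in a disk around
# the injection site advance with fixed step length; in white matter the
# step follows the local tissue-orientation axis (sign persistence keeps
# the heading), in grey matter the heading turns by a random angle whose
# magnitude is uniform on [0, 180] degrees.  Paths stop on
# self-intersection (revisiting a 1-px occupancy cell), on leaving the
# brain, or at a step budget.

#' Simulator configuration
#'
#' @param n_paths number of paths (default 500, matching the scale of the
#'   original simulations).
#' @param seed_center numeric `(x, y)` centre of the seeding disk.
#' @param seed_radius_px seeding disk radius in pixels (>= 0).
#' @param step_px step length in pixels.
#' @param max_steps step budget per path.
#' @param wm_kernel_sigma_px Gaussian window sigma of the orientation
#'   field the simulator follows (5 px gives a stable theta_WM).
#' @param rng_seed integer seed; the full path set is reproducible from
#'   it.
#' @param gm_rule `"isotropic"`: turning magnitude uniform on
#'   \[0, 180\] degrees with random sign (an isotropic reorientation);
#'   `"signed"`: the literal one-sided reading, signed turn uniform on
#'   \[0, 180\].
#' @param truncate_self_intersection terminate a path when it re-enters a
#'   previously visited occupancy cell (`TRUE`, the model rule).  Turning
#'   it off yields an unobstructed walk, useful for diffusion-scaling
#'   checks.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_paths = 500L, seed_center, seed_radius_px = 20,
                       step_px = 1, max_steps = 5000L,
                       wm_kernel_sigma_px = 5, rng_seed = 1L,
                       gm_rule = c("isotropic", "signed"),
                       truncate_self_intersection = TRUE) {
  gm_rule <- match.arg(gm_rule)
  check_number(n_paths, "n_paths", positive = TRUE, integerish = TRUE)
  if (length(seed_center) != 2L || any(!is.finite(seed_center)))
    stop_invalid("`seed_center` must be finite (x, y)")
  check_number(seed_radius_px, "seed_radius_px", nonneg = TRUE)
  check_number(step_px, "step_px", positive = TRUE)
  check_number(max_steps, "max_steps", positive = TRUE, integerish = TRUE)
  check_number(wm_kernel_sigma_px, "wm_kernel_sigma_px", positive = TRUE)
  check_number(rng_seed, "rng_seed", integerish = TRUE)
  structure(list(n_paths = as.integer(n_paths),
                 seed_center = as.numeric(seed_center),
                 seed_radius_px = seed_radius_px,
                 step_px = step_px,
                 max_steps = as.integer(max_steps),
                 wm_kernel_sigma_px = wm_kernel_sigma_px,
                 rng_seed = as.integer(rng_seed),
                 gm_rule = gm_rule,
                 truncate_self_intersection =
                   isTRUE(truncate_self_intersection)),
            class = "sim_config")
}

#' Draw seed points uniformly in the seeding disk
#'
#' @param config a [sim_config()].
#' @param image_shape optional `(nrow, ncol)`; when given, a seeding disk
#'   reaching outside the image raises an error.
#' @param n number of seeds (default `config$n_paths`).
#' @param seed RNG seed; `NULL` continues the current RNG stream.
#' @return `n x 2` matrix of `(x, y)` seed positions.
#' @export
draw_seeds <- function(config, image_shape = NULL, n = config$n_paths,
                       seed = config$rng_seed) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` required")
  if (!is.null(image_shape)) {
    image_shape <- check_size(image_shape)
    r <- config$seed_radius_px
    cx <- config$seed_center[1L]; cy <- config$seed_center[2L]
    if (cx - r < 1 || cx + r > image_shape[2L] ||
        cy - r < 1 || cy + r > image_shape[1L])
      stop_invalid("seeding disk reaches outside the image")
  }
  if (!is.null(seed)) set.seed(seed)
  rr <- config$seed_radius_px * sqrt(stats::runif(n))
  ph <- stats::runif(n, 0, 2 * pi)
  cbind(x = config$seed_center[1L] + rr * cos(ph),
        y = config$seed_center[2L] + rr * sin(ph))
}

#' Sample grey-matter turning angles
#'
#' `"isotropic"`: magnitude uniform on \[0, 180\] degrees, sign +/- with
#' equal probability; `"signed"`: uniform on \[0, 180\] without sign flip.
#'
#' @param n number of draws.
#' @param gm_rule turning rule (see [sim_config()]).
#' @return signed turning angles in degrees.
#' @export
sample_gm_turns <- function(n, gm_rule = c("isotropic", "signed")) {
  gm_rule <- match.arg(gm_rule)
  mag <- stats::runif(n, 0, 180)
  if (gm_rule == "signed") return(mag)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' One step of the migration rule
#'
#' In white matter with a valid orientation the new direction is the unit
#' vector along the local orientation axis whose dot product with the
#' previous direction is non-negative (axis sign persistence); in grey
#' matter (or on degenerate white-matter pixels) the previous direction
#' is rotated by a random turn from [sample_gm_turns()].
#'
#' @param position numeric `(x, y)` inside the brain mask.
#' @param previous_direction unit vector of the last step.
#' @param field orientation field at the simulator window sigma.
#' @param masks [tissue_masks()] object.
#' @param config [sim_config()].
#' @return list `direction` (unit vector) and `tissue` (`"WM"` or
#'   `"GM"`, the rule that was applied).
#' @export
next_step <- function(position, previous_direction, field, masks,
                      config) {
  iy <- round(position[2L]); ix <- round(position[1L])
  n <- nrow(masks$wm); m <- ncol(masks$wm)
  if (ix < 1 || ix > m || iy < 1 || iy > n ||
      masks$background[iy, ix])
    stop_invalid("`position` is outside the brain mask")
  in_wm <- masks$wm[iy, ix] && field$valid[iy, ix]
  if (in_wm) {
    a <- field$theta[iy, ix] * pi / 180
    v <- c(cos(a), sin(a))
    if (sum(v * previous_direction) < 0) v <- -v
    return(list(direction = v, tissue = "WM"))
  }
  turn <- sample_gm_turns(1L, config$gm_rule) * pi / 180
  rot <- matrix(c(cos(turn), sin(turn), -sin(turn), cos(turn)), 2L, 2L)
  v <- as.numeric(rot %*% previous_direction)
  list(direction = v / sqrt(sum(v^2)),
       tissue = if (masks$wm[iy, ix]) "WM" else "GM")
}

#' Simulate NSC migration paths
#'
#' Seeds `config$n_paths` starting points in the seeding disk, then
#' advances each path by `step_px` per step under [next_step()] until it
#' revisits one of its own occupancy cells (`self_intersection`), leaves
#' the brain/image (`boundary`), or exhausts `max_steps`.  Occupancy is
#' tracked per path on the 1-px pixel grid; paths do not block each
#' other.  Fully reproducible from `rng_seed`.
#'
#' @param field orientation field computed at
#'   `config$wm_kernel_sigma_px`.
#' @param masks [tissue_masks()] object.
#' @param config [sim_config()].
#' @return list of `migration_path` objects: `points` (matrix x, y),
#'   `terminated_by`, `steps_in_wm`, `steps_in_gm`.
#' @export
simulate_paths <- function(field, masks, config) {
  if (!inherits(config, "sim_config")) stop_invalid("`config` required")
  n <- nrow(masks$wm); m <- ncol(masks$wm)
  if (!all(dim(field$theta) == c(n, m)))
    stop_invalid("field/mask shape mismatch")
  set.seed(config$rng_seed)
  seeds <- draw_seeds(config, image_shape = c(n, m), seed = NULL)
  stamp <- matrix(0L, n, m)  # path id of the last visit, reused across paths
  theta_rad <- field$theta * pi / 180
  lapply(seq_len(config$n_paths), function(p) {
    pos <- seeds[p, ]
    pts <- matrix(NA_real_, config$max_steps + 1L, 2L)
    pts[1L, ] <- pos
    ang0 <- stats::runif(1L, 0, 2 * pi)
    dir <- c(cos(ang0), sin(ang0))
    cell <- c(round(pos[2L]), round(pos[1L]))
    stamp[cell[1L], cell[2L]] <<- p
    wm_steps <- 0L; gm_steps <- 0L
    cause <- "max_steps"
    k <- 1L
    while (k <= config$max_steps) {
      iy <- cell[1L]; ix <- cell[2L]
      in_wm <- masks$wm[iy, ix] && field$valid[iy, ix]
      if (in_wm) {
        a <- theta_rad[iy, ix]
        v <- c(cos(a), sin(a))
        if (sum(v * dir) < 0) v <- -v
        dir <- v
        wm_steps <- wm_steps + 1L
      } else {
        turn <- sample_gm_turns(1L, config$gm_rule) * pi / 180
        dir <- c(cos(turn) * dir[1L] - sin(turn) * dir[2L],
                 sin(turn) * dir[1L] + cos(turn) * dir[2L])
        if (masks$wm[iy, ix]) wm_steps <- wm_steps + 1L
        else gm_steps <- gm_steps + 1L
      }
      new_pos <- pos + config$step_px * dir
      niy <- round(new_pos[2L]); nix <- round(new_pos[1L])
      if (nix < 1 || nix > m || niy < 1 || niy > n ||
          masks$background[niy, nix]) {
        cause <- "boundary"
        break
      }
      k <- k + 1L
      pts[k, ] <- new_pos
      pos <- new_pos
      if (niy != cell[1L] || nix != cell[2L]) {
        if (config$truncate_self_intersection &&
            stamp[niy, nix] == p) {
          cause <- "self_intersection"
          cell <- c(niy, nix)
          break
        }
        stamp[niy, nix] <<- p
        cell <- c(niy, nix)
      }
    }
    structure(list(points = pts[seq_len(k), , drop = FALSE],
                   terminated_by = cause,
                   steps_in_wm = wm_steps,
                   steps_in_gm = gm_steps),
              class = "migration_path")
  })
}

#' Summary statistics of a path set
#'
#' @param paths list of `migration_path` objects.
#' @param pixel_scale_um micrometres per pixel.
#' @return list with per-path vectors (`net_displacement_um`,
#'   `path_length_um`, `n_steps`) and pooled summaries
#'   (`mean_net_displacement_um`, `mean_path_length_um`,
#'   `pct_steps_in_wm`, `termination_counts`).
#' @export
path_statistics <- function(paths, pixel_scale_um = 1.444) {
  if (!length(paths)) stop_invalid("no paths supplied")
  check_number(pixel_scale_um, "pixel_scale_um", positive = TRUE)
  net <- vapply(paths, function(p) {
    pts <- p$points
    sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
  }, numeric(1)) * pixel_scale_um
  len <- vapply(paths, function(p) {
    pts <- p$points
    if (nrow(pts) < 2L) return(0)
    sum(sqrt(rowSums(diff(pts)^2)))
  }, numeric(1)) * pixel_scale_um
  wm <- vapply(paths, function(p) p$steps_in_wm, integer(1))
  gm <- vapply(paths, function(p) p$steps_in_gm, integer(1))
  total_steps <- sum(wm) + sum(gm)
  list(net_displacement_um = net,
       path_length_um = len,
       n_steps = wm + gm,
       mean_net_displacement_um = mean(net),
       mean_path_length_um = mean(len),
       pct_steps_in_wm = if (total_steps > 0) 100 * sum(wm) / total_steps
                         else NA_real_,
       termination_counts = table(vapply(paths, function(p)
         p$terminated_by, character(1))))
}

#' @export
print.migration_path <- function(x, ...) {
  cat(sprintf(
    "<migration_path> %d points, %s; steps WM %d / GM %d\n",
    nrow(x$points), x$terminated_by, x$steps_in_wm, x$steps_in_gm))
  invisible(x)
}
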
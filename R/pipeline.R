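# End-to-end pipeline orchestration: configuration with literature
# defaults, stage execution in dependency order, and a hashed artifact
# manifest so a fixed configuration reproduces every output byte.

#' Default pipeline configuration
#'
#' Analysis-stage defaults follow the published method parameters:
#' centre dilation 200 px / erosion 100 px, circularity cutoff 0.7,
#' injection exclusion radius 1000 px, orientation-map window 1 px,
#' simulator window 5 px, 500 simulated paths, pixel scale 1.444 um/px.
#' Phantom-stage defaults describe a synthetic section large enough
#' (256 x 2400 px) to be compatible with those radii: a gently curved
#' tract with 24 clusters planted in chains of 4.  Smaller phantoms work
#' with proportionally scaled `dilate_px`/`erode_px`/
#' `exclusion_radius_px`.
#'
#' @return named list of all configuration keys.
#' @export
default_run_config <- function() {
  list(
    # inputs: either a phantom spec (phantom = TRUE) or image paths
    phantom = TRUE,
    dii_path = "",
    nsc_path = "",
    # phantom spec
    size = c(256L, 2400L),
    tract = c(204, -0.24, 1e-4),
    tract_halfwidth_px = 28,
    texture_period_px = 8,
    n_clusters = 24L,
    alignment = 0.75,
    center_jitter_px = 4,
    chain_size = 4L,
    cluster_size_px = 40,
    # geometry / analysis (published method parameters)
    injection_x = NA_real_,
    injection_y = NA_real_,
    pixel_scale_um = 1.444,
    map_sigma = 1,
    sim_sigma = 5,
    gradient_method = "cubic_spline",
    threshold = "otsu",
    min_size_px = 5L,
    dilate_px = 200,
    erode_px = 100,
    circularity_max = 0.7,
    exclusion_radius_px = 1000,
    wm_radius_px = 25,
    coherence_min = 0.2,
    # simulator
    n_paths = 500L,
    seed_radius_px = 20,
    step_px = 1,
    max_steps = 5000L,
    # run control
    rng_seed = 1L,
    out_dir = "nscmigration-run"
  )
}

#' Load a pipeline configuration file
#'
#' YAML key-value file; unknown keys are rejected with the list of valid
#' keys, missing keys fall back to [default_run_config()], and values are
#' coerced to the type of the default (a type mismatch names the field).
#'
#' @param path configuration file; an empty/absent body yields all
#'   defaults.
#' @return full configuration list.
#' @export
load_config <- function(path) {
  defaults <- default_run_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_invalid("unknown configuration key(s): ",
                 paste(unknown, collapse = ", "),
                 "\nvalid keys: ", paste(names(defaults), collapse = ", "))
  for (k in names(user)) {
    v <- user[[k]]
    d <- defaults[[k]]
    if (is.numeric(d) && !is.numeric(v))
      stop_invalid(sprintf("configuration key `%s` must be numeric", k))
    if (is.character(d) && !is.character(v))
      stop_invalid(sprintf("configuration key `%s` must be a string", k))
    if (is.logical(d) && !is.logical(v))
      stop_invalid(sprintf("configuration key `%s` must be true/false", k))
    if (is.integer(d)) v <- as.integer(v)
    defaults[[k]] <- if (is.numeric(d) && length(d) > 1L)
      as.numeric(unlist(v)) else v
  }
  defaults
}

stage_msg <- function(verbose, ...) if (verbose) message(...)

#' Run the full analysis pipeline
#'
#' Stages in dependency order: phantom synthesis (or image loading),
#' orientation/coherence mapping, white-matter segmentation, cluster
#' detection and coalescing, distance statistics, orientation regression,
#' and migration simulation.  Every table and map is written under
#' `out_dir` and listed, with MD5 content hashes, in `manifest.json`;
#' identical configurations give identical manifests.
#'
#' @param config configuration list from [load_config()] /
#'   [default_run_config()] (partial lists are completed with defaults).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param verbose emit progress messages.
#' @return the manifest, invisibly: list of output files and hashes.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL,
                         verbose = FALSE) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_invalid("unknown configuration key(s): ",
                 paste(unknown, collapse = ", "))
  defaults[names(config)] <- config
  config <- defaults
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)))
    })
  }

  # -- stage: inputs -------------------------------------------------
  phantom <- NULL
  stage_msg(verbose, "stage: inputs")
  if (isTRUE(config$phantom)) {
    phantom <- run_stage("synth", {
      ph <- make_tract_phantom(size = config$size, tract = config$tract,
                               tract_halfwidth_px = config$tract_halfwidth_px,
                               texture_period_px = config$texture_period_px,
                               seed = config$rng_seed,
                               pixel_scale_um = config$pixel_scale_um)
      plant_clusters(ph, n_clusters = config$n_clusters,
                     alignment = config$alignment,
                     center_jitter_px = config$center_jitter_px,
                     sizes = rep(config$cluster_size_px, config$n_clusters),
                     seed = config$rng_seed,
                     chain_size = config$chain_size)
    })
    dii <- phantom$dii_image
    nsc <- phantom$nsc_image
    injection <- phantom$injection_site
    write_phantom(phantom, file.path(out_dir, "phantom"))
  } else {
    dii <- run_stage("inputs", read_image(config$dii_path))
    nsc <- run_stage("clusters", {
      if (!nzchar(config$nsc_path))
        stop("missing NSC image (`nsc_path`)")
      read_image(config$nsc_path)
    })
    injection <- c(x = config$injection_x, y = config$injection_y)
    if (anyNA(injection))
      stop_invalid("pipeline stage `inputs` failed: injection_x/injection_y required")
  }

  # -- stage: orientation -------------------------------------------
  stage_msg(verbose, "stage: orientation")
  field <- run_stage("orientation",
                     orientation_field(dii, config$map_sigma,
                                       config$gradient_method))
  write_matrix_csv(round(field$theta, 4), file.path(out_dir, "theta_map.csv"),
                   sprintf("tissue orientation theta (degrees, axial [0,180)), window sigma %g px",
                           config$map_sigma))
  write_matrix_csv(round(field$coherence, 6),
                   file.path(out_dir, "coherence_map.csv"),
                   sprintf("coherence (dimensionless, [0,1]), window sigma %g px",
                           config$map_sigma))

  # -- stage: masks --------------------------------------------------
  stage_msg(verbose, "stage: masks")
  masks <- run_stage("masks",
                     wm_mask_from_dii(dii, threshold = config$threshold,
                                      pixel_scale_um = config$pixel_scale_um))

  # -- stage: clusters ----------------------------------------------
  stage_msg(verbose, "stage: clusters")
  res <- run_stage("clusters", {
    clusters <- detect_clusters(nsc, threshold = config$threshold,
                                min_size_px = config$min_size_px)
    if (!nrow(clusters)) stop("no clusters detected")
    clusters <- classify_clusters(clusters, masks)
    inj_d <- sqrt((clusters$x - injection[1L])^2 +
                    (clusters$y - injection[2L])^2)
    near <- inj_d <= config$exclusion_radius_px
    ext <- extract_cluster_orientations(clusters[!near, ],
                                        dim(nsc),
                                        dilate_px = config$dilate_px,
                                        erode_px = config$erode_px,
                                        circularity_max = config$circularity_max)
    list(clusters = ext$clusters, regions = ext$regions,
         n_near_injection = sum(near))
  })
  clusters <- res$clusters
  out <- as.data.frame(clusters)
  out$x <- out$x - 1; out$y <- out$y - 1  # 0-based in files
  utils::write.csv(out, file.path(out_dir, "clusters.csv"),
                   row.names = FALSE)

  # -- stage: distances ---------------------------------------------
  stage_msg(verbose, "stage: distances")
  dist_summary <- run_stage("distances", {
    dinj <- distances_from_injection(clusters, injection,
                                     exclusion_radius_px = config$exclusion_radius_px,
                                     pixel_scale_um = config$pixel_scale_um,
                                     image_shape = dim(dii))
    keep <- !dinj$excluded
    if (!any(keep)) stop("all clusters inside the exclusion radius")
    cpd_inj <- weighted_cpd(dinj$distance_um[keep], clusters$size[keep])
    diface <- interface_distances(clusters, masks,
                                  pixel_scale_um = config$pixel_scale_um)
    cpd_iface <- weighted_cpd(diface, clusters$size)
    frac <- wm_fraction(clusters)
    write_matrix_csv(cbind(cpd_inj$distances_um, cpd_inj$cum_prob),
                     file.path(out_dir, "cpd_injection.csv"),
                     c("columns: distance_um, cum_prob",
                       "weighted CPD of cluster distance from injection site"))
    write_matrix_csv(cbind(cpd_iface$distances_um, cpd_iface$cum_prob),
                     file.path(out_dir, "cpd_interface.csv"),
                     c("columns: distance_um, cum_prob",
                       "weighted CPD of cluster distance to WM/GM interface"))
    list(median_injection_um = cpd_inj$median_um,
         median_interface_um = cpd_iface$median_um,
         wm_percent = frac$wm_percent,
         gm_percent = frac$gm_percent,
         n_clusters = nrow(clusters),
         n_excluded_injection = sum(dinj$excluded) + res$n_near_injection)
  })
  jsonlite::write_json(dist_summary, file.path(out_dir, "distances.json"),
                       digits = NA, auto_unbox = TRUE)

  # -- stage: correlate ---------------------------------------------
  stage_msg(verbose, "stage: correlate")
  reg <- run_stage("correlate",
                   correlate_by_tissue(clusters, res$regions, field, masks,
                                       radius_px = config$wm_radius_px,
                                       coherence_min = config$coherence_min))
  utils::write.csv(reg$scatter, file.path(out_dir, "orientation_pairs.csv"),
                   row.names = FALSE)
  reg_json <- lapply(reg[c("all", "wm", "gm")], function(r) {
    if (is.null(r)) return(NULL)
    list(slope = r$slope, intercept_deg = r$intercept,
         r_squared = r$r_squared, n = r$n_points)
  })
  jsonlite::write_json(reg_json, file.path(out_dir, "regression.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")

  # -- stage: simulate ----------------------------------------------
  stage_msg(verbose, "stage: simulate")
  sim <- run_stage("simulate", {
    sfield <- orientation_field(dii, config$sim_sigma,
                                config$gradient_method)
    scfg <- sim_config(n_paths = config$n_paths,
                       seed_center = injection,
                       seed_radius_px = config$seed_radius_px,
                       step_px = config$step_px,
                       max_steps = config$max_steps,
                       wm_kernel_sigma_px = config$sim_sigma,
                       rng_seed = config$rng_seed)
    paths <- simulate_paths(sfield, masks, scfg)
    stats <- path_statistics(paths, config$pixel_scale_um)
    tab <- do.call(rbind, lapply(seq_along(paths), function(i) {
      pts <- paths[[i]]$points
      cbind(i, seq_len(nrow(pts)) - 1L, round(pts[, 1L] - 1, 3),
            round(pts[, 2L] - 1, 3))
    }))
    write_matrix_csv(tab, file.path(out_dir, "paths.csv"),
                     "columns: path_id, step, x_px, y_px")
    list(n_paths = length(paths),
         mean_net_displacement_um = stats$mean_net_displacement_um,
         mean_path_length_um = stats$mean_path_length_um,
         pct_steps_in_wm = stats$pct_steps_in_wm,
         termination_counts = as.list(stats$termination_counts))
  })
  jsonlite::write_json(sim, file.path(out_dir, "simulation.json"),
                       digits = NA, auto_unbox = TRUE)

  # -- manifest ------------------------------------------------------
  files <- c("theta_map.csv", "coherence_map.csv", "clusters.csv",
             "cpd_injection.csv", "cpd_interface.csv", "distances.json",
             "orientation_pairs.csv", "regression.json", "paths.csv",
             "simulation.json")
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    config = config[order(names(config))],
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
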
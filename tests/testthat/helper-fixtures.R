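# Shared fixture builders (everything is generated in code at test time).

# A hand-built orientation field with uniform angle/coherence.
uniform_field <- function(n, m, theta_deg, coherence = 1,
                          valid = TRUE, sigma = 5) {
  structure(list(lambda_max = matrix(1, n, m),
                 lambda_min = matrix(1 - coherence, n, m) /
                   (1 + coherence),
                 theta = matrix(theta_deg, n, m),
                 coherence = matrix(coherence, n, m),
                 valid = matrix(valid, n, m),
                 window_sigma_px = sigma),
            class = "orientation_field")
}

all_wm_masks <- function(n, m, scale = 1.444)
  tissue_masks(wm = matrix(TRUE, n, m), gm = matrix(FALSE, n, m),
               pixel_scale_um = scale)

all_gm_masks <- function(n, m, scale = 1.444)
  tissue_masks(wm = matrix(FALSE, n, m), gm = matrix(TRUE, n, m),
               pixel_scale_um = scale)

# The validation phantom used for orientation-regression parameter
# recovery: a wide, gently curved tract (tangent range about +/-18
# degrees) carrying 20 chains of 4 clusters, so that the null
# distribution of r^2 (~1/(chains - 1)) sits well below the 0.1 bound.
validation_regression_run <- function(seed, alignment) {
  width <- 2000L
  x0 <- width / 2
  a <- 0.00016
  coefs <- c(60 + a * x0^2, -2 * a * x0, a)
  ph <- make_tract_phantom(size = c(256L, width), tract = coefs,
                           tract_halfwidth_px = 28, seed = seed)
  ph <- plant_clusters(ph, n_clusters = 80L, alignment = alignment,
                       center_jitter_px = 4, seed = seed + 1000L,
                       chain_size = 4L)
  cl <- classify_clusters(detect_clusters(ph$nsc_image), ph$masks)
  ext <- extract_cluster_orientations(cl, dim(ph$nsc_image),
                                      dilate_px = 16, erode_px = 8)
  f <- orientation_field(ph$dii_image, 1)
  reg <- correlate_by_tissue(ext$clusters, ext$regions, f, ph$masks,
                             radius_px = 12)
  list(phantom = ph, clusters = ext$clusters, regions = ext$regions,
       field = f, regression = reg)
}
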
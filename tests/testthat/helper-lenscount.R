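# shared fixtures: all synthetic, generated at test time

# paper-geometry lens scaled down by radius; cell numbers scale with area so
# local densities (and hence detection difficulty) match the full-size lens
small_params <- function(seed = 1, lens_radius = 300, ...) {
  sc <- (lens_radius / 1250)^2
  lens_sim_params(lens_radius = lens_radius,
                  n_epithelial = round(44000 * sc),
                  n_meridional = round(8000 * sc),
                  n_fiber = round(3000 * sc),
                  seed = seed, ...)
}

# the four projections the counting pipeline consumes (fast path; depth
# filter stands in for the shell mask)
render_views <- function(gt, view_azimuth = 0, mask_depth = 15) {
  list(anterior_dna = render_projection(gt, "anterior", "dna",
                                        mask_depth = mask_depth),
       anterior_edu = render_projection(gt, "anterior", "edu",
                                        mask_depth = mask_depth),
       equatorial_dna = render_projection(gt, "equatorial", "dna",
                                          view_azimuth, mask_depth = mask_depth),
       equatorial_edu = render_projection(gt, "equatorial", "edu",
                                          view_azimuth, mask_depth = mask_depth))
}

# nucleus records built from exact projected ground-truth positions,
# bypassing rendering and detection (for oracle-equivalence tests)
exact_records <- function(gt, aspect, view_azimuth = 0, channel = "dna") {
  nuc <- gt$nuclei[gt$nuclei$class == "epithelial", , drop = FALSE]
  if (channel == "edu") nuc <- nuc[nuc$edu, , drop = FALSE]
  r <- gt$params$lens_radius - nuc$depth
  if (aspect == "anterior") {
    vis <- nuc$colatitude <= pi / 2
    pp <- polar_project(nuc$colatitude[vis], nuc$azimuth[vis], r[vis])
  } else {
    vis <- sin(nuc$colatitude) * cos(nuc$azimuth - view_azimuth) >= 0
    pp <- equatorial_project(nuc$colatitude[vis], nuc$azimuth[vis], r[vis],
                             view_azimuth, check = FALSE)
  }
  rec <- data.frame(id = nuc$id[vis], x = pp$x, y = pp$y,
                    area = pi * 16, equivalent_diameter = 8,
                    mean_intensity = 1000, channel = channel)
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

# render a sparse field of Gaussian blobs at given positions (um) into a
# projection image, without any lens geometry
blob_image <- function(x, y, field = 600, pixel_size = 2.25, fwhm = 8,
                       amp = 1000, noise_sd = 0, seed = 1) {
  n <- 2 * floor(field / (2 * pixel_size)) + 1
  x0 <- -(n - 1) / 2 * pixel_size
  y0 <- (n - 1) / 2 * pixel_size
  cj <- (x - x0) / pixel_size + 1
  ci <- (y0 - y) / pixel_size + 1
  img <- lenscount:::cpp_render_blobs_2d(n, n, ci, cj,
                                         rep(amp, length(x)),
                                         fwhm / 2.355 / pixel_size, 3.5, TRUE)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- matrix(pmax(img + rnorm(length(img), 0, noise_sd), 0), n)
  }
  lens_projection(img, pixel_size)
}

# hard-core planar point set with minimum separation dmin inside a square
hardcore_points_2d <- function(n, dmin, half_width, seed = 1) {
  set.seed(seed)
  cand <- cbind(runif(20 * n, -half_width, half_width),
                runif(20 * n, -half_width, half_width), 0)
  keep <- lenscount:::cpp_hardcore_thin(cand, dmin, as.integer(n), 0L)
  stopifnot(length(keep) >= n)
  cand[keep[seq_len(n)], 1:2, drop = FALSE]
}
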
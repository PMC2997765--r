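#' Parameters of the synthetic lens simulator
#'
#' Assembles and validates the parameter set describing a simulated mouse
#' lens epithelium. Defaults describe an 8-week-old mouse lens: a sphere of
#' 2.5 mm equatorial diameter carrying ~44,000 epithelial nuclei whose
#' surface density increases linearly in colatitude from the anterior pole
#' to the epithelial margin (located just past the equator), an EdU-positive
#' subset concentrated in a pre-equatorial germinative zone, meridional-row
#' nuclei in regular columns beyond the margin, and fiber-cell nuclei below
#' the surface near the equator.
#'
#' @param lens_radius sphere radius, micrometres.
#' @param n_epithelial number of epithelial nuclei.
#' @param margin_colatitude colatitude of the epithelium / meridional-row
#'   border, radians (default 95 degrees).
#' @param density_gradient ratio of surface density at the margin to density
#'   at the pole (linear-in-colatitude profile).
#' @param germinative_zone length-2 vector of colatitudes (radians) bounding
#'   the high-proliferation zone.
#' @param edu_fraction_gz,edu_fraction_central probability that a nucleus is
#'   EdU-positive inside / outside the germinative zone.
#' @param n_meridional,n_fiber numbers of meridional-row and fiber nuclei.
#' @param meridional_extent colatitude extent of the meridional rows beyond
#'   the margin, radians.
#' @param meridional_column_spacing circumferential spacing of meridional
#'   columns, micrometres.
#' @param fiber_depth minimum depth of fiber nuclei below the surface, um.
#' @param fiber_depth_range additional (uniform) depth spread of fiber
#'   nuclei, um.
#' @param fiber_zone length-2 colatitude band occupied by fiber nuclei.
#' @param nucleus_diameter nucleus diameter = rendered blob FWHM, um.
#' @param min_separation hard-core minimum distance between nucleus centers,
#'   um. Nuclei are impenetrable; default one nucleus diameter.
#' @param voxel_size lateral voxel size, um (2.25 um matches a 1.15 mm field
#'   imaged over 512 pixels with a 10x objective).
#' @param z_step axial slice spacing, um.
#' @param axial_fwhm axial FWHM of the confocal point-spread function, um
#'   (~25 um for a 10x / 0.45 NA lens).
#' @param field_width lateral field of view, um; default covers the lens.
#' @param amp_dna,amp_edu peak blob intensity per channel, arbitrary units.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param seed integer seed; every stochastic step derives from it.
#' @return a validated list of class `lens_sim_params`.
#' @export
lens_sim_params <- function(lens_radius = 1250,
                            n_epithelial = 44000,
                            margin_colatitude = deg2rad(95),
                            density_gradient = 4,
                            germinative_zone = deg2rad(c(75, 95)),
                            edu_fraction_gz = 0.08,
                            edu_fraction_central = 0.002,
                            n_meridional = 8000,
                            n_fiber = 3000,
                            meridional_extent = deg2rad(6),
                            meridional_column_spacing = 10,
                            fiber_depth = 30,
                            fiber_depth_range = 50,
                            fiber_zone = deg2rad(c(70, 105)),
                            nucleus_diameter = 8,
                            min_separation = nucleus_diameter,
                            voxel_size = 2.25,
                            z_step = 12.5,
                            axial_fwhm = 25,
                            field_width = NULL,
                            amp_dna = 1000,
                            amp_edu = 1500,
                            noise_sd = 20,
                            seed = 1L) {
  p <- as.list(environment())
  if (is.null(p$field_width))
    p$field_width <- 2 * (lens_radius + 2 * nucleus_diameter)
  with(p, {
    stopifnot(lens_radius > 0, n_epithelial >= 0, n_meridional >= 0,
              n_fiber >= 0, nucleus_diameter > 0, voxel_size > 0,
              z_step > 0, noise_sd >= 0, density_gradient > 0,
              min_separation >= 0)
    if (margin_colatitude <= 0 || margin_colatitude > pi)
      stop("margin_colatitude must lie in (0, pi]")
    if (edu_fraction_gz < 0 || edu_fraction_gz > 1 ||
        edu_fraction_central < 0 || edu_fraction_central > 1)
      stop("EdU fractions must lie in [0, 1]")
    if (length(germinative_zone) != 2 || germinative_zone[1] >= germinative_zone[2])
      stop("germinative_zone must be an increasing colatitude interval")
    if (germinative_zone[1] < 0 || germinative_zone[2] > margin_colatitude + 1e-9)
      stop("germinative zone must lie within [0, margin_colatitude]")
  })
  class(p) <- "lens_sim_params"
  p
}

# derive a child seed from the master seed, kept within 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# draw colatitudes from pdf ~ (1 + (g - 1) * theta / theta_m) * sin(theta)
# on [0, theta_m], by rejection from the uniform-on-cap proposal
sample_colatitude <- function(n, theta_m, g) {
  out <- numeric(0)
  rho_max <- max(1, g)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 1.3 * rho_max / min(1, (1 + g) / 2) + 16)
    th <- acos(runif(m, cos(theta_m), 1))
    rho <- 1 + (g - 1) * th / theta_m
    out <- c(out, th[runif(m) < rho / rho_max])
  }
  out[seq_len(n)]
}

sph_to_cart <- function(colat, az, r) {
  cbind(r * sin(colat) * cos(az), r * sin(colat) * sin(az), r * cos(colat))
}

# hard-core rejection: grow the accepted set until n points are at pairwise
# distance >= dmin, proposing from `propose(m)` (matrix with colat, az, depth)
hardcore_sample <- function(n, propose, lens_radius, dmin, max_attempts) {
  acc <- NULL
  attempts <- 0
  while (is.null(acc) || nrow(acc) < n) {
    need <- n - if (is.null(acc)) 0 else nrow(acc)
    m <- ceiling(need * 1.6) + 8
    attempts <- attempts + m
    if (attempts > max_attempts)
      stop("could not place ", n, " nuclei at min_separation = ", dmin,
           " um: the requested density is too close to jamming")
    cand <- propose(m)
    all_sph <- rbind(acc, cand)
    pts <- sph_to_cart(all_sph[, 1], all_sph[, 2],
                       lens_radius - all_sph[, 3])
    keep <- cpp_hardcore_thin(pts, dmin, as.integer(n),
                              if (is.null(acc)) 0L else nrow(acc))
    acc <- all_sph[keep, , drop = FALSE]
  }
  acc[seq_len(n), , drop = FALSE]
}

#' Sample a ground-truthed synthetic lens epithelium
#'
#' Draws exactly `n_epithelial` epithelial nuclei on the spherical surface
#' with azimuth uniform and colatitude following a linear-in-colatitude
#' surface-density profile (pole : margin = 1 : `density_gradient`),
#' weighted by the `sin(colatitude)` area element; assigns EdU status with
#' zone-dependent Bernoulli probability; and places meridional-row nuclei in
#' regular columns beyond the margin and fiber nuclei beneath the surface at
#' the equator. Nucleus centers respect a hard-core minimum separation.
#' Fully reproducible from `params$seed`.
#'
#' @param params a [lens_sim_params()] object.
#' @return object of class `ground_truth`: list with `nuclei` (data frame:
#'   `id`, `class`, `colatitude`, `azimuth`, `depth`, `edu`) and `params`.
#' @export
sample_epithelium <- function(params) {
  stopifnot(inherits(params, "lens_sim_params"))
  p <- params
  set.seed(derive_seed(p$seed, 1L))

  # --- epithelial nuclei -------------------------------------------------
  propose_epi <- function(m) {
    cbind(sample_colatitude(m, p$margin_colatitude, p$density_gradient),
          runif(m, 0, 2 * pi), 0)
  }
  epi <- if (p$n_epithelial > 0) {
    if (p$min_separation > 0)
      hardcore_sample(p$n_epithelial, propose_epi, p$lens_radius,
                      p$min_separation, max_attempts = 80 * p$n_epithelial + 1e4)
    else propose_epi(p$n_epithelial)[seq_len(p$n_epithelial), , drop = FALSE]
  } else matrix(numeric(0), 0, 3)

  in_gz <- epi[, 1] >= p$germinative_zone[1] & epi[, 1] <= p$germinative_zone[2]
  prob <- ifelse(in_gz, p$edu_fraction_gz, p$edu_fraction_central)
  edu <- runif(nrow(epi)) < prob

  # --- meridional rows: regular columns just beyond the margin -----------
  mer <- matrix(numeric(0), 0, 3)
  if (p$n_meridional > 0) {
    mid <- p$margin_colatitude + p$meridional_extent / 2
    n_col <- max(1, round(2 * pi * p$lens_radius * sin(mid) /
                            p$meridional_column_spacing))
    per <- rep(floor(p$n_meridional / n_col), n_col)
    extra <- p$n_meridional - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
    col_az <- (seq_len(n_col) - 1) * 2 * pi / n_col
    colat <- unlist(lapply(per, function(k) {
      if (k == 0) return(numeric(0))
      p$margin_colatitude + (seq_len(k) - 0.5) / k * p$meridional_extent
    }))
    az <- rep(col_az, per) + rnorm(p$n_meridional, 0, 0.3 / p$lens_radius)
    mer <- cbind(colat, az %% (2 * pi), 0)
  }

  # --- fiber nuclei below the surface near the equator -------------------
  fib <- matrix(numeric(0), 0, 3)
  if (p$n_fiber > 0) {
    fib <- cbind(runif(p$n_fiber, p$fiber_zone[1], p$fiber_zone[2]),
                 runif(p$n_fiber, 0, 2 * pi),
                 runif(p$n_fiber, p$fiber_depth,
                       p$fiber_depth + p$fiber_depth_range))
  }

  nuclei <- data.frame(
    id = seq_len(nrow(epi) + nrow(mer) + nrow(fib)),
    class = rep(c("epithelial", "meridional", "fiber"),
                c(nrow(epi), nrow(mer), nrow(fib))),
    colatitude = c(epi[, 1], mer[, 1], fib[, 1]),
    azimuth = c(epi[, 2], mer[, 2], fib[, 2]) %% (2 * pi),
    depth = c(epi[, 3], mer[, 3], fib[, 3]),
    edu = c(edu, rep(FALSE, nrow(mer) + nrow(fib))),
    stringsAsFactors = FALSE
  )
  structure(list(nuclei = nuclei, params = p), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(x$nuclei$class)
  cat("Synthetic lens ground truth:",
      sprintf("%d nuclei (%s); %d EdU-positive; lens radius %.0f um\n",
              nrow(x$nuclei),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              sum(x$nuclei$edu), x$params$lens_radius))
  invisible(x)
}

#' Brute-force ground-truth count of epithelial nuclei in a region
#'
#' Counts the epithelial nuclei of a [sample_epithelium()] ground truth
#' whose exact projected position lies in a counting region. This is the
#' oracle against which the detection/counting pipeline is judged.
#'
#' @param gt a `ground_truth` object.
#' @param region an [anterior_sector()] (anterior view) or
#'   [equatorial_trapezoid()] (equatorial view).
#' @param view_azimuth viewing azimuth of the equatorial aspect, radians.
#' @return integer count.
#' @export
true_count_in_region <- function(gt, region, view_azimuth = 0) {
  nuc <- gt$nuclei[gt$nuclei$class == "epithelial", , drop = FALSE]
  if (nrow(nuc) == 0) return(0L)
  r <- gt$params$lens_radius - nuc$depth
  if (inherits(region, "anterior_sector")) {
    vis <- nuc$colatitude <= pi / 2
    pp <- polar_project(nuc$colatitude[vis], nuc$azimuth[vis], r[vis])
    sum(point_in_sector(pp$x, pp$y, region))
  } else if (inherits(region, "equatorial_trapezoid")) {
    vis <- sin(nuc$colatitude) * cos(nuc$azimuth - view_azimuth) >= 0
    pp <- equatorial_project(nuc$colatitude[vis], nuc$azimuth[vis], r[vis],
                             view_azimuth, check = FALSE)
    sum(point_in_trapezoid(pp$x, pp$y, region))
  } else stop("unknown region type")
}

#' Write / read ground truth as CSV (angles in degrees)
#'
#' @param gt a `ground_truth` object.
#' @param path CSV file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the nuclei data frame (radians).
#' @export
write_ground_truth <- function(gt, path) {
  df <- gt$nuclei
  out <- data.frame(id = df$id, class = df$class,
                    colatitude_deg = rad2deg(df$colatitude),
                    azimuth_deg = rad2deg(df$azimuth),
                    depth_um = df$depth, edu = as.integer(df$edu))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(id = out$id, class = out$class,
             colatitude = deg2rad(out$colatitude_deg),
             azimuth = deg2rad(out$azimuth_deg),
             depth = out$depth_um, edu = out$edu == 1,
             stringsAsFactors = FALSE)
}
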
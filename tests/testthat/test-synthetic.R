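test_that("sampling is exact in count, seeded, and class-conserving", {
  p <- lens_sim_params(n_epithelial = 1000, n_meridional = 200, n_fiber = 100,
                       seed = 7)
  gt1 <- sample_epithelium(p)
  gt2 <- sample_epithelium(p)
  expect_identical(gt1$nuclei, gt2$nuclei)
  expect_equal(unname(table(gt1$nuclei$class)[c("epithelial", "meridional", "fiber")]),
               c(1000, 200, 100), ignore_attr = TRUE)
  expect_true(all(gt1$nuclei$colatitude[gt1$nuclei$class == "epithelial"] <=
                    p$margin_colatitude))
  mer <- gt1$nuclei[gt1$nuclei$class == "meridional", ]
  expect_true(all(mer$colatitude > p$margin_colatitude))
  fib <- gt1$nuclei[gt1$nuclei$class == "fiber", ]
  expect_true(all(fib$depth >= p$fiber_depth))
  # different seed, different draw
  gt3 <- sample_epithelium(lens_sim_params(n_epithelial = 1000,
                                           n_meridional = 200, n_fiber = 100,
                                           seed = 8))
  expect_false(identical(gt1$nuclei, gt3$nuclei))
})

test_that("hard-core separation holds between epithelial nucleus centers", {
  p <- lens_sim_params(n_epithelial = 3000, n_meridional = 0, n_fiber = 0,
                       seed = 3)
  gt <- sample_epithelium(p)
  nuc <- gt$nuclei
  P <- cbind(p$lens_radius * sin(nuc$colatitude) * cos(nuc$azimuth),
             p$lens_radius * sin(nuc$colatitude) * sin(nuc$azimuth),
             p$lens_radius * cos(nuc$colatitude))
  d <- as.matrix(dist(P[sample.int(nrow(P), 600), ]))
  diag(d) <- Inf
  expect_gte(min(d), p$min_separation - 1e-9)
})

test_that("flat gradient matches uniform-on-cap sampling (KS, alpha = 0.01)", {
  p <- lens_sim_params(n_epithelial = 10000, n_meridional = 0, n_fiber = 0,
                       density_gradient = 1, min_separation = 0, seed = 5)
  gt <- sample_epithelium(p)
  set.seed(99)
  ref <- acos(runif(10000, cos(p$margin_colatitude), 1))
  ks <- suppressWarnings(stats::ks.test(gt$nuclei$colatitude, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("surface density is non-decreasing pole to margin", {
  p <- lens_sim_params(n_epithelial = 25000, n_meridional = 0, n_fiber = 0,
                       seed = 2)
  gt <- sample_epithelium(p)
  br <- seq(0, p$margin_colatitude, length.out = 11)
  counts <- table(cut(gt$nuclei$colatitude, br))
  area <- diff(-cos(br))  # spherical band areas (up to 2*pi*R^2)
  dens <- as.numeric(counts) / area
  expect_lte(sum(diff(dens) < 0), 1)  # allow one inversion from noise
})

test_that("EdU labeling follows the zone probabilities (binomial bound)", {
  p <- lens_sim_params(n_epithelial = 30000, n_meridional = 0, n_fiber = 0,
                       seed = 4)
  gt <- sample_epithelium(p)
  gz <- gt$nuclei$colatitude >= p$germinative_zone[1] &
    gt$nuclei$colatitude <= p$germinative_zone[2]
  n <- sum(gz)
  x <- sum(gt$nuclei$edu[gz])
  expect_lt(abs(x - n * p$edu_fraction_gz),
            3 * sqrt(n * p$edu_fraction_gz * (1 - p$edu_fraction_gz)))
  n0 <- sum(!gz)
  x0 <- sum(gt$nuclei$edu[!gz])
  expect_lt(abs(x0 - n0 * p$edu_fraction_central),
            3 * sqrt(n0 * p$edu_fraction_central) + 3)
})

test_that("infeasible parameters error", {
  expect_error(lens_sim_params(germinative_zone = deg2rad(c(80, 110))),
               "germinative zone")
  expect_error(lens_sim_params(edu_fraction_gz = 1.2), "fractions")
  # density too close to jamming for the hard core
  p <- lens_sim_params(lens_radius = 100, n_epithelial = 5000, seed = 1)
  expect_error(sample_epithelium(p), "jamming")
})

test_that("true_count_in_region is an explicit brute force", {
  p <- small_params(seed = 6)
  gt <- sample_epithelium(p)
  empty <- gt
  empty$nuclei <- gt$nuclei[0, ]
  s <- anterior_sector(c(0, 0), c(200, 100), deg2rad(60))
  expect_identical(true_count_in_region(empty, s), 0L)

  # full-disk sector counts every epithelial nucleus on the visible cap
  full <- anterior_sector(c(0, 0), c(p$lens_radius, 0), 2 * pi)
  epi <- gt$nuclei[gt$nuclei$class == "epithelial", ]
  expect_equal(true_count_in_region(gt, full), sum(epi$colatitude <= pi / 2))

  # restatement as per-nucleus membership sum
  pp <- polar_project(epi$colatitude[epi$colatitude <= pi / 2],
                      epi$azimuth[epi$colatitude <= pi / 2],
                      p$lens_radius)
  expect_equal(true_count_in_region(gt, s),
               sum(point_in_sector(pp$x, pp$y, s)))

  tr <- equatorial_trapezoid(p$lens_radius * cos(deg2rad(80)),
                             p$lens_radius * cos(p$margin_colatitude),
                             p$lens_radius, deg2rad(10))
  va <- 0.4
  vis <- sin(epi$colatitude) * cos(epi$azimuth - va) >= 0
  pe <- equatorial_project(epi$colatitude[vis], epi$azimuth[vis],
                           p$lens_radius, va, check = FALSE)
  expect_equal(true_count_in_region(gt, tr, va),
               sum(point_in_trapezoid(pe$x, pe$y, tr)))
})

test_that("rendered stacks put blob peaks at nucleus positions", {
  p <- lens_sim_params(lens_radius = 150, n_epithelial = 2, n_meridional = 0,
                       n_fiber = 0, noise_sd = 0, seed = 9,
                       germinative_zone = deg2rad(c(40, 60)),
                       margin_colatitude = deg2rad(60))
  gt <- sample_epithelium(p)
  # place two nuclei explicitly, 5 diameters apart on the cap
  gt$nuclei$colatitude <- c(0.3, 0.3 + 40 / 150)
  gt$nuclei$azimuth <- c(1, 1)
  st <- render_stack(gt, "anterior", "dna")
  a <- st$intensities
  peak <- which(a == max(a), arr.ind = TRUE)[1, ]
  # expected voxel of nucleus 1 or 2 (both have the same peak value)
  vc <- with(gt$nuclei, data.frame(
    x = 150 * sin(colatitude) * cos(azimuth),
    y = 150 * sin(colatitude) * sin(azimuth),
    z = 150 * cos(colatitude)))
  grid <- stack_grid(p, "anterior")
  exp_j <- (vc$x - grid$x0) / grid$pixel_size + 1
  exp_i <- (grid$y0 - vc$y) / grid$pixel_size + 1
  exp_k <- (grid$z_vals[1] - vc$z) / p$z_step + 1
  hit <- function(peak, k) {
    abs(peak[1] - exp_k[k]) <= 1 && abs(peak[2] - exp_i[k]) <= 1 &&
      abs(peak[3] - exp_j[k]) <= 1
  }
  expect_true(hit(peak, 1) || hit(peak, 2))
  # both centers are local maxima with near-peak intensity
  v1 <- a[round(exp_k[1]), round(exp_i[1]), round(exp_j[1])]
  v2 <- a[round(exp_k[2]), round(exp_i[2]), round(exp_j[2])]
  # worst-case half-voxel offsets laterally and axially give ~0.75 of amp
  expect_gt(v1, 0.7 * p$amp_dna)
  expect_gt(v2, 0.7 * p$amp_dna)

  # zero nuclei, zero noise -> all-zero stack
  gt0 <- gt; gt0$nuclei <- gt$nuclei[0, ]
  expect_equal(max(render_stack(gt0, "anterior", "dna")$intensities), 0)

  # seeded determinism of the renderer (with noise on)
  p2 <- lens_sim_params(lens_radius = 150, n_epithelial = 50,
                        n_meridional = 0, n_fiber = 0, seed = 10,
                        germinative_zone = deg2rad(c(40, 60)),
                        margin_colatitude = deg2rad(60))
  gtd <- sample_epithelium(p2)
  s1 <- render_stack(gtd, "equatorial", "dna")
  s2 <- render_stack(gtd, "equatorial", "dna")
  expect_identical(s1$intensities, s2$intensities)
})

test_that("ground truth CSV round-trips", {
  gt <- sample_epithelium(lens_sim_params(n_epithelial = 200,
                                          n_meridional = 50, n_fiber = 20,
                                          seed = 12))
  f <- tempfile(fileext = ".csv")
  write_ground_truth(gt, f)
  back <- read_ground_truth(f)
  expect_equal(back$colatitude, gt$nuclei$colatitude, tolerance = 1e-9)
  expect_equal(back$edu, gt$nuclei$edu)
  expect_equal(back$class, gt$nuclei$class)
  unlink(f)
})

test_that("direct projection rendering matches the projected 3-D render", {
  # sparse lens: blobs never overlap, so max_project(render_stack) equals
  # render_projection up to the axial sampling of the blob peak
  # margin kept at 75 deg so no nucleus sits at the equatorial-plane edge
  # of the acquisition volume, where the two paths differ by construction
  p <- lens_sim_params(lens_radius = 180, n_epithelial = 40,
                       n_meridional = 0, n_fiber = 0, noise_sd = 0,
                       seed = 14, min_separation = 40,
                       margin_colatitude = deg2rad(75),
                       germinative_zone = deg2rad(c(60, 75)))
  gt <- sample_epithelium(p)
  sig_z <- sqrt((p$nucleus_diameter / 2.355)^2 + (p$axial_fwhm / 2.355)^2)
  atten <- exp(-(p$z_step / 2)^2 / (2 * sig_z^2))
  for (aspect in c("anterior", "equatorial")) {
    st <- render_stack(gt, aspect, "dna", view_azimuth = 0.3)
    fast <- render_projection(gt, aspect, "dna", view_azimuth = 0.3,
                              noise = FALSE)
    slow <- max_project(st)
    expect_equal(dim(fast), dim(slow))
    bright <- fast > 0.5 * p$amp_dna
    ratio <- slow[bright] / fast[bright]
    expect_gt(min(ratio), 0.95 * atten)
    expect_lt(max(ratio), 1.02)
    r1 <- detect_nuclei(fast); r2 <- detect_nuclei(slow)
    expect_equal(nrow(r1), nrow(r2))
  }

  # dense lens: overlapping blobs add in the stack before the projection,
  # so the true MIP dominates the per-blob maximum; the fast path is the
  # conservative surrogate (its detection counts do not exceed the stack's)
  pd <- lens_sim_params(lens_radius = 180, n_epithelial = 900,
                        n_meridional = 130, n_fiber = 60, noise_sd = 0,
                        seed = 15)
  gtd <- sample_epithelium(pd)
  for (aspect in c("anterior", "equatorial")) {
    st <- render_stack(gtd, aspect, "dna", view_azimuth = 0.3)
    fast <- render_projection(gtd, aspect, "dna", view_azimuth = 0.3,
                              noise = FALSE)
    slow <- max_project(st)
    expect_true(all(slow >= fast * atten - 1e-6))
    r1 <- detect_nuclei(fast); r2 <- detect_nuclei(slow)
    expect_lte(nrow(r1), nrow(r2) * 1.02)
    expect_gt(nrow(r1), 0.85 * nrow(r2))
  }
})
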
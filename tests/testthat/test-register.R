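as_records <- function(x, y) {
  rec <- data.frame(id = seq_along(x), x = x, y = y)
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

test_that("an exact 3-point constellation registers with zero residual", {
  R <- 1000
  th <- c(1.35, 1.2, 1.45); az <- c(0.52, 0.64, 0.70)
  va <- 0.6
  a <- polar_project(th, az, R)
  e <- equatorial_project(th, az, R, va)
  m <- match_constellations(as_records(a$x, a$y), as_records(e$x, e$y), R,
                            tolerance = 10)
  expect_equal(m$n_inliers, 3)
  # residual limited by the 0.01 degree refinement grid, not the data
  expect_lt(m$mean_pair_residual, 0.5)
  expect_lt(abs(m$view_azimuth - va), deg2rad(0.05))
  expect_equal(m$mirror, 1)
})

test_that("non-overlapping fields raise a registration failure", {
  R <- 1000
  # anterior points near the pole (high y in the equatorial frame) cannot
  # pair with equatorial points near the margin at any rotation
  a <- polar_project(c(0.2, 0.25, 0.3), c(0, 2, 4), R)
  e <- equatorial_project(c(1.5, 1.52, 1.54), c(0.1, 0.2, 0.3), R, 0)
  expect_error(match_constellations(as_records(a$x, a$y),
                                    as_records(e$x, e$y), R, tolerance = 10),
               "registration failure")
  expect_error(match_constellations(as_records(1, 1), as_records(1:5, 1:5), R),
               "at least 3")
})

test_that("view azimuth is recovered within 1 degree from simulated views", {
  p <- small_params(seed = 71)
  gt <- sample_epithelium(p)
  va <- deg2rad(37)
  ant <- exact_records(gt, "anterior", channel = "edu")
  eq <- exact_records(gt, "equatorial", view_azimuth = va, channel = "edu")
  expect_gte(min(nrow(ant), nrow(eq)), 20)
  m <- match_constellations(ant, eq, p$lens_radius, tolerance = 15)
  expect_lt(abs(m$view_azimuth - va), deg2rad(1))
  expect_equal(m$mirror, 1)
  # every EdU nucleus visible in both views is an inlier
  shared <- sum(gt$nuclei$edu & gt$nuclei$colatitude <= pi / 2 &
                  cos(gt$nuclei$azimuth - va) >= 0)
  expect_gte(m$n_inliers, shared)
})

test_that("registration is invariant to record ordering", {
  p <- small_params(seed = 72)
  gt <- sample_epithelium(p)
  va <- deg2rad(122)
  ant <- exact_records(gt, "anterior", channel = "edu")
  eq <- exact_records(gt, "equatorial", view_azimuth = va, channel = "edu")
  m1 <- match_constellations(ant, eq, p$lens_radius, tolerance = 15)
  set.seed(1)
  m2 <- match_constellations(ant[sample.int(nrow(ant)), ],
                             eq[sample.int(nrow(eq)), ],
                             p$lens_radius, tolerance = 15)
  expect_equal(m1$view_azimuth, m2$view_azimuth)
  expect_equal(m1$n_inliers, m2$n_inliers)
  o1 <- m1$pairs[order(m1$pairs$anterior_id), ]
  o2 <- m2$pairs[order(m2$pairs$anterior_id), ]
  expect_equal(o1$equatorial_id, o2$equatorial_id)
})

test_that("a mirrored equatorial view is detected and matched", {
  p <- small_params(seed = 73)
  gt <- sample_epithelium(p)
  va <- deg2rad(77)
  ant <- exact_records(gt, "anterior", channel = "edu")
  eq <- exact_records(gt, "equatorial", view_azimuth = va, channel = "edu")
  eq$x <- -eq$x  # viewed from the other side
  m <- match_constellations(ant, eq, p$lens_radius, tolerance = 15)
  expect_equal(m$mirror, -1)
  expect_lt(abs(m$view_azimuth - va), deg2rad(1))
})

test_that("fiduciary selection prefers the projection center", {
  R <- 1000
  match <- structure(list(pairs = data.frame(anterior_id = 1:2,
                                             equatorial_id = 1:2,
                                             residual = c(0, 0)),
                          n_inliers = 2), class = "constellation_match")
  ant <- as_records(c(900, 300), c(100, 850))
  eq <- as_records(c(300, 0), c(420, 380))
  f <- select_fiduciary(match, ant, eq, R)
  expect_equal(unname(f$id_pair), c(2L, 2L))  # x = 0 wins
  expect_equal(f$colatitude, acos(380 / R))

  single <- match
  single$pairs <- match$pairs[1, ]
  f1 <- select_fiduciary(single, ant, eq, R)
  expect_equal(unname(f1$id_pair), c(1L, 1L))

  bad <- match; bad$pairs <- match$pairs[0, ]
  expect_error(select_fiduciary(bad, ant, eq, R), "no inlier")
})

test_that("fiduciary colatitude and cross-view consistency hold in simulation", {
  p <- small_params(seed = 74)
  gt <- sample_epithelium(p)
  va <- deg2rad(210)
  ant <- exact_records(gt, "anterior", channel = "edu")
  eq <- exact_records(gt, "equatorial", view_azimuth = va, channel = "edu")
  m <- match_constellations(ant, eq, p$lens_radius, tolerance = 15)
  f <- select_fiduciary(m, ant, eq, p$lens_radius)
  truth <- gt$nuclei[gt$nuclei$id == f$id_pair["equatorial"], ]
  expect_lt(abs(f$colatitude - truth$colatitude), deg2rad(0.5))
  # r^2 + y^2 = R^2 across the two views (exact records, exact geometry)
  r2 <- sum(f$anterior_position^2)
  y2 <- f$equatorial_position[2]^2
  expect_lt(abs(sqrt(r2 + y2) - p$lens_radius), 1)
})

test_that("match report serializes to JSON", {
  p <- small_params(seed = 75)
  gt <- sample_epithelium(p)
  ant <- exact_records(gt, "anterior", channel = "edu")
  eq <- exact_records(gt, "equatorial", view_azimuth = 1, channel = "edu")
  m <- match_constellations(ant, eq, p$lens_radius, tolerance = 15)
  f <- select_fiduciary(m, ant, eq, p$lens_radius)
  js <- jsonlite::fromJSON(as.character(match_to_json(m, f)))
  expect_equal(js$n_inliers, m$n_inliers)
  expect_equal(deg2rad(js$view_azimuth_deg), m$view_azimuth, tolerance = 1e-9)
  expect_equal(js$fiduciary$colatitude_deg, rad2deg(f$colatitude))
})
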
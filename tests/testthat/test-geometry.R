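test_that("polar projection maps pole, equator and mid-latitudes correctly", {
  expect_equal(unlist(polar_project(0, 1.3, 1250)), c(x = 0, y = 0))
  expect_equal(unlist(polar_project(pi / 2, 0, 1250)), c(x = 1250, y = 0))
  p <- polar_project(pi / 6, pi / 2, 1000)
  expect_equal(p$x, 0, tolerance = 1e-9)
  expect_equal(p$y, 500)
  expect_error(polar_project(pi / 2 + 0.01, 0, 1000), "not visible")
  expect_error(polar_project(-0.1, 0, 1000), "colatitude")
})

test_that("polar projection preserves azimuth and is monotone in colatitude", {
  set.seed(11)
  th <- runif(200, 0, pi / 2)
  az <- runif(200, 0, 2 * pi)
  p <- polar_project(th, az, 1250)
  expect_equal(atan2(p$y, p$x) %% (2 * pi), az, tolerance = 1e-9)
  o <- order(th)
  expect_true(all(diff(sqrt(p$x^2 + p$y^2)[o]) >= 0))
})

test_that("equatorial projection has parallel latitude lines", {
  expect_equal(unlist(equatorial_project(pi / 2, 0.7, 1000, 0.7)),
               c(x = 0, y = 0), tolerance = 1e-9)
  expect_equal(unlist(equatorial_project(0, 2.2, 1000, 0)),
               c(x = 0, y = 1000))
  p <- equatorial_project(pi / 3, pi / 6, 1000, 0)
  expect_equal(p$x, 1000 * sin(pi / 3) * sin(pi / 6))  # 433.0
  expect_equal(p$y, 500)
  # vertical coordinate depends only on latitude
  az <- seq(-1.2, 1.2, length.out = 40)
  p <- equatorial_project(pi / 4, az, 900, 0)
  expect_equal(p$y, rep(900 * cos(pi / 4), 40))
  expect_error(equatorial_project(pi / 2, pi, 1000, 0), "back hemisphere")
})

test_that("polar projection inverts to 1e-9 rad over the visible cap", {
  set.seed(21)
  th <- runif(500, 0, pi / 2 - 1e-6)
  az <- runif(500, 0, 2 * pi)
  p <- polar_project(th, az, 1250)
  inv <- invert_polar(p$x, p$y, 1250)
  expect_equal(inv$colatitude, th, tolerance = 1e-9)
  expect_equal(inv$azimuth, az, tolerance = 1e-9)
})

test_that("circle fit recovers exact and noisy circles", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  f <- fit_circle(1250 * cos(th) + 40, 1250 * sin(th) - 60)
  expect_equal(f$diameter, 2500, tolerance = 1e-9)
  expect_equal(unname(f$center), c(40, -60), tolerance = 1e-7)
  expect_equal(f$rms_residual, 0, tolerance = 1e-8)

  # three points: compare against the independent circumcircle construction
  P <- matrix(c(3, 1, -2, 4, 0, -5), 3, 2, byrow = TRUE)
  ax <- P[1, 1]; ay <- P[1, 2]; bx <- P[2, 1]; by <- P[2, 2]
  cx <- P[3, 1]; cy <- P[3, 2]
  D <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / D
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / D
  f3 <- fit_circle(P[, 1], P[, 2])
  expect_equal(unname(f3$center), c(ux, uy), tolerance = 1e-7)
  expect_equal(f3$diameter / 2, sqrt((ax - ux)^2 + (ay - uy)^2),
               tolerance = 1e-7)

  # Gaussian radial noise: Monte Carlo over seeds, error within 3*sigma/sqrt(n)
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 400
    th <- runif(n, 0, 2 * pi)
    r <- 1250 + rnorm(n, 0, 5)
    f <- fit_circle(r * cos(th), r * sin(th))
    expect_lt(abs(f$diameter - 2500), 2 * 3 * 5 / sqrt(n))
  }

  expect_error(fit_circle(1:5, 2 * (1:5) + 1), "collinear")
  expect_error(fit_circle(1, 2), "at least 3")
})

test_that("anterior sector construction follows the fiduciary", {
  s <- anterior_sector(c(0, 0), c(1000, 0), pi / 3)
  expect_equal(s$sector_radius, 1000)
  s2 <- anterior_sector(c(0, 0), c(600, 800), pi / 3)
  expect_equal(s2$sector_radius, 1000)  # 3-4-5 triangle
  full <- anterior_sector(c(0, 0), c(500, 0), 2 * pi)
  set.seed(5)
  x <- runif(500, -500, 500); y <- runif(500, -500, 500)
  expect_equal(point_in_sector(x, y, full), sqrt(x^2 + y^2) <= 500)
  expect_error(anterior_sector(c(1, 1), c(1, 1)), "degenerate")
  expect_error(anterior_sector(c(0, 0), c(1, 0), central_angle = 0), "central_angle")
})

test_that("sector membership is closed and matches a brute-force oracle", {
  s <- anterior_sector(c(50, -20), c(850, 380), pi / 3)
  expect_true(point_in_sector(s$center[1], s$center[2], s))
  # fiduciary lies on the arc at one angular edge (closed boundary)
  expect_true(point_in_sector(850, 380, s))
  # point at distance sector_radius on the bisector
  b <- s$center + s$sector_radius * c(cos(s$orientation), sin(s$orientation))
  expect_true(point_in_sector(b[1], b[2], s))

  set.seed(7)
  x <- runif(1000, -1100, 1100); y <- runif(1000, -1100, 1100)
  # independent polar-coordinate check
  dx <- x - s$center[1]; dy <- y - s$center[2]
  r <- sqrt(dx^2 + dy^2)
  a <- atan2(dy, dx)
  lo <- s$orientation - s$central_angle / 2
  off <- (a - lo) %% (2 * pi)
  oracle <- r <= s$sector_radius & off <= s$central_angle
  expect_equal(point_in_sector(x, y, s), oracle)
})

test_that("equatorial trapezoid has the chord side lengths and closed membership", {
  t <- equatorial_trapezoid(500, 0, 1000, deg2rad(10))
  expect_equal(t$b, 2 * 1000 * sin(deg2rad(5)), tolerance = 1e-12)  # 174.3 um
  expect_equal(t$a, 2 * sqrt(1000^2 - 500^2) * sin(deg2rad(5)))
  expect_error(equatorial_trapezoid(300, 300, 1000), "degenerate")
  expect_error(equatorial_trapezoid(2000, 0, 1000), "outside the lens")
  expect_error(equatorial_trapezoid(-100, 100, 1000), "anterior of")

  tr <- equatorial_trapezoid(217.5, -108.9, 1250, deg2rad(10))
  # centroid inside; top side on the closed boundary
  expect_true(point_in_trapezoid(0, (tr$top_y + tr$base_y) / 2, tr))
  expect_true(point_in_trapezoid(tr$a / 2, tr$top_y, tr))
  # brute-force half-plane intersection oracle
  v <- rbind(c(-tr$a / 2, tr$top_y), c(tr$a / 2, tr$top_y),
             c(tr$b / 2, tr$base_y), c(-tr$b / 2, tr$base_y))
  set.seed(13)
  x <- runif(1000, -200, 200); y <- runif(1000, -200, 300)
  inside <- rep(TRUE, 1000)
  for (k in 1:4) {
    p1 <- v[k, ]; p2 <- v[k %% 4 + 1, ]
    cross <- (p2[1] - p1[1]) * (y - p1[2]) - (p2[2] - p1[2]) * (x - p1[1])
    inside <- inside & cross <= 1e-9  # vertices are clockwise
  }
  expect_equal(point_in_trapezoid(x, y, tr), inside)
})

test_that("region specs survive a JSON round trip", {
  s <- anterior_sector(c(12.5, -3), c(900, 450), deg2rad(60))
  s2 <- region_from_json(as.character(region_to_json(s)))
  expect_equal(s2$sector_radius, s$sector_radius, tolerance = 1e-9)
  expect_equal(s2$orientation, s$orientation, tolerance = 1e-9)
  expect_equal(s2$central_angle, s$central_angle, tolerance = 1e-9)
  expect_equal(unname(s2$center), unname(s$center))

  t <- equatorial_trapezoid(217, -109, 1254, deg2rad(10), center_x = 2)
  t2 <- region_from_json(as.character(region_to_json(t)))
  expect_equal(t2[c("top_y", "base_y", "lens_radius", "center_x", "a", "b")],
               t[c("top_y", "base_y", "lens_radius", "center_x", "a", "b")],
               tolerance = 1e-9)
})
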
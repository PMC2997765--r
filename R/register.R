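#' Match EdU constellations between the anterior and equatorial projections
#'
#' The two calibrated orthographic views of a sphere differ by a single
#' unknown: the azimuth of the equatorial viewing direction (plus a possible
#' in-plane mirror, since the side-on view may be seen from either side).
#' Each anterior EdU centroid is inverted to (colatitude, azimuth) on the
#' sphere; for every candidate view azimuth on a coarse grid the anterior
#' points are forward-projected into the equatorial frame and greedily
#' paired with the equatorial EdU centroids within `tolerance`; the azimuth
#' maximizing the inlier count (ties broken by residual) is refined on a
#' fine local grid and accepted, RANSAC-style. This automates the visual
#' matching of recognizable EdU "constellations" seen in both projections.
#'
#' @param anterior_edu,equatorial_edu `nucleus_records` from the EdU channel
#'   of the two views, in micrometre coordinates centered on the respective
#'   fitted lens centers.
#' @param lens_radius fitted lens radius, um.
#' @param tolerance pairing distance tolerance, um (default 1.5 nucleus
#'   diameters = 12 um).
#' @param y_scale anisotropy of the pairing metric: the vertical residual is
#'   divided by this factor before comparison with `tolerance`. The vertical
#'   coordinate predicted from an inverted anterior centroid is
#'   ill-conditioned near the rim (a radial centroid error dr propagates as
#'   dy ~ dr * tan(colatitude)), so latitude mismatches are forgiven more
#'   than longitude mismatches. Default 4.
#' @param angle_step coarse search step, radians (default 1 degree).
#' @param try_mirror also test the horizontally mirrored equatorial view and
#'   keep the better of the two (default TRUE).
#' @return object of class `constellation_match`: `pairs` (data frame with
#'   `anterior_id`, `equatorial_id`, `residual`), `view_azimuth` (radians),
#'   `mirror`, `mean_pair_residual` (um), `n_inliers`.
#' @export
match_constellations <- function(anterior_edu, equatorial_edu, lens_radius,
                                 tolerance = 12, angle_step = pi / 180,
                                 try_mirror = TRUE, y_scale = 4) {
  if (nrow(anterior_edu) < 3 || nrow(equatorial_edu) < 3)
    stop("registration failure: need at least 3 EdU nuclei in each view")
  # canonical processing order makes the greedy pairing invariant to the
  # ordering/relabeling of the input records
  anterior_edu <- anterior_edu[order(anterior_edu$y, anterior_edu$x), ]
  equatorial_edu <- equatorial_edu[order(equatorial_edu$y, equatorial_edu$x), ]
  sph <- invert_polar(anterior_edu$x, anterior_edu$y, lens_radius)
  angles <- seq(0, 2 * pi - angle_step, by = angle_step)
  best <- NULL
  for (mir in if (try_mirror) c(1, -1) else 1) {
    ex <- mir * equatorial_edu$x
    sc <- cpp_match_rotation(sph$colatitude, sph$azimuth, ex,
                             equatorial_edu$y, lens_radius, tolerance,
                             y_scale, angles)
    o <- order(-sc[, 1], sc[, 2])[1]
    if (sc[o, 1] == 0) next
    # local refinement on a fine grid around the coarse optimum
    fine <- seq(angles[o] - angle_step, angles[o] + angle_step,
                length.out = 201)
    scf <- cpp_match_rotation(sph$colatitude, sph$azimuth, ex,
                              equatorial_edu$y, lens_radius, tolerance,
                              y_scale, fine)
    of <- order(-scf[, 1], scf[, 2])[1]
    cand <- list(view_azimuth = fine[of] %% (2 * pi), mirror = mir,
                 n_inliers = scf[of, 1], residual = scf[of, 2])
    if (is.null(best) || cand$n_inliers > best$n_inliers ||
        (cand$n_inliers == best$n_inliers && cand$residual < best$residual))
      best <- cand
  }
  if (is.null(best) || best$n_inliers < 3)
    stop("registration failure: no rotation pairs at least 3 EdU nuclei; ",
         "the two stacks may not share a visible germinative-zone field")
  # final explicit pairing at the accepted rotation
  d <- sph$azimuth - best$view_azimuth
  vis <- which(cos(d) >= 0)
  px <- lens_radius * sin(sph$colatitude[vis]) * sin(d[vis])
  py <- lens_radius * cos(sph$colatitude[vis])
  ex <- best$mirror * equatorial_edu$x
  mi <- cpp_greedy_pairs(px, py, ex, equatorial_edu$y, tolerance, y_scale)
  got <- which(!is.na(mi))
  res <- sqrt((px[got] - ex[mi[got]])^2 +
                (py[got] - equatorial_edu$y[mi[got]])^2)
  pairs <- data.frame(anterior_id = anterior_edu$id[vis][got],
                      equatorial_id = equatorial_edu$id[mi[got]],
                      residual = res)
  structure(list(pairs = pairs,
                 view_azimuth = best$view_azimuth,
                 mirror = best$mirror,
                 mean_pair_residual = mean(res),
                 n_inliers = nrow(pairs)),
            class = "constellation_match")
}

#' @export
print.constellation_match <- function(x, ...) {
  cat(sprintf("Constellation match: view azimuth %.2f deg%s, %d inliers, mean residual %.2f um\n",
              rad2deg(x$view_azimuth),
              if (x$mirror < 0) " (mirrored)" else "",
              x$n_inliers, x$mean_pair_residual))
  invisible(x)
}

#' Select the fiduciary nucleus from an accepted match
#'
#' Among the matched EdU pairs, selects the one whose equatorial position is
#' closest to the horizontal center of the equatorial projection, so that
#' the equatorial counting trapezoid sits in the center of the projection
#' where distortion is least; ties are broken toward larger colatitude
#' (closer to the margin, minimizing the extent of the band counted at 10
#' degree sampling). The fiduciary's colatitude is read off the equatorial
#' vertical coordinate via `acos(y / lens_radius)`.
#'
#' @param match a [match_constellations()] result.
#' @param anterior_edu,equatorial_edu the record sets used for the match.
#' @param lens_radius fitted lens radius, um.
#' @return object of class `fiduciary`: `anterior_position`,
#'   `equatorial_position` (um), `colatitude` (radians), `id_pair`.
#' @export
select_fiduciary <- function(match, anterior_edu, equatorial_edu,
                             lens_radius) {
  if (nrow(match$pairs) == 0) stop("selection error: no inlier pairs")
  eq <- equatorial_edu[match(match$pairs$equatorial_id, equatorial_edu$id), ]
  an <- anterior_edu[match(match$pairs$anterior_id, anterior_edu$id), ]
  k <- order(abs(eq$x), eq$y)[1]  # central; ties toward the margin (small y)
  colat <- as.numeric(acos(pmin(1, pmax(-1, eq$y[k] / lens_radius))))
  structure(list(anterior_position = c(x = an$x[k], y = an$y[k]),
                 equatorial_position = c(x = eq$x[k], y = eq$y[k]),
                 colatitude = colat,
                 id_pair = c(anterior = an$id[k], equatorial = eq$id[k])),
            class = "fiduciary")
}

#' @export
print.fiduciary <- function(x, ...) {
  cat(sprintf("Fiduciary nucleus: colatitude %.1f deg; anterior (%.1f, %.1f) um; equatorial (%.1f, %.1f) um\n",
              rad2deg(x$colatitude), x$anterior_position[1],
              x$anterior_position[2], x$equatorial_position[1],
              x$equatorial_position[2]))
  invisible(x)
}

#' Write a registration report as JSON
#'
#' @param match a `constellation_match`.
#' @param fiduciary a `fiduciary` (optional).
#' @param path output path; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written.
#' @export
match_to_json <- function(match, fiduciary = NULL, path = NULL) {
  obj <- list(view_azimuth_deg = rad2deg(match$view_azimuth),
              mirror = match$mirror,
              n_inliers = match$n_inliers,
              mean_residual_um = match$mean_pair_residual,
              pairs = match$pairs)
  if (!is.null(fiduciary))
    obj$fiduciary <- list(
      anterior_um = unname(fiduciary$anterior_position),
      equatorial_um = unname(fiduciary$equatorial_position),
      colatitude_deg = rad2deg(fiduciary$colatitude),
      id_pair = unname(fiduciary$id_pair))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
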
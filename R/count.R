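#' Azimuthal extrapolation of the anterior sector count to the spherical cap
#'
#' Under the lens's radial symmetry about the optical axis, the number of
#' cells in the full spherical cap is the sector count scaled by
#' `360 / central_angle` (a 60 degree sector is multiplied by six), rounded
#' to the nearest integer at this final step only.
#'
#' @param n_sector cells counted in the anterior sector.
#' @param central_angle sector central angle, degrees (default 60).
#' @return integer cap count.
#' @examples
#' extrapolate_cap(2500, 60)  # 15000
#' @export
extrapolate_cap <- function(n_sector, central_angle = 60) {
  if (!is.numeric(central_angle) || central_angle <= 0 || central_angle > 360)
    stop("central_angle must lie in (0, 360] degrees")
  if (any(n_sector < 0)) stop("n_sector must be non-negative")
  round(n_sector * 360 / central_angle)
}

#' Azimuthal extrapolation of the trapezoid count to the equatorial band
#'
#' The equatorial band total is the trapezoid count scaled by
#' `360 / longitude_width` (a 10 degree trapezoid is multiplied by 36).
#'
#' @param n_sector cells counted in the equatorial trapezoid.
#' @param longitude_width trapezoid width, degrees of longitude (default 10).
#' @return integer band count.
#' @examples
#' extrapolate_band(700, 10)  # 25200
#' @export
extrapolate_band <- function(n_sector, longitude_width = 10) {
  if (!is.numeric(longitude_width) || longitude_width <= 0 ||
      longitude_width > 360)
    stop("longitude_width must lie in (0, 360] degrees")
  if (any(n_sector < 0)) stop("n_sector must be non-negative")
  round(n_sector * 360 / longitude_width)
}

#' Total epithelial cell number
#'
#' The total is the sum of the extrapolated spherical-cap and
#' equatorial-band numbers, the two complementary regions into which the
#' epithelium is divided at the fiduciary latitude.
#'
#' @param n_cap,n_band extrapolated cap and band counts.
#' @return their sum.
#' @export
total_epithelium <- function(n_cap, n_band) n_cap + n_band

#' Remove meridional-row cells from a literature estimate
#'
#' Flat-mount studies often include the meridional rows (young fiber cells)
#' in "epithelial" totals; this helper subtracts them so such values can be
#' compared with counts that exclude the rows.
#'
#' @param total_with_mr published total including meridional rows.
#' @param n_mr meridional-row cell number included in it.
#' @return the difference.
#' @examples
#' subtract_meridional(44474, 8913)  # 35561
#' @export
subtract_meridional <- function(total_with_mr, n_mr) {
  if (any(n_mr > total_with_mr))
    stop("meridional count exceeds the total")
  total_with_mr - n_mr
}

#' Relative difference between replicate estimates
#'
#' For each replicate pair (two independent measurements of the same lens),
#' computes the symmetric relative difference
#' `|e1 - e2| / mean(e1, e2) * 100` and, across pairs, its mean and SD.
#'
#' @param estimates a length-2 numeric vector (one pair), an n x 2 matrix,
#'   or a list of length-2 vectors.
#' @return list of class `replicate_spread`: `per_pair` (percent), `mean`,
#'   `sd`, `n_pairs`.
#' @examples
#' replicate_spread(c(110, 90))$per_pair  # 20
#' @export
replicate_spread <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  if (is.numeric(estimates) && is.null(dim(estimates))) {
    if (length(estimates) != 2)
      stop("a replicate pair needs exactly 2 estimates")
    estimates <- matrix(estimates, 1)
  }
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != 2 || any(estimates <= 0))
    stop("each replicate pair needs 2 positive estimates")
  per <- abs(estimates[, 1] - estimates[, 2]) /
    rowMeans(estimates) * 100
  structure(list(per_pair = per, mean = mean(per),
                 sd = if (length(per) > 1) sd(per) else NA_real_,
                 n_pairs = length(per)),
            class = "replicate_spread")
}

#' @export
print.replicate_spread <- function(x, ...) {
  cat(sprintf("Replicate spread: %.1f%%%s (n = %d pair%s)\n", x$mean,
              if (is.na(x$sd)) "" else sprintf(" +/- %.1f%%", x$sd),
              x$n_pairs, if (x$n_pairs == 1) "" else "s"))
  invisible(x)
}

#' Assemble a count result
#'
#' Combines the two region counts into the extrapolated cap, band and total
#' numbers with their provenance.
#'
#' @param n_anterior_sector,n_equatorial_sector raw region counts.
#' @param anterior_angle sector central angle, degrees.
#' @param equatorial_width trapezoid longitude width, degrees.
#' @param fiduciary_colatitude fiduciary colatitude, degrees.
#' @param provenance named list (region specs, parameters, seeds, ...)
#'   carried into the serialized result.
#' @return object of class `count_result`.
#' @export
count_result <- function(n_anterior_sector, n_equatorial_sector,
                         anterior_angle = 60, equatorial_width = 10,
                         fiduciary_colatitude = NA_real_,
                         provenance = list()) {
  n_cap <- extrapolate_cap(n_anterior_sector, anterior_angle)
  n_band <- extrapolate_band(n_equatorial_sector, equatorial_width)
  structure(list(n_anterior_sector = n_anterior_sector,
                 n_equatorial_sector = n_equatorial_sector,
                 anterior_angle = anterior_angle,
                 equatorial_width = equatorial_width,
                 n_cap = n_cap, n_band = n_band,
                 n_total = total_epithelium(n_cap, n_band),
                 fiduciary_colatitude = fiduciary_colatitude,
                 provenance = provenance),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat("Lens epithelium count\n")
  cat(sprintf("  anterior sector (%g deg): %d nuclei -> cap  %d cells\n",
              x$anterior_angle, x$n_anterior_sector, x$n_cap))
  cat(sprintf("  equatorial trapezoid (%g deg): %d nuclei -> band %d cells\n",
              x$equatorial_width, x$n_equatorial_sector, x$n_band))
  cat(sprintf("  total epithelial cells: %d\n", x$n_total))
  if (!is.na(x$fiduciary_colatitude))
    cat(sprintf("  fiduciary colatitude: %.1f deg\n", x$fiduciary_colatitude))
  invisible(x)
}

#' Serialize a count result to JSON and a one-row CSV
#'
#' @param result a [count_result()].
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return the JSON string, invisibly.
#' @export
write_count_result <- function(result, json_path = NULL, csv_path = NULL) {
  js <- jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  if (!is.null(json_path)) writeLines(js, json_path)
  if (!is.null(csv_path)) {
    row <- result[c("n_anterior_sector", "n_equatorial_sector",
                    "anterior_angle", "equatorial_width", "n_cap", "n_band",
                    "n_total", "fiduciary_colatitude")]
    write.csv(as.data.frame(row), csv_path, row.names = FALSE)
  }
  invisible(js)
}

#' Read back a serialized count result
#'
#' @param json_path path written by [write_count_result()].
#' @return a [count_result()].
#' @export
read_count_result <- function(json_path) {
  obj <- jsonlite::fromJSON(json_path)
  count_result(obj$n_anterior_sector, obj$n_equatorial_sector,
               obj$anterior_angle, obj$equatorial_width,
               obj$fiduciary_colatitude %||% NA_real_,
               provenance = obj$provenance %||% list())
}
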
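#' Detection parameters
#'
#' The detector finds nuclei by their expected size and brightness against a
#' potentially fluctuating background: the local background is estimated with
#' a broad box filter and subtracted, the residual is smoothed at a fraction
#' of the expected nucleus scale, pixels above `intensity_above_background`
#' are segmented into connected components, touching nuclei are split from
#' intensity-maximum markers, and segments outside the equivalent-diameter
#' band are discarded.
#'
#' @param min_diameter,max_diameter accepted equivalent-diameter band, um
#'   (mouse lens epithelial nuclei are ~8 um across; default band 4-16 um).
#' @param intensity_above_background threshold over the local background,
#'   intensity units.
#' @param background_scale half-width of the local-background box, um.
#' @param declump split elongated segments that are consistent with two
#'   unresolved nuclei (default FALSE). Two blobs closer than ~2 blob sigmas
#'   have no intensity dip between them, so no watershed can separate them;
#'   moment-based splitting can recover such pairs when clumps are isolated,
#'   but oversplits foreshortened single nuclei inside saturated clusters
#'   (e.g. near the projected lens rim), so it is off by default.
#'   A segment is split into two records along its intensity-weighted major
#'   axis when (a) the major/minor spread ratio exceeds `elongation_ratio`,
#'   (b) the implied pair separation `2 * sqrt(l1 - l2)` (eigenvalues of the
#'   second-moment matrix) is at least half the expected nucleus diameter,
#'   and (c) the minor-axis spread is consistent with a full-width nucleus
#'   (which excludes merely foreshortened single nuclei near the projection
#'   rim).
#' @param elongation_ratio declumping shape threshold (see `declump`).
#' @param sharpen locate split markers on a Wiener-deconvolved copy of the
#'   image (Gaussian blur kernel at the expected nucleus scale), which
#'   restores separability of blob pairs down to ~1.3 blob sigmas where the
#'   blurred image is unimodal (default TRUE). Segmentation and brightness
#'   thresholds still apply to the unsharpened image.
#' @param wiener_eps Wiener regularization (noise-to-signal power); larger
#'   values amplify noise less but sharpen less. `NULL` (default) estimates
#'   it from the image as `(sigma_noise / peak_signal)^2`, with the noise sd
#'   taken from the median absolute difference of adjacent pixels.
#' @return list of class `detect_params`.
#' @export
detect_params <- function(min_diameter = 4, max_diameter = 16,
                          intensity_above_background = 150,
                          background_scale = 60, declump = FALSE,
                          elongation_ratio = 1.25, sharpen = TRUE,
                          wiener_eps = NULL) {
  stopifnot(min_diameter > 0, min_diameter < max_diameter,
            intensity_above_background > 0, background_scale > 0,
            elongation_ratio >= 1, is.null(wiener_eps) || wiener_eps > 0)
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 intensity_above_background = intensity_above_background,
                 background_scale = background_scale, declump = declump,
                 elongation_ratio = elongation_ratio, sharpen = sharpen,
                 wiener_eps = wiener_eps),
            class = "detect_params")
}

# Wiener deconvolution with an isotropic Gaussian kernel of sd sigma_px.
# Returns the sharpened image and the peak gain of an isolated blob.
wiener_sharpen <- function(m, sigma_px, eps) {
  nr <- nrow(m); nc <- ncol(m)
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)
  K <- exp(-outer(ky^2, kx^2, "+") / (2 * sigma_px^2))
  K <- K / sum(K)
  H <- fft(K)
  G <- Conj(H) / (Mod(H)^2 + eps)
  sharp <- Re(fft(fft(m) * G, inverse = TRUE)) / (nr * nc)
  gain <- max(Re(fft(H * G, inverse = TRUE)) / (nr * nc))
  list(image = sharp, gain = gain)
}

# separable Gaussian smoothing; edges are zero-padded (the image background
# is ~0 after local-background subtraction)
gauss_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  w <- max(1, ceiling(3 * sigma_px))
  k <- exp(-((-w:w)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  sm <- stats::filter(m, k, sides = 2)
  sm[is.na(sm)] <- 0
  sm <- t(stats::filter(t(sm), k, sides = 2))
  sm[is.na(sm)] <- 0
  matrix(sm, nrow(m), ncol(m))
}

# separable running min/max over a (2h+1)^2 box, by doubling shifts
box_extreme <- function(m, h, cmp) {
  shift_cmp <- function(x, lag) {
    n <- nrow(x)
    if (lag >= n) return(x)
    if (lag > 0) cmp(x, rbind(x[-seq_len(lag), , drop = FALSE],
                              x[rep(n, lag), , drop = FALSE]))
    else cmp(x, rbind(x[rep(1, -lag), , drop = FALSE],
                      x[seq_len(n + lag), , drop = FALSE]))
  }
  run <- function(x, h) {
    done <- 0; step <- 1
    while (done < h) {
      s <- min(step, h - done)
      x <- shift_cmp(shift_cmp(x, s), -s)
      done <- done + s; step <- 2 * done
    }
    x
  }
  t(run(t(run(m, h)), h))
}

box_min <- function(m, h) box_extreme(m, h, pmin)
box_max <- function(m, h) box_extreme(m, h, pmax)

# rolling-ball-style background: gray opening (erosion then dilation) over
# the background box, then box-mean smoothing. The opening removes
# structure smaller than the box while preserving the intensity pedestal
# inside dense nuclear clusters (a plain box mean would swallow half of
# it) and, unlike a bare erosion, is unbiased against additive noise
box_background <- function(m, h) {
  box_mean(box_max(box_min(m, h), h), h)
}

# local mean over a (2h+1)^2 box via integral images, edge-normalized
box_mean <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i0 <- pmax(seq_len(nr) - h, 1); i1 <- pmin(seq_len(nr) + h, nr)
  j0 <- pmax(seq_len(nc) - h, 1); j1 <- pmin(seq_len(nc) + h, nc)
  # sum over [i0..i1] x [j0..j1] per pixel
  A <- S[i1 + 1, j1 + 1, drop = FALSE] - S[i0, j1 + 1, drop = FALSE] -
    S[i1 + 1, j0, drop = FALSE] + S[i0, j0, drop = FALSE]
  A / outer(i1 - i0 + 1, j1 - j0 + 1)
}

# 8-neighborhood local maxima (>= all neighbors); plateaus yield adjacent
# marker pixels that are merged downstream
local_maxima <- function(m, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ok <- m >= threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & m >= pad[2:(nr + 1) + di, 2:(nc + 1) + dj]
  }
  ok
}

#' Detect nuclei in a 2-D projection
#'
#' Identifies nucleus centroids in a maximum-intensity projection using the
#' expected size and brightness of nuclei. Pipeline: local-background
#' subtraction, band-limited smoothing at the expected blob scale,
#' thresholding, 8-connected segmentation, marker-based splitting of touching
#' nuclei (markers are local intensity maxima; pixels are divided by
#' geodesic proximity, a watershed-style partition), then equivalent-diameter
#' band filtering. Centroids are intensity-weighted centers of mass in
#' micrometres in the projection frame; records are ordered by y then x.
#'
#' @param image a [lens_projection()] (or matrix with `pixel_size`
#'   attribute).
#' @param params a [detect_params()].
#' @return data frame of class `nucleus_records`: `id`, `x`, `y` (um),
#'   `area` (um^2), `equivalent_diameter` (um), `mean_intensity`, `channel`.
#'   The label image is attached as attribute `labels` for audit.
#' @export
detect_nuclei <- function(image, params = detect_params()) {
  ps <- attr(image, "pixel_size")
  if (is.null(ps)) stop("metadata error: image has no pixel_size attribute")
  m <- matrix(as.numeric(image), nrow(image), ncol(image))
  bg <- box_background(m, max(1L, round(params$background_scale / ps)))
  sub <- m - bg
  d0 <- sqrt(params$min_diameter * params$max_diameter)
  sm <- gauss_smooth(sub, d0 / 2.355 / 2 / ps)
  thr <- params$intensity_above_background
  mask <- sm >= thr
  if (!any(mask)) return(empty_records(image))
  labels0 <- cpp_label_components(matrix(as.integer(mask), nrow(m)))
  labels <- labels0
  if (isTRUE(params$sharpen)) {
    eps <- params$wiener_eps
    if (is.null(eps)) {
      sigma_n <- median(abs(diff(m))) / (0.6745 * sqrt(2))
      peak <- quantile(sub, 0.999, names = FALSE)
      # floor keeps the inverse filter from amplifying the model error of
      # overlapping blobs (a MIP is a max, not a sum) on near-noiseless data
      eps <- max((sigma_n / max(peak, 1e-12))^2, 1e-4)
    }
    ws <- wiener_sharpen(sub, d0 / 2.355 / ps, eps)
    mx <- local_maxima(ws$image, thr * ws$gain * 0.5) & mask
  } else {
    mx <- local_maxima(sm, thr) & mask
  }
  # merge plateau markers: adjacent marker pixels form one marker
  mlab <- cpp_label_components(matrix(as.integer(mx), nrow(m)))
  midx <- which(mlab > 0)
  nmark <- integer(max(labels0))
  if (length(midx)) {
    mi <- (midx - 1) %% nrow(m) + 1
    mj <- (midx - 1) %/% nrow(m) + 1
    grp <- mlab[midx]
    mi <- as.integer(round(tapply(mi, grp, mean)))
    mj <- as.integer(round(tapply(mj, grp, mean)))
    labels <- cpp_split_by_markers(labels0, mi, mj)
    nm <- table(labels0[cbind(mi, mj)])
    nmark[as.integer(names(nm))] <- as.integer(nm)
  }
  idx <- which(labels > 0)
  l <- labels[idx]
  i <- (idx - 1) %% nrow(m) + 1
  j <- (idx - 1) %/% nrow(m) + 1
  wgt <- pmax(sub[idx], 0)
  npx <- tabulate(l)
  ok_l <- which(npx > 0)
  wsum <- rowsum(wgt, l)[, 1]
  # fall back to binary centroid if a segment has no positive signal
  wz <- wsum <= 0
  if (any(wz)) wgt[l %in% ok_l[wz]] <- 1
  wsum <- rowsum(wgt, l)[, 1]
  ci <- rowsum(wgt * i, l)[, 1] / wsum
  cj <- rowsum(wgt * j, l)[, 1] / wsum
  meanint <- rowsum(sub[idx], l)[, 1] / npx[ok_l]
  area <- npx[ok_l] * ps^2
  eqd <- 2 * sqrt(area / pi)
  um <- pixel_to_um(image, ci, cj)
  rec <- data.frame(x = um$x, y = um$y, area = area,
                    equivalent_diameter = eqd, mean_intensity = meanint)
  if (isTRUE(params$declump) && nrow(rec) >= 8) {
    # second moments of the segment mask, um^2 (x = column axis, y = -row
    # axis); mask shape is robust to the intensity pedestal that local
    # background subtraction strips inside dense clusters
    bi <- rowsum(i, l)[, 1] / npx[ok_l]
    bj <- rowsum(j, l)[, 1] / npx[ok_l]
    sxx <- (rowsum(as.numeric(j)^2, l)[, 1] / npx[ok_l] - bj^2) * ps^2
    syy <- (rowsum(as.numeric(i)^2, l)[, 1] / npx[ok_l] - bi^2) * ps^2
    sxy <- -(rowsum(as.numeric(i * j), l)[, 1] / npx[ok_l] - bi * bj) * ps^2
    tr <- sxx + syy
    dsc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
    l1 <- pmax((tr + dsc) / 2, 1e-12); l2 <- pmax((tr - dsc) / 2, 1e-12)
    dhat <- 2 * sqrt(pmax(l1 - l2, 0))  # implied pair separation, um
    split <- sqrt(l1 / l2) > params$elongation_ratio &
      dhat >= 0.5 * d0 &
      sqrt(l2) >= 0.25 * d0 &
      rec$equivalent_diameter <= 2 * params$max_diameter &
      rec$equivalent_diameter >= params$min_diameter
    split[is.na(split)] <- FALSE
    if (any(split)) {
      ang <- 0.5 * atan2(2 * sxy[split], sxx[split] - syy[split])
      half <- sqrt(pmax(l1[split] - l2[split], 0))
      twin <- function(s) {
        d <- rec[split, , drop = FALSE]
        d$x <- d$x + s * half * cos(ang)
        d$y <- d$y + s * half * sin(ang)
        d$area <- d$area / 2
        d$equivalent_diameter <- d$equivalent_diameter / sqrt(2)
        d
      }
      rec <- rbind(rec[!split, , drop = FALSE], twin(1), twin(-1))
    }
  }
  rec <- rec[rec$equivalent_diameter >= params$min_diameter &
               rec$equivalent_diameter <= params$max_diameter, ,
             drop = FALSE]
  rec <- rec[order(rec$y, rec$x), , drop = FALSE]
  rec <- cbind(id = seq_len(nrow(rec)), rec)
  rec$channel <- attr(image, "channel") %||% "dna"
  rownames(rec) <- NULL
  attr(rec, "pixel_size") <- ps
  attr(rec, "labels") <- labels
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

empty_records <- function(image) {
  rec <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    area = numeric(0), equivalent_diameter = numeric(0),
                    mean_intensity = numeric(0), channel = character(0))
  attr(rec, "pixel_size") <- attr(image, "pixel_size")
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}

#' Count records whose centroid lies in a counting region
#'
#' Applies the centroid-inclusion rule: a nucleus is counted iff its center
#' of mass lies within the (closed) region.
#'
#' @param records a `nucleus_records` data frame (same projection frame as
#'   the region).
#' @param region an [anterior_sector()] or [equatorial_trapezoid()].
#' @return integer count.
#' @export
count_in_region <- function(records, region) {
  if (nrow(records) == 0) return(0L)
  if (inherits(region, "anterior_sector"))
    sum(point_in_sector(records$x, records$y, region))
  else if (inherits(region, "equatorial_trapezoid"))
    sum(point_in_trapezoid(records$x, records$y, region))
  else stop("unknown region type")
}

#' Export / import nucleus records as CSV
#'
#' @param records a `nucleus_records` data frame.
#' @param path CSV path.
#' @return `write_records` returns `path` invisibly; `read_records` the
#'   records.
#' @export
write_records <- function(records, path) {
  df <- as.data.frame(records)
  names(df) <- c("id", "x_um", "y_um", "area_um2", "eq_diam_um",
                 "mean_intensity", "channel")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rec <- data.frame(id = df$id, x = df$x_um, y = df$y_um, area = df$area_um2,
                    equivalent_diameter = df$eq_diam_um,
                    mean_intensity = df$mean_intensity, channel = df$channel)
  class(rec) <- c("nucleus_records", "data.frame")
  rec
}
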
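#' Maximum-intensity projection of a voxel stack
#'
#' Collapses a stack along its viewing (z) axis: each output pixel is the
#' maximum intensity along the axis. The projection inherits the stack's
#' pixel size and micrometre origin, making it an orthographic azimuthal
#' projection of the lens surface.
#'
#' @param stack a [voxel_stack()].
#' @return a [lens_projection()].
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  a <- stack$intensities
  d <- dim(a)
  if (any(d == 0) || length(a) == 0) stop("empty stack")
  if (abs(stack$voxel_size[2] - stack$voxel_size[3]) > 1e-9)
    stop("anisotropic lateral voxels are not supported in projections")
  img <- matrix(a[1, , ], d[2], d[3])
  if (d[1] > 1)
    for (k in 2:d[1]) img <- pmax(img, matrix(a[k, , ], d[2], d[3]))
  lens_projection(img, stack$voxel_size[2], origin = stack$origin,
                  channel = stack$channel, aspect = stack$aspect,
                  view_azimuth = stack$view_azimuth)
}

# micrometre coordinates (x, y, z) of voxel centers for given array indices
voxel_coords <- function(stack, idx) {
  d <- dim(stack$intensities)
  k <- (idx - 1) %% d[1] + 1
  i <- ((idx - 1) %/% d[1]) %% d[2] + 1
  j <- (idx - 1) %/% (d[1] * d[2]) + 1
  cbind(x = stack$origin[1] + (j - 1) * stack$voxel_size[3],
        y = stack$origin[2] - (i - 1) * stack$voxel_size[2],
        z = stack$z_vals[k])
}

# algebraic least-squares sphere fit: x^2+y^2+z^2 = 2ax + 2by + 2cz + d
sphere_fit_ls <- function(P) {
  b <- rowSums(P^2)
  A <- cbind(2 * P, 1)
  beta <- qr.solve(A, b)
  center <- beta[1:3]
  radius <- sqrt(beta[4] + sum(center^2))
  res <- sqrt(rowSums(sweep(P, 2, center)^2)) - radius
  list(center = center, radius = radius, residuals = res)
}

#' Fit a sphere to the bright epithelial shell of a stack
#'
#' Least-squares sphere fit to the micrometre coordinates of voxels whose
#' intensity exceeds the given quantile, with robust outlier rejection
#' (residuals beyond 3 median absolute deviations are dropped and the fit
#' repeated). This is the automated surrogate for manually locating the
#' plane of the equatorial epithelium: deep fiber-nucleus voxels are
#' rejected as outliers to the shell.
#'
#' @param stack a [voxel_stack()] containing a bright curved shell.
#' @param intensity_quantile fraction of voxels excluded by the brightness
#'   cut (default 0.999 keeps the brightest 0.1 percent).
#' @param min_voxels minimum number of bright voxels required.
#' @return object of class `lens_surface_fit`: list with `center` (x, y, z,
#'   micrometres), `radius`, `rms_residual`, `n_voxels`.
#' @export
fit_lens_surface <- function(stack, intensity_quantile = 0.999,
                             min_voxels = 50) {
  stopifnot(inherits(stack, "voxel_stack"))
  a <- stack$intensities
  thr <- quantile(a, intensity_quantile, names = FALSE)
  idx <- which(a > thr)
  if (length(idx) < min_voxels)
    stop("surface fit error: too few bright voxels above the ",
         intensity_quantile, " quantile")
  P <- voxel_coords(stack, idx)
  fit <- sphere_fit_ls(P)
  for (iter in 1:3) {
    s <- mad(fit$residuals)
    keep <- abs(fit$residuals) <= 3 * max(s, 1e-6)
    if (all(keep) || sum(keep) < min_voxels) break
    P <- P[keep, , drop = FALSE]
    fit <- sphere_fit_ls(P)
  }
  structure(list(center = fit$center, radius = fit$radius,
                 rms_residual = sqrt(mean(fit$residuals^2)),
                 n_voxels = nrow(P)),
            class = "lens_surface_fit")
}

#' @export
print.lens_surface_fit <- function(x, ...) {
  cat(sprintf("Lens surface fit: radius %.1f um, center (%.1f, %.1f, %.1f) um, rms %.2f um (%d voxels)\n",
              x$radius, x$center[1], x$center[2], x$center[3],
              x$rms_residual, x$n_voxels))
  invisible(x)
}

#' Zero the voxels beneath the epithelial shell
#'
#' Replaces the manual deletion of fiber-cell nuclei in optical sections
#' beneath the equatorial epithelium: every voxel lying deeper than
#' `shell_thickness` below the fitted spherical surface is set to zero;
#' voxels within the shell (or outside the sphere) are untouched. The masked
#' stack's projection therefore contains only epithelial and meridional-row
#' signal.
#'
#' @param stack a [voxel_stack()].
#' @param surface a [fit_lens_surface()] result (or any list with `center`
#'   and `radius`).
#' @param shell_thickness retained shell depth below the surface, um
#'   (default 15, about two nucleus radii).
#' @return the masked [voxel_stack()].
#' @export
shell_mask <- function(stack, surface, shell_thickness = 15) {
  stopifnot(inherits(stack, "voxel_stack"))
  d <- dim(stack$intensities)
  xs <- stack$origin[1] + (seq_len(d[3]) - 1) * stack$voxel_size[3]
  ys <- stack$origin[2] - (seq_len(d[2]) - 1) * stack$voxel_size[2]
  lat2 <- outer((ys - surface$center[2])^2, (xs - surface$center[1])^2, "+")
  out <- stack$intensities
  for (k in seq_len(d[1])) {
    dist <- sqrt(lat2 + (stack$z_vals[k] - surface$center[3])^2)
    sl <- matrix(out[k, , ], d[2], d[3])
    sl[surface$radius - dist > shell_thickness] <- 0
    out[k, , ] <- sl
  }
  stack$intensities <- out
  stack
}

#' Honor a user-supplied binary mask verbatim
#'
#' For parity with a manual clean-up workflow: multiplies the stack by a
#' 0/1 mask of identical dimensions.
#'
#' @param stack a [voxel_stack()].
#' @param mask array of the same dimensions; voxels where `mask == 0` are
#'   zeroed.
#' @return the masked [voxel_stack()].
#' @export
apply_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "voxel_stack"),
            all(dim(mask) == dim(stack$intensities)))
  stack$intensities <- stack$intensities * (mask != 0)
  stack
}
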
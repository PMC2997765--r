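# Rendering of ground-truth nuclei into voxel stacks and projections.
#
# Frames: the projection plane is (x right, y up) in micrometres with origin
# at the lens center. Images/stacks store y in rows (row 1 = largest y) and
# x in columns. Stacks are (z, y, x) arrays whose z axis is the viewing
# axis: optical axis (anterior aspect) or the depth axis toward the viewer
# (equatorial aspect); slice 1 is nearest the viewer / outside of the lens.

#' Define the voxel grid of a simulated acquisition
#'
#' @param params a [lens_sim_params()] object.
#' @param aspect `"anterior"` or `"equatorial"`.
#' @return list with pixel dimensions, micrometre coordinates of the first
#'   pixel center and the z slice positions (descending; the viewing-axis
#'   coordinate runs from outside the lens down to the equatorial plane, so
#'   only the visible hemisphere is acquired).
#' @export
stack_grid <- function(params, aspect = c("anterior", "equatorial")) {
  aspect <- match.arg(aspect)
  ps <- params$voxel_size
  n <- 2 * floor(params$field_width / (2 * ps)) + 1
  z_top <- params$lens_radius + 2 * params$nucleus_diameter
  # the last slice lands at or just below the equatorial plane, so nuclei
  # at z ~ 0 are never more than half a step from a slice
  nzs <- floor(z_top / params$z_step) + 2
  list(nx = n, ny = n,
       x0 = -(n - 1) / 2 * ps,   # x of column 1 (pixel center), um
       y0 = (n - 1) / 2 * ps,    # y of row 1, um
       pixel_size = ps,
       z_vals = seq(z_top, by = -params$z_step, length.out = nzs),
       aspect = aspect)
}

#' Construct a voxel stack
#'
#' @param intensities 3-D array, dimensions (z, y, x); non-negative.
#' @param voxel_size length-3 voxel size (z, y, x), micrometres.
#' @param channel `"dna"` or `"edu"`.
#' @param aspect `"anterior"` or `"equatorial"`.
#' @param origin length-2 micrometre coordinates (x, y) of the center of
#'   pixel (row 1, column 1).
#' @param z_vals viewing-axis coordinate of each slice, micrometres.
#' @param view_azimuth viewing azimuth (equatorial aspect), radians.
#' @return object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, voxel_size, channel = "dna",
                        aspect = "anterior", origin = c(0, 0),
                        z_vals = NULL, view_azimuth = 0) {
  stopifnot(length(dim(intensities)) == 3, all(voxel_size > 0))
  if (any(intensities < 0)) stop("voxel intensities must be non-negative")
  structure(list(intensities = intensities,
                 voxel_size = voxel_size,
                 channel = channel, aspect = aspect,
                 origin = origin,
                 z_vals = z_vals %||%
                   ((dim(intensities)[1]:1 - 1) * voxel_size[1]),
                 view_azimuth = view_azimuth),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Voxel stack (%s aspect, %s channel): %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              x$aspect, x$channel, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# viewing-frame coordinates (x, y in the projection plane; z along the
# viewing axis) of nuclei, given the ground truth and the aspect
nucleus_view_coords <- function(gt, aspect, view_azimuth) {
  nuc <- gt$nuclei
  r <- gt$params$lens_radius - nuc$depth
  if (aspect == "anterior") {
    data.frame(x = r * sin(nuc$colatitude) * cos(nuc$azimuth),
               y = r * sin(nuc$colatitude) * sin(nuc$azimuth),
               z = r * cos(nuc$colatitude))
  } else {
    d <- nuc$azimuth - view_azimuth
    data.frame(x = r * sin(nuc$colatitude) * sin(d),
               y = r * cos(nuc$colatitude),
               z = r * sin(nuc$colatitude) * cos(d))
  }
}

select_channel <- function(gt, channel) {
  if (channel == "edu") gt$nuclei$edu else rep(TRUE, nrow(gt$nuclei))
}

#' Render a ground truth as a two-channel confocal-like voxel stack
#'
#' Every visible nucleus of the requested channel (EdU channel: EdU-positive
#' nuclei only; DNA channel: all nuclei) is rendered as a 3-D Gaussian blob
#' whose lateral FWHM equals the nucleus diameter and whose axial extent
#' additionally carries the confocal axial PSF; blobs add, then Gaussian
#' noise of sd `noise_sd` is applied (clamped at zero). The stack spans the
#' visible hemisphere only: nuclei behind the equatorial plane of the view
#' are clipped silently (a message reports how many).
#'
#' @param gt a `ground_truth` object.
#' @param aspect `"anterior"` or `"equatorial"`.
#' @param channel `"dna"` or `"edu"`.
#' @param view_azimuth viewing azimuth for the equatorial aspect, radians.
#' @param params simulator parameters; defaults to `gt$params`.
#' @param grid voxel grid from [stack_grid()]; defaults to the params grid.
#' @return a [voxel_stack()].
#' @export
render_stack <- function(gt, aspect = c("anterior", "equatorial"),
                         channel = c("dna", "edu"), view_azimuth = 0,
                         params = gt$params, grid = NULL) {
  aspect <- match.arg(aspect); channel <- match.arg(channel)
  if (is.null(grid)) grid <- stack_grid(params, aspect)
  vc <- nucleus_view_coords(gt, aspect, view_azimuth)
  keep <- select_channel(gt, channel)
  vc <- vc[keep, , drop = FALSE]
  nz <- length(grid$z_vals)
  z_top <- grid$z_vals[1]
  ps <- grid$pixel_size
  zs <- params$z_step
  # pixel (fractional, 1-based) coordinates of blob centers
  cj <- (vc$x - grid$x0) / ps + 1
  ci <- (grid$y0 - vc$y) / ps + 1
  ck <- (z_top - vc$z) / zs + 1
  sig_xy <- params$nucleus_diameter / 2.355
  sig_z <- sqrt(sig_xy^2 + (params$axial_fwhm / 2.355)^2)
  cut <- 3.5
  inside <- ci > 1 - cut * sig_xy / ps & ci < grid$ny + cut * sig_xy / ps &
    cj > 1 - cut * sig_xy / ps & cj < grid$nx + cut * sig_xy / ps &
    ck > 1 - cut * sig_z / zs & ck < nz + cut * sig_z / zs
  if (any(!inside))
    message(sum(!inside), " nuclei outside the ", aspect,
            " acquisition volume were clipped")
  amp <- if (channel == "edu") params$amp_edu else params$amp_dna
  arr <- cpp_render_blobs_3d(nz, grid$ny, grid$nx,
                             ck[inside], ci[inside], cj[inside],
                             rep(amp, sum(inside)),
                             sig_z / zs, sig_xy / ps, cut)
  dim(arr) <- c(nz, grid$ny, grid$nx)
  if (params$noise_sd > 0) {
    set.seed(derive_seed(params$seed,
                         10L + 2L * (aspect == "equatorial") +
                           (channel == "edu")))
    arr <- pmax(0, arr + rnorm(length(arr), 0, params$noise_sd))
    dim(arr) <- c(nz, grid$ny, grid$nx)
  }
  voxel_stack(arr, c(zs, ps, ps), channel = channel, aspect = aspect,
              origin = c(grid$x0, grid$y0), z_vals = grid$z_vals,
              view_azimuth = view_azimuth)
}

#' Construct a 2-D projection image
#'
#' @param pixels numeric matrix (rows = y, columns = x; row 1 = largest y).
#' @param pixel_size micrometres per pixel.
#' @param origin micrometre coordinates (x, y) of the center of pixel (1,1).
#' @param channel,aspect,view_azimuth metadata carried along the pipeline.
#' @return object of class `lens_projection` (a matrix with attributes).
#' @export
lens_projection <- function(pixels, pixel_size, origin = NULL,
                            channel = "dna", aspect = "anterior",
                            view_azimuth = 0) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (is.null(origin))
    origin <- c(-(ncol(pixels) - 1) / 2, (nrow(pixels) - 1) / 2) * pixel_size
  structure(pixels, pixel_size = pixel_size, origin = origin,
            channel = channel, aspect = aspect, view_azimuth = view_azimuth,
            class = c("lens_projection", "matrix", "array"))
}

#' Pixel-to-micrometre coordinates of a projection
#'
#' @param img a [lens_projection()].
#' @param i,j row and column indices (may be fractional).
#' @return data frame with micrometre `x`, `y`.
#' @export
pixel_to_um <- function(img, i, j) {
  o <- attr(img, "origin"); ps <- attr(img, "pixel_size")
  data.frame(x = o[1] + (j - 1) * ps, y = o[2] - (i - 1) * ps)
}

#' Render a ground truth directly as a maximum-intensity projection
#'
#' Fast path that skips the voxel stack: each visible nucleus contributes a
#' 2-D Gaussian of the same lateral width and peak amplitude as its 3-D
#' blob, and contributions add. For an isolated nucleus this equals the
#' maximum-intensity projection of the 3-D render exactly (up to the axial
#' sampling of the blob peak); where nuclei overlap laterally they usually
#' lie at similar depths (neighbours on the spherical surface), so the MIP
#' of their additive 3-D render is also approximately additive. The noise
#' here is plain Gaussian rather than a maximum over slices. Residual
#' differences are quantified in the test suite and discussed in the
#' methods vignette.
#'
#' @inheritParams render_stack
#' @param pixel_size projection pixel size, um.
#' @param mask_depth if non-`NULL`, nuclei deeper than this below the lens
#'   surface are removed first (the idealized sub-epithelial cleanup that
#'   [shell_mask()] performs on real stacks).
#' @param noise add Gaussian readout noise of sd `params$noise_sd`.
#' @param combine how overlapping blobs combine: `"max"` (default; matches
#'   the maximum-intensity projection of the 3-D render, which takes the
#'   maximum along each ray) or `"sum"` (plain additive 2-D rendering).
#' @return a [lens_projection()].
#' @export
render_projection <- function(gt, aspect = c("anterior", "equatorial"),
                              channel = c("dna", "edu"), view_azimuth = 0,
                              params = gt$params,
                              pixel_size = params$voxel_size,
                              mask_depth = NULL, noise = TRUE,
                              combine = c("max", "sum")) {
  aspect <- match.arg(aspect); channel <- match.arg(channel)
  combine <- match.arg(combine)
  gt2 <- gt
  if (!is.null(mask_depth))
    gt2$nuclei <- gt$nuclei[gt$nuclei$depth <= mask_depth, , drop = FALSE]
  vc <- nucleus_view_coords(gt2, aspect, view_azimuth)
  # same visibility as the voxel grid: nuclei below the last slice (at or
  # just below the equatorial plane) contribute only the axial tail their
  # nearest slice would record, fading over ~one axial sigma
  z_top <- params$lens_radius + 2 * params$nucleus_diameter
  z_floor <- z_top - (floor(z_top / params$z_step) + 1) * params$z_step
  sig_z <- sqrt((params$nucleus_diameter / 2.355)^2 +
                  (params$axial_fwhm / 2.355)^2)
  fade <- ifelse(vc$z >= z_floor, 1,
                 exp(-(z_floor - vc$z)^2 / (2 * sig_z^2)))
  keep <- select_channel(gt2, channel) & vc$z >= z_floor - 3.5 * sig_z
  fade <- fade[keep]
  vc <- vc[keep, , drop = FALSE]
  ps <- pixel_size
  n <- 2 * floor(params$field_width / (2 * ps)) + 1
  x0 <- -(n - 1) / 2 * ps; y0 <- (n - 1) / 2 * ps
  cj <- (vc$x - x0) / ps + 1
  ci <- (y0 - vc$y) / ps + 1
  sig_xy <- params$nucleus_diameter / 2.355
  amp <- if (channel == "edu") params$amp_edu else params$amp_dna
  img <- cpp_render_blobs_2d(n, n, ci, cj, amp * fade,
                             sig_xy / ps, 3.5, combine == "max")
  if (noise && params$noise_sd > 0) {
    set.seed(derive_seed(params$seed,
                         20L + 2L * (aspect == "equatorial") +
                           (channel == "edu")))
    img <- matrix(pmax(img + rnorm(length(img), 0, params$noise_sd), 0),
                  nrow(img))
  }
  lens_projection(img, ps, origin = c(x0, y0), channel = channel,
                  aspect = aspect, view_azimuth = view_azimuth)
}
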
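# End-to-end pipeline: projections -> lens outline -> detection ->
# registration -> counting regions -> extrapolated totals, plus the file
# plumbing (config YAML, TIFF stacks in, JSON/CSV out) used by the CLI.

#' Extract lens-outline points from a projection
#'
#' Bins bright pixels by angle around a provisional center (the intensity
#' centroid of the thresholded image) and keeps the outermost bright pixel
#' per angular bin. On an anterior projection these trace the projected lens
#' rim; on an equatorial projection the outline is only populated where the
#' limb carries nuclei, so the usable angular range can be restricted.
#'
#' @param img a [lens_projection()].
#' @param n_rays number of angular bins.
#' @param threshold intensity threshold; default is a quarter of the way
#'   from the median to the 99.9th percentile.
#' @param angle_range optional length-2 vector (radians): keep bins whose
#'   angle from the provisional center lies in this interval.
#' @return data frame of `x`, `y` rim coordinates, micrometres.
#' @export
extract_rim_points <- function(img, n_rays = 720, threshold = NULL,
                               angle_range = NULL) {
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (is.null(threshold)) {
    bg <- median(m)
    threshold <- bg + 0.25 * (quantile(m, 0.999, names = FALSE) - bg)
  }
  idx <- which(m > threshold)
  if (length(idx) < n_rays / 4)
    stop("rim extraction failed: too few pixels above threshold")
  i <- (idx - 1) %% nrow(m) + 1
  j <- (idx - 1) %/% nrow(m) + 1
  um <- pixel_to_um(img, i, j)
  w <- m[idx]
  cx <- sum(w * um$x) / sum(w); cy <- sum(w * um$y) / sum(w)
  ang <- atan2(um$y - cy, um$x - cx)
  r <- sqrt((um$x - cx)^2 + (um$y - cy)^2)
  bin <- floor((ang + pi) / (2 * pi) * n_rays)
  if (!is.null(angle_range)) {
    keep <- ((ang - angle_range[1]) %% (2 * pi)) <=
      ((angle_range[2] - angle_range[1]) %% (2 * pi))
    bin <- bin[keep]; r <- r[keep]; um <- um[keep, , drop = FALSE]
  }
  o <- order(bin, -r)
  sel <- o[!duplicated(bin[o])]
  data.frame(x = um$x[sel], y = um$y[sel])
}

#' Robust circle fit to rim points
#'
#' Taubin fit with iterated trimming of points whose radial residual exceeds
#' 3 median absolute deviations — bright debris or sparse limb coverage
#' should not drag the lens outline.
#'
#' @param x,y rim point coordinates.
#' @param iterations trimming iterations.
#' @return a [fit_circle()] result.
#' @export
robust_circle_fit <- function(x, y, iterations = 3) {
  fit <- fit_circle(x, y)
  for (it in seq_len(iterations)) {
    r <- sqrt((x - fit$center[1])^2 + (y - fit$center[2])^2)
    res <- r - fit$diameter / 2
    s <- max(mad(res), 1e-9)
    keep <- abs(res) <= 3 * s
    if (all(keep) || sum(keep) < 3) break
    x <- x[keep]; y <- y[keep]
    fit <- fit_circle(x, y)
  }
  fit
}

recenter_records <- function(records, center) {
  records$x <- records$x - center[1]
  records$y <- records$y - center[2]
  records
}

#' Count epithelial cells from four projections
#'
#' The core measurement: given maximum-intensity projections of the DNA and
#' EdU channels in the anterior and equatorial aspects (sub-epithelial
#' signal already removed), fits the lens outline in each view, detects
#' nuclei, registers the views through the EdU constellations, selects the
#' fiduciary nucleus, counts DNA nuclei in the 60 degree anterior sector and
#' the 10 degree equatorial trapezoid, and extrapolates azimuthally.
#'
#' @param anterior_dna,anterior_edu,equatorial_dna,equatorial_edu
#'   [lens_projection()] objects.
#' @param margin_colatitude colatitude of the epithelial margin, radians
#'   (a configured parameter of the protocol; default 95 degrees).
#' @param anterior_angle anterior sector central angle, degrees.
#' @param equatorial_width trapezoid longitude width, degrees.
#' @param detect_dna,detect_edu [detect_params()] per channel.
#' @param tolerance registration pairing tolerance, um.
#' @param placement sector placement relative to the fiduciary
#'   (see [anterior_sector()]).
#' @param provenance named list merged into the result's provenance.
#' @return list of class `lens_count`: `result` (a [count_result()]),
#'   `sector`, `trapezoid`, `match`, `fiduciary`, `anterior_fit`,
#'   `equatorial_fit`, and the per-view records.
#' @export
count_from_projections <- function(anterior_dna, anterior_edu,
                                   equatorial_dna, equatorial_edu,
                                   margin_colatitude = deg2rad(95),
                                   anterior_angle = 60,
                                   equatorial_width = 10,
                                   detect_dna = detect_params(),
                                   detect_edu = detect_dna,
                                   tolerance = 12,
                                   placement = "edge",
                                   provenance = list()) {
  rimA <- extract_rim_points(anterior_dna)
  fitA <- robust_circle_fit(rimA$x, rimA$y)
  rimE <- extract_rim_points(equatorial_dna,
                             angle_range = deg2rad(c(-15, 195)))
  fitE <- robust_circle_fit(rimE$x, rimE$y)

  recA_dna <- recenter_records(detect_nuclei(anterior_dna, detect_dna),
                               fitA$center)
  recA_edu <- recenter_records(detect_nuclei(anterior_edu, detect_edu),
                               fitA$center)
  recE_dna <- recenter_records(detect_nuclei(equatorial_dna, detect_dna),
                               fitE$center)
  recE_edu <- recenter_records(detect_nuclei(equatorial_edu, detect_edu),
                               fitE$center)
  if (nrow(recA_edu) == 0 || nrow(recE_edu) == 0)
    stop("no EdU nuclei detected in the ",
         if (nrow(recA_edu) == 0) "anterior" else "equatorial",
         " view; check the EdU channel and detection threshold")

  R_ant <- fitA$diameter / 2
  R_eq <- fitE$diameter / 2
  match <- match_constellations(recA_edu, recE_edu, R_ant,
                                tolerance = tolerance)
  fid <- select_fiduciary(match, recA_edu, recE_edu, R_eq)

  sector <- anterior_sector(c(0, 0), fid$anterior_position,
                            central_angle = deg2rad(anterior_angle),
                            placement = placement)
  margin_y <- R_eq * cos(margin_colatitude)
  trap <- equatorial_trapezoid(fid$equatorial_position[2], margin_y, R_eq,
                               longitude_width = deg2rad(equatorial_width))
  n_as <- count_in_region(recA_dna, sector)
  n_es <- count_in_region(recE_dna, trap)
  prov <- c(provenance,
            list(lens_radius_anterior_um = R_ant,
                 lens_radius_equatorial_um = R_eq,
                 margin_colatitude_deg = rad2deg(margin_colatitude),
                 view_azimuth_deg = rad2deg(match$view_azimuth),
                 n_registration_inliers = match$n_inliers,
                 fiduciary_ids = unname(fid$id_pair),
                 sector_placement = placement,
                 package_version = as.character(utils::packageVersion("lenscount"))))
  res <- count_result(n_as, n_es, anterior_angle, equatorial_width,
                      fiduciary_colatitude = rad2deg(fid$colatitude),
                      provenance = prov)
  structure(list(result = res, sector = sector, trapezoid = trap,
                 match = match, fiduciary = fid,
                 anterior_fit = fitA, equatorial_fit = fitE,
                 records = list(anterior_dna = recA_dna,
                                anterior_edu = recA_edu,
                                equatorial_dna = recE_dna,
                                equatorial_edu = recE_edu)),
            class = "lens_count")
}

#' @export
print.lens_count <- function(x, ...) {
  print(x$result)
  print(x$match)
  print(x$fiduciary)
  invisible(x)
}

#' Pipeline configuration
#'
#' @param anterior_dna,anterior_edu,equatorial_dna,equatorial_edu paths to
#'   single-channel multi-page TIFF stacks (ignored when projections are
#'   supplied directly to [count_lens()]).
#' @param out_dir output directory.
#' @param margin_colatitude_deg epithelial margin colatitude, degrees; used
#'   unless `margin_y_um` is given.
#' @param margin_y_um alternative margin specification: projection height of
#'   the margin on the equatorial view, um.
#' @param anterior_angle_deg,equatorial_width_deg counting-region angles.
#' @param shell_thickness retained epithelial shell depth for sub-surface
#'   cleanup, um.
#' @param tolerance registration pairing tolerance, um.
#' @param mask_anterior also depth-mask the anterior stack (default TRUE).
#' @param detect_dna,detect_edu [detect_params()] per channel.
#' @param seed integer seed recorded in provenance.
#' @return list of class `lens_config`.
#' @export
lens_config <- function(anterior_dna = NULL, anterior_edu = NULL,
                        equatorial_dna = NULL, equatorial_edu = NULL,
                        out_dir = ".",
                        margin_colatitude_deg = 95, margin_y_um = NULL,
                        anterior_angle_deg = 60, equatorial_width_deg = 10,
                        shell_thickness = 15, tolerance = 12,
                        mask_anterior = TRUE,
                        detect_dna = detect_params(),
                        detect_edu = detect_dna,
                        seed = 1L) {
  stopifnot(anterior_angle_deg > 0, anterior_angle_deg <= 360,
            equatorial_width_deg > 0, equatorial_width_deg <= 360)
  structure(as.list(environment()), class = "lens_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Angles are degrees in the file; detection parameter blocks are nested
#' lists.
#'
#' @param path YAML file.
#' @param config a [lens_config()].
#' @return `read_lens_config` returns a [lens_config()].
#' @export
read_lens_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (ch in c("detect_dna", "detect_edu"))
    if (!is.null(y[[ch]])) y[[ch]] <- do.call(detect_params, y[[ch]])
  do.call(lens_config, y)
}

#' @rdname read_lens_config
#' @export
write_lens_config <- function(config, path) {
  y <- unclass(config)
  for (ch in c("detect_dna", "detect_edu")) y[[ch]] <- unclass(y[[ch]])
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

# simulator params <-> YAML, angles in degrees in the file
#' @rdname read_lens_config
#' @param params a [lens_sim_params()] (for `write_sim_params`).
#' @export
write_sim_params <- function(params, path) {
  p <- unclass(params)
  for (f in c("margin_colatitude", "germinative_zone", "meridional_extent",
              "fiber_zone")) {
    p[[paste0(f, "_deg")]] <- rad2deg(p[[f]])
    p[[f]] <- NULL
  }
  yaml::write_yaml(p, path)
  invisible(path)
}

#' @rdname read_lens_config
#' @export
read_sim_params <- function(path) {
  p <- yaml::read_yaml(path)
  for (f in c("margin_colatitude", "germinative_zone", "meridional_extent",
              "fiber_zone")) {
    d <- paste0(f, "_deg")
    if (!is.null(p[[d]])) { p[[f]] <- deg2rad(unlist(p[[d]])); p[[d]] <- NULL }
  }
  p$germinative_zone <- unlist(p$germinative_zone)
  p$fiber_zone <- unlist(p$fiber_zone)
  do.call(lens_sim_params, p)
}

#' Simulate a lens and write its stacks and ground truth to disk
#'
#' Writes `ground_truth.csv`, `params.yaml` and four multi-page TIFF stacks
#' (anterior/equatorial x DNA/EdU). Bit-identical on re-run with the same
#' parameters.
#'
#' @param params a [lens_sim_params()].
#' @param out_dir output directory (created if missing).
#' @param view_azimuth azimuth of the simulated equatorial view, radians.
#' @return named character vector of the files written, invisibly.
#' @export
simulate_lens <- function(params, out_dir, view_azimuth = deg2rad(30)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- sample_epithelium(params)
  paths <- c(ground_truth = file.path(out_dir, "ground_truth.csv"),
             params = file.path(out_dir, "params.yaml"))
  write_ground_truth(gt, paths["ground_truth"])
  write_sim_params(params, paths["params"])
  for (aspect in c("anterior", "equatorial"))
    for (channel in c("dna", "edu")) {
      st <- render_stack(gt, aspect, channel, view_azimuth = view_azimuth,
                         params = params)
      f <- file.path(out_dir, sprintf("%s_%s.tif", aspect, channel))
      write_tiff_stack(st, f)
      paths[paste(aspect, channel, sep = "_")] <- f
      rm(st)
    }
  invisible(paths)
}

#' Run the full counting pipeline on stacks from disk
#'
#' Reads the four stacks named in the config, removes sub-epithelial signal
#' by depth masking against a sphere fitted to the bright shell, collapses
#' to maximum-intensity projections, and runs [count_from_projections()].
#' Writes the count result (JSON + one-row CSV), the region sidecars, the
#' registration report and audit overlays into `config$out_dir`.
#'
#' @param config a [lens_config()] (or path to its YAML).
#' @param write_outputs write result files (default TRUE).
#' @return the `lens_count` object, invisibly.
#' @export
count_lens <- function(config, write_outputs = TRUE) {
  if (is.character(config)) config <- read_lens_config(config)
  paths <- unlist(config[c("anterior_dna", "anterior_edu",
                           "equatorial_dna", "equatorial_edu")])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  load_view <- function(dna_path, edu_path, mask) {
    dna <- read_tiff_stack(dna_path)
    edu <- read_tiff_stack(edu_path)
    if (mask) {
      surf <- fit_lens_surface(dna)
      dna <- shell_mask(dna, surf, config$shell_thickness)
      edu <- shell_mask(edu, surf, config$shell_thickness)
    }
    list(dna = max_project(dna), edu = max_project(edu))
  }
  ant <- load_view(config$anterior_dna, config$anterior_edu,
                   config$mask_anterior)
  eq <- load_view(config$equatorial_dna, config$equatorial_edu, TRUE)

  margin <- if (!is.null(config$margin_y_um)) {
    # convert the measured margin height to a colatitude inside the counter
    rim <- extract_rim_points(eq$dna, angle_range = deg2rad(c(-15, 195)))
    fit <- robust_circle_fit(rim$x, rim$y)
    acos(pmin(1, pmax(-1, (config$margin_y_um - fit$center[2]) /
                        (fit$diameter / 2))))
  } else deg2rad(config$margin_colatitude_deg)

  lc <- count_from_projections(
    ant$dna, ant$edu, eq$dna, eq$edu,
    margin_colatitude = margin,
    anterior_angle = config$anterior_angle_deg,
    equatorial_width = config$equatorial_width_deg,
    detect_dna = config$detect_dna, detect_edu = config$detect_edu,
    tolerance = config$tolerance,
    provenance = list(seed = config$seed,
                      inputs = as.list(paths),
                      shell_thickness_um = config$shell_thickness))
  if (write_outputs) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write_count_result(lc$result, file.path(od, "count_result.json"),
                       file.path(od, "count_result.csv"))
    region_to_json(lc$sector, file.path(od, "anterior_sector.json"))
    region_to_json(lc$trapezoid, file.path(od, "equatorial_trapezoid.json"))
    match_to_json(lc$match, lc$fiduciary,
                  file.path(od, "registration.json"))
    write_records(lc$records$anterior_dna,
                  file.path(od, "anterior_dna_records.csv"))
    write_records(lc$records$equatorial_dna,
                  file.path(od, "equatorial_dna_records.csv"))
    write_tiff_stack(draw_region_overlay(ant$dna, lc$sector,
                                         lc$records$anterior_dna,
                                         center = lc$anterior_fit$center),
                     file.path(od, "anterior_overlay.tif"))
    write_tiff_stack(draw_region_overlay(eq$dna, lc$trapezoid,
                                         lc$records$equatorial_dna,
                                         center = lc$equatorial_fit$center),
                     file.path(od, "equatorial_overlay.tif"))
  }
  invisible(lc)
}

#' Burn a counting region and counted centroids into a projection
#'
#' Audit overlay: the region outline and the centroids counted inside it are
#' set to 1.1x the image maximum so the geometry can be reviewed in any
#' TIFF viewer.
#'
#' @param img the [lens_projection()] that was counted.
#' @param region the counting region (in lens-centered coordinates).
#' @param records the records counted (lens-centered coordinates), optional.
#' @param center the fitted lens center used to re-center the records, um.
#' @return a [lens_projection()] with the overlay burned in.
#' @export
draw_region_overlay <- function(img, region, records = NULL,
                                center = c(0, 0)) {
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  hi <- 1.1 * max(m, 1)
  ps <- attr(img, "pixel_size"); o <- attr(img, "origin")
  mark <- function(x, y) {
    # region/record coordinates are lens-centered; shift back to the image
    j <- round((x + center[1] - o[1]) / ps) + 1
    i <- round((o[2] - (y + center[2])) / ps) + 1
    ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
    m[cbind(i[ok], j[ok])] <<- hi
  }
  if (inherits(region, "anterior_sector")) {
    a <- region$orientation + region$central_angle / 2 * c(-1, 1)
    th <- seq(a[1], a[2], length.out = 512)
    mark(region$center[1] + region$sector_radius * cos(th),
         region$center[2] + region$sector_radius * sin(th))
    for (ang in a) {
      rr <- seq(0, region$sector_radius, by = ps / 2)
      mark(region$center[1] + rr * cos(ang),
           region$center[2] + rr * sin(ang))
    }
  } else if (inherits(region, "equatorial_trapezoid")) {
    t <- region
    v <- rbind(c(t$center_x - t$a / 2, t$top_y),
               c(t$center_x + t$a / 2, t$top_y),
               c(t$center_x + t$b / 2, t$base_y),
               c(t$center_x - t$b / 2, t$base_y),
               c(t$center_x - t$a / 2, t$top_y))
    for (k in 1:4) {
      s <- seq(0, 1, length.out = 256)
      mark(v[k, 1] + s * (v[k + 1, 1] - v[k, 1]),
           v[k, 2] + s * (v[k + 1, 2] - v[k, 2]))
    }
  }
  if (!is.null(records) && nrow(records)) {
    inside <- if (inherits(region, "anterior_sector"))
      point_in_sector(records$x, records$y, region)
    else point_in_trapezoid(records$x, records$y, region)
    mark(records$x[inside], records$y[inside])
  }
  lens_projection(m, ps, origin = o, channel = attr(img, "channel"),
                  aspect = attr(img, "aspect"),
                  view_azimuth = attr(img, "view_azimuth"))
}

#' Human-readable report of a serialized count result
#'
#' Prints the counts, angles, fiduciary colatitude and provenance of a
#' result written by [count_lens()]; flags an empty count.
#'
#' @param json_path path to `count_result.json`.
#' @return the [count_result()], invisibly.
#' @export
report_count <- function(json_path) {
  res <- read_count_result(json_path)
  print(res)
  if (res$n_total == 0)
    cat("  WARNING: empty count - no nuclei fell inside the regions\n")
  prov <- res$provenance
  if (length(prov)) {
    cat("  provenance:\n")
    for (nm in names(prov))
      cat(sprintf("    %s: %s\n", nm,
                  paste(format(unlist(prov[[nm]]), digits = 6),
                        collapse = ", ")))
  }
  invisible(res)
}
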
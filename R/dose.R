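#' Static beam specification
#'
#' Geometry of one kV beam: the source sits at `source_axis_distance` from
#' the isocenter along the direction obtained by rotating the +z axis by
#' the gantry angle (right-handed about +y) and then the couch angle
#' (right-handed about +z); the beam points from the source to the
#' isocenter and is collimated to a square `field_size` (mm) measured at
#' the isocenter plane.
#'
#' @param gantry_angle,couch_angle Degrees.
#' @param field_size Field side lengths at isocenter, mm (length 1 or 2).
#' @param source_axis_distance Source-axis distance (SAD), mm.
#' @param isocenter World coordinates of the isocenter, mm.
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(gantry_angle = 0, couch_angle = 0, field_size = c(3, 3),
                      source_axis_distance = 350, isocenter = c(0, 0, 0)) {
  field_size <- rep(as.numeric(field_size), length.out = 2)
  if (any(field_size <= 0)) stop("field_size must be positive")
  if (source_axis_distance <= 0) stop("SAD must be positive")
  structure(list(gantry_angle = gantry_angle, couch_angle = couch_angle,
                 field_size = field_size,
                 source_axis_distance = source_axis_distance,
                 isocenter = as.numeric(isocenter)),
            class = "beam_spec")
}

#' Arc specification
#'
#' A gantry arc at fixed couch angle, discretized into
#' `arc_span / angular_step` equal-weight static beams placed at the
#' midpoints of the angular intervals (so the dose is covariant under
#' rotation of the start angle).
#'
#' @param arc_span Arc length in degrees (default 120).
#' @param couch_angle Couch angle in degrees.
#' @param angular_step Discretization step in degrees; must divide the
#'   span (default 5).
#' @param gantry_start Start angle of the arc (default `-arc_span / 2`).
#' @inheritParams beam_spec
#' @return An `arc_spec` object.
#' @export
arc_spec <- function(arc_span = 120, couch_angle = 0, angular_step = 5,
                     gantry_start = -arc_span / 2, field_size = c(3, 3),
                     source_axis_distance = 350, isocenter = c(0, 0, 0)) {
  if (arc_span <= 0) stop("arc_span must be positive")
  k <- arc_span / angular_step
  if (abs(k - round(k)) > 1e-9) stop("angular_step must divide arc_span")
  structure(list(arc_span = arc_span, couch_angle = couch_angle,
                 angular_step = angular_step, gantry_start = gantry_start,
                 field_size = rep(as.numeric(field_size), length.out = 2),
                 source_axis_distance = source_axis_distance,
                 isocenter = as.numeric(isocenter)),
            class = "arc_spec")
}

#' Treatment plan specification
#'
#' @param segments List of [beam_spec()]s and/or [arc_spec()]s.
#' @param prescription_dose Prescribed dose in Gy (default 15), delivered
#'   as the mean dose over the target volume (a D50-based normalization is
#'   available in [plan_dose()]).
#' @param target List with `center` (mm) and `diameter` (mm, default 2.5)
#'   of the spherical target volume of interest.
#' @return A `plan_spec` object.
#' @export
plan_spec <- function(segments, prescription_dose = 15,
                      target = list(center = c(0, 0, 0), diameter = 2.5)) {
  if (length(segments) == 0) stop("plan needs at least one segment")
  if (prescription_dose <= 0) stop("prescription must be positive")
  structure(list(segments = segments, prescription_dose = prescription_dose,
                 target = target),
            class = "plan_spec")
}

# Rotation matrices (right-handed, degrees).
rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

# Source position and orthonormal beam frame for a static beam.
beam_geometry <- function(beam) {
  dir_src <- as.numeric(rot_z(beam$couch_angle) %*% rot_y(beam$gantry_angle) %*% c(0, 0, 1))
  source <- beam$isocenter + beam$source_axis_distance * dir_src
  axis <- -dir_src                      # unit vector source -> isocenter
  ref <- if (abs(axis[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- c(axis[2] * ref[3] - axis[3] * ref[2],
          axis[3] * ref[1] - axis[1] * ref[3],
          axis[1] * ref[2] - axis[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(source = source, axis = axis, e1 = e1, e2 = e2)
}

#' Spherical volume of interest on a voxel grid
#'
#' Voxels whose centres lie within `diameter / 2` of `center`.
#'
#' @param center World coordinates in mm.
#' @param diameter Sphere diameter in mm.
#' @param grid An [image_volume()] supplying the grid.
#' @return Logical array on the grid.
#' @export
sphere_voi <- function(center, diameter, grid) {
  coords <- axis_coords(grid)
  r2 <- (diameter / 2)^2
  m <- outer(outer((coords[[1]] - center[1])^2, (coords[[2]] - center[2])^2, "+"),
             (coords[[3]] - center[3])^2, "+") <= r2
  if (!any(m)) stop("empty VOI: sphere does not cover any voxel centre")
  m
}

#' Radiological path length
#'
#' Exact voxel-intersection (Siddon) line integral of the linear
#' attenuation map between a source and one or more points, dimensionless
#' (`mu` in 1/mm, lengths in mm).  Regions outside the grid contribute
#' zero.
#'
#' @param mu An [image_volume()] of linear attenuation in 1/mm.
#' @param source World coordinates of the source, mm.
#' @param points Numeric vector (one point) or n x 3 matrix.
#' @return Numeric vector of attenuation integrals.
#' @export
radiological_path <- function(mu, source, points) {
  stopifnot(inherits(mu, "image_volume"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  radiological_paths_cpp(mu$data, dim(mu$data), mu$spacing, mu$origin,
                         as.numeric(source), points)
}

#' Dose of a single static kV beam
#'
#' Primary-photon model at a single effective energy: inside the diverging
#' field cone the dose is `(SAD / r)^2 * exp(-radiological path) *
#' mu_en/rho` at the voxel, zero outside; `r` is the source-voxel
#' distance.  Output is in arbitrary machine units until a plan is
#' normalized to its prescription.
#'
#' @param props Property volumes from [assign_properties()].
#' @param beam A [beam_spec()].
#' @return An [image_volume()] of dose (machine units).
#' @export
beam_dose <- function(props, beam) {
  mu <- props$mu
  d <- dim(mu$data)
  geo <- beam_geometry(beam)
  coords <- axis_coords(mu)
  rel <- lapply(1:3, function(a) coords[[a]] - geo$source[a])
  proj <- function(e) {
    outer(outer(rel[[1]] * e[1], rel[[2]] * e[2], "+"), rel[[3]] * e[3], "+")
  }
  tax <- proj(geo$axis)
  u <- proj(geo$e1)
  v <- proj(geo$e2)
  sad <- beam$source_axis_distance
  half <- beam$field_size / 2
  inside <- tax > 1e-6 &
    abs(u) * sad <= half[1] * tax &
    abs(v) * sad <= half[2] * tax
  idx <- which(inside)
  dose <- array(0, d)
  if (length(idx)) {
    ai <- arrayInd(idx, d)
    pts <- cbind(coords[[1]][ai[, 1]], coords[[2]][ai[, 2]], coords[[3]][ai[, 3]])
    paths <- radiological_paths_cpp(mu$data, d, mu$spacing, mu$origin,
                                    geo$source, pts)
    r2 <- (pts[, 1] - geo$source[1])^2 + (pts[, 2] - geo$source[2])^2 +
      (pts[, 3] - geo$source[3])^2
    dose[idx] <- sad^2 / r2 * exp(-paths) * props$mu_en_rho$data[idx]
  }
  volume_like(dose, mu)
}

# Expand a plan's segments into a flat list of equal-weight static beams.
expand_segments <- function(segments) {
  beams <- list()
  for (s in segments) {
    if (inherits(s, "beam_spec")) {
      beams <- c(beams, list(s))
    } else if (inherits(s, "arc_spec")) {
      nb <- round(s$arc_span / s$angular_step)
      angles <- s$gantry_start + (seq_len(nb) - 0.5) * s$angular_step
      beams <- c(beams, lapply(angles, function(g) {
        beam_spec(gantry_angle = g, couch_angle = s$couch_angle,
                  field_size = s$field_size,
                  source_axis_distance = s$source_axis_distance,
                  isocenter = s$isocenter)
      }))
    } else stop("plan segments must be beam_spec or arc_spec objects")
  }
  beams
}

#' Dose of a full plan, normalized to its prescription
#'
#' Sums the equal-weight static-beam doses of all segments (arcs are
#' discretized at their angular step) and scales the total so that the
#' prescription is met in the target sphere: mean target dose (default) or
#' median (D50) equals `prescription_dose`.
#'
#' @param props Property volumes from [assign_properties()].
#' @param plan A [plan_spec()].
#' @param normalization `"mean"` (default) or `"d50"`.
#' @return An [image_volume()] of dose in Gy, with attributes `scale` (the
#'   machine-unit scaling applied), `voi` (target mask) and `n_beams`.
#' @export
plan_dose <- function(props, plan, normalization = c("mean", "d50")) {
  normalization <- match.arg(normalization)
  beams <- expand_segments(plan$segments)
  total <- array(0, dim(props$mu$data))
  for (b in beams) total <- total + beam_dose(props, b)$data
  voi <- sphere_voi(plan$target$center, plan$target$diameter, props$mu)
  ref <- if (normalization == "mean") mean(total[voi]) else median(total[voi])
  if (!is.finite(ref) || ref <= 0) {
    stop("prescription error: plan delivers no dose to the target")
  }
  scale <- plan$prescription_dose / ref
  out <- volume_like(total * scale, props$mu)
  attr(out, "scale") <- scale
  attr(out, "voi") <- voi
  attr(out, "n_beams") <- length(beams)
  out
}
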
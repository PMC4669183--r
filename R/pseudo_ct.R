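#' Bulk tissue property table for kV dosimetry
#'
#' Per-class mass density, linear attenuation coefficient and mass
#' energy-absorption coefficient at a single effective energy of about
#' 40 keV (a 70 kVp beam).  The mass coefficients are standard tabulated
#' values for air, water-equivalent soft tissue and a cortical-bone
#' surrogate; linear attenuation is derived as density times the mass
#' coefficient and stored per millimetre.  Because CT- and MR-based plans
#' share the same table, relative CT-vs-MR dosimetry is insensitive to its
#' absolute calibration.
#'
#' @param density Named vector of mass densities in g/cm^3.
#' @param mass_atten Named vector of mass attenuation coefficients mu/rho
#'   in cm^2/g at the effective energy.
#' @param mass_en_abs Named vector of mass energy-absorption coefficients
#'   mu_en/rho in cm^2/g.
#' @return A `tissue_properties` data.frame with one row per class and
#'   columns `density`, `mu_mm` (1/mm) and `mu_en_rho` (cm^2/g).
#' @export
tissue_properties <- function(density = c(air = 0.0012, soft = 1.00, bone = 1.6),
                              mass_atten = c(air = 0.2485, soft = 0.2683, bone = 0.6655),
                              mass_en_abs = c(air = 0.0305, soft = 0.0647, bone = 0.3056)) {
  classes <- c("air", "soft", "bone")
  for (v in list(density, mass_atten, mass_en_abs)) {
    if (!all(classes %in% names(v))) stop("property tables must name air, soft and bone")
    if (any(v[classes] < 0)) stop("tissue properties must be non-negative")
  }
  if (!(density[["air"]] < density[["soft"]] && density[["soft"]] < density[["bone"]])) {
    stop("densities must be ordered air << soft < bone")
  }
  out <- data.frame(class = classes,
                    density = density[classes],
                    mu_mm = density[classes] * mass_atten[classes] / 10,
                    mu_en_rho = mass_en_abs[classes],
                    row.names = classes)
  class(out) <- c("tissue_properties", class(out))
  out
}

#' Convert a tissue label map into property volumes
#'
#' Purely local bulk assignment: each voxel receives the density, linear
#' attenuation and energy-absorption coefficient of its tissue class.
#' Applied to the reference CT segmentation this yields the reference
#' planning volume; applied to an ASMR image it yields the pseudo-CT.
#'
#' @param labels A [label_volume()].
#' @param table A [tissue_properties()] table.
#' @return List of [image_volume()]s: `density` (g/cm^3), `mu` (1/mm) and
#'   `mu_en_rho` (cm^2/g), plus the `labels` and `table` used.
#' @export
assign_properties <- function(labels, table = tissue_properties()) {
  stopifnot(inherits(labels, "label_volume"), inherits(table, "tissue_properties"))
  if (!all(labels$data %in% TISSUE_CODES)) stop("label outside {air, soft, bone}")
  idx <- labels$data + 1L
  d <- dim(labels$data)
  mk <- function(col) volume_like(array(table[[col]][idx], d), labels)
  list(density = mk("density"), mu = mk("mu_mm"), mu_en_rho = mk("mu_en_rho"),
       labels = labels, table = table)
}
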
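#' Synthetic rat-head phantom specification
#'
#' Defines the geometry of the digital phantom used to exercise the whole
#' MR-only planning workflow: an ellipsoidal soft-tissue head wrapped in a
#' thin skull shell, surrounded by air, with optional internal air cavities
#' and a set of thin coronal bone septa emulating the complex anterior
#' (rostrum) skull structure.  Defaults follow a 128^3 acquisition matrix
#' with 275 x 500 x 275 micrometre voxels.
#'
#' @param grid_shape Integer triple, grid size in voxels.
#' @param spacing Voxel spacing in mm.
#' @param head_axes Ellipsoid semi-axes of the head in mm (x, y, z); the
#'   long axis (y) is the anterior-posterior direction, anterior = +y.
#' @param skull_thickness Bone shell thickness in mm.
#' @param n_air_cavities Number of internal air pockets.
#' @param rostrum_complexity Number of thin anterior bone septa.
#' @param seed RNG seed controlling cavity and septum placement.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128),
                         spacing = c(0.275, 0.5, 0.275),
                         head_axes = c(11, 20, 11),
                         skull_thickness = 0.7,
                         n_air_cavities = 3,
                         rostrum_complexity = 3,
                         seed = 1) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  head_axes <- as.numeric(head_axes)
  if (any(grid_shape < 8)) stop("grid_shape must be at least 8 voxels per axis")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (any(head_axes <= 0)) stop("head_axes must be positive")
  if (skull_thickness < min(spacing)) {
    stop("skull_thickness must be at least one voxel along the thinnest spacing axis")
  }
  if (skull_thickness >= min(head_axes)) stop("skull_thickness must be smaller than head_axes")
  half_extent <- grid_shape * spacing / 2
  for (a in 1:3) {
    if (head_axes[a] + spacing[a] > half_extent[a]) {
      stop(sprintf(
        "grid too small along axis %s: head semi-axis %.2f mm + shell does not fit in half-extent %.2f mm",
        c("x", "y", "z")[a], head_axes[a], half_extent[a]))
    }
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 head_axes = head_axes, skull_thickness = skull_thickness,
                 n_air_cavities = as.integer(n_air_cavities),
                 rostrum_complexity = as.integer(rostrum_complexity),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared normalized ellipsoid radius field for semi-axes `ax` on the grid.
ellipsoid_r2 <- function(coords, ax) {
  x2 <- (coords[[1]] / ax[1])^2
  y2 <- (coords[[2]] / ax[2])^2
  z2 <- (coords[[3]] / ax[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

#' Generate the ground-truth tissue label map
#'
#' Builds a three-class label volume (air = 0, soft = 1, bone = 2): an
#' ellipsoidal head of soft tissue enclosed by a bone shell of the requested
#' thickness, with `n_air_cavities` internal air pockets in the posterior
#' head and `rostrum_complexity` thin coronal bone septa in the anterior
#' (rostrum) region.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
generate_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vol <- image_volume(array(0, d), spec$spacing)
  coords <- axis_coords(vol)
  ax_out <- spec$head_axes
  ax_in <- spec$head_axes - spec$skull_thickness
  r2_out <- ellipsoid_r2(coords, ax_out)
  r2_in <- ellipsoid_r2(coords, ax_in)
  labels <- array(TISSUE_CODES[["air"]], d)
  labels[r2_out <= 1] <- TISSUE_CODES[["bone"]]
  inside <- r2_in <= 1
  labels[inside] <- TISSUE_CODES[["soft"]]

  with_seed(spec$seed, {
    # Anterior coronal bone septa spanning the inner head cross-section,
    # each perforated by an airway aperture (which also keeps the soft
    # tissue 6-connected through the rostrum).
    if (spec$rostrum_complexity > 0) {
      yc <- sort(runif(spec$rostrum_complexity, 0.50, 0.85)) * ax_in[2]
      half <- 0.4 * spec$skull_thickness
      y <- coords[[2]]
      for (v in yc) {
        in_plate <- abs(y - v) <= half
        hx <- runif(1, -0.3, 0.3) * ax_in[1]
        hz <- runif(1, -0.3, 0.3) * ax_in[3]
        hole_r2 <- runif(1, 1.2, 1.8)^2
        if (!any(in_plate)) next
        hole <- outer((coords[[1]] - hx)^2, (coords[[3]] - hz)^2, "+") > hole_r2
        sel <- inside & rep(rep(in_plate, each = d[1]), times = d[3]) &
          aperm(array(hole, c(d[1], d[3], d[2])), c(1, 3, 2))
        labels[sel] <- TISSUE_CODES[["bone"]]
      }
    }
    # Internal air cavities in the posterior-to-central head.
    if (spec$n_air_cavities > 0) {
      for (i in seq_len(spec$n_air_cavities)) {
        repeat {
          ctr <- c(runif(1, -0.5, 0.5) * ax_in[1],
                   runif(1, -0.7, 0.30) * ax_in[2],
                   runif(1, -0.5, 0.5) * ax_in[3])
          if (sum((ctr / (0.8 * ax_in))^2) <= 1) break
        }
        rad <- runif(1, 1.0, 1.8)
        dx2 <- (coords[[1]] - ctr[1])^2
        dy2 <- (coords[[2]] - ctr[2])^2
        dz2 <- (coords[[3]] - ctr[3])^2
        sph <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rad^2
        labels[sph & labels == TISSUE_CODES[["soft"]]] <- TISSUE_CODES[["air"]]
      }
    }
  })
  label_volume(labels, spec$spacing)
}

#' MR sequence intensity model
#'
#' Describes how a named MR sequence renders the three tissue classes:
#' per-class mean intensities, Rician noise scale, and the amplitude and
#' correlation length of a smooth multiplicative bias field.  Conventional
#' sequences (T1, T2, UTE2) must render bone darker than soft tissue;
#' short-echo sequences (UTE1, ZTE) must render bone clearly above the air
#' background (at least 3 noise SDs), which is the contrast property the
#' segmentation relies on.
#'
#' @param name One of `"T1"`, `"T2"`, `"UTE1"`, `"UTE2"`, `"ZTE"`.
#' @param class_means Named numeric vector `c(air=, soft=, bone=)` of mean
#'   intensities (arbitrary units), non-negative.
#' @param noise_sigma Rician noise scale (intensity units).
#' @param bias_amplitude Maximum multiplicative deviation of the bias field
#'   from 1 (dimensionless, in `[0, 1)`).
#' @param bias_smoothness Correlation length of the bias field in mm.
#' @return A `sequence_model` object.
#' @export
sequence_model <- function(name, class_means, noise_sigma = 5,
                           bias_amplitude = 0.3, bias_smoothness = 12) {
  name <- match.arg(name, SEQUENCE_NAMES)
  if (!all(c("air", "soft", "bone") %in% names(class_means))) {
    stop("class_means must name air, soft and bone")
  }
  class_means <- class_means[c("air", "soft", "bone")]
  if (any(class_means < 0)) stop("class_means must be non-negative")
  if (name %in% c("T1", "T2", "UTE2") && class_means[["bone"]] >= class_means[["soft"]]) {
    stop(sprintf("%s is a conventional sequence: bone mean must be below soft mean", name))
  }
  if (name %in% c("UTE1", "ZTE") &&
      class_means[["bone"]] < class_means[["air"]] + 3 * noise_sigma) {
    stop(sprintf("%s is a short-TE sequence: bone mean must exceed air mean by >= 3 noise SDs", name))
  }
  if (bias_amplitude < 0 || bias_amplitude >= 1) stop("bias_amplitude must be in [0, 1)")
  structure(list(name = name, class_means = class_means,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 bias_smoothness = bias_smoothness),
            class = "sequence_model")
}

#' Default intensity models for the five MR sequences
#'
#' Synthetic intensity tables (arbitrary units) encoding the qualitative
#' contrast of each sequence: air gives no signal anywhere; bone is nearly
#' signal-free on the conventional T1/T2 sequences, weak on UTE2 (2 ms
#' echo), and bright on the short-echo UTE1 and ZTE sequences.  These are
#' configuration values, editable per call.
#'
#' @param noise_sigma Rician noise scale shared by all sequences (default 5,
#'   i.e. 5\% of the soft-tissue mean of 100).
#' @param bias_amplitude,bias_smoothness Bias-field parameters shared by all
#'   sequences.
#' @return Named list of [sequence_model()]s.
#' @export
default_sequence_models <- function(noise_sigma = 5, bias_amplitude = 0.3,
                                    bias_smoothness = 12) {
  means <- list(
    T1 = c(air = 0, soft = 100, bone = 8),
    T2 = c(air = 0, soft = 110, bone = 6),
    UTE1 = c(air = 0, soft = 100, bone = 140),
    UTE2 = c(air = 0, soft = 100, bone = 20),
    ZTE = c(air = 0, soft = 90, bone = 160)
  )
  setNames(lapply(SEQUENCE_NAMES, function(nm) {
    sequence_model(nm, means[[nm]], noise_sigma, bias_amplitude, bias_smoothness)
  }), SEQUENCE_NAMES)
}

# Smooth multiplicative bias field with mean exactly 1 over the grid and
# range within [1 - amplitude, 1 + amplitude].
make_bias_field <- function(d, spacing, amplitude, smoothness_mm) {
  if (amplitude == 0) return(array(1, d))
  g <- gaussian_smooth(array(rnorm(prod(d)), d), smoothness_mm, spacing,
                       normalize = TRUE)
  g <- g - mean(g)
  g <- g / max(abs(g))
  1 + amplitude * g
}

#' Simulate one MR acquisition of a label map
#'
#' The clean image is a per-voxel lookup of the class mean; a smooth
#' positive multiplicative bias field (mean 1, bounded by the model's
#' amplitude, correlation length `bias_smoothness`) is applied, and Rician
#' noise of scale `noise_sigma` corrupts the result, reproducing the
#' magnitude-image noise floor in signal-free air.
#'
#' @param labels A [label_volume()].
#' @param model A [sequence_model()].
#' @param seed RNG seed (bias field and noise).
#' @return List with elements `image`, `bias` and `clean`, all
#'   [image_volume()]s.
#' @export
simulate_mr <- function(labels, model, seed = 1) {
  stopifnot(inherits(labels, "label_volume"), inherits(model, "sequence_model"))
  d <- dim(labels$data)
  lut <- as.numeric(model$class_means)
  clean <- array(lut[labels$data + 1L], d)
  with_seed(seed, {
    bias <- make_bias_field(d, labels$spacing, model$bias_amplitude,
                            model$bias_smoothness)
    s <- clean * bias
    noisy <- if (model$noise_sigma > 0) {
      sqrt((s + model$noise_sigma * array(rnorm(prod(d)), d))^2 +
             (model$noise_sigma * array(rnorm(prod(d)), d))^2)
    } else s
  })
  list(image = volume_like(noisy, labels),
       bias = volume_like(bias, labels),
       clean = volume_like(clean, labels))
}

#' Simulate a reference CT of a label map
#'
#' Gaussian-noised Hounsfield-unit image from per-class HU means.  Default
#' means (air -1000, soft 40, bone 700 HU) are configuration values.
#'
#' @param labels A [label_volume()].
#' @param hu_means Named vector `c(air=, soft=, bone=)` in HU.
#' @param noise_sigma Gaussian noise SD in HU.
#' @param seed RNG seed.
#' @return An [image_volume()] in HU.
#' @export
simulate_ct <- function(labels, hu_means = c(air = -1000, soft = 40, bone = 700),
                        noise_sigma = 50, seed = 1) {
  stopifnot(inherits(labels, "label_volume"))
  if (!all(c("air", "soft", "bone") %in% names(hu_means))) {
    stop("hu_means must name air, soft and bone classes")
  }
  lut <- as.numeric(hu_means[c("air", "soft", "bone")])
  d <- dim(labels$data)
  clean <- array(lut[labels$data + 1L], d)
  noisy <- if (noise_sigma > 0) {
    with_seed(seed, clean + noise_sigma * array(rnorm(prod(d)), d))
  } else clean
  volume_like(noisy, labels)
}

#' Threshold segmentation of a CT volume
#'
#' Stand-in for the manual three-class CT segmentation used as planning
#' reference: voxels below `thresholds[1]` HU are air, above `thresholds[2]`
#' bone, soft tissue in between.  The default cut points are the midpoints
#' of the default class means of [simulate_ct()].
#'
#' @param ct An [image_volume()] in HU.
#' @param thresholds Two increasing HU cut points.
#' @return A [label_volume()].
#' @export
segment_ct <- function(ct, thresholds = c(-480, 370)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lab <- array(TISSUE_CODES[["soft"]], dim(ct$data))
  lab[ct$data < thresholds[1]] <- TISSUE_CODES[["air"]]
  lab[ct$data > thresholds[2]] <- TISSUE_CODES[["bone"]]
  label_volume(lab, ct$spacing, ct$origin)
}

#' Simulate a complete multi-sequence phantom dataset
#'
#' One synthetic "animal": ground-truth labels, five (or fewer) MR
#' acquisitions with their true bias fields, and a reference CT.
#'
#' @param spec A [phantom_spec()].
#' @param models Named list of [sequence_model()]s.
#' @param seed Master seed; per-sequence and CT seeds are derived from it.
#' @return List with `labels`, `images` (named list), `bias_fields`,
#'   `clean_images`, `ct` and `spec`.
#' @export
simulate_phantom <- function(spec, models = default_sequence_models(),
                             seed = spec$seed) {
  labels <- generate_labels(spec)
  seeds <- derive_seeds(seed, length(models) + 1L)
  images <- bias_fields <- clean <- list()
  for (i in seq_along(models)) {
    sim <- simulate_mr(labels, models[[i]], seeds[i])
    nm <- models[[i]]$name
    images[[nm]] <- sim$image
    bias_fields[[nm]] <- sim$bias
    clean[[nm]] <- sim$clean
  }
  ct <- simulate_ct(labels, seed = seeds[length(models) + 1L])
  list(labels = labels, images = images, bias_fields = bias_fields,
       clean_images = clean, ct = ct, spec = spec, seed = seed)
}

#' Inject an anterior-bone segmentation error
#'
#' Removes bone from the anterior (rostrum) part of a label map, relabelling
#' it as soft tissue.  This emulates the known failure mode of MR-based
#' segmentation in the complex anterior skull, where conventional sequences
#' see no bone signal: the MR-derived map then under-attenuates anterior
#' beam paths, so plans normalized on it under-dose the target when
#' delivered on the true anatomy.
#'
#' @param labels A [label_volume()].
#' @param y_frac Fraction of the anterior head half-length beyond which bone
#'   is removed (anterior = +y; default 0.35).
#' @param head_axes Head semi-axes in mm (used to locate the anterior
#'   region); defaults taken from [phantom_spec()] defaults.
#' @return A [label_volume()] with the anterior bone relabelled as soft.
#' @export
missegment_rostrum <- function(labels, y_frac = 0.35, head_axes = c(11, 20, 11)) {
  stopifnot(inherits(labels, "label_volume"))
  coords <- axis_coords(labels)
  d <- dim(labels$data)
  anterior <- coords[[2]] > y_frac * head_axes[2]
  sel <- rep(rep(anterior, each = d[1]), times = d[3]) &
    labels$data == TISSUE_CODES[["bone"]]
  out <- labels$data
  out[sel] <- TISSUE_CODES[["soft"]]
  label_volume(out, labels$spacing, labels$origin)
}
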
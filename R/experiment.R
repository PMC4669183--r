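#' Default beam arrangements for plan comparison
#'
#' The three arrangements used for CT-vs-MR dose comparison: a single
#' static 3 x 3 mm beam entering through the anterior skull (gantry 90,
#' couch 90), one coplanar 120-degree arc at couch 0, and three
#' non-coplanar 120-degree arcs at couch 0, 45 and 90 degrees.
#'
#' @param target List with `center` (mm) and `diameter` (mm) of the target
#'   sphere.
#' @param field_size Field size at isocenter in mm.
#' @param sad Source-axis distance in mm.
#' @param prescription_dose Prescription in Gy (default 15).
#' @param angular_step Arc discretization in degrees (default 5).
#' @return Named list of [plan_spec()]s: `beam1`, `arc1`, `arcs3`.
#' @export
default_plans <- function(target, field_size = c(3, 3), sad = 350,
                          prescription_dose = 15, angular_step = 5) {
  iso <- target$center
  mk_arc <- function(couch) {
    arc_spec(arc_span = 120, couch_angle = couch, angular_step = angular_step,
             field_size = field_size, source_axis_distance = sad,
             isocenter = iso)
  }
  list(
    beam1 = plan_spec(list(beam_spec(gantry_angle = 90, couch_angle = 90,
                                     field_size = field_size,
                                     source_axis_distance = sad,
                                     isocenter = iso)),
                      prescription_dose, target),
    arc1 = plan_spec(list(mk_arc(0)), prescription_dose, target),
    arcs3 = plan_spec(list(mk_arc(0), mk_arc(45), mk_arc(90)),
                      prescription_dose, target)
  )
}

#' Configuration of a full phantom experiment
#'
#' Bundles every parameter of the end-to-end workflow: phantom geometry,
#' sequence intensity models, bias correction, segmentation, target and
#' plans, the sequence combinations carried to planning, and the master
#' seed from which all per-animal seeds derive.
#'
#' @param n_animals Number of phantom "animals" (default 6).
#' @param phantom A [phantom_spec()].
#' @param models Named list of [sequence_model()]s.
#' @param correct_bias Run CLIC bias correction before segmentation.
#' @param clic A [clic_params()].
#' @param fcm List of [fcm_cluster()] parameters (`m`, `tol`, `max_iters`).
#' @param target Target sphere; default: 2.5 mm diameter centred in the
#'   anterior dorsal brain (30\% of the head length forward, 25\% up).
#' @param plans Named list of [plan_spec()]s; default [default_plans()].
#' @param methods List of sequence subsets used for MR-based planning.
#' @param seed Master seed.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(n_animals = 6,
                              phantom = phantom_spec(),
                              models = default_sequence_models(),
                              correct_bias = TRUE,
                              clic = clic_params(),
                              fcm = list(m = 2, tol = 1e-5, max_iters = 200),
                              target = NULL,
                              plans = NULL,
                              methods = list(c("ZTE", "UTE2"),
                                             c("T1", "UTE1", "T2"),
                                             c("UTE1", "UTE2")),
                              seed = 1) {
  if (n_animals < 1) stop("n_animals must be at least 1")
  avail <- names(models)
  for (m in methods) {
    if (!all(m %in% avail)) stop("methods must be subsets of the available sequences")
  }
  if (is.null(target)) {
    ax <- phantom$head_axes
    target <- list(center = c(0, 0.3 * ax[2], 0.25 * ax[3]), diameter = 2.5)
  }
  if (is.null(plans)) plans <- default_plans(target)
  structure(list(n_animals = as.integer(n_animals), phantom = phantom,
                 models = models, correct_bias = correct_bias, clic = clic,
                 fcm = fcm, target = target, plans = plans, methods = methods,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

combo_label <- function(subset) {
  paste(SEQUENCE_NAMES[SEQUENCE_NAMES %in% subset], collapse = "+")
}

# Bias-correct every sequence of one animal inside a preliminary head mask.
correct_animal <- function(images, clic) {
  pre_mask <- make_air_mask(images$T1)
  lapply(images, function(img) {
    st <- estimate_bias(img, pre_mask, clic)
    apply_correction(img, st, pre_mask)
  })
}

#' Run the end-to-end phantom experiment
#'
#' For each of `n_animals` phantoms (seeds derived from the master seed):
#' simulate the multi-sequence dataset, optionally bias-correct, build the
#' T1 head mask, segment every sequence combination, score each against
#' the CT-derived reference segmentation, then — for each planning method
#' and beam arrangement — normalize the plan on the MR-based pseudo-CT,
#' deliver it on the CT-based reference anatomy, and extract DVH metrics.
#' MR-planned metrics are normalized to the CT-planned reference and
#' compared by Mann-Whitney U tests across animals.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `dice_sweep.csv`, `dice_summary.csv`, `dose_metrics.csv`,
#'   `dose_summary.csv`, `mann_whitney.csv` and `provenance.json`.
#' @param verbose Print one progress line per stage.
#' @return List with `dice` (per-animal sweep tables), `dice_summary`,
#'   `dose_metrics`, `dose_summary`, `mann_whitney` and `provenance`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  seeds <- derive_seeds(config$seed, config$n_animals)
  dice_tables <- list()
  ct_rows <- mr_rows <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  for (i in seq_len(config$n_animals)) {
    stage <- "phantom"
    res <- tryCatch({
      spec_i <- config$phantom
      spec_i$seed <- seeds[i]
      ph <- simulate_phantom(spec_i, config$models, seed = seeds[i])
      say("animal %d: phantom simulated (seed %d)", i, seeds[i])

      stage <- "bias_correction"
      images <- if (config$correct_bias) correct_animal(ph$images, config$clic)
                else ph$images
      say("animal %d: bias correction %s", i,
          if (config$correct_bias) "done" else "skipped")

      stage <- "air_mask"
      mask <- make_air_mask(images$T1)

      stage <- "reference_segmentation"
      ref <- segment_ct(ph$ct)

      stage <- "fcm_sweep"
      sweep <- sweep_combinations(images, mask,
                                  m = config$fcm$m, tol = config$fcm$tol,
                                  max_iters = config$fcm$max_iters,
                                  seed = seeds[i])
      dice <- evaluate_sweep(ref, sweep)
      dice$animal <- i
      say("animal %d: %d combinations segmented", i, nrow(dice))

      stage <- "planning"
      props_ct <- assign_properties(ref)
      labels_by_combo <- setNames(sweep, vapply(sweep, function(a)
        combo_label(a$combination), ""))
      ct_m <- mr_m <- list()
      for (pn in names(config$plans)) {
        dose_ct <- plan_dose(props_ct, config$plans[[pn]])
        voi <- attr(dose_ct, "voi")
        met_ct <- dvh_metrics(dose_ct, voi)
        ct_m[[pn]] <- data.frame(animal = i, plan = pn, t(met_ct))
        for (meth in config$methods) {
          lbl <- combo_label(meth)
          asmr <- labels_by_combo[[lbl]]
          if (is.null(asmr)) stop(sprintf("method %s not found in sweep", lbl))
          props_mr <- assign_properties(asmr$labels)
          dose_mr <- plan_dose(props_mr, config$plans[[pn]])
          # plan normalized on MR, delivered on the CT reference anatomy
          delivered <- attr(dose_mr, "scale") / attr(dose_ct, "scale") * met_ct
          mr_m[[paste(pn, lbl)]] <- data.frame(animal = i, plan = pn,
                                               method = lbl, t(delivered))
        }
      }
      say("animal %d: planning done", i)
      list(dice = dice, ct = do.call(rbind, ct_m), mr = do.call(rbind, mr_m))
    }, error = function(e) {
      stop(sprintf("experiment failed at stage '%s' for animal %d: %s",
                   stage, i, conditionMessage(e)), call. = FALSE)
    })
    dice_tables[[i]] <- res$dice
    ct_rows[[i]] <- res$ct
    mr_rows[[i]] <- res$mr
  }

  ct_metrics <- do.call(rbind, ct_rows)
  mr_metrics <- do.call(rbind, mr_rows)
  rownames(ct_metrics) <- rownames(mr_metrics) <- NULL
  cmp <- compare_to_ct(ct_metrics, mr_metrics)

  mw <- list()
  if (config$n_animals >= 2) {
    for (pn in unique(mr_metrics$plan)) {
      for (meth in unique(mr_metrics$method)) {
        for (m in c("D5", "D50", "D90")) {
          a <- mr_metrics[[m]][mr_metrics$plan == pn & mr_metrics$method == meth]
          b <- ct_metrics[[m]][ct_metrics$plan == pn]
          t <- mann_whitney(a, b)
          mw[[length(mw) + 1L]] <- data.frame(plan = pn, method = meth,
                                              metric = m, U = t$U,
                                              p_value = t$p_value,
                                              exact = t$exact)
        }
      }
    }
  }
  mw <- if (length(mw)) do.call(rbind, mw) else NULL

  dice_all <- do.call(rbind, dice_tables)
  rownames(dice_all) <- NULL
  dice_summary <- aggregate_dice(dice_tables)

  provenance <- list(
    package_version = as.character(utils::packageVersion("mr2plan")),
    master_seed = config$seed, animal_seeds = seeds,
    n_animals = config$n_animals,
    phantom = unclass(config$phantom),
    models = lapply(config$models, unclass),
    correct_bias = config$correct_bias,
    clic = unclass(config$clic), fcm = config$fcm,
    target = config$target,
    methods = lapply(config$methods, combo_label),
    plans = lapply(config$plans, function(p) {
      list(prescription_dose = p$prescription_dose,
           segments = lapply(p$segments, unclass))
    })
  )

  out <- list(dice = dice_all, dice_summary = dice_summary,
              dose_metrics = list(ct = ct_metrics, mr = mr_metrics),
              dose_per_animal = cmp$per_animal, dose_summary = cmp$summary,
              mann_whitney = mw, provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(dice_all, file.path(out_dir, "dice_sweep.csv"), row.names = FALSE)
    write.csv(dice_summary, file.path(out_dir, "dice_summary.csv"), row.names = FALSE)
    write.csv(cmp$per_animal, file.path(out_dir, "dose_metrics.csv"), row.names = FALSE)
    write.csv(cmp$summary, file.path(out_dir, "dose_summary.csv"), row.names = FALSE)
    if (!is.null(mw)) {
      write.csv(mw, file.path(out_dir, "mann_whitney.csv"), row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
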
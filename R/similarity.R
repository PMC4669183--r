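#' 3D Dice coefficient for one tissue class
#'
#' `D = 2 |A_t intersect B_t| / (|A_t| + |B_t|)` for the voxels labelled
#' `tissue` in the two volumes.  If the class is absent from both volumes
#' the agreement is vacuous and 1 is returned with a warning.
#'
#' @param ref,test [label_volume()]s on the same grid.
#' @param tissue `"air"`, `"soft"` or `"bone"` (or the integer code).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_class <- function(ref, test, tissue) {
  stop_if_grid_mismatch(ref, test)
  code <- if (is.character(tissue)) TISSUE_CODES[[tissue]] else as.integer(tissue)
  a <- ref$data == code
  b <- test$data == code
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning(sprintf("class %s absent from both volumes; Dice is vacuously 1", tissue))
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Per-class Dice report for one segmentation
#'
#' Bone and soft-tissue Dice are the planning-relevant measures and their
#' mean is the ranking score; air Dice is reported as a diagnostic only.
#'
#' @param ref Reference [label_volume()].
#' @param asmr An `asmr_image` (or a [label_volume()]); `combination` names
#'   the row.
#' @param combination Optional combination label override.
#' @return One-row `data.frame` with columns `combination`, `dice_bone`,
#'   `dice_soft`, `dice_air`, `dice_mean` and per-class reference counts.
#' @export
dice_report <- function(ref, asmr, combination = NULL) {
  labels <- if (inherits(asmr, "asmr_image")) asmr$labels else asmr
  if (is.null(combination)) {
    combination <- if (inherits(asmr, "asmr_image")) {
      paste(asmr$combination, collapse = "+")
    } else "segmentation"
  }
  db <- dice_class(ref, labels, "bone")
  ds <- dice_class(ref, labels, "soft")
  da <- dice_class(ref, labels, "air")
  data.frame(combination = combination,
             dice_bone = db, dice_soft = ds, dice_air = da,
             dice_mean = (db + ds) / 2,
             n_ref_air = sum(ref$data == TISSUE_CODES[["air"]]),
             n_ref_soft = sum(ref$data == TISSUE_CODES[["soft"]]),
             n_ref_bone = sum(ref$data == TISSUE_CODES[["bone"]]),
             stringsAsFactors = FALSE)
}

#' Evaluate and rank a combination sweep
#'
#' One [dice_report()] row per segmentation, ranked by mean bone/soft Dice
#' (stable sort, descending).
#'
#' @param ref Reference [label_volume()].
#' @param asmr_list List of `asmr_image`s (e.g. from
#'   [sweep_combinations()]).
#' @return `data.frame` with a `rank` column, ordered by `dice_mean`
#'   descending.
#' @export
evaluate_sweep <- function(ref, asmr_list) {
  if (length(asmr_list) == 0) stop("empty segmentation list")
  rows <- do.call(rbind, lapply(asmr_list, function(a) dice_report(ref, a)))
  ord <- order(-rows$dice_mean)
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Aggregate Dice results over phantoms
#'
#' Mean and SD of the per-animal mean Dice for each combination, mirroring
#' a multi-animal similarity summary.
#'
#' @param reports List of [evaluate_sweep()] tables (one per animal).
#' @return `data.frame` with `combination`, `dice_mean`, `dice_sd`, `n`,
#'   ordered by `dice_mean` descending.
#' @export
aggregate_dice <- function(reports) {
  all <- do.call(rbind, reports)
  agg <- aggregate(dice_mean ~ combination, data = all,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  out <- data.frame(combination = agg$combination,
                    dice_mean = agg$dice_mean[, "mean"],
                    dice_sd = agg$dice_mean[, "sd"],
                    n = agg$dice_mean[, "n"],
                    stringsAsFactors = FALSE)
  out[order(-out$dice_mean), , drop = FALSE]
}
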
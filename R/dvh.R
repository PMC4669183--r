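#' Cumulative dose-volume histogram of a target volume
#'
#' Fraction of the VOI receiving at least each bin dose (the standard
#' ">= dose" convention), computed exactly from the voxel doses on a bin
#' grid no coarser than `bin_width` Gy.
#'
#' @param dose An [image_volume()] of dose in Gy.
#' @param voi Logical array selecting the volume of interest.
#' @param bin_width Bin width in Gy (capped at 0.05).
#' @return A `dvh_curve`: `dose_bins` (Gy, ascending from 0) and
#'   `volume_fraction` (non-increasing, starts at 1, 0 beyond the maximum
#'   dose).
#' @export
cumulative_dvh <- function(dose, voi, bin_width = 0.05) {
  stopifnot(inherits(dose, "image_volume"))
  if (!any(voi)) stop("empty VOI")
  bin_width <- min(bin_width, 0.05)
  dv <- dose$data[voi]
  if (any(!is.finite(dv)) || any(dv < 0)) stop("dose must be finite and non-negative")
  top <- max(dv)
  bins <- seq(0, top + 2 * bin_width, by = bin_width)
  sorted <- sort(dv)
  n <- length(sorted)
  # voxels with dose >= bin  ==  n - (number strictly below bin)
  below <- findInterval(bins, sorted, left.open = TRUE)
  vf <- (n - below) / n
  structure(list(dose_bins = bins, volume_fraction = vf, n_voxels = n),
            class = "dvh_curve")
}

#' Dose received by the hottest x percent of the volume
#'
#' `D_x` is the largest bin dose still covering at least `x`\% of the VOI
#' on the cumulative curve (the right-continuous inverse of the >=-dose
#' convention); exact at curve steps, otherwise accurate to one bin width.
#'
#' @param dvh A [cumulative_dvh()] curve.
#' @param x_percent Percentage in (0, 100).
#' @return Dose in Gy.
#' @export
d_metric <- function(dvh, x_percent) {
  if (x_percent <= 0 || x_percent >= 100) stop("x_percent must be in (0, 100)")
  p <- x_percent / 100
  i <- max(which(dvh$volume_fraction >= p))
  dvh$dose_bins[i]
}

#' D5 / D50 / D90 summary of a dose distribution
#'
#' @param dose An [image_volume()] of dose in Gy.
#' @param voi Logical VOI array.
#' @param percents Coverage percentages (default 5, 50, 90).
#' @inheritParams cumulative_dvh
#' @return Named numeric vector of D_x values in Gy.
#' @export
dvh_metrics <- function(dose, voi, percents = c(5, 50, 90), bin_width = 0.05) {
  dvh <- cumulative_dvh(dose, voi, bin_width)
  setNames(vapply(percents, function(p) d_metric(dvh, p), numeric(1)),
           paste0("D", percents))
}

#' Normalize MR-based dose metrics to the CT reference
#'
#' Joins per-animal CT-planned and MR-planned metric tables, forms the
#' MR/CT ratio for each metric, and aggregates mean and SD of the ratios
#' over animals per plan and segmentation method.
#'
#' @param ct_metrics `data.frame` with columns `animal`, `plan`, and one
#'   column per metric (e.g. `D5`, `D50`, `D90`).
#' @param mr_metrics `data.frame` with columns `animal`, `plan`, `method`,
#'   and the same metric columns (the dose delivered when the plan is
#'   normalized on the MR-based pseudo-CT).
#' @return List with `per_animal` (ratio columns appended) and `summary`
#'   (`mean` and `sd` of each ratio by plan and method).
#' @export
compare_to_ct <- function(ct_metrics, mr_metrics) {
  metrics <- intersect(names(ct_metrics), names(mr_metrics))
  metrics <- metrics[grepl("^D[0-9]+$", metrics)]
  if (length(metrics) == 0) stop("no common D_x metric columns")
  merged <- merge(mr_metrics, ct_metrics, by = c("animal", "plan"),
                  suffixes = c("_mr", "_ct"))
  for (m in metrics) {
    ct <- merged[[paste0(m, "_ct")]]
    if (any(ct == 0)) stop("zero CT metric: ratio undefined")
    merged[[paste0("ratio_", m)]] <- merged[[paste0(m, "_mr")]] / ct
  }
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(plan = merged$plan, method = merged$method, metric = m,
               ratio = merged[[paste0("ratio_", m)]], stringsAsFactors = FALSE)
  }))
  agg <- aggregate(ratio ~ plan + method + metric, data = long,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  summary <- data.frame(plan = agg$plan, method = agg$method, metric = agg$metric,
                        ratio_mean = agg$ratio[, "mean"],
                        ratio_sd = agg$ratio[, "sd"],
                        n = agg$ratio[, "n"], stringsAsFactors = FALSE)
  list(per_animal = merged, summary = summary)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test comparing two groups of dose metrics: the exact
#' null distribution is used for combined samples of at most 20 without
#' ties, otherwise the normal approximation with tie correction.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return List with `U` (statistic for `group_a`), `p_value`, and
#'   `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b)) <= 20 && !ties
  ht <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = TRUE))
  p <- ht$p.value
  # all observations tied across both groups: the rank-sum variance is zero
  # and the normal approximation is 0/0; there is no evidence of difference
  if (is.na(p)) p <- 1
  list(U = unname(ht$statistic), p_value = p, exact = exact)
}
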
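#' Build a head mask from a T1-weighted image
#'
#' Air mask used to suppress artifacts outside the head before
#' classification: Otsu threshold on the T1 volume, largest 6-connected
#' foreground component, morphological closing, then a small dilation so
#' that the signal-poor skull shell (nearly invisible on T1) stays inside
#' the mask.  Everything outside the returned mask is forced to air
#' downstream.
#'
#' @param t1 Bias-corrected T1-weighted [image_volume()].
#' @param close_radius Closing ball radius in voxels (default 2).
#' @param dilate_mm Physical dilation radius in mm (default 1.2, sized to
#'   cover a sub-millimetre skull shell in every direction on an
#'   anisotropic grid).
#' @return Logical array on the T1 grid (`TRUE` = head).
#' @export
make_air_mask <- function(t1, close_radius = 2, dilate_mm = 1.2) {
  stopifnot(inherits(t1, "image_volume"))
  v <- t1$data
  if (diff(range(v)) == 0) stop("masking error: constant image has no foreground")
  thr <- otsu_threshold(v)
  fg <- v > thr
  if (!any(fg)) stop("masking error: empty foreground after thresholding")
  m <- largest_component(fg)
  if (close_radius > 0) m <- close_mask(m, close_radius)
  if (dilate_mm > 0) m <- dilate_mask(m, dilate_mm, spacing = t1$spacing)
  m
}

#' Assemble a multi-channel feature stack for clustering
#'
#' Collects the requested sequences in canonical order (so permuted subsets
#' produce identical stacks) and z-score normalizes each channel over the
#' mask, making the Euclidean norm of the clustering objective comparable
#' across sequences with different intensity scales.  The raw (unscaled)
#' intensities are kept alongside for cluster-identity assignment.
#'
#' @param images Named list of [image_volume()]s (subset of
#'   T1/T2/UTE1/UTE2/ZTE).
#' @param subset Character vector of sequence names to use.
#' @param mask Logical array of voxels entering clustering.
#' @return A `feature_stack`: `channels`, `data` (n x k z-scored matrix),
#'   `raw` (n x k), `mask`, and grid metadata.
#' @export
build_features <- function(images, subset, mask) {
  if (length(subset) == 0) stop("subset must be non-empty")
  subset <- unique(subset)
  if (!all(subset %in% names(images))) {
    stop("subset contains sequences not present in `images`")
  }
  channels <- SEQUENCE_NAMES[SEQUENCE_NAMES %in% subset]
  if (length(channels) != length(subset)) {
    stop("unknown sequence name in subset")
  }
  ref <- images[[channels[1]]]
  for (nm in channels) stop_if_grid_mismatch(images[[nm]], ref)
  if (!identical(dim(mask), dim(ref$data))) stop("mask grid mismatch")
  raw <- vapply(channels, function(nm) images[[nm]]$data[mask],
                numeric(sum(mask)))
  data <- apply(raw, 2, function(x) {
    s <- sd(x)
    if (s == 0) stop("degenerate channel: zero variance over the mask")
    (x - mean(x)) / s
  })
  structure(list(channels = channels, data = data, raw = raw, mask = mask,
                 spacing = ref$spacing, origin = ref$origin,
                 dim = dim(ref$data)),
            class = "feature_stack")
}

# Deterministic k-means++ style centroid initialization on a subsample.
init_centroids <- function(X, c, seed, subsample = 5000L) {
  with_seed(seed, {
    n <- nrow(X)
    rows <- if (n > subsample) sort(sample.int(n, subsample)) else seq_len(n)
    Y <- X[rows, , drop = FALSE]
    cent <- matrix(0, c, ncol(X))
    cent[1, ] <- Y[sample.int(nrow(Y), 1L), ]
    d2 <- rowSums(sweep(Y, 2, cent[1, ])^2)
    for (j in seq_len(c)[-1]) {
      p <- d2 / sum(d2)
      cent[j, ] <- Y[sample.int(nrow(Y), 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(Y, 2, cent[j, ])^2))
    }
    cent
  })
}

#' Multi-channel fuzzy c-means clustering
#'
#' Minimizes `Q = sum_i sum_j u_ij^m ||x_i - c_j||^2` subject to per-point
#' membership sums of 1, by the standard alternating closed-form updates:
#' `u_ij = 1 / sum_k (||x_i - c_j|| / ||x_i - c_k||)^(2/(m-1))` and
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`.  Points coinciding exactly with
#' a centroid receive membership 1 for that cluster.  Iteration stops when
#' the relative change of Q falls below `tol` or after `max_iters` cycles.
#'
#' @param stack A [build_features()] stack (or any list with a numeric
#'   matrix `data`).
#' @param c Number of clusters (default 3).
#' @param m Fuzzification exponent, > 1 (default 2).
#' @param tol Relative objective-change tolerance (default 1e-5).
#' @param max_iters Iteration cap (default 200).
#' @param seed Seed for the deterministic k-means++ initialization.
#' @return An `fcm_result`: `memberships` (n x c, rows sum to 1),
#'   `centroids` (c x k), `objective_trace` (non-increasing), `n_iters`,
#'   `fuzzifier_m` and `seed`.
#' @export
fcm_cluster <- function(stack, c = 3, m = 2, tol = 1e-5, max_iters = 200,
                        seed = 1) {
  X <- stack$data
  if (m <= 1) stop("fuzzifier m must exceed 1")
  n <- nrow(X)
  if (n < c) stop("fewer points than clusters")
  if (nrow(unique(X)) < c) stop("clustering error: fewer than c distinct feature vectors")
  cent <- init_centroids(X, c, seed)
  xs <- rowSums(X^2)
  expo <- 1 / (m - 1)
  trace <- numeric(0)
  u <- NULL
  for (it in seq_len(max_iters)) {
    d2 <- pmax(outer(xs, rowSums(cent^2), "+") - 2 * X %*% t(cent), 0)
    hit <- d2 < 1e-12
    w <- d2^(-expo)
    u <- w / rowSums(w)
    exact <- which(rowSums(hit) > 0)
    if (length(exact)) {
      u[exact, ] <- 0
      u[cbind(exact, max.col(hit[exact, , drop = FALSE], ties.method = "first"))] <- 1
    }
    trace <- c(trace, sum(u^m * d2))
    um <- u^m
    cent <- (t(um) %*% X) / colSums(um)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <= tol * abs(trace[it - 1])) break
  }
  structure(list(memberships = u, centroids = cent, objective_trace = trace,
                 n_iters = length(trace), fuzzifier_m = m, seed = seed),
            class = "fcm_result")
}

#' Name FCM clusters as air / soft tissue / bone
#'
#' Assigns tissue identities from the clusters' mean raw intensities: air
#' is the cluster darkest on average across all channels (air gives no
#' signal on any sequence, whereas bone is bright on at least the
#' short-echo channels when one is present); of the remaining two, when a
#' short-echo channel (UTE1/ZTE) is available the cluster with the larger
#' short-echo to conventional (T1/T2/UTE2) intensity ratio is bone,
#' otherwise the darker remaining cluster is bone.  Ties (relative
#' difference below 1e-6) are broken deterministically by centroid norm
#' with a warning.
#'
#' @param result An [fcm_cluster()] result with 3 clusters.
#' @param stack The [build_features()] stack that produced it.
#' @return Integer vector of length 3 mapping cluster index to tissue code
#'   (air 0, soft 1, bone 2); a bijection.
#' @export
identify_clusters <- function(result, stack) {
  if (ncol(result$memberships) != 3) stop("cluster naming requires exactly 3 clusters")
  u <- result$memberships
  ch <- stack$channels
  conv <- ch[ch %in% c("T1", "T2", "UTE2")]
  short <- ch[ch %in% c("UTE1", "ZTE")]
  wsum <- colSums(u)
  # membership-weighted mean raw intensity per cluster per channel
  means <- t(u) %*% stack$raw / wsum   # 3 x k
  colnames(means) <- ch
  conv_mean <- if (length(conv)) rowMeans(means[, conv, drop = FALSE])
               else rowMeans(means)
  all_mean <- rowMeans(means)
  tie <- function(a, b) abs(a - b) <= 1e-6 * max(abs(a), abs(b), 1e-12)
  ord <- order(all_mean, sqrt(rowSums(result$centroids^2)))
  if (tie(all_mean[ord[1]], all_mean[ord[2]])) {
    warning("ambiguous air signature; tie broken by centroid norm")
  }
  air <- ord[1]
  rest <- setdiff(1:3, air)
  if (length(short)) {
    short_mean <- rowMeans(means[, short, drop = FALSE])
    ratio <- if (length(conv)) short_mean / pmax(conv_mean, 1e-9) else short_mean
    if (tie(ratio[rest[1]], ratio[rest[2]])) {
      warning("ambiguous bone signature; tie broken by centroid norm")
      rest <- rest[order(sqrt(rowSums(result$centroids^2))[rest])]
      bone <- rest[2]
    } else {
      bone <- rest[which.max(ratio[rest])]
    }
  } else {
    bone <- rest[which.min(conv_mean[rest])]
  }
  soft <- setdiff(rest, bone)
  mapping <- integer(3)
  mapping[air] <- TISSUE_CODES[["air"]]
  mapping[soft] <- TISSUE_CODES[["soft"]]
  mapping[bone] <- TISSUE_CODES[["bone"]]
  mapping
}

#' Hard-classify an FCM result into a tissue label map
#'
#' Each in-mask voxel is assigned the tissue class of its highest
#' membership (ties broken toward the class earliest in air, soft, bone);
#' voxels outside the air mask are forced to air.
#'
#' @param result An [fcm_cluster()] result.
#' @param mapping Cluster-to-tissue mapping from [identify_clusters()].
#' @param stack The [build_features()] stack (provides the mask and grid).
#' @return An `asmr_image`: `labels` ([label_volume()]), `combination`
#'   (channel names) and `provenance` (parameters and seed).
#' @export
classify <- function(result, mapping, stack) {
  if (!setequal(mapping, TISSUE_CODES)) stop("mapping must be a bijection onto {air, soft, bone}")
  u <- result$memberships
  # reorder columns into (air, soft, bone) so that ties resolve in that order
  ord <- order(mapping)
  hard <- max.col(u[, ord, drop = FALSE], ties.method = "first") - 1L
  lab <- array(TISSUE_CODES[["air"]], stack$dim)
  lab[stack$mask] <- hard
  structure(list(
    labels = label_volume(lab, stack$spacing, stack$origin),
    combination = stack$channels,
    provenance = list(seed = result$seed, m = result$fuzzifier_m,
                      n_iters = result$n_iters,
                      channels = stack$channels)),
    class = "asmr_image")
}

#' Segment one sequence combination
#'
#' Convenience wrapper: feature stack, FCM, cluster naming and hard
#' classification for a single subset of sequences.
#'
#' @inheritParams build_features
#' @inheritParams fcm_cluster
#' @return An `asmr_image` (see [classify()]).
#' @export
segment_subset <- function(images, subset, mask, c = 3, m = 2, tol = 1e-5,
                           max_iters = 200, seed = 1) {
  stack <- build_features(images, subset, mask)
  res <- fcm_cluster(stack, c = c, m = m, tol = tol, max_iters = max_iters,
                     seed = seed)
  mapping <- identify_clusters(res, stack)
  classify(res, mapping, stack)
}

# All non-empty subsets of `channels`, ordered by size then lexicographic.
sequence_subsets <- function(channels) {
  channels <- SEQUENCE_NAMES[SEQUENCE_NAMES %in% channels]
  out <- list()
  for (k in seq_along(channels)) {
    cmb <- combn(channels, k, simplify = FALSE)
    ord <- order(vapply(cmb, paste, "", collapse = "+"))
    out <- c(out, cmb[ord])
  }
  out
}

#' Segment every combination of the available sequences
#'
#' Runs [segment_subset()] for each non-empty subset of the input
#' sequences, in deterministic order (by subset size, then lexicographic).
#' Five sequences yield the full set of 31 automatically segmented MR
#' (ASMR) images; with fewer inputs a notice reports the reduced count.
#'
#' @inheritParams segment_subset
#' @return List of `asmr_image`s, one per subset.
#' @export
sweep_combinations <- function(images, mask, c = 3, m = 2, tol = 1e-5,
                               max_iters = 200, seed = 1) {
  avail <- names(images)
  if (length(avail) < 5) {
    message(sprintf("only %d sequences available: sweeping %d combinations",
                    length(avail), 2^length(avail) - 1))
  }
  subsets <- sequence_subsets(avail)
  lapply(subsets, function(s) {
    segment_subset(images, s, mask, c = c, m = m, tol = tol,
                   max_iters = max_iters, seed = seed)
  })
}
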
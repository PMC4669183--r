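# Shared fixtures: small phantoms and independent oracles.

# Small phantom spec whose head fits a 48^3 grid at the default spacing.
small_spec <- function(seed = 1, grid = 48, cavities = 2, septa = 2) {
  phantom_spec(grid_shape = rep(grid, 3), head_axes = c(4.5, 9, 4.5),
               skull_thickness = 0.6, n_air_cavities = cavities,
               rostrum_complexity = septa, seed = seed)
}

# 64^3 phantom for bias-field work (head scaled to fit).
bias_spec <- function(seed = 1) {
  phantom_spec(grid_shape = c(64, 64, 64), head_axes = c(7, 13, 7),
               skull_thickness = 0.7, n_air_cavities = 2,
               rostrum_complexity = 2, seed = seed)
}

noise_free_models <- function() default_sequence_models(noise_sigma = 0, bias_amplitude = 0)

# Three well-separated Gaussian point clouds in `k` channels.
make_clouds <- function(n = 200, k = 2, sep = 10, spread = 1, seed = 42) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  if (k > 2) centers <- cbind(centers, matrix(0, 3, k - 2))
  grp <- rep(1:3, length.out = n)
  X <- centers[grp, , drop = FALSE] + matrix(rnorm(n * k, sd = spread), n, k)
  list(X = X, group = grp, centers = centers)
}

# Brute-force alternating FCM optimizer with random restarts: an
# independent oracle for the clustering objective (explicit loops, random
# data-point initialization).
fcm_oracle_q <- function(X, c = 3, m = 2, n_restarts = 50, iters = 500,
                         tol = 1e-12, seed = 99) {
  n <- nrow(X)
  best <- Inf
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    cent <- X[sample.int(n, c), , drop = FALSE]
    q_old <- Inf
    for (it in seq_len(iters)) {
      d2 <- matrix(0, n, c)
      for (j in seq_len(c)) {
        for (i in seq_len(n)) d2[i, j] <- sum((X[i, ] - cent[j, ])^2)
      }
      u <- matrix(0, n, c)
      for (i in seq_len(n)) {
        if (any(d2[i, ] == 0)) {
          u[i, which.min(d2[i, ])] <- 1
        } else {
          for (j in seq_len(c)) {
            u[i, j] <- 1 / sum((d2[i, j] / d2[i, ])^(1 / (m - 1)))
          }
        }
      }
      q <- sum(u^m * d2)
      um <- u^m
      for (j in seq_len(c)) {
        cent[j, ] <- colSums(um[, j] * X) / sum(um[, j])
      }
      if (is.finite(q_old) && abs(q_old - q) <= tol * abs(q)) break
      q_old <- q
    }
    if (q < best) best <- q
  }
  best
}

# Independent re-evaluation of the FCM objective at a result's final state.
fcm_recompute_q <- function(X, result) {
  cent <- result$centroids
  d2 <- matrix(0, nrow(X), nrow(cent))
  for (j in seq_len(nrow(cent))) {
    d2[, j] <- colSums((t(X) - cent[j, ])^2)
  }
  sum(result$memberships^result$fuzzifier_m * d2)
}

# Majority-vote oracle: the tissue class most common among the truth labels
# of each cluster's hard-assigned voxels.
majority_vote_mapping <- function(result, stack, truth) {
  hard <- max.col(result$memberships, ties.method = "first")
  tl <- truth$data[stack$mask]
  vapply(1:3, function(j) {
    as.integer(names(which.max(table(tl[hard == j]))))
  }, integer(1))
}

# Midpoint-rule radiological path with dense supersampling of the in-grid
# segment (independent of the exact voxel-walk implementation).
path_oracle <- function(mu, source, point, n_steps = 50000) {
  d <- dim(mu$data)
  dir <- point - source
  # clip the parametric interval to the grid bounding box
  amin <- 0; amax <- 1
  for (a in 1:3) {
    lo <- mu$origin[a] - mu$spacing[a] / 2
    hi <- mu$origin[a] + (d[a] - 0.5) * mu$spacing[a]
    if (abs(dir[a]) < 1e-12) {
      if (source[a] < lo || source[a] > hi) return(0)
    } else {
      tt <- sort(c((lo - source[a]) / dir[a], (hi - source[a]) / dir[a]))
      amin <- max(amin, tt[1]); amax <- min(amax, tt[2])
    }
  }
  if (amin >= amax) return(0)
  t <- amin + (amax - amin) * (seq_len(n_steps) - 0.5) / n_steps
  seg <- sweep(outer(t, dir), 2, source, "+")
  idx <- sapply(1:3, function(a) {
    pmin(pmax(round((seg[, a] - mu$origin[a]) / mu$spacing[a]) + 1, 1), d[a])
  })
  vals <- mu$data[idx]
  sum(vals) * (amax - amin) * sqrt(sum(dir^2)) / n_steps
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enumerate_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  u_of <- function(ix) sum(r[ix]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  combos <- combn(na + nb, na)
  us <- apply(combos, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}
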
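test_that("the T1 head mask covers the whole head with a bounded air rind", {
  spec <- small_spec(seed = 1)
  ph <- simulate_phantom(spec, noise_free_models(), seed = 1)
  mask <- make_air_mask(ph$images$T1)
  truth <- ph$labels$data != 0L
  # the skull shell (dark on T1) must not be clipped out of the mask
  expect_equal(sum(truth & !mask), 0)
  # and the deliberately generous dilation stays a thin rind
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.80)
  expect_lte(sum(mask), 1.6 * sum(truth))
})

test_that("masking rejects constant images and drops isolated specks", {
  flat <- image_volume(array(5, c(16, 16, 16)))
  expect_error(make_air_mask(flat), "constant")
  spec <- small_spec(seed = 2)
  ph <- simulate_phantom(spec, noise_free_models(), seed = 2)
  t1 <- ph$images$T1
  t1$data[2:3, 2:3, 2:3] <- 200   # bright speck far from the head
  mask <- make_air_mask(t1)
  expect_false(any(mask[2:3, 2:3, 2:3]))
})

test_that("feature stacks are order-invariant and exactly standardized", {
  spec <- small_spec(seed = 3)
  ph <- simulate_phantom(spec, default_sequence_models(bias_amplitude = 0), seed = 3)
  mask <- make_air_mask(ph$images$T1)
  s1 <- build_features(ph$images, c("ZTE", "UTE2"), mask)
  s2 <- build_features(ph$images, c("UTE2", "ZTE"), mask)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$channels, c("UTE2", "ZTE"))
  mom <- apply(s1$data, 2, function(x) c(mean(x), var(x)))
  expect_equal(mom[1, ], c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mom[2, ], c(1, 1), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(build_features(ph$images, character(0), mask), "non-empty")
  expect_error(build_features(ph$images, "PD", mask), "not present")
})

test_that("FCM recovers well-separated clouds and its objective decreases", {
  cl <- make_clouds(n = 300, k = 2, sep = 10, spread = 1)
  stack <- list(data = cl$X)
  res <- fcm_cluster(stack, c = 3, tol = 1e-12, max_iters = 300, seed = 5)
  expect_equal(rowSums(res$memberships), rep(1, nrow(cl$X)), tolerance = 1e-9)
  expect_true(all(diff(res$objective_trace) <= 1e-10 * abs(res$objective_trace[-res$n_iters])))
  # centroids match generating means within 1% of the separation
  got <- res$centroids[order(res$centroids[, 1]), ]
  want <- cl$centers[order(cl$centers[, 1]), ]
  expect_lt(max(abs(got - want)), 0.1 * 10)
  # hard labels agree perfectly with generating groups (up to relabelling)
  hard <- max.col(res$memberships)
  expect_equal(length(unique(paste(hard, cl$group))), 3)
  # independent objective re-evaluation matches the recorded optimum
  expect_equal(fcm_recompute_q(cl$X, res),
               res$objective_trace[res$n_iters], tolerance = 1e-6)
})

test_that("FCM memberships split evenly at a symmetric midpoint and spike on exact hits", {
  X <- matrix(c(-1, 1, 0), ncol = 1)
  res <- fcm_cluster(list(data = X), c = 2, tol = 1e-12, max_iters = 500, seed = 1)
  mid <- which.min(abs(X))
  expect_equal(res$memberships[mid, ], c(0.5, 0.5), tolerance = 1e-6)
  # a point coinciding with a centroid gets membership exactly 1
  X2 <- matrix(c(rep(0, 5), rep(10, 5)), ncol = 1)
  res2 <- fcm_cluster(list(data = X2), c = 2, tol = 1e-12, seed = 2)
  expect_true(all(apply(res2$memberships, 1, max) > 0.999))
  expect_error(fcm_cluster(list(data = matrix(1, 10, 1)), c = 2), "distinct")
})

test_that("FCM matches an established implementation on benign instances", {
  skip_if_not_installed("e1071")
  for (seed in 1:3) {
    cl <- make_clouds(n = 150, k = 2, sep = 8, spread = 1, seed = seed)
    mine <- fcm_cluster(list(data = cl$X), c = 3, tol = 1e-12,
                        max_iters = 500, seed = seed)
    q_mine <- mine$objective_trace[mine$n_iters]
    set.seed(seed)
    ref <- e1071::cmeans(cl$X, centers = 3, m = 2, iter.max = 500)
    q_ref <- fcm_recompute_q(cl$X, list(centroids = ref$centers,
                                        memberships = ref$membership,
                                        fuzzifier_m = 2))
    expect_equal(q_mine, q_ref, tolerance = 1e-4)
  }
})

test_that("cluster naming matches a majority-vote oracle on phantoms", {
  spec <- small_spec(seed = 4)
  ph <- simulate_phantom(spec, default_sequence_models(bias_amplitude = 0), seed = 4)
  mask <- make_air_mask(ph$images$T1)
  for (subset in list(c("ZTE", "UTE2"), "T1")) {
    stack <- build_features(ph$images, subset, mask)
    res <- fcm_cluster(stack, seed = 4)
    mapping <- identify_clusters(res, stack)
    expect_true(setequal(mapping, 0:2))
    oracle <- majority_vote_mapping(res, stack, ph$labels)
    if (setequal(oracle, 0:2)) {
      expect_identical(as.integer(mapping), as.integer(oracle))
    }
  }
})

test_that("classification takes the argmax, breaks ties in class order, and respects the mask", {
  stack <- list(mask = array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)),
                dim = c(4L, 1L, 1L), spacing = c(1, 1, 1),
                origin = c(0, 0, 0), channels = "T1")
  u <- rbind(c(0.2, 0.5, 0.3),
             c(0.5, 0.5, 0.0),
             c(0.1, 0.2, 0.7))
  res <- list(memberships = u, seed = 1, fuzzifier_m = 2, n_iters = 1)
  mapping <- c(0L, 1L, 2L)  # cluster j -> tissue j-1
  asmr <- classify(res, mapping, stack)
  expect_equal(as.integer(asmr$labels$data),
               c(1L,  # argmax cluster 2 -> soft
                 0L,  # tie air/soft -> air (earlier class)
                 2L,  # argmax cluster 3 -> bone
                 0L)) # outside mask -> air
  expect_error(classify(res, c(0L, 0L, 2L), stack), "bijection")
})

test_that("no non-air label ever appears outside the head mask", {
  spec <- small_spec(seed = 5)
  ph <- simulate_phantom(spec, default_sequence_models(bias_amplitude = 0), seed = 5)
  mask <- make_air_mask(ph$images$T1)
  asmr <- segment_subset(ph$images, c("UTE1", "T2"), mask, seed = 5)
  expect_true(all(asmr$labels$data[!mask] == 0L))
})

test_that("the sweep enumerates subsets deterministically and matches single runs", {
  spec <- small_spec(seed = 6)
  ph <- simulate_phantom(spec, default_sequence_models(bias_amplitude = 0), seed = 6)
  mask <- make_air_mask(ph$images$T1)
  two <- ph$images[c("ZTE", "T1")]
  expect_message(sw <- sweep_combinations(two, mask, seed = 6), "3 combinations")
  expect_length(sw, 3)
  expect_equal(lapply(sw, function(a) a$combination),
               list("T1", "ZTE", c("T1", "ZTE")))
  direct <- segment_subset(two, c("ZTE", "T1"), mask, seed = 6)
  expect_identical(sw[[3]]$labels$data, direct$labels$data)
})
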
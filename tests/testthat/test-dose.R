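# Homogeneous water block for closed-form dosimetry checks.
water_props <- function(n = 64, sp = 0.5) {
  assign_properties(label_volume(array(1L, rep(n, 3)), spacing = rep(sp, 3)))
}

test_that("sphere VOI voxel count approximates the analytic volume", {
  grid <- image_volume(array(0, c(64, 64, 64)), spacing = rep(0.275, 3))
  voi <- sphere_voi(c(0, 0, 0), 2.5, grid)
  analytic <- 4 / 3 * pi * 1.25^3 / prod(grid$spacing)
  expect_lt(abs(sum(voi) - analytic) / analytic, 0.15)
  # sub-voxel sphere centred on a voxel centre selects exactly that voxel
  co <- mr2plan:::axis_coords(grid)
  ctr <- c(co[[1]][33], co[[2]][33], co[[3]][33])
  expect_equal(sum(sphere_voi(ctr, 0.2, grid)), 1)
  # translation by one voxel spacing gives a congruent mask
  voi2 <- sphere_voi(ctr + grid$spacing, 2.5, grid)
  expect_equal(sum(sphere_voi(ctr, 2.5, grid)), sum(voi2))
  expect_error(sphere_voi(c(100, 100, 100), 0.1, grid), "empty")
})

test_that("radiological paths match closed forms and a supersampled oracle", {
  props <- water_props()
  mu <- props$mu
  muw <- mu$data[1]
  extent <- 64 * 0.5
  # uniform medium, axial ray from far outside through the whole block
  p <- radiological_path(mu, c(0, 0, 200), c(0, 0, 0))
  expect_equal(p, muw * extent / 2, tolerance = 1e-9)
  # a path through vacuum contributes nothing
  vac <- image_volume(array(0, c(16, 16, 16)))
  expect_identical(radiological_path(vac, c(0, 0, 50), c(0, 0, 0)), 0)
  # heterogeneous phantom vs dense midpoint-rule oracle, oblique rays
  lab <- generate_labels(small_spec(seed = 9))
  hp <- assign_properties(lab)
  set.seed(4)
  for (i in 1:8) {
    src <- c(runif(1, -150, 150), runif(1, -150, 150), 180)
    pt <- runif(3, -4, 4)
    got <- radiological_path(hp$mu, src, pt)
    want <- path_oracle(hp$mu, src, pt)
    if (want > 0.05) expect_lt(abs(got - want) / want, 0.005)
  }
})

test_that("central-axis depth dose follows inverse square times attenuation", {
  props <- water_props()
  beam <- beam_spec(gantry_angle = 0, couch_angle = 0)
  dv <- beam_dose(props, beam)
  co <- mr2plan:::axis_coords(dv)
  ix <- which.min(abs(co[[1]]))
  prof <- dv$data[ix, ix, ]
  z <- co[[3]]
  sad <- beam$source_axis_distance
  zsurf <- max(z) + props$mu$spacing[3] / 2
  muw <- props$mu$data[1]
  expected <- (sad / (sad - z))^2 * exp(-muw * (zsurf - z))
  sel <- prof > 0
  ratio <- prof[sel] / expected[sel]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.01)
})

test_that("dose in near-vacuum is pure inverse square and collimation is sharp", {
  air <- assign_properties(label_volume(array(0L, c(48, 48, 48)),
                                        spacing = rep(0.5, 3)))
  beam <- beam_spec()
  dv <- beam_dose(air, beam)
  co <- mr2plan:::axis_coords(dv)
  ix <- which.min(abs(co[[1]]))
  prof <- dv$data[ix, ix, ]
  sel <- prof > 0
  r <- beam$source_axis_distance - co[[3]][sel]
  expect_lt(diff(range(prof[sel] * r^2)) / mean(prof[sel] * r^2), 0.002)
  # lateral profile at isocenter depth: zero outside the 3 mm field edge
  iz <- which.min(abs(co[[3]]))
  lat <- dv$data[, ix, iz]
  outside <- abs(co[[1]]) > 1.5 + 0.5  # one voxel of slack at the edge
  expect_true(all(lat[outside] == 0))
  expect_gt(lat[ix], 0)
})

test_that("plans are linear in their segments and meet the prescription exactly", {
  props <- water_props(48)
  target <- list(center = c(0, 0, 0), diameter = 2.5)
  b1 <- beam_spec(gantry_angle = 0)
  b2 <- beam_spec(gantry_angle = 90)
  plan <- plan_spec(list(b1, b2), prescription_dose = 15, target = target)
  pd <- plan_dose(props, plan)
  voi <- attr(pd, "voi")
  expect_equal(mean(pd$data[voi]), 15, tolerance = 1e-12)
  # linearity: the plan dose is the scaled sum of its beam doses
  total <- beam_dose(props, b1)$data + beam_dose(props, b2)$data
  expect_equal(pd$data, total * attr(pd, "scale"), tolerance = 1e-12)
  # single-beam plan equals beam_dose rescaled to 15 Gy mean target dose
  plan1 <- plan_spec(list(b1), prescription_dose = 15, target = target)
  pd1 <- plan_dose(props, plan1)
  bd <- beam_dose(props, b1)$data
  expect_equal(pd1$data, bd * 15 / mean(bd[voi]), tolerance = 1e-12)
})

test_that("arc dose at the centre of a symmetric phantom ignores the start angle", {
  props <- water_props(48)
  target <- list(center = c(0, 0, 0), diameter = 2.5)
  d50 <- sapply(c(-60, -23, 10), function(start) {
    plan <- plan_spec(list(arc_spec(gantry_start = start)), target = target)
    pd <- plan_dose(props, plan)
    d_metric(cumulative_dvh(pd, attr(pd, "voi")), 50)
  })
  expect_lt(diff(range(d50)) / mean(d50), 0.01)
})

test_that("refining the arc discretization barely changes D50", {
  props <- water_props(48)
  target <- list(center = c(0, 0, 0), diameter = 2.5)
  d50 <- sapply(c(10, 5), function(step) {
    plan <- plan_spec(list(arc_spec(angular_step = step)), target = target)
    pd <- plan_dose(props, plan)
    d_metric(cumulative_dvh(pd, attr(pd, "voi")), 50)
  })
  expect_lt(abs(d50[2] - d50[1]) / d50[1], 0.005)
})

test_that("inserting bone along a ray never increases downstream dose", {
  lab <- array(1L, c(48, 48, 48))
  soft <- assign_properties(label_volume(lab, spacing = rep(0.5, 3)))
  lab2 <- lab; lab2[, , 30:34] <- 2L   # bone slab between source (+z) and target
  bony <- assign_properties(label_volume(lab2, spacing = rep(0.5, 3)))
  beam <- beam_spec(gantry_angle = 0, couch_angle = 0)
  d_soft <- beam_dose(soft, beam)$data
  d_bone <- beam_dose(bony, beam)$data
  co <- mr2plan:::axis_coords(soft$mu)
  downstream <- which(co[[3]] < co[[3]][30])
  expect_true(all(d_bone[, , downstream] <= d_soft[, , downstream] + 1e-15))
})

test_that("plans refuse targets that receive no dose", {
  props <- water_props(48)
  plan <- plan_spec(list(beam_spec(gantry_angle = 0)),
                    target = list(center = c(10, 10, 0), diameter = 1.5))
  expect_error(plan_dose(props, plan), "prescription error")
})
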
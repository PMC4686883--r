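geom31 <- pipetteGeometry(approachAngle = 31)
axis31 <- approachAxis(geom31)

test_that("approach waypoints lie on the axial line through the target", {
  target <- c(250, 157.4, 180)
  tip <- target - (target[3L] - 10) / axis31[3L] * axis31 + c(0, 4, 0)
  plan <- planTrajectory(tip, target, piaZ = 30, geom31,
                         approachParams(bufferDistance = 12, stepSize = 3))
  wp <- waypoints(plan)
  ph <- phases(plan)
  for (i in which(ph == "approach"))
    expect_lt(rLateral(decomposeSeparation(wp[i, ], target, axis31)), 1e-6)
  # final waypoint sits at the buffer distance
  expect_equal(sqrt(sum((wp[nrow(wp), ] - target)^2)), 12, tolerance = 1e-9)
  # all motion below the pia is axial
  below <- wp[, 3L] > 30
  expect_true(all(ph[below] == "approach"))
})

test_that("a tip already on the approach line needs no lateral translate", {
  target <- c(250, 157.4, 180)
  tip <- target - (target[3L] - 20) / axis31[3L] * axis31
  plan <- planTrajectory(tip, target, 30, geom31)
  wp <- waypoints(plan)
  ph <- phases(plan)
  i <- which(ph == "translate")
  prev <- if (i > 1L) wp[i - 1L, ] else tip
  expect_lt(rLateral(decomposeSeparation(wp[i, ], target, axis31)), 1e-9)
})

test_that("degenerate and shallow geometries are reported", {
  expect_error(planTrajectory(c(0, 0, 0), c(50, 0, 50), 30,
                              pipetteGeometry(approachAngle = 0)),
               class = "noIntersection")
  # target shallower than R below the pia: clamped with a warning
  expect_warning(
    plan <- planTrajectory(c(200, 157, 20), c(250, 157, 35), 30, geom31,
                           approachParams(bufferDistance = 12, stepSize = 3)),
    "clamping")
  expect_equal(plan@termination[3L], 30)
})

test_that("steps never exceed the step size and termination is invariant", {
  target <- c(250, 157.4, 180)
  tip <- c(150, 157.4, 10)
  for (step in c(2, 3, 4)) {
    plan <- planTrajectory(tip, target, 30, geom31,
                           approachParams(12, step))
    wp <- waypoints(plan)
    ap <- which(phases(plan) == "approach")
    d <- sqrt(rowSums((wp[ap[-1L], , drop = FALSE] -
                       wp[ap[-length(ap)], , drop = FALSE])^2))
    expect_true(all(d <= step + 1e-9))
  }
  t2 <- waypoints(planTrajectory(tip, target, 30, geom31,
                                 approachParams(12, 2)))
  t4 <- waypoints(planTrajectory(tip, target, 30, geom31,
                                 approachParams(12, 4)))
  expect_equal(t2[nrow(t2), ], t4[nrow(t4), ], tolerance = 1e-12)
})

test_that("correction decomposes the tip offset against the axis", {
  zero <- computeCorrection(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9), c(9, 9, 9),
                            axis31)
  expect_equal(zero@tipOffset, c(0, 0, 0))
  expect_equal(zero@tipLateralOffset, c(0, 0, 0))
  expect_equal(zero@targetDisplacement, c(0, 0, 0))
  # purely axial offsets have no lateral component
  ax <- computeCorrection(c(0, 0, 0), 4.5 * axis31, c(0, 0, 0), c(0, 0, 0),
                          axis31)
  expect_equal(ax@tipLateralOffset, c(0, 0, 0), tolerance = 1e-12)
  # random offsets: lateral part matches a brute-force projection
  set.seed(17)
  for (i in 1:10) {
    off <- rnorm(3, sd = 8)
    corr <- computeCorrection(c(0, 0, 0), off, c(0, 0, 0), rnorm(3), axis31)
    tHat <- optimize(function(t) sum((off - t * axis31)^2),
                     interval = c(-50, 50), tol = 1e-12)$minimum
    expect_equal(corr@tipLateralOffset, off - tHat * axis31,
                 tolerance = 1e-6)
    expect_equal(sum(corr@tipLateralOffset * axis31), 0, tolerance = 1e-9)
  }
})

test_that("zero correction leaves the plan waypoint-identical", {
  plan <- planTrajectory(c(150, 157.4, 10), c(250, 157.4, 180), 30, geom31)
  corr <- computeCorrection(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                            axis31)
  idx <- which(phases(plan) == "approach")[5L]
  expect_identical(waypoints(adaptTrajectory(plan, corr, idx)),
                   waypoints(plan))
})

test_that("adaptation re-centers the physical tip on the target line", {
  target <- c(250, 157.4, 180)
  plan <- planTrajectory(c(150, 157.4, 10), target, 30, geom31)
  B <- lateralBasis(axis31)
  defl <- 8 * B[1L, ] + 3 * B[2L, ]
  drift <- 5 * B[2L, ] - 2 * B[1L, ]
  idx <- which(phases(plan) == "approach" & waypoints(plan)[, 3L] > 100)[1L]
  cmd <- waypoints(plan)[idx, ]
  corr <- computeCorrection(cmd, cmd + defl, target, target + drift, axis31)
  plan2 <- adaptTrajectory(plan, corr, idx)
  final <- waypoints(plan2)[nrow(waypoints(plan2)), ]
  # physical tip = command + deflection; target has drifted
  m <- decomposeSeparation(final + defl, target + drift, axis31)
  expect_lt(rLateral(m), 1e-6)
  expect_equal(rTotal(m), plan@params$bufferDistance, tolerance = 1e-6)
  expect_true("correct" %in% phases(plan2))
})

test_that("adaptation refuses a termination above the pia", {
  target <- c(250, 157.4, 180)
  plan <- planTrajectory(c(150, 157.4, 10), target, 30, geom31)
  idx <- which(phases(plan) == "approach")[3L]
  cmd <- waypoints(plan)[idx, ]
  corr <- computeCorrection(cmd, cmd, target, target - c(0, 0, 160), axis31)
  expect_error(adaptTrajectory(plan, corr, idx), class = "adaptRefused")
})

test_that("execution sends one command per waypoint, in order", {
  plan <- planTrajectory(c(150, 157.4, 10), c(250, 157.4, 180), 30, geom31)
  ideal <- simulatedManipulator(deflectionModel(), piaZ = 30)
  log <- executePlan(plan, ideal)
  expect_equal(nrow(log), nrow(waypoints(plan)))
  expect_equal(log$index, seq_len(nrow(log)))
  expect_equal(as.matrix(log[, c("ax", "ay", "az")]),
               unname(as.matrix(log[, c("cx", "cy", "cz")])),
               ignore_attr = TRUE)
  # empty execution window yields an empty log
  expect_equal(nrow(executePlan(plan, ideal, fromIndex = 5L, toIndex = 4L)),
               0L)
})

test_that("simulated manipulator applies the deflection model exactly", {
  B <- lateralBasis(axis31)
  model <- deflectionModel(lateral = 6 * B[1L, ], saturationDepth = 50)
  sink <- simulatedManipulator(model, piaZ = 30)
  plan <- planTrajectory(c(150, 157.4, 10), c(250, 157.4, 180), 30, geom31)
  log <- executePlan(plan, sink)
  for (r in seq_len(nrow(log))) {
    cmd <- as.numeric(log[r, c("cx", "cy", "cz")])
    depth <- max(0, cmd[3L] - 30)
    want <- cmd + 6 * B[1L, ] * min(1, depth / 50)
    expect_equal(as.numeric(log[r, c("ax", "ay", "az")]), want,
                 tolerance = 1e-12)
  }
  # a rejecting manipulator aborts with a partial log
  flaky <- function(cmd) if (cmd[3L] > 100) NULL else cmd
  expect_warning(bad <- executePlan(plan, flaky), "rejected")
  expect_true(attr(bad, "aborted"))
  expect_lt(nrow(bad), nrow(waypoints(plan)))
})
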
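test_that("approach axis follows the stated angle convention", {
  expect_equal(axisFromAngles(0, 0), c(1, 0, 0))
  a31 <- axisFromAngles(31, 0)
  expect_equal(a31, c(cos(31 * pi / 180), 0, sin(31 * pi / 180)))
  expect_equal(round(a31, 3), c(0.857, 0, 0.515))
  # near-vertical limit: z component tends to 1
  expect_gt(axisFromAngles(90 - 1e-6, 123)[3L], 1 - 1e-9)
  # azimuth rotates the horizontal component
  a <- axisFromAngles(31, 90)
  expect_equal(a[1L], 0, tolerance = 1e-12)
  expect_equal(a[2L], cos(31 * pi / 180))
  expect_error(axisFromAngles(90, 0), class = "invalidParameter")
  expect_error(axisFromAngles(-95, 0), class = "invalidParameter")
})

test_that("azimuth is periodic with period 360 degrees", {
  for (th in c(-40, 0, 31, 60)) for (ph in c(0, 17, 200))
    expect_equal(axisFromAngles(th, ph), axisFromAngles(th, ph + 360))
})

test_that("separation decomposition reproduces the printed worked example", {
  a <- axisFromAngles(31, 0)
  e1 <- lateralBasis(a)[1L, ]
  tip <- c(100, 120, 150)
  m <- decomposeSeparation(tip, tip + 6.2 * a + 2.5 * e1, a)
  expect_equal(rAxial(m), 6.2)
  expect_equal(rLateral(m), 2.5)
  expect_equal(round(rTotal(m), 1), 6.7)
})

test_that("on-axis target gives purely axial separation", {
  a <- axisFromAngles(31, 25)
  m <- decomposeSeparation(c(1, 2, 3), c(1, 2, 3) + 10 * a, a)
  expect_equal(rLateral(m), 0, tolerance = 1e-9)
  expect_equal(rAxial(m), 10)
  expect_equal(rTotal(m), 10)
})

test_that("decomposition matches dense line-sampling of the axis", {
  set.seed(42)
  for (i in 1:10) {
    tip <- rnorm(3, sd = 20)
    target <- rnorm(3, sd = 20)
    axis <- axisFromAngles(runif(1, -80, 80), runif(1, 0, 360))
    m <- decomposeSeparation(tip, target, axis)
    o <- lineSampleDecompose(tip, target, axis)
    expect_equal(rLateral(m), o$rLateral, tolerance = 1e-3)
    expect_equal(rAxial(m), o$rAxial, tolerance = 1e-2)
    expect_equal(rTotal(m), o$rTotal, tolerance = 1e-9)
  }
})

test_that("non-unit axes are rejected", {
  expect_error(decomposeSeparation(c(0, 0, 0), c(1, 1, 1), c(1, 1, 0)),
               class = "invalidParameter")
})

test_that("decomposition is invariant under rigid motions", {
  set.seed(7)
  for (i in 1:20) {
    tip <- rnorm(3, sd = 50)
    target <- rnorm(3, sd = 50)
    axis <- axisFromAngles(runif(1, -85, 85), runif(1, 0, 360))
    m <- decomposeSeparation(tip, target, axis)
    shift <- rnorm(3, sd = 100)
    mt <- decomposeSeparation(tip + shift, target + shift, axis)
    expect_equal(rLateral(mt), rLateral(m), tolerance = 1e-9)
    expect_equal(rAxial(mt), rAxial(m), tolerance = 1e-9)
    R <- randomRotation()
    mr <- decomposeSeparation(as.numeric(R %*% tip), as.numeric(R %*% target),
                              as.numeric(R %*% axis))
    expect_equal(rLateral(mr), rLateral(m), tolerance = 1e-9)
    expect_equal(rAxial(mr), rAxial(m), tolerance = 1e-9)
    expect_equal(rTotal(mr), rTotal(m), tolerance = 1e-9)
  }
})

test_that("voxel/micron conversion honors voxel size, origin and bounds", {
  g <- voxelGrid(c(256, 256, 150), c(1.23, 1.23, 2))
  expect_equal(voxelToMicron(c(0, 0, 0), g), c(0, 0, 0))
  expect_equal(voxelToMicron(c(10, 10, 5), g), c(12.3, 12.3, 10))
  set.seed(3)
  idx <- matrix(runif(30, 0, 100), 10L, 3L)
  expect_equal(voxelToMicron(idx, g),
               sweep(idx, 2L, c(1.23, 1.23, 2), `*`))
  # round trip and bounds flag
  p <- c(40.2, 17.9, 101.4)
  back <- voxelToMicron(as.numeric(micronToVoxel(p, g)), g)
  expect_equal(back, p, tolerance = 1e-12)
  expect_true(attr(micronToVoxel(c(1, 1, 1), g), "inBounds"))
  expect_false(attr(micronToVoxel(c(-5, 1, 1), g), "inBounds"))
  # an ImageStack origin participates in the mapping
  st <- imageStack(array(0, c(4, 4, 2)), c(1.23, 1.23, 2), origin = c(10, 0, 6))
  expect_equal(voxelToMicron(c(1, 0, 1), st), c(11.23, 0, 8))
})

test_that("separation metrics satisfy the Pythagorean identity", {
  set.seed(11)
  for (i in 1:200) {
    m <- decomposeSeparation(rnorm(3, sd = 30), rnorm(3, sd = 30),
                             axisFromAngles(runif(1, -85, 85),
                                            runif(1, 0, 360)))
    expect_equal(rTotal(m)^2, rLateral(m)^2 + rAxial(m)^2,
                 tolerance = 1e-9)
    expect_gte(rLateral(m), 0)
  }
})
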
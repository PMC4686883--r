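test_that("rendering is bit-identical under a fixed seed", {
  sp <- somaScene(noise = list(type = "poisson", readSigma = 2), seed = 9)
  r1 <- renderStack(sp, region = list(center = c(250, 157, 180),
                                      halfExtent = c(20, 20, 15)))
  r2 <- renderStack(sp, region = list(center = c(250, 157, 180),
                                      halfExtent = c(20, 20, 15)))
  expect_identical(intensities(r1$cells), intensities(r2$cells))
  expect_identical(intensities(r1$pipette), intensities(r2$pipette))
  r3 <- renderStack(sp, region = list(center = c(250, 157, 180),
                                      halfExtent = c(20, 20, 15)), seed = 10)
  expect_false(identical(intensities(r3$cells), intensities(r1$cells)))
})

test_that("noise-free soma renders brightest at its center voxel", {
  ctr <- c(250, 157.4, 180)
  sp <- somaScene(center = ctr)
  st <- cellROI(sp)
  a <- intensities(st)
  idx <- arrayInd(which.max(a), dim(a)) - 1L
  um <- stackOrigin(st) + idx * voxelSize(st)
  expect_lt(max(abs(um - ctr) / voxelSize(st)), 0.75)
})

test_that("integrated soma intensity scales with radius cubed", {
  ratios <- vapply(c(3, 4, 5, 6, 7), function(rad) {
    sp <- somaScene(radius = rad)
    a <- intensities(cellROI(sp)) - sp@backgroundLevel
    sum(a) / rad^3
  }, numeric(1L))
  expect_lt(max(ratios) / min(ratios), 1.05 / 0.95)
})

test_that("cells outside the grid are clipped with a warning", {
  expect_warning(
    renderStack(somaScene(center = c(500, 157, 180))),
    "outside the grid")
})

test_that("rendered tips are recovered by the localization pipeline", {
  tip <- c(140.1, 156.2, 110.7)
  sp <- tipScene(tip, seed = 44)
  est <- locateTip(tipROI(sp), sp@geometry)
  expect_lt(max(abs(est - tip) / voxelUm), 1 + 1e-9)
})

test_that("zero deflection lands the tip on target with either strategy", {
  sp <- batchScene()
  for (strat in c("naive", "adaptive")) {
    rec <- simulateApproach(sp, deflectionModel(), strat, seed = 2L)
    expect_true(rec$success)
    expect_lt(rLateral(rec$final), max(voxelUm))
    expect_equal(abs(rAxial(rec$final)), 12, tolerance = 0.1)
  }
})

test_that("a fixed lateral deflection shows up in full on naive approaches", {
  sp <- batchScene()
  axis <- approachAxis(sp@geometry)
  B <- lateralBasis(axis)
  model <- deflectionModel(lateral = 10 * B[1L, ])
  rec <- simulateApproach(sp, model, "naive", seed = 3L)
  expect_equal(rLateral(rec$final), 10, tolerance = max(voxelUm))
})

test_that("the whole simulated approach is seed-deterministic", {
  sp <- batchScene()
  B <- lateralBasis(approachAxis(sp@geometry))
  model <- deflectionModel(lateral = 7 * B[1L, ], targetDrift = 4 * B[2L, ])
  r1 <- simulateApproach(sp, model, "adaptive", seed = 21L)
  r2 <- simulateApproach(sp, model, "adaptive", seed = 21L)
  expect_identical(r1$finalTip, r2$finalTip)
  expect_identical(rLateral(r1$final), rLateral(r2$final))
})

test_that("batch simulation returns one metrics row per approach", {
  tb <- simulateBatch(4, "naive", seed = 5)
  expect_equal(nrow(tb), 4L)
  expect_true(all(c("rLateral", "rAxial", "rTotal", "success", "snr",
                    "dx", "dy", "dz") %in% names(tb)))
  expect_true(all(tb$rAxial >= 0))
})

test_that("dense labeling still resolves the soma nearest the click", {
  ok <- 0L
  n <- 100L
  for (i in seq_len(n)) {
    base <- phantomSpec(tip = c(137, 157.4, 112),
                        cells = list(list(center = c(250, 157.4, 180),
                                          radius = 5, peak = 150)),
                        noise = list(type = "poisson", readSigma = 2),
                        seed = i)
    sp <- densePhantomSpec(base, nDistractors = 20, seed = i * 7L)
    tru <- sp@cells[[1L]]$center
    set.seed(1000L + i)
    nominal <- tru + runif(3L, -2.8, 2.8)
    shot <- renderStack(sp, region = list(center = nominal,
                                          halfExtent = c(25, 25, 20)),
                        seed = i)
    est <- tryCatch(locateTarget(shot$cells, nominal),
                    pipetteAimError = function(e) NULL)
    if (!is.null(est) && sqrt(sum((est - tru)^2)) < 3) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.95)
})
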
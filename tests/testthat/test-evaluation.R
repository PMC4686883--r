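mkTable <- function(rl, strategy = "adaptive") {
  data.frame(strategy = strategy, rLateral = rl, rAxial = rl + 1,
             rTotal = sqrt(rl^2 + (rl + 1)^2))
}

test_that("summaries report mean, sample SD and N per strategy", {
  tb <- rbind(mkTable(c(3, 4, 5), "adaptive"), mkTable(c(10, 12), "naive"))
  s <- summarizeApproaches(tb)
  row <- s[s$strategy == "adaptive" & s$metric == "rLateral", ]
  expect_equal(row$mean, 4)
  expect_equal(row$sd, 1)
  expect_equal(row$n, 3L)
  expect_equal(s[s$strategy == "naive" & s$metric == "rLateral", ]$mean, 11)
  # surface distance subtracts the soma radius from the center distance
  rowS <- s[s$strategy == "adaptive" & s$metric == "surfaceDistance", ]
  expect_equal(rowS$mean, mean(mkTable(c(3, 4, 5))$rTotal) - 5)
})

test_that("a single approach has no defined SD", {
  s <- summarizeApproaches(mkTable(4.2))
  expect_true(all(is.na(s$sd)))
  expect_true(all(s$n == 1L))
  empty <- data.frame(strategy = character(0L), rLateral = numeric(0L),
                      rAxial = numeric(0L), rTotal = numeric(0L))
  expect_error(summarizeApproaches(empty), class = "invalidParameter")
})

test_that("summaries agree with a streaming mean/variance computation", {
  set.seed(19)
  x <- runif(57, 0, 20)
  s <- summarizeApproaches(mkTable(x))
  # Welford's online algorithm as the independent route
  m <- 0; m2 <- 0; n <- 0
  for (v in x) {
    n <- n + 1
    d <- v - m
    m <- m + d / n
    m2 <- m2 + d * (v - m)
  }
  row <- s[s$metric == "rLateral", ]
  expect_equal(row$mean, m, tolerance = 1e-12)
  expect_equal(row$sd, sqrt(m2 / (n - 1)), tolerance = 1e-12)
})

test_that("precision strings follow the mean +/- SD convention", {
  expect_equal(formatPrecision("r_lateral", 5.04, 2.93, 11),
               "r_lateral = 5.04 +/- 2.93 um, N = 11")
})

test_that("mean square deviation measures spread about the centroid", {
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(meanSquareDeviation(pts), 1)
  shifted <- sweep(pts, 2L, c(5, -3, 2), `+`)
  expect_equal(meanSquareDeviation(shifted), 1)
  expect_error(meanSquareDeviation(pts[1L, , drop = FALSE]),
               class = "invalidParameter")
})

test_that("outlier filtering flags but keeps distant approaches", {
  tb <- mkTable(c(3, 4))
  tb$rTotal <- c(12, 45.8)
  expect_message(out <- outlierFilter(tb, 40), "flagged")
  expect_equal(out$excluded, c(FALSE, TRUE))
  expect_equal(nrow(out), 2L)  # kept in the table
  s <- summarizeApproaches(out)
  expect_true(all(s$n == 1L))  # excluded from the statistics
  # nothing beyond the threshold leaves the table untouched
  tb2 <- outlierFilter(mkTable(c(1, 2)), 40)
  expect_false(any(tb2$excluded))
  # excluded count is non-increasing in the threshold
  set.seed(23)
  tb3 <- mkTable(runif(40, 0, 60))
  counts <- vapply(c(10, 20, 30, 50),
                   function(th) attr(outlierFilter(tb3, th), "nExcluded"),
                   integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("point clouds preserve the lateral/axial decomposition", {
  axis <- axisFromAngles(31, 0)
  # an on-axis approach maps onto the reference axis
  tb <- data.frame(dx = -12 * axis[1L], dy = -12 * axis[2L],
                   dz = -12 * axis[3L])
  pc <- pointCloudExport(tb, axis)
  expect_equal(pc$u, -12, tolerance = 1e-9)
  expect_equal(abs(pc$v) + abs(pc$w), 0, tolerance = 1e-9)
  expect_equal(attr(pc, "somaRadius"), 5)
  # random clouds: r_lateral / r_axial recomputed after rotation agree
  set.seed(29)
  d <- matrix(rnorm(30, sd = 8), 10L, 3L)
  tb2 <- data.frame(dx = d[, 1L], dy = d[, 2L], dz = d[, 3L])
  pc2 <- pointCloudExport(tb2, axis)
  for (i in 1:10) {
    m <- decomposeSeparation(d[i, ], c(0, 0, 0), axis)
    expect_equal(sqrt(pc2$v[i]^2 + pc2$w[i]^2), rLateral(m),
                 tolerance = 1e-9)
    expect_equal(pc2$u[i], -rAxial(m), tolerance = 1e-9)
  }
})
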
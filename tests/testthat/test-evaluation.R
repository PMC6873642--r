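test_that("SSIM: identity, constants, symmetry and loop oracle", {
  a <- withr::with_seed(1, matrix(runif(32 * 32), 32, 32))
  expect_equal(metricSSIM(a, a), 1)

  # constant 0 vs constant 1: stabilizer-dominated, far below 0.01
  expect_lt(metricSSIM(matrix(0, 16, 16), matrix(1, 16, 16)), 0.01)

  b <- withr::with_seed(2, matrix(runif(32 * 32), 32, 32))
  expect_equal(metricSSIM(a, b), metricSSIM(b, a), tolerance = 1e-15)
  expect_equal(metricSSIM(a, b), bfSSIM(a, b), tolerance = 1e-6)
  expect_error(metricSSIM(a, matrix(0, 8, 8)), "shape")
})

test_that("GCF: constants vanish, brightness is ignored, oracle agreement", {
  expect_identical(metricGCF(matrix(0.2, 32, 32)), 0)
  expect_identical(metricGCF(matrix(0.9, 32, 32)), 0)

  # checkerboard and random images match the per-pixel reference
  cb <- outer(1:64, 1:64, function(r, c) (r + c) %% 2)
  expect_equal(metricGCF(cb), bfGCF(cb), tolerance = 1e-9)
  m <- withr::with_seed(3, matrix(runif(48 * 48), 48, 48))
  expect_equal(metricGCF(m), bfGCF(m), tolerance = 1e-9)

  expect_error(metricGCF(matrix(0, 1, 1)), "2 x 2")
})

test_that("contrast improvement has the stated sign convention", {
  m <- withr::with_seed(4, matrix(runif(32 * 32), 32, 32))
  expect_identical(deltaGCF(m, m), 0)
  # a constant test frame against any textured reference is negative
  expect_lt(deltaGCF(matrix(0.5, 32, 32), m), 0)
  n <- withr::with_seed(5, matrix(runif(32 * 32), 32, 32))
  expect_equal(deltaGCF(m, n), metricGCF(m) - metricGCF(n), tolerance = 1e-15)
})

test_that("the composite score matches the printed tables and is monotone", {
  # both normalization anchors
  expect_equal(totCS(0.6, -0.5), 0)
  # published cells for the natural-image and simulated-study columns
  expect_equal(round(totCS(0.86, 0.66), 2), 0.64)
  expect_equal(round(totCS(0.90, 0.01), 2), 0.52)
  # strictly increasing in both arguments over a grid
  g <- expand.grid(s = seq(0, 1, by = 0.1), d = seq(-1, 1.5, by = 0.25))
  v <- totCS(g$s, g$d)
  expect_true(all(totCS(g$s + 0.01, g$d) > v))
  expect_true(all(totCS(g$s, g$d + 0.01) > v))
})

test_that("method evaluation aggregates per-image metrics", {
  frames <- withr::with_seed(6, lapply(1:5, function(i)
    matrix(runif(32 * 32), 32, 32)))
  names(frames) <- sprintf("img%d", 1:5)
  lr <- lapply(frames, function(m) pmax(m - 0.1, 0))

  # sr == hr: SSIM 1 +- 0, contrast improvement 0 +- 0
  rep0 <- evaluateMethod(frames, frames, lr, caseStudy = "CS1")
  ag <- reportAggregates(rep0)
  expect_equal(ag$mean[ag$metric == "ssim_hr"], 1)
  expect_equal(ag$sd[ag$metric == "ssim_hr"], 0)
  expect_equal(ag$mean[ag$metric == "dgcf_hr"], 0)

  # single image: sd fields are zero
  rep1 <- evaluateMethod(frames[1], frames[1], lr[1])
  expect_true(all(reportAggregates(rep1)$sd == 0))

  # aggregates are recomputable from the rows; tot_cs honours its formula
  sr <- withr::with_seed(7, lapply(frames, function(m)
    pmin(pmax(m + matrix(rnorm(1024, 0, 0.05), 32), 0), 1)))
  names(sr) <- names(frames)
  rep2 <- evaluateMethod(sr, frames, lr, caseStudy = "CS2")
  rows <- reportRows(rep2)
  expect_equal(rows$tot_cs, totCS(rows$ssim_hr, rows$dgcf_hr))
  ag2 <- reportAggregates(rep2)
  expect_equal(ag2$mean[ag2$metric == "tot_cs"], mean(rows$tot_cs))
  expect_equal(ag2$sd[ag2$metric == "tot_cs"], sd(rows$tot_cs))

  names(sr)[1] <- "other"
  expect_error(evaluateMethod(sr, frames, lr), "ids")
})

test_that("paired significance test matches the textbook formula", {
  x <- withr::with_seed(8, rnorm(20, 1, 0.3))
  y <- withr::with_seed(9, rnorm(20, 0.8, 0.3))
  got <- pairedSignificance(x, y)
  d <- x - y
  tref <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$statistic, tref, tolerance = 1e-12)
  expect_equal(got$p.value, 2 * pt(-abs(tref), length(d) - 1),
               tolerance = 1e-12)
  expect_false(got$degenerate)

  # identical lists: degenerate, t = 0
  same <- pairedSignificance(x, x)
  expect_true(same$degenerate)
  expect_identical(same$statistic, 0)

  # near-constant positive difference: large |t|, small p
  jit <- withr::with_seed(10, rnorm(20, 0, 1e-3))
  big <- pairedSignificance(x + 0.5 + jit, x)
  expect_gt(big$statistic, 50)
  expect_lt(big$p.value, 1e-10)
})

test_that("MOS tables aggregate to mean and sd per method and question", {
  sc <- data.frame(method = rep(c("A", "B"), each = 4),
                   question = rep(c("Q1", "Q2"), 4),
                   score = c(5, 4, 4, 4, 2, 3, 3, 3))
  ag <- mosAggregate(sc)
  expect_equal(ag$mean[ag$method == "A" & ag$question == "Q1"], 4.5)
  expect_equal(nrow(ag), 4L)
})
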
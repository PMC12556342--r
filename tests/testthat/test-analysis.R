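test_that("membrane intensity normalizes to tissue mean one", {
  mesh <- readSkeleton(thetaRaster())
  img <- matrix(1, 15, 25)
  res <- membraneIntensity(img, mesh)
  expect_equal(res$intensity, rep(1, nrow(res)))

  # one bright membrane dominates
  img2 <- matrix(1, 15, 25)
  img2[8, ] <- 9  # the chord row
  res2 <- membraneIntensity(img2, mesh)
  chordId <- which(vapply(membranes(mesh), function(m) {
    m$cell1 > 0 && m$cell2 > 0
  }, logical(1)))
  expect_equal(which.max(res2$intensity), match(chordId, res2$membrane))
  expect_equal(mean(res2$intensity), 1, tolerance = 1e-12)
})

test_that("membrane intensity equals a naive per-vertex oracle on a smooth image", {
  tis <- relaxedTissue16()
  nr <- ceiling(max(tis@vertices[, 2])) + 5
  nc <- ceiling(max(tis@vertices[, 1])) + 5
  img <- outer(seq_len(nr), seq_len(nc), function(r, c) 1 + 0.01 * c)
  res <- membraneIntensity(img, tis)
  # naive loop oracle with the same smoothing definition
  oracle <- vapply(membranes(tis), function(m) {
    pts <- epiforce:::membranePoints(tis, m)
    if (nrow(pts) >= 5) {
      pts[, 1] <- signal::sgolayfilt(pts[, 1], p = 3, n = 5)
      pts[, 2] <- signal::sgolayfilt(pts[, 2], p = 3, n = 5)
    }
    raw <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      rr <- min(max(round(pts[i, 2]) + 1, 1), nr)
      cc <- min(max(round(pts[i, 1]) + 1, 1), nc)
      raw[i] <- img[rr, cc]
    }
    sm <- numeric(length(raw))
    for (i in seq_along(raw)) {
      sm[i] <- median(raw[max(1, i - 1):min(length(raw), i + 1)])
    }
    mean(sm)
  }, numeric(1))
  oracle <- oracle / mean(oracle)
  expect_equal(res$intensity, unname(oracle), tolerance = 1e-9)
})

test_that("pressure-weighted density integrates to one and weights peaks", {
  d1 <- pressureWeightedDensity(5, weights = NULL, bw = 0.5)
  expect_equal(d1$x[which.max(d1$y)], 5, tolerance = 0.1)
  expect_equal(sum(d1$y) * diff(d1$x[1:2]), 1, tolerance = 0.01)

  # two clusters, one with double the weight
  x <- c(rnorm(50, 0, 0.2), rnorm(50, 10, 0.2))
  w <- c(rep(1, 50), rep(2, 50))
  d2 <- pressureWeightedDensity(x, w, bw = 0.3)
  y0 <- max(d2$y[abs(d2$x - 0) < 1])
  y10 <- max(d2$y[abs(d2$x - 10) < 1])
  expect_gt(y10, y0)
  # negative (mean-zero) weights are shifted and the shift reported
  d3 <- pressureWeightedDensity(c(0, 1, 2), weights = c(-1, 0, 1))
  expect_equal(d3$shift, 1)
})

test_that("density maxima detection equals an exhaustive scan", {
  x <- seq(-5, 15, length.out = 800)
  y <- dnorm(x, 0, 1) + 0.8 * dnorm(x, 9, 1.2)
  mx <- findDensityMaxima(x, y)
  expect_equal(nrow(mx), 2L)
  expect_equal(mx$x, c(0, 9), tolerance = 0.1)
  # brute-force scan oracle
  idx <- which(vapply(2:(length(y) - 1), function(i) {
    y[i] > y[i - 1] && y[i] >= y[i + 1]
  }, logical(1))) + 1L
  expect_equal(mx$x, x[idx], tolerance = 1e-12)
  # monotone curve: no maxima
  expect_equal(nrow(findDensityMaxima(x, exp(x / 10))), 0L)
})

test_that("imposed high-pressure zones are recovered from the weighted density", {
  set.seed(9)
  # synthetic migrating cluster: cells along an axis with two imposed
  # high-pressure zones
  pos <- runif(120, 0, 100)
  press <- -0.5 + dnorm(pos, 30, 4) * 30 + dnorm(pos, 70, 4) * 30 +
    rnorm(120, 0, 0.2)
  d <- pressureWeightedDensity(pos, press, bw = 4)
  mx <- findDensityMaxima(d)
  cellRadius <- 5
  expect_true(any(abs(mx$x - 30) < cellRadius))
  expect_true(any(abs(mx$x - 70) < cellRadius))
})

test_that("recoil fits recover the tension-to-damping ratio", {
  t <- 0:12
  L <- 10 + 2 * 0.5 * t
  fit <- fitRecoil(t, L)
  expect_equal(fit$lambdaEta, 0.5, tolerance = 1e-12)
  expect_equal(fit$L0, 10, tolerance = 1e-12)
  expect_equal(fit$flag, "")
  # relative-elongation input
  fitR <- fitRecoil(t, L / 10, relative = TRUE, L0 = 10)
  expect_equal(fitR$lambdaEta, 0.5, tolerance = 1e-12)
  # negative slope flags no recoil
  expect_equal(fitRecoil(t, 10 - 0.2 * t)$flag, "no_recoil")
  expect_error(fitRecoil(c(0, 1), c(1, 2)), "3 points")
})

test_that("noisy recoil traces recover lambda/eta within Monte Carlo error", {
  set.seed(31)
  trueLE <- 0.8; sigma <- 0.4
  t <- seq(0, 9, by = 1)
  est <- replicate(100, {
    L <- 12 + 2 * trueLE * t + rnorm(length(t), 0, sigma)
    fitRecoil(t, L)$lambdaEta
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - trueLE), 2 * se + 1e-12)
})

test_that("a saturating plateau distorts the fit only if included", {
  t <- 0:30
  L <- ifelse(t <= 10, 10 + 1.0 * t, 20)  # linear then plateau
  early <- fitRecoil(t, L, window = c(0, 10))
  late <- fitRecoil(t, L, window = c(0, 30))
  expect_equal(early$lambdaEta, 0.5, tolerance = 1e-12)
  expect_lt(late$lambdaEta, early$lambdaEta)
})

test_that("scale-parameter estimates follow the viscous/elastic definition", {
  est <- estimateScaleParameter(lambdaEta = c(2, 2), vbar = 2)
  expect_equal(est$rho, c(1, 1))
  expect_equal(estimateScaleParameter(1, 0)$rho, 0)
  expect_message(est2 <- estimateScaleParameter(c(1, -2, 2), vbar = 1),
                 "excluded")
  expect_equal(est2$excluded, 2L)
  # cohort with true rho: vbar = rho * lambdaEta
  set.seed(12)
  le <- rlnorm(200, log(0.6), 0.2)
  est3 <- estimateScaleParameter(le, vbar = 0.15 * le)
  expect_equal(est3$mean, 0.15, tolerance = 1e-12)
})
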
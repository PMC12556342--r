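staticSeries <- function(nFrames = 3) {
  tis <- relaxedTissue16()
  lapply(seq_len(nFrames), function(i) { tis@frameId <- i; tis })
}

test_that("a static tissue duplicated over frames tracks with zero displacement", {
  series <- trackPivots(staticSeries(3))
  tr <- tracks(series)
  expect_equal(length(unique(tr$track)), length(pivots(relaxedTissue16())))
  disp <- tapply(seq_len(nrow(tr)), tr$track, function(i) {
    max(dist(tr[i, c("x", "y")]))
  })
  expect_true(all(disp == 0))
})

test_that("tracking recovers generator identities on a moving series", {
  tis <- relaxedTissue16()
  tis2 <- applyCondition(tis, "circular", seed = 9)
  snaps <- relaxOverdamped(tis2, nFrames = 4)
  series <- trackPivots(snaps)
  tr <- tracks(series)
  # generator frames share vertex ids: a correct track keeps one pivot id
  consistent <- tapply(tr$pivot, tr$track, function(p) length(unique(p)) == 1)
  expect_gte(mean(consistent), 0.95)
})

test_that("correction entries override the automatic matching", {
  frames <- staticSeries(2)
  p <- pivots(frames[[1]])
  # deliberately force pivot p1 to map onto a different pivot p2
  co <- list(list(frame_from = 1L, pivot_from = p[1], frame_to = 2L,
                  pivot_to = p[2]))
  series <- trackPivots(frames, corrections = co)
  tr <- tracks(series)
  t1 <- tr$track[tr$frame == 1 & tr$pivot == p[1]]
  expect_equal(tr$pivot[tr$frame == 2 & tr$track == t1], p[2])
  # unknown pivots are reported with the offending entries listed
  bad <- list(list(frame_from = 1L, pivot_from = 999999L, frame_to = 2L,
                   pivot_to = p[2]))
  expect_error(trackPivots(frames, corrections = bad), "entry 1")
})

test_that("velocities use forward differences with a backward final frame", {
  tis <- relaxedTissue16()
  u <- c(0.8, -0.5)
  frames <- lapply(1:4, function(i) {
    f <- tis; f@vertices <- sweep(tis@vertices, 2, -(i - 1) * u)
    f@frameId <- i
    epiforce:::fitMeshGeometry(f)
  })
  series <- trackPivots(frames)
  cv <- computeVelocities(series)
  v <- cv$velocities
  expect_equal(unique(round(v$vx, 10)), u[1])
  expect_equal(unique(round(v$vy, 10)), u[2])
  # final frame uses the backward difference and matches too
  expect_equal(v$vx[v$frame == 4], rep(u[1], sum(v$frame == 4)))
  expect_equal(cv$vbar, sqrt(sum(u^2)), tolerance = 1e-12)
})

test_that("a track missing in a frame is assigned zero velocity", {
  tis <- relaxedTissue16()
  tr <- data.frame(track = c(1, 1, 2), frame = c(1, 3, 1),
                   pivot = c(pivots(tis)[1], pivots(tis)[1], pivots(tis)[2]),
                   x = c(0, 2, 5), y = c(0, 0, 5))
  series <- new("FrameSeries", frames = staticSeries(3), tracks = tr, dt = 1)
  cv <- computeVelocities(series)
  v1 <- cv$velocities[cv$velocities$track == 1 & cv$velocities$frame == 1, ]
  expect_equal(c(v1$vx, v1$vy), c(0, 0)) # successor frame missing
  expect_true(v1$assigned)
})

test_that("rho = 0 reproduces the static system bitwise", {
  tis <- relaxedTissue16()
  vt <- data.frame(pivot = pivots(tis),
                   vx = rnorm(length(pivots(tis))),
                   vy = rnorm(length(pivots(tis))))
  sysS <- assembleStaticSystem(tis)
  sysD <- assembleDynamicSystem(tis, vt, rho = 0, vbar = 1)
  expect_identical(sysD@M, sysS@M)
  expect_identical(sysD@B, sysS@B)
  expect_error(assembleDynamicSystem(tis, vt, rho = -0.1), "non-negative")
})

test_that("dynamic right-hand side carries rho-scaled nondimensional velocities", {
  mesh <- starMesh(c(90, 210, 330))
  vbar <- 2
  vt <- data.frame(pivot = 1L, vx = vbar, vy = 0)
  sys <- assembleDynamicSystem(mesh, vt, rho = 0.1, vbar = vbar)
  expect_equal(sys@B[1], 0.1)  # x row of the moving pivot
  expect_equal(sys@B[2], 0)    # y row
  expect_equal(sys@B[3], 3)    # constraint row keeps E
  expect_equal(sys@meta$vnorm, 0.1)
})

test_that("uniform drift changes only the right-hand side", {
  tis <- relaxedTissue16()
  p <- pivots(tis)
  vt0 <- data.frame(pivot = p, vx = rnorm(length(p), 0, 0.1),
                    vy = rnorm(length(p), 0, 0.1))
  vt1 <- vt0; vt1$vx <- vt1$vx + 5
  s0 <- assembleDynamicSystem(tis, vt0, rho = 0.1, vbar = 1)
  s1 <- assembleDynamicSystem(tis, vt1, rho = 0.1, vbar = 1)
  expect_identical(s0@M, s1@M)
  expect_false(identical(s0@B, s1@B))
})

test_that("series inference at rho 0 or zero motion equals static inference", {
  frames <- staticSeries(2)
  series <- trackPivots(frames)
  resD <- inferSeries(series, rho = 0.1) # zero velocities: static limit
  resS <- inferSeries(series, rho = 0)
  expect_equal(resD$tensions$lambda, resS$tensions$lambda, tolerance = 1e-12)
  # identical frames give identical per-frame solutions
  l1 <- resD$tensions$lambda[resD$tensions$frame == 1]
  l2 <- resD$tensions$lambda[resD$tensions$frame == 2]
  expect_equal(l1, l2, tolerance = 1e-12)
  stat <- solveStresses(assembleStaticSystem(frames[[1]]), mesh = frames[[1]])
  expect_equal(l1, unname(tensions(stat)), tolerance = 1e-12)
})

test_that("dynamic inference beats static inference on a moving synthetic series", {
  tis <- relaxedTissue16()
  tis2 <- applyCondition(tis, "x_furrow", seed = 4)
  snaps <- relaxOverdamped(tis2, nFrames = 6)
  series <- trackPivots(snaps)
  truth <- snaps[[1]]@trueTensions
  grid <- c(0, 0.02, 0.05, 0.1, 0.2)
  sc <- epiforce:::scoreRhoCurve(series, truth, grid)
  expect_gt(max(sc[-1]), sc[1]) # some rho > 0 beats the static solution
})
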
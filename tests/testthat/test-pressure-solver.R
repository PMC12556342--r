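mkStress <- function(mesh, lam) {
  new("StressSolution",
      tensions = stats::setNames(lam, seq_along(lam)),
      lagrange = 0, residualNorm = 0, solverPath = "direct_inverse",
      normalization = "mean_one")
}

test_that("straight interface between two cells gives zero pressures", {
  mesh <- twoCellCurvedMesh(kappa = 1e-9)
  mesh@membranes[[1]]$curvature <- 0
  sol <- solvePressures(assemblePressureSystem(mesh, mkStress(mesh, c(1, 1, 1))))
  expect_equal(unname(pressures(sol)), c(0, 0), tolerance = 1e-12)
})

test_that("curved two-cell interface follows the Young-Laplace closed form", {
  kappa <- 0.05
  mesh <- twoCellCurvedMesh(kappa = kappa)
  sol <- solvePressures(assemblePressureSystem(mesh, mkStress(mesh, c(1, 1, 1))))
  # center of curvature sits inside cell 1: higher pressure on the
  # center side, so P = (+kappa/2, -kappa/2) under the mean-zero gauge
  expect_equal(unname(pressures(sol)), c(kappa / 2, -kappa / 2),
               tolerance = 1e-3)
  # doubling all tensions doubles all pressures (linearity); plain
  # tension vectors bypass the mean-one solution container
  sol2 <- solvePressures(assemblePressureSystem(
    mesh, stats::setNames(c(2, 2, 2), 1:3)))
  expect_equal(unname(pressures(sol2)), 2 * unname(pressures(sol)),
               tolerance = 1e-9)
  # flipping the curvature sign convention flips all pressures
  mesh2 <- mesh
  mesh2@membranes[[1]]$curvature <- -mesh@membranes[[1]]$curvature
  sol3 <- solvePressures(assemblePressureSystem(mesh2, mkStress(mesh2, c(1, 1, 1))))
  expect_equal(unname(pressures(sol3)), -unname(pressures(sol)),
               tolerance = 1e-9)
})

test_that("multicell pressures match a dense least-squares oracle", {
  tis <- relaxTissue(generateVoronoiTissue(n = 4, seed = 5))
  st <- solveStresses(assembleStaticSystem(tis, includeBorder = TRUE),
                      mesh = tis)
  sys <- assemblePressureSystem(tis, st)
  sol <- solvePressures(sys)
  # oracle: explicit minimization over pressures with mean fixed to zero
  nc <- ncol(sys@M)
  rowsF <- seq_len(nrow(sys@M) - 1L)
  obj <- function(free) {
    P <- c(free, -sum(free))
    sum((sys@M[rowsF, ] %*% P - sys@B[rowsF])^2)
  }
  o <- optim(rep(0, nc - 1), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-15))
  PO <- c(o$par, -sum(o$par))
  keep <- !is.na(pressures(sol))
  expect_equal(unname(pressures(sol))[keep], PO, tolerance = 1e-6)
  expect_equal(mean(pressures(sol), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("pressures are independent of cell indexing order", {
  kappa <- 0.04
  mesh <- twoCellCurvedMesh(kappa = kappa)
  sol <- solvePressures(assemblePressureSystem(mesh, mkStress(mesh, c(1, 1, 1))))
  # relabel: swap cells 1 and 2 everywhere (curvature sign refitted)
  mesh2 <- mesh
  mesh2@membranes <- lapply(mesh@membranes, function(m) {
    m$cell1 <- c(2L, 1L, 0L)[match(m$cell1, c(1L, 2L, 0L))]
    m$cell2 <- c(2L, 1L, 0L)[match(m$cell2, c(1L, 2L, 0L))]
    if (m$cell1 == 0L && m$cell2 > 0L) { tmp <- m$cell1; m$cell1 <- m$cell2; m$cell2 <- tmp }
    m
  })
  mesh2@cells <- list(
    within(mesh@cells[[2]], id <- 1L),
    within(mesh@cells[[1]], id <- 2L))
  mesh2 <- epiforce:::fitMeshGeometry(mesh2)
  sol2 <- solvePressures(assemblePressureSystem(mesh2, mkStress(mesh2, c(1, 1, 1))))
  expect_equal(unname(pressures(sol2)), rev(unname(pressures(sol))),
               tolerance = 1e-9)
})

test_that("inferred pressures correlate with ground truth on a relaxed tissue", {
  tis <- relaxedTissue16()
  st <- solveStresses(assembleStaticSystem(tis), mesh = tis)
  pr <- solvePressures(assemblePressureSystem(tis, st))
  gt <- groundTruthPressures(tis)
  keep <- !is.na(pressures(pr))
  expect_gt(cor(pressures(pr)[keep], gt[keep]), 0.8)
  expect_equal(mean(pressures(pr)[keep]), 0, tolerance = 1e-9)
})
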
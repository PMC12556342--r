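test_that("all-black skeleton yields an empty mesh and bad input is rejected", {
  m <- readSkeleton(matrix(0L, 3, 3))
  expect_equal(length(cells(m)), 0L)
  expect_equal(length(membranes(m)), 0L)
  expect_error(readSkeleton(matrix(c(0, 1, 2, 0), 2, 2)), "binary")
  expect_error(readSkeleton(matrix(numeric(0), 0, 0)), "empty")
})

test_that("theta-shaped skeleton gives 2 cells, 2 pivots, 3 membranes", {
  mesh <- readSkeleton(thetaRaster())
  expect_equal(length(cells(mesh)), 2L)
  real <- Filter(function(m) m$flag != "self", membranes(mesh))
  expect_equal(length(real), 3L)
  pivInfo <- identifyPivots(mesh)
  junctions <- pivInfo[pivInfo$degree >= 3, ]
  expect_equal(nrow(junctions), 2L)
  # the chord membrane separates the two lobes
  chord <- Filter(function(m) m$cell1 > 0 & m$cell2 > 0, membranes(mesh))
  expect_equal(length(chord), 1L)
  expect_setequal(c(chord[[1]]$cell1, chord[[1]]$cell2), c(1L, 2L))
})

test_that("labeled-mask reader recovers cells, membranes and pivots", {
  mesh <- readLabeledMask(twoLabelMask())
  expect_equal(length(cells(mesh)), 2L)
  interior <- Filter(function(m) m$cell1 > 0 & m$cell2 > 0, membranes(mesh))
  expect_equal(length(interior), 1L)
  # the shared wall ends in two pivots on the tissue border
  pA <- interior[[1]]$pivotA; pB <- interior[[1]]$pivotB
  pt <- pivotType(mesh)
  expect_equal(unname(pt[as.character(c(pA, pB))]), c("border", "border"))

  mesh4 <- readLabeledMask(fourLabelMask())
  expect_equal(length(cells(mesh4)), 4L)
  pi4 <- identifyPivots(mesh4)
  inner <- pi4[pi4$type == "interior", ]
  expect_equal(nrow(inner), 1L)
  expect_equal(inner$degree, 4L)
  expect_true(inner$multiJunction)
})

test_that("single-label mask yields one cell against background only", {
  m <- matrix(0L, 10, 10); m[3:8, 3:8] <- 5L
  mesh <- readLabeledMask(m)
  expect_equal(length(cells(mesh)), 1L)
  expect_true(all(vapply(membranes(mesh), function(mm) {
    mm$cell2 == 0L
  }, logical(1))))
})

test_that("non-contiguous labels are flagged and reduced to largest piece", {
  m <- matrix(0L, 10, 14)
  m[2:9, 2:6] <- 1L
  m[2:5, 9:13] <- 2L
  m[8:9, 9:13] <- 2L  # second, smaller piece of label 2
  expect_warning(mesh <- readLabeledMask(m), "non-contiguous")
  expect_equal(length(cells(mesh)), 2L)
  expect_equal(cells(mesh)[[2]]$area, 4 * 5)
})

test_that("pivot identification distinguishes junctions, borders and multi-junctions", {
  # isolated cell: a closed loop has no junctions at all
  img <- matrix(0L, 12, 12)
  img[c(3, 9), 3:9] <- 1L; img[3:9, c(3, 9)] <- 1L
  mesh <- readSkeleton(img)
  expect_equal(length(cells(mesh)), 1L)
  pv <- identifyPivots(mesh)
  expect_equal(sum(pv$degree >= 3), 0L)
  # self-membrane excluded from force balance
  expect_true(any(vapply(membranes(mesh), function(m) m$flag == "self",
                         logical(1))))

  # two interior degree-3 pivots at the ends of a central shared wall
  piv <- rbind(c(0, 0), c(0, 10), c(-10, -5), c(10, -5),
               c(-10, 15), c(10, 15), c(-14, 5), c(14, 5))
  cycles <- list(c(1, 2, 7, 3), c(1, 4, 8, 2), c(1, 3, 4), c(2, 8, 6, 5, 7))
  mesh2 <- meshFromCells(piv, cycles, subdiv = 3)
  info <- identifyPivots(mesh2)
  inner <- info[info$type == "interior", ]
  expect_equal(sort(inner$pivot), c(1L, 2L))
  expect_equal(inner$degree, c(3L, 3L))
  expect_false(any(inner$multiJunction))
})

test_that("membrane chains partition the edge set", {
  mesh <- readSkeleton(thetaRaster())
  segCount <- sum(vapply(membranes(mesh), function(m) {
    length(m$chain) + (if (m$pivotA == m$pivotB) 1L else 2L) - 1L +
      (if (m$pivotA == m$pivotB) 1L else 0L)
  }, integer(1)))
  expect_equal(segCount, nrow(meshEdges(mesh)))
  # every membrane endpoint is a pivot
  for (m in membranes(mesh)) {
    expect_true(all(c(m$pivotA, m$pivotB) %in% pivots(mesh)))
  }
})

test_that("honeycomb center cell is bounded by six membranes", {
  mesh <- hexTissue()
  # the central cell of a 3x3 triangular lattice Voronoi
  cent <- colMeans(meshVertices(mesh))
  d <- vapply(cells(mesh), function(cl) {
    sum((cl$centroid - cent)^2)
  }, numeric(1))
  ctr <- which.min(d)
  expect_equal(length(cells(mesh)[[ctr]]$membranes), 6L)
})

test_that("skeleton and mask exports of the same tissue give isomorphic adjacency", {
  tis <- relaxedTissue16()
  skel <- exportSkeleton(tis, scale = 2)
  mask <- exportLabeledMask(tis, scale = 2)
  m1 <- readSkeleton(skel)
  m2 <- readLabeledMask(mask)
  expect_equal(length(cells(m1)), nCells(tis))
  expect_equal(length(cells(m2)), nCells(tis))
  adjGraph <- function(mesh) {
    pairs <- t(vapply(Filter(function(m) m$cell1 > 0 && m$cell2 > 0,
                             membranes(mesh)), function(m) {
      c(m$cell1, m$cell2)
    }, integer(2)))
    igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  }
  # the readers number cells differently: compare up to isomorphism
  expect_true(igraph::isomorphic(adjGraph(m1), adjGraph(m2)))
})
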
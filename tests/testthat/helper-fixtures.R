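# Fixtures are built in code: small rasters drawn by hand and vector
# meshes assembled through the package's own constructors.

# "theta" raster: a rectangular loop with one horizontal chord; two
# enclosed cells, two junction pixels, three membranes
thetaRaster <- function() {
  img <- matrix(0L, 15, 25)
  img[3, 3:23] <- 1L   # top wall
  img[13, 3:23] <- 1L  # bottom wall
  img[3:13, 3] <- 1L   # left wall
  img[3:13, 23] <- 1L  # right wall
  img[8, 3:23] <- 1L   # chord
  img
}

# two adjacent rectangular labels
twoLabelMask <- function() {
  m <- matrix(0L, 12, 20)
  m[3:10, 3:10] <- 1L
  m[3:10, 11:18] <- 2L
  m
}

# 2 x 2 grid of square labels: one interior corner where 4 labels meet
fourLabelMask <- function() {
  m <- matrix(0L, 14, 14)
  m[2:7, 2:7] <- 1L
  m[2:7, 8:13] <- 2L
  m[8:13, 2:7] <- 3L
  m[8:13, 8:13] <- 4L
  m
}

# honeycomb tissue: Voronoi of a triangular lattice is hexagonal
hexTissue <- function(rows = 3, cols = 3, s = 20, subdiv = 4L) {
  pts <- list()
  for (r in seq_len(rows)) {
    off <- if (r %% 2 == 0) s / 2 else 0
    for (c in seq_len(cols)) {
      pts[[length(pts) + 1L]] <- c((c - 0.5) * s + off,
                                   (r - 0.5) * s * sqrt(3) / 2)
    }
  }
  sites <- do.call(rbind, pts)
  rect <- c(min(sites[, 1]) - s / 2, max(sites[, 1]) + s / 2,
            min(sites[, 2]) - s / 2, max(sites[, 2]) + s / 2)
  polys <- epiforce:::voronoiPolygons(sites, rect)
  dd <- epiforce:::dedupeVertices(polys)
  meshFromCells(dd$vertices, dd$cycles, subdiv = subdiv)
}

# minimal hand-built junction mesh: one interior pivot at the origin
# with nArms straight membranes to outer tips at the given angles
starMesh <- function(anglesDeg, len = 10) {
  n <- length(anglesDeg)
  th <- anglesDeg * pi / 180
  verts <- rbind(c(0, 0), cbind(len * cos(th), len * sin(th)))
  edges <- cbind(rep(1L, n), 1L + seq_len(n))
  membs <- lapply(seq_len(n), function(i) {
    list(id = i, pivotA = 1L, pivotB = i + 1L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = "")
  })
  mesh <- new("TissueMesh", vertices = verts, edges = edges,
              cells = list(), membranes = membs,
              pivots = as.integer(1:(n + 1)),
              pivotType = c("interior", rep("border", n)),
              frameId = 1L, pixelSize = 1)
  epiforce:::fitMeshGeometry(mesh)
}

# K4 junction network: a triangle of junctions plus a center junction
# joined to all three (the three-bubble foam cluster). Six membranes,
# nine equations - the smallest network whose constrained solution is
# unique, with an all-positive self-stress.
k4Mesh <- function(perturb = 0) {
  j <- rbind(c(0, 0), c(10, 0), c(5, 8.66), c(5, 2.89) + perturb)
  membs <- list(
    list(id = 1L, pivotA = 1L, pivotB = 2L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = ""),
    list(id = 2L, pivotA = 2L, pivotB = 3L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = ""),
    list(id = 3L, pivotA = 3L, pivotB = 1L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = ""),
    list(id = 4L, pivotA = 1L, pivotB = 4L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = ""),
    list(id = 5L, pivotA = 2L, pivotB = 4L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = ""),
    list(id = 6L, pivotA = 3L, pivotB = 4L, chain = integer(0),
         cell1 = 0L, cell2 = 0L, flag = ""))
  edges <- do.call(rbind, lapply(membs, function(m) c(m$pivotA, m$pivotB)))
  storage.mode(edges) <- "integer"
  mesh <- new("TissueMesh", vertices = j, edges = edges,
              cells = list(), membranes = membs,
              pivots = 1:4,
              pivotType = rep("interior", 4),
              frameId = 1L, pixelSize = 1)
  epiforce:::fitMeshGeometry(mesh)
}

# two-cell mesh with a single curved interface of known curvature;
# everything else is background-facing scaffolding
twoCellCurvedMesh <- function(kappa = 0.05, lambda = 1) {
  R <- 1 / kappa
  # interface arc from (0,-5) to (0,5) bulging right; circle center on
  # the left (inside cell 1)
  half <- asin(5 / R)
  th <- seq(-half, half, length.out = 9)
  cx <- -sqrt(R^2 - 25)
  arc <- cbind(cx + R * cos(th), R * sin(th))
  nA <- nrow(arc)
  # outer box through the arc endpoints
  boxL <- rbind(c(-12, -5), c(-12, 5))
  boxR <- rbind(c(12, -5), c(12, 5))
  verts <- rbind(arc, boxL, boxR)
  iA <- 1L; iB <- nA # arc endpoints = pivots
  iBL1 <- nA + 1L; iBL2 <- nA + 2L; iBR1 <- nA + 3L; iBR2 <- nA + 4L
  membs <- list(
    list(id = 1L, pivotA = iA, pivotB = iB,
         chain = as.integer(2:(nA - 1L)),
         cell1 = 1L, cell2 = 2L, flag = ""),
    # left outer wall (cell 1 vs background) via the two box corners
    list(id = 2L, pivotA = iA, pivotB = iB, chain = c(iBL1, iBL2),
         cell1 = 1L, cell2 = 0L, flag = ""),
    # right outer wall (cell 2 vs background)
    list(id = 3L, pivotA = iA, pivotB = iB, chain = c(iBR1, iBR2),
         cell1 = 2L, cell2 = 0L, flag = "")
  )
  edges <- do.call(rbind, lapply(membs, function(m) {
    ids <- c(m$pivotA, m$chain, m$pivotB)
    cbind(ids[-length(ids)], ids[-1])
  }))
  storage.mode(edges) <- "integer"
  cellsL <- list(
    list(id = 1L, pivots = integer(0), membranes = c(1L, 2L),
         area = 100, centroid = c(-6, 0)),
    list(id = 2L, pivots = integer(0), membranes = c(1L, 3L),
         area = 100, centroid = c(6, 0))
  )
  mesh <- new("TissueMesh", vertices = verts, edges = edges,
              cells = cellsL, membranes = membs,
              pivots = c(iA, iB), pivotType = c("border", "border"),
              frameId = 1L, pixelSize = 1)
  epiforce:::fitMeshGeometry(mesh)
}

# small relaxed ground-truth tissue, cached per session
relaxedTissue16 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- relaxTissue(generateVoronoiTissue(n = 16, seed = 42))
    cache
  }
})

# rigid rotation of all mesh coordinates
rotateMesh <- function(mesh, thetaDeg, shift = c(0, 0)) {
  th <- thetaDeg * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mesh@vertices <- sweep(mesh@vertices %*% t(Rm), 2, -shift)
  mesh@cells <- lapply(mesh@cells, function(cl) {
    cl$centroid <- as.numeric(Rm %*% cl$centroid) + shift
    cl
  })
  epiforce:::fitMeshGeometry(mesh)
}
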
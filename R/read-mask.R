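#' Read a labeled cell mask into a tissue mesh
#'
#' Converts an integer label image (one positive label per cell, 0 =
#' background, Cellpose-style) into a [TissueMesh-class]. Membranes are
#' traced on the half-pixel corner lattice: a lattice edge exists
#' wherever two adjacent pixels carry different labels, and a corner
#' where three or more labels (counting the background and the outside
#' of the canvas) meet becomes a pivot. Downstream behavior is
#' identical to [readSkeleton()]; the two readers produce isomorphic
#' membrane adjacency graphs for the same tissue.
#'
#' Labels occupying several disconnected regions are flagged and
#' reduced to their largest component (the rest becomes background).
#'
#' @param mask integer matrix (or file path); 0 background, each
#'   positive label a cell
#' @param frameId frame index stored on the mesh
#' @return a [TissueMesh-class] with membranes and fitted geometry
#' @export
readLabeledMask <- function(mask, frameId = 1L) {
  if (is.character(mask)) mask <- readRasterImage(mask, "mask")
  m <- as.matrix(mask)
  if (!length(m)) stop("empty mask")
  if (any(m < 0) || any(m != round(m)))
    stop("mask must contain non-negative integer labels")
  storage.mode(m) <- "integer"

  # split labels into connected components; keep the largest per label
  for (lb in setdiff(sort(unique(as.vector(m))), 0L)) {
    lcomp <- labelRegions(m == lb)
    own <- lcomp[m == lb]
    if (length(unique(own)) > 1L) {
      warning(sprintf("label %d is non-contiguous; keeping largest region",
                      lb))
      sizes <- table(own)
      keep <- as.integer(names(sizes))[which.max(sizes)]
      m[m == lb & lcomp != keep] <- 0L
    }
  }

  nr <- nrow(m); nc <- ncol(m)
  labAt <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    out <- integer(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }

  # corner lattice: corner (i, j) sits between pixel rows i, i+1 and
  # pixel columns j, j+1 (i in 0..nr, j in 0..nc);
  # id = i * (nc + 1) + j + 1
  cid <- function(i, j) i * (nc + 1L) + j + 1L
  # vertical lattice edges: corner (i-1, j) -- (i, j) separates pixels
  # (i, j) and (i, j + 1) for i in 1..nr, j in 1..nc-1 plus borders
  vi <- rep(1:nr, times = nc + 1L)
  vj <- rep(0:nc, each = nr)
  vl <- labAt(vi, vj); vr <- labAt(vi, vj + 1L)
  vsel <- vl != vr
  vEdges <- cbind(cid(vi - 1L, vj), cid(vi, vj))[vsel, , drop = FALSE]
  vCells <- cbind(vl, vr)[vsel, , drop = FALSE]
  # horizontal lattice edges: corner (i, j-1) -- (i, j) separates
  # pixels (i, j) (above) and (i+1, j) (below)
  hi <- rep(0:nr, times = nc)
  hj <- rep(1:nc, each = nr + 1L)
  ht <- labAt(hi, hj); hb <- labAt(hi + 1L, hj)
  hsel <- ht != hb
  hEdges <- cbind(cid(hi, hj - 1L), cid(hi, hj))[hsel, , drop = FALSE]
  hCells <- cbind(ht, hb)[hsel, , drop = FALSE]

  edges0 <- rbind(vEdges, hEdges)
  sideLabels <- rbind(vCells, hCells)
  if (!nrow(edges0)) {
    # single uniform image: no boundaries at all
    if (all(m == 0L)) return(new("TissueMesh", frameId = as.integer(frameId)))
    stop("mask has no boundaries; cannot build a mesh")
  }

  usedC <- sort(unique(as.vector(edges0)))
  newId <- integer(max(usedC))
  newId[usedC] <- seq_along(usedC)
  # corner (i, j) -> x = j - 0.5, y = i - 0.5 (0-based pixel coords)
  ci <- (usedC - 1L) %/% (nc + 1L)
  cj <- (usedC - 1L) %% (nc + 1L)
  verts <- cbind(cj - 0.5, ci - 0.5)
  edges <- matrix(newId[edges0], ncol = 2)

  # pivots: corners where >= 3 labels meet (outside canvas = background)
  deg <- tabulate(edges[, 1], nrow(verts)) + tabulate(edges[, 2], nrow(verts))
  cornerLabels <- function(k) {
    i <- ci[k]; j <- cj[k]
    labAt(c(i, i, i + 1L, i + 1L), c(j, j + 1L, j, j + 1L))
  }
  nDistinct <- vapply(seq_along(usedC), function(k) {
    length(unique(cornerLabels(k)))
  }, integer(1))
  pivotSet <- which(nDistinct >= 3L | deg >= 3L | deg == 1L)

  labels <- setdiff(sort(unique(as.vector(m))), 0L)
  cellOf <- integer(max(labels, 1L))
  cellOf[labels] <- seq_along(labels)

  res <- chainsFromGraph(nrow(verts), edges, pivotSet)
  # map each unit lattice edge to its side labels for membrane cells
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  sideOf <- stats::setNames(split(sideLabels, seq_len(nrow(sideLabels))), ekey)

  membs <- vector("list", length(res$chains))
  for (i in seq_along(res$chains)) {
    path <- res$chains[[i]]
    selfMb <- res$anchors[i] > 0L
    tal <- integer(0)
    for (k in seq_len(length(path) - 1L)) {
      kk <- paste(min(path[k], path[k + 1L]), max(path[k], path[k + 1L]))
      tal <- c(tal, sideOf[[kk]])
    }
    tab <- sort(table(tal), decreasing = TRUE)
    two <- as.integer(names(tab))[seq_len(min(2L, length(tab)))]
    if (length(two) == 1L) two <- c(two, 0L)
    two <- vapply(two, function(l) if (l == 0L) 0L else cellOf[l],
                  integer(1))
    if (two[1] == 0L) two <- rev(two)
    membs[[i]] <- list(id = i, pivotA = path[1],
                       pivotB = path[length(path)],
                       chain = as.integer(path[-c(1, length(path))]),
                       cell1 = as.integer(two[1]), cell2 = as.integer(two[2]),
                       flag = if (selfMb) "self" else "")
  }

  cellsL <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    pix <- which(m == labels[k])
    rr <- (pix - 1L) %% nr + 1L
    cc <- (pix - 1L) %/% nr + 1L
    mids <- which(vapply(membs, function(mm) {
      k %in% c(mm$cell1, mm$cell2)
    }, logical(1)))
    cellsL[[k]] <- list(id = k, pivots = integer(0), membranes = mids,
                       area = length(pix),
                       centroid = c(mean(cc - 1), mean(rr - 1)),
                       label = labels[k])
  }

  allPivots <- sort(unique(c(pivotSet,
                             res$anchors[res$anchors > 0L])))
  ptype <- vapply(allPivots, function(p) {
    if (0L %in% cornerLabels(p)) "border" else "interior"
  }, character(1))

  mesh <- new("TissueMesh", vertices = verts, edges = edges,
              cells = cellsL, membranes = membs,
              pivots = as.integer(allPivots), pivotType = ptype,
              frameId = as.integer(frameId), pixelSize = 1)
  fitMeshGeometry(mesh)
}
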
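#' Read a skeletonized segmentation into a tissue mesh
#'
#' Converts a binary skeleton image (1-pixel-wide, 8-connected membrane
#' curves, as produced by standard segmentation pipelines) into a
#' [TissueMesh-class]: membrane pixels become vertices, junction pixels
#' (3 or more white neighbors) become candidate pivots, and the closed
#' black regions enclosed by the curves become cells, with the
#' border-touching black phase as background.
#'
#' Redundant diagonal adjacencies (a diagonal pair that also shares a
#' white 4-neighbor) are pruned so that chain vertices have exactly two
#' incident edges. Touching junction pixels (e.g. 2 x 2 blocks) are
#' merged into a single pivot at their centroid, so raster artifacts do
#' not create spurious pivots. Junctions with more than 3 arms are
#' accepted but flagged as multi-junctions.
#'
#' @param image binary matrix (0 background / 1 membrane) or a file
#'   path accepted by [readRasterImage()]
#' @param frameId frame index stored on the mesh
#' @return a [TissueMesh-class] with membranes and fitted geometry
#' @export
readSkeleton <- function(image, frameId = 1L) {
  if (is.character(image)) image <- readRasterImage(image, "skeleton")
  img <- as.matrix(image)
  if (!length(img)) stop("empty image")
  vals <- sort(unique(as.vector(img)))
  if (length(vals) > 2 || !all(vals %in% c(0, vals[length(vals)])))
    stop("skeleton image must be binary")
  if (length(vals) == 2 && vals[1] != 0) stop("skeleton image must be binary")
  white <- img == max(vals) & max(vals) > 0

  nr <- nrow(img); nc <- ncol(img)
  on <- which(white)
  # all-black image: a valid mesh with no cells and no membranes
  if (!length(on))
    return(new("TissueMesh", frameId = as.integer(frameId)))

  idx <- matrix(0L, nr, nc)
  idx[on] <- seq_along(on)
  pr <- (on - 1L) %% nr + 1L
  pc <- (on - 1L) %/% nr + 1L
  at <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    out <- integer(length(r)); out[ok] <- idx[cbind(r[ok], c[ok])]
    out
  }
  # candidate edges: E, S, SE, SW neighbors; diagonals pruned when a
  # shared white 4-neighbor exists (standard skeleton-graph rule)
  eE <- at(pr, pc + 1L)
  eS <- at(pr + 1L, pc)
  eSE <- at(pr + 1L, pc + 1L)
  eSW <- at(pr + 1L, pc - 1L)
  keepSE <- eSE > 0L & !(at(pr, pc + 1L) > 0L | at(pr + 1L, pc) > 0L)
  keepSW <- eSW > 0L & !(at(pr, pc - 1L) > 0L | at(pr + 1L, pc) > 0L)
  self <- seq_along(on)
  edges <- rbind(cbind(self[eE > 0L], eE[eE > 0L]),
                 cbind(self[eS > 0L], eS[eS > 0L]),
                 cbind(self[keepSE], eSE[keepSE]),
                 cbind(self[keepSW], eSW[keepSW]))
  storage.mode(edges) <- "integer"

  # positions: x = column - 1, y = row - 1 (0-based pixel coordinates)
  verts <- cbind(pc - 1, pr - 1)

  deg <- integer(length(on))
  if (nrow(edges)) {
    deg <- tabulate(edges[, 1], length(on)) + tabulate(edges[, 2], length(on))
  }
  # raw 8-neighborhood white count, used to flag >3-neighbor pixels
  raw8 <- vapply(seq_along(on), function(i) {
    sum(at(pr[i] + c(-1, -1, -1, 0, 0, 1, 1, 1),
           pc[i] + c(-1, 0, 1, -1, 1, -1, 0, 1)) > 0L)
  }, integer(1))
  junction <- deg >= 3L

  # merge 8-connected clusters of junction pixels into single pivots
  vmap <- seq_along(on)
  if (any(junction)) {
    jid <- which(junction)
    jset <- logical(length(on)); jset[jid] <- TRUE
    je <- edges[jset[edges[, 1]] & jset[edges[, 2]], , drop = FALSE]
    # also consider pruned diagonal adjacency within clusters
    dSE <- cbind(self[eSE > 0L], eSE[eSE > 0L])
    dSW <- cbind(self[eSW > 0L], eSW[eSW > 0L])
    dd <- rbind(dSE, dSW)
    if (nrow(dd)) {
      dd <- dd[jset[dd[, 1]] & jset[dd[, 2]], , drop = FALSE]
      je <- rbind(je, dd)
    }
    if (nrow(je)) {
      g <- igraph::make_empty_graph(length(on), directed = FALSE)
      g <- igraph::add_edges(g, t(je))
      comp <- igraph::components(g)$membership
      for (cmp in unique(comp[jid])) {
        members <- which(comp == cmp & jset)
        if (length(members) > 1L) {
          keep <- members[1]
          vmap[members] <- keep
          verts[keep, ] <- colMeans(verts[members, , drop = FALSE])
        }
      }
    }
  }
  edges[] <- vmap[edges]
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  edges <- unique(t(apply(edges, 1, sort)))
  storage.mode(edges) <- "integer"

  # compact vertex ids
  usedV <- sort(unique(as.vector(edges)))
  if (!length(usedV)) usedV <- unique(vmap)
  newId <- integer(length(on)); newId[usedV] <- seq_along(usedV)
  verts2 <- verts[usedV, , drop = FALSE]
  edges2 <- matrix(newId[edges], ncol = 2)
  pixOf <- lapply(seq_along(usedV), function(k) {
    which(vmap == usedV[k])  # original pixel rows merged into vertex k
  })

  deg2 <- integer(nrow(verts2))
  if (nrow(edges2))
    deg2 <- tabulate(edges2[, 1], nrow(verts2)) +
      tabulate(edges2[, 2], nrow(verts2))
  if (any(raw8 > 3L))
    message(sprintf("%d pixel(s) with >3 white neighbors (multi-junction)",
                    sum(raw8 > 3L)))

  # cells: connected black regions; border-touching ones are background
  lab <- labelRegions(!white)
  bg <- borderLabels(lab)
  regions <- setdiff(sort(unique(as.vector(lab))), c(0L, bg))
  cellOf <- integer(max(lab, 1L))
  cellOf[regions] <- seq_along(regions)

  # black-neighbor labels of each pixel (cell id, or 0 for background)
  labAt <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
    out <- rep(NA_integer_, length(r))
    val <- lab[cbind(r[ok], c[ok])]
    out[ok] <- ifelse(val == 0L, NA_integer_,
                      ifelse(val %in% bg, 0L, cellOf[val]))
    out[!ok] <- 0L   # outside the canvas counts as background
    out
  }
  neighborCells <- function(pixRows) {
    res <- integer(0)
    for (p in pixRows) {
      nb <- labAt(pr[p] + c(-1, -1, -1, 0, 0, 1, 1, 1),
                  pc[p] + c(-1, 0, 1, -1, 1, -1, 0, 1))
      res <- c(res, nb[!is.na(nb)])
    }
    res
  }

  # pivots: junction vertices and loose chain ends
  pivotSet <- which(deg2 >= 3L | deg2 == 1L)
  mesh <- new("TissueMesh", vertices = verts2, edges = edges2,
              cells = list(), membranes = list(),
              pivots = as.integer(pivotSet),
              pivotType = rep("interior", length(pivotSet)),
              frameId = as.integer(frameId), pixelSize = 1)

  res <- chainsFromGraph(nrow(verts2), edges2, pivotSet)
  membs <- vector("list", length(res$chains))
  for (i in seq_along(res$chains)) {
    path <- res$chains[[i]]
    selfMb <- res$anchors[i] > 0L
    nbs <- neighborCells(unlist(pixOf[path]))
    tab <- sort(table(nbs), decreasing = TRUE)
    two <- as.integer(names(tab))[seq_len(min(2L, length(tab)))]
    if (length(two) == 0L) two <- c(0L, 0L)
    if (length(two) == 1L) two <- c(two, 0L)
    # prefer a real cell as cell1
    if (two[1] == 0L) two <- rev(two)
    membs[[i]] <- list(id = i, pivotA = path[1],
                       pivotB = path[length(path)],
                       chain = as.integer(path[-c(1, length(path))]),
                       cell1 = two[1], cell2 = two[2],
                       flag = if (selfMb) "self" else "")
  }
  mesh@membranes <- membs
  if (any(res$anchors > 0L)) {
    anchors <- unique(res$anchors[res$anchors > 0L])
    mesh@pivots <- sort(unique(c(mesh@pivots, anchors)))
  }

  # cells: area and centroid from region pixels, membrane membership
  cellsL <- vector("list", length(regions))
  for (k in seq_along(regions)) {
    pix <- which(lab == regions[k])
    rr <- (pix - 1L) %% nr + 1L
    cc <- (pix - 1L) %/% nr + 1L
    mids <- which(vapply(membs, function(m) {
      k %in% c(m$cell1, m$cell2)
    }, logical(1)))
    cellsL[[k]] <- list(id = k, pivots = integer(0), membranes = mids,
                       area = length(pix),
                       centroid = c(mean(cc - 1), mean(rr - 1)))
  }
  mesh@cells <- cellsL

  # border pivots: adjacent to the background phase
  ptype <- vapply(mesh@pivots, function(p) {
    nb <- neighborCells(pixOf[[p]])
    if (any(nb == 0L)) "border" else "interior"
  }, character(1))
  mesh@pivotType <- ptype

  fitMeshGeometry(mesh)
}
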
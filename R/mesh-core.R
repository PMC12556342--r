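#' Build a tissue mesh from cell polygons
#'
#' Constructs a [TissueMesh-class] from pivot (corner) positions and one
#' ordered pivot cycle per cell, subdividing every pivot-to-pivot wall
#' into a chain of virtual vertices. This is the native constructor used
#' by the synthetic-tissue generator and by tests; image-derived meshes
#' come from [readSkeleton()] / [readLabeledMask()].
#'
#' Cell cycles are reoriented to positive signed (shoelace) area. A wall
#' traversed by two cells becomes a membrane with \code{cell1} the cell
#' traversing it first, \code{cell2} the other; walls traversed by a
#' single cell face the background (\code{cell2 = 0}).
#'
#' @param pivotPos numeric matrix (p x 2) of junction positions.
#' @param cycles list of integer vectors, one ordered pivot cycle per
#'   cell (indices into \code{pivotPos} rows).
#' @param subdiv number of segments per membrane (\code{subdiv - 1}
#'   interior virtual vertices); minimum 1.
#' @param chainPos optional named list of pre-existing chain coordinate
#'   matrices keyed by \code{"a_b"} pivot pairs (used to preserve
#'   membrane shapes across topology edits).
#' @param frameId frame index stored on the mesh.
#' @return a [TissueMesh-class] with fitted membrane geometry.
#' @export
meshFromCells <- function(pivotPos, cycles, subdiv = 6L, chainPos = NULL,
                          frameId = 1L) {
  pivotPos <- as.matrix(pivotPos)
  stopifnot(ncol(pivotPos) == 2, subdiv >= 1)
  cycles <- lapply(cycles, function(cy) {
    if (signedArea(pivotPos[cy, , drop = FALSE]) < 0) rev(cy) else cy
  })

  verts <- pivotPos
  membs <- list()
  keyOf <- function(a, b) paste(min(a, b), max(a, b), sep = "_")
  lookup <- new.env(parent = emptyenv()) # key -> membrane indices

  addMembrane <- function(a, b, cellId) {
    key <- keyOf(a, b)
    idx <- if (exists(key, lookup)) get(key, lookup) else integer(0)
    for (mi in idx) {
      m <- membs[[mi]]
      if (m$cell2 == 0L && m$cell1 != cellId) {
        membs[[mi]]$cell2 <<- cellId
        return(mi)
      }
    }
    # new membrane a -> b with subdivided straight chain
    pa <- pivotPos[a, ]; pb <- pivotPos[b, ]
    chain <- integer(0)
    if (subdiv > 1) {
      prev <- if (!is.null(chainPos[[key]])) chainPos[[key]] else NULL
      if (!is.null(prev) && nrow(prev) == subdiv - 1) {
        pts <- prev
        # stored chains run min(a,b) -> max(a,b)
        if (a > b) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      } else {
        tt <- seq_len(subdiv - 1) / subdiv
        pts <- cbind(pa[1] + tt * (pb[1] - pa[1]),
                     pa[2] + tt * (pb[2] - pa[2]))
      }
      chain <- nrow(verts) + seq_len(nrow(pts))
      verts <<- rbind(verts, pts)
    }
    mi <- length(membs) + 1L
    membs[[mi]] <<- list(id = mi, pivotA = a, pivotB = b,
                        chain = as.integer(chain),
                        cell1 = cellId, cell2 = 0L, flag = "")
    assign(key, c(idx, mi), lookup)
    mi
  }

  cellList <- vector("list", length(cycles))
  for (ci in seq_along(cycles)) {
    cy <- cycles[[ci]]
    mids <- integer(length(cy))
    for (k in seq_along(cy)) {
      a <- cy[k]; b <- cy[if (k == length(cy)) 1L else k + 1L]
      mids[k] <- addMembrane(a, b, ci)
    }
    cellList[[ci]] <- list(id = ci, pivots = as.integer(cy),
                           membranes = mids, area = NA_real_,
                           centroid = c(NA_real_, NA_real_))
  }

  edges <- do.call(rbind, lapply(membs, function(m) {
    ids <- c(m$pivotA, m$chain, m$pivotB)
    cbind(ids[-length(ids)], ids[-1])
  }))
  storage.mode(edges) <- "integer"

  np <- nrow(pivotPos)
  pivotIds <- seq_len(np)
  borderPivot <- rep(FALSE, np)
  for (m in membs) {
    if (m$cell2 == 0L) borderPivot[c(m$pivotA, m$pivotB)] <- TRUE
  }

  mesh <- new("TissueMesh", vertices = unname(verts), edges = edges,
              cells = cellList, membranes = membs,
              pivots = as.integer(pivotIds),
              pivotType = ifelse(borderPivot, "border", "interior"),
              frameId = as.integer(frameId), pixelSize = 1)
  mesh <- updateCellGeometry(mesh)
  fitMeshGeometry(mesh)
}

#' Full boundary polyline of a cell
#'
#' Concatenates the oriented membrane chains around a cell's pivot cycle
#' into one closed polyline (last point not repeated).
#'
#' @param mesh a [TissueMesh-class]
#' @param cid cell id
#' @return numeric matrix of boundary coordinates in cycle order
#' @export
cellPolygon <- function(mesh, cid) {
  mesh@vertices[cellPolygonIds(mesh, cid), , drop = FALSE]
}

# ordered vertex ids (pivots + chain vertices) around a cell
cellPolygonIds <- function(mesh, cid) {
  cell <- mesh@cells[[cid]]
  cy <- cell$pivots
  if (!length(cy)) stop("cell has no stored pivot cycle")
  used <- logical(length(cell$membranes))
  out <- list()
  for (k in seq_along(cy)) {
    a <- cy[k]; b <- cy[if (k == length(cy)) 1L else k + 1L]
    hit <- NA_integer_; rv <- FALSE
    for (j in seq_along(cell$membranes)) {
      if (used[j]) next
      m <- mesh@membranes[[cell$membranes[j]]]
      if (m$pivotA == a && m$pivotB == b) { hit <- j; rv <- FALSE; break }
      if (m$pivotA == b && m$pivotB == a) { hit <- j; rv <- TRUE; break }
    }
    if (is.na(hit)) stop("broken pivot cycle for cell ", cid)
    used[hit] <- TRUE
    m <- mesh@membranes[[cell$membranes[hit]]]
    out[[k]] <- c(a, if (rv) rev(m$chain) else m$chain)
  }
  as.integer(unlist(out))
}

# recompute per-cell area and centroid from polygons (vector meshes)
updateCellGeometry <- function(mesh) {
  mesh@cells <- lapply(mesh@cells, function(cell) {
    if (length(cell$pivots)) {
      poly <- cellPolygon(mesh, cell$id)
      cell$area <- abs(signedArea(poly))
      cell$centroid <- polygonCentroid(poly)
    }
    cell
  })
  mesh
}

#' Identify pivot vertices of a mesh
#'
#' Pivot vertices are junctions between three or more cells (vertex
#' degree >= 3 in the edge graph), chain endpoints (degree 1), and
#' vertices at the border of the tissue. All other vertices are virtual.
#' Junctions of degree >= 4 are accepted but flagged as multi-junctions,
#' since force balance at such vertices is less stable.
#'
#' @param mesh a [TissueMesh-class]
#' @return data.frame with columns \code{pivot}, \code{type}
#'   (interior/border), \code{degree}, \code{multiJunction}
#' @export
identifyPivots <- function(mesh) {
  deg <- vertexDegrees(mesh)
  ids <- sort(unique(c(which(deg >= 3L | deg == 1L), mesh@pivots)))
  type <- rep("interior", length(ids))
  if (length(mesh@pivots)) {
    known <- match(ids, mesh@pivots)
    type[!is.na(known)] <- mesh@pivotType[known[!is.na(known)]]
  }
  data.frame(pivot = ids, type = type, degree = deg[ids],
             multiJunction = deg[ids] >= 4L)
}

# Partition the edges of a (vertices, edges, pivot-set) graph into
# maximal pivot-to-pivot chains. Returns a list of integer paths, each
# starting and ending at a pivot; closed virtual loops (isolated cells)
# are returned as cycles starting/ending at a synthetic anchor vertex.
chainsFromGraph <- function(nVertices, edges, pivotSet) {
  adj <- vector("list", nVertices)
  eid <- vector("list", nVertices)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); eid[[a]] <- c(eid[[a]], k)
    adj[[b]] <- c(adj[[b]], a); eid[[b]] <- c(eid[[b]], k)
  }
  isPivot <- logical(nVertices)
  isPivot[pivotSet] <- TRUE
  usedEdge <- logical(nrow(edges))
  chains <- list(); anchors <- integer(0)

  walk <- function(start, firstNb, firstEdge) {
    path <- c(start, firstNb)
    usedEdge[firstEdge] <<- TRUE
    cur <- firstNb; prev <- start
    while (!isPivot[cur]) {
      nbs <- adj[[cur]]; es <- eid[[cur]]
      nxt <- which(!usedEdge[es])
      if (!length(nxt)) break # dead end at a degree-1 virtual (shouldn't occur)
      j <- nxt[1]
      usedEdge[es[j]] <<- TRUE
      prev <- cur; cur <- nbs[j]
      path <- c(path, cur)
    }
    path
  }

  for (p in which(isPivot)) {
    for (j in seq_along(adj[[p]])) {
      if (usedEdge[eid[[p]][j]]) next
      chains[[length(chains) + 1L]] <- walk(p, adj[[p]][j], eid[[p]][j])
      anchors <- c(anchors, 0L)
    }
  }
  # leftover closed loops with no pivot: anchor at the lowest vertex id
  repeat {
    left <- which(!usedEdge)
    if (!length(left)) break
    k <- left[1]
    start <- min(edges[k, ])
    nb <- edges[k, 1] + edges[k, 2] - start
    isPivot[start] <- TRUE # temporary anchor so the walk terminates
    path <- walk(start, nb, k)
    isPivot[start] <- FALSE
    chains[[length(chains) + 1L]] <- path
    anchors <- c(anchors, start)
  }
  list(chains = chains, anchors = anchors)
}

#' Partition mesh edges into pivot-to-pivot membranes
#'
#' Rebuilds the membrane list of a mesh from its edge graph and pivot
#' set: edges are partitioned into maximal chains whose endpoints are
#' pivots, every vertex strictly inside a chain being virtual. Existing
#' cell assignments of membranes are preserved by matching chains
#' against the previous membrane list when available. Closed chains
#' without any pivot (isolated cells) become self-membranes anchored at
#' a synthetic pivot and flagged \code{"self"}; they are excluded from
#' force balance.
#'
#' @param mesh a [TissueMesh-class] with vertices, edges and pivots set
#' @return the mesh with a rebuilt membrane list and fitted geometry
#' @export
buildMembranes <- function(mesh) {
  res <- chainsFromGraph(nrow(mesh@vertices), mesh@edges, mesh@pivots)
  old <- mesh@membranes
  oldKey <- vapply(old, function(m) {
    paste(sort(c(m$pivotA, m$pivotB)), collapse = "_")
  }, character(1))
  membs <- vector("list", length(res$chains))
  for (i in seq_along(res$chains)) {
    path <- res$chains[[i]]
    self <- res$anchors[i] > 0L
    a <- path[1]; b <- path[length(path)]
    chain <- path[-c(1, length(path))]
    if (self && length(path) >= 2 && path[1] == path[length(path)])
      chain <- path[-c(1, length(path))]
    m <- list(id = i, pivotA = a, pivotB = b, chain = as.integer(chain),
              cell1 = 0L, cell2 = 0L,
              flag = if (self) "self" else "")
    key <- paste(sort(c(a, b)), collapse = "_")
    j <- match(key, oldKey)
    if (!is.na(j)) { m$cell1 <- old[[j]]$cell1; m$cell2 <- old[[j]]$cell2 }
    membs[[i]] <- m
  }
  mesh@membranes <- membs
  if (length(res$anchors) && any(res$anchors > 0L)) {
    extra <- res$anchors[res$anchors > 0L]
    mesh@pivots <- sort(unique(c(mesh@pivots, extra)))
    mesh@pivotType <- ifelse(
      mesh@pivots %in% extra, "border",
      mesh@pivotType[match(mesh@pivots, mesh@pivots)])
  }
  fitMeshGeometry(mesh)
}

#' Serialize a mesh to JSON
#'
#' Dumps vertices, edges, cells, membranes and pivots in a plain JSON
#' structure for downstream tools; [readMeshJSON()] restores it.
#'
#' @param mesh a [TissueMesh-class]
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeMeshJSON <- function(mesh, path) {
  obj <- list(
    vertices = unname(mesh@vertices),
    edges = unname(mesh@edges),
    cells = mesh@cells,
    membranes = lapply(mesh@membranes, function(m) {
      m[c("id", "pivotA", "pivotB", "chain", "cell1", "cell2",
          "curvature", "flag")]
    }),
    pivots = mesh@pivots,
    pivotType = mesh@pivotType,
    frameId = mesh@frameId,
    pixelSize = mesh@pixelSize
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMeshJSON
#' @export
readMeshJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num2 <- function(x) do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
  cells <- lapply(obj$cells, function(cl) {
    list(id = as.integer(cl$id),
         pivots = as.integer(unlist(cl$pivots)),
         membranes = as.integer(unlist(cl$membranes)),
         area = as.numeric(cl$area),
         centroid = as.numeric(unlist(cl$centroid)))
  })
  membs <- lapply(obj$membranes, function(m) {
    list(id = as.integer(m$id), pivotA = as.integer(m$pivotA),
         pivotB = as.integer(m$pivotB),
         chain = as.integer(unlist(m$chain)),
         cell1 = as.integer(m$cell1), cell2 = as.integer(m$cell2),
         flag = if (is.null(m$flag)) "" else as.character(m$flag))
  })
  mesh <- new("TissueMesh",
              vertices = num2(obj$vertices),
              edges = {
                e <- num2(obj$edges); storage.mode(e) <- "integer"; e
              },
              cells = cells, membranes = membs,
              pivots = as.integer(unlist(obj$pivots)),
              pivotType = as.character(unlist(obj$pivotType)),
              frameId = as.integer(obj$frameId),
              pixelSize = as.numeric(obj$pixelSize))
  fitMeshGeometry(mesh)
}
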
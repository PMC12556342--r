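# Sutherland-Hodgman clip of a convex polygon by the half-plane
# {x : dot(x - p0, nrm) <= 0}
clipHalfPlane <- function(poly, p0, nrm) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- (poly[, 1] - p0[1]) * nrm[1] + (poly[, 2] - p0[2]) * nrm[2]
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out[[length(out) + 1L]] <- poly[i, ]
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out[[length(out) + 1L]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# Voronoi cells of a small site set clipped to a rectangle, by direct
# half-plane intersection (exact and deterministic for desk-scale n)
voronoiPolygons <- function(sites, rect) {
  n <- nrow(sites)
  base <- rbind(c(rect[1], rect[3]), c(rect[2], rect[3]),
                c(rect[2], rect[4]), c(rect[1], rect[4]))
  lapply(seq_len(n), function(i) {
    poly <- base
    for (j in seq_len(n)) {
      if (j == i || nrow(poly) == 0) next
      mid <- (sites[i, ] + sites[j, ]) / 2
      nrm <- sites[j, ] - sites[i, ]
      poly <- clipHalfPlane(poly, mid, nrm)
    }
    poly
  })
}

# collapse numerically coincident polygon corners to shared vertex ids
dedupeVertices <- function(polys, tol = 1e-6) {
  env <- new.env(parent = emptyenv())
  verts <- list()
  findId <- function(p) {
    kx <- round(p[1] / tol); ky <- round(p[2] / tol)
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(kx + dx, ky + dy)
      if (exists(key, env)) {
        id <- get(key, env)
        if (max(abs(verts[[id]] - p)) <= 2 * tol) return(id)
      }
    }
    NA_integer_
  }
  cycles <- lapply(polys, function(poly) {
    ids <- integer(nrow(poly))
    for (k in seq_len(nrow(poly))) {
      id <- findId(poly[k, ])
      if (is.na(id)) {
        verts[[length(verts) + 1L]] <<- poly[k, ]
        id <- length(verts)
        assign(paste(round(poly[k, 1] / tol), round(poly[k, 2] / tol)),
               id, env)
      }
      ids[k] <- id
    }
    # drop consecutive duplicates introduced by near-degenerate corners
    keep <- ids != c(ids[-1], ids[1])
    ids[keep]
  })
  list(vertices = do.call(rbind, verts), cycles = cycles)
}

#' Generate a seeded Voronoi ground-truth tissue
#'
#' Emulates the validation protocol: \code{n} points on a square grid
#' (default 64 = 8 x 8, grid spacing \eqn{\sqrt{450}} so cell areas sit
#' near the target), each perturbed by centered Gaussian jitter, give a
#' Voronoi tessellation clipped to the bounding rectangle. Cell target
#' areas are drawn from N(\code{areaMean}, \code{areaSd}) and membrane
#' tensions from N(\code{tensionMean}, \code{tensionSd}). Each
#' membrane is subdivided into a chain of virtual vertices so that it
#' can bow under pressure differences during relaxation.
#'
#' @param n number of cells; must be a perfect square
#' @param jitterSd site jitter standard deviation in pixels; default
#'   0.15 of the grid spacing
#' @param areaMean,areaSd target-area distribution
#' @param tensionMean,tensionSd initial tension distribution
#' @param K area stiffness of the quadratic area penalty
#' @param subdiv segments per membrane
#' @param seed integer seed; generation is fully deterministic given it
#' @return a [GroundTruthTissue-class] (unrelaxed)
#' @export
generateVoronoiTissue <- function(n = 64, jitterSd = NULL, areaMean = 450,
                                  areaSd = 5, tensionMean = 1,
                                  tensionSd = 0.1, K = 1, subdiv = 6L,
                                  seed = 1L) {
  g <- sqrt(n)
  if (g != round(g)) stop("n must be a perfect square grid count")
  g <- as.integer(g)
  s <- sqrt(areaMean)
  if (is.null(jitterSd)) jitterSd <- 0.15 * s

  attempt <- 0L
  repeat {
    set.seed(as.integer(seed) + attempt * 131071L)
    gx <- rep(seq_len(g) - 0.5, g) * s
    gy <- rep(seq_len(g) - 0.5, each = g) * s
    sites <- cbind(gx + stats::rnorm(n, 0, jitterSd),
                   gy + stats::rnorm(n, 0, jitterSd))
    rect <- c(0, g * s, 0, g * s)
    polys <- voronoiPolygons(sites, rect)
    if (all(vapply(polys, nrow, integer(1)) >= 3)) break
    attempt <- attempt + 1L
    message("degenerate Voronoi cell; regenerating with next substream")
    if (attempt > 25L) stop("could not generate a non-degenerate tissue")
  }

  dd <- dedupeVertices(polys)
  mesh <- meshFromCells(dd$vertices, dd$cycles, subdiv = subdiv)
  E <- length(mesh@membranes)
  tensions <- stats::rnorm(E, tensionMean, tensionSd)
  tensions <- pmax(tensions, 0.05)
  areas <- stats::rnorm(n, areaMean, areaSd)

  new("GroundTruthTissue",
      mesh,
      trueTensions = tensions, targetAreas = areas, K = K,
      condition = "none", seed = as.integer(seed), simTime = 0,
      relaxed = list(converged = FALSE, residual = Inf))
}
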
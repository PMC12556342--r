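cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

vecnorm <- function(v) sqrt(sum(v^2))

unitvec <- function(v) {
  n <- vecnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# shoelace signed area of an (n x 2) polygon (not closed)
signedArea <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  0.5 * sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])
}

polygonCentroid <- function(p) {
  n <- nrow(p)
  if (n < 3) return(colMeans(p))
  j <- c(2:n, 1)
  w <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(w) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * w), sum((p[, 2] + p[j, 2]) * w)) / (6 * a)
}

polylineLength <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# membrane point matrix ordered pivotA -> chain -> pivotB
membranePoints <- function(mesh, m) {
  if (is.numeric(m)) m <- mesh@membranes[[m]]
  ids <- if (identical(m$pivotA, m$pivotB) && length(m$chain)) {
    c(m$pivotA, m$chain, m$pivotA)
  } else c(m$pivotA, m$chain, m$pivotB)
  mesh@vertices[ids, , drop = FALSE]
}

membraneMidpoint <- function(mesh, m) {
  p <- membranePoints(mesh, m)
  # point at half the arc length
  if (nrow(p) == 2) return((p[1, ] + p[2, ]) / 2)
  seglen <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- cumsum(seglen); half <- s[length(s)] / 2
  k <- which(s >= half)[1]
  over <- s[k] - half
  frac <- if (seglen[k] > 0) 1 - over / seglen[k] else 0
  p[k, ] + frac * (p[k + 1, ] - p[k, ])
}

#' Degree of every vertex of a mesh
#' @param mesh a [TissueMesh-class]
#' @return integer vector of incident-edge counts per vertex
#' @export
vertexDegrees <- function(mesh) {
  d <- integer(nrow(mesh@vertices))
  t1 <- tabulate(mesh@edges[, 1], nbins = length(d))
  t2 <- tabulate(mesh@edges[, 2], nbins = length(d))
  d + t1 + t2
}
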
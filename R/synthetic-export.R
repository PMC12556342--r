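# Bresenham raster line: 8-connected, 1 pixel wide
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  rr <- integer(0); cc <- integer(0)
  repeat {
    rr <- c(rr, r0); cc <- c(cc, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc)  { err <- err + dc; r0 <- r0 + sr }
  }
  cbind(rr, cc)
}

rasterFrame <- function(tissue, scale, margin) {
  v <- tissue@vertices
  xmin <- min(v[, 1]); ymin <- min(v[, 2])
  toCol <- function(x) as.integer(round((x - xmin) * scale)) + margin + 1L
  toRow <- function(y) as.integer(round((y - ymin) * scale)) + margin + 1L
  nc <- toCol(max(v[, 1])) + margin
  nr <- toRow(max(v[, 2])) + margin
  list(toCol = toCol, toRow = toRow, nr = nr, nc = nc)
}

#' Rasterize a synthetic tissue as a skeleton image
#'
#' Draws every membrane polyline as a 1-pixel-wide 8-connected curve
#' (Bresenham lines between consecutive chain points) on a binary
#' canvas, so the full read-then-infer pipeline can be exercised end to
#' end against the generator's known topology. Fails if the requested
#' resolution is too coarse for the reader to separate all cells.
#'
#' @param tissue a [GroundTruthTissue-class] (or any vector mesh)
#' @param scale pixels per tissue length unit
#' @param margin blank border in pixels
#' @param check verify that the rasterized skeleton encloses exactly
#'   \code{nCells(tissue)} regions
#' @return integer 0/1 matrix (rows = y, columns = x)
#' @export
exportSkeleton <- function(tissue, scale = 2, margin = 3L, check = TRUE) {
  fr <- rasterFrame(tissue, scale, margin)
  img <- matrix(0L, fr$nr, fr$nc)
  for (m in tissue@membranes) {
    pts <- membranePoints(tissue, m)
    rr <- fr$toRow(pts[, 2]); cc <- fr$toCol(pts[, 1])
    for (k in seq_len(nrow(pts) - 1L)) {
      px <- bresenham(rr[k], cc[k], rr[k + 1L], cc[k + 1L])
      img[px] <- 1L
    }
  }
  if (check) {
    lab <- labelRegions(img == 0L)
    interior <- setdiff(unique(as.vector(lab)), c(0L, borderLabels(lab)))
    if (length(interior) != length(tissue@cells))
      stop(sprintf(
        "resolution too coarse: %d of %d cells recovered at scale %g",
        length(interior), length(tissue@cells), scale))
  }
  img
}

#' Rasterize a synthetic tissue as a labeled cell mask
#'
#' Assigns every pixel center its containing cell id by even-odd
#' polygon tests against the cell boundary polylines; pixels outside
#' all cells are background (0). The companion of [exportSkeleton()]
#' for exercising the labeled-mask reader.
#'
#' @inheritParams exportSkeleton
#' @return integer label matrix (0 = background)
#' @export
exportLabeledMask <- function(tissue, scale = 2, margin = 3L) {
  fr <- rasterFrame(tissue, scale, margin)
  img <- matrix(0L, fr$nr, fr$nc)
  v <- tissue@vertices
  xmin <- min(v[, 1]); ymin <- min(v[, 2])
  # pixel centers in tissue coordinates
  colX <- (seq_len(fr$nc) - margin - 1L) / scale + xmin
  rowY <- (seq_len(fr$nr) - margin - 1L) / scale + ymin
  for (cell in tissue@cells) {
    poly <- cellPolygon(tissue, cell$id)
    cs <- range(poly[, 1]); rs <- range(poly[, 2])
    ccand <- which(colX >= cs[1] - 1 & colX <= cs[2] + 1)
    rcand <- which(rowY >= rs[1] - 1 & rowY <= rs[2] + 1)
    if (!length(ccand) || !length(rcand)) next
    px <- rep(colX[ccand], each = length(rcand))
    py <- rep(rowY[rcand], times = length(ccand))
    inside <- rep(FALSE, length(px))
    n <- nrow(poly)
    xj <- poly[c(2:n, 1), 1]; yj <- poly[c(2:n, 1), 2]
    for (k in seq_len(n)) {
      xi <- poly[k, 1]; yi <- poly[k, 2]
      crosses <- ((yi > py) != (yj[k] > py)) &
        (px < (xj[k] - xi) * (py - yi) / (yj[k] - yi) + xi)
      inside <- xor(inside, crosses)
    }
    idx <- which(inside)
    if (length(idx)) {
      rr <- rcand[(idx - 1L) %% length(rcand) + 1L]
      cc <- ccand[(idx - 1L) %/% length(rcand) + 1L]
      sel <- img[cbind(rr, cc)] == 0L
      img[cbind(rr[sel], cc[sel])] <- cell$id
    }
  }
  img
}
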
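#' Read a raster image into a matrix
#'
#' Thin wrapper over the TIFF/PNG readers plus plain-text matrices
#' (CSV/TSV, no header), returning a numeric matrix in row = y,
#' column = x orientation. Multi-channel images are reduced to their
#' first channel. Label images (\code{kind = "mask"}) are read with
#' integer values preserved.
#'
#' @param path image file (.tif/.tiff, .png, .csv, .tsv, .txt)
#' @param kind \code{"skeleton"} (binary) or \code{"mask"} (labels)
#' @return numeric matrix
#' @export
readRasterImage <- function(path, kind = c("skeleton", "mask")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path, as.is = (kind == "mask"))
    },
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      p <- png::readPNG(path)
      if (kind == "mask") p * 65535 else p
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    tsv = , txt = as.matrix(utils::read.table(path, header = FALSE)),
    stop("unsupported raster format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  unname(as.matrix(img))
}

# connected-component labeling of a logical mask (4-connectivity)
labelRegions <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  on <- which(mask)
  if (!length(on)) return(lab)
  idx <- matrix(0L, nr, nc)
  idx[on] <- seq_along(on)
  r <- (on - 1L) %% nr + 1L
  cc <- (on - 1L) %/% nr + 1L
  edges <- NULL
  hr <- which(cc < nc)
  if (length(hr)) {
    sel <- hr[mask[cbind(r[hr], cc[hr] + 1L)]]
    if (length(sel))
      edges <- cbind(idx[cbind(r[sel], cc[sel])],
                     idx[cbind(r[sel], cc[sel] + 1L)])
  }
  hd <- which(r < nr)
  if (length(hd)) {
    sel <- hd[mask[cbind(r[hd] + 1L, cc[hd])]]
    if (length(sel))
      edges <- rbind(edges, cbind(idx[cbind(r[sel], cc[sel])],
                                  idx[cbind(r[sel] + 1L, cc[sel])]))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[on] <- as.integer(comp)
  lab
}

# labels of regions touching the image border
borderLabels <- function(lab) {
  b <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  sort(unique(b[b != 0L]))
}
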
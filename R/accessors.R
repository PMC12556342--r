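#' @include AllClasses.R
NULL

#' Accessors for tissue meshes and solutions
#'
#' Small accessor generics for the S4 containers: vertex coordinates,
#' membranes, cells, pivot ids and types, inferred tensions and
#' pressures.
#'
#' @param object a [TissueMesh-class], [StressSolution-class],
#'   [PressureSolution-class] or [FrameSeries-class].
#' @return the corresponding slot content; `tensions()` and
#'   `pressures()` return named numeric vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setMethod("meshVertices", "TissueMesh", function(object) object@vertices)

#' @rdname accessors
#' @export
setGeneric("meshEdges", function(object) standardGeneric("meshEdges"))
#' @rdname accessors
#' @export
setMethod("meshEdges", "TissueMesh", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("membranes", function(object) standardGeneric("membranes"))
#' @rdname accessors
#' @export
setMethod("membranes", "TissueMesh", function(object) object@membranes)

#' @rdname accessors
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))
#' @rdname accessors
#' @export
setMethod("cells", "TissueMesh", function(object) object@cells)

#' @rdname accessors
#' @export
setGeneric("pivots", function(object) standardGeneric("pivots"))
#' @rdname accessors
#' @export
setMethod("pivots", "TissueMesh", function(object) object@pivots)

#' @rdname accessors
#' @export
setGeneric("pivotType", function(object) standardGeneric("pivotType"))
#' @rdname accessors
#' @export
setMethod("pivotType", "TissueMesh", function(object) {
  stats::setNames(object@pivotType, object@pivots)
})

#' @rdname accessors
#' @export
nCells <- function(object) length(object@cells)

#' @rdname accessors
#' @export
nMembranes <- function(object) length(object@membranes)

#' @rdname accessors
#' @export
setGeneric("tensions", function(object) standardGeneric("tensions"))
#' @rdname accessors
#' @export
setMethod("tensions", "StressSolution", function(object) object@tensions)
#' @rdname accessors
#' @export
setMethod("tensions", "GroundTruthTissue", function(object) {
  stats::setNames(object@trueTensions, seq_along(object@trueTensions))
})

#' @rdname accessors
#' @export
setGeneric("pressures", function(object) standardGeneric("pressures"))
#' @rdname accessors
#' @export
setMethod("pressures", "PressureSolution", function(object) object@pressures)

#' @rdname accessors
#' @export
setGeneric("solverPath", function(object) standardGeneric("solverPath"))
#' @rdname accessors
#' @export
setMethod("solverPath", "StressSolution", function(object) object@solverPath)
#' @rdname accessors
#' @export
setMethod("solverPath", "PressureSolution", function(object) object@solverPath)

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FrameSeries", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))
#' @rdname accessors
#' @export
setMethod("tracks", "FrameSeries", function(object) object@tracks)

setMethod("show", "TissueMesh", function(object) {
  cat(sprintf("TissueMesh: %d vertices, %d edges, %d cells, %d membranes\n",
              nrow(object@vertices), nrow(object@edges),
              length(object@cells), length(object@membranes)))
  cat(sprintf("  pivots: %d (%d interior, %d border)\n",
              length(object@pivots),
              sum(object@pivotType == "interior"),
              sum(object@pivotType == "border")))
  invisible(object)
})

setMethod("show", "GroundTruthTissue", function(object) {
  callNextMethod()
  cat(sprintf("  condition: %s | seed: %s | relaxed residual: %.3g\n",
              object@condition, object@seed, object@relaxed$residual))
  invisible(object)
})

setMethod("show", "StressSolution", function(object) {
  lam <- object@tensions[!is.na(object@tensions)]
  cat(sprintf(
    "StressSolution: %d membranes (%d inferred), solver: %s\n",
    length(object@tensions), length(lam), object@solverPath))
  if (length(lam))
    cat(sprintf("  tension range [%.3f, %.3f], mean %.6f, residual %.3g\n",
                min(lam), max(lam), mean(lam), object@residualNorm))
  invisible(object)
})

setMethod("show", "PressureSolution", function(object) {
  p <- object@pressures[!is.na(object@pressures)]
  cat(sprintf("PressureSolution: %d cells (%d inferred), solver: %s\n",
              length(object@pressures), length(p), object@solverPath))
  if (length(p))
    cat(sprintf("  pressure range [%.3g, %.3g], mean %.2e\n",
                min(p), max(p), mean(p)))
  invisible(object)
})

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries: %d frames, %d tracks, dt = %g\n",
              length(object@frames),
              if (nrow(object@tracks)) length(unique(object@tracks$track)) else 0L,
              object@dt))
  invisible(object)
})

setMethod("show", "LinearSystem", function(object) {
  cat(sprintf("LinearSystem: %d rows x %d cols (%s mode)\n",
              nrow(object@M), ncol(object@M),
              if (is.null(object@meta$mode)) "static" else object@meta$mode))
  invisible(object)
})
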
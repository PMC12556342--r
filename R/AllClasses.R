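#' @import methods
NULL

#' Polygonal tissue graph built from a segmentation
#'
#' A \code{TissueMesh} holds the geometry and topology extracted from a
#' segmented 2D tissue image (or built directly by the synthetic-tissue
#' generator): vertex positions, unit edges, cells, pivot junctions and
#' membranes. Vertices are classified as \emph{pivots} (tricellular or
#' higher-order junctions, and vertices at the tissue border) or
#' \emph{virtual} (degree-2 chain vertices along a membrane). A
#' \emph{membrane} is the maximal chain of vertices between two pivots,
#' shared by two cells; it carries one tension unknown in the force
#' balance.
#'
#' Coordinates are 0-based pixel coordinates: \code{x} is the column,
#' \code{y} the row, \code{y} increases downward. Physical units attach
#' only through the optional \code{pixelSize} metadata.
#'
#' @slot vertices numeric matrix (n x 2) of vertex positions (x, y).
#' @slot edges integer matrix (m x 2) of vertex-index pairs; each edge
#'   belongs to exactly one membrane.
#' @slot cells list of cells; each cell is a list with elements
#'   \code{id}, \code{pivots} (ordered pivot cycle, possibly empty for
#'   raster-derived meshes), \code{membranes} (membrane ids bounding the
#'   cell), \code{area} and \code{centroid}.
#' @slot membranes list of membranes; each membrane is a list with
#'   elements \code{id}, \code{pivotA}, \code{pivotB}, \code{chain}
#'   (ordered virtual vertex ids from A to B), \code{cell1},
#'   \code{cell2} (0 = background), and after geometry fitting
#'   \code{center}, \code{radius}, \code{curvature} (signed, positive
#'   when the fitted circle's center lies on the \code{cell2} side),
#'   \code{versorA}, \code{versorB} (unit tangents of the fitted circle
#'   at the pivots, pointing away from each pivot along the membrane)
#'   and \code{flag}.
#' @slot pivots integer vector of pivot vertex ids.
#' @slot pivotType character vector parallel to \code{pivots}:
#'   \code{"interior"} or \code{"border"}.
#' @slot frameId integer frame index (time series).
#' @slot pixelSize physical length per pixel (default 1).
#'
#' @seealso [readSkeleton()], [readLabeledMask()], [buildMembranes()],
#'   [assembleStaticSystem()]
#' @export
setClass("TissueMesh",
  representation(
    vertices  = "matrix",
    edges     = "matrix",
    cells     = "list",
    membranes = "list",
    pivots    = "integer",
    pivotType = "character",
    frameId   = "integer",
    pixelSize = "numeric"
  ),
  prototype(
    vertices  = matrix(numeric(0), ncol = 2),
    edges     = matrix(integer(0), ncol = 2),
    cells     = list(),
    membranes = list(),
    pivots    = integer(0),
    pivotType = character(0),
    frameId   = 1L,
    pixelSize = 1
  )
)

setValidity("TissueMesh", function(object) {
  msg <- character(0)
  if (ncol(object@vertices) != 2)
    msg <- c(msg, "vertices must be an n x 2 matrix")
  if (length(object@pivotType) != length(object@pivots))
    msg <- c(msg, "pivotType must be parallel to pivots")
  if (length(object@pivotType) &&
      !all(object@pivotType %in% c("interior", "border")))
    msg <- c(msg, "pivotType entries must be 'interior' or 'border'")
  ne <- nrow(object@edges)
  nm <- sum(vapply(object@membranes, function(m) {
    npts <- length(m$chain) + if (identical(m$pivotA, m$pivotB)) 1L else 2L
    max(npts - 1L, 0L) + if (identical(m$pivotA, m$pivotB)) 1L else 0L
  }, integer(1)))
  # every edge in exactly one membrane: segment counts must partition edges
  if (length(object@membranes) && nm != ne)
    msg <- c(msg, sprintf(
      "edges (%d) are not partitioned by membrane chains (%d segments)",
      ne, nm))
  if (length(msg)) msg else TRUE
})

#' Constrained linear system for tension or pressure inference
#'
#' Matrix form of the force balance (or Young-Laplace) equations. For the
#' tension system, rows are two force-balance equations per included
#' pivot (one per coordinate) plus one trailing constraint row; columns
#' are one per included membrane plus one Lagrange column of ones. The
#' constraint row of ones with right-hand side \code{E} (the number of
#' membrane unknowns) encodes the mean-tension-one normalization. In
#' static mode the right-hand side is zero except for the constraint
#' entry; in dynamic mode force rows carry the scale-parameter-weighted
#' nondimensional velocity components.
#'
#' @slot M coefficient matrix.
#' @slot B right-hand side.
#' @slot rowIndex data.frame mapping rows to (pivot, axis); the final
#'   constraint row has pivot \code{NA}.
#' @slot colIndex character vector mapping columns to membrane (or cell)
#'   ids, with the final entry \code{"LAGRANGE"} where present.
#' @slot meta list of assembly metadata (mode, rho, vbar, vnorm,
#'   included ids, warnings).
#' @export
setClass("LinearSystem",
  representation(M = "matrix", B = "numeric", rowIndex = "data.frame",
                 colIndex = "character", meta = "list"),
  prototype(meta = list())
)

setValidity("LinearSystem", function(object) {
  if (nrow(object@M) != length(object@B))
    return("M and B dimensions disagree")
  if (ncol(object@M) != length(object@colIndex))
    return("colIndex must map every column")
  TRUE
})

#' Inferred membrane tensions
#'
#' Per-membrane tension moduli, dimensionless and normalized so that the
#' mean over included membranes is one. Membranes that enter no
#' force-balance row (for example outer-rim membranes when border pivots
#' are excluded) are reported as \code{NA}.
#'
#' @slot tensions numeric vector named by membrane id; mean of the
#'   non-\code{NA} entries is 1.
#' @slot lagrange the Lagrange-multiplier unknown of the augmented
#'   system.
#' @slot residualNorm 2-norm of the force-row residual at the solution.
#' @slot solverPath one of \code{"direct_inverse"},
#'   \code{"least_squares"}, \code{"nonneg_least_squares"}.
#' @slot normalization \code{"mean_one"} (stored values) or
#'   \code{"absolute"} (rendering tag only; stored tensions are never
#'   clipped).
#' @export
setClass("StressSolution",
  representation(tensions = "numeric", lagrange = "numeric",
                 residualNorm = "numeric", solverPath = "character",
                 normalization = "character"),
  prototype(normalization = "mean_one")
)

setValidity("StressSolution", function(object) {
  lam <- object@tensions[!is.na(object@tensions)]
  if (length(lam) && abs(mean(lam) - 1) > 1e-6)
    return("mean tension must equal one")
  if (identical(object@solverPath, "nonneg_least_squares") &&
      length(lam) && min(lam) < -1e-12)
    return("non-negative solver path returned negative tension")
  TRUE
})

#' Inferred relative intracellular pressures
#'
#' Per-cell pressures from the Young-Laplace relation, dimensionless and
#' normalized to mean zero over included cells. The background region is
#' never a pressure unknown.
#'
#' @slot pressures numeric vector named by cell id (NA for cells with no
#'   cell-cell membrane); mean of non-\code{NA} entries is 0.
#' @slot residualNorm 2-norm of the membrane-row residual.
#' @slot solverPath solver provenance, as for [StressSolution-class].
#' @export
setClass("PressureSolution",
  representation(pressures = "numeric", residualNorm = "numeric",
                 solverPath = "character")
)

setValidity("PressureSolution", function(object) {
  p <- object@pressures[!is.na(object@pressures)]
  if (length(p) && abs(mean(p)) > 1e-6)
    return("mean pressure must equal zero")
  TRUE
})

#' Time series of tissue meshes with pivot tracks
#'
#' Ordered frames plus pivot trajectories obtained by mutual
#' nearest-neighbor matching (optionally overridden by a correction
#' table). A track occupies at most one pivot per frame; frames where a
#' track is missing are assigned zero velocity downstream.
#'
#' @slot frames list of [TissueMesh-class] objects in time order.
#' @slot tracks data.frame with columns \code{track}, \code{frame},
#'   \code{pivot}, \code{x}, \code{y}.
#' @slot dt time per frame (default 1 frame).
#' @slot corrections list of applied correction entries.
#' @export
setClass("FrameSeries",
  representation(frames = "list", tracks = "data.frame", dt = "numeric",
                 corrections = "list"),
  prototype(dt = 1, corrections = list())
)

setValidity("FrameSeries", function(object) {
  tr <- object@tracks
  if (nrow(tr)) {
    if (!all(c("track", "frame", "pivot", "x", "y") %in% names(tr)))
      return("tracks must have columns track, frame, pivot, x, y")
    if (anyDuplicated(tr[, c("track", "frame")]))
      return("a track may occupy at most one pivot per frame")
  }
  TRUE
})

#' Synthetic tissue with known tensions and pressures
#'
#' A [TissueMesh-class] extended with the generator's ground truth: the
#' prescribed per-membrane tension, per-cell target areas of the
#' quadratic area constraint, the area stiffness, the condition tag and
#' the simulation clock (steps times step scale).
#'
#' @slot trueTensions numeric vector, one prescribed tension per
#'   membrane (all positive).
#' @slot targetAreas numeric vector, one target area per cell.
#' @slot K area stiffness of the quadratic area penalty.
#' @slot condition one of \code{"none"}, \code{"x_furrow"},
#'   \code{"y_furrow"}, \code{"circular"}, \code{"random"}.
#' @slot seed integer seed the tissue was generated from.
#' @slot simTime simulation clock (relaxation time elapsed).
#' @slot relaxed list with elements \code{converged} (logical) and
#'   \code{residual} (max vertex force imbalance).
#' @export
setClass("GroundTruthTissue",
  contains = "TissueMesh",
  representation(trueTensions = "numeric", targetAreas = "numeric",
                 K = "numeric", condition = "character", seed = "integer",
                 simTime = "numeric", relaxed = "list"),
  prototype(K = 1, condition = "none", seed = NA_integer_, simTime = 0,
            relaxed = list(converged = FALSE, residual = Inf))
)

setValidity("GroundTruthTissue", function(object) {
  if (length(object@trueTensions) != length(object@membranes))
    return("one true tension per membrane required")
  if (length(object@trueTensions) && any(object@trueTensions <= 0))
    return("true tensions must be positive")
  if (length(object@targetAreas) != length(object@cells))
    return("one target area per cell required")
  TRUE
})
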
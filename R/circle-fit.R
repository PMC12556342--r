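#' Fit a circle to a membrane's chain of points
#'
#' Algebraic (Kasa-style) linear least-squares circle fit: with
#' \eqn{x^2 + y^2 = 2 c_x x + 2 c_y y + t} solved for
#' \eqn{(c_x, c_y, t)}, the radius is
#' \eqn{R = \sqrt{t + c_x^2 + c_y^2}}. The fit is closed-form and
#' deterministic, translation-invariant and rotation-equivariant.
#'
#' If the points are collinear within tolerance (ratio of the singular
#' values of the centered point matrix below \code{tol}), or fewer than
#' 3 points are supplied, the membrane is treated as a straight chord:
#' curvature 0 and versors equal to the unit chord directions.
#'
#' The \emph{versor} at each endpoint is the unit tangent of the fitted
#' circle at the nearest-point projection of that endpoint, oriented
#' away from the endpoint along the membrane (into the chain).
#'
#' @param pts numeric matrix (n x 2) of membrane points ordered from one
#'   pivot to the other (endpoints are the pivots).
#' @param tol collinearity tolerance on the singular-value ratio.
#' @return list with \code{center} (length-2, \code{NA} for the straight
#'   case), \code{radius} (\code{Inf} for straight), \code{curvature}
#'   (unsigned, \code{1/radius}), \code{versorA}, \code{versorB} (unit
#'   tangents at the first and last point) and \code{straight}.
#' @examples
#' th <- seq(0, pi / 2, length.out = 20)
#' fit <- fitMembraneCircle(cbind(50 * cos(th), 50 * sin(th)))
#' abs(fit$radius - 50) < 1e-6
#' @export
fitMembraneCircle <- function(pts, tol = 1e-6) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 2) stop("at least 2 points are required to fit a membrane")
  pA <- pts[1, ]; pB <- pts[n, ]

  straightFit <- function() {
    chord <- pB - pA
    if (vecnorm(chord) < .Machine$double.eps) {
      # degenerate closed loop: use first chain step
      chord <- pts[2, ] - pA
    }
    u <- unitvec(chord)
    list(center = c(NA_real_, NA_real_), radius = Inf, curvature = 0,
         versorA = u, versorB = -u, straight = TRUE)
  }

  if (n == 2) return(straightFit())

  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[1] < .Machine$double.eps || sv[2] / sv[1] < tol)
    return(straightFit())

  # Kasa fit on centered coordinates for conditioning
  z <- rowSums(ctr^2)
  A <- cbind(2 * ctr[, 1], 2 * ctr[, 2], 1)
  coef <- tryCatch(qr.solve(A, z), error = function(e) NULL)
  if (is.null(coef)) return(straightFit())
  center <- coef[1:2] + colMeans(pts)
  radius <- sqrt(max(coef[3] + sum(coef[1:2]^2), 0))
  if (!is.finite(radius) || radius <= 0) return(straightFit())

  tangentAt <- function(p, towards) {
    # tangent of the circle at the projection of p, oriented toward the
    # neighboring chain point so it points away from the endpoint
    rad <- p - center
    if (vecnorm(rad) < .Machine$double.eps) rad <- towards - center
    u <- unitvec(rad)
    tg <- c(-u[2], u[1])
    if (sum(tg * (towards - p)) < 0) tg <- -tg
    tg
  }
  list(center = center, radius = radius, curvature = 1 / radius,
       versorA = tangentAt(pA, pts[2, ]),
       versorB = tangentAt(pB, pts[n - 1, ]),
       straight = FALSE)
}

# Fit circles for all membranes of a mesh and attach signed curvature.
#
# Curvature sign convention: for the ordered cell pair
# (cell1, cell2) of a membrane, curvature > 0 when the fitted circle's
# center lies on the cell2 side of the chord, so that the Young-Laplace
# row P2 - P1 = lambda * curvature yields higher pressure on the concave
# side. The cell side is decided by the cell centroid's side of the
# chord; for background (cell 0) the opposite side of the real cell is
# used.
fitMeshGeometry <- function(mesh, tol = 1e-6) {
  if (!length(mesh@membranes)) return(mesh)
  cellCentroid <- function(cid) mesh@cells[[cid]]$centroid
  mesh@membranes <- lapply(mesh@membranes, function(m) {
    pts <- membranePoints(mesh, m)
    fit <- fitMembraneCircle(pts, tol = tol)
    m$center <- fit$center
    m$radius <- fit$radius
    m$versorA <- fit$versorA
    m$versorB <- fit$versorB
    kappa <- fit$curvature
    if (kappa > 0 && !isTRUE(fit$straight)) {
      pA <- pts[1, ]; pB <- pts[nrow(pts), ]
      chord <- pB - pA
      sideCenter <- sign(cross2(chord, fit$center - pA))
      side2 <- NA_real_
      if (!is.null(m$cell2) && m$cell2 > 0) {
        side2 <- sign(cross2(chord, cellCentroid(m$cell2) - pA))
      } else if (!is.null(m$cell1) && m$cell1 > 0) {
        side2 <- -sign(cross2(chord, cellCentroid(m$cell1) - pA))
      }
      if (!is.na(side2) && side2 != 0 && sideCenter != 0) {
        kappa <- kappa * (if (sideCenter == side2) 1 else -1)
      } else {
        # fall back: arc bulges away from the center
        mid <- colMeans(pts)
        sideBulge <- sign(cross2(chord, mid - pA))
        if (sideBulge != 0 && sideCenter != 0 && sideBulge == sideCenter)
          kappa <- -kappa
      }
    }
    m$curvature <- kappa
    m
  })
  mesh
}
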
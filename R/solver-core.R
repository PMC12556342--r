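#' @importFrom stats setNames
NULL

# Shared solver core: minimize ||M x - B||^2 subject to sum over the
# constrained unknowns c'x = value, solved through the KKT system
#   [ 2 M'M  c ] [x ]   [ 2 M'B ]
#   [   c'   0 ] [mu] = [ value ]
# The direct path requires the KKT matrix to be well conditioned;
# otherwise (or when tensions come out negative and nonneg = TRUE) a
# fallback least-squares / non-negative least-squares path is taken.
kktSolve <- function(M, B, consMask, consValue, nonneg = FALSE,
                     condLimit = 1e12, negTol = 1e-9) {
  nx <- ncol(M)
  H <- crossprod(M)
  f <- crossprod(M, B)
  cc <- as.numeric(consMask)
  K <- rbind(cbind(2 * H, cc), c(cc, 0))
  rhs <- c(2 * f, consValue)

  path <- "direct_inverse"
  x <- NULL
  kap <- tryCatch(kappa(K, exact = FALSE), error = function(e) Inf)
  if (is.finite(kap) && kap < condLimit) {
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (!is.null(sol)) x <- sol[seq_len(nx)]
  }
  if (is.null(x)) {
    # rank-deficient: minimum-norm least-squares on the KKT system
    sol <- pracma::pinv(K) %*% rhs
    x <- sol[seq_len(nx)]
    path <- "least_squares"
  }

  if (nonneg && any(x[consMask] < -negTol)) {
    x <- nnlsConstrained(M, B, consMask, consValue)
    path <- "nonneg_least_squares"
  }
  list(x = x, path = path, kappa = kap)
}

# Non-negative least squares under the equality constraint: active-set
# scheme on min ||Mx - B||^2 s.t. c'x = value, x_i >= 0 for the
# constrained unknowns (the Lagrange column stays free). Variables
# pinned at zero are moved in and out of the active set by
# primal feasibility and dual sign checks; each subproblem is the
# equality-constrained solve on the free columns.
nnlsConstrained <- function(M, B, consMask, consValue, tol = 1e-10) {
  nx <- ncol(M)
  active <- rep(FALSE, nx) # TRUE: pinned at zero (only constrained vars)
  solveFree <- function(active) {
    free <- which(!active)
    Mf <- M[, free, drop = FALSE]
    cf <- as.numeric(consMask[free])
    H <- crossprod(Mf); f <- crossprod(Mf, B)
    K <- rbind(cbind(2 * H, cf), c(cf, 0))
    sol <- tryCatch(solve(K, c(2 * f, consValue)),
                    error = function(e) pracma::pinv(K) %*% c(2 * f, consValue))
    x <- numeric(nx)
    x[free] <- sol[seq_along(free)]
    list(x = x, mu = sol[length(free) + 1L])
  }
  for (it in seq_len(3L * nx + 10L)) {
    s <- solveFree(active)
    x <- s$x
    viol <- which(consMask & !active & x < -tol)
    if (length(viol)) {
      active[viol[which.min(x[viol])]] <- TRUE
      next
    }
    # dual check: releasing an active variable must not decrease the
    # objective; dual_i = 2 M_i'(Mx - B) + mu c_i
    r <- as.numeric(M %*% x - B)
    dual <- 2 * as.numeric(crossprod(M, r)) + s$mu * as.numeric(consMask)
    rel <- which(active & dual < -1e-8)
    if (!length(rel)) {
      x[consMask & abs(x) < tol] <- 0
      return(x)
    }
    active[rel[which.min(dual[rel])]] <- FALSE
  }
  warning("constrained NNLS did not settle; returning last iterate")
  x
}

# membranes eligible as unknowns: not self-membranes, incident to at
# least one included pivot
includedMembranes <- function(mesh, includedPivots) {
  keep <- vapply(mesh@membranes, function(m) {
    !identical(m$flag, "self") &&
      (m$pivotA %in% includedPivots || m$pivotB %in% includedPivots)
  }, logical(1))
  which(keep)
}

#' Assemble the static force-balance system
#'
#' Builds the homogeneous force-balance system at pivot junctions: for
#' every included pivot, one equation per coordinate states that the
#' tension-weighted sum of the membrane versors leaving that pivot
#' vanishes. A trailing Lagrange column of ones and a constraint row of
#' ones with right-hand side \eqn{E} (the number of membrane unknowns)
#' impose the mean-tension-one normalization, avoiding the trivial
#' solution. The system has \eqn{2 V + 1} rows and \eqn{E + 1} columns
#' over the included pivots and membranes.
#'
#' Border pivots are excluded by default: the external forces acting on
#' them are unknown, so their balance rows would bias interior
#' tensions. Membranes touching no included pivot drop out of the
#' unknowns (they are reported \code{NA} by [solveStresses()]).
#'
#' @param mesh a [TissueMesh-class] with fitted membrane geometry
#' @param includeBorder also build force rows for border pivots
#' @return a [LinearSystem-class]
#' @export
assembleStaticSystem <- function(mesh, includeBorder = FALSE) {
  keepType <- if (includeBorder) c("interior", "border") else "interior"
  inc <- mesh@pivots[mesh@pivotType %in% keepType]
  if (!length(inc))
    stop("underdetermined tissue: no ",
         if (includeBorder) "" else "interior ", "pivots")
  mIdx <- includedMembranes(mesh, inc)
  E <- length(mIdx)
  if (!E) stop("underdetermined tissue: no membranes touch included pivots")

  deg <- vertexDegrees(mesh)
  multi <- inc[deg[inc] >= 4L & mesh@pivotType[match(inc, mesh@pivots)] == "interior"]
  if (length(multi))
    message(sprintf(
      "%d multi-junction pivot(s) of degree >= 4 included in the balance",
      length(multi)))

  nr <- 2L * length(inc) + 1L
  M <- matrix(0, nr, E + 1L)
  rowPivot <- rep(NA_integer_, nr)
  rowAxis <- rep(NA_character_, nr)
  rowOf <- setNames(seq_along(inc), inc)
  colOf <- setNames(seq_len(E), mIdx)

  for (k in seq_len(E)) {
    m <- mesh@membranes[[mIdx[k]]]
    for (side in c("A", "B")) {
      p <- if (side == "A") m$pivotA else m$pivotB
      if (!(p %in% inc)) next
      v <- if (side == "A") m$versorA else m$versorB
      r <- 2L * (rowOf[[as.character(p)]] - 1L) + 1L
      M[r, k] <- M[r, k] + v[1]
      M[r + 1L, k] <- M[r + 1L, k] + v[2]
    }
  }
  for (j in seq_along(inc)) {
    r <- 2L * (j - 1L) + 1L
    rowPivot[c(r, r + 1L)] <- inc[j]
    rowAxis[c(r, r + 1L)] <- c("x", "y")
    M[c(r, r + 1L), E + 1L] <- 1 # Lagrange column
  }
  M[nr, seq_len(E)] <- 1 # constraint row
  B <- c(rep(0, nr - 1L), E)

  new("LinearSystem", M = M, B = B,
      rowIndex = data.frame(pivot = rowPivot, axis = rowAxis),
      colIndex = c(as.character(mIdx), "LAGRANGE"),
      meta = list(mode = "static", membranes = mIdx,
                  includedPivots = inc, E = E,
                  includeBorder = includeBorder))
}

#' Solve for membrane tensions
#'
#' Solves the assembled force-balance system as a least-squares problem
#' with the mean-tension-one constraint: the normal equations are formed
#' and solved directly when well conditioned; if the system is singular,
#' or any resulting tension is negative, the solver falls back to
#' non-negative least squares under the same constraint.
#'
#' @param system a [LinearSystem-class] from [assembleStaticSystem()] or
#'   [assembleDynamicSystem()]
#' @param mesh optional mesh; when given, the returned tension vector
#'   covers all membranes (NA where excluded)
#' @param condLimit condition-number threshold for the direct inverse
#' @return a [StressSolution-class]
#' @export
solveStresses <- function(system, mesh = NULL, condLimit = 1e12) {
  M <- system@M; B <- system@B
  if (all(M == 0)) stop("all-zero system")
  E <- system@meta$E
  consMask <- c(rep(TRUE, E), FALSE)
  res <- kktSolve(M, B, consMask, E, nonneg = TRUE, condLimit = condLimit)
  lam <- res$x[seq_len(E)]
  lagr <- res$x[E + 1L]
  # exact mean-one (guards rounding in the fallback paths)
  lam <- lam / mean(lam)
  forceRows <- seq_len(nrow(M) - 1L)
  resid <- vecnorm(M[forceRows, , drop = FALSE] %*% c(lam, lagr) -
                     B[forceRows])
  ids <- system@meta$membranes
  if (!is.null(mesh)) {
    full <- rep(NA_real_, length(mesh@membranes))
    full[ids] <- lam
    tens <- setNames(full, seq_along(full))
  } else {
    tens <- setNames(lam, ids)
  }
  new("StressSolution", tensions = tens, lagrange = lagr,
      residualNorm = as.numeric(resid), solverPath = res$path,
      normalization = "mean_one")
}

#' Assemble the Young-Laplace pressure system
#'
#' One row per cell-cell membrane relating the pressure difference of
#' the two adjacent cells to the product of the membrane's tension and
#' signed curvature: \eqn{P_2 - P_1 = \lambda \kappa} with curvature
#' positive when the fitted circle's center lies on the cell-2 side.
#' Membranes against the background contribute no rows (the exterior
#' pressure is not inferable); near-straight membranes contribute a row
#' with zero right-hand side, preserving the equality constraint across
#' flat interfaces. The trailing constraint row imposes mean pressure
#' zero.
#'
#' @param mesh a [TissueMesh-class] with fitted curvature
#' @param stresses a [StressSolution-class] for the same mesh, or a
#'   numeric tension vector named by membrane id
#' @param flatTol curvatures below this magnitude are treated as flat
#' @return a [LinearSystem-class]
#' @export
assemblePressureSystem <- function(mesh, stresses, flatTol = 1e-6) {
  lam <- if (is(stresses, "StressSolution")) stresses@tensions else stresses
  getLam <- function(mid) {
    v <- if (!is.null(names(lam))) lam[[as.character(mid)]] else lam[mid]
    if (is.null(v)) NA_real_ else v
  }
  rows <- list()
  for (m in mesh@membranes) {
    if (m$cell1 <= 0L || m$cell2 <= 0L) next
    l <- getLam(m$id)
    if (is.na(l)) next
    kap <- if (abs(m$curvature) < flatTol) 0 else m$curvature
    rows[[length(rows) + 1L]] <- list(m$id, m$cell1, m$cell2, l * kap)
  }
  cellsIn <- sort(unique(unlist(lapply(rows, function(r) c(r[[2]], r[[3]])))))
  if (!length(cellsIn)) {
    if (length(mesh@cells) == 1L) {
      warning("single-cell tissue: pressure fixed to zero by the constraint")
      cellsIn <- 1L
    } else stop("no cell-cell membranes with inferred tension")
  }
  C <- length(cellsIn)
  nr <- length(rows) + 1L
  M <- matrix(0, nr, C)
  B <- numeric(nr)
  rowMem <- rep(NA_integer_, nr)
  colOf <- setNames(seq_len(C), cellsIn)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    M[i, colOf[[as.character(r[[2]])]]] <- -1
    M[i, colOf[[as.character(r[[3]])]]] <- 1
    B[i] <- r[[4]]
    rowMem[i] <- r[[1]]
  }
  M[nr, ] <- 1 # mean-zero constraint
  B[nr] <- 0
  new("LinearSystem", M = M, B = B,
      rowIndex = data.frame(pivot = rowMem, axis = NA_character_),
      colIndex = as.character(cellsIn),
      meta = list(mode = "pressure", cells = cellsIn,
                  nCells = length(mesh@cells)))
}

#' Solve for relative cell pressures
#'
#' Solves the Young-Laplace system by constrained least squares with
#' the zero-mean constraint, mirroring the tension solver (without the
#' non-negativity fallback: relative pressures may be negative).
#'
#' @param system a [LinearSystem-class] from [assemblePressureSystem()]
#' @param condLimit condition-number threshold for the direct inverse
#' @return a [PressureSolution-class]
#' @export
solvePressures <- function(system, condLimit = 1e12) {
  M <- system@M; B <- system@B
  C <- ncol(M)
  res <- kktSolve(M, B, rep(TRUE, C), 0, nonneg = FALSE,
                  condLimit = condLimit)
  P <- res$x - mean(res$x)
  rowsF <- seq_len(nrow(M) - 1L)
  resid <- if (length(rowsF)) {
    vecnorm(M[rowsF, , drop = FALSE] %*% P - B[rowsF])
  } else 0
  nAll <- system@meta$nCells
  full <- rep(NA_real_, nAll)
  full[as.integer(system@colIndex)] <- P
  new("PressureSolution", pressures = setNames(full, seq_len(nAll)),
      residualNorm = as.numeric(resid), solverPath = res$path)
}

#' Infer tensions and pressures from a mesh in one call
#'
#' Convenience wrapper: assembles and solves the static (or dynamic)
#' tension system, then the pressure system.
#'
#' @param mesh a [TissueMesh-class]
#' @param includeBorder include border-pivot balance rows
#' @param velocities optional per-pivot velocity matrix (rows aligned
#'   with \code{pivots(mesh)}) for dynamic mode
#' @param rho scale parameter for dynamic mode
#' @param vbar reference velocity for dynamic mode
#' @return list with elements \code{stress} ([StressSolution-class]),
#'   \code{pressure} ([PressureSolution-class]) and \code{system}
#' @export
inferForces <- function(mesh, includeBorder = FALSE, velocities = NULL,
                        rho = 0, vbar = NULL) {
  sys <- if (is.null(velocities) || rho == 0) {
    assembleStaticSystem(mesh, includeBorder = includeBorder)
  } else {
    assembleDynamicSystem(mesh, velocities, rho = rho, vbar = vbar,
                          includeBorder = includeBorder)
  }
  st <- solveStresses(sys, mesh = mesh)
  pr <- solvePressures(assemblePressureSystem(mesh, st))
  list(stress = st, pressure = pr, system = sys)
}
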
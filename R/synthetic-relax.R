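# Vertex-model energy machinery.
#
# E(x) = sum_cells K/2 (A_c - A0_c)^2 + sum_segments lambda_m L_s
#
# where segments are the unit edges of subdivided membranes, each
# inheriting its membrane's prescribed tension. All vertices (pivots
# and chain vertices) are free; the tissue boundary carries tension
# like any other membrane, so the blob neither collapses (area
# penalty) nor drifts (translation-invariant energy).

buildEnergyIndex <- function(tissue) {
  segA <- integer(0); segB <- integer(0); segLam <- numeric(0)
  for (m in tissue@membranes) {
    ids <- c(m$pivotA, m$chain, m$pivotB)
    segA <- c(segA, ids[-length(ids)])
    segB <- c(segB, ids[-1])
    segLam <- c(segLam, rep(tissue@trueTensions[m$id], length(ids) - 1L))
  }
  ci <- integer(0); vi <- integer(0); vj <- integer(0)
  for (cell in tissue@cells) {
    ids <- cellPolygonIds(tissue, cell$id)
    nx <- c(ids[-1], ids[1])
    ci <- c(ci, rep(cell$id, length(ids)))
    vi <- c(vi, ids); vj <- c(vj, nx)
  }
  list(segA = segA, segB = segB, segLam = segLam,
       ci = ci, vi = vi, vj = vj,
       A0 = tissue@targetAreas, K = tissue@K,
       nV = nrow(tissue@vertices), nC = length(tissue@cells))
}

cellAreasFromIndex <- function(x, y, idx) {
  cr <- x[idx$vi] * y[idx$vj] - x[idx$vj] * y[idx$vi]
  0.5 * as.numeric(rowsum(cr, idx$ci, reorder = TRUE))
}

tissueEnergy <- function(par, idx) {
  n <- idx$nV
  x <- par[seq_len(n)]; y <- par[n + seq_len(n)]
  A <- cellAreasFromIndex(x, y, idx)
  dx <- x[idx$segA] - x[idx$segB]
  dy <- y[idx$segA] - y[idx$segB]
  L <- sqrt(dx^2 + dy^2)
  0.5 * idx$K * sum((A - idx$A0)^2) + sum(idx$segLam * L)
}

tissueGradient <- function(par, idx) {
  n <- idx$nV
  x <- par[seq_len(n)]; y <- par[n + seq_len(n)]
  A <- cellAreasFromIndex(x, y, idx)
  w <- idx$K * (A - idx$A0)        # dE/dA per cell
  wf <- w[idx$ci]                  # per flat polygon entry
  gx <- numeric(n); gy <- numeric(n)
  acc <- function(g, id, val) {
    r <- rowsum(val, id, reorder = FALSE)
    g[as.integer(rownames(r))] <- g[as.integer(rownames(r))] + r[, 1]
    g
  }
  # area term: A_c = 0.5 sum (x_i y_j - x_j y_i)
  gx <- acc(gx, idx$vi,  0.5 * wf * y[idx$vj])
  gx <- acc(gx, idx$vj, -0.5 * wf * y[idx$vi])
  gy <- acc(gy, idx$vi, -0.5 * wf * x[idx$vj])
  gy <- acc(gy, idx$vj,  0.5 * wf * x[idx$vi])
  # tension term
  dx <- x[idx$segA] - x[idx$segB]
  dy <- y[idx$segA] - y[idx$segB]
  L <- pmax(sqrt(dx^2 + dy^2), 1e-12)
  ux <- idx$segLam * dx / L; uy <- idx$segLam * dy / L
  gx <- acc(gx, idx$segA, ux); gx <- acc(gx, idx$segB, -ux)
  gy <- acc(gy, idx$segA, uy); gy <- acc(gy, idx$segB, -uy)
  c(gx, gy)
}

# Max per-vertex force magnitude (gradient norm), in tension units.
# which = "balanced" excludes border pivots: at a free tissue boundary
# a corner between two walls of unequal tension carries an irreducible
# tangential force (a contact-line effect), which no interior
# quantity depends on - border pivots are also excluded from inference.
maxResidualForce <- function(tissue, idx = buildEnergyIndex(tissue),
                             which = c("balanced", "all")) {
  which <- match.arg(which)
  par <- c(tissue@vertices[, 1], tissue@vertices[, 2])
  g <- tissueGradient(par, idx)
  n <- idx$nV
  fmag <- sqrt(g[seq_len(n)]^2 + g[n + seq_len(n)]^2)
  if (which == "balanced") {
    borderPiv <- tissue@pivots[tissue@pivotType == "border"]
    if (length(borderPiv)) fmag <- fmag[-borderPiv]
  }
  max(fmag)
}

# Redistribute the virtual vertices of every membrane at equal arc
# length along the current polyline (the "vertex averaging" of the
# relaxation protocol). New points lie on the old path, so the
# membrane length - and hence the energy - cannot increase; it cures
# the tangential degeneracy of the line-tension term, under which
# chain vertices otherwise bunch up and stall the descent.
respaceChains <- function(tissue) {
  v <- tissue@vertices
  for (m in tissue@membranes) {
    k <- length(m$chain)
    if (!k) next
    ids <- c(m$pivotA, m$chain, m$pivotB)
    pts <- v[ids, , drop = FALSE]
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    cum <- c(0, cumsum(seg))
    tot <- cum[length(cum)]
    if (tot < .Machine$double.eps) next
    want <- tot * seq_len(k) / (k + 1)
    j <- findInterval(want, cum, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), length(seg))
    frac <- (want - cum[j]) / pmax(seg[j], .Machine$double.eps)
    v[m$chain, ] <- pts[j, , drop = FALSE] +
      frac * (pts[j + 1L, , drop = FALSE] - pts[j, , drop = FALSE])
  }
  tissue@vertices <- v
  tissue
}

setTissueVertices <- function(tissue, par) {
  n <- nrow(tissue@vertices)
  tissue@vertices <- cbind(par[seq_len(n)], par[n + seq_len(n)])
  tissue <- updateCellGeometry(tissue)
  fitMeshGeometry(tissue)
}

# flattened parameter indices (x then y) of border-pivot coordinates
fixedDofs <- function(tissue, nV) {
  bp <- tissue@pivots[tissue@pivotType == "border"]
  c(bp, nV + bp)
}

#' Relax a synthetic tissue to mechanical equilibrium
#'
#' Quasistatic energy descent on the vertex-model energy
#' \eqn{E = \sum_c K/2 (A_c - A_0)^2 + \sum_e \lambda_e L_e} with the
#' prescribed membrane tensions: rounds of bounded quasi-Newton descent
#' (L-BFGS with analytic gradient) interleaved with T1 checks - when a
#' pivot-pivot wall shortens below a fraction of the mean wall length,
#' the neighbor exchange is performed and descent resumes. Membrane
#' chains bow under cell pressure differences, so the relaxed state
#' carries the Young-Laplace curvature the inference reads out.
#'
#' @param tissue a [GroundTruthTissue-class]
#' @param tol convergence tolerance on the maximum per-vertex residual
#'   force, in tension units
#' @param maxRounds maximum descent rounds
#' @param itersPerRound descent iterations per round
#' @param t1Frac T1 threshold as a fraction of the mean pivot-pivot
#'   wall length (0 disables swaps)
#' @param fixedBorder pin border pivots at their current positions
#'   (default). A free boundary lets wall corners slide along the rim
#'   under tension differences (a contact-line effect) until boundary
#'   walls collapse; pinning the rim frame gives a clean equilibrium
#'   for every degree of freedom the inference actually uses, since
#'   border pivots carry no balance equations.
#' @return the relaxed tissue; \code{@relaxed$converged} reports
#'   whether the residual dropped below \code{tol}, and
#'   \code{@relaxed$energyTrace} the per-round energies
#' @export
relaxTissue <- function(tissue, tol = 1e-3, maxRounds = 40L,
                        itersPerRound = 1000L, t1Frac = 0.05,
                        fixedBorder = TRUE) {
  energyTrace <- numeric(0)
  t1Guard <- new.env(parent = emptyenv())
  for (round in seq_len(maxRounds)) {
    idx <- buildEnergyIndex(tissue)
    par <- c(tissue@vertices[, 1], tissue@vertices[, 2])
    lower <- rep(-Inf, length(par)); upper <- rep(Inf, length(par))
    if (fixedBorder) {
      fix <- fixedDofs(tissue, idx$nV)
      lower[fix] <- upper[fix] <- par[fix]
    }
    opt <- stats::optim(par, fn = tissueEnergy, gr = tissueGradient,
                        idx = idx, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = itersPerRound,
                                       factr = 10))
    tissue@vertices <- cbind(opt$par[seq_len(idx$nV)],
                             opt$par[idx$nV + seq_len(idx$nV)])
    tissue <- respaceChains(tissue)
    energyTrace <- c(energyTrace, opt$value)
    swapped <- FALSE
    if (t1Frac > 0) {
      sw <- performT1IfNeeded(tissue, t1Frac, guard = t1Guard)
      tissue <- sw$tissue
      swapped <- sw$swapped
    }
    res <- maxResidualForce(tissue)
    if (!swapped && res < tol) break
  }
  tissue <- setTissueVertices(tissue, c(tissue@vertices[, 1],
                                        tissue@vertices[, 2]))
  res <- maxResidualForce(tissue)
  tissue@relaxed <- list(converged = res < tol, residual = res,
                         energyTrace = energyTrace)
  if (!tissue@relaxed$converged)
    tissue@relaxed$flag <- "non-converged"
  tissue
}

# wall (pivot-to-pivot chord) lengths of non-background membranes
wallChords <- function(tissue) {
  vapply(tissue@membranes, function(m) {
    vecnorm(tissue@vertices[m$pivotB, ] - tissue@vertices[m$pivotA, ])
  }, numeric(1))
}

# Perform the needed T1 swaps (shortest eligible wall first, several
# per call). `guard` is an environment counting swap signatures (the
# four cells involved): a wall that keeps re-collapsing against its
# own swap partner is swapped at most twice and then left as a short
# wall - the stable configuration there is effectively a fourfold
# junction, and endless flip-flops would stall the descent.
performT1IfNeeded <- function(tissue, t1Frac = 0.05, maxSwaps = 10L,
                              guard = new.env(parent = emptyenv())) {
  nSwaps <- 0L
  repeat {
    if (nSwaps >= maxSwaps) break
    chords <- wallChords(tissue)
    thr <- t1Frac * mean(chords)
    deg <- vertexDegrees(tissue)
    eligible <- which(vapply(tissue@membranes, function(m) {
      m$cell1 > 0L && m$cell2 > 0L &&
        deg[m$pivotA] == 3L && deg[m$pivotB] == 3L &&
        tissue@pivotType[match(m$pivotA, tissue@pivots)] == "interior" &&
        tissue@pivotType[match(m$pivotB, tissue@pivots)] == "interior"
    }, logical(1)) & chords < thr)
    if (!length(eligible)) break
    ord <- eligible[order(chords[eligible])]
    done <- FALSE
    for (mId in ord) {
      out <- tryCatch(t1Swap(tissue, mId, newLen = 1.5 * thr),
                      error = function(e) NULL)
      if (is.null(out)) next
      m <- tissue@membranes[[mId]]
      sig <- paste("t1", min(m$cell1, m$cell2), max(m$cell1, m$cell2),
                   sep = "_")
      cnt <- if (exists(sig, guard)) get(sig, guard) else 0L
      if (cnt >= 2L) next
      assign(sig, cnt + 1L, guard)
      tissue <- out
      nSwaps <- nSwaps + 1L
      done <- TRUE
      break
    }
    if (!done) break
  }
  list(tissue = tissue, swapped = nSwaps > 0L, nSwaps = nSwaps)
}

# Neighbor exchange on membrane mId: the wall between cells L and R
# collapses and reopens between the two third cells C_A, C_B.
t1Swap <- function(tissue, mId, newLen) {
  m <- tissue@membranes[[mId]]
  a <- m$pivotA; b <- m$pivotB
  L <- m$cell1; R <- m$cell2
  thirdCell <- function(p) {
    for (cell in tissue@cells) {
      if (cell$id %in% c(L, R)) next
      if (p %in% cell$pivots) return(cell$id)
    }
    0L
  }
  CA <- thirdCell(a); CB <- thirdCell(b)
  if (CA == 0L || CB == 0L || CA == CB) stop("no eligible third cells")
  # already-adjacent third cells would create a doubled wall
  for (mm in tissue@membranes) {
    cc <- c(mm$cell1, mm$cell2)
    if (all(c(CA, CB) %in% cc)) stop("third cells already adjacent")
  }

  pa <- tissue@vertices[a, ]; pb <- tissue@vertices[b, ]
  mid <- (pa + pb) / 2
  dir <- unitvec(pb - pa)
  perp <- c(-dir[2], dir[1])
  centL <- tissue@cells[[L]]$centroid
  sL <- sign(sum(perp * (centL - mid)))
  if (sL == 0) sL <- 1
  # after the swap, a stays with cell L and b with cell R
  posA <- mid + sL * perp * newLen / 2
  posB <- mid - sL * perp * newLen / 2

  replacePair <- function(cy, u, v, rep) {
    # replace the consecutive pair (u,v) in cycle cy by rep
    n <- length(cy)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if (cy[k] == u && cy[k2] == v) {
        rest <- if (k2 > k) cy[-c(k, k2)] else cy[-c(k, k2)]
        # rebuild preserving order starting after the pair
        ord <- c(cy, cy)[(k2 + 1):(k2 + n - 2)]
        return(c(rep, ord))
      }
    }
    stop("pair not found in cycle")
  }
  replaceOne <- function(cy, u, rep) {
    k <- match(u, cy)
    if (is.na(k)) stop("vertex not in cycle")
    n <- length(cy)
    ord <- if (n > 1) c(cy, cy)[(k + 1):(k + n - 1)] else integer(0)
    c(rep, ord)
  }

  np <- max(tissue@pivots)
  pivotPos <- tissue@vertices[seq_len(np), , drop = FALSE]
  pivotPos[a, ] <- posA; pivotPos[b, ] <- posB

  cycles <- lapply(tissue@cells, function(cell) cell$pivots)
  cycles[[L]] <- replacePair(cycles[[L]], a, b, a)
  cycles[[R]] <- replacePair(cycles[[R]], b, a, b)
  insertTwo <- function(cy, u) {
    cand1 <- replaceOne(cy, u, c(a, b))
    cand2 <- replaceOne(cy, u, c(b, a))
    a1 <- abs(signedArea(pivotPos[cand1, , drop = FALSE]))
    a2 <- abs(signedArea(pivotPos[cand2, , drop = FALSE]))
    if (a1 >= a2) cand1 else cand2
  }
  cycles[[CA]] <- insertTwo(cycles[[CA]], a)
  cycles[[CB]] <- insertTwo(cycles[[CB]], b)

  # preserve chain shapes of untouched membranes
  subdiv <- max(2L, length(tissue@membranes[[1]]$chain) + 1L)
  chainPos <- list()
  touching <- c(a, b)
  for (mm in tissue@membranes) {
    if (mm$id == mId) next
    key <- paste(min(mm$pivotA, mm$pivotB), max(mm$pivotA, mm$pivotB),
                 sep = "_")
    pts <- tissue@vertices[mm$chain, , drop = FALSE]
    if (mm$pivotA > mm$pivotB) pts <- pts[rev(seq_len(nrow(pts))), ,
                                          drop = FALSE]
    chainPos[[key]] <- pts
  }
  chainPos[[paste(min(a, b), max(a, b), sep = "_")]] <- NULL

  newMesh <- meshFromCells(pivotPos, cycles, subdiv = subdiv,
                           chainPos = chainPos,
                           frameId = tissue@frameId)

  # remap prescribed tensions by pivot-pair key; the swapped wall
  # inherits the collapsed wall's tension
  oldByKey <- new.env(parent = emptyenv())
  for (mm in tissue@membranes) {
    assign(paste(min(mm$pivotA, mm$pivotB), max(mm$pivotA, mm$pivotB),
                 sep = "_"),
           tissue@trueTensions[mm$id], oldByKey)
  }
  newTension <- vapply(newMesh@membranes, function(mm) {
    key <- paste(min(mm$pivotA, mm$pivotB), max(mm$pivotA, mm$pivotB),
                 sep = "_")
    if (exists(key, oldByKey)) get(key, oldByKey)
    else tissue@trueTensions[mId]
  }, numeric(1))

  new("GroundTruthTissue", newMesh,
      trueTensions = newTension, targetAreas = tissue@targetAreas,
      K = tissue@K, condition = tissue@condition, seed = tissue@seed,
      simTime = tissue@simTime,
      relaxed = list(converged = FALSE, residual = Inf))
}

#' Overdamped relaxation with frame snapshots
#'
#' Integrates the overdamped gradient flow
#' \eqn{\dot x = -\nabla E / \eta} with explicit Euler steps and
#' records a snapshot every \code{frameTime} time units. Because frame
#' displacements are proportional to the unbalanced force at each
#' vertex, the resulting series moves exactly in the regime the
#' dynamic inference mode assumes, with an emergent scale parameter
#' \eqn{\rho = \eta \bar v / \bar\lambda}.
#'
#' @param tissue a [GroundTruthTissue-class] (typically a relaxed
#'   tissue whose tensions were just changed by [applyCondition()])
#' @param nFrames number of snapshots to record after the initial state
#' @param frameTime simulated time between snapshots
#' @param stepSize Euler integration step (stability-bounded)
#' @param eta viscous damping coefficient
#' @param t1Frac T1 threshold fraction (checked between frames)
#' @param fixedBorder pin border pivots (see [relaxTissue()])
#' @return list of [GroundTruthTissue-class] snapshots
#'   (\code{nFrames + 1} frames including the initial state)
#' @export
relaxOverdamped <- function(tissue, nFrames = 10L, frameTime = 0.25,
                            stepSize = 0.002, eta = 1, t1Frac = 0.05,
                            fixedBorder = TRUE) {
  stepsPerFrame <- max(1L, round(frameTime / stepSize))
  h <- frameTime / stepsPerFrame
  snaps <- vector("list", nFrames + 1L)
  t1Guard <- new.env(parent = emptyenv())
  tissue@frameId <- 1L
  snaps[[1L]] <- tissue
  cur <- tissue
  for (f in seq_len(nFrames)) {
    idx <- buildEnergyIndex(cur)
    par <- c(cur@vertices[, 1], cur@vertices[, 2])
    fix <- if (fixedBorder) fixedDofs(cur, idx$nV) else integer(0)
    for (s in seq_len(stepsPerFrame)) {
      g <- tissueGradient(par, idx)
      if (length(fix)) g[fix] <- 0
      par <- par - (h / eta) * g
    }
    cur <- setTissueVertices(cur, par)
    if (t1Frac > 0) {
      sw <- performT1IfNeeded(cur, t1Frac, guard = t1Guard)
      cur <- sw$tissue
    }
    cur@simTime <- cur@simTime + frameTime
    cur@frameId <- f + 1L
    res <- maxResidualForce(cur)
    cur@relaxed <- list(converged = res < 1e-3, residual = res)
    snaps[[f + 1L]] <- cur
  }
  snaps
}
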
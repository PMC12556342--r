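#' Track pivot vertices across frames
#'
#' Greedy mutual nearest-neighbor matching of pivot positions between
#' consecutive frames: pairs are accepted in order of increasing
#' distance (ties broken by lowest index) up to a maximum displacement;
#' unmatched pivots end or start tracks. User-supplied correction
#' entries override the automatic matches, which keeps mistracked
#' junctions repairable without touching the segmentation.
#'
#' @param frameList list of [TissueMesh-class] objects in time order
#' @param maxDisp maximum matching displacement in pixels; default half
#'   the median membrane chain length of the first frame
#' @param corrections optional corrections: a JSON file path or a list
#'   of entries \code{list(frame_from, pivot_from, frame_to, pivot_to)}
#'   with \code{frame_to = frame_from + 1}
#' @param dt time per frame
#' @return a [FrameSeries-class]
#' @export
trackPivots <- function(frameList, maxDisp = NULL, corrections = NULL,
                        dt = 1) {
  stopifnot(length(frameList) >= 2)
  if (is.character(corrections))
    corrections <- jsonlite::read_json(corrections, simplifyVector = FALSE)
  if (is.null(corrections)) corrections <- list()

  if (is.null(maxDisp)) {
    m1 <- frameList[[1]]
    lens <- vapply(m1@membranes, function(m) {
      polylineLength(membranePoints(m1, m))
    }, numeric(1))
    maxDisp <- 0.5 * stats::median(lens)
  }

  # validate corrections up front, listing every offending entry
  bad <- character(0)
  for (i in seq_along(corrections)) {
    co <- corrections[[i]]
    ff <- co$frame_from; ft <- co$frame_to
    ok <- !is.null(ff) && !is.null(ft) && ft == ff + 1 &&
      ff >= 1 && ft <= length(frameList) &&
      co$pivot_from %in% frameList[[ff]]@pivots &&
      co$pivot_to %in% frameList[[ft]]@pivots
    if (!ok) bad <- c(bad, sprintf("entry %d (%s)", i,
                                   paste(unlist(co), collapse = ",")))
  }
  if (length(bad))
    stop("invalid correction entries: ", paste(bad, collapse = "; "))

  matchFrames <- function(t) {
    p1 <- frameList[[t]]@pivots
    p2 <- frameList[[t + 1]]@pivots
    x1 <- frameList[[t]]@vertices[p1, , drop = FALSE]
    x2 <- frameList[[t + 1]]@vertices[p2, , drop = FALSE]
    D <- outer(x1[, 1], x2[, 1], "-")^2 + outer(x1[, 2], x2[, 2], "-")^2
    D <- sqrt(D)
    match12 <- rep(NA_integer_, length(p1))
    while (TRUE) {
      k <- which.min(D)
      if (!length(k) || !is.finite(D[k]) || D[k] > maxDisp) break
      i <- (k - 1) %% nrow(D) + 1
      j <- (k - 1) %/% nrow(D) + 1
      match12[i] <- p2[j]
      D[i, ] <- Inf; D[, j] <- Inf
    }
    out <- stats::setNames(match12, p1)
    # corrections for this transition override
    for (co in corrections) {
      if (co$frame_from != t) next
      out[names(out) == as.character(co$pivot_from)] <- co$pivot_to
      clash <- names(out)[!is.na(out) & out == co$pivot_to &
                            names(out) != as.character(co$pivot_from)]
      out[clash] <- NA_integer_
      out[[as.character(co$pivot_from)]] <- co$pivot_to
    }
    out
  }

  nF <- length(frameList)
  trackOf <- stats::setNames(seq_along(frameList[[1]]@pivots),
                             frameList[[1]]@pivots)
  nextTrack <- length(trackOf) + 1L
  rows <- list()
  addRows <- function(t, mapping) {
    mesh <- frameList[[t]]
    for (p in mesh@pivots) {
      tr <- mapping[[as.character(p)]]
      rows[[length(rows) + 1L]] <<- data.frame(
        track = tr, frame = t, pivot = p,
        x = mesh@vertices[p, 1], y = mesh@vertices[p, 2])
    }
  }
  addRows(1L, as.list(trackOf))
  for (t in seq_len(nF - 1L)) {
    m12 <- matchFrames(t)
    newTrackOf <- list()
    for (i in seq_along(m12)) {
      if (is.na(m12[i])) next
      newTrackOf[[as.character(m12[i])]] <- trackOf[[names(m12)[i]]]
    }
    for (p in frameList[[t + 1]]@pivots) {
      if (is.null(newTrackOf[[as.character(p)]])) {
        newTrackOf[[as.character(p)]] <- nextTrack
        nextTrack <- nextTrack + 1L
      }
    }
    trackOf <- newTrackOf
    addRows(t + 1L, trackOf)
  }
  tr <- do.call(rbind, rows)
  tr$track <- as.integer(tr$track)
  new("FrameSeries", frames = frameList, tracks = tr, dt = dt,
      corrections = corrections)
}

#' Per-pivot velocities and the reference velocity
#'
#' Forward finite-difference velocities for every track,
#' \eqn{v(t) = (x(t+1) - x(t)) / dt}, with the backward difference in
#' the final frame; frames where a track cannot be followed are
#' assigned zero velocity. The reference velocity \code{vbar} is the
#' time average over frames of the mean junction speed.
#'
#' @param series a [FrameSeries-class]
#' @return list with \code{velocities} (data.frame: track, frame,
#'   pivot, vx, vy, speed, assigned) and \code{vbar}
#' @export
computeVelocities <- function(series) {
  tr <- series@tracks
  dt <- series@dt
  nF <- length(series@frames)
  if (nF < 2)
    warning("single frame: all velocities zero (static limit)")
  tr <- tr[order(tr$track, tr$frame), ]
  vx <- vy <- numeric(nrow(tr))
  assigned <- logical(nrow(tr)) # TRUE when a null velocity was assigned
  key <- paste(tr$track, tr$frame)
  idxOf <- stats::setNames(seq_len(nrow(tr)), key)
  for (i in seq_len(nrow(tr))) {
    t <- tr$frame[i]
    if (t < nF) {
      j <- idxOf[paste(tr$track[i], t + 1)]
      if (!is.na(j)) {
        vx[i] <- (tr$x[j] - tr$x[i]) / dt
        vy[i] <- (tr$y[j] - tr$y[i]) / dt
      } else assigned[i] <- TRUE
    } else {
      j <- idxOf[paste(tr$track[i], t - 1)]
      if (!is.na(j)) {
        vx[i] <- (tr$x[i] - tr$x[j]) / dt
        vy[i] <- (tr$y[i] - tr$y[j]) / dt
      } else assigned[i] <- TRUE
    }
  }
  vel <- data.frame(track = tr$track, frame = tr$frame, pivot = tr$pivot,
                    vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
                    assigned = assigned)
  perFrame <- tapply(vel$speed, vel$frame, mean)
  vbar <- mean(perFrame)
  list(velocities = vel, vbar = vbar)
}

#' Assemble the dynamic (overdamped) force-balance system
#'
#' Same coefficient matrix as the static assembly; the right-hand side
#' of the force rows carries the nondimensional velocity scaled by the
#' scale parameter: for pivot \eqn{i} and axis \eqn{a}, the entry is
#' \eqn{\rho \, v_{ia} / \bar v}. The constraint row keeps \eqn{E} on
#' the right-hand side. The per-frame tissue motility \code{vnorm}
#' (\eqn{|v|_2}) is the 2-norm of the force-row right-hand side.
#'
#' At \eqn{\rho = 0}, or when \code{vbar} is zero, the system reduces
#' bitwise to the static assembly.
#'
#' @param mesh a [TissueMesh-class]
#' @param velocities matrix with rownames = pivot ids and columns
#'   (vx, vy), or the data.frame from [computeVelocities()] filtered to
#'   this frame
#' @param rho scale parameter (>= 0), the ratio of viscous to elastic
#'   force scales
#' @param vbar reference velocity; when 0 the static system is returned
#'   with a warning
#' @param includeBorder include border-pivot rows
#' @return a [LinearSystem-class]
#' @export
assembleDynamicSystem <- function(mesh, velocities, rho = 0.1, vbar = NULL,
                                  includeBorder = FALSE) {
  if (rho < 0) stop("rho must be non-negative")
  if (is.data.frame(velocities)) {
    vm <- as.matrix(velocities[, c("vx", "vy")])
    rownames(vm) <- velocities$pivot
    velocities <- vm
  }
  if (is.null(vbar)) {
    sp <- sqrt(rowSums(velocities^2))
    vbar <- mean(sp)
  }
  sys <- assembleStaticSystem(mesh, includeBorder = includeBorder)
  if (vbar <= 0) {
    if (rho > 0)
      warning("zero reference velocity: falling back to the static system")
    sys@meta$mode <- "dynamic"; sys@meta$rho <- rho
    sys@meta$vbar <- 0; sys@meta$vnorm <- 0
    return(sys)
  }
  B <- sys@B
  for (r in seq_len(nrow(sys@M) - 1L)) {
    p <- sys@rowIndex$pivot[r]
    ax <- if (sys@rowIndex$axis[r] == "x") 1L else 2L
    v <- if (as.character(p) %in% rownames(velocities)) {
      velocities[as.character(p), ax]
    } else 0
    B[r] <- rho * v / vbar
  }
  sys@B <- B
  sys@meta$mode <- "dynamic"
  sys@meta$rho <- rho
  sys@meta$vbar <- vbar
  sys@meta$vnorm <- vecnorm(B[-length(B)])
  sys
}

#' Run dynamic inference over a tracked series
#'
#' Tracking, velocities, a per-frame dynamic tension solve and the
#' pressure solve, returned in tidy long format keyed by frame and
#' entity id.
#'
#' @param series a [FrameSeries-class] (see [trackPivots()])
#' @param rho scale parameter (default 0.1, the in-silico optimum)
#' @param includeBorder include border-pivot rows
#' @return list with data.frames \code{tensions} (frame, membrane,
#'   pivotA, pivotB, cell1, cell2, curvature, lambda), \code{pressures}
#'   (frame, cell, P), \code{velocities}, per-frame \code{vnorm},
#'   \code{vbar}, and the per-frame solution objects in
#'   \code{solutions}
#' @export
inferSeries <- function(series, rho = 0.1, includeBorder = FALSE) {
  cv <- computeVelocities(series)
  vel <- cv$velocities
  nF <- length(series@frames)
  tensL <- list(); presL <- list(); sols <- vector("list", nF)
  vnorm <- numeric(nF)
  for (t in seq_len(nF)) {
    mesh <- series@frames[[t]]
    vt <- vel[vel$frame == t, , drop = FALSE]
    res <- inferForces(mesh, includeBorder = includeBorder,
                       velocities = if (rho > 0 && cv$vbar > 0) vt else NULL,
                       rho = rho, vbar = cv$vbar)
    vnorm[t] <- if (!is.null(res$system@meta$vnorm)) res$system@meta$vnorm else 0
    lam <- res$stress@tensions
    tensL[[t]] <- do.call(rbind, lapply(mesh@membranes, function(m) {
      data.frame(frame = t, membrane = m$id, pivotA = m$pivotA,
                 pivotB = m$pivotB, cell1 = m$cell1, cell2 = m$cell2,
                 curvature = m$curvature, lambda = lam[[as.character(m$id)]])
    }))
    P <- res$pressure@pressures
    presL[[t]] <- data.frame(frame = t, cell = seq_along(P), P = unname(P))
    sols[[t]] <- res
  }
  list(tensions = do.call(rbind, tensL),
       pressures = do.call(rbind, presL),
       velocities = vel, vnorm = vnorm, vbar = cv$vbar,
       rho = rho, solutions = sols)
}
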
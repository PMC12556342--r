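#' Mean absolute percentage error
#'
#' \code{mean(|pred - truth| / |truth|)}, returned as a fraction
#' (multiply by 100 for percent). Entries with zero truth are excluded
#' with a warning.
#'
#' @param predicted,truth numeric vectors of equal length
#' @return MAPE as a fraction
#' @export
mape <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  keep <- !is.na(predicted) & !is.na(truth)
  predicted <- predicted[keep]; truth <- truth[keep]
  z <- truth == 0
  if (any(z)) {
    warning(sum(z), " zero-truth entries excluded from MAPE")
    predicted <- predicted[!z]; truth <- truth[!z]
  }
  mean(abs(predicted - truth) / abs(truth))
}

# coefficient of determination against the identity line pred = truth
# (not a refit): 1 - SS_res / SS_tot
identityR2 <- function(predicted, truth) {
  keep <- !is.na(predicted) & !is.na(truth)
  predicted <- predicted[keep]; truth <- truth[keep]
  sstot <- sum((truth - mean(truth))^2)
  if (sstot == 0) return(NA_real_)
  1 - sum((predicted - truth)^2) / sstot
}

#' Saturated goodness-of-fit score
#'
#' Composite score combining the MAPE fraction \eqn{M}, the Pearson
#' correlation \eqn{p} and the coefficient of determination \eqn{r}:
#' \deqn{s(M, p, r) = \alpha/M + (\beta/2)(1 + p)/(1 - p) + \gamma/(1 - r)}
#' with unit weights by default. The score is unbounded from above and
#' is capped at 299.5 - the value attained at a 1\% error,
#' \eqn{s(0.01, 0.99, 0.99) = 299.5}. Degenerate perfect inputs
#' (\eqn{M \le 0}, \eqn{p \ge 1} or \eqn{r \ge 1}) return the cap.
#'
#' @param M MAPE as a fraction
#' @param p Pearson correlation coefficient
#' @param r coefficient of determination
#' @param alpha,beta,gamma component weights
#' @param cap saturation value
#' @return the saturated score
#' @export
saturatedScore <- function(M, p, r, alpha = 1, beta = 1, gamma = 1,
                           cap = 299.5) {
  if (any(is.na(c(M, p, r)))) return(NA_real_)
  if (M <= 0 || p >= 1 || r >= 1) return(cap)
  s <- alpha / M + (beta / 2) * (1 + p) / (1 - p) + gamma / (1 - r)
  min(s, cap)
}

#' Score a tension (or pressure) inference against ground truth
#'
#' Computes MAPE, Pearson correlation, identity-line coefficient of
#' determination and the saturated score. The truth is mean-normalized
#' over the compared entries, matching the mean-one calibration of the
#' inference.
#'
#' @param predicted inferred values (NA entries dropped)
#' @param truth ground-truth values
#' @param normalizeTruth divide truth by its mean over compared entries
#' @param cap saturation cap for the score (Inf for the raw score, as
#'   used when locating a score optimum: the cap is for representation)
#' @return list with \code{M} (fraction), \code{p}, \code{r}, \code{s}
#' @export
scoreInference <- function(predicted, truth, normalizeTruth = TRUE,
                           cap = 299.5) {
  keep <- !is.na(predicted) & !is.na(truth)
  predicted <- predicted[keep]; truth <- truth[keep]
  if (normalizeTruth && mean(truth) != 0) truth <- truth / mean(truth)
  M <- mape(predicted, truth)
  p <- suppressWarnings(stats::cor(predicted, truth))
  r <- identityR2(predicted, truth)
  list(M = M, p = p, r = r, s = saturatedScore(M, p, r, cap = cap))
}

#' Log ratio of dynamic to static scores
#'
#' \code{log(scoreDyn / scoreStat)}: positive values mean the dynamic
#' solution outperformed the static one on the same frames.
#'
#' @param scoreDyn,scoreStat positive scores
#' @return the log ratio
#' @export
dynamicStaticRatio <- function(scoreDyn, scoreStat) {
  if (any(scoreDyn <= 0) || any(scoreStat <= 0))
    stop("scores must be positive")
  log(scoreDyn / scoreStat)
}

#' Summarize scores by tissue-motility bin
#'
#' Partitions per-frame results into \eqn{|v|_2} bins (the 2-norm of
#' the dynamic right-hand side, constraint row excluded) and reports
#' per-bin medians and interquartile ranges. Empty bins are reported
#' empty rather than dropped.
#'
#' @param results data.frame with a \code{vnorm} column and one or more
#'   score columns
#' @param bins numeric vector of bin breaks, or a single bin count
#' @param cols score columns to summarize
#' @return data.frame with one row per bin
#' @export
binScoresByVelocity <- function(results, bins = 5,
                                cols = setdiff(names(results), "vnorm")) {
  if (length(bins) == 1L) {
    rng <- range(results$vnorm)
    if (diff(rng) == 0) {
      bins <- c(rng[1] - 0.5, rng[1] + 0.5)
    } else {
      bins <- seq(rng[1], rng[2], length.out = bins + 1L)
    }
  }
  grp <- cut(results$vnorm, bins, include.lowest = TRUE)
  out <- data.frame(bin = levels(grp),
                    n = as.vector(table(grp)))
  for (cl in cols) {
    agg <- tapply(results[[cl]], grp, stats::median, na.rm = TRUE)
    q1 <- tapply(results[[cl]], grp, stats::quantile, probs = 0.25,
                 na.rm = TRUE)
    q3 <- tapply(results[[cl]], grp, stats::quantile, probs = 0.75,
                 na.rm = TRUE)
    out[[paste0(cl, "_median")]] <- as.numeric(agg)
    out[[paste0(cl, "_q1")]] <- as.numeric(q1)
    out[[paste0(cl, "_q3")]] <- as.numeric(q3)
  }
  out
}

#' Sweep the scale parameter over a dynamic series suite
#'
#' For each ground-truth series, runs dynamic inference at every value
#' of the grid (0 to 0.5 in steps of 0.01 by default, matching the
#' two-decimal resolution of the in-silico optima), scores the inferred
#' tensions against the prescribed ones per frame, and takes the
#' score-maximizing rho per replicate (median score across frames).
#' The per-condition summary is the median across replicates.
#'
#' A series with zero velocities yields a flat score curve, reported
#' with a degenerate-optimum flag.
#'
#' @param seriesSuite list of entries, each a list with \code{series}
#'   (a [FrameSeries-class]), \code{truth} (prescribed tensions named
#'   by membrane id), and optional \code{condition} tag
#' @param rhoGrid scale-parameter grid
#' @param includeBorder include border-pivot rows
#' @return list with \code{perReplicate} (data.frame: condition,
#'   replicate, rhoOpt, flat), \code{perCondition} (median rhoOpt per
#'   condition), \code{curves} (list of score-vs-rho matrices)
#' @export
sweepScaleParameter <- function(seriesSuite, rhoGrid = seq(0, 0.5, 0.01),
                                includeBorder = FALSE) {
  perRep <- list(); curves <- list()
  for (k in seq_along(seriesSuite)) {
    entry <- seriesSuite[[k]]
    sc <- scoreRhoCurve(entry$series, entry$truth, rhoGrid,
                        includeBorder = includeBorder)
    flat <- diff(range(sc)) < 1e-9
    if (flat)
      warning("flat score curve: degenerate scale-parameter optimum")
    rhoOpt <- rhoGrid[which.max(sc)]
    cond <- if (is.null(entry$condition)) "unknown" else entry$condition
    perRep[[k]] <- data.frame(condition = cond, replicate = k,
                              rhoOpt = rhoOpt, flat = flat)
    curves[[k]] <- data.frame(rho = rhoGrid, score = sc)
  }
  perRep <- do.call(rbind, perRep)
  perCond <- stats::aggregate(rhoOpt ~ condition, perRep, stats::median)
  list(perReplicate = perRep, perCondition = perCond, curves = curves)
}

# median-over-frames score of dynamic inference at each rho of a grid.
# The coefficient matrix is rho-independent and the solution is affine
# in rho (the right-hand side is), so each frame needs two constrained
# solves; the non-negative fallback is only run for grid points where
# the affine path would go negative.
scoreRhoCurve <- function(series, truth, rhoGrid, includeBorder = FALSE) {
  cv <- computeVelocities(series)
  nF <- length(series@frames)
  scores <- matrix(NA_real_, nF, length(rhoGrid))
  for (t in seq_len(nF)) {
    mesh <- series@frames[[t]]
    vt <- cv$velocities[cv$velocities$frame == t, , drop = FALSE]
    sys0 <- assembleStaticSystem(mesh, includeBorder = includeBorder)
    E <- sys0@meta$E
    lam0 <- lam1 <- NULL
    if (cv$vbar > 0) {
      sys1 <- assembleDynamicSystem(mesh, vt, rho = 1, vbar = cv$vbar,
                                    includeBorder = includeBorder)
      consMask <- c(rep(TRUE, E), FALSE)
      r0 <- kktSolve(sys0@M, sys0@B, consMask, E, nonneg = FALSE)
      r1 <- kktSolve(sys1@M, sys1@B, consMask, E, nonneg = FALSE)
      lam0 <- r0$x[seq_len(E)]; lam1 <- r1$x[seq_len(E)]
    }
    ids <- sys0@meta$membranes
    tru <- truth[ids]
    for (j in seq_along(rhoGrid)) {
      rho <- rhoGrid[j]
      if (is.null(lam0)) { # zero-velocity series: flat in rho
        st <- solveStresses(sys0)
        scores[t, j] <- scoreInference(st@tensions, tru, cap = Inf)$s
        next
      }
      lam <- (1 - rho) * lam0 + rho * lam1
      if (any(lam < -1e-9)) {
        sys <- assembleDynamicSystem(mesh, vt, rho = rho, vbar = cv$vbar,
                                     includeBorder = includeBorder)
        lam <- solveStresses(sys)@tensions
      } else {
        lam <- lam / mean(lam)
      }
      scores[t, j] <- scoreInference(lam, tru, cap = Inf)$s
    }
  }
  apply(scores, 2, stats::median, na.rm = TRUE)
}

#' One-dimensional Wasserstein (earth mover's) distance
#'
#' Integral of the absolute difference of the two empirical CDFs; zero
#' exactly when the two empirical distributions coincide.
#'
#' @param a,b numeric samples (any lengths)
#' @return the distance
#' @export
wasserstein1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  x <- sort(unique(c(a, b)))
  if (length(x) == 1L) return(0)
  Fa <- stats::ecdf(a)(x); Fb <- stats::ecdf(b)(x)
  dx <- diff(x)
  sum(abs(Fa[-length(Fa)] - Fb[-length(Fb)]) * dx)
}
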
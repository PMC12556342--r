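#' Per-membrane normalized intensity from a raster image
#'
#' Measures a fluorescence intensity (e.g. a myosin reporter) along
#' every membrane of a mesh: membrane shapes are smoothed with a
#' third-order Savitzky-Golay filter over a 5-pixel window, per-vertex
#' intensities (sampled from the image at the smoothed positions) are
#' replaced by the median over the vertex and its first chain
#' neighbors, the membrane value is the mean of its smoothed vertex
#' intensities, and all values are normalized to a tissue mean of one.
#' Membranes shorter than the filter window use their raw chain and are
#' flagged.
#'
#' @param image numeric intensity matrix aligned with the mesh
#'   coordinates (row = y + 1, column = x + 1)
#' @param mesh a [TissueMesh-class]
#' @param window,order Savitzky-Golay filter window (odd) and
#'   polynomial order
#' @return data.frame with \code{membrane}, \code{intensity}
#'   (tissue mean 1), \code{flag}
#' @export
membraneIntensity <- function(image, mesh, window = 5L, order = 3L) {
  img <- as.matrix(image)
  nr <- nrow(img); nc <- ncol(img)
  sampleAt <- function(pts) {
    # nearest-pixel lookup, clamped to the canvas
    rr <- pmin(pmax(round(pts[, 2]) + 1L, 1L), nr)
    cc <- pmin(pmax(round(pts[, 1]) + 1L, 1L), nc)
    img[cbind(rr, cc)]
  }
  res <- lapply(mesh@membranes, function(m) {
    pts <- membranePoints(mesh, m)
    flag <- ""
    if (nrow(pts) >= window) {
      pts[, 1] <- signal::sgolayfilt(pts[, 1], p = order, n = window)
      pts[, 2] <- signal::sgolayfilt(pts[, 2], p = order, n = window)
    } else {
      flag <- "short"
    }
    raw <- sampleAt(pts)
    sm <- vapply(seq_along(raw), function(i) {
      lo <- max(1L, i - 1L); hi <- min(length(raw), i + 1L)
      stats::median(raw[lo:hi])
    }, numeric(1))
    data.frame(membrane = m$id, intensity = mean(sm), flag = flag)
  })
  out <- do.call(rbind, res)
  out$intensity <- out$intensity / mean(out$intensity)
  out
}

#' Pressure-weighted density along an axis
#'
#' Gaussian-kernel density of per-cell positions along an axis with
#' the inferred pressures as weights, used to locate zones of elevated
#' intracellular pressure (e.g. forming rosettes) along a migration
#' axis. Since relative pressures are mean-zero, weights are shifted by
#' subtraction of their minimum before the estimate; the shift is
#' reported. All-equal weights reduce to a plain KDE.
#'
#' @param coords per-cell coordinate along the chosen axis
#' @param weights per-cell weights (typically inferred pressures)
#' @param bw kernel bandwidth; default Scott-like rule of the base
#'   density estimator
#' @param n grid size
#' @return list with \code{x}, \code{y} (density on a uniform grid),
#'   \code{shift} (amount added to the weights), \code{bw}
#' @export
pressureWeightedDensity <- function(coords, weights = NULL, bw = "nrd0",
                                    n = 512) {
  keep <- !is.na(coords) & (if (is.null(weights)) TRUE else !is.na(weights))
  coords <- coords[keep]
  shift <- 0
  if (is.null(weights) || diff(range(weights[keep])) == 0) {
    w <- rep(1 / length(coords), length(coords))
  } else {
    w <- weights[keep]
    if (min(w) < 0) {
      shift <- -min(w)
      w <- w + shift
    }
    if (sum(w) == 0) w <- rep(1, length(w))
    w <- w / sum(w)
  }
  # resolve bandwidth rules on the unweighted sample (the base
  # estimator would warn about rule-based selection under weights)
  if (is.character(bw) && length(coords) < 2) {
    bw <- 1
  } else if (is.character(bw)) {
    bw <- switch(bw,
                 nrd0 = stats::bw.nrd0(coords),
                 nrd = stats::bw.nrd(coords),
                 SJ = stats::bw.SJ(coords),
                 stats::bw.nrd0(coords))
  }
  d <- stats::density(coords, weights = w, bw = bw, n = n)
  list(x = d$x, y = d$y, shift = shift, bw = d$bw)
}

#' Local maxima of a sampled curve
#'
#' Finds points where the first finite difference changes sign from
#' positive to negative and the second difference is negative, i.e.
#' interior local maxima of the sampled curve, sorted by position. A
#' monotone curve yields an empty result.
#'
#' @param x,y the sampled curve (or a list with \code{x}, \code{y})
#' @return data.frame with \code{x}, \code{y} of each maximum
#' @export
findDensityMaxima <- function(x, y = NULL) {
  if (is.list(x) && is.null(y)) { y <- x$y; x <- x$x }
  stopifnot(length(x) == length(y), length(x) >= 3)
  d1 <- diff(y)
  idx <- which(d1[-length(d1)] > 0 & d1[-1] <= 0) + 1L
  d2 <- diff(y, differences = 2)
  idx <- idx[d2[idx - 1L] < 0]
  out <- data.frame(x = x[idx], y = y[idx])
  out[order(out$x), , drop = FALSE]
}

#' Fit a post-ablation recoil trace
#'
#' After a membrane is cut, the separation between its two pivot
#' vertices grows linearly at short times,
#' \eqn{L(t) = L_0 + 2 (\lambda/\eta) t}: membrane tension is balanced
#' only by viscous damping once the elastic connection is severed. An
#' ordinary least-squares line on the fitting window yields
#' \eqn{\lambda/\eta} as slope/2. Traces given as relative elongation
#' \eqn{L(t)/L_0} are supported through \code{L0}; a negative fitted
#' slope is flagged (no recoil).
#'
#' @param times time points (seconds), 0 at ablation
#' @param L separation lengths (pixels), or relative elongation if
#'   \code{relative = TRUE}
#' @param window fitting window \code{c(tmin, tmax)}; default from the
#'   first point to 10 s
#' @param relative interpret \code{L} as relative elongation
#'   \eqn{L(t)/L_0}; requires \code{L0}
#' @param L0 pre-ablation length, required for relative input
#' @return list with \code{L0} (fitted intercept), \code{lambdaEta}
#'   (\eqn{\lambda/\eta}), \code{slope}, \code{flag}, \code{fit}
#' @export
fitRecoil <- function(times, L, window = NULL, relative = FALSE,
                      L0 = NULL) {
  if (is.null(window)) window <- c(min(times), min(times) + 10)
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 3) stop("need at least 3 points in the fitting window")
  t <- times[keep]; y <- L[keep]
  if (relative) {
    if (is.null(L0)) stop("relative traces require L0")
    y <- y * L0
  }
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)[2])
  flag <- if (slope < 0) "no_recoil" else ""
  list(L0 = unname(stats::coef(fit)[1]), lambdaEta = slope / 2,
       slope = slope, flag = flag, fit = fit)
}

#' Scale parameter from recoil fits and a characteristic velocity
#'
#' Combines per-experiment \eqn{\lambda/\eta} ratios (from
#' [fitRecoil()]) with the characteristic junction velocity \eqn{\bar v}
#' of the same tissue class into scale-parameter estimates
#' \eqn{\hat\rho = \bar v / (\lambda/\eta)} (the dimensionless ratio of
#' viscous to elastic force scales). Non-positive ratios are excluded
#' and logged.
#'
#' @param lambdaEta vector of per-experiment \eqn{\lambda/\eta}
#' @param vbar characteristic velocity (scalar or per-experiment)
#' @return list with \code{rho} (per experiment), \code{mean},
#'   \code{sd}, \code{excluded} (indices dropped)
#' @export
estimateScaleParameter <- function(lambdaEta, vbar) {
  bad <- which(lambdaEta <= 0)
  if (length(bad))
    message(length(bad), " experiment(s) with non-positive lambda/eta excluded")
  keep <- setdiff(seq_along(lambdaEta), bad)
  if (length(vbar) == 1L) vbar <- rep(vbar, length(lambdaEta))
  rho <- vbar[keep] / lambdaEta[keep]
  list(rho = rho, mean = mean(rho), sd = stats::sd(rho), excluded = bad)
}
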
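#' Impose a validation tension pattern on a tissue
#'
#' Reassigns the prescribed membrane tensions according to one of the
#' four ground-truth conditions:
#' \describe{
#'   \item{x_furrow / y_furrow}{each tension gains the standard-normal
#'     PDF of the z-scored membrane-center coordinate (x or y), peaked
#'     at the tissue centroid with standard deviation two mean cell
#'     radii - a vertical or horizontal high-tension furrow.}
#'   \item{circular}{the same profile on the distance of the membrane
#'     center to the tissue centroid: a central high-tension zone
#'     decaying radially.}
#'   \item{random}{each membrane draws one of the five base values
#'     (1, 1.1, 1.2, 1.3, 1.5) uniformly, then a Gaussian spread of
#'     50\% of that value around it.}
#' }
#' Tensions are floored at a small positive epsilon. The tissue is
#' returned unrelaxed (the new tensions unbalance the junctions);
#' follow with [relaxTissue()] for a static ground truth or
#' [relaxOverdamped()] for a dynamic series.
#'
#' @param tissue a [GroundTruthTissue-class]
#' @param condition one of \code{"x_furrow"}, \code{"y_furrow"},
#'   \code{"circular"}, \code{"random"}
#' @param seed seed for the random condition (ignored otherwise)
#' @param amplitude multiplier on the Gaussian tension profile. The
#'   profile is stated only up to scale; the defaults (12 for the two
#'   linear furrows, 1 for the circular zone) are calibrated so the
#'   relaxed ground-truth pressure spans sit in the 0.05-0.4 range
#'   typical of epithelial vertex-model tissues at unit tension scale,
#'   per condition. Ignored for
#'   \code{"random"}, whose spread is fully specified.
#' @param floorEps lower bound on tensions
#' @return the tissue with new \code{trueTensions} and condition tag
#' @export
applyCondition <- function(tissue, condition, seed = tissue@seed,
                           amplitude = NULL, floorEps = 0.05) {
  condition <- match.arg(condition,
                         c("x_furrow", "y_furrow", "circular", "random"))
  E <- length(tissue@membranes)
  centers <- t(vapply(seq_len(E), function(i) {
    membraneMidpoint(tissue, i)
  }, numeric(2)))
  cent <- colMeans(do.call(rbind,
                           lapply(tissue@cells, function(cl) cl$centroid)))
  radii <- vapply(tissue@cells, function(cl) sqrt(cl$area / pi), numeric(1))
  sdlen <- 2 * mean(radii)

  if (is.null(amplitude))
    amplitude <- if (condition == "circular") 1 else 12

  lam <- tissue@trueTensions
  if (condition == "x_furrow") {
    lam <- lam + amplitude * stats::dnorm((centers[, 1] - cent[1]) / sdlen)
  } else if (condition == "y_furrow") {
    lam <- lam + amplitude * stats::dnorm((centers[, 2] - cent[2]) / sdlen)
  } else if (condition == "circular") {
    d <- sqrt((centers[, 1] - cent[1])^2 + (centers[, 2] - cent[2])^2)
    lam <- lam + amplitude * stats::dnorm(d / sdlen)
  } else {
    set.seed(as.integer(seed) + 7919L)
    base <- sample(c(1, 1.1, 1.2, 1.3, 1.5), E, replace = TRUE)
    lam <- stats::rnorm(E, mean = base, sd = 0.5 * base)
  }
  tissue@trueTensions <- pmax(lam, floorEps)
  tissue@condition <- condition
  tissue@relaxed <- list(converged = FALSE, residual = Inf)
  tissue
}

#' Ground-truth cell pressures of a relaxed tissue
#'
#' The area-constraint multiplier of the quadratic penalty at
#' stationarity, \eqn{P_c = K (A_0 - A_c)} (equivalently
#' \eqn{\partial E / \partial A_0}), mean-centered for comparison with
#' inferred pressures (which are normalized to mean zero). A compressed
#' cell (area below target) has positive relative pressure.
#'
#' @param tissue a [GroundTruthTissue-class]; should be relaxed, since
#'   the multipliers are only meaningful near equilibrium
#' @param center mean-center the result (default TRUE)
#' @return numeric vector of per-cell pressures
#' @export
groundTruthPressures <- function(tissue, center = TRUE) {
  if (!isTRUE(tissue@relaxed$converged))
    warning("tissue is not relaxed; area multipliers are only ",
            "meaningful near equilibrium")
  A <- vapply(tissue@cells, function(cl) cl$area, numeric(1))
  P <- tissue@K * (tissue@targetAreas - A)
  if (center) P <- P - mean(P)
  stats::setNames(P, seq_along(P))
}
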
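# Fiber-angle measurement in the local frame, axial circular statistics,
# and fiber-field comparison metrics.
#
# A measured fiber vector is embedded in the wall's tangent plane by
# Gram-Schmidt against the transmural axis; its signed angle from the
# longitudinal direction, folded by the axial identity (a fiber equals its
# negation) into (-90, 90] degrees, is the measured angle. Per-bundle,
# per-layer histograms give the dominant (modal) angle; means and SDs use
# doubled-angle circular statistics as appropriate for axial data.

#' Embed a measured fiber vector in a local frame
#'
#' Gram-Schmidt projection into the wall tangent plane: `s = e_t`,
#' `f = normalize(f_m - (f_m . e_t) e_t)`, `n = e_t x f`. Vectorized over
#' rows.
#'
#' @param fMeasured n x 3 matrix (or length-3 vector) of measured fibers.
#' @param frame list with `el`, `en`, `et` matrices.
#' @param tol projection norm below which a node is flagged unmeasurable
#'   (measured vector parallel to the transmural axis).
#' @return list of matrices `f`, `s`, `n` and logical `unmeasurable`.
#' @export
embedInFrame <- function(fMeasured, frame, tol = 1e-8) {
  if (!is.matrix(fMeasured)) fMeasured <- matrix(fMeasured, ncol = 3)
  et <- frame$et
  stopifnot(nrow(fMeasured) == nrow(et))
  norms <- rowNorm(fMeasured)
  if (any(norms == 0)) stop("zero measured vectors")
  proj <- rowSums(fMeasured * et)
  f <- fMeasured - proj * et
  fn <- rowNorm(f)
  unmeasurable <- fn < tol * norms
  fn[fn == 0] <- 1
  f <- f / fn
  n <- rowCross(et, f)
  f[unmeasurable, ] <- NA_real_
  n[unmeasurable, ] <- NA_real_
  list(f = f, s = et, n = n, unmeasurable = unmeasurable)
}

#' Signed axial fiber angle
#'
#' Angle from `el` to the in-plane fiber about `et`, positive toward `en`,
#' folded by the axial identity into (-90, 90] degrees.
#'
#' @param f n x 3 matrix of in-plane unit fibers (rows may be NA).
#' @param frame list with `el`, `en`, `et`.
#' @return numeric vector of degrees in (-90, 90]
#' @export
fiberAngle <- function(f, frame) {
  if (!is.matrix(f)) f <- matrix(f, ncol = 3)
  cosc <- rowSums(f * frame$el)
  sinc <- rowSums(f * frame$en)
  ang <- atan2(sinc, cosc) * 180 / pi      # (-180, 180]
  ang <- ifelse(ang > 90, ang - 180, ifelse(ang <= -90, ang + 180, ang))
  # fold the boundary into the half-open interval
  ang[ang == -90] <- 90
  ang
}

# axial circular mean / SD on doubled angles (degrees in (-90, 90])
axialCircStats <- function(angles) {
  a2 <- angles * pi / 90          # doubled angle in radians
  C <- mean(cos(a2)); S <- mean(sin(a2))
  R <- sqrt(C^2 + S^2)
  mu <- atan2(S, C) / 2 * 180 / pi
  if (mu > 90) mu <- mu - 180
  if (mu <= -90) mu <- mu + 180
  sd <- if (R > 0) sqrt(-2 * log(R)) / 2 * 180 / pi else Inf
  list(mean = mu, sd = sd, R = R)
}

#' Per-bundle, per-layer angle statistics
#'
#' Histogram over (-90, 90] with the given bin width, dominant angle (the
#' centre of the maximal-count bin; ties resolved toward 0 degrees),
#' axial circular mean, angular SD and mean resultant length.
#'
#' @param angles numeric vector of degrees in (-90, 90] (NA = unmeasurable,
#'   excluded and counted).
#' @param bundle,layer grouping vectors (optional: one global group when
#'   omitted).
#' @param binWidth histogram bin width in degrees (default 10).
#' @return data.frame with one row per (bundle, layer) group: `n`,
#'   `dominant`, `mean`, `sd`, `R`, `unmeasurable`.
#' @export
angleStats <- function(angles, bundle = NULL, layer = NULL, binWidth = 10) {
  stopifnot(binWidth > 0)
  if (is.null(bundle)) bundle <- rep("all", length(angles))
  if (is.null(layer)) layer <- rep("all", length(angles))
  breaks <- seq(-90, 90, by = binWidth)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  groups <- split(seq_along(angles), list(bundle = bundle, layer = layer),
                  drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    a <- angles[idx]
    nUnm <- sum(is.na(a))
    a <- a[!is.na(a)]
    if (!length(a)) stop(sprintf("group '%s' has no measurable nodes", g))
    # half-open bins (lo, hi]
    counts <- tabulate(findInterval(a, breaks, left.open = TRUE,
                                    rightmost.closed = TRUE),
                       nbins = length(centres))
    best <- which(counts == max(counts))
    dominant <- centres[best[which.min(abs(centres[best]))]]
    cs <- axialCircStats(a)
    parts <- strsplit(g, "\\.")[[1]]
    data.frame(bundle = parts[1], layer = parts[2], n = length(a),
               dominant = dominant, mean = cs$mean, sd = cs$sd, R = cs$R,
               unmeasurable = nUnm)
  })
  out <- do.call(rbind, rows)
  attr(out, "breaks") <- breaks
  out
}

#' Pointwise fiber difference map
#'
#' `diff(x) = 1 - |f_a(x) . f_b(x)|`: zero for parallel or anti-parallel
#' fibers (axial invariance), one for orthogonal ones.
#'
#' @param fa,fb n x 3 matrices of unit vectors.
#' @param tol tolerated deviation from unit norm.
#' @return numeric vector in `[0, 1]`
#' @export
fiberDiff <- function(fa, fb, tol = 1e-6) {
  stopifnot(nrow(fa) == nrow(fb))
  if (max(abs(rowNorm(fa) - 1), abs(rowNorm(fb) - 1)) > tol) {
    stop("fiber fields must be unit-norm")
  }
  pmin(1, pmax(0, 1 - abs(rowSums(fa * fb))))
}

#' Fraction of fibers in agreement
#'
#' Percentage of nodes whose axial angle between the two fields is at most
#' `thresholdDeg`, i.e. `diff <= 1 - cos(threshold)`.
#'
#' @param diffField output of [fiberDiff()].
#' @param thresholdDeg agreement cutoff in degrees, in (0, 90).
#' @return percentage in `[0, 100]`
#' @export
agreementFraction <- function(diffField, thresholdDeg = 30) {
  stopifnot(thresholdDeg > 0, thresholdDeg < 90)
  100 * mean(diffField <= 1 - cos(thresholdDeg * pi / 180))
}
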
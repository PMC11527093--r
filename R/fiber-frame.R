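# Local orthonormal frames and the two-layer fiber rotation.
#
# Per node: e_t = gamma/|gamma|; e_n = Gram-Schmidt of k against e_t;
# e_l = e_n x e_t. The triad is then rotated about e_t by the bundle's
# layer angle: f = cos(a) e_l + sin(a) e_n, n = -sin(a) e_l + cos(a) e_n,
# s = e_t. Flip bundles (the inter-atrial bridges) negate e_l and e_t
# between the frame build and the rotation.

#' Build local frames from transmural and normal directions
#'
#' Vectorized over rows. Degenerate rows (|gamma| below `tol`, or k parallel
#' to gamma within `tolParallel` radians) are flagged; their frame rows are
#' NA and the caller substitutes a neighbour's frame.
#'
#' @param gamma numeric matrix (n x 3) or length-3 vector.
#' @param k same shape as `gamma`.
#' @param tol minimum usable norm.
#' @param tolParallel minimum angle (radians) between k and gamma.
#' @return list of matrices `el`, `en`, `et` and logical `degenerate`.
#' @export
axisSystem <- function(gamma, k, tol = 1e-12, tolParallel = 1e-8) {
  if (!is.matrix(gamma)) gamma <- matrix(gamma, ncol = 3)
  if (!is.matrix(k)) k <- matrix(k, ncol = 3)
  stopifnot(nrow(gamma) == nrow(k))
  gn <- rowNorm(gamma)
  bad <- !is.finite(gn) | gn < tol
  gn[gn == 0 | !is.finite(gn)] <- 1
  et <- gamma / gn
  proj <- rowSums(k * et)
  kperp <- k - proj * et
  kn <- rowNorm(kperp)
  kTot <- rowNorm(k)
  # k parallel to gamma: perpendicular residual vanishes
  bad <- bad | !is.finite(kn) | kn <= kTot * sin(tolParallel) | kTot < tol
  kn[kn == 0 | !is.finite(kn)] <- 1
  en <- kperp / kn
  el <- rowCross(en, et)
  el[bad, ] <- NA_real_
  en[bad, ] <- NA_real_
  et[bad, ] <- NA_real_
  list(el = el, en = en, et = et, degenerate = bad)
}

#' Rotate a local frame into the fiber triad
#'
#' Applies the in-plane rotation by the layer's angle: the longitudinal
#' direction turns about the transmural axis, the transmural axis becomes
#' the sheet direction.
#'
#' @param frame list with matrices `el`, `en`, `et` (as from
#'   [axisSystem()]).
#' @param alphaEndo,alphaEpi rotation angles in degrees (scalar or
#'   per-row).
#' @param layer character/factor per row: `"endo"` or `"epi"`.
#' @return list of matrices `f`, `n`, `s`.
#' @export
orientFrame <- function(frame, alphaEndo, alphaEpi, layer = "endo") {
  nr <- nrow(frame$el)
  a <- ifelse(as.character(layer) == "endo", alphaEndo, alphaEpi)
  a <- rep_len(a, nr) * pi / 180
  ca <- cos(a); sa <- sin(a)
  f <- ca * frame$el + sa * frame$en
  n <- -sa * frame$el + ca * frame$en
  list(f = f, n = n, s = frame$et)
}

#' Generate the fiber triad field
#'
#' For every node: resolve the transmural (gamma) and normal (k) gradient
#' fields named by the bundle assignment (layer-conditional k resolved by
#' the node's layer), build the local frame, apply the flip for the flagged
#' bridge bundles, rotate by the layer angle. Degenerate nodes inherit the
#' nearest non-degenerate frame within the same bundle (mesh-edge
#' breadth-first search); more than `maxDegenerate` unrepaired nodes is an
#' error (it signals broken geometry or labels).
#'
#' @param mesh a [LabeledTetMesh-class]
#' @param distances a [DistanceFieldSet-class]
#' @param assignment a [BundleAssignment-class]
#' @param maxDegenerate maximum tolerated fraction of degenerate nodes
#'   after repair (default 0.01).
#' @return a [FiberField-class]
#' @export
generateFibers <- function(mesh, distances, assignment, maxDegenerate = 0.01) {
  n <- nNodes(mesh)
  stopifnot(length(assignment@label) == n)
  grads <- distances@gradients
  pick <- function(fieldNames) {
    out <- matrix(NA_real_, n, 3)
    for (nm in unique(fieldNames)) {
      g <- grads[[nm]]
      if (is.null(g)) stop(sprintf("assignment references absent field '%s'", nm))
      sel <- fieldNames == nm
      out[sel, ] <- g[sel, , drop = FALSE]
    }
    out
  }
  kName <- ifelse(assignment@layer == "endo", assignment@kEndo, assignment@kEpi)
  gamma <- pick(assignment@gammaField)
  k <- pick(kName)
  fr <- axisSystem(gamma, k)
  # flip bundles: negate longitudinal and transmural AFTER the frame build,
  # BEFORE the rotation
  fl <- assignment@flip & !fr$degenerate
  fr$el[fl, ] <- -fr$el[fl, , drop = FALSE]
  fr$et[fl, ] <- -fr$et[fl, , drop = FALSE]
  deg <- fr$degenerate
  if (any(deg)) {
    # repair: inherit the nearest same-bundle non-degenerate frame
    lab <- as.integer(assignment@label)
    packed <- cbind(fr$el, fr$en, fr$et, lab)
    packed[deg, seq_len(9)] <- NA_real_
    # per-bundle fill: restrict donors to the same bundle
    for (b in unique(lab[deg])) {
      sel <- lab == b
      vals <- packed[, 1:9, drop = FALSE]
      vals[!sel, ] <- NA_real_
      need <- deg & sel
      filled <- bfsFill(vals, mesh@tets, restrictTo = sel)
      fr$el[need, ] <- filled[need, 1:3, drop = FALSE]
      fr$en[need, ] <- filled[need, 4:6, drop = FALSE]
      fr$et[need, ] <- filled[need, 7:9, drop = FALSE]
    }
    unrepaired <- !is.finite(fr$el[, 1])
    if (mean(unrepaired) > maxDegenerate) {
      stop(sprintf("%.1f%% of nodes have unrepairable degenerate frames",
                   100 * mean(unrepaired)))
    }
    if (any(unrepaired)) {
      # last resort: global nearest non-degenerate frame
      vals <- cbind(fr$el, fr$en, fr$et)
      vals[unrepaired, ] <- NA_real_
      filled <- bfsFill(vals, mesh@tets)
      fr$el[unrepaired, ] <- filled[unrepaired, 1:3, drop = FALSE]
      fr$en[unrepaired, ] <- filled[unrepaired, 4:6, drop = FALSE]
      fr$et[unrepaired, ] <- filled[unrepaired, 7:9, drop = FALSE]
    }
  }
  tri <- orientFrame(fr, assignment@alphaEndo, assignment@alphaEpi,
                     assignment@layer)
  new("FiberField", f = tri$f, s = tri$s, n = tri$n,
      el = fr$el, en = fr$en, et = fr$et,
      bundle = assignment@label, layer = assignment@layer,
      degenerate = deg)
}
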
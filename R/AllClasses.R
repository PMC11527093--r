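#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve
NULL

#' Tetrahedral mesh
#'
#' Plain volumetric tetrahedral mesh: node coordinates in metres, positively
#' oriented tetrahedra, and the derived boundary triangulation (faces
#' incident to exactly one tet, outward oriented).
#'
#' @slot nodes numeric matrix (n x 3), coordinates in metres.
#' @slot tets integer matrix (m x 4), 1-based node indices.
#' @slot boundaryTris integer matrix (b x 3), 1-based node indices.
#' @exportClass TetMesh
setClass("TetMesh", representation(
  nodes = "matrix",
  tets = "matrix",
  boundaryTris = "matrix"
))

setValidity("TetMesh", function(object) {
  msgs <- character()
  if (ncol(object@nodes) != 3) msgs <- c(msgs, "nodes must be an n x 3 matrix")
  if (ncol(object@tets) != 4) msgs <- c(msgs, "tets must be an m x 4 matrix")
  n <- nrow(object@nodes)
  if (nrow(object@tets) && (min(object@tets) < 1 || max(object@tets) > n)) {
    msgs <- c(msgs, "tet indices out of node range")
  }
  if (nrow(object@tets)) {
    v <- tetSignedVolumes(object@nodes, object@tets)
    if (any(v <= 0)) msgs <- c(msgs, sprintf("%d non-positive tet volumes", sum(v <= 0)))
  }
  if (length(msgs)) msgs else TRUE
})

#' Labeled tetrahedral atrial mesh
#'
#' A [TetMesh-class] together with named boundary tag sets (each tag a set of
#' boundary-triangle indices), landmark node indices and optional named node
#' fields (scalar vectors or n x 3 matrices).
#'
#' The bi-atrial tag vocabulary is: `la_endo`, `la_endo_sept`, `la_endo_lat`,
#' `ra_endo`, `ra_endo_ant`, `ra_endo_post`, `epi`, `epi_top_la`,
#' `epi_top_lp`, `epi_top_ra`, `lspv`, `lipv`, `rspv`, `ripv`, `scv`, `icv`,
#' `mv_ant`, `mv_post`, `tv_ant`, `tv_post`, `tv_sept`, `tv_lat`; landmarks
#' are `laa_apex`, `raa_apex`, `fo_centre`, `csm_apex`.
#'
#' @slot tags named list of integer vectors (boundary triangle indices).
#' @slot landmarks named integer vector of node indices.
#' @slot nodeFields named list of per-node scalar vectors or n x 3 matrices.
#' @exportClass LabeledTetMesh
setClass("LabeledTetMesh", contains = "TetMesh", representation(
  tags = "list",
  landmarks = "integer",
  nodeFields = "list"
))

setValidity("LabeledTetMesh", function(object) {
  msgs <- character()
  b <- nrow(object@boundaryTris)
  n <- nrow(object@nodes)
  for (nm in names(object@tags)) {
    tri <- object@tags[[nm]]
    if (length(tri) && (min(tri) < 1 || max(tri) > b)) {
      msgs <- c(msgs, sprintf("tag '%s' references non-boundary triangles", nm))
    }
  }
  lm <- object@landmarks
  if (length(lm) && (min(lm) < 1 || max(lm) > n)) {
    msgs <- c(msgs, "landmark indices out of node range")
  }
  for (nm in names(object@nodeFields)) {
    f <- object@nodeFields[[nm]]
    len <- if (is.matrix(f)) nrow(f) else length(f)
    if (len != n) msgs <- c(msgs, sprintf("field '%s' length != node count", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Harmonic distance-field catalog
#'
#' Named nodal harmonic scalar fields (inter-atrial xi, transmural phi and
#' its per-chamber variants, intra-atrial psi_* per chamber) with their
#' recovered nodal gradients and degeneracy flags.
#'
#' Field names follow `xi`, `phi`, `phi_la`, `phi_ra`, and `<chamber>.psi_<i>`
#' (e.g. `la.psi_r`, `ra.psi_ct`).
#'
#' @slot fields named list of numeric per-node vectors.
#' @slot gradients named list of n x 3 matrices (one per field).
#' @slot degenerate named list of logical per-node vectors.
#' @slot chamber list with integer node-index vectors `la` and `ra`.
#' @slot mode character: "biatrial", "la_only" or "ra_only".
#' @exportClass DistanceFieldSet
setClass("DistanceFieldSet", representation(
  fields = "list",
  gradients = "list",
  degenerate = "list",
  chamber = "list",
  mode = "character"
))

setValidity("DistanceFieldSet", function(object) {
  if (!identical(sort(names(object@fields)), sort(names(object@gradients)))) {
    return("fields and gradients must carry the same names")
  }
  TRUE
})

#' Per-node bundle assignment
#'
#' Output of the rule engine: one anatomical bundle label per node plus the
#' selected (gamma, k, alpha_endo, alpha_epi, flip) tuple that the frame
#' construction consumes. `kEndo`/`kEpi` name the distance field whose
#' gradient supplies the normal direction on each transmural layer (equal
#' for all bundles except the layer-conditional ones).
#'
#' @slot label factor, one bundle name per node.
#' @slot gammaField character per node (field name for the transmural gamma).
#' @slot kEndo,kEpi character per node (field names for the normal k).
#' @slot alphaEndo,alphaEpi numeric per node, degrees.
#' @slot flip logical per node (longitudinal/transmural flip bundles).
#' @slot layer factor per node: "endo" or "epi".
#' @exportClass BundleAssignment
setClass("BundleAssignment", representation(
  label = "factor",
  gammaField = "character",
  kEndo = "character",
  kEpi = "character",
  alphaEndo = "numeric",
  alphaEpi = "numeric",
  flip = "logical",
  layer = "factor"
))

setValidity("BundleAssignment", function(object) {
  n <- length(object@label)
  lens <- c(length(object@gammaField), length(object@kEndo), length(object@kEpi),
            length(object@alphaEndo), length(object@alphaEpi),
            length(object@flip), length(object@layer))
  if (any(lens != n)) return("all per-node slots must have equal length")
  if (anyNA(object@label)) return("unlabeled nodes present")
  TRUE
})

#' Fiber triad field
#'
#' Per-node orthonormal right-handed triad: fiber `f`, sheet `s` and
#' sheet-normal `n` directions, with the local frame it was rotated from.
#'
#' @slot f,s,n numeric n x 3 matrices of unit vectors.
#' @slot el,en,et numeric n x 3 matrices: the (possibly flipped) local frame.
#' @slot bundle factor per node.
#' @slot layer factor per node ("endo"/"epi").
#' @slot degenerate logical per node (frame unavailable before repair).
#' @exportClass FiberField
setClass("FiberField", representation(
  f = "matrix", s = "matrix", n = "matrix",
  el = "matrix", en = "matrix", et = "matrix",
  bundle = "factor", layer = "factor", degenerate = "logical"
))

setValidity("FiberField", function(object) {
  nn <- nrow(object@f)
  if (nrow(object@s) != nn || nrow(object@n) != nn) {
    return("f, s, n must have equal row counts")
  }
  ok <- !object@degenerate
  if (any(ok)) {
    err <- abs(rowNorm(object@f[ok, , drop = FALSE]) - 1)
    if (max(err) > 1e-6) return("non-unit fiber vectors at non-degenerate nodes")
  }
  TRUE
})

#' Activation map
#'
#' Per-node activation time (seconds) from the eikonal-diffusion solve.
#' Unreached nodes (disconnected from the stimulus) carry `Inf`.
#'
#' @slot times numeric per-node activation times, seconds.
#' @slot stimulusNodes integer vector of clamped (t = 0) nodes.
#' @slot iterations integer, pseudo-time steps used.
#' @slot converged logical.
#' @exportClass ActivationMap
setClass("ActivationMap", representation(
  times = "numeric",
  stimulusNodes = "integer",
  iterations = "integer",
  converged = "logical"
))

setValidity("ActivationMap", function(object) {
  fin <- object@times[is.finite(object@times)]
  if (length(fin) && min(fin) < 0) return("negative activation times")
  if (length(object@stimulusNodes) &&
      any(object@times[object@stimulusNodes] != 0)) {
    return("stimulus nodes must have zero activation time")
  }
  TRUE
})
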
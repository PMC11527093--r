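# Constructors and label validation for labeled tetrahedral meshes.

REQUIRED_TAGS <- list(
  biatrial = c("la_endo", "la_endo_sept", "la_endo_lat",
               "ra_endo", "ra_endo_ant", "ra_endo_post",
               "epi", "epi_top_la", "epi_top_lp", "epi_top_ra",
               "lspv", "lipv", "rspv", "ripv", "scv", "icv",
               "mv_ant", "mv_post", "tv_ant", "tv_post", "tv_sept", "tv_lat"),
  la_only = c("la_endo", "la_endo_sept", "la_endo_lat",
              "epi", "epi_top_la", "epi_top_lp",
              "lspv", "lipv", "rspv", "ripv", "mv_ant", "mv_post"),
  ra_only = c("ra_endo", "ra_endo_ant", "ra_endo_post",
              "epi", "epi_top_ra",
              "scv", "icv", "tv_ant", "tv_post", "tv_sept", "tv_lat")
)

REQUIRED_LANDMARKS <- list(
  biatrial = c("laa_apex", "raa_apex", "fo_centre", "csm_apex"),
  la_only = c("laa_apex", "fo_centre"),
  ra_only = c("raa_apex", "csm_apex")
)

#' Construct a TetMesh
#'
#' Orients all tets positively and derives the boundary triangulation.
#'
#' @param nodes numeric n x 3 matrix of coordinates (metres).
#' @param tets integer m x 4 matrix of node indices (1-based).
#' @return a [TetMesh-class]
#' @export
newTetMesh <- function(nodes, tets) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  tets <- orientTets(nodes, tets)
  new("TetMesh", nodes = nodes, tets = tets,
      boundaryTris = extractBoundary(tets))
}

#' Construct a LabeledTetMesh
#'
#' @param mesh a [TetMesh-class] (or nodes to pass to [newTetMesh()]).
#' @param tags named list of integer boundary-triangle index vectors.
#' @param landmarks named integer vector of node indices.
#' @param nodeFields named list of per-node fields.
#' @return a [LabeledTetMesh-class]
#' @export
newLabeledTetMesh <- function(mesh, tags = list(), landmarks = integer(),
                              nodeFields = list()) {
  stopifnot(is(mesh, "TetMesh"))
  tags <- lapply(tags, function(v) sort(unique(as.integer(v))))
  new("LabeledTetMesh", nodes = mesh@nodes, tets = mesh@tets,
      boundaryTris = mesh@boundaryTris, tags = tags,
      landmarks = vapply(landmarks, as.integer, integer(1)),
      nodeFields = nodeFields)
}

#' Set or replace a node field
#' @param mesh a [LabeledTetMesh-class]
#' @param name field name
#' @param value per-node vector or n x 3 matrix
#' @return the modified mesh
#' @export
setNodeField <- function(mesh, name, value) {
  mesh@nodeFields[[name]] <- value
  validObject(mesh)
  mesh
}

#' Validate boundary labels
#'
#' Checks that all tags required by the given mode are present and
#' non-empty, that tagged triangles are boundary triangles, and reports the
#' boundary area fraction not covered by any tag. Report-only: never throws.
#'
#' @param mesh a [LabeledTetMesh-class]
#' @param mode `"biatrial"`, `"la_only"` or `"ra_only"`.
#' @return a list with `ok` (logical), `missing` (absent/empty required
#'   tags), `missingLandmarks`, `uncoveredFraction` (of boundary area), and
#'   `messages`.
#' @export
validateLabels <- function(mesh, mode = c("biatrial", "la_only", "ra_only")) {
  mode <- match.arg(mode)
  req <- REQUIRED_TAGS[[mode]]
  reqLm <- REQUIRED_LANDMARKS[[mode]]
  msgs <- character()
  present <- vapply(req, function(t) {
    t %in% names(mesh@tags) && length(mesh@tags[[t]]) > 0
  }, logical(1))
  missing <- req[!present]
  for (t in missing) {
    msgs <- c(msgs, sprintf("tag '%s' %s", t,
                            if (t %in% names(mesh@tags)) "empty" else "missing"))
  }
  missingLm <- setdiff(reqLm, names(mesh@landmarks))
  for (t in missingLm) msgs <- c(msgs, sprintf("landmark '%s' missing", t))

  b <- nrow(mesh@boundaryTris)
  covered <- rep(FALSE, b)
  for (t in names(mesh@tags)) covered[mesh@tags[[t]]] <- TRUE
  # area-weighted uncovered fraction
  tri <- mesh@boundaryTris
  e1 <- mesh@nodes[tri[, 2], , drop = FALSE] - mesh@nodes[tri[, 1], , drop = FALSE]
  e2 <- mesh@nodes[tri[, 3], , drop = FALSE] - mesh@nodes[tri[, 1], , drop = FALSE]
  area <- rowNorm(rowCross(e1, e2)) / 2
  uncov <- if (sum(area) > 0) sum(area[!covered]) / sum(area) else 0
  if (uncov > 0) {
    msgs <- c(msgs, sprintf("%.2f%% of boundary area untagged", 100 * uncov))
  }
  list(ok = length(missing) == 0 && length(missingLm) == 0 && uncov == 0,
       missing = missing, missingLandmarks = missingLm,
       uncoveredFraction = uncov, messages = msgs)
}

#' Project a vector field from a point cloud onto mesh nodes
#'
#' Transfers per-point vectors (e.g. externally measured fibers) onto the
#' mesh: if the source coordinates coincide with the mesh nodes the field is
#' copied exactly; otherwise each node receives the vector of its nearest
#' source point. Nonzero vectors are renormalized to unit length.
#'
#' @param sourcePoints numeric p x 3 matrix of source coordinates.
#' @param sourceVectors numeric p x 3 matrix of vectors.
#' @param mesh a [TetMesh-class]
#' @return an n x 3 matrix of unit (or zero) vectors
#' @export
projectField <- function(sourcePoints, sourceVectors, mesh) {
  sourcePoints <- as.matrix(sourcePoints)
  sourceVectors <- as.matrix(sourceVectors)
  if (nrow(sourcePoints) == 0) stop("empty source cloud")
  stopifnot(nrow(sourcePoints) == nrow(sourceVectors))
  nodes <- mesh@nodes
  if (nrow(sourcePoints) == nrow(nodes) &&
      isTRUE(all.equal(sourcePoints, nodes, check.attributes = FALSE,
                       tolerance = 1e-12))) {
    out <- sourceVectors
  } else {
    idx <- nearestPointIndex(nodes, sourcePoints)
    out <- sourceVectors[idx, , drop = FALSE]
  }
  nrm <- rowNorm(out)
  renorm <- nrm > 0 & abs(nrm - 1) > 1e-12   # already-unit input passes through
  out[renorm, ] <- out[renorm, , drop = FALSE] / nrm[renorm]
  out
}
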
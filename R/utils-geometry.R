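# Low-level tetrahedral mesh primitives shared by the solver and the
# synthetic geometry generators. All node/element indices are 1-based.

#' Signed volumes of tetrahedra
#'
#' @param nodes numeric matrix (n x 3) of node coordinates.
#' @param tets integer matrix (m x 4) of node indices.
#' @return numeric vector of signed volumes (positive for right-handed tets).
#' @keywords internal
tetSignedVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  # det[e1; e2; e3] / 6 via scalar triple product
  cx <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  cy <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  cz <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  (e1[, 1] * cx + e1[, 2] * cy + e1[, 3] * cz) / 6
}

#' Reorient tetrahedra to positive signed volume
#' @keywords internal
orientTets <- function(nodes, tets) {
  v <- tetSignedVolumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3]
    tets[neg, 3] <- tets[neg, 4]
    tets[neg, 4] <- tmp
  }
  tets
}

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowNorm <- function(a) sqrt(rowSums(a * a))

rowUnit <- function(a) {
  n <- rowNorm(a)
  n[n == 0] <- 1
  a / n
}

#' Barycentric shape-function gradients per tetrahedron
#'
#' Returns the P1 basis gradients: a list of four (m x 3) matrices,
#' `grads[[i]]` holding the gradient of the basis function of local node i
#' in every tet, plus the positive volumes.
#' @keywords internal
tetShapeGradients <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  e1 <- nodes[tets[, 2], , drop = FALSE] - a
  e2 <- nodes[tets[, 3], , drop = FALSE] - a
  e3 <- nodes[tets[, 4], , drop = FALSE] - a
  c23 <- rowCross(e2, e3)
  v6 <- e1[, 1] * c23[, 1] + e1[, 2] * c23[, 2] + e1[, 3] * c23[, 3]
  if (any(v6 <= 0)) {
    stop("degenerate or negatively oriented tetrahedra present")
  }
  g2 <- c23 / v6
  g3 <- rowCross(e3, e1) / v6
  g4 <- rowCross(e1, e2) / v6
  g1 <- -(g2 + g3 + g4)
  list(grads = list(g1, g2, g3, g4), volume = v6 / 6)
}

# Canonical (sorted) face key for a triangle given as 3 index columns.
faceKeys <- function(f) {
  s <- t(apply(f, 1L, sort.int, method = "radix"))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

#' Extract boundary triangles of a tet mesh
#'
#' The boundary is the set of faces incident to exactly one tetrahedron.
#' Triangles are returned outward-oriented (assuming positively oriented
#' tets).
#' @keywords internal
extractBoundary <- function(tets) {
  m <- nrow(tets)
  # outward-oriented faces of a positively oriented tet (1,2,3,4)
  f1 <- tets[, c(2, 3, 4), drop = FALSE]
  f2 <- tets[, c(1, 4, 3), drop = FALSE]
  f3 <- tets[, c(1, 2, 4), drop = FALSE]
  f4 <- tets[, c(1, 3, 2), drop = FALSE]
  faces <- rbind(f1, f2, f3, f4)
  keys <- faceKeys(faces)
  cnt <- table(keys)
  solo <- names(cnt)[cnt == 1L]
  faces[keys %in% solo, , drop = FALSE]
}

#' Count how many tets share each interior face (watertightness check)
#' @keywords internal
faceIncidenceCounts <- function(tets) {
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  table(faceKeys(faces))
}

#' Node-to-node edges of a tet mesh (undirected, unique)
#' @keywords internal
meshEdges <- function(tets) {
  pairs <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  lo <- pmin(pairs[, 1], pairs[, 2])
  hi <- pmax(pairs[, 1], pairs[, 2])
  keep <- !duplicated(lo * (max(hi) + 1) + hi)
  cbind(lo[keep], hi[keep])
}

#' Connected components of the node graph
#'
#' Plain union-find on mesh edges; returns an integer component id per node.
#' @keywords internal
nodeComponents <- function(nNodes, tets) {
  parent <- seq_len(nNodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- meshEdges(tets)
  for (i in seq_len(nrow(e))) {
    ra <- find(e[i, 1]); rb <- find(e[i, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(nNodes), find, integer(1))
  match(roots, unique(roots))
}

#' Breadth-first value fill over mesh edges
#'
#' Extends `values` (NA where undefined) to all nodes by repeatedly copying
#' from the lowest-index defined neighbour. Deterministic. Used to extend
#' chamber-restricted fields across the whole mesh and to repair degenerate
#' frames.
#'
#' @param restrictTo optional logical vector; when given, a node may only
#'   copy from neighbours where `restrictTo` is TRUE (e.g. same bundle).
#' @keywords internal
bfsFill <- function(values, tets, restrictTo = NULL) {
  n <- if (is.matrix(values)) nrow(values) else length(values)
  defined <- if (is.matrix(values)) !is.na(values[, 1]) else !is.na(values)
  if (all(defined)) return(values)
  e <- meshEdges(tets)
  # adjacency as sorted edge list used repeatedly
  adjFrom <- c(e[, 1], e[, 2])
  adjTo <- c(e[, 2], e[, 1])
  repeat {
    todo <- which(!defined)
    if (!length(todo)) break
    srcOK <- defined
    if (!is.null(restrictTo)) srcOK <- srcOK & restrictTo
    sel <- srcOK[adjFrom] & !defined[adjTo]
    if (!any(sel)) break  # unreachable remainder
    from <- adjFrom[sel]
    to <- adjTo[sel]
    ord <- order(to, from)   # lowest-index donor wins, deterministically
    from <- from[ord]; to <- to[ord]
    first <- !duplicated(to)
    from <- from[first]; to <- to[first]
    if (is.matrix(values)) values[to, ] <- values[from, , drop = FALSE]
    else values[to] <- values[from]
    defined[to] <- TRUE
  }
  values
}

#' Nearest-point index lookup (brute force, chunked)
#' @keywords internal
nearestPointIndex <- function(query, ref) {
  nq <- nrow(query)
  out <- integer(nq)
  chunk <- max(1L, floor(2e7 / max(1L, nrow(ref))))
  for (s in seq(1L, nq, by = chunk)) {
    idx <- s:min(nq, s + chunk - 1L)
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), rowSums(ref^2), "+") -
      2 * query[idx, , drop = FALSE] %*% t(ref)
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}
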
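# P1 Galerkin solver for Laplace-Dirichlet problems on tetrahedral meshes,
# with volume-weighted gradient recovery. The harmonic solves are the
# workhorse of the whole method: every inter/intra-atrial "distance" is a
# solution of -div(grad chi) = 0 with piecewise-constant Dirichlet data on
# named boundary partitions and homogeneous Neumann elsewhere.

#' Assemble the P1 stiffness matrix
#'
#' @param mesh a [TetMesh-class]
#' @param tensor optional per-tet conductivity, an m x 6 matrix of symmetric
#'   tensor components (xx, yy, zz, xy, xz, yz); identity when NULL.
#' @return a sparse symmetric matrix (n x n)
#' @keywords internal
assembleStiffness <- function(mesh, tensor = NULL) {
  sg <- tetShapeGradients(mesh@nodes, mesh@tets)
  g <- sg$grads
  vol <- sg$volume
  m <- nrow(mesh@tets)
  n <- nrow(mesh@nodes)
  applyD <- function(gi) {
    if (is.null(tensor)) return(gi)
    cbind(tensor[, 1] * gi[, 1] + tensor[, 4] * gi[, 2] + tensor[, 5] * gi[, 3],
          tensor[, 4] * gi[, 1] + tensor[, 2] * gi[, 2] + tensor[, 6] * gi[, 3],
          tensor[, 5] * gi[, 1] + tensor[, 6] * gi[, 2] + tensor[, 3] * gi[, 3])
  }
  Dg <- lapply(g, applyD)
  ii <- jj <- integer(16L * m)
  xx <- numeric(16L * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- (k * m + 1L):((k + 1L) * m)
    ii[idx] <- mesh@tets[, a]
    jj[idx] <- mesh@tets[, b]
    xx[idx] <- vol * rowSums(g[[a]] * Dg[[b]])
    k <- k + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Solve a Laplace-Dirichlet problem
#'
#' P1 Galerkin solution of the harmonic problem: zero Laplacian in the
#' volume, fixed values on the listed Dirichlet node sets, natural
#' (zero-flux) conditions elsewhere. The sparse SPD reduced system is solved
#' by Cholesky factorization; the relative residual is verified to 1e-10.
#'
#' @param mesh a [TetMesh-class]
#' @param dirichlet list of `list(nodes = <integer vector>, value = <scalar>)`
#'   pairs. Node sets must be pairwise disjoint (first occurrence wins if a
#'   node appears twice with the same value; conflicting values are an
#'   error). At least two distinct values are required for a non-constant
#'   solution; a single value is permitted and returns the constant field.
#' @param subset optional integer vector of node indices: solve on the
#'   sub-mesh induced by tets whose four nodes all belong to `subset`
#'   (values outside are NA).
#' @return numeric per-node solution vector
#' @export
solveLaplace <- function(mesh, dirichlet, subset = NULL) {
  n <- nNodes(mesh)
  tets <- mesh@tets
  if (!is.null(subset)) {
    inSub <- rep(FALSE, n)
    inSub[subset] <- TRUE
    keep <- inSub[tets[, 1]] & inSub[tets[, 2]] & inSub[tets[, 3]] & inSub[tets[, 4]]
    tets <- tets[keep, , drop = FALSE]
    if (!nrow(tets)) stop("empty solve sub-domain")
  }
  subNodes <- sort(unique(as.vector(tets)))
  remap <- integer(n)
  remap[subNodes] <- seq_along(subNodes)
  subMesh <- new("TetMesh", nodes = mesh@nodes[subNodes, , drop = FALSE],
                 tets = matrix(remap[tets], ncol = 4),
                 boundaryTris = matrix(integer(), 0, 3))
  ns <- length(subNodes)
  bcVal <- rep(NA_real_, ns)
  for (d in dirichlet) {
    idx <- remap[intersect(d$nodes, subNodes)]
    idx <- idx[idx > 0]
    clash <- idx[!is.na(bcVal[idx]) & bcVal[idx] != d$value]
    if (length(clash)) stop("conflicting Dirichlet values on shared nodes")
    bcVal[idx] <- d$value
  }
  fixed <- which(!is.na(bcVal))
  if (!length(fixed)) stop("no Dirichlet data inside the solve domain")
  # every connected component needs data
  comp <- nodeComponents(ns, subMesh@tets)
  if (!all(unique(comp) %in% unique(comp[fixed]))) {
    stop("a connected component carries no Dirichlet data (singular system)")
  }
  u <- numeric(ns)
  u[fixed] <- bcVal[fixed]
  free <- setdiff(seq_len(ns), fixed)
  if (length(free)) {
    K <- assembleStiffness(subMesh)
    Kff <- K[free, free, drop = FALSE]
    rhs <- -K[free, fixed, drop = FALSE] %*% u[fixed]
    sol <- Matrix::solve(Matrix::forceSymmetric(Kff), rhs)
    u[free] <- as.numeric(sol)
    res <- sqrt(sum((Kff %*% u[free] - rhs)^2))
    scale <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
    if (res / scale > 1e-10) {
      stop(sprintf("Laplace solve did not reach residual tolerance (%.2e)",
                   res / scale))
    }
  }
  out <- rep(NA_real_, n)
  out[subNodes] <- u
  out
}

#' Recover nodal gradients of a P1 field
#'
#' The per-tet constant gradient is averaged to nodes with tet-volume
#' weights. Nodes whose averaged gradient norm falls below
#' `1e-12 * range(field) / bboxDiagonal` are flagged degenerate.
#'
#' @param mesh a [TetMesh-class]
#' @param field numeric per-node vector (NA allowed outside a sub-domain;
#'   tets touching NA nodes are skipped).
#' @return list with `gradient` (n x 3 matrix, NA rows where undefined) and
#'   `degenerate` (logical per node).
#' @export
nodalGradient <- function(mesh, field) {
  n <- nNodes(mesh)
  tets <- mesh@tets
  ok <- !(is.na(field[tets[, 1]]) | is.na(field[tets[, 2]]) |
            is.na(field[tets[, 3]]) | is.na(field[tets[, 4]]))
  tets <- tets[ok, , drop = FALSE]
  grad <- matrix(NA_real_, n, 3)
  deg <- rep(TRUE, n)
  if (nrow(tets)) {
    sg <- tetShapeGradients(mesh@nodes, tets)
    gt <- sg$grads[[1]] * field[tets[, 1]] + sg$grads[[2]] * field[tets[, 2]] +
      sg$grads[[3]] * field[tets[, 3]] + sg$grads[[4]] * field[tets[, 4]]
    w <- sg$volume
    num <- matrix(0, n, 3)
    den <- numeric(n)
    for (a in 1:4) {
      idx <- tets[, a]
      num[, 1] <- num[, 1] + unname(tapplySum(gt[, 1] * w, idx, n))
      num[, 2] <- num[, 2] + unname(tapplySum(gt[, 2] * w, idx, n))
      num[, 3] <- num[, 3] + unname(tapplySum(gt[, 3] * w, idx, n))
      den <- den + unname(tapplySum(w, idx, n))
    }
    touched <- den > 0
    grad[touched, ] <- num[touched, , drop = FALSE] / den[touched]
    bbox <- sqrt(sum((apply(mesh@nodes, 2, max) - apply(mesh@nodes, 2, min))^2))
    rng <- diff(range(field, na.rm = TRUE))
    tolGrad <- 1e-12 * rng / max(bbox, .Machine$double.eps)
    deg[touched] <- rowNorm(grad[touched, , drop = FALSE]) <= tolGrad
  }
  list(gradient = grad, degenerate = deg)
}

# grouped sum helper (base R rowsum, kept tiny and fast)
tapplySum <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
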
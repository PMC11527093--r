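# Structured slab fixture: a box tetrahedralized by the 6-tet (Kuhn)
# subdivision of a regular hex grid. Deterministic; used for affine-exactness
# Laplace checks and planar-front conduction-velocity experiments.

# Kuhn subdivision of the unit cube around the main diagonal (c000 -> c111);
# identical in every cell, hence face-conformal across the grid.
KUHN_TETS <- matrix(c(
  1, 2, 4, 8,   # c000 c100 c110 c111
  1, 4, 3, 8,   # c000 c110 c010 c111
  1, 3, 7, 8,   # c000 c010 c011 c111
  1, 7, 5, 8,   # c000 c011 c001 c111
  1, 5, 6, 8,   # c000 c001 c101 c111
  1, 6, 2, 8    # c000 c101 c100 c111
), ncol = 4, byrow = TRUE)

# corner order: c000 c100 c010 c110 c001 c101 c011 c111 indexed as
# 1 + i + 2j + 4k -> local index below
cubeCornerOffsets <- function() {
  # (di, dj, dk) for local corners 1..8 used in KUHN_TETS:
  # 1=c000 2=c100 3=c010 4=c110 5=c001 6=c101 7=c011 8=c111
  matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  1, 1, 0,
           0, 0, 1,  1, 0, 1,  0, 1, 1,  1, 1, 1), ncol = 3, byrow = TRUE)
}

#' Tetrahedralize a structured grid
#'
#' @param nx,ny,nz numbers of cells per axis.
#' @param keepCell optional logical vector/array over cells (column-major in
#'   i, j, k) selecting which cells to keep; unreferenced nodes are dropped.
#' @param spacing cell size per axis (length 3).
#' @param origin lower corner (length 3).
#' @return list with `nodes`, `tets`, `cellOfTet` (grid cell index of each
#'   tet) and `nodeMap` (original structured index of each kept node).
#' @keywords internal
structuredTetGrid <- function(nx, ny, nz, spacing, origin = c(0, 0, 0),
                              keepCell = NULL) {
  nxp <- nx + 1L; nyp <- ny + 1L; nzp <- nz + 1L
  nodeId <- function(i, j, k) i + nxp * (j - 1L) + nxp * nyp * (k - 1L)
  ii <- rep(seq_len(nxp), times = nyp * nzp)
  jj <- rep(rep(seq_len(nyp), each = nxp), times = nzp)
  kk <- rep(seq_len(nzp), each = nxp * nyp)
  nodes <- cbind(origin[1] + (ii - 1) * spacing[1],
                 origin[2] + (jj - 1) * spacing[2],
                 origin[3] + (kk - 1) * spacing[3])
  ci <- rep(seq_len(nx), times = ny * nz)
  cj <- rep(rep(seq_len(ny), each = nx), times = nz)
  ck <- rep(seq_len(nz), each = nx * ny)
  if (!is.null(keepCell)) {
    keep <- as.logical(keepCell)
    ci <- ci[keep]; cj <- cj[keep]; ck <- ck[keep]
    cellIdx <- which(keep)
  } else {
    cellIdx <- seq_len(nx * ny * nz)
  }
  off <- cubeCornerOffsets()
  corners <- matrix(0L, length(ci), 8L)
  for (c8 in 1:8) {
    corners[, c8] <- nodeId(ci + off[c8, 1], cj + off[c8, 2], ck + off[c8, 3])
  }
  tets <- matrix(0L, 6L * length(ci), 4L)
  cellOfTet <- integer(6L * length(ci))
  for (t6 in 1:6) {
    rows <- seq.int(t6, by = 6L, length.out = length(ci))
    tets[rows, ] <- corners[, KUHN_TETS[t6, ], drop = FALSE]
    cellOfTet[rows] <- cellIdx
  }
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nxp * nyp * nzp)
  remap[used] <- seq_along(used)
  tets[] <- remap[tets]
  list(nodes = nodes[used, , drop = FALSE], tets = tets,
       cellOfTet = cellOfTet, nodeMap = used,
       dims = c(nx, ny, nz), spacing = spacing, origin = origin)
}

#' Labeled slab fixture
#'
#' Box of size `lx` x `ly` x `lz` metres with target edge length `h`
#' (cells = `round(l/h)` per axis, at least 1). Face tags: `dirichlet_a`
#' (x = 0), `dirichlet_b` (x = lx), `side_y0`, `side_y1`, `endo` (z = 0),
#' `epi` (z = lz) -- the z faces emulate a mono-chamber transmural pair.
#'
#' @param lx,ly,lz box dimensions (metres), positive.
#' @param h target edge length (metres), smaller than every dimension.
#' @return a [LabeledTetMesh-class]
#' @export
makeSlab <- function(lx, ly, lz, h) {
  if (any(c(lx, ly, lz) <= 0)) stop("degenerate slab dimensions")
  if (h <= 0 || h > min(lx, ly, lz)) stop("h must be positive and < min dimension")
  nx <- max(1L, as.integer(round(lx / h)))
  ny <- max(1L, as.integer(round(ly / h)))
  nz <- max(1L, as.integer(round(lz / h)))
  g <- structuredTetGrid(nx, ny, nz, spacing = c(lx / nx, ly / ny, lz / nz))
  mesh <- newTetMesh(g$nodes, g$tets)
  tris <- mesh@boundaryTris
  cen <- (mesh@nodes[tris[, 1], ] + mesh@nodes[tris[, 2], ] +
            mesh@nodes[tris[, 3], ]) / 3
  tol <- 1e-9 * max(lx, ly, lz)
  tags <- list(
    dirichlet_a = which(abs(cen[, 1]) < tol),
    dirichlet_b = which(abs(cen[, 1] - lx) < tol),
    side_y0 = which(abs(cen[, 2]) < tol),
    side_y1 = which(abs(cen[, 2] - ly) < tol),
    endo = which(abs(cen[, 3]) < tol),
    epi = which(abs(cen[, 3] - lz) < tol)
  )
  newLabeledTetMesh(mesh, tags = tags)
}
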
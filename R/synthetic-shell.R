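# Idealized mono-atrial chamber: a hollow spherical shell built by radial
# extrusion of a subdivided icosahedron (nodes lie exactly on spheres, so
# harmonic closed-form oracles apply), with circular orifices cut for the
# valve and vein rings, endocardial bands, epicardial top bands and a
# landmark node.

icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- matrix(c(
    -1,  t,  0,   1,  t,  0,  -1, -t,  0,   1, -t,  0,
     0, -1,  t,   0,  1,  t,   0, -1, -t,   0,  1, -t,
     t,  0, -1,   t,  0,  1,  -t,  0, -1,  -t,  0,  1
  ), ncol = 3, byrow = TRUE)
  v <- v / sqrt(1 + t^2)
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,  1, 2, 8,  1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3,  11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,  4, 3, 7,  4, 7, 9,  4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,  10, 9, 2
  ), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

#' Unit icosphere by midpoint subdivision
#' @param level number of 4-way subdivisions (0 = icosahedron)
#' @keywords internal
icosphere <- function(level) {
  s <- icosahedron()
  for (l in seq_len(level)) {
    v <- s$vertices
    f <- s$faces
    edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(hash = TRUE)
    verts <- v
    getMid <- function(a, b) {
      k <- edgeKey(a, b)
      id <- mids[[k]]
      if (is.null(id)) {
        p <- (verts[a, ] + verts[b, ])
        p <- p / sqrt(sum(p^2))
        verts <<- rbind(verts, p)
        id <- nrow(verts)
        mids[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, c_); ca <- getMid(c_, a)
      nf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    s <- list(vertices = verts, faces = nf)
  }
  s
}

# Split one triangular prism (bottom a,b,c; top a+off,b+off,c+off given as
# explicit indices) into 3 tets with the smallest-global-index diagonal rule,
# which is face-consistent across neighbouring prisms.
prismToTets <- function(bot, top) {
  # rotate so the smallest of the six indices sits at position 1 (bottom)
  six <- c(bot, top)
  w <- which.min(six)
  if (w > 3) { tmp <- bot; bot <- top; top <- tmp; w <- w - 3L }
  rot <- switch(w, 1:3, c(2L, 3L, 1L), c(3L, 1L, 2L))
  b <- bot[rot]; t <- top[rot]
  # quad face (b2, b3, t3, t2): diagonal through its smallest vertex
  if (min(b[2], t[3]) < min(b[3], t[2])) {
    rbind(c(b[1], b[2], b[3], t[3]),
          c(b[1], b[2], t[3], t[2]),
          c(b[1], t[2], t[3], t[1]))
  } else {
    rbind(c(b[1], b[2], b[3], t[2]),
          c(b[1], t[2], b[3], t[3]),
          c(b[1], t[2], t[3], t[1]))
  }
}

# angular distance (radians) between unit vectors
angDist <- function(u, v) acos(pmin(1, pmax(-1, u %*% v)))

# angular distance from unit rows `p` to the great-circle arc d1->d2
arcDistance <- function(p, d1, d2) {
  n <- c(d1[2] * d2[3] - d1[3] * d2[2],
         d1[3] * d2[1] - d1[1] * d2[3],
         d1[1] * d2[2] - d1[2] * d2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) return(as.vector(apply(p, 1, function(u) angDist(u, d1))))
  n <- n / nn
  s <- as.vector(p %*% n)
  # foot of the great-circle projection
  foot <- p - outer(s, n)
  fn <- rowNorm(foot)
  fn[fn == 0] <- 1
  foot <- foot / fn
  # inside the arc? (foot between d1 and d2)
  a12 <- acos(pmin(1, pmax(-1, sum(d1 * d2))))
  a1 <- acos(pmin(1, pmax(-1, as.vector(foot %*% d1))))
  a2 <- acos(pmin(1, pmax(-1, as.vector(foot %*% d2))))
  inside <- abs(a1 + a2 - a12) < 1e-6
  d <- abs(asin(pmin(1, pmax(-1, s))))
  dEnds <- pmin(acos(pmin(1, pmax(-1, as.vector(p %*% d1)))),
                acos(pmin(1, pmax(-1, as.vector(p %*% d2)))))
  ifelse(inside, d, dEnds)
}

unit3 <- function(v) v / sqrt(sum(v^2))

# default orifice layouts (direction vectors are from the chamber centre;
# x points from LA toward RA, y anterior, z superior)
laOrificeSpec <- function() {
  list(
    list(tag = "mv",   dir = unit3(c(0, 0.15, -1)),          radius = 35 * pi / 180),
    list(tag = "lspv", dir = unit3(c(-0.65, -0.60, 0.55)),   radius = 16 * pi / 180),
    list(tag = "lipv", dir = unit3(c(-0.65, -0.60, -0.40)),  radius = 16 * pi / 180),
    list(tag = "rspv", dir = unit3(c(0.45, -0.78, 0.55)),    radius = 16 * pi / 180),
    list(tag = "ripv", dir = unit3(c(0.45, -0.78, -0.40)),   radius = 16 * pi / 180)
  )
}

raOrificeSpec <- function() {
  list(
    list(tag = "tv",  dir = unit3(c(0, 0.80, -0.55)),        radius = 35 * pi / 180),
    list(tag = "scv", dir = unit3(c(0.40, -0.25, 0.88)),     radius = 16 * pi / 180),
    list(tag = "icv", dir = unit3(c(0.40, -0.25, -0.88)),    radius = 16 * pi / 180)
  )
}

#' Idealized hollow-shell atrial chamber fixture
#'
#' A spherical shell (inner radius `rEndo`, outer `rEpi`) with circular
#' orifices cut through the wall. Exposed cut faces are tagged as the
#' orifice's ring; the inner surface is tagged endocardium with septal/
#' lateral (LA) or anterior/posterior (RA) bands; the outer surface is
#' epicardium with top bands between the stated vein pairs. One landmark
#' node per chamber rule (LAA + FO for LA; RAA + CSM for RA).
#'
#' @param chamber `"la"` or `"ra"`.
#' @param rEndo,rEpi shell radii (metres), `rEndo < rEpi`.
#' @param orificeSpec list of `list(tag, dir, radius)` entries (radians of
#'   angular radius); defaults to the chamber's canonical set. The `mv`
#'   (`tv`) tag is automatically split into its anterior/posterior
#'   (quadrant) ring sectors.
#' @param level icosphere subdivision level (angular resolution).
#' @param nLayers radial layers across the wall.
#' @param centre chamber centre (metres).
#' @return a [LabeledTetMesh-class]
#' @export
makeAtrialShell <- function(chamber = c("la", "ra"), rEndo = 0.012,
                            rEpi = 0.018, orificeSpec = NULL, level = 3,
                            nLayers = 3, centre = c(0, 0, 0)) {
  chamber <- match.arg(chamber)
  if (rEndo >= rEpi) stop("rEndo must be smaller than rEpi")
  if (is.null(orificeSpec)) {
    orificeSpec <- if (chamber == "la") laOrificeSpec() else raOrificeSpec()
  }
  for (o in orificeSpec) {
    if (o$radius <= 0) stop(sprintf("orifice '%s' has non-positive angular radius", o$tag))
  }
  # pairwise non-overlap
  if (length(orificeSpec) > 1) {
    for (i in seq_along(orificeSpec)) for (j in seq_len(i - 1L)) {
      sep <- angDist(orificeSpec[[i]]$dir, orificeSpec[[j]]$dir)
      if (sep < orificeSpec[[i]]$radius + orificeSpec[[j]]$radius) {
        stop(sprintf("orifices '%s' and '%s' overlap",
                     orificeSpec[[i]]$tag, orificeSpec[[j]]$tag))
      }
    }
  }
  ico <- icosphere(level)
  nv <- nrow(ico$vertices)
  radii <- seq(rEndo, rEpi, length.out = nLayers + 1L)
  nodes <- do.call(rbind, lapply(radii, function(r)
    sweep(ico$vertices * r, 2, centre, "+")))
  # drop surface triangles inside any orifice cone (cut through all layers)
  cen <- (ico$vertices[ico$faces[, 1], ] + ico$vertices[ico$faces[, 2], ] +
            ico$vertices[ico$faces[, 3], ]) / 3
  cen <- rowUnit(cen)
  keep <- rep(TRUE, nrow(ico$faces))
  for (o in orificeSpec) {
    keep <- keep & (acos(pmin(1, pmax(-1, as.vector(cen %*% o$dir)))) > o$radius)
  }
  faces <- ico$faces[keep, , drop = FALSE]
  if (!nrow(faces)) stop("orifices removed the whole shell")
  tets <- vector("list", nrow(faces) * nLayers)
  idx <- 0L
  for (l in seq_len(nLayers)) {
    off0 <- (l - 1L) * nv
    off1 <- l * nv
    for (fi in seq_len(nrow(faces))) {
      idx <- idx + 1L
      tets[[idx]] <- prismToTets(faces[fi, ] + off0, faces[fi, ] + off1)
    }
  }
  allTets <- do.call(rbind, tets)
  # drop nodes orphaned by the orifice cuts
  used <- sort(unique(as.vector(allTets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  mesh0 <- newTetMesh(nodes[used, , drop = FALSE],
                      matrix(remap[allTets], ncol = 4))
  # classify boundary triangles by vertex radii
  tris <- mesh0@boundaryTris
  rad <- sqrt(rowSums(sweep(mesh0@nodes, 2, centre, "-")^2))
  rtol <- 1e-9 * rEpi
  onInner <- matrix(abs(rad[tris] - rEndo) < rtol, ncol = 3)
  onOuter <- matrix(abs(rad[tris] - rEpi) < rtol, ncol = 3)
  innerTri <- which(rowSums(onInner) == 3L)
  outerTri <- which(rowSums(onOuter) == 3L)
  rimTri <- setdiff(seq_len(nrow(tris)), c(innerTri, outerTri))
  triDir <- rowUnit(sweep((mesh0@nodes[tris[, 1], ] + mesh0@nodes[tris[, 2], ] +
                             mesh0@nodes[tris[, 3], ]) / 3, 2, centre, "-"))
  tags <- list()
  addTag <- function(tags, name, ids) {
    if (length(ids)) tags[[name]] <- sort(unique(c(tags[[name]], ids)))
    tags
  }
  # rim triangles -> nearest orifice, then split valve rings into sectors
  if (length(rimTri)) {
    dmat <- vapply(orificeSpec, function(o) {
      acos(pmin(1, pmax(-1, as.vector(triDir[rimTri, , drop = FALSE] %*% o$dir))))
    }, numeric(length(rimTri)))
    dmat <- matrix(dmat, nrow = length(rimTri))
    owner <- max.col(-dmat, ties.method = "first")
    for (oi in seq_along(orificeSpec)) {
      o <- orificeSpec[[oi]]
      ids <- rimTri[owner == oi]
      if (!length(ids)) next
      if (o$tag == "mv") {
        # anterior = positive y residual w.r.t. the orifice axis
        resid <- triDir[ids, , drop = FALSE] -
          outer(as.vector(triDir[ids, , drop = FALSE] %*% o$dir), o$dir)
        ant <- resid[, 2] >= 0
        tags <- addTag(tags, "mv_ant", ids[ant])
        tags <- addTag(tags, "mv_post", ids[!ant])
      } else if (o$tag == "tv") {
        resid <- triDir[ids, , drop = FALSE] -
          outer(as.vector(triDir[ids, , drop = FALSE] %*% o$dir), o$dir)
        # quadrants in the ring plane: septal (-x), lateral (+x),
        # anterior (+y), posterior (-y)
        sect <- ifelse(abs(resid[, 1]) >= abs(resid[, 2]),
                       ifelse(resid[, 1] < 0, "tv_sept", "tv_lat"),
                       ifelse(resid[, 2] >= 0, "tv_ant", "tv_post"))
        for (s in unique(sect)) tags <- addTag(tags, s, ids[sect == s])
      } else {
        tags <- addTag(tags, o$tag, ids)
      }
    }
  }
  # endocardial bands
  bandAng <- 35 * pi / 180
  dirIn <- triDir[innerTri, , drop = FALSE]
  if (chamber == "la") {
    sept <- acos(pmin(1, pmax(-1, dirIn[, 1]))) < bandAng          # toward +x (RA side)
    lat <- acos(pmin(1, pmax(-1, -dirIn[, 1]))) < bandAng          # toward -x
    tags <- addTag(tags, "la_endo_sept", innerTri[sept])
    tags <- addTag(tags, "la_endo_lat", innerTri[lat])
    tags <- addTag(tags, "la_endo", innerTri[!sept & !lat])
  } else {
    ant <- acos(pmin(1, pmax(-1, dirIn[, 2]))) < bandAng           # toward +y
    post <- acos(pmin(1, pmax(-1, -dirIn[, 2]))) < bandAng
    tags <- addTag(tags, "ra_endo_ant", innerTri[ant])
    tags <- addTag(tags, "ra_endo_post", innerTri[post])
    tags <- addTag(tags, "ra_endo", innerTri[!ant & !post])
  }
  # epicardial top bands between vein pairs
  bandHalf <- 8 * pi / 180
  dirOut <- triDir[outerTri, , drop = FALSE]
  specByTag <- stats::setNames(orificeSpec, vapply(orificeSpec, `[[`, "", "tag"))
  inBand <- function(t1, t2) {
    if (!(t1 %in% names(specByTag)) || !(t2 %in% names(specByTag))) {
      return(rep(FALSE, nrow(dirOut)))
    }
    arcDistance(dirOut, specByTag[[t1]]$dir, specByTag[[t2]]$dir) < bandHalf
  }
  if (chamber == "la") {
    topLa <- inBand("lspv", "rspv")
    topLp <- inBand("lipv", "ripv")
    tags <- addTag(tags, "epi_top_la", outerTri[topLa & !topLp])
    tags <- addTag(tags, "epi_top_lp", outerTri[topLp & !topLa])
    tags <- addTag(tags, "epi", outerTri[!topLa & !topLp])
  } else {
    topRa <- inBand("scv", "icv")
    tags <- addTag(tags, "epi_top_ra", outerTri[topRa])
    tags <- addTag(tags, "epi", outerTri[!topRa])
  }
  # landmarks: epi node nearest the stated direction; FO on the septal endo
  landmarkNode <- function(dir, r) {
    target <- centre + r * dir
    nearestPointIndex(matrix(target, 1), mesh0@nodes)
  }
  landmarks <- if (chamber == "la") {
    c(laa_apex = landmarkNode(unit3(c(-0.25, 0.92, 0.30)), rEpi),
      fo_centre = landmarkNode(unit3(c(1, 0, 0)), rEndo))
  } else {
    c(raa_apex = landmarkNode(unit3(c(0.35, 0.85, 0.35)), rEpi),
      csm_apex = landmarkNode(unit3(c(-0.45, -0.55, -0.70)), rEpi))
  }
  newLabeledTetMesh(mesh0, tags = tags, landmarks = landmarks)
}
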
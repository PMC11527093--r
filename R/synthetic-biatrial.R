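# Bridged two-shell bi-atrial toy: two hollow spherical chambers joined by
# a septal wall block, carved out of one structured Kuhn grid so the mesh is
# conformal and watertight by construction. Boundary tags are assigned from
# the *reason* the neighbouring grid cell is absent (cavity, orifice cone,
# or outside the wall), which makes the full 22-tag vocabulary available on
# a topologically faithful, if voxelized, geometry. Deterministic: no RNG.

#' Default parameters of the bi-atrial toy
#'
#' Geometry in metres. Chamber radii emulate adult atria (endocardial radius
#' 10 mm, wall capped by a 16 mm epicardial radius); the septal block
#' bridges the two chambers around the fossa ovalis.
#' @return named list of parameters accepted by [makeBiatrialToy()]
#' @export
biatrialToyParams <- function() {
  list(
    h = 2e-3,                      # grid cell size (m)
    laCentre = c(-0.021, 0, 0),
    raCentre = c(0.021, 0, 0),
    rEndo = 0.010,
    rEpi = 0.016,
    septHalfWidth = 0.0062,        # half width (y, z) of the septal block
    bandAngle = 35 * pi / 180,     # endocardial band half-angle
    topBandHalf = 10 * pi / 180    # epicardial top band half-width
  )
}

laToyOrifices <- function() laOrificeSpec()
raToyOrifices <- function() raOrificeSpec()

inCone <- function(rel, dir, radius) {
  r <- rowNorm(rel)
  r[r == 0] <- 1
  acos(pmin(1, pmax(-1, (rel %*% dir) / r))) < radius
}

#' Bridged bi-atrial toy fixture
#'
#' Two hollow-sphere chambers (LA with MV and four pulmonary vein orifices,
#' RA with TV quadrants and both caval veins) joined by a septal wall block;
#' carries the complete bi-atrial tag set and the four landmark nodes
#' (LAA/RAA apices, FO centre, CSM apex). Deterministic for fixed
#' parameters.
#'
#' @param params parameter list, see [biatrialToyParams()]. Any subset may
#'   be overridden.
#' @param withSeptum keep the septal bridge (setting `FALSE` splits the
#'   mesh into two components; used for topology checks).
#' @return a [LabeledTetMesh-class]
#' @export
makeBiatrialToy <- function(params = list(), withSeptum = TRUE) {
  p <- utils::modifyList(biatrialToyParams(), params)
  h <- p$h
  if (p$rEpi - p$rEndo < 2 * h) stop("resolution too coarse to resolve the wall")
  pad <- 2 * h
  lo <- c(p$laCentre[1] - p$rEpi - pad, -p$rEpi - pad, -p$rEpi - pad)
  hi <- c(p$raCentre[1] + p$rEpi + pad, p$rEpi + pad, p$rEpi + pad)
  nx <- ceiling((hi[1] - lo[1]) / h)
  ny <- ceiling((hi[2] - lo[2]) / h)
  nz <- ceiling((hi[3] - lo[3]) / h)
  # cell centres
  cx <- lo[1] + (seq_len(nx) - 0.5) * h
  cy <- lo[2] + (seq_len(ny) - 0.5) * h
  cz <- lo[3] + (seq_len(nz) - 0.5) * h
  cc <- cbind(rep(cx, times = ny * nz),
              rep(rep(cy, each = nx), times = nz),
              rep(cz, each = nx * ny))
  laOri <- laToyOrifices()
  raOri <- raToyOrifices()
  classifyCells <- function(cc) {
    relLa <- sweep(cc, 2, p$laCentre)
    relRa <- sweep(cc, 2, p$raCentre)
    rLa <- rowNorm(relLa)
    rRa <- rowNorm(relRa)
    laCone <- rep(FALSE, nrow(cc))
    for (o in laOri) laCone <- laCone | inCone(relLa, o$dir, o$radius)
    raCone <- rep(FALSE, nrow(cc))
    for (o in raOri) raCone <- raCone | inCone(relRa, o$dir, o$radius)
    laWall <- rLa > p$rEndo & rLa < p$rEpi & !laCone
    raWall <- rRa > p$rEndo & rRa < p$rEpi & !raCone
    sept <- abs(cc[, 2]) < p$septHalfWidth & abs(cc[, 3]) < p$septHalfWidth &
      cc[, 1] > p$laCentre[1] & cc[, 1] < p$raCentre[1] &
      rLa > p$rEndo & rRa > p$rEndo & !laCone & !raCone
    keep <- laWall | raWall
    if (withSeptum) keep <- keep | sept
    list(keep = keep, rLa = rLa, rRa = rRa, relLa = relLa, relRa = relRa,
         laCone = laCone, raCone = raCone)
  }
  cls <- classifyCells(cc)
  if (!any(cls$keep)) stop("empty toy geometry")
  g <- structuredTetGrid(nx, ny, nz, spacing = c(h, h, h), origin = lo,
                         keepCell = cls$keep)
  mesh0 <- newTetMesh(g$nodes, g$tets)
  tris <- mesh0@boundaryTris
  cen <- (mesh0@nodes[tris[, 1], ] + mesh0@nodes[tris[, 2], ] +
            mesh0@nodes[tris[, 3], ]) / 3
  # outward normal of each boundary triangle -> the absent neighbour cell
  # centre sits half a cell along it
  e1 <- mesh0@nodes[tris[, 2], ] - mesh0@nodes[tris[, 1], ]
  e2 <- mesh0@nodes[tris[, 3], ] - mesh0@nodes[tris[, 1], ]
  nrm <- rowUnit(rowCross(e1, e2))
  # the absent neighbour cell: step half a cell outward, then snap to the
  # centre of the grid cube containing that point (classification must use
  # the same cell centres as the keep test)
  ghost <- cen + (h / 2) * round(nrm)
  ghost <- sweep((floor(sweep(ghost, 2, lo) / h) + 0.5) * h, 2, lo, "+")
  relLaG <- sweep(ghost, 2, p$laCentre)
  relRaG <- sweep(ghost, 2, p$raCentre)
  rLaG <- rowNorm(relLaG)
  rRaG <- rowNorm(relRaG)
  nT <- nrow(tris)
  tag <- character(nT)
  # 1) cavity neighbours -> endocardium
  laCav <- rLaG <= p$rEndo
  raCav <- rRaG <= p$rEndo
  tag[laCav] <- "la_endo"
  tag[raCav & tag == ""] <- "ra_endo"
  # 2) orifice cones within the wall annulus -> ring tags
  dirLaG <- relLaG / pmax(rLaG, 1e-30)
  dirRaG <- relRaG / pmax(rRaG, 1e-30)
  for (o in laOri) {
    sel <- tag == "" & rLaG < p$rEpi + h &
      acos(pmin(1, pmax(-1, as.vector(dirLaG %*% o$dir)))) < o$radius
    if (o$tag == "mv") {
      resid <- dirLaG[sel, , drop = FALSE] -
        outer(as.vector(dirLaG[sel, , drop = FALSE] %*% o$dir), o$dir)
      tag[sel] <- ifelse(resid[, 2] >= 0, "mv_ant", "mv_post")
    } else {
      tag[sel] <- o$tag
    }
  }
  for (o in raOri) {
    sel <- tag == "" & rRaG < p$rEpi + h &
      acos(pmin(1, pmax(-1, as.vector(dirRaG %*% o$dir)))) < o$radius
    if (o$tag == "tv") {
      resid <- dirRaG[sel, , drop = FALSE] -
        outer(as.vector(dirRaG[sel, , drop = FALSE] %*% o$dir), o$dir)
      tag[sel] <- ifelse(abs(resid[, 1]) >= abs(resid[, 2]),
                         ifelse(resid[, 1] < 0, "tv_sept", "tv_lat"),
                         ifelse(resid[, 2] >= 0, "tv_ant", "tv_post"))
    } else {
      tag[sel] <- o$tag
    }
  }
  # 3) remaining exposed faces -> epicardium (with top bands and endo bands)
  epi <- tag == ""
  onLa <- cen[, 1] < 0
  dirLaC <- rowUnit(sweep(cen, 2, p$laCentre))
  dirRaC <- rowUnit(sweep(cen, 2, p$raCentre))
  laSpecs <- stats::setNames(laOri, vapply(laOri, `[[`, "", "tag"))
  raSpecs <- stats::setNames(raOri, vapply(raOri, `[[`, "", "tag"))
  topLa <- epi & onLa &
    arcDistance(dirLaC, laSpecs$lspv$dir, laSpecs$rspv$dir) < p$topBandHalf
  topLp <- epi & onLa & !topLa &
    arcDistance(dirLaC, laSpecs$lipv$dir, laSpecs$ripv$dir) < p$topBandHalf
  topRa <- epi & !onLa &
    arcDistance(dirRaC, raSpecs$scv$dir, raSpecs$icv$dir) < p$topBandHalf
  tag[topLa] <- "epi_top_la"
  tag[topLp] <- "epi_top_lp"
  tag[topRa] <- "epi_top_ra"
  tag[tag == ""] <- "epi"
  # endocardial bands by direction from the chamber centre
  sel <- tag == "la_endo"
  bA <- p$bandAngle
  sept <- sel & acos(pmin(1, pmax(-1, dirLaC[, 1]))) < bA
  lat <- sel & acos(pmin(1, pmax(-1, -dirLaC[, 1]))) < bA
  tag[sept] <- "la_endo_sept"
  tag[lat] <- "la_endo_lat"
  sel <- tag == "ra_endo"
  ant <- sel & acos(pmin(1, pmax(-1, dirRaC[, 2]))) < bA
  post <- sel & acos(pmin(1, pmax(-1, -dirRaC[, 2]))) < bA
  tag[ant] <- "ra_endo_ant"
  tag[post] <- "ra_endo_post"
  tags <- split(seq_len(nT), tag)
  # landmarks: nearest node to anatomical target points
  lmTarget <- rbind(
    laa_apex = p$laCentre + p$rEpi * unit3(c(-0.25, 0.92, 0.30)),
    raa_apex = p$raCentre + p$rEpi * unit3(c(0.35, 0.85, 0.35)),
    fo_centre = c(0, 0, 0),
    csm_apex = p$raCentre + p$rEpi * unit3(c(-0.45, -0.55, -0.70))
  )
  lm <- stats::setNames(nearestPointIndex(lmTarget, mesh0@nodes),
                        rownames(lmTarget))
  newLabeledTetMesh(mesh0, tags = tags, landmarks = lm)
}
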
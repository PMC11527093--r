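# The harmonic distance catalog. Each row pairs named boundary tag sets
# with Dirichlet values; the inter-atrial fields (xi, phi) are solved on the
# full domain, the intra-atrial psi fields on the chamber sub-mesh
# ({xi > 0} for LA, {xi < 0} for RA, interface nodes assigned to both) and
# then extended across the whole mesh by breadth-first nearest-value fill so
# the inter-atrial-connection rules can read them anywhere.

laEndoTags <- c("la_endo", "la_endo_sept", "la_endo_lat")
raEndoTags <- c("ra_endo", "ra_endo_ant", "ra_endo_post")
mvTags <- c("mv_ant", "mv_post")
tvTags <- c("tv_ant", "tv_post", "tv_sept", "tv_lat")
lpvTags <- c("lspv", "lipv")
rpvTags <- c("rspv", "ripv")

# Dirichlet recipes for the intra-atrial psi fields; entries are
# list(value, tags, landmarks). Order matters: when a node falls in two
# sets, the first listed set keeps it (thin adjacent bands can share nodes).
psiCatalog <- function(chamber) {
  if (chamber == "la") list(
    psi_ab = list(list(2, rpvTags), list(0, lpvTags), list(1, mvTags),
                  list(-1, NULL, "laa_apex")),
    psi_v = list(list(1, rpvTags), list(0, lpvTags)),
    psi_r = list(list(1, mvTags),
                 list(0, c(lpvTags, rpvTags, "epi_top_la", "epi_top_lp"))),
    psi_w = list(list(1, c("rspv", "lspv", "mv_ant")),
                 list(-1, c("ripv", "lipv", "mv_post"))),
    psi_t = list(list(1, mvTags), list(0, c("epi_top_la", "epi_top_lp"))),
    psi_a = list(list(1, "la_endo_sept"), list(0, "la_endo_lat")),
    psi_aa = list(list(1, NULL, "fo_centre"), list(-2, NULL, "laa_apex")),
    psi_s = list(list(1, "mv_ant"),
                 list(0, c("epi_top_la", "la_endo_sept", "la_endo_lat")),
                 list(-0.5, "epi_top_lp"), list(-1, "mv_post"))
  ) else list(
    psi_ab = list(list(2, "icv"), list(0, "scv"), list(1, tvTags),
                  list(-2, NULL, c("raa_apex", "csm_apex"))),
    psi_v = list(list(1, "icv"), list(0, "scv")),
    psi_r = list(list(1, tvTags), list(0, c("icv", "scv", "epi_top_ra"))),
    psi_w = list(list(1, "tv_sept"), list(-1, "tv_lat"), list(0, "epi_top_ra")),
    psi_t = list(list(1, tvTags), list(0, "epi_top_ra")),
    psi_a = list(list(2, NULL, "raa_apex"),
                 list(1, c("ra_endo_ant", "scv")),
                 list(-1, c("ra_endo_post", "icv"))),
    psi_aa = list(list(-2, NULL, "raa_apex"),
                  list(1, c("icv", "ra_endo_post")), list(0, "scv")),
    psi_ct = list(list(1, c("tv_sept", "tv_ant", "tv_post")),
                  list(-1, "tv_lat"))
  )
}

# Turn a recipe into solveLaplace dirichlet pairs; earlier entries win on
# shared nodes.
recipeToDirichlet <- function(mesh, recipe) {
  taken <- integer()
  out <- list()
  for (entry in recipe) {
    value <- entry[[1]]
    tags <- entry[[2]]
    lms <- if (length(entry) >= 3) entry[[3]] else NULL
    nodes <- integer()
    for (t in tags) {
      if (!t %in% names(mesh@tags)) {
        stop(sprintf("required tag '%s' absent from mesh", t))
      }
      if (!length(mesh@tags[[t]])) {
        stop(sprintf("required tag '%s' is empty", t))
      }
      nodes <- c(nodes, tagNodes(mesh, t))
    }
    for (l in lms) {
      if (!l %in% names(mesh@landmarks)) {
        stop(sprintf("required landmark '%s' absent from mesh", l))
      }
      nodes <- c(nodes, mesh@landmarks[[l]])
    }
    nodes <- setdiff(unique(nodes), taken)
    taken <- c(taken, nodes)
    out[[length(out) + 1L]] <- list(nodes = nodes, value = value)
  }
  out
}

#' Compute the full harmonic distance-field catalog
#'
#' Solves, per chamber and mode, the whole set of inter- and intra-atrial
#' harmonic fields: the inter-atrial `xi` (+1 on the LA endocardium, -1 on
#' the RA endocardium), the transmural `phi` (+1 LA endo, -1 RA endo, 0
#' epicardium) with the derived per-chamber `phi_la = 1 - phi` and
#' `phi_ra = 1 + phi`, and the intra-atrial `psi_ab, psi_v, psi_r, psi_w,
#' psi_t, psi_a, psi_aa` plus `psi_s` (LA) and `psi_ct` (RA). Intra-atrial
#' fields are solved on the chamber sub-mesh and stored under
#' `la.<name>` / `ra.<name>`; nodal gradients accompany every field.
#'
#' @param mesh a [LabeledTetMesh-class] whose labels validate for `mode`.
#' @param mode `"biatrial"`, `"la_only"` or `"ra_only"`.
#' @return a [DistanceFieldSet-class]
#' @export
computeDistanceSet <- function(mesh, mode = c("biatrial", "la_only", "ra_only")) {
  mode <- match.arg(mode)
  rep <- validateLabels(mesh, mode)
  if (!rep$ok) {
    stop(sprintf("label validation failed: %s", paste(rep$messages, collapse = "; ")))
  }
  n <- nNodes(mesh)
  fields <- list()
  nodesOf <- function(tags) unique(unlist(lapply(tags, tagNodes, x = mesh)))
  if (mode == "biatrial") {
    laN <- nodesOf(laEndoTags)
    raN <- nodesOf(raEndoTags)
    fields$xi <- solveLaplace(mesh, list(list(nodes = laN, value = 1),
                                         list(nodes = raN, value = -1)))
    epiN <- setdiff(nodesOf(c("epi", "epi_top_la", "epi_top_lp", "epi_top_ra")),
                    c(laN, raN))
    fields$phi <- solveLaplace(mesh, list(list(nodes = laN, value = 1),
                                          list(nodes = raN, value = -1),
                                          list(nodes = epiN, value = 0)))
    fields$phi_la <- 1 - fields$phi
    fields$phi_ra <- 1 + fields$phi
    chamberLa <- which(fields$xi >= 0)
    chamberRa <- which(fields$xi <= 0)
  } else if (mode == "la_only") {
    laN <- nodesOf(laEndoTags)
    epiN <- setdiff(nodesOf(c("epi", "epi_top_la", "epi_top_lp")), laN)
    fields$phi <- solveLaplace(mesh, list(list(nodes = laN, value = 1),
                                          list(nodes = epiN, value = 0)))
    fields$xi <- rep(1, n)            # whole domain is LA
    fields$phi_la <- 1 - fields$phi
    chamberLa <- seq_len(n)
    chamberRa <- integer()
  } else {
    raN <- nodesOf(raEndoTags)
    epiN <- setdiff(nodesOf(c("epi", "epi_top_ra")), raN)
    fields$phi <- solveLaplace(mesh, list(list(nodes = raN, value = -1),
                                          list(nodes = epiN, value = 0)))
    fields$xi <- rep(-1, n)
    fields$phi_ra <- 1 + fields$phi
    chamberLa <- integer()
    chamberRa <- seq_len(n)
  }
  gradients <- list()
  degenerate <- list()
  # intra-atrial psi fields: solve on the chamber sub-mesh, take gradients
  # there, then extend field AND gradient across the mesh so the IC rules
  # (whose xi window spans both chambers) can read them anywhere
  doChamber <- function(chamber, subset) {
    if (!length(subset)) return()
    inSub <- rep(FALSE, n)
    inSub[subset] <- TRUE
    for (nm in names(psiCatalog(chamber))) {
      recipe <- psiCatalog(chamber)[[nm]]
      dir <- recipeToDirichlet(mesh, recipe)
      # landmark points sitting just across the chamber interface (xi = 0)
      # are snapped to the nearest node inside the chamber sub-mesh, so a
      # single-node Dirichlet set is never silently dropped by the solve
      dir <- lapply(dir, function(d) {
        if (length(d$nodes) && !any(inSub[d$nodes])) {
          d$nodes <- subset[nearestPointIndex(
            mesh@nodes[d$nodes, , drop = FALSE],
            mesh@nodes[subset, , drop = FALSE])]
        }
        d
      })
      u <- solveLaplace(mesh, dir, subset = subset)
      g <- nodalGradient(mesh, u)
      key <- paste(chamber, nm, sep = ".")
      fields[[key]] <<- bfsFill(u, mesh@tets)
      gradients[[key]] <<- bfsFill(g$gradient, mesh@tets)
      degFill <- bfsFill(ifelse(g$degenerate & is.finite(u), 1, ifelse(is.na(u), NA, 0)),
                         mesh@tets)
      degenerate[[key]] <<- !is.na(degFill) & degFill > 0
    }
  }
  doChamber("la", chamberLa)
  doChamber("ra", chamberRa)
  for (nm in setdiff(names(fields), names(gradients))) {
    g <- nodalGradient(mesh, fields[[nm]])
    gradients[[nm]] <- g$gradient
    degenerate[[nm]] <- g$degenerate
  }
  new("DistanceFieldSet", fields = fields, gradients = gradients,
      degenerate = degenerate,
      chamber = list(la = chamberLa, ra = chamberRa), mode = mode)
}
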
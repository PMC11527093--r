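# The bundle-selection rule engine. Rules are evaluated per node,
# top-to-bottom, first match wins, exactly in the printed ladder order of
# the method's three decision tables (inter-atrial connections first, then
# the LA ladder for xi > 0 nodes, the RA ladder otherwise). Every rule
# stores the selected (gamma, k, alpha_endo, alpha_epi, flip) tuple; k may
# be layer-conditional (a sub-endo/sub-epi pair of distance fields).

# one rule: bundle label, condition closure over (v = named field list,
# tau, flags, pm), tuple of field references, angle selection
newRule <- function(bundle, cond, gamma, kEndo, kEpi = kEndo,
                    angleBundle = bundle, aEndoKey = "endo", aEpiKey = "epi",
                    flip = FALSE) {
  list(bundle = bundle, cond = cond, gamma = gamma, kEndo = kEndo,
       kEpi = kEpi, angleBundle = angleBundle, aEndoKey = aEndoKey,
       aEpiKey = aEpiKey, flip = flip)
}

icRules <- function() {
  list(
    newRule("BB_IC",
            function(v, tau, flags, pm)
              flags$bb_ic & v$xi >= tau$bbic_r & v$xi <= tau$bbic_l &
                v$ra.psi_v <= tau$bbic,
            gamma = "xi", kEndo = "phi",
            aEndoKey = "epi", aEpiKey = "epi", flip = TRUE),
    newRule("FO_IC",
            function(v, tau, flags, pm)
              flags$fo_ic & v$xi >= tau$foic_r & v$xi <= tau$foic_l &
                v$ra.psi_v > tau$bbic &
                v$la.psi_aa >= tau$foic & v$la.psi_aa <= tau$foic_in,
            gamma = "xi", kEndo = "la.psi_aa",
            aEndoKey = "epi", aEpiKey = "epi"),
    newRule("CS_IC",
            function(v, tau, flags, pm)
              flags$cs_ic & v$xi >= tau$csic_r & v$xi <= tau$csic_l &
                v$ra.psi_v > tau$bbic & v$ra.psi_ab <= tau$csic,
            gamma = "xi", kEndo = "phi",
            aEndoKey = "zero", aEpiKey = "zero", flip = TRUE)
  )
}

laRules <- function() {
  P <- function(nm) paste0("la.psi_", nm)
  list(
    newRule("MV", function(v, tau, flags, pm) v$la.psi_r >= tau$mv,
            gamma = "phi", kEndo = P("r")),
    newRule("RIPV", function(v, tau, flags, pm)
      v$la.psi_v >= tau$rpv & v$la.psi_r <= tau$rpv_up & v$la.psi_w <= tau$ripv,
      gamma = "phi", kEndo = P("v")),
    newRule("RSPV", function(v, tau, flags, pm)
      v$la.psi_v >= tau$rpv & v$la.psi_r <= tau$rpv_up & v$la.psi_w >= tau$rspv,
      gamma = "phi", kEndo = P("v")),
    newRule("RC", function(v, tau, flags, pm)
      v$la.psi_v >= tau$rpv & v$la.psi_r <= tau$rpv_up,
      gamma = "phi", kEndo = P("w")),
    newRule("LIPV", function(v, tau, flags, pm)
      v$la.psi_v <= tau$lpv & v$la.psi_r <= tau$lpv_up & v$la.psi_w <= tau$lipv,
      gamma = "phi", kEndo = P("v")),
    newRule("LSPV", function(v, tau, flags, pm)
      v$la.psi_v <= tau$lpv & v$la.psi_r <= tau$lpv_up & v$la.psi_w >= tau$lspv,
      gamma = "phi", kEndo = P("v")),
    newRule("LC", function(v, tau, flags, pm)
      v$la.psi_v <= tau$lpv & v$la.psi_r <= tau$lpv_up,
      gamma = "phi", kEndo = P("w")),
    newRule("LAA", function(v, tau, flags, pm) v$la.psi_aa <= tau$laa,
            gamma = "phi", kEndo = P("aa")),
    # anterior-septal block (psi_s <= tau_las), flattened in ladder order
    newRule("LLW", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_a <= tau$plw_la & v$la.psi_t >= tau$plw_la_up,
      gamma = "phi", kEndo = P("r")),
    newRule("LAR", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_a <= tau$plw_la & v$la.psi_t < tau$plw_la_up,
      gamma = "phi", kEndo = P("ab")),
    newRule("LSW", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_a >= tau$psw_la & v$la.psi_t >= tau$psw_la_up,
      gamma = "phi", kEndo = P("r")),
    newRule("LAR", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_a >= tau$psw_la & v$la.psi_t < tau$psw_la_up,
      gamma = "phi", kEndo = P("ab")),
    newRule("LAR", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_w > 0,
      gamma = "phi", kEndo = P("ab")),
    newRule("LAR", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_t <= tau$lar,
      gamma = "phi", kEndo = P("ab")),
    newRule("LAW_top", function(v, tau, flags, pm)
      v$la.psi_s <= tau$las & v$la.psi_r <= tau$law,
      gamma = "phi", kEndo = P("v"), kEpi = P("ab")),
    newRule("LAW_bot", function(v, tau, flags, pm) v$la.psi_s <= tau$las,
            gamma = "phi", kEndo = P("v"), kEpi = P("r")),
    newRule("LSW", function(v, tau, flags, pm) v$la.psi_a >= tau$asw_la,
            gamma = "phi", kEndo = P("r")),
    newRule("LLW", function(v, tau, flags, pm) v$la.psi_a <= tau$alw_la,
            gamma = "phi", kEndo = P("r")),
    newRule("BB", function(v, tau, flags, pm) v$la.psi_r >= tau$bb,
            gamma = "phi", kEndo = P("ab"), kEpi = P("r")),
    newRule("LAS", function(v, tau, flags, pm) rep(TRUE, length(v$xi)),
            gamma = "phi", kEndo = P("ab"))
  )
}

# pectinate stripe membership: stripes [PMi, PMf] with
# PMi = tau_raa + (n-1)(tk+rg), PMf = PMi + tk, n = 1..Npm
pmStripe <- function(paa, tau, pm) {
  period <- pm$tk + pm$rg
  rel <- paa - tau$raa
  inRange <- paa >= tau$raa & paa <= pm$end
  nIdx <- floor(rel / period) + 1
  within <- rel - (nIdx - 1) * period
  inRange & nIdx >= 1 & nIdx <= pm$n & within <= pm$tk
}

raRules <- function() {
  P <- function(nm) paste0("ra.psi_", nm)
  list(
    newRule("TV", function(v, tau, flags, pm)
      v$ra.psi_r >= tau$tv & v$ra.psi_ab >= tau$tvaa,
      gamma = "phi", kEndo = P("r")),
    newRule("SCV", function(v, tau, flags, pm)
      v$ra.psi_v <= tau$scv & v$ra.psi_r <= tau$scv_up,
      gamma = "phi", kEndo = P("v")),
    newRule("ICV", function(v, tau, flags, pm)
      v$ra.psi_v >= tau$icv & v$ra.psi_r <= tau$icv_up,
      gamma = "phi", kEndo = P("v")),
    newRule("RAA", function(v, tau, flags, pm)
      v$ra.psi_aa <= tau$raa & v$ra.psi_w <= tau$raaw & v$ra.psi_t >= tau$raa_up,
      gamma = "phi", kEndo = P("aa")),
    newRule("CSM", function(v, tau, flags, pm)
      flags$csm & v$ra.psi_ab <= tau$csm & v$ra.psi_v >= tau$csmv,
      gamma = "phi", kEndo = P("ab")),
    # septal block (psi_w >= tau_ras), flattened
    newRule("RPW", function(v, tau, flags, pm)
      v$ra.psi_w >= tau$ras & v$ra.psi_a <= tau$psw_ra & v$ra.psi_t >= tau$psw_ra_up,
      gamma = "phi", kEndo = P("r")),
    newRule("RAW", function(v, tau, flags, pm)
      v$ra.psi_w >= tau$ras & v$ra.psi_a >= tau$asw_ra & v$ra.psi_t >= tau$psw_ra_up,
      gamma = "phi", kEndo = P("r")),
    newRule("IB", function(v, tau, flags, pm)
      v$ra.psi_w >= tau$ras & v$ra.psi_t <= tau$ibs,
      gamma = "phi", kEndo = P("v")),
    # the printed RAS rule reuses the IB angle pair with k = grad(psi_t)
    newRule("RAS", function(v, tau, flags, pm) v$ra.psi_w >= tau$ras,
            gamma = "phi", kEndo = P("t"), angleBundle = "IB"),
    newRule("RPW", function(v, tau, flags, pm)
      v$ra.psi_a <= tau$plw_ra & v$ra.psi_t >= tau$plw_ra_up,
      gamma = "phi", kEndo = P("r")),
    newRule("RAW", function(v, tau, flags, pm) v$ra.psi_a >= tau$alw_ra,
            gamma = "phi", kEndo = P("r")),
    newRule("IB", function(v, tau, flags, pm) v$ra.psi_t <= tau$ibl,
            gamma = "phi", kEndo = P("v")),
    newRule("CT", function(v, tau, flags, pm)
      v$ra.psi_ct >= tau$ct_minus & v$ra.psi_ct <= tau$ct_plus &
        v$phi_ra <= tau$ct_phi,
      gamma = "phi", kEndo = P("ct"),
      aEndoKey = "endo", aEpiKey = "endo"),
    newRule("RLW", function(v, tau, flags, pm) v$ra.psi_ct > tau$ct_plus,
            gamma = "phi", kEndo = P("ab")),
    # final else: pectinate striping when enabled, lateral wall otherwise
    newRule("RLW", function(v, tau, flags, pm)
      if (isTRUE(flags$pm)) v$phi_ra > tau$ct_phi else rep(FALSE, length(v$xi)),
      gamma = "phi", kEndo = P("ab")),
    newRule("PM", function(v, tau, flags, pm)
      if (isTRUE(flags$pm)) pmStripe(v$ra.psi_aa, tau, pm)
      else rep(FALSE, length(v$xi)),
      gamma = "phi", kEndo = P("aa"),
      aEndoKey = "endo", aEpiKey = "endo"),
    newRule("RLW", function(v, tau, flags, pm) rep(TRUE, length(v$xi)),
            gamma = "phi", kEndo = P("ab"))
  )
}

#' Canonical rule evaluation order
#'
#' The engine stores rule order as data; this returns the bundle name of
#' every rule in evaluation order for each decision table, so the default
#' order is testable against the documented ladder.
#' @return list with `ic`, `la`, `ra` character vectors
#' @export
bundleRuleOrder <- function() {
  list(ic = vapply(icRules(), `[[`, "", "bundle"),
       la = vapply(laRules(), `[[`, "", "bundle"),
       ra = vapply(raRules(), `[[`, "", "bundle"))
}

# Evaluate an ordered rule list on the nodes in `mask`; fills the output
# environment `out` in place and returns the updated unassigned mask.
applyRules <- function(rules, v, mask, cfg, out) {
  for (r in rules) {
    hit <- mask & r$cond(v, cfg$tau, cfg$flags, cfg$pm)
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) next
    out$label[hit] <- r$bundle
    out$gamma[hit] <- r$gamma
    out$kEndo[hit] <- r$kEndo
    out$kEpi[hit] <- r$kEpi
    ang <- cfg$angles[[r$angleBundle]]
    out$aEndo[hit] <- switch(r$aEndoKey, endo = ang[1], epi = ang[2], zero = 0)
    out$aEpi[hit] <- switch(r$aEpiKey, endo = ang[1], epi = ang[2], zero = 0)
    out$flip[hit] <- r$flip
    mask <- mask & !hit
    if (!any(mask)) break
  }
  mask
}

#' Evaluate the bundle decision tables on raw field values
#'
#' Low-level entry point used by [assignBundles()] and by decision-table
#' tests: takes named per-node vectors (`xi`, `phi`, `phi_ra`, `la.psi_*`,
#' `ra.psi_*`) rather than a mesh.
#'
#' @param v named list of per-node numeric vectors.
#' @param cfg configuration list (see [defaultBundleConfig()]).
#' @param biatrial apply the inter-atrial connection rules first.
#' @return list of per-node vectors: `label`, `gamma`, `kEndo`, `kEpi`,
#'   `aEndo`, `aEpi`, `flip`.
#' @export
evalBundleRules <- function(v, cfg = defaultBundleConfig(), biatrial = TRUE) {
  n <- length(v$xi)
  out <- new.env()
  out$label <- rep(NA_character_, n)
  out$gamma <- rep(NA_character_, n)
  out$kEndo <- rep(NA_character_, n)
  out$kEpi <- rep(NA_character_, n)
  out$aEndo <- rep(NA_real_, n)
  out$aEpi <- rep(NA_real_, n)
  out$flip <- rep(FALSE, n)
  mask <- rep(TRUE, n)
  if (biatrial) mask <- applyRules(icRules(), v, mask, cfg, out)
  # route by the sign of xi: positive to the LA ladder, the rest to RA
  laMask <- mask & v$xi > 0
  raMask <- mask & !(v$xi > 0)
  if (any(laMask)) applyRules(laRules(), v, laMask, cfg, out)
  if (any(raMask)) applyRules(raRules(), v, raMask, cfg, out)
  as.list(out)
}

#' Assign anatomical bundles to every node
#'
#' Runs the three decision tables on the harmonic distance catalog and
#' returns the per-node bundle label together with the selected frame
#' sources and rotation angles. The final else branches of the LA/RA
#' ladders guarantee totality; this is asserted.
#'
#' @param mesh a [LabeledTetMesh-class]
#' @param distances a [DistanceFieldSet-class] from [computeDistanceSet()]
#' @param config configuration list, default [defaultBundleConfig()]
#' @return a [BundleAssignment-class]
#' @export
assignBundles <- function(mesh, distances, config = defaultBundleConfig()) {
  validateBundleConfig(config)
  v <- distances@fields
  n <- nNodes(mesh)
  mode <- distances@mode
  needs <- if (mode == "biatrial") c("xi", "phi") else "phi"
  for (nm in needs) {
    if (is.null(v[[nm]])) stop(sprintf("distance field '%s' missing", nm))
  }
  res <- evalBundleRules(v, config, biatrial = (mode == "biatrial"))
  if (anyNA(res$label)) stop("rule engine left unlabeled nodes")
  # transmural coordinate (endo = 1, epi = 0) and layer indicator
  tcoord <- pmin(1, pmax(0, abs(v$phi)))
  layer <- factor(ifelse(tcoord > config$tauLayer, "endo", "epi"),
                  levels = c("endo", "epi"))
  new("BundleAssignment",
      label = factor(res$label, levels = BUNDLE_NAMES),
      gammaField = res$gamma, kEndo = res$kEndo, kEpi = res$kEpi,
      alphaEndo = res$aEndo, alphaEpi = res$aEpi, flip = res$flip,
      layer = layer)
}

#' Per-bundle node counts and volume fractions
#'
#' Node volume is the quarter-share of incident tet volumes; fractions sum
#' to one.
#'
#' @param assignment a [BundleAssignment-class]
#' @param mesh the mesh the assignment was computed on
#' @return data.frame with `bundle`, `nodes`, `volumeFraction`
#' @export
bundleVolumeReport <- function(assignment, mesh) {
  vol <- tetSignedVolumes(mesh@nodes, mesh@tets)
  nodeVol <- numeric(nNodes(mesh))
  for (a in 1:4) {
    nodeVol <- nodeVol + tapplySum(vol / 4, mesh@tets[, a], nNodes(mesh))
  }
  lab <- droplevels(assignment@label)
  counts <- table(lab)
  volByBundle <- tapply(nodeVol, lab, sum)
  data.frame(bundle = names(counts),
             nodes = as.integer(counts),
             volumeFraction = as.numeric(volByBundle[names(counts)]) / sum(nodeVol),
             row.names = NULL)
}
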
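# Decision-table rule engine: printed-branch reproduction on hand-built
# single-node inputs, totality and order properties on the toy.

# a single node's field values, defaulting to "hits nothing special"
nodeValues <- function(...) {
  v <- list(xi = 0.5, phi = 0.5, phi_la = 0.5, phi_ra = 0.5,
            la.psi_ab = 0, la.psi_v = 0.5, la.psi_r = 0.5, la.psi_w = 0,
            la.psi_t = 0.5, la.psi_a = 0.5, la.psi_aa = 0, la.psi_s = 0.5,
            ra.psi_ab = 0.5, ra.psi_v = 0.5, ra.psi_r = 0.5, ra.psi_w = 0,
            ra.psi_t = 0.5, ra.psi_a = 0, ra.psi_aa = 0.5, ra.psi_ct = 0)
  utils::modifyList(v, list(...))
}

labelOf <- function(v, cfg = defaultBundleConfig()) {
  evalBundleRules(lapply(v, as.numeric), cfg)
}

test_that("inter-atrial connection rules fire in their printed windows", {
  cfg <- defaultBundleConfig()
  tau <- cfg$tau
  # BB_IC: xi inside window, ra psi_v at or below its threshold; flip set
  r <- labelOf(nodeValues(xi = 0, ra.psi_v = tau$bbic))
  expect_identical(r$label, "BB_IC")
  expect_identical(r$gamma, "xi")
  expect_identical(r$kEndo, "phi")
  expect_true(r$flip)
  expect_identical(r$aEndo, cfg$angles$BB_IC[2])   # epi angle on both layers
  expect_identical(r$aEpi, cfg$angles$BB_IC[2])
  # FO_IC: psi_v above the BB threshold, la psi_aa inside its window
  r <- labelOf(nodeValues(xi = 0, ra.psi_v = tau$bbic + 0.1,
                          la.psi_aa = (tau$foic + tau$foic_in) / 2))
  expect_identical(r$label, "FO_IC")
  expect_identical(r$kEndo, "la.psi_aa")
  expect_false(r$flip)
  # CS_IC: angles pinned to zero, flip set
  r <- labelOf(nodeValues(xi = 0, ra.psi_v = tau$bbic + 0.1,
                          la.psi_aa = tau$foic - 1, ra.psi_ab = tau$csic))
  expect_identical(r$label, "CS_IC")
  expect_identical(r$aEndo, 0)
  expect_true(r$flip)
  # outside every IC window, positive xi routes to the LA ladder
  r <- labelOf(nodeValues(xi = 0.5, la.psi_r = 0.9))
  expect_identical(r$label, "MV")
  # ... and non-positive xi to the RA ladder
  r <- labelOf(nodeValues(xi = -0.5, ra.psi_r = 0.9, ra.psi_ab = 0.5))
  expect_identical(r$label, "TV")
  # disabling a flag skips its rule
  cfgOff <- cfg; cfgOff$flags$bb_ic <- FALSE
  r <- labelOf(nodeValues(xi = 0.2, ra.psi_v = 0), cfgOff)
  expect_false(identical(r$label, "BB_IC"))
})

test_that("LA ladder reproduces each printed branch", {
  cfg <- defaultBundleConfig()
  tau <- cfg$tau
  mv <- labelOf(nodeValues(la.psi_r = 0.9))
  expect_identical(mv$label, "MV")
  expect_identical(mv$gamma, "phi")
  expect_identical(mv$kEndo, "la.psi_r")
  expect_identical(c(mv$aEndo, mv$aEpi), cfg$angles$MV)
  ripv <- labelOf(nodeValues(la.psi_v = 0.9, la.psi_r = 0.1, la.psi_w = -0.9))
  expect_identical(ripv$label, "RIPV")
  expect_identical(ripv$kEndo, "la.psi_v")
  rspv <- labelOf(nodeValues(la.psi_v = 0.9, la.psi_r = 0.1, la.psi_w = 0.9))
  expect_identical(rspv$label, "RSPV")
  rc <- labelOf(nodeValues(la.psi_v = 0.9, la.psi_r = 0.1, la.psi_w = 0))
  expect_identical(rc$label, "RC")
  expect_identical(rc$kEndo, "la.psi_w")
  lipv <- labelOf(nodeValues(la.psi_v = 0.1, la.psi_r = 0.1, la.psi_w = -0.9))
  expect_identical(lipv$label, "LIPV")
  lc <- labelOf(nodeValues(la.psi_v = 0.1, la.psi_r = 0.1, la.psi_w = 0))
  expect_identical(lc$label, "LC")
  laa <- labelOf(nodeValues(la.psi_aa = tau$laa - 0.1))
  expect_identical(laa$label, "LAA")
  expect_identical(laa$kEndo, "la.psi_aa")
  # anterior-septal block
  llw <- labelOf(nodeValues(la.psi_s = tau$las - 0.1, la.psi_a = tau$plw_la - 0.1,
                            la.psi_t = tau$plw_la_up + 0.1, la.psi_w = -0.1))
  expect_identical(llw$label, "LLW")
  lar <- labelOf(nodeValues(la.psi_s = tau$las - 0.1, la.psi_a = tau$plw_la - 0.1,
                            la.psi_t = tau$plw_la_up - 0.1, la.psi_w = -0.1))
  expect_identical(lar$label, "LAR")
  lawT <- labelOf(nodeValues(la.psi_s = tau$las - 0.1, la.psi_a = 0.5,
                             la.psi_w = -0.1, la.psi_t = tau$lar + 0.1,
                             la.psi_r = tau$law - 0.1))
  expect_identical(lawT$label, "LAW_top")
  expect_identical(c(lawT$kEndo, lawT$kEpi), c("la.psi_v", "la.psi_ab"))
  lawB <- labelOf(nodeValues(la.psi_s = tau$las - 0.1, la.psi_a = 0.5,
                             la.psi_w = -0.1, la.psi_t = tau$lar + 0.1,
                             la.psi_r = tau$law + 0.1))
  expect_identical(lawB$label, "LAW_bot")
  expect_identical(c(lawB$kEndo, lawB$kEpi), c("la.psi_v", "la.psi_r"))
  bb <- labelOf(nodeValues(la.psi_a = 0.5, la.psi_r = tau$bb + 0.1))
  expect_identical(bb$label, "BB")
  expect_identical(c(bb$kEndo, bb$kEpi), c("la.psi_ab", "la.psi_r"))
  las <- labelOf(nodeValues(la.psi_a = 0.5, la.psi_r = tau$bb - 0.1))
  expect_identical(las$label, "LAS")
  expect_identical(las$kEndo, "la.psi_ab")
})

test_that("RA ladder reproduces each printed branch including CT and PM", {
  cfg <- defaultBundleConfig()
  tau <- cfg$tau
  base <- function(...) nodeValues(xi = -0.5, ...)
  tv <- labelOf(base(ra.psi_r = 0.9, ra.psi_ab = tau$tvaa + 0.1))
  expect_identical(tv$label, "TV")
  scv <- labelOf(base(ra.psi_v = 0.1, ra.psi_r = 0.1))
  expect_identical(scv$label, "SCV")
  icv <- labelOf(base(ra.psi_v = 0.9, ra.psi_r = 0.1))
  expect_identical(icv$label, "ICV")
  raa <- labelOf(base(ra.psi_aa = tau$raa - 0.1, ra.psi_w = tau$raaw - 0.1,
                      ra.psi_t = tau$raa_up + 0.1))
  expect_identical(raa$label, "RAA")
  csm <- labelOf(base(ra.psi_ab = tau$csm - 0.1, ra.psi_v = tau$csmv + 0.1))
  expect_identical(csm$label, "CSM")
  # septal block: RAS takes grad(psi_t) with the IB angle pair
  ras <- labelOf(base(ra.psi_w = tau$ras + 0.1, ra.psi_a = 0,
                      ra.psi_t = tau$ibs + 0.1))
  expect_identical(ras$label, "RAS")
  expect_identical(ras$kEndo, "ra.psi_t")
  expect_identical(c(ras$aEndo, ras$aEpi), cfg$angles$IB)
  ib <- labelOf(base(ra.psi_w = tau$ras + 0.1, ra.psi_a = 0,
                     ra.psi_t = tau$ibs - 0.1))
  expect_identical(ib$label, "IB")
  # CT needs the psi_ct window AND the sub-endocardial phi_ra condition
  ct <- labelOf(base(ra.psi_ct = (tau$ct_minus + tau$ct_plus) / 2,
                     phi_ra = tau$ct_phi - 0.1))
  expect_identical(ct$label, "CT")
  expect_identical(ct$kEndo, "ra.psi_ct")
  expect_identical(ct$aEpi, cfg$angles$CT[1])   # endo angle on both layers
  noCt <- labelOf(base(ra.psi_ct = (tau$ct_minus + tau$ct_plus) / 2,
                       phi_ra = tau$ct_phi + 0.1))
  expect_false(identical(noCt$label, "CT"))
  rlw <- labelOf(base(ra.psi_ct = tau$ct_plus + 0.1))
  expect_identical(rlw$label, "RLW")
})

test_that("pectinate striping follows the printed arithmetic", {
  cfg <- defaultBundleConfig()
  cfg$tau$raa <- 0.1
  cfg$pm <- list(tk = 0.05, rg = 0.05, end = 0.9, n = 4L)
  # stripe n = 2 occupies [0.20, 0.25]
  probe <- function(paa) {
    labelOf(nodeValues(xi = -0.5, phi_ra = 0, ra.psi_ct = 0.99,
                       ra.psi_aa = paa, ra.psi_t = 0.2), cfg)$label
  }
  # note: ra.psi_ct must fall outside its window and below ct_plus override
  cfg$tau$ct_plus <- 2; cfg$tau$ct_minus <- 1.5
  expect_identical(probe(0.20), "PM")
  expect_identical(probe(0.225), "PM")
  expect_identical(probe(0.25), "PM")
  expect_identical(probe(0.26), "RLW")    # gap (PMf, PMs)
  expect_identical(probe(0.19), "RLW")    # gap below stripe 2
  expect_identical(probe(0.05), "RLW")    # below tau_raa
  expect_identical(probe(0.95), "RLW")    # beyond pm_end
  # epicardial-side nodes never become PM
  cfg2 <- cfg
  expect_identical(labelOf(nodeValues(xi = -0.5, phi_ra = 0.9,
                                      ra.psi_ct = 1.7, ra.psi_aa = 0.2,
                                      ra.psi_t = 0.2), cfg2)$label, "RLW")
  # PM disabled: plain lateral wall
  cfg$flags$pm <- FALSE
  expect_identical(probe(0.225), "RLW")
})

test_that("assignment on the toy is total and exhaustive", {
  asn <- toyAssignment()
  toy <- toyFixture()
  expect_identical(length(bundleLabels(asn)), nNodes(toy))
  expect_false(anyNA(bundleLabels(asn)))
  rep <- bundleVolumeReport(asn, toy)
  expect_equal(sum(rep$volumeFraction), 1, tolerance = 1e-12)
  expect_identical(sum(rep$nodes), nNodes(toy))
  # the anatomically required regions are all populated
  for (b in c("MV", "LIPV", "LSPV", "RIPV", "RSPV", "LAA",
              "TV", "SCV", "ICV")) {
    expect_gt(sum(bundleLabels(asn) == b), 0, label = b)
  }
  # flip only ever set for the flip bundles
  expect_true(all(as.character(asn@label[asn@flip]) %in% c("BB_IC", "CS_IC")))
})

test_that("default rule order equals the documented ladder", {
  ord <- bundleRuleOrder()
  expect_identical(ord$ic, c("BB_IC", "FO_IC", "CS_IC"))
  expect_identical(ord$la,
                   c("MV", "RIPV", "RSPV", "RC", "LIPV", "LSPV", "LC", "LAA",
                     "LLW", "LAR", "LSW", "LAR", "LAR", "LAR", "LAW_top",
                     "LAW_bot", "LSW", "LLW", "BB", "LAS"))
  expect_identical(ord$ra,
                   c("TV", "SCV", "ICV", "RAA", "CSM", "RPW", "RAW", "IB",
                     "RAS", "RPW", "RAW", "IB", "CT", "RLW", "RLW", "PM",
                     "RLW"))
})

test_that("raising tau_mv never grows the MV set; degenerate tau gives MV everywhere", {
  ds <- toyDistances()
  toy <- toyFixture()
  cfgLo <- defaultBundleConfig(); cfgLo$tau$mv <- 0.80
  cfgHi <- defaultBundleConfig(); cfgHi$tau$mv <- 0.90
  mvLo <- which(bundleLabels(assignBundles(toy, ds, cfgLo)) == "MV")
  mvHi <- which(bundleLabels(assignBundles(toy, ds, cfgHi)) == "MV")
  expect_true(all(mvHi %in% mvLo))
  # tau_mv below the field minimum claims every LA-ladder node
  shell <- laShellFixture()
  dsla <- computeDistanceSet(shell, "la_only")
  cfgAll <- defaultBundleConfig(); cfgAll$tau$mv <- -10
  asnAll <- assignBundles(shell, dsla, cfgAll)
  expect_true(all(bundleLabels(asnAll) == "MV"))
  repAll <- bundleVolumeReport(asnAll, shell)
  expect_equal(repAll$volumeFraction[repAll$bundle == "MV"], 1,
               tolerance = 1e-12)
})
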
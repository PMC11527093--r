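# Rule configuration: thresholds (tau), pectinate-muscle striping
# parameters, per-bundle rotation-angle pairs and feature flags. The
# shipped defaults are a documented mid-range profile tuned once for the
# synthetic bi-atrial toy; real anatomies carry their own per-geometry
# profile (YAML).

BUNDLE_NAMES <- c("BB_IC", "FO_IC", "CS_IC",
                  "MV", "LIPV", "LSPV", "RIPV", "RSPV", "LC", "RC", "LAA",
                  "LAS", "LLW", "LSW", "LAW_top", "LAW_bot", "LAR", "BB",
                  "TV", "ICV", "SCV", "RAA", "CSM", "RAS", "RLW", "RAW",
                  "RPW", "IB", "CT", "PM")

#' Default bundle-rule configuration
#'
#' Thresholds are expressed in the raw Dirichlet-data units of the distance
#' catalog (fields are never rescaled after the solve); angles in degrees.
#' `tauLayer` splits the wall into the sub-endocardial (transmural
#' coordinate > tauLayer) and sub-epicardial layers.
#'
#' @return nested list: `flags`, `tau`, `pm`, `tauLayer`, `angles`.
#' @export
defaultBundleConfig <- function() {
  list(
    flags = list(bb_ic = TRUE, fo_ic = TRUE, cs_ic = TRUE,
                 csm = TRUE, pm = TRUE),
    tauLayer = 0.5,
    tau = list(
      # inter-atrial connection windows (on xi) and companions
      bbic_r = -0.25, bbic_l = 0.25, bbic = 0.465,
      foic_r = -0.25, foic_l = 0.25, foic = -0.2, foic_in = 1.0,
      csic_r = -0.25, csic_l = 0.25, csic = 0.71,
      # LA
      mv = 0.85, lpv = 0.25, lpv_up = 0.4, lipv = -0.35, lspv = 0.35,
      rpv = 0.75, rpv_up = 0.4, ripv = -0.35, rspv = 0.35,
      laa = -0.95, las = -0.2,
      plw_la = 0.3, plw_la_up = 0.35, alw_la = 0.3,
      psw_la = 0.7, psw_la_up = 0.35, asw_la = 0.7,
      lar = 0.2, law = 0.55, bb = 0.5,
      # RA
      tv = 0.85, tvaa = -0.8, icv = 0.75, icv_up = 0.4,
      scv = 0.25, scv_up = 0.4,
      raa = -0.25, raaw = 0.6, raa_up = 0.25,
      csm = -0.5, csmv = 0.55, ras = 0.45,
      asw_ra = 0.5, asw_ra_up = 0.3, alw_ra = 0.5,
      psw_ra = -0.5, psw_ra_up = 0.3, plw_ra = -0.5, plw_ra_up = 0.3,
      ibs = 0.18, ibl = 0.18,
      ct_plus = 0.4, ct_minus = -0.2, ct_phi = 0.35
    ),
    pm = list(tk = 0.15, rg = 0.15, end = 0.9, n = 4L),
    angles = list(
      # c(endo, epi) in degrees; bundles whose rule prescribes a single
      # angle for both layers (BB_IC, FO_IC, CS_IC, CT, PM) still carry a
      # pair here -- the engine picks the entry the rule names.
      BB_IC = c(-20, -20), FO_IC = c(35, 35), CS_IC = c(0, 0),
      MV = c(-60, -60), LIPV = c(10, 50), LSPV = c(-10, 40),
      RIPV = c(10, 50), RSPV = c(-10, 40), LC = c(0, 45), RC = c(0, 45),
      LAA = c(-30, 30), LAS = c(5, 45), LLW = c(-65, -65),
      LSW = c(-65, -20), LAW_top = c(70, 70), LAW_bot = c(70, 40),
      LAR = c(70, 70), BB = c(-20, -50),
      TV = c(-60, -30), ICV = c(20, 60), SCV = c(20, 60), RAA = c(-45, 45),
      CSM = c(-70, -70), RAS = c(60, 30), RLW = c(-20, 20),
      RAW = c(70, 40), RPW = c(75, 45), IB = c(-10, -10),
      CT = c(-70, -70), PM = c(-50, -50)
    )
  )
}

#' Read a bundle-rule configuration from YAML
#'
#' The file may override any subset of [defaultBundleConfig()]; unknown
#' angle keys raise an error naming the offending bundle.
#'
#' @param path YAML file with optional sections `flags`, `tau`, `pm`,
#'   `tauLayer`, `angles`.
#' @return full configuration list
#' @export
readBundleConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- defaultBundleConfig()
  for (sec in c("flags", "tau", "pm")) {
    if (!is.null(raw[[sec]])) cfg[[sec]] <- utils::modifyList(cfg[[sec]], raw[[sec]])
  }
  if (!is.null(raw$tauLayer)) cfg$tauLayer <- raw$tauLayer
  cfg$pm$n <- as.integer(cfg$pm$n)
  if (!is.null(raw$angles)) {
    bad <- setdiff(names(raw$angles), BUNDLE_NAMES)
    if (length(bad)) {
      stop(sprintf("unknown bundle name(s) in angles table: %s",
                   paste(bad, collapse = ", ")))
    }
    for (nm in names(raw$angles)) cfg$angles[[nm]] <- as.numeric(raw$angles[[nm]])
  }
  validateBundleConfig(cfg)
  cfg
}

#' @keywords internal
validateBundleConfig <- function(cfg) {
  stopifnot(all(vapply(cfg$tau, is.finite, logical(1))))
  if (cfg$pm$n < 0) stop("number of pectinate muscles must be >= 0")
  if (isTRUE(cfg$flags$pm) && (cfg$pm$tk <= 0 || cfg$pm$rg <= 0)) {
    stop("pm thickness/range must be positive when PM are enabled")
  }
  bad <- setdiff(names(cfg$angles), BUNDLE_NAMES)
  if (length(bad)) {
    stop(sprintf("unknown bundle name(s) in angles table: %s",
                 paste(bad, collapse = ", ")))
  }
  for (nm in names(cfg$angles)) {
    a <- cfg$angles[[nm]]
    if (length(a) != 2 || any(a <= -180) || any(a > 180)) {
      stop(sprintf("angles for bundle '%s' must be a pair in (-180, 180]", nm))
    }
  }
  invisible(cfg)
}
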
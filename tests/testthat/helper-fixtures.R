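# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated programmatically; no files ship with the tests.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

toyFixture <- function() cachedFixture("toy", makeBiatrialToy)

toyDistances <- function() {
  cachedFixture("toyDistances", function() computeDistanceSet(toyFixture(), "biatrial"))
}

toyAssignment <- function() {
  cachedFixture("toyAssignment", function() {
    assignBundles(toyFixture(), toyDistances(), defaultBundleConfig())
  })
}

toyFibers <- function() {
  cachedFixture("toyFibers", function() {
    generateFibers(toyFixture(), toyDistances(), toyAssignment())
  })
}

laShellFixture <- function() cachedFixture("laShell", function() makeAtrialShell("la"))

# uniform-triad fiber field on a mesh (f0, s0, n0 must be orthonormal)
uniformFiberField <- function(mesh, f0, s0, n0) {
  n <- nNodes(mesh)
  rep3 <- function(v) matrix(rep(v, each = n), n)
  new("FiberField", f = rep3(f0), s = rep3(s0), n = rep3(n0),
      el = rep3(f0), en = rep3(n0), et = rep3(s0),
      bundle = factor(rep("MV", n), levels = atrialLDRBM:::BUNDLE_NAMES),
      layer = factor(rep("endo", n), levels = c("endo", "epi")),
      degenerate = rep(FALSE, n))
}

# random orthonormal frames (rows), deterministic under the caller's seed
randomFrames <- function(n) {
  g <- matrix(stats::rnorm(3 * n), n, 3)
  k <- matrix(stats::rnorm(3 * n), n, 3)
  axisSystem(g, k)
}

# minimal distance-set carrier for hand-built frame tests
manualDistanceSet <- function(mesh, fields) {
  grads <- list(); degs <- list()
  for (nm in names(fields)) {
    g <- nodalGradient(mesh, fields[[nm]])
    grads[[nm]] <- g$gradient
    degs[[nm]] <- g$degenerate
  }
  new("DistanceFieldSet", fields = fields, gradients = grads,
      degenerate = degs,
      chamber = list(la = seq_len(nNodes(mesh)), ra = integer()),
      mode = "la_only")
}

# uniform single-bundle assignment for slab experiments
uniformAssignment <- function(n, bundle = "MV", gamma = "phi", kEndo = "psi",
                              kEpi = kEndo, aEndo = 0, aEpi = 0,
                              flip = FALSE, layer = rep("endo", n)) {
  new("BundleAssignment",
      label = factor(rep(bundle, n), levels = atrialLDRBM:::BUNDLE_NAMES),
      gammaField = rep(gamma, n), kEndo = rep(kEndo, n), kEpi = rep(kEpi, n),
      alphaEndo = rep(aEndo, n), alphaEpi = rep(aEpi, n),
      flip = rep(flip, n),
      layer = factor(layer, levels = c("endo", "epi")))
}

expect_rows_equal <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected)), tol)
}
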
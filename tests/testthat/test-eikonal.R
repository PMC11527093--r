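# Conductivity construction and the eikonal-diffusion activation solver.

test_that("conductivity tensor: canonical, isotropic and spectral checks", {
  slab <- makeSlab(4e-3, 3e-3, 2e-3, 1e-3)
  fib <- uniformFiberField(slab, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  p <- epParameters()
  D <- buildConductivity(fib, p)
  expect_rows_equal(D[, 1], rep(p$sigma_f, nNodes(slab)))
  expect_rows_equal(D[, 2], rep(p$sigma_s, nNodes(slab)))
  expect_rows_equal(D[, 3], rep(p$sigma_n, nNodes(slab)))
  expect_rows_equal(D[, 4:6], matrix(0, nNodes(slab), 3))
  # isotropic limit: D = sigma I for any triad
  set.seed(5)
  fr <- randomFrames(nNodes(slab))
  rot <- new("FiberField", f = fr$el, s = fr$et, n = fr$en,
             el = fr$el, en = fr$en, et = fr$et,
             bundle = fib@bundle, layer = fib@layer,
             degenerate = rep(FALSE, nNodes(slab)))
  pIso <- epParameters(sigma_f = 2e-4, sigma_s = 2e-4, sigma_n = 2e-4)
  Diso <- buildConductivity(rot, pIso)
  expect_rows_equal(Diso[, 1:3], matrix(2e-4, nNodes(slab), 3), tol = 1e-18)
  expect_rows_equal(Diso[, 4:6], matrix(0, nNodes(slab), 3), tol = 1e-18)
  # eigenvalues equal the sigmas for random orthonormal triads
  Drot <- buildConductivity(rot, p)
  for (i in c(1, 17, 53)) {
    M <- matrix(c(Drot[i, 1], Drot[i, 4], Drot[i, 5],
                  Drot[i, 4], Drot[i, 2], Drot[i, 6],
                  Drot[i, 5], Drot[i, 6], Drot[i, 3]), 3)
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_rows_equal(ev, sort(c(p$sigma_f, p$sigma_s, p$sigma_n)), tol = 1e-12)
  }
  expect_error(epParameters(cf = -1), "positive")
})

test_that("degenerate stimuli and unreached components are handled", {
  slab <- makeSlab(4e-3, 3e-3, 2e-3, 1e-3)
  fib <- uniformFiberField(slab, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  D <- buildConductivity(fib)
  # stimulus covering the whole mesh: identically zero activation
  am <- solveEikonal(slab, D, 100, list(nodes = seq_len(nNodes(slab))))
  expect_identical(activationTimes(am), rep(0, nNodes(slab)))
  # disconnected chamber: unreached nodes get the +Inf sentinel
  open <- makeBiatrialToy(withSeptum = FALSE)
  fibO <- uniformFiberField(open, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  stimNode <- which.min(nodeCoords(open)[, 1])   # deep in the LA shell
  amO <- solveEikonal(open, buildConductivity(fibO), 100,
                      list(nodes = stimNode),
                      settings = eikonalSettings(tol = 1e-2, maxIter = 500))
  comp <- atrialLDRBM:::nodeComponents(nNodes(open), tetConn(open))
  other <- comp != comp[stimNode]
  expect_true(all(is.infinite(activationTimes(amO)[other])))
  expect_true(all(is.finite(activationTimes(amO)[!other])))
  expect_error(solveEikonal(slab, D, 100, list(centre = c(1, 1, 1), radius = 1e-9)),
               "no nodes")
})

test_that("activation is causal and bitwise invariant under fiber sign flips", {
  slab <- makeSlab(8e-3, 4e-3, 2e-3, 1e-3)
  fib <- uniformFiberField(slab, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  stim <- list(nodes = tagNodes(slab, "dirichlet_a"))
  am <- solveEikonal(slab, buildConductivity(fib), 100, stim)
  u <- activationTimes(am)
  expect_gte(min(u), 0)
  expect_identical(u[stim$nodes], rep(0, length(stim$nodes)))
  # u non-decreasing with distance from the stimulus plane along x columns
  x <- nodeCoords(slab)
  ord <- order(x[, 2], x[, 3], x[, 1])
  perCol <- split(u[ord], paste(x[ord, 2], x[ord, 3]))
  expect_true(all(vapply(perCol, function(col) all(diff(col) >= -1e-9),
                         logical(1))))
  flipped <- uniformFiberField(slab, c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  amF <- solveEikonal(slab, buildConductivity(flipped), 100, stim)
  expect_identical(activationTimes(amF), u)
})

test_that("isotropic point stimulus yields spherical fronts", {
  slab <- makeSlab(8e-3, 8e-3, 8e-3, 8e-4)
  pIso <- epParameters(sigma_f = 1e-4, sigma_s = 1e-4, sigma_n = 1e-4)
  fib <- uniformFiberField(slab, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  centre <- c(4e-3, 4e-3, 4e-3)
  am <- solveEikonal(slab, buildConductivity(fib, pIso), 100,
                     list(centre = centre, radius = 8e-4))
  u <- activationTimes(am)
  # level-set radius along each axis at a fixed activation time
  probeRadius <- function(axis) {
    sel <- abs(nodeCoords(slab)[, axis %% 3 + 1] - 4e-3) < 4e-4 &
      abs(nodeCoords(slab)[, (axis + 1) %% 3 + 1] - 4e-3) < 4e-4 &
      nodeCoords(slab)[, axis] > 4e-3
    r <- nodeCoords(slab)[sel, axis] - 4e-3
    tt <- u[sel]
    stats::approx(tt, r, xout = 2e-3)$y
  }
  radii <- vapply(1:3, probeRadius, numeric(1))
  expect_lt(max(radii) / min(radii), 1.05)
})

test_that("dispersion holds on a coarse slab, also in pure-eikonal mode and under refinement", {
  lx <- 0.02
  mkrun <- function(h, diffusion = TRUE) {
    slab <- makeSlab(lx, 0.006, 0.003, h)
    fib <- uniformFiberField(slab, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    am <- solveEikonal(slab, buildConductivity(fib), 100,
                       list(nodes = tagNodes(slab, "dirichlet_a")),
                       settings = eikonalSettings(diffusion = diffusion))
    frontSpeed(slab, am, 1, 0.005, 0.015, h)
  }
  vCoarse <- mkrun(2e-3)
  expect_equal(vCoarse, 1, tolerance = 0.05)
  vPure <- mkrun(2e-3, diffusion = FALSE)
  expect_equal(vPure, 1, tolerance = 0.05)
  vFine <- mkrun(1e-3)
  expect_lt(abs(vFine - vCoarse) / vCoarse, 0.02)
})

test_that("activation comparison metrics follow their definitions", {
  slab <- makeSlab(4e-3, 3e-3, 2e-3, 1e-3)
  n <- nNodes(slab)
  mkMap <- function(times) new("ActivationMap", times = times,
                               stimulusNodes = which(times == 0),
                               iterations = 1L, converged = TRUE)
  u <- (nodeCoords(slab)[, 1]) / 1  # linear ramp, zero on the x = 0 face
  a <- mkMap(u)
  same <- compareActivation(a, mkMap(u))
  expect_identical(same$err_TAT, 0)
  expect_identical(same$max_err_AT, 0)
  expect_identical(same$vol_gt10, 0)
  # constructed: exactly 2 of 200 nodes beyond 10% relative error
  u200 <- c(0, seq_len(199) / 199) * 0.1
  b200 <- u200
  b200[c(50, 60)] <- b200[c(50, 60)] + 0.2 * max(u200)
  cmp <- compareActivation(mkMap(u200), mkMap(b200))
  expect_equal(cmp$vol_gt10, 2 / 200 * 100)
  # uniform 5% inflation: no node beyond 10%, TAT error = 5%
  infl <- compareActivation(a, mkMap(1.05 * u))
  expect_identical(infl$vol_gt10, 0)
  expect_equal(infl$err_TAT, 0.05 * max(u), tolerance = 1e-12)
  expect_error(compareActivation(a, mkMap(u200)), "different meshes")
})
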
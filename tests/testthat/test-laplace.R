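# Harmonic solver: affine exactness, closed-form shells, gradient recovery,
# maximum principle and determinism of the distance catalog.

test_that("P1 solve reproduces affine solutions to machine precision", {
  slab <- makeSlab(5e-3, 3e-3, 2e-3, 1e-3)
  u <- solveLaplace(slab, list(
    list(nodes = tagNodes(slab, "dirichlet_a"), value = 0),
    list(nodes = tagNodes(slab, "dirichlet_b"), value = 1)))
  expect_rows_equal(u, nodeCoords(slab)[, 1] / 5e-3, tol = 1e-12)
})

test_that("equal Dirichlet data yields the constant field", {
  slab <- makeSlab(4e-3, 3e-3, 2e-3, 1e-3)
  u <- solveLaplace(slab, list(
    list(nodes = tagNodes(slab, "dirichlet_a"), value = 0.7),
    list(nodes = tagNodes(slab, "dirichlet_b"), value = 0.7)))
  expect_rows_equal(u, rep(0.7, nNodes(slab)), tol = 1e-12)
})

test_that("hollow-sphere solve matches the radial closed form", {
  sh <- makeAtrialShell("la", rEndo = 1, rEpi = 2, orificeSpec = list(),
                        level = 2, nLayers = 2)
  r <- sqrt(rowSums(nodeCoords(sh)^2))
  inner <- which(abs(r - 1) < 1e-9)
  outer <- which(abs(r - 2) < 1e-9)
  u <- solveLaplace(sh, list(list(nodes = inner, value = 1),
                             list(nodes = outer, value = 0)))
  exact <- (1 / r - 1 / 2) / (1 - 1 / 2)
  expect_lt(max(abs(u - exact)), 0.01)   # O(h^2) at this resolution
  # recovered gradient approaches -rhat * |dchi/dr| at first order
  gradErr <- function(level, nLayers) {
    shf <- makeAtrialShell("la", rEndo = 1, rEpi = 2, orificeSpec = list(),
                           level = level, nLayers = nLayers)
    rf <- sqrt(rowSums(nodeCoords(shf)^2))
    uf <- solveLaplace(shf, list(
      list(nodes = which(abs(rf - 1) < 1e-9), value = 1),
      list(nodes = which(abs(rf - 2) < 1e-9), value = 0)))
    gf <- nodalGradient(shf, uf)
    interior <- rf > 1.2 & rf < 1.8
    ex <- -nodeCoords(shf)[interior, ] / rf[interior] * (2 / rf[interior]^2)
    max(abs(gf$gradient[interior, ] - ex))
  }
  eC <- gradErr(2, 4)
  eF <- gradErr(3, 6)
  expect_lt(eF, 0.1)
  expect_gt(eC / eF, 1.6)   # roughly halves under refinement
})

test_that("gradient recovery is exact for affine fields and flags constants", {
  slab <- makeSlab(5e-3, 3e-3, 2e-3, 1e-3)
  a <- c(3, -2, 5)
  f <- nodeCoords(slab) %*% a + 1
  g <- nodalGradient(slab, as.numeric(f))
  expect_rows_equal(g$gradient, matrix(rep(a, each = nNodes(slab)), ncol = 3),
                    tol = 1e-9)
  expect_false(any(g$degenerate))
  gc <- nodalGradient(slab, rep(2.5, nNodes(slab)))
  expect_true(all(gc$degenerate))
  expect_rows_equal(gc$gradient, matrix(0, nNodes(slab), 3), tol = 1e-20)
})

test_that("solver errors on missing Dirichlet data and dangling components", {
  slab <- makeSlab(4e-3, 3e-3, 2e-3, 1e-3)
  expect_error(solveLaplace(slab, list()), "Dirichlet")
  open <- makeBiatrialToy(withSeptum = FALSE)
  laN <- tagNodes(open, "la_endo")
  expect_error(solveLaplace(open, list(list(nodes = laN, value = 1))),
               "component")
})

test_that("distance catalog obeys the discrete maximum principle", {
  ds <- toyDistances()
  ranges <- list(xi = c(-1, 1), phi = c(-1, 1),
                 la.psi_v = c(0, 1), la.psi_r = c(0, 1), la.psi_w = c(-1, 1),
                 la.psi_ab = c(-1, 2), la.psi_aa = c(-2, 1), la.psi_s = c(-1, 1),
                 ra.psi_v = c(0, 1), ra.psi_r = c(0, 1), ra.psi_ab = c(-2, 2),
                 ra.psi_a = c(-1, 2), ra.psi_aa = c(-2, 1), ra.psi_ct = c(-1, 1))
  for (nm in names(ranges)) {
    f <- distanceField(ds, nm)
    expect_gte(min(f), ranges[[nm]][1] - 1e-10)
    expect_lte(max(f), ranges[[nm]][2] + 1e-10)
  }
})

test_that("catalog boundary values and monotone structure on the toy", {
  toy <- toyFixture()
  ds <- toyDistances()
  xi <- distanceField(ds, "xi")
  laEndo <- unique(unlist(lapply(c("la_endo", "la_endo_sept", "la_endo_lat"),
                                 tagNodes, x = toy)))
  raEndo <- unique(unlist(lapply(c("ra_endo", "ra_endo_ant", "ra_endo_post"),
                                 tagNodes, x = toy)))
  expect_rows_equal(xi[laEndo], rep(1, length(laEndo)), tol = 1e-10)
  expect_rows_equal(xi[raEndo], rep(-1, length(raEndo)), tol = 1e-10)
  other <- setdiff(seq_len(nNodes(toy)), c(laEndo, raEndo))
  expect_true(all(xi[other] > -1 & xi[other] < 1))
  # phi_la is 0 on the LA endocardium, 1 on the epicardium
  phiLa <- distanceField(ds, "phi_la")
  expect_rows_equal(phiLa[laEndo], rep(0, length(laEndo)), tol = 1e-10)
  epiN <- tagNodes(toy, "epi")
  expect_rows_equal(phiLa[intersect(epiN, which(xi > 0.5))],
                    rep(1, sum(xi[epiN] > 0.5)), tol = 1e-10)
  # psi_v: 1 on RPV rims, 0 on LPV rims
  pv <- distanceField(ds, "la.psi_v")
  rpvN <- unique(unlist(lapply(c("rspv", "ripv"), tagNodes, x = toy)))
  lpvN <- unique(unlist(lapply(c("lspv", "lipv"), tagNodes, x = toy)))
  expect_rows_equal(pv[rpvN], rep(1, length(rpvN)), tol = 1e-10)
  expect_rows_equal(pv[lpvN], rep(0, length(lpvN)), tol = 1e-10)
})

test_that("repeated solves are bitwise identical", {
  slab <- makeSlab(5e-3, 3e-3, 2e-3, 1e-3)
  dir <- list(list(nodes = tagNodes(slab, "endo"), value = 1),
              list(nodes = tagNodes(slab, "epi"), value = 0))
  expect_identical(solveLaplace(slab, dir), solveLaplace(slab, dir))
})
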
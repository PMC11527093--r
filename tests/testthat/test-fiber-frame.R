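# Local frame algebra and fiber generation.

test_that("axisSystem matches hand-computed frames and flags degeneracy", {
  fr <- axisSystem(c(0, 0, 2), c(1, 0, 0))
  expect_rows_equal(fr$et, matrix(c(0, 0, 1), 1))
  expect_rows_equal(fr$en, matrix(c(1, 0, 0), 1))
  expect_rows_equal(fr$el, matrix(c(0, -1, 0), 1))
  expect_false(fr$degenerate)
  # Gram-Schmidt removes the transmural component of k
  fr2 <- axisSystem(c(0, 0, 1), c(1, 0, 1))
  expect_rows_equal(fr2$en, matrix(c(1, 0, 0), 1), tol = 1e-12)
  expect_rows_equal(fr2$el, matrix(c(0, -1, 0), 1), tol = 1e-12)
  # degenerate inputs
  expect_true(axisSystem(c(0, 0, 1), c(0, 0, 3))$degenerate)
  expect_true(axisSystem(c(0, 0, 0), c(1, 0, 0))$degenerate)
})

test_that("orientFrame: identity, quarter turn and composition", {
  set.seed(42)
  fr <- randomFrames(200)
  expect_false(any(fr$degenerate))
  id <- orientFrame(fr, 0, 0)
  expect_rows_equal(id$f, fr$el, tol = 1e-12)
  expect_rows_equal(id$n, fr$en, tol = 1e-12)
  expect_rows_equal(id$s, fr$et, tol = 1e-12)
  q <- orientFrame(fr, 90, 90)
  expect_rows_equal(q$f, fr$en, tol = 1e-12)
  expect_rows_equal(q$n, -fr$el, tol = 1e-12)
  # composition: rotating by a1 then a2 equals rotating by a1 + a2
  a1 <- 37.5; a2 <- -58.25
  once <- orientFrame(fr, a1, a1)
  frameOnce <- list(el = once$f, en = once$n, et = once$s)
  twice <- orientFrame(frameOnce, a2, a2)
  direct <- orientFrame(fr, a1 + a2, a1 + a2)
  expect_rows_equal(twice$f, direct$f, tol = 1e-10)
  expect_rows_equal(twice$s, direct$s, tol = 1e-10)
})

test_that("uniform slab fibers follow the prescribed gradients", {
  slab <- makeSlab(5e-3, 4e-3, 2e-3, 1e-3)
  n <- nNodes(slab)
  x <- nodeCoords(slab)
  ds <- manualDistanceSet(slab, list(phi = x[, 3] / 2e-3, psi = x[, 2] / 4e-3))
  asn <- uniformAssignment(n, gamma = "phi", kEndo = "psi")
  fib <- generateFibers(slab, ds, asn)
  # gamma = z-hat, k = y-hat -> et = z, en = y, el = y x z = x
  expect_rows_equal(fib@f, matrix(rep(c(1, 0, 0), each = n), ncol = 3), tol = 1e-9)
  expect_rows_equal(fib@s, matrix(rep(c(0, 0, 1), each = n), ncol = 3), tol = 1e-9)
  # determinism
  fib2 <- generateFibers(slab, ds, asn)
  expect_identical(fib@f, fib2@f)
  expect_identical(fiberDiff(fib@f, fib2@f), rep(0, n))
})

test_that("two-layer rotation jumps by the angle difference at mid-wall", {
  slab <- makeSlab(5e-3, 4e-3, 2e-3, 5e-4)
  n <- nNodes(slab)
  x <- nodeCoords(slab)
  tcoord <- x[, 3] / 2e-3        # transmural coordinate, endo at z = lz
  ds <- manualDistanceSet(slab, list(phi = tcoord, psi = x[, 2] / 4e-3))
  layer <- ifelse(tcoord > 0.5, "endo", "epi")
  asn <- uniformAssignment(n, gamma = "phi", kEndo = "psi",
                           aEndo = 60, aEpi = -60, layer = layer)
  fib <- generateFibers(slab, ds, asn)
  frame <- list(el = fib@el, en = fib@en, et = fib@et)
  ang <- fiberAngle(embedInFrame(fib@f, frame)$f, frame)
  expect_rows_equal(ang[layer == "endo"], rep(60, sum(layer == "endo")), tol = 1e-8)
  expect_rows_equal(ang[layer == "epi"], rep(-60, sum(layer == "epi")), tol = 1e-8)
})

test_that("flip negates longitudinal and transmural axes before rotation", {
  slab <- makeSlab(5e-3, 4e-3, 2e-3, 1e-3)
  n <- nNodes(slab)
  x <- nodeCoords(slab)
  ds <- manualDistanceSet(slab, list(phi = x[, 3] / 2e-3, psi = x[, 2] / 4e-3))
  plain <- generateFibers(slab, ds, uniformAssignment(n, kEndo = "psi"))
  flipped <- generateFibers(slab, ds,
                            uniformAssignment(n, bundle = "BB_IC",
                                              kEndo = "psi", flip = TRUE))
  expect_rows_equal(flipped@f, -plain@f, tol = 1e-12)
  expect_rows_equal(flipped@s, -plain@s, tol = 1e-12)
  # axially invariant difference is zero
  expect_rows_equal(fiberDiff(flipped@f, plain@f), rep(0, n), tol = 1e-12)
})

test_that("toy fibers are orthonormal, right-handed and bundle-smooth", {
  fib <- toyFibers()
  f <- fib@f; s <- fib@s; nn <- fib@n
  expect_lt(max(abs(sqrt(rowSums(f^2)) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(f * s))), 1e-8)
  expect_lt(max(abs(rowSums(f * nn))), 1e-8)
  cx <- cbind(f[, 2] * nn[, 3] - f[, 3] * nn[, 2],
              f[, 3] * nn[, 1] - f[, 1] * nn[, 3],
              f[, 1] * nn[, 2] - f[, 2] * nn[, 1])
  expect_lt(max(abs(cx - s)), 1e-8)        # right-handed: f x n = s
  # smoothness smoke test: within one bundle and layer the fiber field is
  # coherent in the bulk (adjacent angles < 45 degrees); frames rotate
  # rapidly only around ring/landmark singularities of the harmonic fields
  toy <- toyFixture()
  e <- atrialLDRBM:::meshEdges(tetConn(toy))
  same <- fib@bundle[e[, 1]] == fib@bundle[e[, 2]] &
    fib@layer[e[, 1]] == fib@layer[e[, 2]]
  dots <- abs(rowSums(f[e[same, 1], ] * f[e[same, 2], ]))
  expect_gt(mean(dots > cos(45 * pi / 180)), 0.95)
  expect_gt(stats::median(dots), cos(20 * pi / 180))
})
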
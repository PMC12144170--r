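test_that("zero applied force gives zero displacement", {
  m <- barMesh(2, 2, 4)
  lc <- loadCase("null", dirichlet = list(set = "DISTAL_FIX"))
  sol <- assembleAndSolve(m, uniformMaterials(m), lc)
  expect_lt(max(abs(displacements(sol))), 1e-14)
  expect_lt(max(abs(strainTensors(sol))), 1e-14)
})

test_that("the axial bar matches F*L/(E*A) to near machine precision", {
  F <- 100; E <- 1000; A <- 16; L <- 20
  for (ord in 1:2) {
    m <- barMesh(4, 4, 20, h = 1, order = ord)
    w <- faceTributaryWeights(m, "PROXIMAL_LOAD")
    lc <- loadCase("axial", dirichlet = list(set = "DISTAL_FIX"),
                   neumann = list(list(set = "PROXIMAL_LOAD",
                                       force = c(0, 0, F), weights = w)))
    sol <- assembleAndSolve(m, uniformMaterials(m, E = E, nu = 0), lc)
    tip <- nodeSets(m)$PROXIMAL_LOAD
    expect_equal(mean(displacements(sol)[tip, 3]), F * L / (E * A),
                 tolerance = 1e-10)
    ## constant uniaxial strain field, exactly representable
    expect_equal(unname(strainTensors(sol)[, "zz"]),
                 rep(F / (E * A), nrow(strainTensors(sol))),
                 tolerance = 1e-9)
    off <- strainTensors(sol)[, c("xy", "yz", "zx")]
    expect_lt(max(abs(off)), 1e-12)
    ## uniaxial stress with nu = 0: lateral normal stresses vanish
    expect_lt(max(abs(stressTensors(sol)[, c("xx", "yy")])), 1e-9)
  }
})

test_that("the patch test reproduces a linear field exactly", {
  m <- barMesh(3, 3, 3)
  nd <- meshNodes(m)
  hull <- which(nd[, 1] %in% range(nd[, 1]) |
                nd[, 2] %in% range(nd[, 2]) |
                nd[, 3] %in% range(nd[, 3]))
  m@nodeSets$HULL <- hull
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                2e-4, -5e-4, 3e-4,
                -1e-4, 3e-4, 8e-4), 3, 3)  # symmetric gradient
  b <- c(0.01, -0.02, 0.005)
  ufun <- function(x) x %*% t(A) + rep(b, each = nrow(x))
  lc <- loadCase("patch",
                 dirichlet = list(set = "HULL",
                                  value = ufun(nd[hull, , drop = FALSE])))
  sol <- assembleAndSolve(m, uniformMaterials(m, E = 500, nu = 0.3), lc)
  expect_equal(unname(displacements(sol)), unname(ufun(nd)),
               tolerance = 1e-10)
  eps_exact <- (A + t(A)) / 2
  voigt <- c(eps_exact[1, 1], eps_exact[2, 2], eps_exact[3, 3],
             eps_exact[1, 2], eps_exact[2, 3], eps_exact[1, 3])
  for (k in 1:6)
    expect_equal(unname(strainTensors(sol)[, k]),
                 rep(voigt[k], nrow(strainTensors(sol))),
                 tolerance = 1e-9)
})

test_that("rigid translation produces zero strain", {
  m <- barMesh(2, 2, 4)
  lc <- loadCase("rigid",
                 dirichlet = list(set = "DISTAL_FIX",
                                  value = c(0.5, -0.2, 0.1)))
  ## also pin the far end to the same translation: still rigid
  lc2 <- loadCase("rigid",
                  dirichlet = list(
                    list(set = "DISTAL_FIX", value = c(0.5, -0.2, 0.1)),
                    list(set = "PROXIMAL_LOAD", value = c(0.5, -0.2, 0.1))))
  for (l in list(lc, lc2)) {
    sol <- assembleAndSolve(m, uniformMaterials(m, nu = 0.25), l)
    expect_lt(max(abs(strainTensors(sol))), 1e-12)
  }
})

test_that("the solution is linear in the applied load", {
  m <- barMesh(3, 3, 6)
  mat <- uniformMaterials(m, E = 2000, nu = 0.3)
  mk <- function(alpha)
    loadCase("l", dirichlet = list(set = "DISTAL_FIX"),
             neumann = list(list(set = "PROXIMAL_LOAD",
                                 force = alpha * c(10, -5, -50))))
  s1 <- assembleAndSolve(m, mat, mk(1))
  s3 <- assembleAndSolve(m, mat, mk(3))
  expect_equal(3 * displacements(s1), displacements(s3),
               tolerance = 1e-10)
  expect_equal(3 * strainTensors(s1), strainTensors(s3),
               tolerance = 1e-10)
  expect_equal(3 * stressTensors(s1), stressTensors(s3),
               tolerance = 1e-10)
  expect_equal(3 * reactionForces(s1), reactionForces(s3),
               tolerance = 1e-10)
})

test_that("reactions balance applied loads to tight relative tolerance", {
  cv <- generateConstruct(smallSpec())
  seg <- thresholdSegment(cv$volume, defaultThresholdTable())
  m <- voxelsToTetMesh(seg)
  m <- defineCuboidNodeset(m, "DISTAL_FIX", c(-10, 10, -10, 10, -1, 2))
  m <- defineCuboidNodeset(m, "PROXIMAL_LOAD",
                           c(-10, 10, -10, 10, 38, 41))
  mat <- assignMaterials(m, cv$volume, seg)
  lc <- loadCase("walk", dirichlet = list(set = "DISTAL_FIX"),
                 neumann = list(list(set = "PROXIMAL_LOAD",
                                     force = c(30, 0, -300))))
  sol <- assembleAndSolve(m, mat, lc)
  expect_lt(equilibriumResidual(sol, m), 1e-8)
  ## prescribed values reproduced exactly on constrained dofs
  fix <- nodeSets(m)$DISTAL_FIX
  expect_identical(max(abs(displacements(sol)[fix, ])), 0)
})

test_that("the solution is frame-objective under rigid rotation", {
  set.seed(5)
  Q <- randomRotation()
  m <- barMesh(2, 2, 6)
  mat <- uniformMaterials(m, E = 800, nu = 0.3)
  f <- c(5, 2, -40)
  lc <- loadCase("l", dirichlet = list(set = "DISTAL_FIX"),
                 neumann = list(list(set = "PROXIMAL_LOAD", force = f)))
  sol <- assembleAndSolve(m, mat, lc)
  ## rotate geometry and load
  mr <- m
  mr@nodes <- m@nodes %*% t(Q)
  lcr <- loadCase("l", dirichlet = list(set = "DISTAL_FIX"),
                  neumann = list(list(set = "PROXIMAL_LOAD",
                                      force = as.numeric(Q %*% f))))
  solr <- assembleAndSolve(mr, mat, lcr)
  expect_equal(unname(displacements(solr)),
               unname(displacements(sol) %*% t(Q)), tolerance = 1e-9)
  ## stress rotates as a tensor: von Mises is unchanged
  expect_equal(vonMises(stressTensors(solr)),
               vonMises(stressTensors(sol)), tolerance = 1e-9)
})

test_that("insufficient constraints are rejected with the mode count", {
  m <- barMesh(2, 2, 4)
  nd <- meshNodes(m)
  m@nodeSets$ONE <- 1L
  lc <- loadCase("bad", dirichlet = list(set = "ONE"))
  expect_error(assembleAndSolve(m, uniformMaterials(m), lc),
               "3 unconstrained rigid-body mode")
  ## constraining one axis only leaves more modes
  lcz <- loadCase("badz", dirichlet = list(set = "DISTAL_FIX",
                                           axes = 3L))
  expect_error(assembleAndSolve(m, uniformMaterials(m), lcz),
               "unconstrained rigid-body mode")
})

test_that("cantilever deflection converges monotonically to beam theory", {
  a <- 4; L <- 40; E <- 1000; F <- 1
  I <- a^4 / 12
  eb <- F * L^3 / (3 * E * I)
  tip <- function(h, ord) {
    m <- barMesh(a / h, a / h, L / h, h = h, order = ord)
    lc <- loadCase("tip", dirichlet = list(set = "DISTAL_FIX"),
                   neumann = list(list(set = "PROXIMAL_LOAD",
                                       force = c(F, 0, 0))))
    sol <- assembleAndSolve(m, uniformMaterials(m, E = E, nu = 0), lc)
    mean(displacements(sol)[nodeSets(m)$PROXIMAL_LOAD, 1])
  }
  err1 <- vapply(c(2, 1, 0.5), function(h) abs(tip(h, 1) - eb) / eb,
                 numeric(1))
  expect_true(all(diff(err1) < 0))          # monotone error decay
  expect_lt(err1[3], 0.10)                  # finest mesh within 10 %
  err2 <- abs(tip(2, 2) - eb) / eb
  expect_lt(err2, err1[1])                  # order 2 strictly better
  expect_lt(err2, 0.10)
})

test_that("the iterative solver agrees with the direct factorization", {
  cv <- generateConstruct(smallSpec())
  seg <- thresholdSegment(cv$volume, defaultThresholdTable())
  m <- voxelsToTetMesh(seg)
  m <- defineCuboidNodeset(m, "DISTAL_FIX", c(-10, 10, -10, 10, -1, 2))
  m <- defineCuboidNodeset(m, "PROXIMAL_LOAD",
                           c(-10, 10, -10, 10, 38, 41))
  mat <- assignMaterials(m, cv$volume, seg)
  lc <- loadCase("walk", dirichlet = list(set = "DISTAL_FIX"),
                 neumann = list(list(set = "PROXIMAL_LOAD",
                                     force = c(30, 0, -300))))
  sd_ <- assembleAndSolve(m, mat, lc, method = "direct")
  si <- assembleAndSolve(m, mat, lc, method = "cg")
  scale <- max(abs(displacements(sd_)))
  expect_lt(max(abs(displacements(sd_) - displacements(si))) / scale,
            1e-7)
})

test_that("a mesh read from an .inp file solves identically", {
  m <- barMesh(2, 2, 6)
  f <- tempfile(fileext = ".inp")
  writeInp(m, f)
  m2 <- readInp(f)
  lc <- loadCase("axial", dirichlet = list(set = "DISTAL_FIX"),
                 neumann = list(list(set = "PROXIMAL_LOAD",
                                     force = c(0, 0, 10))))
  s1 <- assembleAndSolve(m, uniformMaterials(m), lc)
  s2 <- assembleAndSolve(m2, uniformMaterials(m2), lc)
  expect_equal(displacements(s1), displacements(s2), tolerance = 1e-12)
})
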
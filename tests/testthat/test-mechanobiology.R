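test_that("strain invariants match hand-computed values", {
  ## pure volumetric state: no distortion
  inv <- strainInvariants(diag(c(0.05, 0.05, 0.05)))
  expect_equal(inv$gamma_oct, 0, tolerance = 1e-15)
  expect_equal(inv$eps_vol, 0.15, tolerance = 1e-15)
  ## uniaxial strain: gamma_oct = (2/3) sqrt(2) * 0.03
  inv <- strainInvariants(diag(c(0.03, 0, 0)))
  expect_equal(inv$gamma_oct, 2 / 3 * sqrt(2) * 0.03, tolerance = 1e-12)
  expect_equal(inv$eps_vol, 0.03, tolerance = 1e-15)
  ## trace of a mixed state
  inv <- strainInvariants(diag(c(0.01, -0.02, 0.005)))
  expect_equal(inv$eps_vol, -0.005, tolerance = 1e-15)
  ## principal-strain formula oracle on a non-diagonal tensor
  set.seed(2)
  S <- matrix(rnorm(9, sd = 0.02), 3, 3)
  eps <- (S + t(S)) / 2
  ev <- eigen(eps, symmetric = TRUE)$values
  oracle <- (2 / 3) * sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                           (ev[3] - ev[1])^2)
  inv <- strainInvariants(eps)
  expect_equal(inv$gamma_oct, oracle, tolerance = 1e-12)
  expect_equal(inv$eps_vol, sum(ev), tolerance = 1e-12)
})

test_that("von Mises stress matches its defining cases", {
  expect_equal(vonMises(diag(c(-80, -80, -80))), 0, tolerance = 1e-12)
  expect_equal(vonMises(diag(c(100, 0, 0))), 100, tolerance = 1e-12)
  s <- matrix(0, 3, 3); s[1, 2] <- s[2, 1] <- 50
  expect_equal(vonMises(s), 50 * sqrt(3), tolerance = 1e-12)
})

test_that("asymmetric tensors are rejected", {
  bad <- matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(strainInvariants(bad), "symmetric")
  expect_error(vonMises(bad), "symmetric")
})

test_that("invariants are frame-invariant under random rotations", {
  set.seed(17)
  S <- matrix(rnorm(9, sd = 0.03), 3, 3)
  eps <- (S + t(S)) / 2
  T <- matrix(rnorm(9, sd = 40), 3, 3)
  sig <- (T + t(T)) / 2
  inv0 <- strainInvariants(eps)
  vm0 <- vonMises(sig)
  for (k in seq_len(200)) {
    Q <- randomRotation()
    invq <- strainInvariants(Q %*% eps %*% t(Q))
    expect_lt(abs(invq$gamma_oct - inv0$gamma_oct) /
              max(inv0$gamma_oct, 1e-300), 1e-10)
    expect_lt(abs(invq$eps_vol - inv0$eps_vol) /
              max(abs(inv0$eps_vol), 1e-300), 1e-10)
    vmq <- vonMises(Q %*% sig %*% t(Q))
    expect_lt(abs(vmq - vm0) / vm0, 1e-10)
  }
})

test_that("zone configs are validated", {
  expect_error(healingZoneConfig(gamma_low = 0), "gamma_low")
  expect_error(healingZoneConfig(gamma_im = 0.2), "gamma_im")
  expect_error(healingZoneConfig(gamma_ec = Inf), "finite")
})

test_that("zone assignment matches a pointwise membership oracle on a grid", {
  cfg <- healingZoneConfig()
  ## independent pointwise rule table (nested rectangles, <= on upper
  ## bounds, innermost wins)
  oracle <- function(g, v) {
    if (g < cfg$gamma_low && abs(v) < cfg$eps_low) return("understimulated")
    if (g <= cfg$gamma_im && v >= -cfg$eps_im && v <= cfg$eps_im)
      return("intramembranous")
    if (g <= cfg$gamma_ec && v >= cfg$eps_ec_compressive &&
        v <= cfg$eps_ec_tensile) return("endochondral")
    "excessive"
  }
  gs <- seq(0, 0.2, length.out = 200)
  vs <- seq(-0.2, 0.1, length.out = 200)
  grid <- expand.grid(g = gs, v = vs)
  got <- healingZone(grid$g, grid$v, cfg)
  want <- mapply(oracle, grid$g, grid$v)
  expect_identical(got, unname(want))
})

test_that("boundary states take the lower-strain zone and fractions partition", {
  cfg <- healingZoneConfig()
  expect_identical(healingZone(cfg$gamma_im, 0, cfg), "intramembranous")
  expect_identical(healingZone(cfg$gamma_ec, 0, cfg), "endochondral")
  expect_identical(healingZone(cfg$gamma_low, 0, cfg), "intramembranous")
  ## classify a synthetic solution: fractions sum to 1, both weightings
  cv <- generateConstruct(smallSpec())
  seg <- thresholdSegment(cv$volume, defaultThresholdTable())
  m <- voxelsToTetMesh(seg)
  m <- defineCuboidNodeset(m, "DISTAL_FIX", c(-10, 10, -10, 10, -1, 2))
  m <- defineCuboidNodeset(m, "PROXIMAL_LOAD",
                           c(-10, 10, -10, 10, 38, 41))
  mat <- assignMaterials(m, cv$volume, seg)
  lc <- loadCase("walk", dirichlet = list(set = "DISTAL_FIX"),
                 neumann = list(list(set = "PROXIMAL_LOAD",
                                     force = c(50, 0, -500))))
  sol <- assembleAndSolve(m, mat, lc)
  hw <- classifyHealing(sol, m)
  expect_equal(sum(zoneFractions(hw, "volume")), 1, tolerance = 1e-12)
  expect_equal(sum(zoneFractions(hw, "count")), 1, tolerance = 1e-12)
  ## uniform element volumes on the voxel mesh: both weightings coincide
  expect_equal(zoneFractions(hw, "volume"), zoneFractions(hw, "count"),
               tolerance = 1e-12)
  expect_equal(healingWindowFraction(hw, "volume"),
               sum(zoneFractions(hw)[c("intramembranous",
                                       "endochondral")]),
               tolerance = 1e-15)
})

test_that("a uniform strain state classifies wholly into one zone", {
  m <- barMesh(2, 2, 2)
  m@elementRegion[] <- "callus"
  n <- nrow(meshElements(m))
  eps <- matrix(0, n, 6)
  eps[, 4] <- 0.015  # tensor shear -> gamma_oct = 0.0245, eps_vol 0
  sol <- new("FESolution", displacements = matrix(0, nrow(meshNodes(m)), 3),
             strain = eps, stress = eps, reactions = matrix(0, 0, 3),
             loadCase = list(name = "synthetic"))
  hw <- classifyHealing(sol, m)
  expect_identical(unique(hw@zone), "intramembranous")
  expect_equal(unname(healingWindowFraction(hw)), 1, tolerance = 1e-15)
})

test_that("classifyHealing rejects meshes without a callus region", {
  m <- barMesh(2, 2, 2)
  sol <- new("FESolution",
             displacements = matrix(0, nrow(meshNodes(m)), 3),
             strain = matrix(0, nrow(meshElements(m)), 6),
             stress = matrix(0, nrow(meshElements(m)), 6),
             reactions = matrix(0, 0, 3), loadCase = list(name = "x"))
  expect_error(classifyHealing(sol, m), "no fracture region")
})

test_that("peak stress is the regional max with lowest-id tie-break", {
  m <- barMesh(2, 2, 4)
  n <- nrow(meshElements(m))
  stress <- matrix(0, n, 6)
  stress[, 1] <- seq_len(n)  # sigma_xx ramp
  stress[5, 1] <- 1000; stress[9, 1] <- 1000  # tie at the max
  sol <- new("FESolution", displacements = matrix(0, nrow(meshNodes(m)), 3),
             strain = stress, stress = stress,
             reactions = matrix(0, 0, 3), loadCase = list(name = "x"))
  pk <- peakStress(sol, m, "cortical")
  expect_equal(pk$sigma_vm_max, 1000)
  expect_identical(pk$element, 5L)
  expect_error(peakStress(sol, m, "nail"), "unknown or empty")
  ## region monotonicity: a subset region cannot exceed the whole
  m2 <- m
  m2@elementRegion[1:10] <- "sub"
  pk_sub <- peakStress(sol, m2, "sub")
  pk_all <- max(pk_sub$sigma_vm_max,
                peakStress(sol, m2, "cortical")$sigma_vm_max)
  expect_gte(pk_all, pk_sub$sigma_vm_max)
})
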
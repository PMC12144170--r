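## End-to-end case tests run on coarse variants of the shipped
## configurations (2 mm voxels, short shaft) so the whole suite stays
## fast; the full-resolution conditions are exercised in the acceptance
## tests.

test_that("baseline and revision differ only in the treatment parameter", {
  case <- caseDefinition("usecase1_nail_diameter", seed = 1)
  sb <- FractureTwin:::.variantSpec(case, "baseline")
  sr <- FractureTwin:::.variantSpec(case, "revision")
  diff_fields <- names(sb)[!mapply(identical, sb, sr)]
  expect_identical(diff_fields, "nail_radius")
  expect_identical(sb$nail_radius * 2, 8)   # 8 mm nail
  expect_identical(sr$nail_radius * 2, 11)  # 11 mm nail
})

test_that("an identical revision yields exactly zero stress reduction", {
  ov <- coarseOverrides()
  ov$revision <- list(nail_radius = 4.0)  # same as baseline
  res <- runCase(caseDefinition("usecase1_nail_diameter", seed = 1,
                                overrides = ov))
  d <- res$report@deltas$peak_stress$nail
  expect_identical(d$percent_reduction, 0)
  expect_identical(d$ratio, 1)
  expect_true(all(abs(unlist(res$report@deltas$zone_fractions)) == 0))
})

test_that("thickening the nail reduces its peak stress (coarse analogue)", {
  res <- runCase(caseDefinition("usecase1_nail_diameter", seed = 1,
                                overrides = coarseOverrides()))
  d <- res$report@deltas$peak_stress$nail
  expect_gt(d$percent_reduction, 0)
  expect_gt(d$ratio, 1)
})

test_that("identical case definition and seed give byte-identical reports", {
  ov <- coarseOverrides()
  d1 <- tempfile(); d2 <- tempfile()
  runCase(caseDefinition("usecase1_nail_diameter", seed = 3,
                         overrides = ov), out_dir = d1)
  runCase(caseDefinition("usecase1_nail_diameter", seed = 3,
                         overrides = ov), out_dir = d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  ## a different seed changes the noise field, hence the report
  d3 <- tempfile()
  runCase(caseDefinition("usecase1_nail_diameter", seed = 4,
                         overrides = ov), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "report.json")),
                         readLines(file.path(d3, "report.json"))))
})

test_that("augmentative plates share load: nail peak never increases", {
  for (nm in c("usecase2_plate_humerus_analogue",
               "usecase3_plate_femur_analogue")) {
    ov <- coarseOverrides()
    ov$revision <- list(plate = list(length = 30))
    res <- runCase(caseDefinition(nm, seed = 1, overrides = ov))
    d <- res$report@deltas$peak_stress$nail
    expect_lt(d$revised, d$baseline)
    zx <- res$report@deltas$zone_fractions$volume$excessive
    expect_lte(zx, 0)  # excessive-movement fraction does not increase
  }
})

test_that("strain-reduction screws do not worsen the torsional construct", {
  ov <- list(construct = list(bone_length = 60, voxel_spacing = 2),
             revision = list(screws = list(
               list(axial_offset = 8, axis = c(1, 0, 0), radius = 2,
                    length = 24),
               list(axial_offset = -8, axis = c(1, 0, 0), radius = 2,
                    length = 24))))
  res <- runCase(caseDefinition("usecase4_screw_torsion", seed = 1,
                                overrides = ov))
  d <- res$report@deltas$peak_stress$nail
  expect_lte(d$revised, d$baseline * (1 + 1e-9))
  expect_lte(res$report@deltas$zone_fractions$volume$excessive, 0)
})

test_that("scaling the load tenfold increases the excessive fraction", {
  ## full-length shaft at 2 mm voxels so gap strains are realistic
  ov <- list(construct = list(voxel_spacing = 2))
  base <- runCase(caseDefinition("usecase1_nail_diameter", seed = 1,
                                 overrides = ov))
  ov10 <- ov
  ov10$load <- list(axial_n = -15000, transverse_n = 1500)
  big <- runCase(caseDefinition("usecase1_nail_diameter", seed = 1,
                                overrides = ov10))
  x1 <- zoneFractions(base$baseline$healing)[["excessive"]]
  x10 <- zoneFractions(big$baseline$healing)[["excessive"]]
  expect_gt(x10, x1)
})

test_that("the wrist case restores the full deviation range", {
  res <- runCase(caseDefinition("usecase5_wrist", seed = 1,
                                overrides = list(sweep = list(step = 1))))
  expect_lt(res$baseline@ulnarLimit, 40)   # impingement preoperatively
  expect_equal(res$revised@ulnarLimit, 40) # full motion postoperatively
  expect_equal(res$revised@radialLimit, 40)
  expect_false(res$revised@contactAtNeutral)
})

test_that("stage errors propagate with the failing variant named", {
  ov <- coarseOverrides()
  ov$revision <- list(nail_radius = 10)  # exceeds the canal
  expect_error(runCase(caseDefinition("usecase1_nail_diameter", seed = 1,
                                      overrides = ov)),
               "variant 'revision'")
})

test_that("comparison arithmetic matches the reported clinical reductions", {
  ## synthetic single-region solutions with prescribed uniaxial peaks:
  ## 240 -> 78 MPa is a reduction of 67.5 % (a factor of about 3);
  ## 160 -> 30 MPa is 81.25 % (factor ~5.33)
  mkvariant <- function(peak) {
    m <- barMesh(2, 2, 2)
    m@elementRegion[] <- "nail"
    m@elementRegion[1:6] <- "callus"
    n <- nrow(meshElements(m))
    stress <- matrix(0, n, 6)
    stress[, 1] <- peak / 2
    stress[n, 1] <- peak
    sol <- new("FESolution",
               displacements = matrix(0, nrow(meshNodes(m)), 3),
               strain = stress * 1e-5, stress = stress,
               reactions = matrix(0, 0, 3),
               loadCase = list(name = "shared"))
    list(solution = sol, mesh = m,
         healing = classifyHealing(sol, m))
  }
  r1 <- compareTreatments(mkvariant(240), mkvariant(78))
  d1 <- r1@deltas$peak_stress$nail
  expect_equal(d1$percent_reduction, 67.5, tolerance = 1e-12)
  expect_equal(d1$ratio, 240 / 78, tolerance = 1e-12)
  expect_gt(d1$ratio, 3)  # "a factor of approximately 3"
  r2 <- compareTreatments(mkvariant(160), mkvariant(30))
  d2 <- r2@deltas$peak_stress$nail
  expect_equal(d2$percent_reduction, 81.25, tolerance = 1e-12)
  expect_equal(d2$ratio, 160 / 30, tolerance = 1e-12)
  ## self-comparison is the identity
  r0 <- compareTreatments(mkvariant(160), mkvariant(160))
  expect_identical(r0@deltas$peak_stress$nail$percent_reduction, 0)
  expect_identical(r0@deltas$peak_stress$nail$ratio, 1)
})

test_that("variants with different zone configs are rejected as incomparable", {
  m <- barMesh(2, 2, 2)
  m@elementRegion[] <- "callus"
  n <- nrow(meshElements(m))
  sol <- new("FESolution", displacements = matrix(0, nrow(meshNodes(m)), 3),
             strain = matrix(0, n, 6), stress = matrix(0, n, 6),
             reactions = matrix(0, 0, 3), loadCase = list(name = "x"))
  v1 <- list(solution = sol, mesh = m,
             healing = classifyHealing(sol, m))
  v2 <- list(solution = sol, mesh = m,
             healing = classifyHealing(sol, m,
                                       healingZoneConfig(gamma_im = 0.04)))
  expect_error(compareTreatments(v1, v2, regions = character(0)),
               "not comparable")
})
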
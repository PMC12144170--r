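test_that("deviation angles follow the arccos definition", {
  expect_equal(deviationAngle(c(0, 0, 1), c(0, 0, 2)), 0,
               tolerance = 1e-12)
  expect_equal(deviationAngle(c(1, 0, 0), c(0, 1, 0)), 90,
               tolerance = 1e-12)
  expect_equal(deviationAngle(c(1, 0, 0), c(1, 1, 0)), 45,
               tolerance = 1e-12)
  expect_error(deviationAngle(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("rigid rotation preserves edge lengths and enclosed volume", {
  sc <- generateWristScene()
  carp <- sc@carpalMesh
  rot <- rotateMesh(carp, c(3, -2, 7), c(1, 2, 2) / 3, 33)
  edgeLengths <- function(m) {
    v <- m@vertices; t <- m@triangles
    sqrt(rowSums((v[t[, 1], ] - v[t[, 2], ])^2))
  }
  expect_equal(edgeLengths(rot), edgeLengths(carp), tolerance = 1e-10)
  vol <- function(m) {
    v <- m@vertices; t <- m@triangles
    a <- v[t[, 1], ]; b <- v[t[, 2], ]; c <- v[t[, 3], ]
    sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
        a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  }
  expect_equal(abs(vol(rot)), abs(vol(carp)), tolerance = 1e-10)
  ## the carpal sphere volume approximates 4/3 pi r^3
  expect_equal(abs(vol(carp)), 4 / 3 * pi * 6^3, tolerance = 0.05 * 905)
})

test_that("a clearance scene is contact-free over the full sweep", {
  sc <- generateWristScene()
  r <- sweepContact(sc, step = 1)
  expect_false(any(r@contact))
  expect_equal(r@radialLimit, 40)
  expect_equal(r@ulnarLimit, 40)
  expect_null(r@firstContact)
})

test_that("scene generation rejects zero clearance", {
  expect_error(generateWristScene(carpal_radius = 10, carpal_offset = 24,
                                  cup_radius = 32), "clearance")
})

test_that("a prominence causes contact near its band, matching a dense oracle", {
  sc <- generateWristScene(prominence = list(angle_deg = 25,
                                             half_width_deg = 5,
                                             height_mm = 4))
  r <- sweepContact(sc, step = 0.5)
  expect_true(any(r@contact))
  expect_false(r@contactAtNeutral)
  expect_lt(r@ulnarLimit, 40)
  expect_equal(r@radialLimit, 40)  # radial side unaffected
  ## dense brute-force oracle on the same meshes at step / 10
  oracleFirst <- NA_real_
  for (th in seq(0, 40, by = 0.05)) {
    carp <- rotateMesh(sc@carpalMesh, sc@rotationCenter,
                       sc@rotationAxis, th)
    if (!is.null(meshContact(carp, sc@radiusMesh))) {
      oracleFirst <- th
      break
    }
  }
  expect_false(is.na(oracleFirst))
  expect_lte(abs(r@firstContact$angle - oracleFirst), 0.5)
  expect_lte(oracleFirst - r@ulnarLimit, 0.5 + 1e-9)
})

test_that("refining the step never shrinks the contact-free range by more than one step", {
  sc <- generateWristScene(prominence = list(angle_deg = 25,
                                             half_width_deg = 5,
                                             height_mm = 4))
  r1 <- sweepContact(sc, step = 1)
  r05 <- sweepContact(sc, step = 0.5)
  expect_gte(r05@ulnarLimit, r1@ulnarLimit - 1)
  expect_gte(r05@radialLimit, r1@radialLimit - 1)
})

test_that("mirror-symmetric scenes give equal radial and ulnar limits", {
  sc <- generateWristScene(cup_half_angle = 40)
  r <- sweepContact(sc, angle_range = c(-35, 35), step = 1)
  expect_equal(r@radialLimit, r@ulnarLimit)
})

test_that("the contact decision is invariant to triangle ordering", {
  sc <- generateWristScene(prominence = list(angle_deg = 25,
                                             half_width_deg = 5,
                                             height_mm = 4))
  carp <- rotateMesh(sc@carpalMesh, sc@rotationCenter, sc@rotationAxis,
                     25)
  hit0 <- !is.null(meshContact(carp, sc@radiusMesh))
  set.seed(9)
  perm <- sample(nrow(carp@triangles))
  carp_perm <- triMesh(carp@vertices, carp@triangles[perm, ])
  expect_identical(!is.null(meshContact(carp_perm, sc@radiusMesh)), hit0)
  ## vertex relabeling
  vperm <- sample(nrow(carp@vertices))
  inv <- integer(length(vperm)); inv[vperm] <- seq_along(vperm)
  carp_v <- triMesh(carp@vertices[vperm, ],
                    matrix(inv[carp@triangles], ncol = 3))
  expect_identical(!is.null(meshContact(carp_v, sc@radiusMesh)), hit0)
})

test_that("contact at neutral is reported, not raised", {
  sc <- generateWristScene(prominence = list(angle_deg = 0,
                                             half_width_deg = 10,
                                             height_mm = 6))
  r <- sweepContact(sc, step = 1)
  expect_true(r@contactAtNeutral)
  expect_equal(r@firstContact$angle, 0)
})

test_that("clearance epsilon detects near-contact", {
  sc <- generateWristScene()  # clearance 2 mm
  ## with eps above the clearance the carpal counts as contacting
  hit <- meshContact(sc@carpalMesh, sc@radiusMesh, eps = 3)
  expect_false(is.null(hit))
  expect_null(meshContact(sc@carpalMesh, sc@radiusMesh, eps = 0.5))
})
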
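## Fixtures are built in code at test time; no data files.

## uniform-property material table for a mesh
uniformMaterials <- function(mesh, E = 1000, nu = 0) {
  m <- nrow(meshElements(mesh))
  new("MaterialTable", E = rep(E, m), nu = rep(nu, m),
      provenance = rep("fixed-region", m), calibration = NULL)
}

## voxel-meshed rectangular bar along z with end node sets
barMesh <- function(nx = 4, ny = 4, nz = 20, h = 1, order = 1L) {
  lab <- asLabelMap(array(1L, dim = c(nx, ny, nz)),
                    legend = c("0" = "background", "1" = "cortical"),
                    spacing = rep(h, 3))
  m <- voxelsToTetMesh(lab, element_order = order)
  L <- nz * h
  m <- defineCuboidNodeset(m, "DISTAL_FIX",
                           c(-1, nx * h + 1, -1, ny * h + 1,
                             -1e-9, 1e-9))
  defineCuboidNodeset(m, "PROXIMAL_LOAD",
                      c(-1, nx * h + 1, -1, ny * h + 1,
                        L - 1e-9, L + 1e-9))
}

## small quick construct spec
smallSpec <- function(...) {
  args <- list(bone_length = 40, outer_radius = 6,
               cortical_thickness = 2, canal_radius = 3,
               gap_position = 20, gap_width = 4, nail_radius = 2.5,
               nail_length = 32, voxel_spacing = 2, noise_sd = 0,
               seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(constructSpec, args)
}

## uniformly distributed random rotation matrix (via QR of a Gaussian)
randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Voigt row (xx,yy,zz,xy,yz,zx) -> symmetric 3x3 tensor
voigtToTensor <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}

## coarse shipped-case overrides used across case tests
coarseOverrides <- function() {
  list(construct = list(bone_length = 60, voxel_spacing = 2))
}
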
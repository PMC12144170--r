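## Synthetic wrist scene for range-of-motion impingement analysis: a
## spherical articular cup on the distal radius analogue, a small ulna
## patch beside it, and the proximal carpal unit (scaphoid + lunate +
## triquetrum as one rigid body) idealized as a sphere carried at a
## fixed offset from the rotation center. An optional prominence (bony
## malalignment) indents the cup toward the carpal unit over a limited
## angular band, producing impingement near that band.

#' Construct a TriMesh
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @return a \linkS4class{TriMesh}.
#' @export
triMesh <- function(vertices, triangles) {
  new("TriMesh", vertices = as.matrix(vertices),
      triangles = matrix(as.integer(as.matrix(triangles)),
                         ncol = 3L))
}

## UV-sphere (full) centered at ctr
.uvSphere <- function(ctr, radius, n_theta = 16L, n_phi = 24L) {
  theta <- seq(0, pi, length.out = n_theta + 1L)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  verts <- list(ctr + c(0, 0, radius))
  idx <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  for (i in seq_len(n_theta - 1L))
    for (j in seq_len(n_phi))
      verts[[length(verts) + 1L]] <-
        ctr + radius * c(sin(theta[i + 1]) * cos(phi[j]),
                         sin(theta[i + 1]) * sin(phi[j]),
                         cos(theta[i + 1]))
  south <- length(verts) + 1L
  verts[[south]] <- ctr + c(0, 0, -radius)
  tris <- list()
  for (j in seq_len(n_phi)) {
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(south, idx(n_theta - 1L, j + 1L),
                                   idx(n_theta - 1L, j))
  }
  if (n_theta > 2L)
    for (i in seq_len(n_theta - 2L))
      for (j in seq_len(n_phi)) {
        a <- idx(i, j); b <- idx(i, j + 1L)
        c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
        tris[[length(tris) + 1L]] <- c(a, c2, d)
        tris[[length(tris) + 1L]] <- c(a, d, b)
      }
  triMesh(do.call(rbind, verts), do.call(rbind, tris))
}

## spherical patch of given radius about +z, polar angle <= half_angle,
## optionally indented by a prominence (inward radial displacement)
.sphericalCup <- function(radius, half_angle_deg, rotation_axis,
                          prominence = NULL, n_u = 36L, n_v = 18L) {
  ha <- half_angle_deg * pi / 180
  u <- seq(0, 2 * pi, length.out = n_u + 1L)[-(n_u + 1L)]
  v <- seq(ha / n_v, ha, length.out = n_v)  # exclude apex ring
  verts <- list(c(0, 0, radius))
  for (i in seq_along(v))
    for (j in seq_along(u))
      verts[[length(verts) + 1L]] <-
        c(sin(v[i]) * cos(u[j]), sin(v[i]) * sin(u[j]), cos(v[i]))
  V <- do.call(rbind, verts)
  V[-1, ] <- V[-1, ] * radius
  if (!is.null(prominence)) {
    ## inward indentation with quadratic falloff in great-circle angle
    ## from the band center direction (in the rotation plane)
    th_b <- prominence$angle_deg * pi / 180
    hw <- prominence$half_width_deg * pi / 180
    ## band center: arm direction rotated by th_b about rotation_axis
    R <- rotationMatrix(rotation_axis, prominence$angle_deg)
    ctr_dir <- as.numeric(R %*% c(0, 0, 1))
    dir <- V / sqrt(rowSums(V^2))
    dth <- acos(pmin(pmax(dir %*% ctr_dir, -1), 1))
    fall <- pmax(0, 1 - (as.numeric(dth) / hw)^2)
    V <- V * (1 - prominence$height_mm * fall / radius)
  }
  idx <- function(i, j) 1L + (i - 1L) * n_u + ((j - 1L) %% n_u) + 1L
  tris <- list()
  for (j in seq_len(n_u))
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  if (n_v > 1L)
    for (i in seq_len(n_v - 1L))
      for (j in seq_len(n_u)) {
        a <- idx(i, j); b <- idx(i, j + 1L)
        c2 <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
        tris[[length(tris) + 1L]] <- c(a, c2, d)
        tris[[length(tris) + 1L]] <- c(a, d, b)
      }
  triMesh(V, do.call(rbind, tris))
}

#' Generate a synthetic wrist scene
#'
#' The rotation center sits at the origin; the radius anatomical axis
#' and the neutral carpal arm point along +z; deviation rotates the
#' carpal unit about +y (positive = ulnar). The radius articular surface
#' is a spherical cup of radius \code{cup_radius} concave toward the
#' carpal sphere (radius \code{carpal_radius}, center at
#' \code{carpal_offset} along the arm), leaving a radial clearance of
#' \code{cup_radius - carpal_offset - carpal_radius} at every angle.
#' A prominence of height exceeding that clearance causes contact near
#' its angular position; without one, the sweep is contact-free by
#' construction.
#'
#' @param cup_radius articular cup radius (mm).
#' @param carpal_radius carpal-unit sphere radius (mm).
#' @param carpal_offset distance of the carpal sphere center from the
#'   rotation center (mm); \code{carpal_offset + carpal_radius} must be
#'   less than \code{cup_radius}.
#' @param cup_half_angle angular half-extent of the cup (deg).
#' @param prominence optional list with \code{angle_deg},
#'   \code{half_width_deg} and \code{height_mm}.
#' @param ulna_angle_deg angular position of the small ulna patch (deg,
#'   beyond the cup rim on the ulnar side).
#' @param resolution angular facet count of the generated surfaces.
#' @return a \linkS4class{RomScene}. The cup and ulna patch are open
#'   surfaces (flagged in \code{params$open_surfaces}); the carpal
#'   sphere is watertight.
#' @export
generateWristScene <- function(cup_radius = 32, carpal_radius = 6,
                               carpal_offset = 24, cup_half_angle = 60,
                               prominence = NULL, ulna_angle_deg = 75,
                               resolution = 36L) {
  clearance <- cup_radius - carpal_offset - carpal_radius
  if (!(clearance > 0))
    stop("no clearance: carpal_offset + carpal_radius must be < ",
         "cup_radius", call. = FALSE)
  if (!is.null(prominence) &&
      !all(c("angle_deg", "half_width_deg", "height_mm") %in%
           names(prominence)))
    stop("prominence needs angle_deg, half_width_deg, height_mm",
         call. = FALSE)
  rot_axis <- c(0, 1, 0)
  cup <- .sphericalCup(cup_radius, cup_half_angle, rot_axis, prominence,
                       n_u = resolution, n_v = resolution %/% 2L)
  carpal <- .uvSphere(c(0, 0, carpal_offset), carpal_radius,
                      n_theta = resolution %/% 2L, n_phi = resolution)
  ## small ulna patch beyond the cup rim on the ulnar (+x) side
  Ru <- rotationMatrix(rot_axis, ulna_angle_deg)
  ulna_ctr <- as.numeric(Ru %*% c(0, 0, cup_radius))
  sz <- carpal_radius
  b1 <- as.numeric(Ru %*% c(sz, 0, 0))
  b2 <- c(0, sz, 0)
  ulna <- triMesh(rbind(ulna_ctr - b1 - b2, ulna_ctr + b1 - b2,
                        ulna_ctr + b1 + b2, ulna_ctr - b1 + b2),
                  rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  new("RomScene", radiusMesh = cup, ulnaMesh = ulna,
      carpalMesh = carpal, rotationCenter = c(0, 0, 0),
      rotationAxis = rot_axis, radiusAxis = c(0, 0, 1),
      prominence = prominence,
      params = list(cup_radius = cup_radius,
                    carpal_radius = carpal_radius,
                    carpal_offset = carpal_offset,
                    cup_half_angle = cup_half_angle,
                    clearance = clearance,
                    ulna_angle_deg = ulna_angle_deg,
                    resolution = resolution,
                    open_surfaces = c(radius = TRUE, ulna = TRUE,
                                      carpal = FALSE)))
}
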
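## Rigid-body range-of-motion sweep with impingement detection. All
## bodies are rigid for the contact query; contact is exact
## triangle-triangle intersection (separating-axis test) with an
## optional clearance epsilon evaluated as exact triangle-triangle
## distance.

#' Angle between the radius axis and a carpal motion vector
#'
#' @param radius_axis anatomical axis of the radius (nonzero vector).
#' @param motion_vector combined motion vector of the proximal carpal
#'   unit (nonzero vector).
#' @return deviation angle in degrees, in [0, 180].
#' @examples
#' deviationAngle(c(1, 0, 0), c(1, 1, 0))  # 45
#' @export
deviationAngle <- function(radius_axis, motion_vector) {
  na <- sqrt(sum(radius_axis^2))
  nb <- sqrt(sum(motion_vector^2))
  if (na == 0 || nb == 0)
    stop("deviation angle undefined for a zero vector", call. = FALSE)
  ct <- sum(radius_axis * motion_vector) / (na * nb)
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by \code{angle_deg} about the unit vector
#' \code{axis}.
#'
#' @param axis numeric(3) unit vector.
#' @param angle_deg rotation angle in degrees.
#' @return a 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigidly rotate a surface mesh
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param center rotation center (mm).
#' @param axis rotation axis (unit vector).
#' @param angle_deg rotation angle (degrees).
#' @return the rotated \linkS4class{TriMesh}.
#' @export
rotateMesh <- function(mesh, center, axis, angle_deg) {
  R <- rotationMatrix(axis, angle_deg)
  v <- sweep(mesh@vertices, 2, center)
  v <- v %*% t(R)
  initialize(mesh, vertices = sweep(v, 2, center, `+`))
}

## ---- batched triangle-triangle predicates -------------------------------

## separating-axis intersection test for paired triangles
## (a1,a2,a3,b1,b2,b3: n x 3 matrices); touching counts as intersecting
.triTriIntersect <- function(a1, a2, a3, b1, b2, b3) {
  n <- nrow(a1)
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  ea <- list(a2 - a1, a3 - a2, a1 - a3)
  eb <- list(b2 - b1, b3 - b2, b1 - b3)
  na <- cross(ea[[1]], ea[[2]])
  nb <- cross(eb[[1]], eb[[2]])
  axes <- c(list(na, nb),
            lapply(seq_len(9) - 1L, function(k)
              cross(ea[[k %/% 3L + 1L]], eb[[k %% 3L + 1L]])),
            lapply(ea, function(e) cross(na, e)),
            lapply(eb, function(e) cross(nb, e)))
  scale2 <- pmax(rowSums(na^2), rowSums(nb^2), 1e-300)
  separated <- rep(FALSE, n)
  for (ax in axes) {
    nrm2 <- rowSums(ax^2)
    valid <- nrm2 > 1e-14 * scale2
    pa1 <- rowSums(a1 * ax); pa2 <- rowSums(a2 * ax)
    pa3 <- rowSums(a3 * ax)
    pb1 <- rowSums(b1 * ax); pb2 <- rowSums(b2 * ax)
    pb3 <- rowSums(b3 * ax)
    amin <- pmin(pa1, pa2, pa3); amax <- pmax(pa1, pa2, pa3)
    bmin <- pmin(pb1, pb2, pb3); bmax <- pmax(pb1, pb2, pb3)
    separated <- separated | (valid & (amin > bmax | bmin > amax))
  }
  !separated
}

## squared distance from points p to triangles (t1,t2,t3), all n x 3
.pointTriDist2 <- function(p, t1, t2, t3) {
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- cross(t2 - t1, t3 - t1)
  nn <- rowSums(nrm^2)
  w <- p - t1
  dist_plane <- rowSums(w * nrm)
  ## barycentric test of the in-plane projection
  inside <- rep(FALSE, nrow(p))
  ok <- nn > 0
  if (any(ok)) {
    c1 <- rowSums(cross(t2 - t1, p - t1) * nrm)
    c2 <- rowSums(cross(t3 - t2, p - t2) * nrm)
    c3 <- rowSums(cross(t1 - t3, p - t3) * nrm)
    inside <- ok & c1 >= 0 & c2 >= 0 & c3 >= 0
  }
  d2 <- pmin(.pointSegDist2(p, t1, t2), .pointSegDist2(p, t2, t3),
             .pointSegDist2(p, t3, t1))
  d2[inside] <- (dist_plane[inside]^2) / nn[inside]
  d2
}

.pointSegDist2 <- function(p, s1, s2) {
  d <- s2 - s1
  t <- rowSums((p - s1) * d) / pmax(rowSums(d^2), 1e-300)
  t <- pmin(pmax(t, 0), 1)
  q <- s1 + d * t
  rowSums((p - q)^2)
}

## squared distance between segments (p1,q1) and (p2,q2), n x 3 each
.segSegDist2 <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- rowSums(d1^2); e <- rowSums(d2^2); f <- rowSums(d2 * r)
  b <- rowSums(d1 * d2); c <- rowSums(d1 * r)
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-300, (b * f - c * e) / denom, 0)
  s <- pmin(pmax(s, 0), 1)
  t <- ifelse(e > 1e-300, (b * s + f) / e, 0)
  ## re-clamp s for clamped t
  tc <- pmin(pmax(t, 0), 1)
  s <- ifelse(e > 1e-300 & (t != tc),
              pmin(pmax((tc * b - c) / pmax(a, 1e-300), 0), 1), s)
  t <- tc
  w <- p1 + d1 * s - (p2 + d2 * t)
  rowSums(w^2)
}

## exact distance between non-intersecting triangle pairs
.triTriDist2 <- function(a1, a2, a3, b1, b2, b3) {
  d2 <- pmin(
    .pointTriDist2(a1, b1, b2, b3), .pointTriDist2(a2, b1, b2, b3),
    .pointTriDist2(a3, b1, b2, b3),
    .pointTriDist2(b1, a1, a2, a3), .pointTriDist2(b2, a1, a2, a3),
    .pointTriDist2(b3, a1, a2, a3))
  ea <- list(list(a1, a2), list(a2, a3), list(a3, a1))
  eb <- list(list(b1, b2), list(b2, b3), list(b3, b1))
  for (i in 1:3)
    for (j in 1:3)
      d2 <- pmin(d2, .segSegDist2(ea[[i]][[1]], ea[[i]][[2]],
                                  eb[[j]][[1]], eb[[j]][[2]]))
  d2
}

## any contact between two triangle meshes (bounding-box prefilter, then
## exact tests); returns NULL or c(triangle id in A, triangle id in B)
.meshContactPair <- function(meshA, meshB, eps = 0) {
  va <- meshA@vertices; ta <- meshA@triangles
  vb <- meshB@vertices; tb <- meshB@triangles
  boxes <- function(v, tr) {
    x1 <- v[tr[, 1], , drop = FALSE]
    x2 <- v[tr[, 2], , drop = FALSE]
    x3 <- v[tr[, 3], , drop = FALSE]
    list(min = pmin(x1, x2, x3), max = pmax(x1, x2, x3))
  }
  ba <- boxes(va, ta); bb <- boxes(vb, tb)
  ## global box prefilter
  if (any(apply(ba$min, 2, min) > apply(bb$max, 2, max) + eps) ||
      any(apply(bb$min, 2, min) > apply(ba$max, 2, max) + eps))
    return(NULL)
  na <- nrow(ta); nb <- nrow(tb)
  cand <- matrix(TRUE, na, nb)
  for (k in 1:3) {
    cand <- cand & outer(ba$min[, k], bb$max[, k] + eps, `<=`) &
      outer(ba$max[, k], bb$min[, k] - eps, `>=`)
  }
  idx <- which(cand, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  ## deterministic order: lowest A triangle id, then B id
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  a1 <- va[ta[idx[, 1], 1], , drop = FALSE]
  a2 <- va[ta[idx[, 1], 2], , drop = FALSE]
  a3 <- va[ta[idx[, 1], 3], , drop = FALSE]
  b1 <- vb[tb[idx[, 2], 1], , drop = FALSE]
  b2 <- vb[tb[idx[, 2], 2], , drop = FALSE]
  b3 <- vb[tb[idx[, 2], 3], , drop = FALSE]
  hit <- .triTriIntersect(a1, a2, a3, b1, b2, b3)
  if (eps > 0 && !any(hit)) {
    d2 <- .triTriDist2(a1, a2, a3, b1, b2, b3)
    hit <- d2 < eps^2
  }
  if (!any(hit)) return(NULL)
  first <- which(hit)[1]
  c(idx[first, 1], idx[first, 2])
}

#' Sweep a rigid carpal unit through a deviation range
#'
#' Rotates the carpal mesh rigidly about the scene's rotation axis at
#' each sampled angle and tests for contact (triangle-triangle
#' intersection, optionally with a clearance epsilon) against the radius
#' and ulna surfaces. Positive angles are ulnar deviation, negative
#' radial. The per-direction limit is the last contact-free sampled
#' angle before the first contact, starting from neutral; contact at the
#' neutral position is reported, not raised.
#'
#' @param scene a \linkS4class{RomScene}.
#' @param angle_range numeric(2), swept range in degrees (default
#'   \code{c(-40, 40)} covering the clinical radial/ulnar targets).
#' @param step sampling step in degrees (> 0; default 0.5).
#' @param eps clearance distance counted as contact (mm, default 0 =
#'   touching/intersecting only).
#' @return a \linkS4class{RomResult}.
#' @export
sweepContact <- function(scene, angle_range = c(-40, 40), step = 0.5,
                         eps = 0) {
  if (!(step > 0)) stop("step must be positive", call. = FALSE)
  if (!(angle_range[1] < angle_range[2]))
    stop("degenerate angle range", call. = FALSE)
  angles <- seq(angle_range[1], angle_range[2], by = step)
  if (!any(angles == 0)) angles <- sort(c(angles, 0))
  contact <- logical(length(angles))
  pairs <- vector("list", length(angles))
  for (k in seq_along(angles)) {
    carp <- rotateMesh(scene@carpalMesh, scene@rotationCenter,
                       scene@rotationAxis, angles[k])
    hit <- .meshContactPair(carp, scene@radiusMesh, eps)
    body <- "radius"
    if (is.null(hit)) {
      hit <- .meshContactPair(carp, scene@ulnaMesh, eps)
      body <- "ulna"
    }
    contact[k] <- !is.null(hit)
    if (!is.null(hit))
      pairs[[k]] <- list(carpal_triangle = unname(hit[1]),
                         fixed_triangle = unname(hit[2]), body = body)
  }
  i0 <- which(angles == 0)
  atNeutral <- contact[i0]
  ## walk outward from neutral in each direction
  ulnar <- 0; radial <- 0
  firstContact <- NULL
  if (!atNeutral) {
    if (i0 < length(angles)) for (k in (i0 + 1L):length(angles)) {
      if (contact[k]) {
        firstContact <- c(pairs[[k]], list(angle = angles[k]))
        break
      }
      ulnar <- angles[k]
    }
    if (i0 > 1L) for (k in (i0 - 1L):1L) {
      if (contact[k]) {
        if (is.null(firstContact))
          firstContact <- c(pairs[[k]], list(angle = angles[k]))
        break
      }
      radial <- abs(angles[k])
    }
  } else {
    firstContact <- c(pairs[[i0]], list(angle = 0))
  }
  new("RomResult", angles = angles, contact = contact,
      radialLimit = radial, ulnarLimit = ulnar,
      firstContact = firstContact, contactAtNeutral = atNeutral)
}

#' Test two surface meshes for contact
#'
#' Exact triangle-triangle intersection between two meshes with an
#' optional clearance distance, after an axis-aligned bounding-box
#' prefilter.
#'
#' @param mesh_a,mesh_b \linkS4class{TriMesh} surfaces.
#' @param eps clearance distance counted as contact (mm).
#' @return NULL when contact-free, otherwise an integer pair (triangle
#'   id in \code{mesh_a}, triangle id in \code{mesh_b}).
#' @export
meshContact <- function(mesh_a, mesh_b, eps = 0) {
  .meshContactPair(mesh_a, mesh_b, eps)
}
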
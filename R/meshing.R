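## Voxel label map -> conforming tetrahedral mesh. Every non-background
## voxel is subdivided into the 6 Kuhn tetrahedra sharing the voxel's
## main diagonal; the subdivision is translation-invariant, so shared
## faces of neighboring voxels carry matching diagonals and the mesh is
## conforming by construction. Nodes are deduplicated by exact integer
## grid arithmetic (corner grid for order 1, doubled grid for the
## mid-edge nodes of order 2), never by floating-point tolerance.

## Local corner ids (bit code bx + 2*by + 4*bz) of the 6 Kuhn tets,
## ordered for positive signed volume.
.KUHN_TETS <- rbind(
  c(0L, 1L, 3L, 7L),
  c(0L, 1L, 7L, 5L),
  c(0L, 2L, 7L, 3L),
  c(0L, 2L, 6L, 7L),
  c(0L, 4L, 5L, 7L),
  c(0L, 4L, 7L, 6L)
)

.CORNER_OFFSETS <- cbind(
  bx = bitwAnd(0:7, 1L),
  by = bitwAnd(0:7 %/% 2L, 1L),
  bz = bitwAnd(0:7 %/% 4L, 1L)
)

## C3D10 edge ordering: mid-edge nodes 5..10 lie on these corner pairs
.TET10_EDGES <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                      c(1L, 4L), c(2L, 4L), c(3L, 4L))

#' Convert a label map into a conforming tetrahedral mesh
#'
#' Subdivides every non-background voxel into 6 tetrahedra with a
#' globally consistent diagonal orientation, deduplicates shared nodes
#' exactly, and labels each element with its source voxel's region.
#' \code{element_order = 2} inserts one unique mid-edge node per edge of
#' the tetrahedral complex (10-node tetrahedra, C3D10-style ordering).
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param element_order 1 (linear) or 2 (quadratic) tetrahedra.
#' @param background_region region name excluded from the mesh.
#' @return a \linkS4class{TetMesh}; total mesh volume equals the
#'   foreground voxel count times the voxel volume exactly (up to
#'   floating-point rounding).
#' @examples
#' lab <- asLabelMap(array(c(0L, 1L), dim = c(2, 1, 1)),
#'                   legend = c("0" = "background", "1" = "cortical"))
#' m <- voxelsToTetMesh(lab)
#' nrow(meshElements(m))  # 6
#' @export
voxelsToTetMesh <- function(labels, element_order = 1L,
                            background_region = "background") {
  element_order <- as.integer(element_order)
  if (!(element_order %in% c(1L, 2L)))
    stop("element_order must be 1 or 2", call. = FALSE)
  legend <- labels@legend
  bg <- as.integer(names(legend)[legend == background_region])
  lab <- labels@labels
  vox <- which(!(lab %in% bg))
  if (!length(vox))
    stop("label map has no foreground voxels to mesh", call. = FALSE)

  dims <- labels@dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ## 1-based voxel coordinates
  v0 <- vox - 1L
  ix <- v0 %% nx
  iy <- (v0 %/% nx) %% ny
  iz <- v0 %/% (nx * ny)

  nvox <- length(vox)
  ## doubled-grid corner coordinates per voxel corner (0..2*n per axis);
  ## corners are even, mid-edge nodes odd. Stored as doubles to avoid
  ## integer overflow on large grids.
  d1 <- 2 * nx + 1
  d12 <- d1 * (2 * ny + 1)
  gid <- function(cx, cy, cz) cx + d1 * cy + d12 * cz

  ## per-voxel global ids of its 8 corners: nvox x 8
  cgid <- matrix(0, nvox, 8L)
  for (c in 1:8) {
    off <- .CORNER_OFFSETS[c, ]
    cgid[, c] <- gid(2 * (ix + off[1]), 2 * (iy + off[2]),
                     2 * (iz + off[3]))
  }

  ## element connectivity in global grid ids: (6*nvox) x 4, elements of
  ## one voxel consecutive
  conn <- matrix(0, 6L * nvox, 4L)
  for (t in 1:6)
    conn[seq.int(t, by = 6L, length.out = nvox), ] <-
      cgid[, .KUHN_TETS[t, ] + 1L, drop = FALSE]

  if (element_order == 2L) {
    mids <- matrix(0, nrow(conn), 6L)
    for (e in 1:6)
      mids[, e] <- (conn[, .TET10_EDGES[e, 1]] +
                    conn[, .TET10_EDGES[e, 2]]) / 2
    conn <- cbind(conn, mids)
  }

  ids <- sort(unique(as.vector(conn)))
  elements <- matrix(match(as.vector(conn), ids), nrow = nrow(conn))
  storage.mode(elements) <- "integer"

  ## decode doubled-grid ids back to coordinates
  cz <- ids %/% d12
  rem <- ids - cz * d12
  cy <- rem %/% d1
  cx <- rem - cy * d1
  nodes <- cbind(labels@origin[1] + (cx / 2) * labels@spacing[1],
                 labels@origin[2] + (cy / 2) * labels@spacing[2],
                 labels@origin[3] + (cz / 2) * labels@spacing[3])
  colnames(nodes) <- c("x", "y", "z")

  elementVoxel <- rep(as.integer(vox), each = 6L)
  elementRegion <- unname(legend[as.character(lab[elementVoxel])])

  new("TetMesh", nodes = nodes, elements = elements,
      elementRegion = elementRegion, elementVoxel = elementVoxel,
      nodeSets = list(), order = element_order,
      grid = list(dims = dims, spacing = labels@spacing,
                  origin = labels@origin))
}

#' Signed volumes of the tetrahedral elements
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @return numeric vector of signed element volumes (mm^3); positive for
#'   a valid mesh.
#' @export
tetVolumes <- function(mesh) {
  nd <- mesh@nodes
  el <- mesh@elements[, 1:4, drop = FALSE]
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  c <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
   a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Add a cuboid boundary node set to a mesh
#'
#' Collects exactly the nodes whose coordinates lie inside the given
#' closed axis-aligned box, mirroring the cuboid reference regions used
#' at the distal and proximal bone ends for constraints and loads.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param name node set name (conventionally \code{"DISTAL_FIX"} /
#'   \code{"PROXIMAL_LOAD"}).
#' @param box numeric(6): xmin, xmax, ymin, ymax, zmin, zmax (mm);
#'   min < max per axis.
#' @return the mesh with the node set added; an empty set is an error
#'   (a boundary set must be non-empty).
#' @export
defineCuboidNodeset <- function(mesh, name, box) {
  stopifnot(is.character(name), length(name) == 1L, length(box) == 6L)
  box <- as.numeric(box)
  if (any(box[c(1, 3, 5)] >= box[c(2, 4, 6)]))
    stop("malformed box: min must be < max per axis", call. = FALSE)
  nd <- mesh@nodes
  sel <- which(nd[, 1] >= box[1] & nd[, 1] <= box[2] &
               nd[, 2] >= box[3] & nd[, 2] <= box[4] &
               nd[, 3] >= box[5] & nd[, 3] <= box[6])
  if (!length(sel))
    stop("node set '", name, "' is empty: the box contains no mesh nodes",
         call. = FALSE)
  sets <- mesh@nodeSets
  sets[[name]] <- as.integer(sel)
  initialize(mesh, nodeSets = sets)
}

#' Per-region element volume totals
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @return named numeric vector, summed element volume per region
#'   (mm^3).
#' @export
regionVolumes <- function(mesh) {
  v <- tetVolumes(mesh)
  vapply(split(v, mesh@elementRegion), sum, numeric(1))
}
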
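#' @import methods
NULL

## Central data containers. All spatial quantities are in a fixed
## mm-N-MPa unit system; greyvalues are HU-like scalars.

setClassUnion("listOrNULL", c("list", "NULL"))

#' VoxelVolume: a greyscale volume on a regular grid
#'
#' A scalar (HU-like) image on a regular axis-aligned grid, standing in
#' for a clinical CT stack. Voxel centers sit at
#' \code{origin + (index - 0.5) * spacing} per axis.
#'
#' @slot dims integer(3), voxel counts per axis.
#' @slot spacing numeric(3), voxel edge length per axis (mm).
#' @slot origin numeric(3), position of the grid corner (mm); the first
#'   voxel center is at \code{origin + spacing/2}.
#' @slot values 3-D numeric array of greyvalues, \code{dim = dims}.
#' @export
setClass("VoxelVolume",
  representation(
    dims = "integer",
    spacing = "numeric",
    origin = "numeric",
    values = "array"
  )
)

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three counts >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values")
  if (!identical(dim(object@values), as.integer(object@dims)))
    msg <- c(msg, "values array dimensions must equal dims")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all greyvalues must be finite")
  if (length(msg)) msg else TRUE
})

#' LabelMap: integer region labels on a regular grid
#'
#' Tissue / implant region labels on the same grid convention as
#' \linkS4class{VoxelVolume}. The legend maps integer codes to region
#' names (e.g. background, cortical, trabecular, callus, nail, plate,
#' screw).
#'
#' @slot dims,spacing,origin grid description, as in
#'   \linkS4class{VoxelVolume}.
#' @slot labels 3-D integer array of region codes.
#' @slot legend named character vector; names are integer codes as
#'   strings, values are region names.
#' @export
setClass("LabelMap",
  representation(
    dims = "integer",
    spacing = "numeric",
    origin = "numeric",
    labels = "array",
    legend = "character"
  )
)

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three counts >= 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values")
  if (!identical(dim(object@labels), as.integer(object@dims)))
    msg <- c(msg, "labels array dimensions must equal dims")
  if (is.null(names(object@legend)) || anyDuplicated(names(object@legend)))
    msg <- c(msg, "legend must be named by unique integer codes")
  codes <- suppressWarnings(as.integer(names(object@legend)))
  if (any(is.na(codes)))
    msg <- c(msg, "legend names must be integer codes")
  present <- unique(as.integer(object@labels))
  if (!all(present %in% codes))
    msg <- c(msg, "every label present must appear in the legend")
  if (anyDuplicated(object@legend))
    msg <- c(msg, "legend region names must be unique")
  if (length(msg)) msg else TRUE
})

#' TetMesh: a labeled tetrahedral mesh with named node sets
#'
#' Conforming tetrahedral mesh with one region label per element and
#' named boundary node sets. Elements are 4-node (linear) or 10-node
#' (quadratic) tetrahedra; quadratic connectivity follows the usual
#' C3D10 ordering (4 corners, then mid-edge nodes on edges 1-2, 2-3,
#' 3-1, 1-4, 2-4, 3-4).
#'
#' @slot nodes numeric matrix, one row per node, columns x/y/z (mm).
#' @slot elements integer matrix, one row per element, 4 or 10 columns
#'   of 1-based node indices.
#' @slot elementRegion character, region name per element.
#' @slot elementVoxel integer, linear index of the source voxel per
#'   element (NA when the mesh was not built from a grid).
#' @slot nodeSets named list of integer vectors of node indices.
#' @slot order integer, 1 (linear) or 2 (quadratic).
#' @slot grid list with the source grid (dims, spacing, origin) or NULL.
#' @export
setClass("TetMesh",
  representation(
    nodes = "matrix",
    elements = "matrix",
    elementRegion = "character",
    elementVoxel = "integer",
    nodeSets = "list",
    order = "integer",
    grid = "listOrNULL"
  )
)

setValidity("TetMesh", function(object) {
  msg <- character()
  nn <- nrow(object@nodes)
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must have 3 columns")
  nc <- ncol(object@elements)
  if (!(nc %in% c(4L, 10L)))
    msg <- c(msg, "elements must have 4 or 10 columns")
  if (!(object@order %in% c(1L, 2L)) ||
      (object@order == 1L && nc != 4L) || (object@order == 2L && nc != 10L))
    msg <- c(msg, "order must match element connectivity width")
  if (nrow(object@elements) > 0) {
    if (min(object@elements) < 1L || max(object@elements) > nn)
      msg <- c(msg, "element connectivity indices out of range")
  }
  if (length(object@elementRegion) != nrow(object@elements))
    msg <- c(msg, "one region label per element required")
  if (length(object@elementVoxel) != nrow(object@elements))
    msg <- c(msg, "one source-voxel entry per element required")
  if (length(object@nodeSets)) {
    if (is.null(names(object@nodeSets)) || any(names(object@nodeSets) == ""))
      msg <- c(msg, "node sets must be named")
    ok <- vapply(object@nodeSets, function(s)
      length(s) > 0 && all(s >= 1L & s <= nn), logical(1))
    if (!all(ok))
      msg <- c(msg, "node sets must be non-empty subsets of node indices")
  }
  if (length(msg)) msg else TRUE
})

#' MaterialTable: per-element isotropic elastic properties
#'
#' @slot E numeric, Young's modulus per element (MPa).
#' @slot nu numeric, Poisson ratio per element.
#' @slot provenance character per element: "ct-derived" or
#'   "fixed-region".
#' @slot calibration list, the density calibration used (for
#'   provenance), or NULL.
#' @export
setClass("MaterialTable",
  representation(
    E = "numeric",
    nu = "numeric",
    provenance = "character",
    calibration = "listOrNULL"
  )
)

setValidity("MaterialTable", function(object) {
  msg <- character()
  n <- length(object@E)
  if (length(object@nu) != n || length(object@provenance) != n)
    msg <- c(msg, "E, nu and provenance must have equal length")
  if (any(!is.finite(object@E)) || any(object@E <= 0))
    msg <- c(msg, "E must be positive and finite")
  if (any(!is.finite(object@nu)) || any(object@nu <= -1) ||
      any(object@nu >= 0.5))
    msg <- c(msg, "nu must lie in (-1, 0.5)")
  if (!all(object@provenance %in% c("ct-derived", "fixed-region")))
    msg <- c(msg, "provenance must be 'ct-derived' or 'fixed-region'")
  if (length(msg)) msg else TRUE
})

#' FESolution: displacements and recovered element fields
#'
#' Static linear-elastic solution. Strain and stress tensors are stored
#' per element in Voigt order (xx, yy, zz, xy, yz, xz) with *tensor*
#' shear components (not engineering shear).
#'
#' @slot displacements numeric matrix, nodes x 3 (mm).
#' @slot strain numeric matrix, elements x 6, tensor components.
#' @slot stress numeric matrix, elements x 6 (MPa).
#' @slot reactions numeric matrix, constrained nodes x 3 (N), with node
#'   indices in \code{rownames}.
#' @slot loadCase list, the load case that produced the solution.
#' @export
setClass("FESolution",
  representation(
    displacements = "matrix",
    strain = "matrix",
    stress = "matrix",
    reactions = "matrix",
    loadCase = "list"
  )
)

setValidity("FESolution", function(object) {
  msg <- character()
  if (ncol(object@displacements) != 3L)
    msg <- c(msg, "displacements must be an n x 3 matrix")
  if (ncol(object@strain) != 6L || ncol(object@stress) != 6L)
    msg <- c(msg, "strain and stress must be m x 6 Voigt matrices")
  if (nrow(object@strain) != nrow(object@stress))
    msg <- c(msg, "strain and stress must describe the same elements")
  if (length(msg)) msg else TRUE
})

#' TriMesh: a triangulated surface
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot triangles integer matrix, m x 3 of 1-based vertex indices.
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", triangles = "matrix")
)

setValidity("TriMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
  if (nrow(object@triangles) > 0 &&
      (min(object@triangles) < 1L ||
       max(object@triangles) > nrow(object@vertices)))
    msg <- c(msg, "triangle indices out of range")
  if (length(msg)) msg else TRUE
})

#' RomScene: rigid-body wrist scene for range-of-motion sweeps
#'
#' Surface meshes of a radius/ulna analogue and a rigid proximal carpal
#' unit, plus the rotation axis for deviation and the anatomical axis of
#' the radius.
#'
#' @slot radiusMesh,ulnaMesh,carpalMesh \linkS4class{TriMesh} surfaces.
#' @slot rotationCenter numeric(3), mm.
#' @slot rotationAxis numeric(3), unit vector.
#' @slot radiusAxis numeric(3), unit vector (anatomical axis).
#' @slot prominence list (angle_deg, half_width_deg, height_mm) or NULL.
#' @slot params list, generator parameters for provenance.
#' @export
setClass("RomScene",
  representation(
    radiusMesh = "TriMesh",
    ulnaMesh = "TriMesh",
    carpalMesh = "TriMesh",
    rotationCenter = "numeric",
    rotationAxis = "numeric",
    radiusAxis = "numeric",
    prominence = "listOrNULL",
    params = "list"
  )
)

setValidity("RomScene", function(object) {
  msg <- character()
  for (nm in c("rotationCenter", "rotationAxis", "radiusAxis"))
    if (length(slot(object, nm)) != 3L)
      msg <- c(msg, paste(nm, "must have length 3"))
  for (nm in c("rotationAxis", "radiusAxis")) {
    v <- slot(object, nm)
    if (length(v) == 3L && abs(sqrt(sum(v^2)) - 1) > 1e-8)
      msg <- c(msg, paste(nm, "must be a unit vector"))
  }
  if (length(msg)) msg else TRUE
})

#' HealingWindowResult: mechanobiological zone classification
#'
#' Per-callus-element healing-zone labels plus volume-weighted and
#' element-count zone fractions. The healing window is the union of the
#' intramembranous and endochondral zones.
#'
#' @slot zone character per callus element.
#' @slot gammaOct,epsVol numeric per callus element (dimensionless).
#' @slot elementIds integer, element indices in the parent mesh.
#' @slot volumeFractions,countFractions named numeric over zones,
#'   each summing to 1.
#' @slot healingWindow named numeric: volume and count fraction inside
#'   the healing window.
#' @slot config list, the zone thresholds used.
#' @export
setClass("HealingWindowResult",
  representation(
    zone = "character",
    gammaOct = "numeric",
    epsVol = "numeric",
    elementIds = "integer",
    volumeFractions = "numeric",
    countFractions = "numeric",
    healingWindow = "numeric",
    config = "list"
  )
)

setValidity("HealingWindowResult", function(object) {
  msg <- character()
  n <- length(object@zone)
  if (length(object@gammaOct) != n || length(object@epsVol) != n ||
      length(object@elementIds) != n)
    msg <- c(msg, "per-element slots must have equal length")
  for (nm in c("volumeFractions", "countFractions")) {
    f <- slot(object, nm)
    if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-9)
      msg <- c(msg, paste(nm, "must be nonnegative and sum to 1"))
  }
  if (length(msg)) msg else TRUE
})

#' RomResult: outcome of a range-of-motion sweep
#'
#' @slot angles numeric, sampled angles (deg); negative = radial,
#'   positive = ulnar deviation.
#' @slot contact logical per angle.
#' @slot radialLimit,ulnarLimit numeric (deg), largest contact-free
#'   deviation magnitude per direction.
#' @slot firstContact list (angle, carpal triangle id, fixed triangle
#'   id, body) or NULL when contact-free.
#' @slot contactAtNeutral logical.
#' @export
setClass("RomResult",
  representation(
    angles = "numeric",
    contact = "logical",
    radialLimit = "numeric",
    ulnarLimit = "numeric",
    firstContact = "listOrNULL",
    contactAtNeutral = "logical"
  )
)

setValidity("RomResult", function(object) {
  msg <- character()
  if (length(object@angles) != length(object@contact))
    msg <- c(msg, "one contact flag per sampled angle required")
  if (length(msg)) msg else TRUE
})

#' ComparisonReport: baseline-vs-revision treatment comparison
#'
#' @slot caseId character scalar.
#' @slot variants named list (baseline, revised), each holding per-region
#'   peak von Mises stress and healing-zone fractions.
#' @slot deltas list: percent stress reduction, stress ratio and
#'   zone-fraction differences per region.
#' @slot provenance list: thresholds, materials, calibration, seeds,
#'   mesh sizes; sufficient to re-run the comparison.
#' @export
setClass("ComparisonReport",
  representation(
    caseId = "character",
    variants = "list",
    deltas = "list",
    provenance = "list"
  )
)
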
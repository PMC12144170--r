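## Parametric idealized bone-implant constructs: a cortical tube with a
## trabecular/medullary interior, a transverse fracture gap filled with
## soft callus, and optional metallic implants (intramedullary nail,
## lateral plate, transverse screws), rendered onto a regular voxel grid
## as an HU-like greyscale volume plus a ground-truth label map.

.REGION_CODES <- c(background = 0L, cortical = 1L, trabecular = 2L,
                   callus = 3L, nail = 4L, plate = 5L, screw = 6L)

#' Default tissue greyvalues (HU-like)
#'
#' Well-separated per-region greyvalue levels in the order of clinical
#' CT: air/soft background far below, soft callus just above water,
#' trabecular bone, cortical bone, and metallic implants at the top.
#' Each implant component gets its own level so that threshold
#' segmentation can recover the full ground-truth label map; adjacent
#' levels are at least 300 HU apart, 12 standard deviations at the
#' default noise level, so misclassification is negligible.
#'
#' @return named numeric vector of greyvalues per region.
#' @export
defaultTissueGreyvalues <- function() {
  c(background = -1000, callus = 50, trabecular = 300, cortical = 1500,
    screw = 2400, plate = 2700, nail = 3000)
}

#' Specify an idealized bone-implant construct
#'
#' Parameters of a synthetic long-bone construct: a cortical shell of
#' given outer radius and thickness along +z (distal end at z = 0), a
#' trabecular interior, a transverse fracture gap of given width filled
#' with soft callus, and optional implants. All lengths in mm.
#'
#' @param bone_length bone extent along z (mm).
#' @param outer_radius periosteal radius (mm).
#' @param cortical_thickness cortical shell thickness (mm).
#' @param canal_radius medullary canal radius available for a nail (mm);
#'   must not exceed \code{outer_radius - cortical_thickness}.
#' @param gap_position fracture gap center along z (mm).
#' @param gap_width fracture gap width (mm).
#' @param nail_radius intramedullary nail radius (mm); 0 means no nail.
#' @param nail_length nail extent along z, centered on the gap (mm).
#' @param screws list of transverse screws, each a list with
#'   \code{axial_position} (mm), \code{axis} (unit vector),
#'   \code{radius} (mm), \code{length} (mm).
#' @param plate optional lateral plate: a list with \code{length},
#'   \code{width}, \code{thickness} (mm) and \code{angle_deg} (angular
#'   position around the shaft); modeled as a partial cylindrical shell
#'   flush with the periosteal surface, centered on the gap.
#' @param tissue_greyvalues named numeric, greyvalue per region.
#' @param noise_sd standard deviation of i.i.d. Gaussian greyvalue
#'   noise (HU); 0 disables noise.
#' @param voxel_spacing isotropic voxel edge length (mm), or length-3.
#' @param seed integer seed for the noise field.
#' @return a list of class \code{ConstructSpec}.
#' @examples
#' spec <- constructSpec(bone_length = 40, outer_radius = 6,
#'                       cortical_thickness = 2, canal_radius = 3,
#'                       gap_position = 20, voxel_spacing = 2)
#' @export
constructSpec <- function(bone_length = 200,
                          outer_radius = 12,
                          cortical_thickness = 4,
                          canal_radius = 5.5,
                          gap_position = bone_length / 2,
                          gap_width = 4,
                          nail_radius = 4,
                          nail_length = 0.8 * bone_length,
                          screws = list(),
                          plate = NULL,
                          tissue_greyvalues = defaultTissueGreyvalues(),
                          noise_sd = 25,
                          voxel_spacing = 1,
                          seed = 0L) {
  spec <- list(bone_length = bone_length, outer_radius = outer_radius,
               cortical_thickness = cortical_thickness,
               canal_radius = canal_radius, gap_position = gap_position,
               gap_width = gap_width, nail_radius = nail_radius,
               nail_length = nail_length, screws = screws, plate = plate,
               tissue_greyvalues = tissue_greyvalues, noise_sd = noise_sd,
               voxel_spacing = rep(voxel_spacing, length.out = 3),
               seed = as.integer(seed))
  class(spec) <- "ConstructSpec"
  validateConstructSpec(spec)
  spec
}

validateConstructSpec <- function(spec) {
  with(spec, {
    if (!(bone_length > 0))
      stop("invariant violated: bone_length > 0", call. = FALSE)
    if (!(cortical_thickness > 0 && cortical_thickness < outer_radius))
      stop("invariant violated: 0 < cortical_thickness < outer_radius",
           call. = FALSE)
    if (!(canal_radius <= outer_radius - cortical_thickness))
      stop("invariant violated: canal_radius <= outer_radius - cortical_thickness",
           call. = FALSE)
    if (!(nail_radius >= 0 && nail_radius <= canal_radius))
      stop("invariant violated: 0 <= nail_radius <= canal_radius ",
           "(nail does not fit the medullary canal)", call. = FALSE)
    if (!(gap_width > 0 && gap_width < bone_length))
      stop("invariant violated: 0 < gap_width < bone_length", call. = FALSE)
    if (!(gap_position > 0 && gap_position < bone_length))
      stop("invariant violated: 0 < gap_position < bone_length", call. = FALSE)
    if (any(voxel_spacing <= 0))
      stop("invariant violated: voxel_spacing > 0", call. = FALSE)
    if (noise_sd < 0)
      stop("invariant violated: noise_sd >= 0", call. = FALSE)
    for (s in screws) {
      if (!all(c("axial_position", "axis", "radius", "length") %in% names(s)))
        stop("each screw needs axial_position, axis, radius, length",
             call. = FALSE)
      if (abs(sqrt(sum(s$axis^2)) - 1) > 1e-8)
        stop("invariant violated: screw axis must be a unit vector",
             call. = FALSE)
    }
    if (!is.null(plate) &&
        !all(c("length", "width", "thickness", "angle_deg") %in% names(plate)))
      stop("plate needs length, width, thickness, angle_deg", call. = FALSE)
    needed <- c("background", "cortical", "trabecular", "callus")
    if (nail_radius > 0) needed <- c(needed, "nail")
    if (!is.null(plate)) needed <- c(needed, "plate")
    if (length(screws)) needed <- c(needed, "screw")
    miss <- setdiff(needed, names(tissue_greyvalues))
    if (length(miss))
      stop("tissue_greyvalues missing region(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    invisible(TRUE)
  })
}

## Voxel-center coordinates of the grid implied by a spec. The grid is
## centered on the bone axis in x/y and padded by one background voxel
## layer on every side; z = 0 (distal bone end) falls on a voxel
## boundary so a gap centered between layers stays exactly resolved.
constructGrid <- function(spec) {
  h <- spec$voxel_spacing
  rmax <- spec$outer_radius +
    (if (!is.null(spec$plate)) spec$plate$thickness else 0)
  nx <- 2L * (as.integer(ceiling(rmax / h[1])) + 1L)
  ny <- 2L * (as.integer(ceiling(rmax / h[2])) + 1L)
  nz <- as.integer(ceiling(spec$bone_length / h[3])) + 2L
  origin <- c(-nx / 2 * h[1], -ny / 2 * h[2], -h[3])
  list(dims = c(nx, ny, nz), spacing = h, origin = origin)
}

voxelCenters <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid$origin[k] + (seq_len(grid$dims[k]) - 0.5) * grid$spacing[k])
  names(ax) <- c("x", "y", "z")
  ax
}

#' Generate a synthetic CT volume and ground-truth label map
#'
#' Renders the construct described by a \code{\link{constructSpec}} onto
#' a regular voxel grid. Region membership is evaluated analytically at
#' voxel centers (no anti-aliasing) with precedence
#' implant > callus > cortical > trabecular > background; the greyvalue
#' of each voxel is its region's level plus seeded i.i.d. Gaussian
#' noise. Identical spec and seed give bit-identical output.
#'
#' @param spec a \code{\link{constructSpec}}.
#' @return list with elements \code{volume} (\linkS4class{VoxelVolume})
#'   and \code{labels} (\linkS4class{LabelMap}).
#' @examples
#' spec <- constructSpec(bone_length = 40, outer_radius = 6,
#'                       cortical_thickness = 2, canal_radius = 3,
#'                       nail_radius = 2.5, nail_length = 30,
#'                       gap_position = 20, voxel_spacing = 2,
#'                       noise_sd = 0)
#' cv <- generateConstruct(spec)
#' table(labelLegend(cv$labels)[as.character(labelArray(cv$labels))])
#' @export
generateConstruct <- function(spec) {
  validateConstructSpec(spec)
  grid <- constructGrid(spec)
  ax <- voxelCenters(grid)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]

  ## broadcast voxel-center coordinates over the full grid
  X <- array(rep(ax$x, times = ny * nz), dim = grid$dims)
  Y <- array(rep(rep(ax$y, each = nx), times = nz), dim = grid$dims)
  Z <- array(rep(ax$z, each = nx * ny), dim = grid$dims)
  R2 <- X^2 + Y^2

  inner_r <- spec$outer_radius - spec$cortical_thickness
  in_bone_z <- Z >= 0 & Z <= spec$bone_length
  in_gap <- abs(Z - spec$gap_position) < spec$gap_width / 2

  lab <- array(.REGION_CODES[["background"]], dim = grid$dims)
  lab[in_bone_z & R2 <= inner_r^2] <- .REGION_CODES[["trabecular"]]
  lab[in_bone_z & R2 <= spec$outer_radius^2 & R2 > inner_r^2] <-
    .REGION_CODES[["cortical"]]
  lab[in_bone_z & in_gap & R2 <= spec$outer_radius^2] <-
    .REGION_CODES[["callus"]]

  if (length(spec$screws)) {
    for (s in spec$screws) {
      c0 <- c(0, 0, s$axial_position)
      dx <- X - c0[1]; dy <- Y - c0[2]; dz <- Z - c0[3]
      t <- dx * s$axis[1] + dy * s$axis[2] + dz * s$axis[3]
      d2 <- dx^2 + dy^2 + dz^2 - t^2
      lab[d2 <= s$radius^2 & abs(t) <= s$length / 2] <-
        .REGION_CODES[["screw"]]
    }
  }
  if (!is.null(spec$plate)) {
    p <- spec$plate
    half_ang <- (p$width / spec$outer_radius) / 2
    ang0 <- p$angle_deg * pi / 180
    dang <- atan2(Y, X) - ang0
    dang <- atan2(sin(dang), cos(dang))  # wrap to (-pi, pi]
    sel <- in_bone_z & R2 > spec$outer_radius^2 &
      R2 <= (spec$outer_radius + p$thickness)^2 &
      abs(Z - spec$gap_position) <= p$length / 2 &
      abs(dang) <= half_ang
    lab[sel] <- .REGION_CODES[["plate"]]
  }
  if (spec$nail_radius > 0) {
    in_nail_z <- abs(Z - spec$gap_position) <= spec$nail_length / 2 &
      in_bone_z
    lab[in_nail_z & R2 <= spec$nail_radius^2] <- .REGION_CODES[["nail"]]
  }

  present <- sort(unique(as.integer(lab)))
  legend <- stats::setNames(names(.REGION_CODES)[match(present, .REGION_CODES)],
                            as.character(present))

  gv <- spec$tissue_greyvalues[legend[as.character(lab)]]
  values <- array(as.numeric(gv), dim = grid$dims)
  if (spec$noise_sd > 0) {
    rng <- .withSeed(spec$seed,
                     stats::rnorm(length(values), 0, spec$noise_sd))
    values <- values + array(rng, dim = grid$dims)
  }

  vol <- new("VoxelVolume", dims = as.integer(grid$dims),
             spacing = grid$spacing, origin = grid$origin, values = values)
  lm <- new("LabelMap", dims = as.integer(grid$dims),
            spacing = grid$spacing, origin = grid$origin,
            labels = lab, legend = legend)
  list(volume = vol, labels = lm)
}

## evaluate expr with a local RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Region codes used by the construct generator
#'
#' @return named integer vector mapping region names to label codes.
#' @export
regionCodes <- function() .REGION_CODES
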
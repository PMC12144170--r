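## Greyvalue -> isotropic linear elasticity. Bone regions get a modulus
## from an HU -> apparent-density -> power-law chain; implant and callus
## regions get fixed region properties.

#' Density calibration for greyvalue-to-modulus mapping
#'
#' Linear HU-to-apparent-density ramp with a floor, followed by a
#' density power law: rho = max(a + b * HU, rho_min) in g/cm^3 and
#' E = c * rho^d in MPa. The defaults are a published apparent-density
#' power law (c = 6850 MPa, d = 1.49) on a water-anchored ramp; they are
#' configurable and recorded in every report's provenance.
#'
#' @param a density at 0 HU (g/cm^3).
#' @param b density slope (g/cm^3 per HU).
#' @param c modulus coefficient (MPa per (g/cm^3)^d).
#' @param d power-law exponent (dimensionless).
#' @param rho_min density clamp floor (g/cm^3).
#' @return a list of class \code{DensityCalibration}.
#' @export
densityCalibration <- function(a = 1.0, b = 0.001, c = 6850, d = 1.49,
                               rho_min = 0.05) {
  if (!(b > 0)) stop("invariant violated: b > 0", call. = FALSE)
  if (!(c > 0)) stop("invariant violated: c > 0", call. = FALSE)
  if (!(d > 0)) stop("invariant violated: d > 0", call. = FALSE)
  if (!(rho_min > 0)) stop("invariant violated: rho_min > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, rho_min = rho_min),
            class = "DensityCalibration")
}

#' Map greyvalues to Young's modulus
#'
#' \code{E = c * max(a + b * hu, rho_min)^d}; strictly nondecreasing in
#' \code{hu}, with the density clamped at \code{rho_min}.
#'
#' @param hu greyvalue(s), HU-like; must be finite.
#' @param calib a \code{\link{densityCalibration}}.
#' @return Young's modulus in MPa, same length as \code{hu}.
#' @examples
#' huToModulus(0)  # water-equivalent density: c * a^d
#' @export
huToModulus <- function(hu, calib = densityCalibration()) {
  if (any(!is.finite(hu)))
    stop("non-finite greyvalue passed to huToModulus", call. = FALSE)
  rho <- pmax(calib$a + calib$b * hu, calib$rho_min)
  calib$c * rho^calib$d
}

#' Default fixed region materials
#'
#' Soft callus at 3 MPa (nu 0.4) following soft-callus conventions of
#' the tissue-differentiation literature; titanium-alloy implants at
#' 110 GPa (nu 0.3). Bone regions carry only a Poisson ratio here; their
#' modulus is CT-derived. \code{steel} is provided as an optional
#' implant alternative (200 GPa).
#'
#' @return a named list: per region, \code{list(E = MPa or NA, nu = )}.
#' @export
defaultRegionMaterials <- function() {
  list(
    cortical   = list(E = NA_real_, nu = 0.3),  # CT-derived modulus
    trabecular = list(E = NA_real_, nu = 0.3),  # CT-derived modulus
    callus     = list(E = 3,        nu = 0.4),
    nail       = list(E = 110000,   nu = 0.3),
    plate      = list(E = 110000,   nu = 0.3),
    screw      = list(E = 110000,   nu = 0.3),
    steel      = list(E = 200000,   nu = 0.3)
  )
}

#' Assign per-element elastic properties
#'
#' Elements in implant and callus regions receive the fixed (E, nu) of
#' their region; elements in bone regions (any region whose table entry
#' has \code{E = NA}) receive \code{E = huToModulus(HU of the element's
#' source voxel)} and the region's Poisson ratio. On the voxel mesh each
#' element maps to exactly one source voxel, so all 6 tetrahedra of a
#' voxel share identical properties.
#'
#' @param mesh a \linkS4class{TetMesh} built from the same grid as
#'   \code{volume}.
#' @param volume the \linkS4class{VoxelVolume} supplying greyvalues.
#' @param labels the \linkS4class{LabelMap} the mesh was built from
#'   (used for a congruence check); may be NULL.
#' @param region_table named list of per-region \code{list(E, nu)}; see
#'   \code{\link{defaultRegionMaterials}}.
#' @param calib a \code{\link{densityCalibration}}.
#' @return a \linkS4class{MaterialTable}.
#' @export
assignMaterials <- function(mesh, volume, labels = NULL,
                            region_table = defaultRegionMaterials(),
                            calib = densityCalibration()) {
  if (!is.null(mesh@grid)) {
    gd <- mesh@grid
    if (!identical(as.integer(gd$dims), as.integer(volume@dims)) ||
        max(abs(gd$spacing - volume@spacing)) > 1e-12)
      stop("mesh grid is not congruent with the greyvalue volume",
           call. = FALSE)
  }
  regions <- mesh@elementRegion
  miss <- setdiff(unique(regions), names(region_table))
  if (length(miss))
    stop("region(s) missing from the material table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(mesh@elementVoxel))
    stop("mesh carries no source-voxel mapping; cannot derive bone ",
         "moduli from greyvalues", call. = FALSE)

  n <- length(regions)
  E <- numeric(n)
  nu <- numeric(n)
  prov <- character(n)
  hu <- as.vector(volume@values)[mesh@elementVoxel]
  for (rg in unique(regions)) {
    sel <- regions == rg
    entry <- region_table[[rg]]
    nu[sel] <- entry$nu
    if (is.na(entry$E)) {
      E[sel] <- huToModulus(hu[sel], calib)
      prov[sel] <- "ct-derived"
    } else {
      E[sel] <- entry$E
      prov[sel] <- "fixed-region"
    }
  }
  new("MaterialTable", E = E, nu = nu, provenance = prov,
      calibration = unclass(calib))
}
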
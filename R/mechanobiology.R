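## Strain invariants, von Mises stress and healing-window zone
## classification of the fracture callus.

.asTensor6 <- function(x, what = "tensor", tol = 1e-8) {
  if (is.matrix(x) && identical(dim(x), c(3L, 3L))) {
    scale <- max(abs(x), 1e-300)
    if (max(abs(x - t(x))) > tol * scale)
      stop(what, " must be symmetric (asymmetry beyond tolerance)",
           call. = FALSE)
    x <- (x + t(x)) / 2
    matrix(c(x[1, 1], x[2, 2], x[3, 3], x[1, 2], x[2, 3], x[1, 3]),
           nrow = 1)
  } else if (is.matrix(x) && ncol(x) == 6L) {
    x
  } else if (is.numeric(x) && length(x) == 6L) {
    matrix(x, nrow = 1)
  } else stop(what, " must be a symmetric 3x3 matrix or m x 6 Voigt rows",
              call. = FALSE)
}

#' Octahedral shear strain and volumetric strain
#'
#' For a small-strain tensor with principal strains e1, e2, e3:
#' volumetric strain is the trace e1 + e2 + e3 and octahedral shear
#' strain is (2/3) * sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2). Both are
#' computed from tensor invariants (trace and the contraction eps:eps),
#' so they are frame-invariant by construction and need no eigen
#' decomposition.
#'
#' @param eps a symmetric 3x3 strain tensor, or an m x 6 matrix of Voigt
#'   rows (xx, yy, zz, xy, yz, zx; tensor shear components).
#' @param tol relative symmetry tolerance for 3x3 input.
#' @return a list with numeric vectors \code{gamma_oct} and
#'   \code{eps_vol}.
#' @examples
#' strainInvariants(diag(c(0.03, 0, 0)))  # gamma_oct ~ 0.028284
#' @export
strainInvariants <- function(eps, tol = 1e-8) {
  v <- .asTensor6(eps, "strain tensor", tol)
  tr <- v[, 1] + v[, 2] + v[, 3]
  ## eps : eps = sum of squares with shear counted twice
  ss <- v[, 1]^2 + v[, 2]^2 + v[, 3]^2 +
    2 * (v[, 4]^2 + v[, 5]^2 + v[, 6]^2)
  ## (e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2 = 3 eps:eps - tr^2
  gamma_oct <- (2 / 3) * sqrt(pmax(3 * ss - tr^2, 0))
  list(gamma_oct = unname(gamma_oct), eps_vol = unname(tr))
}

#' Von Mises equivalent stress
#'
#' sqrt(3/2 * s:s) with s the stress deviator; zero for hydrostatic
#' states, equal to the axial stress for uniaxial states.
#'
#' @param sigma a symmetric 3x3 stress tensor (MPa) or m x 6 Voigt rows.
#' @param tol relative symmetry tolerance for 3x3 input.
#' @return numeric vector of von Mises stresses (MPa).
#' @examples
#' s <- matrix(0, 3, 3); s[1, 2] <- s[2, 1] <- 50
#' vonMises(s)  # 50 * sqrt(3)
#' @export
vonMises <- function(sigma, tol = 1e-8) {
  v <- .asTensor6(sigma, "stress tensor", tol)
  unname(sqrt(pmax(
    0.5 * ((v[, 1] - v[, 2])^2 + (v[, 2] - v[, 3])^2 +
           (v[, 3] - v[, 1])^2) +
      3 * (v[, 4]^2 + v[, 5]^2 + v[, 6]^2), 0)))
}

#' Healing-window zone thresholds
#'
#' Nested rectangular zones in the (gamma_oct, eps_vol) plane, evaluated
#' innermost first with <= on upper bounds (a boundary value belongs to
#' the lower-strain zone):
#' \itemize{
#'   \item understimulated: gamma_oct < gamma_low and |eps_vol| <
#'     eps_low (too little stimulus, resorption risk);
#'   \item intramembranous: gamma_oct <= gamma_im and |eps_vol| <=
#'     eps_im (direct bone formation);
#'   \item endochondral: gamma_oct <= gamma_ec and eps_ec_compressive <=
#'     eps_vol <= eps_ec_tensile (cartilage-mediated ossification);
#'   \item excessive: everything else ("too much movement").
#' }
#' The healing window is intramembranous plus endochondral. Thresholds
#' are configurable; the defaults mirror the +/-5 % / +/-15 % structure
#' of the tissue-differentiation literature and are embedded in every
#' report.
#'
#' @param gamma_low,eps_low understimulated bounds.
#' @param gamma_im,eps_im intramembranous bounds.
#' @param gamma_ec endochondral distortional bound.
#' @param eps_ec_compressive,eps_ec_tensile endochondral volumetric
#'   bounds (signed).
#' @return a list of class \code{HealingZoneConfig}.
#' @export
healingZoneConfig <- function(gamma_low = 0.0025, eps_low = 0.0025,
                              gamma_im = 0.05, eps_im = 0.05,
                              gamma_ec = 0.15,
                              eps_ec_compressive = -0.15,
                              eps_ec_tensile = 0.05) {
  cfg <- list(gamma_low = gamma_low, eps_low = eps_low,
              gamma_im = gamma_im, eps_im = eps_im, gamma_ec = gamma_ec,
              eps_ec_compressive = eps_ec_compressive,
              eps_ec_tensile = eps_ec_tensile)
  if (!all(vapply(cfg, is.finite, logical(1))))
    stop("zone bounds must be finite", call. = FALSE)
  if (!(0 < gamma_low && gamma_low < gamma_im && gamma_im < gamma_ec))
    stop("invariant violated: 0 < gamma_low < gamma_im < gamma_ec",
         call. = FALSE)
  class(cfg) <- "HealingZoneConfig"
  cfg
}

.ZONES <- c("understimulated", "intramembranous", "endochondral",
            "excessive")

#' Assign healing zones to strain states
#'
#' Vectorized zone lookup; every (gamma_oct, eps_vol) pair maps to
#' exactly one zone.
#'
#' @param gamma_oct,epsilon_vol numeric vectors.
#' @param config a \code{\link{healingZoneConfig}}.
#' @return character vector of zone names.
#' @export
healingZone <- function(gamma_oct, epsilon_vol,
                        config = healingZoneConfig()) {
  stopifnot(length(gamma_oct) == length(epsilon_vol))
  zone <- rep("excessive", length(gamma_oct))
  ec <- gamma_oct <= config$gamma_ec &
    epsilon_vol >= config$eps_ec_compressive &
    epsilon_vol <= config$eps_ec_tensile
  zone[ec] <- "endochondral"
  im <- gamma_oct <= config$gamma_im & abs(epsilon_vol) <= config$eps_im
  zone[im] <- "intramembranous"
  us <- gamma_oct < config$gamma_low & abs(epsilon_vol) < config$eps_low
  zone[us] <- "understimulated"
  zone
}

#' Classify callus elements into healing-window zones
#'
#' Computes (gamma_oct, eps_vol) for the callus elements of a solution,
#' assigns each to its unique zone, and reports both volume-weighted and
#' element-count zone fractions plus the healing-window fraction
#' (intramembranous + endochondral).
#'
#' @param solution an \linkS4class{FESolution}.
#' @param mesh the \linkS4class{TetMesh} the solution was computed on.
#' @param config a \code{\link{healingZoneConfig}}.
#' @param region region name of the fracture callus.
#' @return a \linkS4class{HealingWindowResult}.
#' @export
classifyHealing <- function(solution, mesh, config = healingZoneConfig(),
                            region = "callus") {
  sel <- which(mesh@elementRegion == region)
  if (!length(sel))
    stop("no fracture region defined: no elements labeled '", region,
         "'", call. = FALSE)
  inv <- strainInvariants(solution@strain[sel, , drop = FALSE])
  zone <- healingZone(inv$gamma_oct, inv$eps_vol, config)
  vol <- tetVolumes(mesh)[sel]
  vf <- vapply(.ZONES, function(z) sum(vol[zone == z]), numeric(1)) /
    sum(vol)
  cf <- vapply(.ZONES, function(z) sum(zone == z), numeric(1)) /
    length(zone)
  hw <- c(volume = sum(vf[c("intramembranous", "endochondral")]),
          count = sum(cf[c("intramembranous", "endochondral")]))
  new("HealingWindowResult", zone = zone, gammaOct = inv$gamma_oct,
      epsVol = inv$eps_vol, elementIds = as.integer(sel),
      volumeFractions = vf, countFractions = cf, healingWindow = hw,
      config = unclass(config))
}

#' Peak von Mises stress over a region
#'
#' Maximum per-element von Mises stress over the region's elements, with
#' a deterministic tie-break to the lowest element id.
#'
#' @param solution an \linkS4class{FESolution}.
#' @param mesh the \linkS4class{TetMesh} the solution was computed on.
#' @param region region name (e.g. \code{"nail"}).
#' @return list with \code{sigma_vm_max} (MPa) and \code{element} (id in
#'   the mesh).
#' @export
peakStress <- function(solution, mesh, region) {
  sel <- which(mesh@elementRegion == region)
  if (!length(sel))
    stop("region '", region, "' is unknown or empty in this mesh",
         call. = FALSE)
  svm <- vonMises(solution@stress[sel, , drop = FALSE])
  best <- which.max(svm)  # which.max returns the first (lowest id) max
  list(sigma_vm_max = svm[best], element = sel[best])
}
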
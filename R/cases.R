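## Scripted, seeded desk-scale treatment-comparison cases wiring all
## stages together: generate -> segment -> mesh -> materials -> solve ->
## evaluate -> compare (plus the wrist range-of-motion sweep). Case
## definitions ship as editable YAML configs under
## inst/extdata/cases/.

.CASE_NAMES <- c("usecase1_nail_diameter",
                 "usecase2_plate_humerus_analogue",
                 "usecase3_plate_femur_analogue",
                 "usecase4_screw_torsion",
                 "usecase5_wrist")

## recursive list merge; `override` wins, lists merge by name
.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a shipped case definition
#'
#' Reads one of the shipped treatment-comparison case configs and
#' applies optional overrides (e.g. a coarser \code{voxel_spacing} or a
#' shorter \code{bone_length} for quick runs). Baseline and revision
#' differ only in the intended treatment parameters.
#'
#' @param name one of \code{"usecase1_nail_diameter"},
#'   \code{"usecase2_plate_humerus_analogue"},
#'   \code{"usecase3_plate_femur_analogue"},
#'   \code{"usecase4_screw_torsion"}, \code{"usecase5_wrist"}.
#' @param seed integer seed for all stochastic stages.
#' @param overrides named list merged over the shipped config
#'   (recursively); entries under \code{construct}, \code{load},
#'   \code{baseline}, \code{revision}, \code{sweep} etc.
#' @param config_file read this YAML file instead of a shipped one.
#' @return a list of class \code{CaseDefinition}.
#' @export
caseDefinition <- function(name = .CASE_NAMES, seed = 0L,
                           overrides = list(), config_file = NULL) {
  if (is.null(config_file)) {
    name <- match.arg(name)
    config_file <- system.file("extdata", "cases",
                               paste0(name, ".yaml"),
                               package = "FractureTwin", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(config_file)
  cfg <- .mergeConfig(cfg, overrides)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "CaseDefinition"
  cfg
}

## build the ConstructSpec of one variant of an FE case
.variantSpec <- function(case, variant) {
  args <- case$construct
  v <- case[[variant]]
  L <- args$bone_length
  for (nm in names(v)) {
    if (nm == "screws") {
      args$screws <- lapply(v$screws, function(s) {
        list(axial_position = L / 2 + s$axial_offset,
             axis = as.numeric(s$axis), radius = s$radius,
             length = s$length)
      })
    } else args[[nm]] <- v[[nm]]
  }
  args$seed <- case$seed
  do.call(constructSpec, args)
}

## run one FE variant through the full chain
.runVariant <- function(spec, case, element_order = 1L) {
  cv <- generateConstruct(spec)
  seg <- thresholdSegment(cv$volume, defaultThresholdTable(
    spec$tissue_greyvalues))
  mesh <- voxelsToTetMesh(seg, element_order = element_order)
  L <- spec$bone_length
  d <- case$cuboid_depth
  lim <- max(spec$outer_radius * 4, 100)
  mesh <- defineCuboidNodeset(mesh, "DISTAL_FIX",
                              c(-lim, lim, -lim, lim, -d, d))
  mesh <- defineCuboidNodeset(mesh, "PROXIMAL_LOAD",
                              c(-lim, lim, -lim, lim, L - d, L + d))
  neumann <- list()
  ld <- case$load
  if (ld$axial_n != 0 || ld$transverse_n != 0)
    neumann[[length(neumann) + 1L]] <-
      list(set = "PROXIMAL_LOAD",
           force = c(ld$transverse_n, 0, ld$axial_n))
  if (!is.null(ld$torque_nm) && ld$torque_nm != 0) {
    ## equilibrated force couple over the two halves of the proximal
    ## cuboid, scaled to the requested torque about the bone axis
    h <- spec$voxel_spacing[1]
    mesh <- defineCuboidNodeset(mesh, "PROXIMAL_COUPLE_POS",
                                c(h / 2, lim, -lim, lim, L - d, L + d))
    mesh <- defineCuboidNodeset(mesh, "PROXIMAL_COUPLE_NEG",
                                c(-lim, -h / 2, -lim, lim, L - d, L + d))
    xpos <- mean(mesh@nodes[mesh@nodeSets$PROXIMAL_COUPLE_POS, 1])
    xneg <- mean(mesh@nodes[mesh@nodeSets$PROXIMAL_COUPLE_NEG, 1])
    Fc <- ld$torque_nm * 1000 / (xpos - xneg)  # N.m -> N.mm lever
    neumann[[length(neumann) + 1L]] <-
      list(set = "PROXIMAL_COUPLE_POS", force = c(0, Fc, 0))
    neumann[[length(neumann) + 1L]] <-
      list(set = "PROXIMAL_COUPLE_NEG", force = c(0, -Fc, 0))
  }
  lc <- loadCase(paste0(case$name, "_peak_load"),
                 dirichlet = list(set = "DISTAL_FIX"),
                 neumann = neumann)
  mat <- assignMaterials(mesh, cv$volume, seg)
  sol <- assembleAndSolve(mesh, mat, lc)
  healing <- classifyHealing(sol, mesh, healingZoneConfig())
  list(spec = spec, volume = cv$volume, labels = seg, mesh = mesh,
       materials = mat, solution = sol, healing = healing)
}

#' Run a treatment-comparison case end to end
#'
#' Executes generate, segment, mesh, material assignment, solve,
#' healing-window evaluation and comparison for both variants of an FE
#' case, or the range-of-motion sweep for the wrist case. Identical case
#' definition and seed give identical reports.
#'
#' @param case a \code{\link{caseDefinition}}.
#' @param out_dir optional output directory; when given, the report is
#'   written as JSON and CSV and each variant's mesh and fields as
#'   \code{.vtu}.
#' @param element_order tetrahedra order for the FE cases (1 or 2).
#' @return for FE cases, a list with \code{report}
#'   (\linkS4class{ComparisonReport}) and the full \code{baseline} /
#'   \code{revised} variant results; for the wrist case, a list with
#'   both \linkS4class{RomResult}s and a summary \code{report} list.
#' @export
runCase <- function(case, out_dir = NULL, element_order = 1L) {
  stopifnot(inherits(case, "CaseDefinition"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (identical(case$kind, "rom")) return(.runRomCase(case, out_dir))

  variants <- list()
  for (v in c("baseline", "revision")) {
    variants[[v]] <- tryCatch({
      spec <- .variantSpec(case, v)
      .runVariant(spec, case, element_order)
    }, error = function(e)
      stop("case stage failed for variant '", v, "': ",
           conditionMessage(e), call. = FALSE))
  }
  prov <- list(
    case = case$name, seed = case$seed,
    construct = case$construct,
    baseline = case$baseline, revision = case$revision,
    load = case$load,
    element_order = element_order,
    materials = defaultRegionMaterials(),
    calibration = unclass(densityCalibration()),
    tissue_greyvalues = as.list(defaultTissueGreyvalues()),
    mesh_sizes = lapply(variants, function(v)
      c(nodes = nrow(meshNodes(v$mesh)),
        elements = nrow(meshElements(v$mesh)))))
  report <- compareTreatments(
    baseline = variants$baseline, revised = variants$revision,
    regions = unlist(case$regions), case_id = case$name,
    provenance = prov)
  if (!is.null(out_dir)) {
    reportToJson(report, file.path(out_dir, "report.json"))
    reportToCsv(report, file.path(out_dir, "report.csv"))
    for (v in names(variants)) {
      vr <- variants[[v]]
      svm <- vonMises(stressTensors(vr$solution))
      inv <- strainInvariants(strainTensors(vr$solution))
      exportVtk(vr$mesh,
                file.path(out_dir, paste0(v, ".vtu")),
                fields = list(von_mises = svm,
                              gamma_oct = inv$gamma_oct,
                              eps_vol = inv$eps_vol,
                              E = vr$materials@E))
    }
  }
  list(report = report, baseline = variants$baseline,
       revised = variants$revision)
}

.runRomCase <- function(case, out_dir = NULL) {
  mkScene <- function(v) {
    args <- case$scene
    if (!is.null(case[[v]]$prominence))
      args$prominence <- case[[v]]$prominence
    do.call(generateWristScene, args)
  }
  results <- list()
  for (v in c("baseline", "revision")) {
    scene <- mkScene(v)
    results[[v]] <- sweepContact(scene,
                                 angle_range = unlist(case$sweep$range),
                                 step = case$sweep$step,
                                 eps = case$sweep$eps %||% 0)
  }
  summary <- list(
    case = case$name, seed = case$seed,
    baseline = list(radial_limit = results$baseline@radialLimit,
                    ulnar_limit = results$baseline@ulnarLimit,
                    contact_at_neutral =
                      results$baseline@contactAtNeutral),
    revision = list(radial_limit = results$revision@radialLimit,
                    ulnar_limit = results$revision@ulnarLimit,
                    contact_at_neutral =
                      results$revision@contactAtNeutral),
    provenance = list(scene = case$scene, sweep = case$sweep,
                      baseline = case$baseline,
                      revision = case$revision))
  if (!is.null(out_dir)) {
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(out_dir, "rom_report.json"))
    for (v in names(results)) {
      df <- data.frame(angle_deg = results[[v]]@angles,
                       contact = results[[v]]@contact)
      utils::write.csv(df, file.path(out_dir, paste0(v, "_sweep.csv")),
                       row.names = FALSE)
    }
  }
  list(baseline = results$baseline, revised = results$revision,
       report = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
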
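## Baseline-vs-revision comparison reports: per-region peak von Mises
## stress, healing-zone fractions, percent reductions / ratios, and a
## provenance block sufficient to re-run the comparison.

.variantSummary <- function(solution, mesh, healing, regions) {
  ## a region may exist in only one variant (e.g. an added plate)
  peaks <- lapply(regions, function(rg) {
    if (!any(mesh@elementRegion == rg))
      return(list(sigma_vm_max = NA_real_, element = NA_integer_))
    peakStress(solution, mesh, rg)
  })
  names(peaks) <- regions
  list(
    peak_stress = lapply(peaks, function(p)
      list(sigma_vm_max = p$sigma_vm_max, element = p$element)),
    zone_fractions = list(
      volume = as.list(healing@volumeFractions),
      count = as.list(healing@countFractions)),
    healing_window = as.list(healing@healingWindow),
    n_nodes = nrow(solution@displacements),
    n_elements = nrow(solution@strain))
}

#' Compare a baseline and a revised treatment variant
#'
#' Builds a \linkS4class{ComparisonReport} with per-region peak von
#' Mises stresses, healing-zone fractions (volume- and count-weighted),
#' percent stress reductions (relative to baseline), stress ratios
#' (baseline / revised), and zone-fraction differences. Variants must
#' have been evaluated under the same load case name and the same zone
#' thresholds, otherwise they are not comparable.
#'
#' @param baseline,revised lists with elements \code{solution}
#'   (\linkS4class{FESolution}), \code{mesh} (\linkS4class{TetMesh}) and
#'   \code{healing} (\linkS4class{HealingWindowResult}).
#' @param regions character, regions to report peak stresses for
#'   (default \code{"nail"}).
#' @param case_id identifier recorded in the report.
#' @param provenance list merged into the report's provenance block.
#' @return a \linkS4class{ComparisonReport}.
#' @export
compareTreatments <- function(baseline, revised, regions = "nail",
                              case_id = "comparison",
                              provenance = list()) {
  if (!identical(baseline$healing@config, revised$healing@config))
    stop("variants use different healing-zone configs; not comparable",
         call. = FALSE)
  if (!identical(baseline$solution@loadCase$name,
                 revised$solution@loadCase$name))
    stop("variants were solved under different load cases; not ",
         "comparable", call. = FALSE)
  vb <- .variantSummary(baseline$solution, baseline$mesh,
                        baseline$healing, regions)
  vr <- .variantSummary(revised$solution, revised$mesh,
                        revised$healing, regions)
  peak_deltas <- lapply(regions, function(rg) {
    b <- vb$peak_stress[[rg]]$sigma_vm_max
    r <- vr$peak_stress[[rg]]$sigma_vm_max
    if (is.na(b) || is.na(r))
      return(list(baseline = b, revised = r,
                  percent_reduction = NA_real_, ratio = NA_real_))
    list(baseline = b, revised = r,
         percent_reduction = 100 * (b - r) / b,
         ratio = b / r)
  })
  names(peak_deltas) <- regions
  zone_deltas <- lapply(c(volume = "volume", count = "count"),
    function(w) {
      zb <- unlist(vb$zone_fractions[[w]])
      zr <- unlist(vr$zone_fractions[[w]])
      as.list(zr - zb)
    })
  prov <- c(provenance, list(
    load_case = baseline$solution@loadCase$name,
    zone_config = baseline$healing@config,
    regions = regions))
  new("ComparisonReport", caseId = case_id,
      variants = list(baseline = vb, revised = vr),
      deltas = list(peak_stress = peak_deltas,
                    zone_fractions = zone_deltas,
                    healing_window = list(
                      volume = vr$healing_window$volume -
                        vb$healing_window$volume,
                      count = vr$healing_window$count -
                        vb$healing_window$count)),
      provenance = prov)
}

#' Serialize a comparison report to JSON
#'
#' @param report a \linkS4class{ComparisonReport}.
#' @param file optional output path; when NULL the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to file).
#' @export
reportToJson <- function(report, file = NULL) {
  obj <- list(case_id = report@caseId, variants = report@variants,
              deltas = report@deltas, provenance = report@provenance)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Flatten a comparison report to a CSV table
#'
#' One row per (variant, metric); numeric values round-trip to at least
#' 1e-12 relative precision.
#'
#' @param report a \linkS4class{ComparisonReport}.
#' @param file optional output path; when NULL the data.frame is
#'   returned.
#' @return a data.frame (invisibly when written to file).
#' @export
reportToCsv <- function(report, file = NULL) {
  rows <- list()
  for (v in names(report@variants)) {
    s <- report@variants[[v]]
    for (rg in names(s$peak_stress))
      rows[[length(rows) + 1L]] <- data.frame(
        case = report@caseId, variant = v,
        metric = paste0("peak_sigma_vm.", rg),
        value = s$peak_stress[[rg]]$sigma_vm_max)
    for (w in c("volume", "count")) {
      zf <- s$zone_fractions[[w]]
      for (z in names(zf))
        rows[[length(rows) + 1L]] <- data.frame(
          case = report@caseId, variant = v,
          metric = paste0("zone_fraction.", w, ".", z),
          value = zf[[z]])
      rows[[length(rows) + 1L]] <- data.frame(
        case = report@caseId, variant = v,
        metric = paste0("healing_window.", w),
        value = s$healing_window[[w]])
    }
  }
  for (rg in names(report@deltas$peak_stress)) {
    d <- report@deltas$peak_stress[[rg]]
    for (metric in c("percent_reduction", "ratio"))
      rows[[length(rows) + 1L]] <- data.frame(
        case = report@caseId, variant = "delta",
        metric = paste0(metric, ".", rg), value = d[[metric]])
  }
  df <- do.call(rbind, rows)
  if (is.null(file)) return(df)
  utils::write.csv(format(df, digits = 17, scientific = TRUE),
                   file, row.names = FALSE)
  invisible(df)
}
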
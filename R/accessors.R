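#' @rdname FractureTwin-accessors
#' @export
setMethod("dim", "VoxelVolume", function(x) x@dims)

#' @rdname FractureTwin-accessors
#' @export
setMethod("dim", "LabelMap", function(x) x@dims)

#' @rdname FractureTwin-accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)

#' @rdname FractureTwin-accessors
#' @export
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)

#' @rdname FractureTwin-accessors
#' @export
setMethod("voxelOrigin", "VoxelVolume", function(x) x@origin)

#' @rdname FractureTwin-accessors
#' @export
setMethod("voxelOrigin", "LabelMap", function(x) x@origin)

#' @rdname FractureTwin-accessors
#' @export
setMethod("voxelValues", "VoxelVolume", function(x) x@values)

#' @rdname FractureTwin-accessors
#' @export
setMethod("labelArray", "LabelMap", function(x) x@labels)

#' @rdname FractureTwin-accessors
#' @export
setMethod("labelLegend", "LabelMap", function(x) x@legend)

#' @rdname FractureTwin-accessors
#' @export
setMethod("meshNodes", "TetMesh", function(x) x@nodes)

#' @rdname FractureTwin-accessors
#' @export
setMethod("meshElements", "TetMesh", function(x) x@elements)

#' @rdname FractureTwin-accessors
#' @export
setMethod("elementRegion", "TetMesh", function(x) x@elementRegion)

#' @rdname FractureTwin-accessors
#' @export
setMethod("nodeSets", "TetMesh", function(x) x@nodeSets)

#' @rdname FractureTwin-accessors
#' @export
setMethod("elementOrder", "TetMesh", function(x) x@order)

#' @rdname FractureTwin-accessors
#' @export
setMethod("displacements", "FESolution", function(x) x@displacements)

#' @rdname FractureTwin-accessors
#' @export
setMethod("strainTensors", "FESolution", function(x) x@strain)

#' @rdname FractureTwin-accessors
#' @export
setMethod("stressTensors", "FESolution", function(x) x@stress)

#' @rdname FractureTwin-accessors
#' @export
setMethod("reactionForces", "FESolution", function(x) x@reactions)

#' @rdname FractureTwin-accessors
#' @export
setMethod("zoneFractions", "HealingWindowResult",
  function(x, weighting = c("volume", "count")) {
    weighting <- match.arg(weighting)
    if (weighting == "volume") x@volumeFractions else x@countFractions
  })

#' @rdname FractureTwin-accessors
#' @export
setMethod("healingWindowFraction", "HealingWindowResult",
  function(x, weighting = c("volume", "count")) {
    weighting <- match.arg(weighting)
    unname(x@healingWindow[weighting])
  })

setMethod("show", "VoxelVolume", function(object) {
  cat("VoxelVolume:", paste(object@dims, collapse = " x "), "voxels, spacing",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
  cat("  greyvalue range:", paste(signif(range(object@values), 5),
      collapse = " .. "), "\n")
})

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap:", paste(object@dims, collapse = " x "), "voxels\n")
  tab <- table(object@labels)
  nm <- object@legend[names(tab)]
  cat("  regions:", paste(sprintf("%s (%d)", nm, as.integer(tab)),
      collapse = ", "), "\n")
})

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("TetMesh: %d nodes, %d order-%d tetrahedra\n",
      nrow(object@nodes), nrow(object@elements), object@order))
  cat("  regions:", paste(names(table(object@elementRegion)), collapse = ", "),
      "\n")
  if (length(object@nodeSets))
    cat("  node sets:", paste(sprintf("%s (%d)", names(object@nodeSets),
        lengths(object@nodeSets)), collapse = ", "), "\n")
})

setMethod("show", "FESolution", function(object) {
  umax <- sqrt(max(rowSums(object@displacements^2)))
  cat(sprintf("FESolution: %d nodes, %d elements, |u|max = %.4g mm\n",
      nrow(object@displacements), nrow(object@strain), umax))
})

setMethod("show", "HealingWindowResult", function(object) {
  cat("HealingWindowResult over", length(object@zone), "callus elements\n")
  f <- object@volumeFractions
  for (z in names(f))
    cat(sprintf("  %-16s %6.2f%% (volume) %6.2f%% (count)\n", z,
        100 * f[[z]], 100 * object@countFractions[[z]]))
  cat(sprintf("  healing window:  %6.2f%% (volume) %6.2f%% (count)\n",
      100 * object@healingWindow[["volume"]],
      100 * object@healingWindow[["count"]]))
})

setMethod("show", "RomResult", function(object) {
  cat(sprintf("RomResult: %d sampled angles; radial limit %.2f deg, ulnar limit %.2f deg\n",
      length(object@angles), object@radialLimit, object@ulnarLimit))
  if (object@contactAtNeutral) cat("  contact at neutral position\n")
  if (!is.null(object@firstContact))
    cat(sprintf("  first contact at %.2f deg against %s\n",
        object@firstContact$angle, object@firstContact$body))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport:", object@caseId, "\n")
  for (rg in names(object@deltas$peak_stress)) {
    d <- object@deltas$peak_stress[[rg]]
    cat(sprintf("  %-10s peak sigma_vm %.4g -> %.4g MPa (reduction %.1f%%, ratio %.3g)\n",
        rg, d$baseline, d$revised, d$percent_reduction, d$ratio))
  }
})
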
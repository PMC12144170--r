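#' @name FractureTwin-accessors
#' @title Accessors for FractureTwin containers
#' @description Slot accessors for the core S4 containers. Use these
#'   rather than \code{@} access.
#' @param x an object.
#' @param object an object.
#' @keywords internal
NULL

#' @rdname FractureTwin-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("elementRegion", function(x) standardGeneric("elementRegion"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("nodeSets", function(x) standardGeneric("nodeSets"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("elementOrder", function(x) standardGeneric("elementOrder"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("strainTensors", function(x) standardGeneric("strainTensors"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("stressTensors", function(x) standardGeneric("stressTensors"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("reactionForces", function(x) standardGeneric("reactionForces"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("zoneFractions", function(x, weighting = c("volume", "count"))
  standardGeneric("zoneFractions"))

#' @rdname FractureTwin-accessors
#' @export
setGeneric("healingWindowFraction",
  function(x, weighting = c("volume", "count"))
    standardGeneric("healingWindowFraction"))
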
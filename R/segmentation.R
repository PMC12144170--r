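## Threshold-based multi-region segmentation of a greyscale volume,
## mirroring the automated masking stage of a clinical CT workflow.

#' Build and validate a threshold table
#'
#' An ordered set of half-open greyvalue intervals \code{[lower, upper)}
#' mapping to region names. Intervals must be non-overlapping and must
#' cover the whole greyvalue range (use \code{-Inf} / \code{Inf} at the
#' ends); a boundary value belongs to the interval where it is the lower
#' endpoint.
#'
#' @param lower,upper numeric vectors of interval bounds (HU-like);
#'   lower inclusive, upper exclusive.
#' @param region character vector of region names.
#' @return a data.frame of class \code{ThresholdTable}, sorted by lower
#'   bound.
#' @examples
#' thresholdTable(c(-Inf, 0), c(0, Inf), c("background", "bone"))
#' @export
thresholdTable <- function(lower, upper, region) {
  stopifnot(length(lower) == length(upper),
            length(lower) == length(region))
  tab <- data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
                    region = as.character(region),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$lower), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$upper <= tab$lower))
    stop("threshold table invalid: empty interval (upper <= lower)",
         call. = FALSE)
  if (nrow(tab) > 1) {
    lo <- tab$lower[-1]; hi <- tab$upper[-nrow(tab)]
    if (any(lo < hi))
      stop("threshold table invalid: overlapping intervals", call. = FALSE)
    if (any(lo > hi))
      stop("threshold table invalid: gap between intervals", call. = FALSE)
  }
  if (is.finite(tab$lower[1]) || is.finite(tab$upper[nrow(tab)]))
    stop("threshold table invalid: intervals must cover the full ",
         "greyvalue range (-Inf .. Inf)", call. = FALSE)
  class(tab) <- c("ThresholdTable", "data.frame")
  tab
}

#' Default threshold table matching the default tissue greyvalues
#'
#' Interval boundaries are placed at midpoints between consecutive
#' default region greyvalues, so a noise-free synthetic volume segments
#' exactly back to its ground-truth label map.
#'
#' @param greyvalues named numeric, greyvalue level per region (default
#'   \code{\link{defaultTissueGreyvalues}}).
#' @return a \code{\link{thresholdTable}}.
#' @export
defaultThresholdTable <- function(greyvalues = defaultTissueGreyvalues()) {
  gv <- sort(greyvalues)
  mids <- (gv[-1] + gv[-length(gv)]) / 2
  thresholdTable(lower = c(-Inf, mids), upper = c(mids, Inf),
                 region = names(gv))
}

#' Threshold-segment a greyscale volume into a label map
#'
#' Each voxel is assigned the unique half-open interval containing its
#' greyvalue. The output grid is congruent with the input grid.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param table a \code{\link{thresholdTable}}.
#' @param cleanup if TRUE, apply \code{\link{largestComponentFilter}} to
#'   each non-background region (off by default: the raw threshold
#'   result is the oracle-comparable output).
#' @param background_region region treated as background by the cleanup
#'   pass.
#' @return a \linkS4class{LabelMap}.
#' @examples
#' cv <- generateConstruct(constructSpec(bone_length = 40, outer_radius = 6,
#'   cortical_thickness = 2, canal_radius = 3, gap_position = 20,
#'   voxel_spacing = 2, noise_sd = 0))
#' seg <- thresholdSegment(cv$volume, defaultThresholdTable())
#' identical(labelArray(seg), labelArray(cv$labels))
#' @export
thresholdSegment <- function(volume, table, cleanup = FALSE,
                             background_region = "background") {
  if (!inherits(table, "ThresholdTable"))
    table <- thresholdTable(table$lower, table$upper, table$region)
  ## half-open [lower, upper): findInterval with left-closed intervals
  idx <- findInterval(as.vector(volume@values), table$lower)
  regions <- table$region[idx]
  codes <- .REGION_CODES[match(table$region, names(.REGION_CODES))]
  unknown <- is.na(codes)
  if (any(unknown))
    codes[unknown] <- max(.REGION_CODES) + seq_len(sum(unknown))
  lab <- array(as.integer(codes[idx]), dim = volume@dims)
  legend <- stats::setNames(table$region, as.character(codes))
  present <- as.character(sort(unique(as.integer(lab))))
  lm <- new("LabelMap", dims = volume@dims, spacing = volume@spacing,
            origin = volume@origin, labels = lab,
            legend = legend[present])
  if (cleanup)
    lm <- largestComponentFilter(lm, background_region = background_region)
  lm
}

#' Keep only the largest connected component of each region
#'
#' Optional morphological post-pass (off by default in
#' \code{\link{thresholdSegment}}): for every non-background region,
#' voxels outside the largest 6-connected component are reassigned to
#' background. Intended for noisy volumes; it breaks exact ground-truth
#' comparisons and is therefore never applied implicitly.
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param background_region name of the background region.
#' @return a \linkS4class{LabelMap}.
#' @export
largestComponentFilter <- function(labels, background_region = "background") {
  lab <- labels@labels
  legend <- labels@legend
  bg_code <- as.integer(names(legend)[legend == background_region])
  if (length(bg_code) != 1L)
    stop("background region '", background_region, "' not in legend",
         call. = FALSE)
  dims <- dim(lab)
  for (code in setdiff(as.integer(names(legend)), bg_code)) {
    sel <- which(lab == code)
    if (!length(sel)) next
    comp <- .connectedComponents(sel, dims)
    keep <- sel[comp == which.max(tabulate(comp))]
    drop <- setdiff(sel, keep)
    lab[drop] <- bg_code
  }
  initialize(labels, labels = lab)
}

## label 6-connected components among linear voxel indices `sel`
.connectedComponents <- function(sel, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  inset <- integer(prod(dims))
  inset[sel] <- seq_along(sel)
  comp <- integer(length(sel))
  cur <- 0L
  offs <- c(-1L, 1L, -nx, nx, -nx * ny, nx * ny)
  ## precomputed per-voxel coordinates to guard against wrap-around
  ix <- ((sel - 1L) %% nx) + 1L
  iy <- (((sel - 1L) %/% nx) %% ny) + 1L
  iz <- ((sel - 1L) %/% (nx * ny)) + 1L
  coord <- cbind(ix, iy, iz)
  for (s in seq_along(sel)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      here <- coord[v, ]
      for (d in 1:6) {
        ax <- ((d - 1L) %/% 2L) + 1L
        step <- if (d %% 2L == 1L) -1L else 1L
        if (here[ax] + step < 1L || here[ax] + step > dims[ax]) next
        nb <- inset[sel[v] + offs[d]]
        if (nb != 0L && comp[nb] == 0L) {
          comp[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

#' Use an externally produced label map directly
#'
#' Real-data entry point: wraps an integer label array (e.g. a manual
#' clinical segmentation exported from other software) as a
#' \linkS4class{LabelMap}, bypassing threshold segmentation.
#'
#' @param labels 3-D integer array of region codes.
#' @param legend named character vector mapping codes to region names.
#' @param spacing,origin grid geometry (mm).
#' @return a \linkS4class{LabelMap}.
#' @export
asLabelMap <- function(labels, legend, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  new("LabelMap", dims = dim(labels),
      spacing = rep(as.numeric(spacing), length.out = 3),
      origin = rep(as.numeric(origin), length.out = 3),
      labels = array(as.integer(labels), dim = dim(labels)),
      legend = legend)
}
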
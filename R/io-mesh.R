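## Text-based mesh interchange: Abaqus-style .inp (nodes, elements,
## element sets per region, node sets) and STL / PLY surface formats.

#' Write a mesh as an Abaqus-style .inp text file
#'
#' Emits *NODE, *ELEMENT (TYPE=C3D4 or C3D10, one *ELEMENT block per
#' region with ELSET=<region>), and one *NSET block per node set.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeInp <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("*HEADING", con)
  writeLines("FractureTwin tetrahedral mesh export", con)
  writeLines("*NODE", con)
  writeLines(paste(seq_len(nrow(mesh@nodes)),
                   .fmtNum(mesh@nodes[, 1]), .fmtNum(mesh@nodes[, 2]),
                   .fmtNum(mesh@nodes[, 3]), sep = ", "), con)
  type <- if (mesh@order == 1L) "C3D4" else "C3D10"
  for (rg in unique(mesh@elementRegion)) {
    sel <- which(mesh@elementRegion == rg)
    writeLines(paste0("*ELEMENT, TYPE=", type, ", ELSET=",
                      toupper(rg)), con)
    el <- mesh@elements[sel, , drop = FALSE]
    writeLines(paste(sel, apply(el, 1, paste, collapse = ", "),
                     sep = ", "), con)
  }
  for (nm in names(mesh@nodeSets)) {
    writeLines(paste0("*NSET, NSET=", nm), con)
    set <- mesh@nodeSets[[nm]]
    chunks <- split(set, ceiling(seq_along(set) / 10))
    writeLines(vapply(chunks, paste, character(1), collapse = ", "),
               con)
  }
  invisible(file)
}

#' Read the Abaqus-style .inp subset written by writeInp
#'
#' Parses *NODE, *ELEMENT (C3D4/C3D10 with ELSET=region) and *NSET
#' cards. Elements may be listed in any order; element ids are
#' renumbered consecutively in file order.
#'
#' @param file path to an .inp file.
#' @return a \linkS4class{TetMesh} (with no source-voxel mapping).
#' @export
readInp <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\*\\*", lines)]
  kw <- grep("^\\*", lines)
  nodes <- NULL
  elems <- list()
  regions <- list()
  nsets <- list()
  order <- NA_integer_
  for (k in seq_along(kw)) {
    start <- kw[k] + 1L
    end <- if (k < length(kw)) kw[k + 1L] - 1L else length(lines)
    if (end < start) next
    card <- toupper(lines[kw[k]])
    body <- lines[start:end]
    body <- body[nzchar(trimws(body))]
    if (grepl("^\\*NODE", card) && !grepl("OUTPUT", card)) {
      vals <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
      nodes <- vals[order(vals[, 1]), 2:4, drop = FALSE]
    } else if (grepl("^\\*ELEMENT", card)) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", card)
      order <- if (type == "C3D10") 2L else 1L
      elset <- if (grepl("ELSET=", card))
        tolower(sub(".*ELSET=([^,\\s]+).*", "\\1", card)) else "solid"
      vals <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
      elems[[length(elems) + 1L]] <- vals[, -1, drop = FALSE]
      regions[[length(regions) + 1L]] <-
        rep(elset, nrow(vals))
    } else if (grepl("^\\*NSET", card)) {
      nm <- sub(".*NSET=([^,\\s]+).*", "\\1", lines[kw[k]])
      nsets[[nm]] <- as.integer(unlist(lapply(strsplit(body, ","),
                                              as.numeric)))
    }
  }
  if (is.null(nodes) || !length(elems))
    stop("no *NODE / *ELEMENT cards found in ", file, call. = FALSE)
  elements <- do.call(rbind, elems)
  storage.mode(elements) <- "integer"
  colnames(nodes) <- c("x", "y", "z")
  new("TetMesh", nodes = nodes, elements = elements,
      elementRegion = unlist(regions),
      elementVoxel = rep(NA_integer_, nrow(elements)),
      nodeSets = nsets, order = order, grid = NULL)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param file output path.
#' @param name solid name recorded in the file.
#' @return the file path, invisibly.
#' @export
writeStl <- function(mesh, file, name = "surface") {
  v <- mesh@vertices
  tr <- mesh@triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- pmax(sqrt(rowSums(nrm^2)), 1e-300)
  nrm <- nrm / len
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (k in seq_len(nrow(tr))) {
    writeLines(sprintf("  facet normal %s %s %s", .fmtNum(nrm[k, 1]),
                       .fmtNum(nrm[k, 2]), .fmtNum(nrm[k, 3])), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[tr[k, j], ]
      writeLines(sprintf("      vertex %s %s %s", .fmtNum(p[1]),
                         .fmtNum(p[2]), .fmtNum(p[3])), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(file)
}

#' Read an ASCII STL surface
#'
#' Vertices are deduplicated exactly (by coordinate string), so a
#' write/read round trip of a shared-vertex mesh preserves connectivity
#' up to vertex numbering.
#'
#' @param file path to an ASCII STL file.
#' @return a \linkS4class{TriMesh}.
#' @export
readStl <- function(file) {
  lines <- readLines(file)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  key <- paste(vl)
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  verts <- coords[uk, , drop = FALSE]
  triMesh(verts, matrix(ids, ncol = 3, byrow = TRUE))
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePly <- function(mesh, file) {
  v <- mesh@vertices
  tr <- mesh@triangles
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property double x", "property double y",
               "property double z",
               paste("element face", nrow(tr)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(.fmtNum(v[, 1]), .fmtNum(v[, 2]), .fmtNum(v[, 3])),
             con)
  writeLines(paste(3L, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  invisible(file)
}
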
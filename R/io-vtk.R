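## VTK XML unstructured-grid export of meshes and per-element/per-node
## fields (the canonical field format of the pipeline), plus a reader
## for the subset this package writes, used for round-trip checks and
## downstream visualization.

.VTK_TET4 <- 10L
.VTK_TET10 <- 24L

.fmtNum <- function(x) sprintf("%.17g", x)

#' Export a mesh with named fields as a VTK unstructured grid (.vtu)
#'
#' Writes an ASCII VTK XML file with the mesh geometry, the element
#' region codes, and any number of named per-element (cell) or per-node
#' (point) numeric fields. Field placement is decided by length; a field
#' whose length matches neither the node nor the element count is
#' rejected by name. Values round-trip through
#' \code{\link{readVtu}} bitwise for integers and to full double
#' precision for floats.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param file output path (conventionally \code{.vtu}).
#' @param fields named list of numeric/integer vectors.
#' @return the file path, invisibly.
#' @export
exportVtk <- function(mesh, file, fields = list()) {
  nn <- nrow(mesh@nodes)
  m <- nrow(mesh@elements)
  if (length(fields) && (is.null(names(fields)) ||
                         any(names(fields) == "")))
    stop("all fields must be named", call. = FALSE)
  cell_fields <- list()
  point_fields <- list()
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (length(f) == m) cell_fields[[nm]] <- f
    else if (length(f) == nn) point_fields[[nm]] <- f
    else stop("field '", nm, "' has length ", length(f),
              "; expected ", m, " (cells) or ", nn, " (points)",
              call. = FALSE)
  }
  ## region codes always included as cell data
  rcode <- .REGION_CODES[mesh@elementRegion]
  rcode[is.na(rcode)] <- -1L
  cell_fields[["region"]] <- as.integer(rcode)

  darray <- function(x, name = NULL, ncomp = NULL) {
    type <- if (is.integer(x)) "Int32" else "Float64"
    vals <- if (is.integer(x)) paste(x, collapse = " ")
            else paste(.fmtNum(x), collapse = " ")
    paste0("<DataArray type=\"", type, "\"",
           if (!is.null(name)) paste0(" Name=\"", name, "\""),
           if (!is.null(ncomp)) paste0(" NumberOfComponents=\"", ncomp,
                                       "\""),
           " format=\"ascii\">\n", vals, "\n</DataArray>")
  }
  conn <- as.vector(t(mesh@elements)) - 1L
  offsets <- seq_len(m) * ncol(mesh@elements)
  ctype <- rep(if (mesh@order == 1L) .VTK_TET4 else .VTK_TET10, m)

  lines <- c(
    "<?xml version=\"1.0\"?>",
    paste0("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" ",
           "byte_order=\"LittleEndian\">"),
    "<UnstructuredGrid>",
    paste0("<Piece NumberOfPoints=\"", nn, "\" NumberOfCells=\"", m,
           "\">"),
    "<Points>",
    darray(as.numeric(t(mesh@nodes)), ncomp = 3),
    "</Points>",
    "<Cells>",
    darray(as.integer(conn), name = "connectivity"),
    darray(as.integer(offsets), name = "offsets"),
    darray(as.integer(ctype), name = "types"),
    "</Cells>",
    "<CellData>",
    vapply(names(cell_fields), function(nm)
      darray(cell_fields[[nm]], name = nm), character(1)),
    "</CellData>",
    "<PointData>",
    if (length(point_fields))
      vapply(names(point_fields), function(nm)
        darray(point_fields[[nm]], name = nm), character(1)),
    "</PointData>",
    "</Piece>",
    "</UnstructuredGrid>",
    "</VTKFile>")
  writeLines(unlist(lines), file)
  invisible(file)
}

#' Read a VTK unstructured grid written by exportVtk
#'
#' Parses the ASCII XML subset produced by \code{\link{exportVtk}}.
#'
#' @param file path to a \code{.vtu} file.
#' @return a list with \code{nodes}, \code{elements} (1-based),
#'   \code{cell_data} and \code{point_data} (named lists).
#' @export
readVtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  nn <- as.integer(xml2::xml_attr(piece, "NumberOfPoints"))
  m <- as.integer(xml2::xml_attr(piece, "NumberOfCells"))
  parseArray <- function(node) {
    txt <- xml2::xml_text(node)
    vals <- scan(text = txt, what = numeric(), quiet = TRUE)
    if (xml2::xml_attr(node, "type") == "Int32")
      vals <- as.integer(vals)
    vals
  }
  pts <- parseArray(xml2::xml_find_first(piece,
                                         ".//Points/DataArray"))
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  cells <- xml2::xml_find_all(piece, ".//Cells/DataArray")
  nmv <- vapply(cells, function(x) xml2::xml_attr(x, "Name"),
                character(1))
  conn <- parseArray(cells[[which(nmv == "connectivity")]])
  offs <- parseArray(cells[[which(nmv == "offsets")]])
  nper <- offs[1]
  elements <- matrix(as.integer(conn) + 1L, ncol = nper, byrow = TRUE)
  getData <- function(xp) {
    arrs <- xml2::xml_find_all(piece, xp)
    out <- lapply(arrs, parseArray)
    names(out) <- vapply(arrs, function(x) xml2::xml_attr(x, "Name"),
                         character(1))
    out
  }
  list(nodes = nodes, elements = elements,
       cell_data = getData(".//CellData/DataArray"),
       point_data = getData(".//PointData/DataArray"))
}
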
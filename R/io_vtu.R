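# Minimal ASCII VTK XML unstructured-grid IO for hexahedral meshes.
# Only what the pipeline needs: points, hexahedron cells, one integer cell
# field (element class) and optional point fields (enrichment set, solved
# displacement). No R package in the stack reads/writes VTU, so this is a
# deliberately small hand-written round-trippable subset.

#' Write a (possibly enriched, possibly solved) mesh as ASCII .vtu
#'
#' @param enr an `enriched_hex_mesh` (or `hex_mesh`).
#' @param path output path.
#' @param displacements optional `n x 3` nodal displacement point data.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(enr, path, displacements = NULL) {
  mesh <- if (inherits(enr, "enriched_hex_mesh")) enr$mesh else enr
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  eclass <- if (inherits(enr, "enriched_hex_mesh")) {
    match(enr$elem_class, c("standard", "cut", "tip")) - 1L
  } else rep(0L, ne)
  nset <- integer(nn)
  if (inherits(enr, "enriched_hex_mesh")) {
    nset[enr$J] <- 1L
    nset[enr$M] <- 2L
  }
  num <- function(x) paste(format(x, digits = 10, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, num), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(num(seq_len(ne) * 8L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(num(rep(12L, ne)), con)
  w('</DataArray></Cells>')
  w('<CellData Scalars="elem_class">')
  w('<DataArray type="Int32" Name="elem_class" format="ascii">')
  writeLines(num(eclass), con)
  w('</DataArray></CellData>')
  w('<PointData Scalars="enrichment">')
  w('<DataArray type="Int32" Name="enrichment" format="ascii">')
  writeLines(num(nset), con)
  w('</DataArray>')
  if (!is.null(displacements)) {
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    writeLines(apply(matrix(displacements, ncol = 3), 1, num), con)
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Read back an ASCII .vtu written by [write_mesh_vtu()]
#'
#' @param path file path.
#' @return list with `nodes`, `elems`, `elem_class`, `enrichment` and
#'   (when present) `displacements`.
#' @export
read_mesh_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  arr <- function(xpath) {
    nd <- xml2::xml_find_first(doc, xpath)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- matrix(arr("//Points/DataArray"), ncol = 3, byrow = TRUE)
  conn <- matrix(arr("//Cells/DataArray[@Name='connectivity']"),
                 ncol = 8, byrow = TRUE) + 1
  ecl <- arr("//CellData/DataArray[@Name='elem_class']")
  enrich <- arr("//PointData/DataArray[@Name='enrichment']")
  out <- list(nodes = pts, elems = conn,
              elem_class = c("standard", "cut", "tip")[ecl + 1],
              enrichment = as.integer(enrich))
  dnode <- xml2::xml_find_first(doc, "//PointData/DataArray[@Name='displacement']")
  if (!inherits(dnode, "xml_missing"))
    out$displacements <- matrix(scan(text = xml2::xml_text(dnode),
                                     quiet = TRUE), ncol = 3, byrow = TRUE)
  out
}
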
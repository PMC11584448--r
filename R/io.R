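#' Export a mesh (or deformed frame) as ASCII VTU
#'
#' Writes the tetrahedral volume mesh as a VTK XML unstructured grid
#' with the component label attached as cell data (integer code in the
#' order soft_layer, adipose, pectoralis, ligament, gland) and, when
#' given, a nodal displacement field as point data.
#'
#' @param mesh a `labelled_tet_mesh`.
#' @param path output `.vtu` path.
#' @param displacement optional length-`3n` displacement vector to store
#'   as a `displacement` point-data array.
#' @param cell_values optional named list of per-tet numeric arrays to
#'   store as extra cell data (e.g. von Mises stress).
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, displacement = NULL,
                      cell_values = NULL) {
  stopifnot(inherits(mesh, "labelled_tet_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  comp_levels <- c("soft_layer", "adipose", "pectoralis", "ligament",
                   "gland")
  code <- match(mesh$element_component, comp_levels)
  num <- function(x, collapse = " ") paste(format(x, trim = TRUE,
                                                  digits = 9),
                                           collapse = collapse)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('<Points>')
  w('<DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(mesh$nodes))))
  w('</DataArray>')
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(num(as.vector(t(mesh$tets)) - 1L))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(num(4L * seq_len(m)))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(num(rep(10L, m)))
  w('</DataArray>')
  w('</Cells>')
  w('<CellData Scalars="component">')
  w('<DataArray type="Int32" Name="component" format="ascii">')
  w(num(code))
  w('</DataArray>')
  if (!is.null(cell_values)) {
    for (nm in names(cell_values)) {
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      w(num(cell_values[[nm]]))
      w('</DataArray>')
    }
  }
  w('</CellData>')
  if (!is.null(displacement)) {
    w('<PointData Vectors="displacement">')
    w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    w(num(displacement))
    w('</DataArray>')
    w('</PointData>')
  }
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Export the breast outer surface as ASCII STL or OBJ
#'
#' Writes the skin shell triangles (optionally restricted to the breast
#' surface node set) as a triangle soup.
#'
#' @param mesh a `labelled_tet_mesh`.
#' @param path output path; format chosen by extension (`.stl`/`.obj`).
#' @param breast_only keep only triangles whose vertices all lie on the
#'   `breast_surface` node set?
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, breast_only = TRUE) {
  stopifnot(inherits(mesh, "labelled_tet_mesh"))
  tris <- mesh$shells
  if (breast_only) {
    keep <- matrixStats_all_in(tris, mesh$node_sets$breast_surface)
    tris <- tris[keep, , drop = FALSE]
  }
  nd <- mesh$nodes
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid breast", con)
    for (i in seq_len(nrow(tris))) {
      a <- nd[tris[i, 1], ]; b <- nd[tris[i, 2], ]; c <- nd[tris[i, 3], ]
      nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
               (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
               (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
      nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
      writeLines(c(sprintf("facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                   "  outer loop",
                   sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                   sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                   sprintf("    vertex %g %g %g", c[1], c[2], c[3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid breast", con)
  } else if (ext == "obj") {
    ids <- sort(unique(as.vector(tris)))
    remap <- match(seq_len(nrow(nd)), ids)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %g %g %g", nd[ids, 1], nd[ids, 2], nd[ids, 3]),
               con)
    writeLines(sprintf("f %d %d %d", remap[tris[, 1]], remap[tris[, 2]],
                       remap[tris[, 3]]), con)
  } else stop("unsupported surface format: .", ext)
  invisible(path)
}

#' Read a triangle surface mesh (ASCII STL or OBJ)
#'
#' Entry point for real scan data: reads a triangulated surface into the
#' `nodes`/`triangles` list layout used by [surface_sequence()].
#'
#' @param path `.stl` (ASCII) or `.obj` file.
#' @return List with `nodes` (n x 3) and `triangles` (t x 3).
#' @export
read_surface <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    ln <- readLines(path)
    vs <- ln[startsWith(ln, "v ")]
    fs <- ln[startsWith(ln, "f ")]
    nodes <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(p)
      as.numeric(p[2:4])))
    tris <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(p)
      as.integer(sub("/.*", "", p[2:4]))))
    return(list(nodes = nodes, triangles = tris))
  }
  if (ext == "stl") {
    ln <- readLines(path)
    vx <- ln[grepl("^\\s*vertex", ln)]
    co <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p)
      as.numeric(p[2:4])))
    key <- paste(co[, 1], co[, 2], co[, 3])
    ids <- match(key, unique(key))
    nodes <- co[!duplicated(key), , drop = FALSE]
    tris <- matrix(ids, ncol = 3, byrow = TRUE)
    return(list(nodes = nodes, triangles = tris))
  }
  stop("unsupported surface format: .", ext)
}
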
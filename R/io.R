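## Mesh and solution I/O: ASCII VTU (XML unstructured grid) writer/reader
## and ASCII STL surface export. Node indexing is 1-based internally and
## converted to the 0-based VTU dialect on write.

#' Write a mesh (with optional fields) as ASCII VTU
#'
#' Part/region/zone labels are written as integer cell data, the fiber
#' direction as a cell vector field, and any user-supplied point/cell data
#' alongside.
#'
#' @param mesh `fe_mesh`.
#' @param file output path (.vtu).
#' @param point_data named list of per-node vectors or (N x k) matrices.
#' @param cell_data named list of per-element vectors or matrices.
#' @return Invisibly, the file path.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  N <- nrow(mesh$nodes); M <- nrow(mesh$tets)
  if (!is.null(mesh$region)) cell_data$region <- as.integer(mesh$region)
  if (!is.null(mesh$zone)) cell_data$zone <- as.integer(mesh$zone)
  if (!is.null(mesh$fiber)) cell_data$fiber_dir <- mesh$fiber
  num <- function(x) paste(format(x, digits = 10, trim = TRUE, scientific = TRUE),
                           collapse = " ")
  da <- function(name, x) {
    x <- as.matrix(x)
    nc <- ncol(x)
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, nc, num(as.numeric(t(x))))
  }
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(fmt, ...) {
    if (...length()) writeLines(sprintf(fmt, ...), con) else writeLines(fmt, con)
  }
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w('<Piece NumberOfPoints="%d" NumberOfCells="%d">', N, M)
  w('<Points>')
  w(da("Points", mesh$nodes))
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">\n%s\n</DataArray>',
    paste(as.integer(t(mesh$tets)) - 1L, collapse = " "))
  w('<DataArray type="Int32" Name="offsets" format="ascii">\n%s\n</DataArray>',
    paste(seq_len(M) * 4L, collapse = " "))
  w('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>',
    paste(rep(10L, M), collapse = " "))
  w('</Cells>')
  w('<PointData>')
  for (nm in names(point_data)) w(da(nm, point_data[[nm]]))
  w('</PointData>')
  w('<CellData>')
  for (nm in names(cell_data)) w(da(nm, cell_data[[nm]]))
  w('</CellData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Read an ASCII VTU tetrahedral mesh
#'
#' Reads meshes written by [write_vtu()] (and other ASCII VTU files with
#' linear tetrahedra). Point/cell data arrays are returned alongside.
#'
#' @param file path to a .vtu file.
#' @return `fe_mesh` with `point_data` and `cell_data` attributes.
#' @export
read_vtu <- function(file) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "\n")
  getblock <- function(name, all = FALSE) {
    pat <- sprintf('<DataArray[^>]*Name="%s"[^>]*>([^<]*)</DataArray>', name)
    m <- regmatches(txt, gregexpr(pat, txt))[[1]]
    vals <- lapply(m, function(s) {
      body <- sub(pat, "\\1", s)
      as.numeric(strsplit(trimws(body), "[ \t\n]+")[[1]])
    })
    if (all) vals else vals[[1]]
  }
  pts <- matrix(getblock("Points"), ncol = 3L, byrow = TRUE)
  conn <- as.integer(getblock("connectivity")) + 1L
  types <- as.integer(getblock("types"))
  if (any(types != 10L)) stop("read_vtu supports linear tetrahedra only")
  tets <- matrix(conn, ncol = 4L, byrow = TRUE)
  ## named arrays other than the structural ones
  nms <- regmatches(txt, gregexpr('<DataArray[^>]*Name="([^"]+)"', txt))[[1]]
  nms <- unique(sub('.*Name="([^"]+)".*', "\\1", nms))
  nms <- setdiff(nms, c("Points", "connectivity", "offsets", "types"))
  extra <- lapply(nms, function(nm) {
    v <- getblock(nm)
    ncomp <- as.integer(sub('.*NumberOfComponents="(\\d+)".*', "\\1",
                            regmatches(txt, regexpr(
                              sprintf('<DataArray[^>]*Name="%s"[^>]*>', nm), txt))))
    if (is.na(ncomp) || ncomp <= 1L) v else matrix(v, ncol = ncomp, byrow = TRUE)
  })
  names(extra) <- nms
  bf <- boundary_faces(tets)
  mesh <- new_fe_mesh(pts, tets, part = "imported",
                      facets = list(boundary = bf$faces))
  attr(mesh, "data") <- extra
  mesh
}

#' Write a triangulated surface as ASCII STL
#'
#' @param nodes N x 3 coordinates.
#' @param faces F x 3 triangle node ids.
#' @param file output path.
#' @param name solid name.
#' @return Invisibly, the file path.
#' @export
write_stl <- function(nodes, faces, file, name = "surface") {
  fa <- facet_areas_normals(nodes, faces)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (f in seq_len(nrow(faces))) {
    writeLines(sprintf("  facet normal %g %g %g",
                       fa$normal[f, 1], fa$normal[f, 2], fa$normal[f, 3]), con)
    writeLines("    outer loop", con)
    for (v in 1:3) {
      p <- nodes[faces[f, v], ]
      writeLines(sprintf("      vertex %g %g %g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(file)
}

#' Export the synthetic geometry surfaces as STL
#'
#' Writes the boundary surface of each meshed solid to
#' `<dir>/<part>.stl`.
#'
#' @param geometry `knee_geometry`.
#' @param dir output directory.
#' @param resolution `mesh_resolution` used for surface triangulation.
#' @return Invisibly, the written file paths.
#' @export
export_geometry_stl <- function(geometry, dir, resolution = mesh_resolution()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meshes <- list(
    meniscus_MM = mesh_meniscus(geometry, "MM", resolution),
    meniscus_LM = mesh_meniscus(geometry, "LM", resolution),
    tibial_cartilage_med = mesh_tibial_cartilage(geometry, "MM", resolution),
    tibial_cartilage_lat = mesh_tibial_cartilage(geometry, "LM", resolution),
    femoral_cartilage_med = mesh_femoral_cartilage(geometry, "MM", resolution),
    femoral_cartilage_lat = mesh_femoral_cartilage(geometry, "LM", resolution))
  paths <- character(0)
  for (nm in names(meshes)) {
    mesh <- meshes[[nm]]
    faces <- do.call(rbind, mesh$facets)
    path <- file.path(dir, paste0(nm, ".stl"))
    write_stl(mesh$nodes, faces, path, name = nm)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Export a knee solution as VTU
#'
#' One VTU file per part with displacement (point data), the Voigt stress,
#' principal stresses and contact force (where applicable).
#'
#' @param solution `knee_solution`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Invisibly, the written file paths.
#' @export
export_solution_vtu <- function(solution, dir, prefix = "solution") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- solution$knee$fe
  paths <- character(0)
  for (p in names(model$parts)) {
    mesh <- model$parts[[p]]$mesh
    gn <- global_nodes(model, p)
    path <- file.path(dir, sprintf("%s_%s.vtu", prefix, p))
    write_vtu(mesh, path,
              point_data = list(displacement = solution$u[gn, , drop = FALSE],
                                contact_force = solution$contact_force[gn, , drop = FALSE]),
              cell_data = list(stress_voigt = solution$stresses[[p]]$voigt,
                               principal_stress = solution$stresses[[p]]$principal))
    paths <- c(paths, path)
  }
  invisible(paths)
}
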
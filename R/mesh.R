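## Structured sweep meshing of the deformable solids with linear tetrahedra.
##
## All solids are meshed as structured (i, j, k) grids of hexahedral cells,
## each split into 6 tetrahedra by the Freudenthal (Kuhn) subdivision, which
## is face-consistent across a structured grid and therefore reproducible
## bit-for-bit. Meniscal meshes retain their sweep parameterisation
## (psi, s, v) per node and per element, which downstream modules use for
## region/zone labelling and tear insertion.

#' Mesh resolution settings
#'
#' @param circumferential number of element divisions along the meniscal arc
#'   (>= 2; a multiple of 6 places region boundaries, region mid-lines and
#'   the longitudinal tear line on element boundaries).
#' @param radial element divisions across the rim width (multiple of 3 so
#'   zone boundaries fall on element boundaries; the default 12 also puts
#'   the longitudinal tear line s = 5/6 on a boundary).
#' @param vertical element divisions through the wedge height (>= 2).
#' @param cartilage element divisions across each cartilage block/cap edge.
#' @param cartilage_thickness_div through-thickness divisions for cartilage.
#' @return Object of class `mesh_resolution`.
#' @export
mesh_resolution <- function(circumferential = 60, radial = 12, vertical = 2,
                            cartilage = 10, cartilage_thickness_div = 2) {
  r <- list(circumferential = as.integer(circumferential),
            radial = as.integer(radial),
            vertical = as.integer(vertical),
            cartilage = as.integer(cartilage),
            cartilage_thickness_div = as.integer(cartilage_thickness_div))
  if (any(unlist(r) < 2L) || r$cartilage_thickness_div < 1L)
    stop("mesh resolution divisions must all be >= 2 (thickness >= 1)")
  if (r$radial %% 3L != 0L)
    stop("radial divisions must be a multiple of 3 so zone boundaries fall on element boundaries")
  structure(r, class = "mesh_resolution")
}

## The 6 tetrahedra of the Freudenthal split of a unit cell, as corner
## indices into the (dx, dy, dz) binary corner table, one row per increment
## permutation. Corner id = 1 + dx + 2*dy + 4*dz.
freudenthal_tets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  t(vapply(perms, function(p) {
    v <- matrix(0, 4, 3)
    v[2, p[1]] <- 1
    v[3, ] <- v[2, ]; v[3, p[2]] <- 1
    v[4, ] <- c(1, 1, 1)
    as.integer(1 + v[, 1] + 2 * v[, 2] + 4 * v[, 3])
  }, integer(4)))
}

## Build tets for an (n1 x n2 x n3) cell grid whose node ids follow
## id = 1 + i*(n2+1)*(n3+1) + j*(n3+1) + k  (i = 0..n1 etc.).
structured_tets <- function(n1, n2, n3) {
  nid <- function(i, j, k) 1L + i * (n2 + 1L) * (n3 + 1L) + j * (n3 + 1L) + k
  cells <- expand.grid(i = 0:(n1 - 1L), j = 0:(n2 - 1L), k = 0:(n3 - 1L))
  corn <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)      # corner id order 1..8
  corner_ids <- matrix(0L, nrow(cells), 8L)
  for (c8 in 1:8)
    corner_ids[, c8] <- nid(cells$i + corn$dx[c8], cells$j + corn$dy[c8], cells$k + corn$dz[c8])
  tpl <- freudenthal_tets()
  tets <- matrix(0L, nrow(cells) * 6L, 4L)
  cell_of <- integer(nrow(cells) * 6L)
  for (tt in 1:6) {
    rows <- seq(tt, by = 6L, length.out = nrow(cells))
    tets[rows, ] <- corner_ids[, tpl[tt, ]]
    cell_of[rows] <- seq_len(nrow(cells))
  }
  list(tets = tets, cell = cells[cell_of, , drop = FALSE])
}

#' Signed volumes of tetrahedral elements
#'
#' @param nodes N x 3 node coordinates, mm.
#' @param tets M x 4 node indices.
#' @return Length-M vector of signed volumes, mm^3.
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
     a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
     a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

## Flip tets with negative volume (swap last two nodes); curvilinear cell
## mappings may reverse handedness (e.g. the mirrored lateral sweep frame).
orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  neg <- v < 0
  if (any(neg)) tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  v0 <- tet_volumes(nodes, tets)
  if (any(v0 <= 0)) stop("meshing error: degenerate (zero-volume) tetrahedra")
  tets
}

## Boundary triangles of a tet mesh: faces appearing exactly once.
## Returns matrix with columns n1, n2, n3 (original winding), elem.
boundary_faces <- function(tets) {
  fidx <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  M <- nrow(tets)
  faces <- matrix(0L, 4L * M, 3L)
  elem <- rep(seq_len(M), each = 4L)
  for (f in 1:4) faces[seq(f, by = 4L, length.out = M), ] <- tets[, fidx[f, ]]
  sorted <- t(apply(faces, 1L, sort))
  key <- paste(sorted[, 1], sorted[, 2], sorted[, 3])
  tab <- table(key)
  once <- key %in% names(tab)[tab == 1L]
  list(faces = faces[once, , drop = FALSE], elem = elem[once])
}

## Classify boundary triangles of a structured grid into the six grid faces
## using per-node grid indices (N x 3 matrix, 0-based) and grid extents.
classify_grid_boundary <- function(bf, ijk, n, names6) {
  out <- stats::setNames(vector("list", 6L), names6)
  sel <- function(cond) bf$faces[cond, , drop = FALSE]
  at <- function(dim, val) {
    m <- matrix(ijk[bf$faces, dim], nrow(bf$faces), 3L)
    rowSums(m == val) == 3L
  }
  out[[1]] <- sel(at(1L, 0L));    out[[2]] <- sel(at(1L, n[1]))
  out[[3]] <- sel(at(2L, 0L));    out[[4]] <- sel(at(2L, n[2]))
  out[[5]] <- sel(at(3L, 0L));    out[[6]] <- sel(at(3L, n[3]))
  out
}

.mesh_counter <- new.env(parent = emptyenv())

new_fe_mesh <- function(nodes, tets, part, facets, ...) {
  n <- (get0("n", envir = .mesh_counter, ifnotfound = 0L)) + 1L
  assign("n", n, envir = .mesh_counter)
  structure(c(list(nodes = nodes, tets = tets, part = part, facets = facets,
                   uid = sprintf("%s#%d", part, n)),
              list(...)),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("FE mesh '%s': %d nodes, %d linear tets, facet sets: %s\n",
              x$part, nrow(x$nodes), nrow(x$tets),
              paste(names(x$facets), collapse = ", ")))
  invisible(x)
}

#' Mesh a meniscus as a swept structured tetrahedral grid
#'
#' Sweeps the wedge cross-section along the meniscal arc and splits each
#' cell into 6 tetrahedra. Populates part/region/zone labels, per-element
#' circumferential fiber directions and the boundary facet sets
#' (`inferior`, `superior`, `inner_rim`, `outer_wall`, `end_anterior`,
#' `end_posterior`).
#'
#' @param geometry `knee_geometry`.
#' @param side "MM" or "LM".
#' @param resolution `mesh_resolution`.
#' @return `fe_mesh` carrying sweep parameters (`node_param`, `elem_param`).
#' @export
mesh_meniscus <- function(geometry, side = c("MM", "LM"), resolution = mesh_resolution()) {
  side <- match.arg(side)
  men <- geometry$menisci[[side]]
  if (men$h_in <= 1e-9 || men$h <= 1e-9)
    stop("meshing error: degenerate wedge cross-section (zero height)")
  nc <- resolution$circumferential; nr <- resolution$radial; nv <- resolution$vertical
  psi <- seq(men$psi0, men$psi1, length.out = nc + 1L)
  s <- seq(0, 1, length.out = nr + 1L)
  v <- seq(0, 1, length.out = nv + 1L)
  g <- expand.grid(k = 0:nv, j = 0:nr, i = 0:nc)   # k fastest: matches structured_tets id order
  g <- g[, c("i", "j", "k")]
  nodes <- meniscus_point(men, psi[g$i + 1L], s[g$j + 1L], v[g$k + 1L])
  node_param <- cbind(psi = psi[g$i + 1L], s = s[g$j + 1L], v = v[g$k + 1L])
  st <- structured_tets(nc, nr, nv)
  tets <- orient_tets(nodes, st$tets)
  elem_param <- cbind(psi = psi[st$cell$i + 1L] + diff(psi[1:2]) / 2,
                      s = s[st$cell$j + 1L] + diff(s[1:2]) / 2,
                      v = v[st$cell$k + 1L] + diff(v[1:2]) / 2)
  bf <- boundary_faces(tets)
  facets <- classify_grid_boundary(bf, as.matrix(g), c(nc, nr, nv),
                                   c("end_anterior", "end_posterior",
                                     "inner_rim", "outer_wall",
                                     "inferior", "superior"))
  mesh <- new_fe_mesh(nodes, tets, part = paste0("meniscus_", side), facets = facets,
                      side = side, resolution = resolution,
                      node_ijk = as.matrix(g), elem_cell = as.matrix(st$cell),
                      node_param = node_param, elem_param = elem_param,
                      sweep = list(psi0 = men$psi0, psi1 = men$psi1,
                                   centre = men$centre, u_mid = men$u_mid,
                                   u_ant = men$u_ant, r_in = men$r_in,
                                   r_out = men$r_out))
  mesh <- assign_fiber_directions(mesh)
  label_regions_zones(mesh, geometry)
}

#' Assign per-element circumferential fiber directions
#'
#' The fiber direction of every meniscal element is the unit tangent of the
#' sweep at the element centroid. Idempotent.
#'
#' @param mesh meniscal `fe_mesh` (sweep parameterisation retained).
#' @return The mesh with `fiber` (M x 3) populated.
#' @export
assign_fiber_directions <- function(mesh) {
  if (is.null(mesh$sweep)) stop("mesh has no sweep parameterisation (not a meniscal mesh)")
  sw <- mesh$sweep
  ## arc angle of each element's true centroid (not the cell centre), so
  ## the tangent is orthogonal to the element's own radial direction
  cen <- (mesh$nodes[mesh$tets[, 1], , drop = FALSE] +
            mesh$nodes[mesh$tets[, 2], , drop = FALSE] +
            mesh$nodes[mesh$tets[, 3], , drop = FALSE] +
            mesh$nodes[mesh$tets[, 4], , drop = FALSE]) / 4
  d <- cen - matrix(c(sw$centre, 0), nrow(cen), 3L, byrow = TRUE)
  psi <- atan2(d[, 1] * sw$u_ant[1] + d[, 2] * sw$u_ant[2],
               d[, 1] * sw$u_mid[1] + d[, 2] * sw$u_mid[2])
  psi <- ifelse(psi < sw$psi0 - 1e-9, psi + 2 * pi, psi)
  f <- outer(-sin(psi), sw$u_mid) + outer(cos(psi), sw$u_ant)
  mesh$fiber <- f / sqrt(rowSums(f^2))
  mesh
}

#' Label meniscal regions and zones
#'
#' Region = circumferential tercile of the arc (anterior, middle, posterior
#' thirds, anterior to posterior); zone = radial tercile of the normalised
#' rim-width coordinate s (inner/white, middle/red-white, outer/red). An
#' element's labels are determined by its centroid, so labelling is
#' invariant to mesh resolution.
#'
#' @param mesh meniscal `fe_mesh`.
#' @param geometry `knee_geometry` (unused beyond validation; labels derive
#'   from the sweep parameterisation carried by the mesh).
#' @return The mesh with `region` and `zone` factors populated.
#' @export
label_regions_zones <- function(mesh, geometry = NULL) {
  if (is.null(mesh$sweep)) stop("mesh has no sweep parameterisation (not a meniscal mesh)")
  frac <- (mesh$elem_param[, "psi"] - mesh$sweep$psi0) /
    (mesh$sweep$psi1 - mesh$sweep$psi0)
  mesh$region <- factor(c("anterior", "middle", "posterior")[pmin(3L, 1L + floor(frac * 3))],
                        levels = c("anterior", "middle", "posterior"))
  sfrac <- mesh$elem_param[, "s"]
  mesh$zone <- factor(c("inner", "middle", "outer")[pmin(3L, 1L + floor(sfrac * 3))],
                      levels = c("inner", "middle", "outer"))
  mesh
}

#' Mesh a tibial cartilage block
#'
#' Rectangular layer of thickness `cartilage_thickness_tibial` bonded to the
#' tibial plateau under one compartment. Facet sets: `bone` (inferior, bonded),
#' `articular` (superior), and four side walls in `rim`.
#'
#' @param geometry `knee_geometry`.
#' @param side compartment, "MM" (medial) or "LM" (lateral).
#' @param resolution `mesh_resolution`.
#' @param margin extra footprint beyond the meniscal outer radius, mm.
#' @return `fe_mesh`.
#' @export
mesh_tibial_cartilage <- function(geometry, side = c("MM", "LM"),
                                  resolution = mesh_resolution(), margin = 2) {
  side <- match.arg(side)
  men <- geometry$menisci[[side]]
  t_t <- geometry$tibia$cartilage_thickness
  half <- men$r_out + margin
  n <- resolution$cartilage; nt <- resolution$cartilage_thickness_div
  xs <- seq(men$centre[1] - half, men$centre[1] + half, length.out = n + 1L)
  ys <- seq(men$centre[2] - half, men$centre[2] + half, length.out = n + 1L)
  zs <- seq(0, t_t, length.out = nt + 1L)
  g <- expand.grid(k = 0:nt, j = 0:n, i = 0:n)[, c("i", "j", "k")]
  nodes <- cbind(xs[g$i + 1L], ys[g$j + 1L], zs[g$k + 1L])
  st <- structured_tets(n, n, nt)
  tets <- orient_tets(nodes, st$tets)
  bf <- boundary_faces(tets)
  f6 <- classify_grid_boundary(bf, as.matrix(g), c(n, n, nt),
                               c("xmin", "xmax", "ymin", "ymax", "bone", "articular"))
  facets <- list(bone = f6$bone, articular = f6$articular,
                 rim = do.call(rbind, f6[c("xmin", "xmax", "ymin", "ymax")]))
  part <- if (side == "MM") "tibial_cartilage_med" else "tibial_cartilage_lat"
  new_fe_mesh(nodes, tets, part = part, facets = facets,
              side = side, resolution = resolution, node_ijk = as.matrix(g))
}

#' Mesh a femoral cartilage cap
#'
#' Spherical shell between the rigid condylar bone sphere (radius R) and the
#' articular surface (radius R + thickness), meshed over a uniform angular
#' grid centred on the downward axis of the posed condyle. Because the
#' condylar surfaces are spheres, generating the cap about the posed
#' downward axis represents the posed cartilage exactly. Facet sets:
#' `bone` (inner, bonded to the femur), `articular` (outer), `rim`.
#'
#' @param geometry `knee_geometry`.
#' @param side "MM" or "LM".
#' @param resolution `mesh_resolution`.
#' @param pose optional `bone_pose` (default reference pose).
#' @param cap_half_angle_deg angular halfwidth of the cap, degrees.
#' @return `fe_mesh`; carries the posed sphere `centre` and radii.
#' @export
mesh_femoral_cartilage <- function(geometry, side = c("MM", "LM"),
                                   resolution = mesh_resolution(), pose = NULL,
                                   cap_half_angle_deg = 40) {
  side <- match.arg(side)
  cdl <- geometry$femur$condyles[[side]]
  centre <- if (is.null(pose)) cdl$centre else transform_points(pose$transform, cdl$centre)
  Rb <- cdl$radius_bone; Ro <- cdl$radius_outer
  n <- resolution$cartilage; nt <- resolution$cartilage_thickness_div
  amax <- cap_half_angle_deg * pi / 180
  al <- seq(-amax, amax, length.out = n + 1L)   # rotation towards +y (anterior)
  be <- seq(-amax, amax, length.out = n + 1L)   # rotation towards +x (lateral)
  ws <- seq(0, 1, length.out = nt + 1L)         # 0 = articular, 1 = bone side
  g <- expand.grid(k = 0:nt, j = 0:n, i = 0:n)[, c("i", "j", "k")]
  a <- al[g$i + 1L]; b <- be[g$j + 1L]
  dir <- cbind(sin(b), cos(b) * sin(a), -cos(b) * cos(a))
  rho <- Ro - ws[g$k + 1L] * (Ro - Rb)
  nodes <- sweep(dir * rho, 2L, centre, "+")
  st <- structured_tets(n, n, nt)
  tets <- orient_tets(nodes, st$tets)
  bf <- boundary_faces(tets)
  f6 <- classify_grid_boundary(bf, as.matrix(g), c(n, n, nt),
                               c("amin", "amax", "bmin", "bmax", "articular", "bone"))
  facets <- list(bone = f6$bone, articular = f6$articular,
                 rim = do.call(rbind, f6[c("amin", "amax", "bmin", "bmax")]))
  part <- if (side == "MM") "femoral_cartilage_med" else "femoral_cartilage_lat"
  new_fe_mesh(nodes, tets, part = part, facets = facets,
              side = side, resolution = resolution, node_ijk = as.matrix(g),
              sphere = list(centre = centre, radius_bone = Rb, radius_outer = Ro))
}

#' Mesh cartilage layers
#'
#' Convenience wrapper returning the requested cartilage layer mesh.
#'
#' @param geometry `knee_geometry`.
#' @param resolution `mesh_resolution`.
#' @param part one of "tibial_med", "tibial_lat", "femoral_med", "femoral_lat".
#' @param pose optional `bone_pose` for femoral caps.
#' @return `fe_mesh`.
#' @export
mesh_cartilage <- function(geometry, resolution = mesh_resolution(),
                           part = c("tibial_med", "tibial_lat", "femoral_med", "femoral_lat"),
                           pose = NULL) {
  part <- match.arg(part)
  switch(part,
         tibial_med  = mesh_tibial_cartilage(geometry, "MM", resolution),
         tibial_lat  = mesh_tibial_cartilage(geometry, "LM", resolution),
         femoral_med = mesh_femoral_cartilage(geometry, "MM", resolution, pose),
         femoral_lat = mesh_femoral_cartilage(geometry, "LM", resolution, pose))
}

#' Total mesh volume
#' @param mesh `fe_mesh`.
#' @return Sum of element volumes, mm^3.
#' @export
mesh_volume <- function(mesh) sum(tet_volumes(mesh$nodes, mesh$tets))

## Areas and outward-ish normals of a facet triangle set on given coordinates.
facet_areas_normals <- function(nodes, faces) {
  p1 <- nodes[faces[, 1], , drop = FALSE]
  e1 <- nodes[faces[, 2], , drop = FALSE] - p1
  e2 <- nodes[faces[, 3], , drop = FALSE] - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a <- sqrt(rowSums(cr^2))
  list(area = a / 2, normal = cr / a)
}
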
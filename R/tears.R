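## Meniscal tear insertion by node duplication along a tear surface.
##
## Tears are realised on existing element faces of the structured sweep mesh
## (snap-to-mesh): a longitudinal tear lies on the cylindrical element
## boundary s = 5/6 (the centre of the outer/red third); a radial tear lies
## on a radial element-boundary plane at the circumferential centre of its
## region, starting at the inner rim. Both are full thickness. The achieved
## length is reported so the snapping discretisation error is explicit.

#' Specify a meniscal tear
#'
#' @param tear_type "longitudinal" (vertical, parallel to the circumferential
#'   fibers, centred radially at s = 5/6) or "radial" (radial plane starting
#'   at the inner rim, in the white zone).
#' @param meniscus "MM" or "LM".
#' @param region "anterior", "middle" or "posterior" circumferential third.
#' @param stability "stable" or "unstable". Stable/unstable longitudinal
#'   tears are 7/14 mm long; stable/unstable radial tears extend 1/6 and 1/2
#'   of the local rim width from the inner rim.
#' @param length_mm longitudinal tear arc length, mm (default by stability).
#' @param extent_fraction radial tear rim-width fraction (default by
#'   stability).
#' @return Object of class `tear_spec`.
#' @export
tear_spec <- function(tear_type = c("longitudinal", "radial"),
                      meniscus = c("MM", "LM"),
                      region = c("anterior", "middle", "posterior"),
                      stability = c("stable", "unstable"),
                      length_mm = NULL, extent_fraction = NULL) {
  tear_type <- match.arg(tear_type)
  meniscus <- match.arg(meniscus)
  region <- match.arg(region)
  stability <- match.arg(stability)
  if (tear_type == "longitudinal") {
    if (is.null(length_mm)) length_mm <- if (stability == "stable") 7 else 14
    if (length_mm <= 0) stop("empty tear path: longitudinal tear length must be > 0")
    extent_fraction <- NA_real_
  } else {
    if (is.null(extent_fraction)) extent_fraction <- if (stability == "stable") 1 / 6 else 1 / 2
    if (extent_fraction <= 0 || extent_fraction > 1)
      stop("empty tear path: radial extent fraction must be in (0, 1]")
    length_mm <- NA_real_
  }
  structure(list(tear_type = tear_type, meniscus = meniscus, region = region,
                 stability = stability, length_mm = length_mm,
                 extent_fraction = extent_fraction, depth = "full"),
            class = "tear_spec")
}

#' @export
print.tear_spec <- function(x, ...) {
  sz <- if (x$tear_type == "longitudinal") sprintf("%.1f mm", x$length_mm)
        else sprintf("%.3g of rim width", x$extent_fraction)
  cat(sprintf("%s %s tear, %s meniscus, %s region, %s\n",
              x$stability, x$tear_type, x$meniscus, x$region, sz))
  invisible(x)
}

## region centre as arc fraction
region_centre_fraction <- function(region) {
  c(anterior = 1 / 6, middle = 1 / 2, posterior = 5 / 6)[[region]]
}

#' Locate the tear surface on a meniscal mesh
#'
#' Snaps the requested tear to element boundaries and returns the cut
#' description: the node columns to duplicate, the shared front (tip/apex)
#' nodes, the cut side rule and the achieved size.
#'
#' @param mesh meniscal `fe_mesh`.
#' @param spec `tear_spec`.
#' @return Object of class `tear_surface` with `achieved_length_mm`
#'   (longitudinal) or `achieved_extent_fraction` (radial).
#' @export
locate_tear_surface <- function(mesh, spec) {
  if (is.null(mesh$sweep)) stop("not a meniscal mesh")
  if (!is.null(mesh$side) && !identical(mesh$side, spec$meniscus))
    stop(sprintf("tear specifies meniscus %s but mesh is %s", spec$meniscus, mesh$side))
  sw <- mesh$sweep
  nc <- mesh$resolution$circumferential
  nr <- mesh$resolution$radial
  nv <- mesh$resolution$vertical
  span <- sw$psi1 - sw$psi0
  dpsi <- span / nc
  W <- sw$r_out - sw$r_in
  ijk <- mesh$node_ijk
  cf <- region_centre_fraction(spec$region)
  if (spec$tear_type == "longitudinal") {
    s_cut <- 5 / 6
    j_cut <- s_cut * nr
    if (abs(j_cut - round(j_cut)) > 1e-9)
      stop("resolution too coarse: radial divisions must place s = 5/6 on an element boundary (use a multiple of 6)")
    j_cut <- as.integer(round(j_cut))
    r_cut <- sw$r_in + s_cut * W
    edge <- dpsi * r_cut
    k <- as.integer(round(spec$length_mm / edge))
    if (k < 2L)
      stop(sprintf("resolution too coarse: requested %.1f mm tear spans %d element edge(s); need >= 2",
                   spec$length_mm, k))
    if (k * dpsi > span / 3 + 1e-9)
      stop("requested tear exceeds the circumferential extent of its region")
    i_mid <- cf * nc
    i0 <- as.integer(round(i_mid - k / 2))
    i0 <- max(0L, min(nc - k, i0))
    achieved <- k * edge
    dup <- which(ijk[, 2] == j_cut & ijk[, 1] > i0 & ijk[, 1] < i0 + k)
    front <- which(ijk[, 2] == j_cut & (ijk[, 1] == i0 | ijk[, 1] == i0 + k))
    structure(list(type = "longitudinal", spec = spec,
                   dup_nodes = dup, front_nodes = front,
                   side_var = "s", cut_value = s_cut,
                   i_range = c(i0, i0 + k), j_cut = j_cut,
                   achieved_length_mm = achieved,
                   edge_length_mm = edge),
              class = "tear_surface")
  } else {
    i_cut <- cf * nc
    if (abs(i_cut - round(i_cut)) > 1e-9)
      stop("resolution too coarse: circumferential divisions must place the region centre on an element boundary (use a multiple of 6)")
    i_cut <- as.integer(round(i_cut))
    layers <- as.integer(round(spec$extent_fraction * nr))
    if (layers < 2L)
      stop(sprintf("resolution too coarse: requested extent %.3g of rim width spans %d element layer(s); need >= 2",
                   spec$extent_fraction, layers))
    if (layers > nr) stop("requested tear exceeds the rim width")
    psi_cut <- sw$psi0 + i_cut * dpsi
    dup <- which(ijk[, 1] == i_cut & ijk[, 2] < layers)
    front <- which(ijk[, 1] == i_cut & ijk[, 2] == layers)
    structure(list(type = "radial", spec = spec,
                   dup_nodes = dup, front_nodes = front,
                   side_var = "psi", cut_value = psi_cut,
                   i_cut = i_cut, layers = layers,
                   achieved_extent_fraction = layers / nr,
                   achieved_length_mm = layers / nr * W,
                   edge_length_mm = W / nr),
              class = "tear_surface")
  }
}

#' @export
print.tear_surface <- function(x, ...) {
  if (x$type == "longitudinal")
    cat(sprintf("Longitudinal tear surface at s = 5/6: achieved length %.2f mm (element edge %.2f mm)\n",
                x$achieved_length_mm, x$edge_length_mm))
  else
    cat(sprintf("Radial tear surface: achieved extent %.3f of rim width (%.2f mm)\n",
                x$achieved_extent_fraction, x$achieved_length_mm))
  invisible(x)
}

#' Split a meniscal mesh along a tear surface
#'
#' Duplicates the interior tear-surface nodes, reconnects the elements on
#' the positive side to the copies, rebuilds the boundary facet sets and
#' adds the two tear faces as facet sets (`tear_face_neg`, `tear_face_pos`;
#' for a longitudinal tear the negative face is the inner one). Element
#' count is unchanged; the two faces are geometrically coincident in the
#' unloaded state; the front (tip/apex) nodes remain shared.
#'
#' @param mesh meniscal `fe_mesh`.
#' @param surface `tear_surface` from [locate_tear_surface()].
#' @return list(mesh = torn `fe_mesh`, topology = `tear_topology`).
#' @export
split_mesh <- function(mesh, surface) {
  dup <- surface$dup_nodes
  if (!length(dup)) stop("empty tear path")
  N <- nrow(mesh$nodes)
  nd <- length(dup)
  copy_ids <- N + seq_len(nd)
  map <- integer(N); map[dup] <- copy_ids       # original -> copy
  new_nodes <- rbind(mesh$nodes, mesh$nodes[dup, , drop = FALSE])
  new_ijk <- rbind(mesh$node_ijk, mesh$node_ijk[dup, , drop = FALSE])
  new_param <- rbind(mesh$node_param, mesh$node_param[dup, , drop = FALSE])

  side_val <- if (surface$side_var == "s") mesh$elem_param[, "s"]
              else mesh$elem_param[, "psi"]
  pos_side <- side_val > surface$cut_value
  tets <- mesh$tets
  touches <- matrix(tets %in% dup, nrow(tets), 4L)
  fix_rows <- which(pos_side & rowSums(touches) > 0)
  for (r in fix_rows) {
    hit <- touches[r, ]
    tets[r, hit] <- map[tets[r, hit]]
  }

  out <- mesh
  out$uid <- paste0(mesh$uid, "+tear")
  out$nodes <- new_nodes
  out$tets <- tets
  out$node_ijk <- new_ijk
  out$node_param <- new_param
  ## rebuild boundary facet sets (copies carry the grid indices of their originals)
  nres <- c(mesh$resolution$circumferential, mesh$resolution$radial,
            mesh$resolution$vertical)
  bf <- boundary_faces(tets)
  facets <- classify_grid_boundary(bf, new_ijk, nres,
                                   c("end_anterior", "end_posterior",
                                     "inner_rim", "outer_wall",
                                     "inferior", "superior"))
  ## tear faces: boundary triangles whose nodes all lie on the cut surface
  cut_orig <- c(dup, surface$front_nodes)
  cut_copy <- c(copy_ids, surface$front_nodes)
  on_neg <- matrix(bf$faces %in% cut_orig, nrow(bf$faces), 3L)
  on_pos <- matrix(bf$faces %in% cut_copy, nrow(bf$faces), 3L)
  neg_rows <- rowSums(on_neg) == 3L
  pos_rows <- rowSums(on_pos) == 3L & !neg_rows
  facets$tear_face_neg <- bf$faces[neg_rows, , drop = FALSE]
  facets$tear_face_pos <- bf$faces[pos_rows, , drop = FALSE]
  out$facets <- facets

  topo <- structure(list(
    spec = surface$spec, surface = surface,
    node_pairs = cbind(original = dup, copy = copy_ids),
    front_nodes = surface$front_nodes,
    elem_neg = bf$elem[neg_rows], elem_pos = bf$elem[pos_rows],
    n_original_nodes = N),
    class = "tear_topology")
  list(mesh = out, topology = topo)
}

#' @export
print.tear_topology <- function(x, ...) {
  cat(sprintf("Tear topology: %d duplicated node pairs, %d front (tip/apex) nodes, %d/%d face triangles\n",
              nrow(x$node_pairs), length(x$front_nodes),
              length(x$elem_neg), length(x$elem_pos)))
  invisible(x)
}

#' Merge a torn mesh back to the intact mesh (round trip)
#'
#' Replaces every duplicated node by its original and drops the copies;
#' exact inverse of [split_mesh()].
#'
#' @param mesh torn `fe_mesh`.
#' @param topology `tear_topology`.
#' @return The intact `fe_mesh` node/element arrays (facet sets rebuilt).
#' @export
merge_tear <- function(mesh, topology) {
  N <- topology$n_original_nodes
  back <- seq_len(nrow(mesh$nodes))
  back[topology$node_pairs[, "copy"]] <- topology$node_pairs[, "original"]
  tets <- matrix(back[mesh$tets], nrow(mesh$tets), 4L)
  out <- mesh
  out$nodes <- mesh$nodes[seq_len(N), , drop = FALSE]
  out$node_ijk <- mesh$node_ijk[seq_len(N), , drop = FALSE]
  out$node_param <- mesh$node_param[seq_len(N), , drop = FALSE]
  out$tets <- tets
  nres <- c(mesh$resolution$circumferential, mesh$resolution$radial,
            mesh$resolution$vertical)
  bf <- boundary_faces(tets)
  out$facets <- classify_grid_boundary(bf, out$node_ijk, nres,
                                       c("end_anterior", "end_posterior",
                                         "inner_rim", "outer_wall",
                                         "inferior", "superior"))
  out
}

#' Self-contact pair between the two tear faces
#'
#' @param topology `tear_topology`.
#' @param mesh torn `fe_mesh` (local numbering) or NULL to use local ids.
#' @param offset global node offset of the meniscal part in the assembled
#'   model (0 for standalone use).
#' @param friction_mu friction coefficient (default 0.02, as between the
#'   articular surfaces).
#' @param penalty_normal,penalty_tangent penalty stiffnesses, N/mm^3.
#' @return `contact_pair` with the positive face as follower and the
#'   negative face as target.
#' @export
tear_contact_pairs <- function(topology, mesh, offset = 0L, friction_mu = 0.02,
                               penalty_normal = 300, penalty_tangent = 30) {
  fol_faces <- mesh$facets$tear_face_pos + offset
  tgt_faces <- mesh$facets$tear_face_neg + offset
  ## followers are the duplicated copies only: the shared front (tip/apex)
  ## nodes lie on both faces and must not contact themselves
  fol <- setdiff(sort(unique(as.integer(fol_faces))),
                 topology$front_nodes + offset)
  contact_pair(follower_nodes = fol,
               follower_faces = fol_faces,
               target_faces = tgt_faces,
               friction_mu = friction_mu,
               penalty_normal = penalty_normal,
               penalty_tangent = penalty_tangent,
               kind = "tear-face", search_radius = 4)
}

#' Insert a tear into a meniscal mesh
#'
#' Convenience wrapper: locate the tear surface, split the mesh, and return
#' the torn mesh plus topology and tear report.
#'
#' @param mesh meniscal `fe_mesh`.
#' @param spec `tear_spec`.
#' @return list(mesh, topology, surface, report). `report` is a list with
#'   the achieved size and node-pair count.
#' @export
insert_tear <- function(mesh, spec) {
  surf <- locate_tear_surface(mesh, spec)
  sm <- split_mesh(mesh, surf)
  report <- list(tear_type = spec$tear_type, meniscus = spec$meniscus,
                 region = spec$region, stability = spec$stability,
                 achieved_length_mm = surf$achieved_length_mm,
                 achieved_extent_fraction = if (surf$type == "radial")
                   surf$achieved_extent_fraction else NA_real_,
                 n_node_pairs = nrow(sm$topology$node_pairs))
  c(sm, list(surface = surf, report = report))
}
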
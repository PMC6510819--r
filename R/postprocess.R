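## Outcome measures: hoop-stress transects, tear-surface stress differences
## and favourability, apex stress deltas, compartmental contact metrics,
## and meniscal segment displacements.

men_part <- function(side) paste0("meniscus_", side)

## element ids of the cell (i, j, k) of a structured meniscal mesh
cell_elems <- function(mesh, i, j, k) {
  ec <- mesh$elem_cell
  which(ec[, 1] == i & ec[, 2] == j & ec[, 3] == k)
}

#' Hoop-stress transect across the rim width
#'
#' Samples the maximum principal stress (the hoop-stress indicator) from
#' the inner rim (normalised length s = 0) to the outer rim (s = 1) along
#' the mid-arc, mid-height line of a circumferential region. Values are
#' element-wise constant (linear tetrahedra); each sample reports the mean
#' over the tetrahedra of the containing cell.
#'
#' @param solution `knee_solution` (or any list with `stresses` and a
#'   `knee$fe` model).
#' @param meniscus "MM" or "LM".
#' @param region "anterior", "middle" or "posterior".
#' @param n_samples number of radial samples (default: radial divisions + 1).
#' @return data.frame of class `transect_profile` with columns `s` (strictly
#'   increasing, 0 to 1) and `max_pcs` (MPa), plus attributes.
#' @export
sample_transect <- function(solution, meniscus = c("MM", "LM"),
                            region = c("anterior", "middle", "posterior"),
                            n_samples = NULL) {
  meniscus <- match.arg(meniscus); region <- match.arg(region)
  part <- men_part(meniscus)
  mesh <- solution$knee$fe$parts[[part]]$mesh
  if (is.null(mesh)) stop("region empty: no such meniscal part in the model")
  res <- mesh$resolution
  if (is.null(n_samples)) n_samples <- res$radial + 1L
  if (n_samples < res$radial) n_samples <- res$radial + 1L
  s1 <- solution$stresses[[part]]$principal[, 1]
  nc <- res$circumferential; nr <- res$radial; nv <- res$vertical
  i_mid <- min(nc - 1L, max(0L, floor(region_centre_fraction(region) * nc)))
  k_mid <- max(0L, floor(nv / 2) - 0L)
  s <- seq(0, 1, length.out = n_samples)
  j_cell <- pmin(nr - 1L, floor(s * nr))
  val <- vapply(seq_along(s), function(ii) {
    ee <- cell_elems(mesh, i_mid, j_cell[ii], k_mid)
    if (!length(ee)) stop("region empty: no elements found at the sampling line")
    mean(s1[ee])
  }, numeric(1))
  out <- data.frame(s = s, max_pcs = val)
  attr(out, "meniscus") <- meniscus
  attr(out, "region") <- region
  attr(out, "flexion_angle") <- solution$knee$loadcase$flexion_angle
  class(out) <- c("transect_profile", "data.frame")
  out
}

#' @export
plot.transect_profile <- function(x, ...) {
  graphics::plot(x$s, x$max_pcs, type = "b", pch = 16,
                 xlab = "normalised length (0 = inner rim, 1 = outer rim)",
                 ylab = "max principal stress (MPa)",
                 main = sprintf("%s %s, %g deg flexion", attr(x, "meniscus"),
                                attr(x, "region"), attr(x, "flexion_angle")), ...)
  invisible(x)
}

## fiber-projected normal stress f' sigma f from Voigt rows
fiber_normal_stress <- function(voigt, fiber) {
  f1 <- fiber[, 1]; f2 <- fiber[, 2]; f3 <- fiber[, 3]
  voigt[, 1] * f1^2 + voigt[, 2] * f2^2 + voigt[, 3] * f3^2 +
    2 * (voigt[, 4] * f2 * f3 + voigt[, 5] * f1 * f3 + voigt[, 6] * f1 * f2)
}

#' Hoop-stress difference across a longitudinal tear
#'
#' Mean hoop stress (stress component along the local fiber direction) over
#' the elements adjacent to each tear face; the difference is outer minus
#' inner. A positive difference compresses the tear surfaces together and
#' is classified favourable; a tie (difference exactly 0) is unfavourable
#' (strict inequality). The max-PCS means are reported alongside as the
#' cross-check output.
#'
#' @param solution `knee_solution` of the torn model.
#' @param topology `tear_topology` (longitudinal).
#' @return Object of class `tear_surface_report`.
#' @export
tear_surface_difference <- function(solution, topology) {
  if (topology$spec$tear_type != "longitudinal")
    stop("tear_surface_difference applies to longitudinal tears; use apex_stress_delta for radial tears")
  part <- men_part(topology$spec$meniscus)
  st <- solution$stresses[[part]]
  mesh <- solution$knee$fe$parts[[part]]$mesh
  inner_e <- topology$elem_neg      # smaller s side
  outer_e <- topology$elem_pos
  hoop_in <- mean(fiber_normal_stress(st$voigt[inner_e, , drop = FALSE],
                                      mesh$fiber[inner_e, , drop = FALSE]))
  hoop_out <- mean(fiber_normal_stress(st$voigt[outer_e, , drop = FALSE],
                                       mesh$fiber[outer_e, , drop = FALSE]))
  pcs_in <- mean(st$principal[inner_e, 1])
  pcs_out <- mean(st$principal[outer_e, 1])
  diff <- hoop_out - hoop_in
  structure(list(spec = topology$spec,
                 flexion_angle = solution$knee$loadcase$flexion_angle,
                 hoop_inner = hoop_in, hoop_outer = hoop_out,
                 difference = diff,
                 max_pcs_inner = pcs_in, max_pcs_outer = pcs_out,
                 max_pcs_difference = pcs_out - pcs_in,
                 classification = if (diff > 0) "favourable" else "unfavourable"),
            class = "tear_surface_report")
}

#' @export
print.tear_surface_report <- function(x, ...) {
  cat(sprintf("Longitudinal tear surfaces (%s %s, %s, %g deg): inner %.3f MPa, outer %.3f MPa, difference %+.3f MPa -> %s\n",
              x$spec$meniscus, x$spec$region, x$spec$stability,
              x$flexion_angle, x$hoop_inner, x$hoop_outer, x$difference,
              x$classification))
  invisible(x)
}

#' Apex stress delta of a tear relative to the intact state
#'
#' Mean maximum principal stress over the elements adjacent to the tear
#' front (the apex node ring), minus the value over the same elements in
#' the intact solution (element identity is preserved by tear insertion).
#' Positive delta = added tension at the apex, negative = compression.
#'
#' @param solution_torn,solution_intact `knee_solution`s on geometrically
#'   identical models (the intact one without the tear).
#' @param topology `tear_topology`.
#' @return Object of class `apex_report`.
#' @export
apex_stress_delta <- function(solution_torn, solution_intact, topology) {
  part <- men_part(topology$spec$meniscus)
  mesh_t <- solution_torn$knee$fe$parts[[part]]$mesh
  mesh_i <- solution_intact$knee$fe$parts[[part]]$mesh
  if (nrow(mesh_t$tets) != nrow(mesh_i$tets))
    stop("mismatched meshes: torn and intact models must share element numbering")
  front <- topology$front_nodes
  touches <- matrix(mesh_t$tets %in% front, nrow(mesh_t$tets), 4L)
  apex_e <- which(rowSums(touches) > 0)
  if (topology$spec$tear_type == "radial") {
    ## the apex is the tear front at the outer end of the cut; for
    ## longitudinal tears both circumferential ends form the front
    apex_e <- apex_e
  }
  v_t <- mean(solution_torn$stresses[[part]]$principal[apex_e, 1])
  v_i <- mean(solution_intact$stresses[[part]]$principal[apex_e, 1])
  structure(list(spec = topology$spec,
                 flexion_angle = solution_torn$knee$loadcase$flexion_angle,
                 apex_elements = apex_e,
                 apex_max_pcs_torn = v_t,
                 apex_max_pcs_intact = v_i,
                 delta = v_t - v_i),
            class = "apex_report")
}

#' @export
print.apex_report <- function(x, ...) {
  cat(sprintf("Tear apex (%s %s %s, %g deg): max PCS %.3f MPa torn vs %.3f MPa intact, delta %+.3f MPa\n",
              x$spec$stability, x$spec$tear_type, x$spec$region,
              x$flexion_angle, x$apex_max_pcs_torn, x$apex_max_pcs_intact,
              x$delta))
  invisible(x)
}

#' Compartmental contact metrics
#'
#' Peak compressive minimum-principal stress in each tibial cartilage
#' compartment, the active contact area of its articular surface (sum of
#' facet areas carrying nonzero contact force) and the force-weighted
#' contact centroid.
#'
#' @param solution `knee_solution`.
#' @param force_tol nodal contact force below which a node counts as
#'   unloaded, N.
#' @return data.frame with one row per compartment.
#' @export
compartment_contact_metrics <- function(solution, force_tol = 1e-6) {
  model <- solution$knee$fe
  out <- NULL
  for (p in c("tibial_cartilage_med", "tibial_cartilage_lat")) {
    mesh <- model$parts[[p]]$mesh
    off <- model$offsets[[p]]
    s3 <- solution$stresses[[p]]$principal[, 3]
    peak <- max(0, -min(s3))
    faces <- mesh$facets$articular
    gn <- faces + off
    fmag <- sqrt(rowSums(solution$contact_force^2))
    loaded_node <- fmag > force_tol
    face_loaded <- matrix(loaded_node[gn], nrow(gn), 3L)
    active <- rowSums(face_loaded) == 3L
    fa <- facet_areas_normals(mesh$nodes, faces)
    area <- sum(fa$area[active])
    nid <- unique(as.integer(gn))
    w <- fmag[nid]
    cen <- if (sum(w) > 0)
      colSums(solution$knee$fe$X[nid, , drop = FALSE] * w) / sum(w)
    else c(NA_real_, NA_real_, NA_real_)
    out <- rbind(out, data.frame(
      side = if (grepl("med", p)) "medial" else "lateral",
      peak_compressive_stress = peak, contact_area = area,
      centroid_x = cen[1], centroid_y = cen[2]))
  }
  out
}

#' Meniscal segment displacements between two load cases
#'
#' Anteroposterior displacement of the anterior and posterior segment
#' (circumferential third) centroids and mediolateral displacement of the
#' most external midsection point, between two solved flexion poses.
#' Positive values are anterior and medial.
#'
#' @param solution_a,solution_b `knee_solution`s on the same meshes
#'   (e.g. 0 and 20 degrees); displacements are b minus a.
#' @param meniscus "MM", "LM" or "both".
#' @return data.frame with columns meniscus, segment, ap_mm, ml_mm.
#' @export
segment_displacements <- function(solution_a, solution_b, meniscus = "both") {
  sides <- if (meniscus == "both") c("MM", "LM") else meniscus
  model <- solution_a$knee$fe
  hx <- if (solution_a$knee$geometry$params$handedness == "right") 1 else -1
  out <- NULL
  for (side in sides) {
    part <- men_part(side)
    mesh <- model$parts[[part]]$mesh
    if (nrow(mesh$nodes) != nrow(solution_b$knee$fe$parts[[part]]$mesh$nodes))
      stop("mismatched meshes between the two solutions")
    gn <- global_nodes(model, part)
    du <- solution_b$u[gn, , drop = FALSE] - solution_a$u[gn, , drop = FALSE]
    frac <- (mesh$node_param[, "psi"] - mesh$sweep$psi0) /
      (mesh$sweep$psi1 - mesh$sweep$psi0)
    medial_sign <- -hx                      # +medial is -x for a right knee
    seg <- function(name, sel) {
      data.frame(meniscus = side, segment = name,
                 ap_mm = mean(du[sel, 2]),
                 ml_mm = medial_sign * mean(du[sel, 1]))
    }
    ant <- frac <= 1 / 3 + 1e-12
    post <- frac >= 2 / 3 - 1e-12
    mid <- !ant & !post
    ## most external midsection point: farthest from the joint midline
    ext_score <- abs(mesh$nodes[, 1])
    ext_score[!mid] <- -Inf
    ext <- which.max(ext_score)
    out <- rbind(out,
                 seg("anterior", which(ant)),
                 seg("posterior", which(post)),
                 seg("midsection", ext))
  }
  out
}
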
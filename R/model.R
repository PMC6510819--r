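## Knee model assembly: geometry -> meshes -> FE model with bonded bone
## interfaces, insertional-ligament springs, frictional contact pairs and
## the rigid femur load case.

#' Insertional ligament stiffnesses (N/mm)
#'
#' Defaults: lateral anterior 216, lateral posterior 130, medial anterior
#' 169, medial posterior 207.
#' @export
ligament_stiffness_defaults <- function() {
  c(lateral_anterior = 216, lateral_posterior = 130,
    medial_anterior = 169, medial_posterior = 207)
}

#' Load case for the tibiofemoral model
#'
#' The tibia is fully constrained. The femur is rigid, constrained in
#' flexion-extension, internal-external rotation and anteroposterior
#' translation (these are imposed by the pose), and free in mediolateral
#' translation, varus-valgus rotation and the load-driven axial
#' translation. The compressive load is applied along the tibial long axis
#' (-z on the femur).
#'
#' @param flexion_angle degrees in [0, 30].
#' @param axial_load compressive load, N (375 = approximately half body
#'   weight, 750 = full body weight for a 75 kg subject).
#' @return Object of class `load_case`.
#' @export
load_case <- function(flexion_angle = 0, axial_load = 750) {
  if (axial_load < 0) stop("axial_load must be >= 0")
  structure(list(flexion_angle = flexion_angle, axial_load = axial_load,
                 constrained_femur_dofs = c("flexion-extension",
                                            "internal-external rotation",
                                            "anteroposterior translation"),
                 free_femur_dofs = c("mediolateral translation",
                                     "varus-valgus rotation",
                                     "axial translation")),
            class = "load_case")
}

#' Build a tibiofemoral finite-element model
#'
#' Generates (or accepts) the synthetic geometry, meshes all deformable
#' parts, optionally inserts a meniscal tear, and assembles the FE model:
#' tibial cartilage bonded to the fixed tibia, femoral cartilage bonded to
#' the rigid femur (free DOFs: mediolateral, axial, varus-valgus), four
#' tension-only insertional-ligament springs, and frictional contact
#' between all articulating surfaces (and between tear faces).
#'
#' @param params `knee_params` or `knee_geometry`.
#' @param resolution `mesh_resolution` for all parts.
#' @param loadcase `load_case`.
#' @param tear optional `tear_spec`.
#' @param materials list with `cartilage` and `meniscus` materials.
#' @param ligament_k named stiffness vector, N/mm.
#' @param friction_mu friction coefficient for all contact (default 0.02).
#' @param penalty_normal,penalty_tangent contact penalties, N/mm^3; the
#'   normal default is 100x the softest participating modulus per cartilage
#'   thickness (which keeps residual penetration under 1% of the layer).
#' @param screw_home_deg screw-home coupling magnitude, degrees.
#' @param tear_contact logical: enrol tear faces as a self-contact pair.
#' @param resolution_other optional coarser `mesh_resolution` for the
#'   meniscus that does not carry the tear.
#' @param base optional intact `knee_model` with the same geometry, pose and
#'   resolutions: its meshes are reused (the torn meniscus is re-derived
#'   from the base mesh), which lets the assembly cache skip unchanged parts.
#' @return Object of class `knee_model`.
#' @export
knee_model <- function(params = knee_params(), resolution = mesh_resolution(),
                       loadcase = load_case(), tear = NULL,
                       materials = list(cartilage = elastic_isotropic(),
                                        meniscus = elastic_transverse_isotropic()),
                       ligament_k = ligament_stiffness_defaults(),
                       friction_mu = 0.02,
                       penalty_normal = NULL, penalty_tangent = NULL,
                       screw_home_deg = 5, tear_contact = TRUE,
                       resolution_other = NULL, base = NULL) {
  geometry <- if (!is.null(base)) base$geometry
              else if (inherits(params, "knee_geometry")) params
              else knee_geometry(params)
  pose <- if (!is.null(base) &&
              isTRUE(all.equal(base$loadcase$flexion_angle, loadcase$flexion_angle)))
    base$pose else pose_femur(geometry, loadcase$flexion_angle, screw_home_deg)
  if (is.null(penalty_normal)) {
    ## 100x the softest participating modulus per cartilage thickness keeps
    ## the residual penetration under 1% of the layer thickness at the
    ## bundled study resolutions
    soft <- min(materials$cartilage$E,
                if (!is.null(materials$meniscus$E_p)) materials$meniscus$E_p else Inf)
    penalty_normal <- 100 * soft / geometry$tibia$cartilage_thickness
  }
  if (is.null(penalty_tangent)) penalty_tangent <- penalty_normal / 10

  res_for <- function(side) {
    if (!is.null(tear) && !is.null(resolution_other) && side != tear$meniscus)
      resolution_other else resolution
  }
  if (!is.null(base)) {
    men_MM <- base$fe$parts$meniscus_MM$mesh
    men_LM <- base$fe$parts$meniscus_LM$mesh
  } else {
    men_MM <- mesh_meniscus(geometry, "MM", res_for("MM"))
    men_LM <- mesh_meniscus(geometry, "LM", res_for("LM"))
  }
  tear_info <- NULL
  if (!is.null(tear)) {
    target <- if (tear$meniscus == "MM") men_MM else men_LM
    ti <- insert_tear(target, tear)
    if (tear$meniscus == "MM") men_MM <- ti$mesh else men_LM <- ti$mesh
    tear_info <- ti
  }
  if (!is.null(base)) {
    tib_med <- base$fe$parts$tibial_cartilage_med$mesh
    tib_lat <- base$fe$parts$tibial_cartilage_lat$mesh
    fem_med <- base$fe$parts$femoral_cartilage_med$mesh
    fem_lat <- base$fe$parts$femoral_cartilage_lat$mesh
  } else {
    tib_med <- mesh_tibial_cartilage(geometry, "MM", resolution)
    tib_lat <- mesh_tibial_cartilage(geometry, "LM", resolution)
    fem_med <- mesh_femoral_cartilage(geometry, "MM", resolution, pose)
    fem_lat <- mesh_femoral_cartilage(geometry, "LM", resolution, pose)
  }

  parts <- list(
    meniscus_MM = list(mesh = men_MM, material = materials$meniscus),
    meniscus_LM = list(mesh = men_LM, material = materials$meniscus),
    tibial_cartilage_med = list(mesh = tib_med, material = materials$cartilage),
    tibial_cartilage_lat = list(mesh = tib_lat, material = materials$cartilage),
    femoral_cartilage_med = list(mesh = fem_med, material = materials$cartilage),
    femoral_cartilage_lat = list(mesh = fem_lat, material = materials$cartilage))
  model <- fe_model(parts)

  ## tibial cartilage bonded to the fixed tibia
  fixed <- rbind(rigid_bone_constraints(model, "tibial_cartilage_med", "bone", "fixed"),
                 rigid_bone_constraints(model, "tibial_cartilage_lat", "bone", "fixed"))
  ## femoral cartilage bonded to the rigid femur
  fem_nodes <- c(rigid_bone_constraints(model, "femoral_cartilage_med", "bone", "rigid"),
                 rigid_bone_constraints(model, "femoral_cartilage_lat", "bone", "rigid"))
  ref <- transform_points(pose$transform, geometry$femur$reference_point)
  femur <- list(name = "femur", nodes = fem_nodes,
                free = list(
                  list(name = "tx", type = "trans", dir = c(1, 0, 0)),
                  list(name = "tz", type = "trans", dir = c(0, 0, 1)),
                  list(name = "ry", type = "rot", axis = c(0, 1, 0), point = ref)))

  ## insertional ligament springs at the horn end faces
  spring_of <- function(lig_name, mesh_name, facet, k) {
    mesh <- model$parts[[mesh_name]]$mesh
    loc <- facet_nodes(mesh, facet)
    lig <- geometry$ligaments[[lig_name]]
    list(name = lig_name, nodes = global_nodes(model, mesh_name, loc),
         k = k, ground = lig$insertion, slack = NULL)
  }
  springs <- list(
    spring_of("medial_anterior", "meniscus_MM", "end_anterior", ligament_k[["medial_anterior"]]),
    spring_of("medial_posterior", "meniscus_MM", "end_posterior", ligament_k[["medial_posterior"]]),
    spring_of("lateral_anterior", "meniscus_LM", "end_anterior", ligament_k[["lateral_anterior"]]),
    spring_of("lateral_posterior", "meniscus_LM", "end_posterior", ligament_k[["lateral_posterior"]]))

  gfaces <- function(part, set) model$parts[[part]]$mesh$facets[[set]] + model$offsets[[part]]
  gnodes <- function(part, set) global_nodes(model, part, facet_nodes(model$parts[[part]]$mesh, set))
  cp <- function(fpart, fset, tpart, tset, kind = "deformable-deformable", sr = 6)
    contact_pair(follower_nodes = gnodes(fpart, fset),
                 follower_faces = gfaces(fpart, fset),
                 target_faces = gfaces(tpart, tset),
                 friction_mu = friction_mu,
                 penalty_normal = penalty_normal, penalty_tangent = penalty_tangent,
                 kind = kind, search_radius = sr)
  contacts <- list(
    mm_inferior = cp("meniscus_MM", "inferior", "tibial_cartilage_med", "articular"),
    lm_inferior = cp("meniscus_LM", "inferior", "tibial_cartilage_lat", "articular"),
    mm_superior = cp("meniscus_MM", "superior", "femoral_cartilage_med", "articular"),
    lm_superior = cp("meniscus_LM", "superior", "femoral_cartilage_lat", "articular"),
    tt_med = cp("tibial_cartilage_med", "articular", "femoral_cartilage_med", "articular"),
    tt_lat = cp("tibial_cartilage_lat", "articular", "femoral_cartilage_lat", "articular"))
  if (!is.null(tear_info) && tear_contact) {
    part <- paste0("meniscus_", tear$meniscus)
    contacts$tear <- tear_contact_pairs(tear_info$topology,
                                        model$parts[[part]]$mesh,
                                        offset = model$offsets[[part]],
                                        friction_mu = friction_mu,
                                        penalty_normal = penalty_normal,
                                        penalty_tangent = penalty_tangent)
  }
  loads <- list(rigid = c(femur.tz = -loadcase$axial_load))
  model <- fe_model(parts, fixed = fixed, rigid_bodies = list(femur),
                    springs = springs, contacts = contacts, loads = loads)

  structure(list(geometry = geometry, pose = pose, loadcase = loadcase,
                 resolution = resolution, tear = tear_info,
                 materials = materials, friction_mu = friction_mu,
                 penalty_normal = penalty_normal,
                 penalty_tangent = penalty_tangent,
                 fe = model),
            class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  nn <- nrow(x$fe$X)
  ne <- sum(vapply(x$fe$parts, function(p) nrow(p$mesh$tets), numeric(1)))
  cat(sprintf("Tibiofemoral FE model: %d nodes, %d tets, flexion %g deg, load %g N\n",
              nn, ne, x$loadcase$flexion_angle, x$loadcase$axial_load))
  if (!is.null(x$tear)) {
    cat("  tear: "); print(x$tear$surface$spec)
  }
  invisible(x)
}

#' Solve a knee model
#'
#' Assembles and solves the static contact problem; returns a
#' `knee_solution` (an `fe_solution` subclass with knee-specific reports).
#'
#' @param model `knee_model`.
#' @param warm_from optional `knee_solution` of a geometrically matching
#'   model (typically the intact model at the same flexion angle) used to
#'   warm-start displacements and friction anchors; duplicated tear nodes
#'   inherit the state of their originals.
#' @param ... solver settings passed to [solve_static()].
#' @return Object of class `c("knee_solution", "fe_solution")`.
#' @export
fe_solve <- function(model, warm_from = NULL, ...) {
  sys <- fe_assemble(model$fe,
                     reuse = if (!is.null(warm_from)) warm_from$system)
  state0 <- if (!is.null(warm_from)) warm_start_state(model, sys, warm_from)
  sol <- solve_static(sys, state0 = state0, ...)
  sol$knee <- model
  ## vertical force transmitted to the tibia: the bonded cartilage-bottom
  ## interface carries minus the support force on the system, and the
  ## insertional ligaments pull on their tibial insertion points; at
  ## equilibrium the total equals the applied axial load (downward)
  rz <- sum(sol$support_force[seq(3, length(sol$support_force), by = 3)])
  spz <- sum(vapply(sol$springs, function(s) s$on_ground[3], numeric(1)))
  sol$tibial_reaction_z <- -rz + spz
  class(sol) <- c("knee_solution", class(sol))
  sol
}



## Map a solved (typically intact) model's state onto a torn model's
## unknown vector and friction anchors. Parts must match by name; extra
## nodes (tear duplicates) inherit the values of their originals.
warm_start_state <- function(model, sys, warm_from) {
  src <- warm_from$knee$fe
  dst <- model$fe
  ## per-destination-node source global node id
  nmap <- integer(nrow(dst$X))
  for (p in names(dst$parts)) {
    dm <- dst$parts[[p]]$mesh; sm <- src$parts[[p]]$mesh
    if (is.null(sm)) return(NULL)
    nd <- nrow(dm$nodes); ns <- nrow(sm$nodes)
    local_src <- seq_len(nd)
    if (nd != ns) {
      if (is.null(model$tear) || !identical(paste0("meniscus_", model$tear$topology$spec$meniscus), p))
        return(NULL)
      np <- model$tear$topology$node_pairs
      if (nd != ns + nrow(np)) return(NULL)
      local_src[np[, "copy"]] <- np[, "original"]
    }
    nmap[global_nodes(dst, p)] <- global_nodes(src, p, local_src)
  }
  u_src <- warm_from$u
  u0 <- u_src[nmap, , drop = FALSE]
  u_full <- as.numeric(t(u0))
  ## least-squares lift onto the unknowns: free DOFs copy directly, rigid
  ## DOFs copy from the source solution
  q <- numeric(sys$nq)
  q[seq_len(sys$n_free)] <- u_full[sys$free]
  if (length(sys$rb_cols)) {
    pos <- match(sys$rb_cols, names(warm_from$rigid_dofs))
    q[sys$n_free + seq_along(sys$rb_cols)] <- ifelse(is.na(pos), 0,
                                                     warm_from$rigid_dofs[pos])
  }
  ## friction anchors for contact pairs with matching follower node sets
  anchors <- vector("list", length(dst$contacts))
  src_states <- warm_from$state$anchors
  for (i in seq_along(dst$contacts)) {
    nmd <- names(dst$contacts)[i]
    j <- match(nmd, names(src$contacts))
    if (is.na(j) || is.null(src_states[[j]])) next
    fd <- dst$contacts[[i]]$follower_nodes
    fs <- src$contacts[[j]]$follower_nodes
    idx <- match(nmap[fd], fs)
    if (anyNA(idx)) next
    anchors[[i]] <- src_states[[j]][idx, , drop = FALSE]
  }
  list(q = q, anchors = anchors)
}

#' @export
print.knee_solution <- function(x, ...) {
  NextMethod()
  cat(sprintf("Flexion %g deg, axial load %g N; vertical tibial reaction %.2f N\n",
              x$knee$loadcase$flexion_angle, x$knee$loadcase$axial_load,
              x$tibial_reaction_z))
  invisible(x)
}

#' @export
summary.knee_solution <- function(object, ...) {
  cm <- compartment_contact_metrics(object)
  peaks <- vapply(c("meniscus_MM", "meniscus_LM"), function(p)
    max(object$stresses[[p]]$principal[, 1]), numeric(1))
  out <- list(flexion_angle = object$knee$loadcase$flexion_angle,
              axial_load = object$knee$loadcase$axial_load,
              converged = object$converged,
              residual_norm = object$residual_norm,
              max_penetration = object$max_penetration,
              tibial_reaction_z = object$tibial_reaction_z,
              compartments = cm,
              peak_hoop_stress = peaks,
              springs = vapply(object$springs, function(s) s$force, numeric(1)),
              femur_dofs = object$rigid_dofs)
  class(out) <- "summary.knee_solution"
  out
}

#' @export
print.summary.knee_solution <- function(x, ...) {
  cat(sprintf("Knee solution at %g deg flexion, %g N axial load (%s)\n",
              x$flexion_angle, x$axial_load,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  vertical tibial reaction: %.2f N\n", x$tibial_reaction_z))
  cat(sprintf("  max penetration: %.4f mm; residual %.3g\n",
              x$max_penetration, x$residual_norm))
  cat("  compartment contact:\n")
  print(x$compartments, row.names = FALSE)
  cat(sprintf("  peak meniscal hoop stress (max PCS): MM %.3f MPa, LM %.3f MPa\n",
              x$peak_hoop_stress[["meniscus_MM"]], x$peak_hoop_stress[["meniscus_LM"]]))
  cat("  ligament spring forces (N):\n")
  for (nm in names(x$springs)) cat(sprintf("    %-18s %8.2f\n", nm, x$springs[[nm]]))
  invisible(x)
}

#' Plot a knee solution
#'
#' Contour-style map of the tibial cartilage minimum principal stress
#' (compression) over the plateau, per compartment, with the contact areas
#' visible as the loaded regions.
#'
#' @param x `knee_solution`.
#' @param ... ignored.
#' @export
plot.knee_solution <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in c("tibial_cartilage_med", "tibial_cartilage_lat")) {
    mesh <- x$knee$fe$parts[[p]]$mesh
    off <- x$knee$fe$offsets[[p]]
    s3 <- x$stresses[[p]]$principal[, 3]
    cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
              mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
    cols <- grDevices::hcl.colors(32, "Blues 3", rev = TRUE)
    ci <- pmin(32L, pmax(1L, 1L + floor(31 * (-s3) / max(1e-9, max(-s3)))))
    graphics::plot(cen[, 1], cen[, 2], col = cols[ci], pch = 15, cex = 0.9,
                   xlab = "x (mm, +lateral)", ylab = "y (mm, +anterior)",
                   main = sprintf("%s: min PCS (peak %.2f MPa)", mesh$part, min(s3)),
                   asp = 1)
  }
  invisible(x)
}
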
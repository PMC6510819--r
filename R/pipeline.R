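## Configuration, experiment-matrix orchestration and reproducibility
## plumbing: YAML config with defaults, the tear experiment matrix
## (2 menisci x 3 regions x 2 tear types x 2 stabilities x flexion angles),
## per-cell failure isolation, and a checksummed run manifest.

#' Default experiment configuration
#'
#' Materials default to the model constants (cartilage E = 13 MPa,
#' nu = 0.42; meniscus 20/0.2/8.3 MPa in-plane and 150/0.3/57.7 MPa
#' circumferentially), ligament stiffnesses to 216/130/169/207 N/mm,
#' friction to 0.02, body weight to 750 N, and the tear matrix to all
#' combinations of meniscus, region, tear type and stability at 0/20/30
#' degrees of flexion under one body weight.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    geometry = as.list(unclass(knee_params()))[
      setdiff(names(unclass(knee_params())), "ligament_insertion_offsets")],
    mesh = list(circumferential = 60L, radial = 12L, vertical = 2L,
                cartilage = 10L, cartilage_thickness_div = 2L),
    materials = list(
      cartilage = list(E = 13, nu = 0.42),
      meniscus = list(E_p = 20, nu_p = 0.2, G_p = 8.3,
                      E_f = 150, nu_f = 0.3, G_f = 57.7)),
    ligaments = as.list(ligament_stiffness_defaults()),
    contact = list(friction_mu = 0.02, penalty_normal = NULL,
                   penalty_tangent = NULL, tear_contact = TRUE),
    solver = list(rtol = 1e-4, max_iter = 60L, load_steps = 3L,
                  step_limit = 1.0, active_tol = 0.5,
                  penetration_tol = 0.025),
    loads = list(body_weight_N = 750, tear_load_bw = 1, angles = c(0, 20, 30)),
    tears = list(enabled = TRUE,
                 menisci = c("MM", "LM"),
                 regions = c("anterior", "middle", "posterior"),
                 types = c("longitudinal", "radial"),
                 stabilities = c("stable", "unstable")),
    output = list(dir = "kneefem_output", write_vtu = FALSE))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      warning("unknown config key '", here, "' (ignored)")
      next
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    else base[[nm]] <- user[[nm]]
  }
  base
}

check_config <- function(cfg) {
  err <- function(key, msg) stop("config error at `", key, "`: ", msg, call. = FALSE)
  m <- cfg$materials
  for (k in c("E_p", "G_p", "E_f", "G_f"))
    if (m$meniscus[[k]] <= 0) err(paste0("materials.meniscus.", k), "modulus must be > 0")
  if (m$cartilage$E <= 0) err("materials.cartilage.E", "modulus must be > 0")
  if (m$cartilage$nu <= -1 || m$cartilage$nu >= 0.5)
    err("materials.cartilage.nu", "need -1 < nu < 0.5")
  for (k in names(cfg$ligaments))
    if (cfg$ligaments[[k]] <= 0) err(paste0("ligaments.", k), "stiffness must be > 0")
  if (cfg$contact$friction_mu < 0) err("contact.friction_mu", "must be >= 0")
  if (cfg$loads$body_weight_N < 0) err("loads.body_weight_N", "must be >= 0")
  if (any(cfg$loads$angles < 0 | cfg$loads$angles > 30))
    err("loads.angles", "flexion angles must lie in [0, 30]")
  invisible(cfg)
}

#' Validate and complete an experiment configuration
#'
#' Reads a YAML (or JSON) configuration file, fills in defaults for any
#' missing key, validates values (reporting the offending key path) and
#' warns on unknown keys.
#'
#' @param path path to a YAML/JSON config file, a list, or NULL/empty file
#'   for the full defaults.
#' @return Object of class `experiment_config`.
#' @export
validate_config <- function(path = NULL) {
  user <- list()
  if (is.list(path)) {
    user <- path
  } else if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
            else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(default_config(), user)
  check_config(cfg)
  structure(cfg, class = "experiment_config")
}

config_objects <- function(cfg) {
  gp <- cfg$geometry
  gp$random_seed <- cfg$seed
  params <- do.call(knee_params, gp)
  res <- do.call(mesh_resolution, cfg$mesh)
  mats <- list(cartilage = do.call(elastic_isotropic, cfg$materials$cartilage),
               meniscus = do.call(elastic_transverse_isotropic, cfg$materials$meniscus))
  list(params = params, resolution = res, materials = mats,
       ligament_k = unlist(cfg$ligaments))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

run_cell <- function(obj, cfg, angle, tear, sol_params, out_dir, tag, intact_sols) {
  lc <- load_case(angle, if (is.null(tear)) cfg$loads$body_weight_N
                  else cfg$loads$tear_load_bw * cfg$loads$body_weight_N)
  km <- knee_model(obj$params, obj$resolution, lc, tear = tear,
                   materials = obj$materials, ligament_k = obj$ligament_k,
                   friction_mu = cfg$contact$friction_mu,
                   penalty_normal = cfg$contact$penalty_normal,
                   penalty_tangent = cfg$contact$penalty_tangent,
                   tear_contact = isTRUE(cfg$contact$tear_contact))
  sol <- do.call(fe_solve, c(list(km), sol_params))
  files <- character(0)
  ## transect CSVs
  tr <- do.call(rbind, lapply(c("MM", "LM"), function(side)
    do.call(rbind, lapply(c("anterior", "middle", "posterior"), function(reg) {
      pr <- sample_transect(sol, side, reg)
      data.frame(meniscus = side, region = reg, s = pr$s, max_pcs = pr$max_pcs)
    }))))
  tr_path <- file.path(out_dir, sprintf("transects_%s.csv", tag))
  utils::write.csv(tr, tr_path, row.names = FALSE)
  files <- c(files, tr_path)
  rep <- list(tag = tag, flexion_angle = angle,
              axial_load = lc$axial_load,
              converged = sol$converged,
              tibial_reaction_z = sol$tibial_reaction_z,
              max_penetration = sol$max_penetration,
              compartments = compartment_contact_metrics(sol))
  if (!is.null(tear)) {
    rep$tear <- km$tear$report
    if (tear$tear_type == "longitudinal") {
      tsr <- tear_surface_difference(sol, km$tear$topology)
      rep$tear_surface <- tsr[c("hoop_inner", "hoop_outer", "difference",
                                "classification")]
    }
    key <- as.character(angle)
    if (!is.null(intact_sols[[key]])) {
      ad <- apex_stress_delta(sol, intact_sols[[key]], km$tear$topology)
      rep$apex <- ad[c("apex_max_pcs_torn", "apex_max_pcs_intact", "delta")]
    }
  }
  rep_path <- file.path(out_dir, sprintf("report_%s.json", tag))
  jsonlite::write_json(rep, rep_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  files <- c(files, rep_path)
  if (isTRUE(cfg$output$write_vtu))
    files <- c(files, export_solution_vtu(sol, out_dir, prefix = tag))
  list(solution = sol, files = files, report = rep)
}

#' Run the full experiment pipeline
#'
#' Executes geometry -> mesh -> (tear) -> solve -> postprocess for the
#' intact model at every configured flexion angle and for every cell of
#' the tear matrix. Cells fail independently: any error is recorded in the
#' manifest and the pipeline continues.
#'
#' @param config `experiment_config`, path, or NULL for defaults.
#' @param out_dir output directory (overrides the config).
#' @param keep_solutions logical: keep the solved objects in the returned
#'   manifest (memory-heavy; default FALSE).
#' @return Object of class `run_manifest`: config hash, per-cell status,
#'   file inventory with checksums, convergence summaries.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, keep_solutions = FALSE) {
  cfg <- if (inherits(config, "experiment_config")) config else validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(cfg)
  sol_params <- cfg$solver[c("rtol", "max_iter", "load_steps", "step_limit",
                             "active_tol", "penetration_tol")]
  cells <- list()
  status <- list()
  files <- character(0)
  solutions <- list()
  intact_sols <- list()
  for (angle in cfg$loads$angles)
    cells[[length(cells) + 1L]] <- list(angle = angle, tear = NULL,
                                        tag = sprintf("intact_%gdeg", angle))
  if (isTRUE(cfg$tears$enabled)) {
    for (angle in cfg$loads$angles)
      for (men in cfg$tears$menisci)
        for (reg in cfg$tears$regions)
          for (ty in cfg$tears$types)
            for (stb in cfg$tears$stabilities)
              cells[[length(cells) + 1L]] <- list(
                angle = angle,
                tear = tryCatch(tear_spec(ty, men, reg, stb), error = identity),
                tag = sprintf("%s_%s_%s_%s_%gdeg", ty, men, reg, stb, angle))
  }
  for (cell in cells) {
    res <- tryCatch({
      if (inherits(cell$tear, "error")) stop(conditionMessage(cell$tear))
      r <- run_cell(obj, cfg, cell$angle, cell$tear, sol_params, out_dir,
                    cell$tag, intact_sols)
      if (is.null(cell$tear)) intact_sols[[as.character(cell$angle)]] <- r$solution
      if (keep_solutions) solutions[[cell$tag]] <- r$solution
      files <- c(files, r$files)
      list(status = "ok", converged = r$report$converged,
           reaction = r$report$tibial_reaction_z)
    }, error = function(e) list(status = "error", message = conditionMessage(e)))
    status[[cell$tag]] <- res
  }
  inv <- data.frame(file = files,
                    md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
  manifest <- structure(list(config = cfg, config_hash = config_hash(cfg),
                             version = as.character(utils::packageVersion("kneefem")),
                             cells = status, inventory = inv,
                             solutions = if (keep_solutions) solutions else NULL),
                        class = "run_manifest")
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(config_hash = manifest$config_hash,
                            version = manifest$version,
                            cells = status, inventory = inv),
                       man_path, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  ok <- sum(vapply(x$cells, function(c) identical(c$status, "ok"), logical(1)))
  cat(sprintf("Pipeline run %s: %d/%d cells succeeded, %d output files\n",
              substr(x$config_hash, 1, 8), ok, length(x$cells), nrow(x$inventory)))
  bad <- names(x$cells)[vapply(x$cells, function(c) !identical(c$status, "ok"), logical(1))]
  if (length(bad)) cat("  failed:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Run the physics invariant suite on a coarse model
#'
#' Quick verification used by the command-line `verify` subcommand:
#' checks mesh validity, spring non-compression, global equilibrium and
#' penetration limits on a coarse intact solve.
#'
#' @param config optional `experiment_config` or path.
#' @return Named logical vector of check results.
#' @export
verify_model <- function(config = NULL) {
  cfg <- if (inherits(config, "experiment_config")) config else validate_config(config)
  obj <- config_objects(cfg)
  res <- mesh_resolution(18, 6, 2, 8, 2)
  km <- knee_model(obj$params, res, load_case(0, cfg$loads$body_weight_N),
                   materials = obj$materials, ligament_k = obj$ligament_k)
  checks <- c(positive_volumes = all(vapply(km$fe$parts, function(p)
    min(tet_volumes(p$mesh$nodes, p$mesh$tets)) > 0, logical(1))))
  sol <- fe_solve(km)
  checks["converged"] <- sol$converged
  checks["equilibrium"] <- abs(abs(sol$tibial_reaction_z) -
                                 cfg$loads$body_weight_N) <
    0.005 * cfg$loads$body_weight_N
  checks["springs_tension_only"] <- all(vapply(sol$springs, function(s)
    s$force >= 0, logical(1)))
  checks["penetration"] <- sol$max_penetration <= sol$penetration_tol
  checks
}

#' Run the tear experiment matrix efficiently
#'
#' Solves the intact model once per flexion angle and then every requested
#' tear cell warm-started from the matching intact solution, reusing the
#' unchanged part assemblies. Returns tidy per-cell outcome tables for the
#' tear-surface favourability and apex-stress analyses.
#'
#' @param angles flexion angles, degrees.
#' @param menisci,regions,types,stabilities matrix factors.
#' @param resolution `mesh_resolution` for all parts (must support the
#'   requested tears).
#' @param params `knee_params`.
#' @param axial_load compressive load, N (default one body weight, 750).
#' @param penalty_tangent tangential penalty, N/mm^3.
#' @param ... further arguments to [solve_static()].
#' @return list with `longitudinal` and `radial` data.frames (one row per
#'   converged cell) and `intact` (list of intact `knee_solution`s by angle).
#' @export
tear_matrix_study <- function(angles = c(0, 20, 30),
                              menisci = c("MM", "LM"),
                              regions = c("anterior", "middle", "posterior"),
                              types = c("longitudinal", "radial"),
                              stabilities = c("stable", "unstable"),
                              resolution = mesh_resolution(30, 12, 2, 8, 2),
                              params = knee_params(),
                              axial_load = 750,
                              penalty_tangent = 2, ...) {
  long <- NULL; rad <- NULL
  intact <- list()
  done <- new.env(parent = emptyenv())
  geometry <- knee_geometry(params)
  for (angle in angles) {
    ## load cases whose posed models coincide (e.g. flexion angles beyond
    ## the screw-home interval of spherical condyles) are solved once and
    ## their deterministic results reused
    pose <- pose_femur(geometry, angle)
    key <- paste(round(c(pose$transform$R, pose$transform$t), 10),
                 collapse = ",")
    if (!is.null(done[[key]])) {
      prev <- done[[key]]
      intact[[as.character(angle)]] <- prev$sol0
      lg2 <- prev$long; lg2$angle <- angle
      rd2 <- prev$rad; rd2$angle <- angle
      long <- rbind(long, lg2); rad <- rbind(rad, rd2)
      next
    }
    km0 <- knee_model(geometry, resolution, load_case(angle, axial_load),
                      penalty_tangent = penalty_tangent)
    sol0 <- suppressWarnings(fe_solve(km0, ...))
    intact[[as.character(angle)]] <- sol0
    long_a <- NULL; rad_a <- NULL
    for (men in menisci) for (reg in regions)
      for (ty in types) for (stb in stabilities) {
        ts <- tear_spec(ty, men, reg, stb)
        kmT <- knee_model(loadcase = load_case(angle, axial_load),
                          penalty_tangent = penalty_tangent,
                          tear = ts, base = km0)
        solT <- suppressWarnings(fe_solve(kmT, warm_from = sol0, ...))
        if (ty == "longitudinal") {
          tsr <- tear_surface_difference(solT, kmT$tear$topology)
          long_a <- rbind(long_a, data.frame(
            angle = angle, meniscus = men, region = reg, stability = stb,
            achieved_mm = kmT$tear$report$achieved_length_mm,
            hoop_inner = tsr$hoop_inner, hoop_outer = tsr$hoop_outer,
            difference = tsr$difference,
            classification = tsr$classification,
            residual = solT$residual_norm,
            converged = solT$converged))
        } else {
          ad <- apex_stress_delta(solT, sol0, kmT$tear$topology)
          rad_a <- rbind(rad_a, data.frame(
            angle = angle, meniscus = men, region = reg, stability = stb,
            achieved_fraction = kmT$tear$report$achieved_extent_fraction,
            apex_torn = ad$apex_max_pcs_torn,
            apex_intact = ad$apex_max_pcs_intact,
            delta = ad$delta,
            residual = solT$residual_norm,
            converged = solT$converged))
        }
      }
    done[[key]] <- list(sol0 = sol0, long = long_a, rad = rad_a)
    long <- rbind(long, long_a); rad <- rbind(rad, rad_a)
  }
  list(longitudinal = long, radial = rad, intact = intact)
}
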
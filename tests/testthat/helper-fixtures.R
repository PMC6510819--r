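# Shared fixtures. Heavy objects (geometry, solved models) are built once
# per session and memoised in this environment so test files can share them.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_geometry <- function() cached("geometry", knee_geometry())

# coarse resolutions used throughout the suite
coarse_res <- function() mesh_resolution(18, 6, 2, 8, 2)
tiny_res <- function() mesh_resolution(12, 3, 2, 4, 2)

# study resolution for tear runs: fine enough that a stable longitudinal
# tear spans >= 2 element edges on both menisci and a stable radial tear
# spans 2 element layers
study_res <- function() mesh_resolution(30, 12, 2, 8, 2)

# intact coarse knee solution at 0 degrees, 750 N (shared across files)
intact_coarse_solution <- function() {
  cached("intact_coarse", {
    km <- knee_model(resolution = coarse_res(), loadcase = load_case(0, 750),
                     penalty_tangent = 2)
    suppressWarnings(fe_solve(km))
  })
}

# intact solutions at the study resolution, one per flexion angle
intact_study_solution <- function(angle) {
  cached(paste0("intact_study_", angle), {
    km <- knee_model(resolution = study_res(),
                     loadcase = load_case(angle, 750), penalty_tangent = 2)
    suppressWarnings(fe_solve(km))
  })
}

# a torn knee solution at the study resolution, warm-started from the
# matching intact solve
torn_study_solution <- function(tear, angle = 0) {
  key <- paste("torn", tear$tear_type, tear$meniscus, tear$region,
               tear$stability, angle, sep = "_")
  cached(key, {
    km <- knee_model(resolution = study_res(),
                     loadcase = load_case(angle, 750), penalty_tangent = 2,
                     tear = tear)
    list(model = km,
         solution = suppressWarnings(
           fe_solve(km, warm_from = intact_study_solution(angle))))
  })
}

# minimal fake solution for postprocess unit tests on manufactured fields
manufactured_solution <- function(km, stress_fun) {
  parts <- km$fe$parts
  stresses <- list()
  for (p in names(parts)) {
    mesh <- parts[[p]]$mesh
    cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
              mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
    voigt <- stress_fun(p, mesh, cen)
    stresses[[p]] <- list(voigt = voigt,
                          principal = principal_stresses_many(voigt))
  }
  structure(list(knee = km, stresses = stresses,
                 u = matrix(0, nrow(km$fe$X), 3),
                 contact_force = matrix(0, nrow(km$fe$X), 3)),
            class = c("knee_solution", "fe_solution"))
}
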
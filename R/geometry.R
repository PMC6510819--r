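## Parametric synthetic tibiofemoral geometry.
##
## Coordinate convention: origin at the tibial plateau centre, +x lateral,
## +y anterior, +z proximal; units mm. The tibial plateau is the plane z = 0
## carrying an isotropic cartilage layer; each femoral condyle is a sphere
## carrying a spherical cartilage shell; each meniscus is a C-shaped solid
## swept from a wedge cross-section (flat inferior face congruent with the
## tibial cartilage surface, sloped superior face, vertical peripheral wall)
## with flat anterior/posterior terminal faces for the insertional ligaments.
##
## Each meniscal arc is parameterised in a per-compartment frame whose first
## axis points toward the knee midline and second axis anteriorly, so the
## C-opening faces the intercondylar area for both menisci and the medial
## and lateral definitions are exact sagittal mirror images of one another.
## Arc angle psi increases from the anterior horn to the posterior horn.

#' Parameters of the synthetic knee geometry
#'
#' Houses all geometric free parameters of the parametric stand-in for a
#' subject-specific segmented knee. Lengths in mm, angles in degrees.
#' Defaults are anatomically plausible adult values.
#'
#' @param condyle_radius_medial,condyle_radius_lateral femoral condyle
#'   (bone) sphere radii, mm.
#' @param condyle_separation mediolateral distance between compartment
#'   centres, mm.
#' @param plateau_halfwidth halfwidth of the tibial plateau, mm.
#' @param cartilage_thickness_femoral,cartilage_thickness_tibial layer
#'   thicknesses, mm.
#' @param meniscus_outer_radius_MM,meniscus_inner_radius_MM,
#'   meniscus_peripheral_height_MM,arc_start_deg_MM,arc_end_deg_MM medial
#'   meniscus annulus radii, peripheral (outer-wall) height and arc limits
#'   in the midline-anterior compartment frame.
#' @param meniscus_outer_radius_LM,meniscus_inner_radius_LM,
#'   meniscus_peripheral_height_LM,arc_start_deg_LM,arc_end_deg_LM same for
#'   the lateral meniscus.
#' @param inner_rim_height height of the wedge at the inner rim, mm; small
#'   but positive (the cross-section tapers towards the inner rim).
#' @param ligament_insertion_offsets 4 x 3 matrix of offsets (mm) added to
#'   the default tibial insertion points, rows ordered (MM anterior,
#'   MM posterior, LM anterior, LM posterior).
#' @param initial_gap gap between the femoral cartilage and its first point
#'   of support at the reference (0 degree) pose, mm; 0 = just touching.
#' @param roughness_amplitude relative amplitude of the optional
#'   seed-controlled perturbation of the meniscal outer wall (default 0,
#'   i.e. smooth).
#' @param random_seed integer seed controlling the roughness harmonics only.
#' @param handedness "right" (medial compartment on -x) or "left" (its
#'   sagittal mirror image).
#' @return Object of class `knee_params`.
#' @export
knee_params <- function(condyle_radius_medial = 37,
                        condyle_radius_lateral = 35,
                        condyle_separation = 44,
                        plateau_halfwidth = 38,
                        cartilage_thickness_femoral = 2.5,
                        cartilage_thickness_tibial = 2.5,
                        meniscus_outer_radius_MM = 22,
                        meniscus_inner_radius_MM = 9,
                        meniscus_peripheral_height_MM = 6,
                        arc_start_deg_MM = 30,
                        arc_end_deg_MM = 330,
                        meniscus_outer_radius_LM = 18,
                        meniscus_inner_radius_LM = 7,
                        meniscus_peripheral_height_LM = 5.5,
                        arc_start_deg_LM = 45,
                        arc_end_deg_LM = 315,
                        inner_rim_height = 0.5,
                        ligament_insertion_offsets = matrix(0, 4, 3),
                        initial_gap = 0,
                        roughness_amplitude = 0,
                        random_seed = 1L,
                        handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  p <- list(condyle_radius_medial = condyle_radius_medial,
            condyle_radius_lateral = condyle_radius_lateral,
            condyle_separation = condyle_separation,
            plateau_halfwidth = plateau_halfwidth,
            cartilage_thickness_femoral = cartilage_thickness_femoral,
            cartilage_thickness_tibial = cartilage_thickness_tibial,
            meniscus_outer_radius_MM = meniscus_outer_radius_MM,
            meniscus_inner_radius_MM = meniscus_inner_radius_MM,
            meniscus_peripheral_height_MM = meniscus_peripheral_height_MM,
            arc_start_deg_MM = arc_start_deg_MM,
            arc_end_deg_MM = arc_end_deg_MM,
            meniscus_outer_radius_LM = meniscus_outer_radius_LM,
            meniscus_inner_radius_LM = meniscus_inner_radius_LM,
            meniscus_peripheral_height_LM = meniscus_peripheral_height_LM,
            arc_start_deg_LM = arc_start_deg_LM,
            arc_end_deg_LM = arc_end_deg_LM,
            inner_rim_height = inner_rim_height,
            ligament_insertion_offsets = as.matrix(ligament_insertion_offsets),
            initial_gap = initial_gap,
            roughness_amplitude = roughness_amplitude,
            random_seed = as.integer(random_seed),
            handedness = handedness)
  validate_knee_params(p)
  structure(p, class = "knee_params")
}

validate_knee_params <- function(p) {
  fail <- function(msg) stop("invalid knee parameters: ", msg, call. = FALSE)
  for (side in c("MM", "LM")) {
    ro <- p[[paste0("meniscus_outer_radius_", side)]]
    ri <- p[[paste0("meniscus_inner_radius_", side)]]
    h  <- p[[paste0("meniscus_peripheral_height_", side)]]
    a0 <- p[[paste0("arc_start_deg_", side)]]
    a1 <- p[[paste0("arc_end_deg_", side)]]
    if (!(ro > ri && ri > 0))
      fail(sprintf("outer_radius > inner_radius > 0 violated for %s", side))
    if (!(a1 > a0)) fail(sprintf("arc_end > arc_start violated for %s", side))
    if (!(h > 0)) fail(sprintf("peripheral_height > 0 violated for %s", side))
  }
  span_MM <- p$arc_end_deg_MM - p$arc_start_deg_MM
  span_LM <- p$arc_end_deg_LM - p$arc_start_deg_LM
  if (!(span_MM > span_LM))
    fail("MM arc span must exceed LM arc span (medial meniscus is the more open C)")
  if (!(p$inner_rim_height >= 0 &&
        p$inner_rim_height < min(p$meniscus_peripheral_height_MM,
                                 p$meniscus_peripheral_height_LM)))
    fail("inner_rim_height must be >= 0 and below the peripheral heights")
  if (p$condyle_radius_medial <= 0 || p$condyle_radius_lateral <= 0)
    fail("condyle radii must be > 0")
  if (p$cartilage_thickness_femoral <= 0 || p$cartilage_thickness_tibial <= 0)
    fail("cartilage thicknesses must be > 0")
  if (!all(dim(p$ligament_insertion_offsets) == c(4L, 3L)))
    fail("ligament_insertion_offsets must be a 4 x 3 matrix")
  invisible(TRUE)
}

## Wedge cross-section height at normalised radial coordinate s in [0, 1]
## (0 = inner rim, 1 = outer rim).
wedge_height <- function(men, s) men$h_in + (men$h - men$h_in) * s

## Seed-controlled outer-wall roughness: relative radial perturbation as a
## low-order Fourier series in psi. Amplitude 0 -> identically zero.
roughness_fun <- function(amp, seed, tag) {
  if (amp <= 0) return(function(psi) rep(0, length(psi)))
  r <- withr_seed_draw(seed + match(tag, c("MM", "LM")), 8L)
  a <- amp * r[1:4]; b <- amp * r[5:8]
  function(psi) {
    out <- 0
    for (k in 1:4) out <- out + a[k] * cos(k * psi) + b[k] * sin(k * psi)
    out
  }
}

## Draw n standard normals from an isolated RNG stream (does not disturb
## the global .Random.seed).
withr_seed_draw <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Generate the synthetic knee geometry
#'
#' Builds the analytic description of the joint: rigid-bone articular
#' surfaces, cartilage layers, both meniscal solids, the four insertional
#' ligament attachment pairs and the femoral bony landmarks. The femur is
#' placed vertically so that at the reference (0 degree) pose its cartilage
#' just touches its first point of support (tibial cartilage or meniscus)
#' in each compartment's support envelope, with no interpenetration.
#'
#' @param params `knee_params` object.
#' @return Object of class `knee_geometry`.
#' @export
knee_geometry <- function(params = knee_params()) {
  if (!inherits(params, "knee_params")) params <- do.call(knee_params, params)
  validate_knee_params(params)
  sep <- params$condyle_separation / 2
  t_t <- params$cartilage_thickness_tibial
  t_f <- params$cartilage_thickness_femoral

  hx <- if (params$handedness == "right") 1 else -1  # sign of the lateral x direction
  compartment <- function(side) {
    lateral <- side == "LM"
    centre <- c(hx * (if (lateral) sep else -sep), 0)
    u_mid <- c(hx * (if (lateral) -1 else 1), 0, 0)  # toward the knee midline
    u_ant <- c(0, 1, 0)
    list(side = side, centre = centre, u_mid = u_mid, u_ant = u_ant)
  }

  meniscus <- function(side) {
    comp <- compartment(side)
    men <- list(
      side = side,
      centre = comp$centre, u_mid = comp$u_mid, u_ant = comp$u_ant,
      r_in = params[[paste0("meniscus_inner_radius_", side)]],
      r_out = params[[paste0("meniscus_outer_radius_", side)]],
      h = params[[paste0("meniscus_peripheral_height_", side)]],
      h_in = params$inner_rim_height,
      psi0 = params[[paste0("arc_start_deg_", side)]] * pi / 180,
      psi1 = params[[paste0("arc_end_deg_", side)]] * pi / 180,
      z_base = t_t,
      rough = roughness_fun(params$roughness_amplitude, params$random_seed, side))
    men
  }

  MM <- meniscus("MM"); LM <- meniscus("LM")

  condyle <- function(side) {
    comp <- compartment(side)
    men <- if (side == "MM") MM else LM
    Rb <- if (side == "MM") params$condyle_radius_medial else params$condyle_radius_lateral
    Ro <- Rb + t_f
    ## support envelope under the condyle: cartilage plane + meniscus wedge
    r <- seq(0, men$r_out, length.out = 400L)
    sup <- rep(t_t, length(r))
    on_men <- r >= men$r_in & r <= men$r_out
    s <- (r[on_men] - men$r_in) / (men$r_out - men$r_in)
    sup[on_men] <- pmax(sup[on_men], men$z_base + wedge_height(men, s))
    ok <- r < Ro
    zc <- max(sup[ok] + sqrt(Ro^2 - r[ok]^2)) + params$initial_gap
    list(side = side, centre = c(comp$centre[1], comp$centre[2], zc),
         radius_bone = Rb, radius_outer = Ro)
  }
  cond_MM <- condyle("MM"); cond_LM <- condyle("LM")

  ## terminal-face (horn) area centroid of the wedge cross-section at psi
  horn_centroid <- function(men, psi) {
    s <- seq(0, 1, length.out = 200L)
    hgt <- wedge_height(men, s)
    r <- men$r_in + s * (men$r_out - men$r_in)
    rbar <- sum(r * hgt) / sum(hgt)
    zbar <- men$z_base + sum(hgt^2 / 2) / sum(hgt)
    dir <- cos(psi) * men$u_mid + sin(psi) * men$u_ant
    c(men$centre, 0) + rbar * dir + c(0, 0, zbar)
  }

  ## tibial insertion: toward the intercondylar area on the plateau surface
  insertion_point <- function(men, psi, offset) {
    dir <- cos(psi) * men$u_mid + sin(psi) * men$u_ant
    base <- c(men$centre, 0) + 0.45 * men$r_in * dir
    base[3] <- 0
    base + offset
  }

  off <- params$ligament_insertion_offsets
  ligs <- list(
    medial_anterior   = list(meniscus = "MM", horn = "anterior",
                             horn_point = horn_centroid(MM, MM$psi0),
                             insertion = insertion_point(MM, MM$psi0, off[1, ])),
    medial_posterior  = list(meniscus = "MM", horn = "posterior",
                             horn_point = horn_centroid(MM, MM$psi1),
                             insertion = insertion_point(MM, MM$psi1, off[2, ])),
    lateral_anterior  = list(meniscus = "LM", horn = "anterior",
                             horn_point = horn_centroid(LM, LM$psi0),
                             insertion = insertion_point(LM, LM$psi0, off[3, ])),
    lateral_posterior = list(meniscus = "LM", horn = "posterior",
                             horn_point = horn_centroid(LM, LM$psi1),
                             insertion = insertion_point(LM, LM$psi1, off[4, ])))

  ## femoral bony landmarks (move rigidly with the femur)
  epi_off <- 6
  landmarks <- rbind(
    medial_epicondyle  = cond_MM$centre + c(-hx * (cond_MM$radius_bone + epi_off), 0, 0),
    lateral_epicondyle = cond_LM$centre + c(hx * (cond_LM$radius_bone + epi_off), 0, 0),
    adductor_tubercle  = cond_MM$centre + c(-hx * (cond_MM$radius_bone + epi_off), -4, 18))

  geom <- structure(list(
    params = params,
    tibia = list(plateau_z = 0, halfwidth = params$plateau_halfwidth,
                 cartilage_thickness = t_t),
    femur = list(condyles = list(MM = cond_MM, LM = cond_LM),
                 cartilage_thickness = t_f,
                 reference_point = (cond_MM$centre + cond_LM$centre) / 2),
    menisci = list(MM = MM, LM = LM),
    ligaments = ligs,
    landmarks = landmarks), class = "knee_geometry")
  geom
}

#' @rdname knee_geometry
#' @param ... passed to [knee_params()].
#' @export
generate_geometry <- function(...) {
  args <- list(...)
  if (length(args) == 1L && inherits(args[[1]], "knee_params"))
    knee_geometry(args[[1]])
  else knee_geometry(do.call(knee_params, args))
}

#' @export
print.knee_geometry <- function(x, ...) {
  cat("Synthetic tibiofemoral geometry (mm; +x lateral, +y anterior, +z proximal)\n")
  for (side in c("MM", "LM")) {
    m <- x$menisci[[side]]
    cat(sprintf("  %s meniscus: annulus %.1f-%.1f mm, arc %.0f-%.0f deg, peripheral height %.1f mm\n",
                side, m$r_in, m$r_out, m$psi0 * 180 / pi, m$psi1 * 180 / pi, m$h))
  }
  for (side in c("MM", "LM")) {
    cdl <- x$femur$condyles[[side]]
    cat(sprintf("  %s condyle sphere: bone radius %.1f mm, centre (%.1f, %.1f, %.1f)\n",
                side, cdl$radius_bone, cdl$centre[1], cdl$centre[2], cdl$centre[3]))
  }
  cat(sprintf("  %d ligament attachment pairs, %d landmarks\n",
              length(x$ligaments), nrow(x$landmarks)))
  invisible(x)
}

## Point on / inside a meniscus solid at sweep parameters
## (psi, s in [0,1] inner->outer, v in [0,1] inferior->superior).
meniscus_point <- function(men, psi, s, v) {
  r_out_loc <- men$r_out * (1 + men$rough(psi))
  r <- men$r_in + s * (r_out_loc - men$r_in)
  dir <- outer(cos(psi), men$u_mid) + outer(sin(psi), men$u_ant)
  xy <- dir * r
  xy[, 1] <- xy[, 1] + men$centre[1]
  xy[, 2] <- xy[, 2] + men$centre[2]
  xy[, 3] <- men$z_base + v * wedge_height(men, s)
  xy
}

#' Analytic volume of a meniscal solid
#'
#' Exact swept-wedge volume integral (for the smooth, unperturbed wall):
#' V = (psi1 - psi0) * integral_{r_in}^{r_out} r * height(r) dr.
#'
#' @param geometry `knee_geometry`.
#' @param side "MM" or "LM".
#' @return Volume in mm^3.
#' @export
meniscus_volume_analytic <- function(geometry, side) {
  men <- geometry$menisci[[side]]
  W <- men$r_out - men$r_in
  ## height(r) = h_in + (h - h_in) (r - r_in)/W ; integrate r*height over [r_in, r_out]
  a <- men$h_in; b <- (men$h - men$h_in) / W
  f <- function(r) a * r + b * r * (r - men$r_in)
  int <- a * (men$r_out^2 - men$r_in^2) / 2 +
    b * ((men$r_out^3 - men$r_in^3) / 3 - men$r_in * (men$r_out^2 - men$r_in^2) / 2)
  (men$psi1 - men$psi0) * int
}

#' Pose the femur at a flexion angle
#'
#' Rigid transform rotating the femur about the fixed flexion axis through
#' the two condylar sphere centres, composed with a medial-pivot screw-home
#' internal rotation (about the vertical axis through the medial compartment
#' centre) that accrues linearly from 0 to `screw_home_deg` over 0-20
#' degrees of flexion and is constant thereafter.
#'
#' @param geometry `knee_geometry`.
#' @param flexion_angle flexion angle in degrees, in [0, 30].
#' @param screw_home_deg total internal-rotation coupling magnitude over
#'   0-20 degrees (default 5).
#' @return Object of class `bone_pose`: list with `flexion_angle`,
#'   `transform` (`rigid_transform`), and `source = "parametric"`.
#' @export
pose_femur <- function(geometry, flexion_angle, screw_home_deg = 5) {
  if (!is.finite(flexion_angle) || flexion_angle < 0 || flexion_angle > 30)
    stop("flexion angle out of supported range [0, 30] degrees")
  cM <- geometry$femur$condyles$MM$centre
  cL <- geometry$femur$condyles$LM$centre
  axis <- cL - cM                      # medial -> lateral flexion axis
  flex <- rotation_about_axis(axis, flexion_angle, point = cM)
  ir <- -screw_home_deg * min(flexion_angle, 20) / 20   # internal rotation (lateral condyle posterior)
  screw <- rotation_about_axis(c(0, 0, 1), ir,
                               point = c(geometry$menisci$MM$centre, 0))
  tf <- compose_transforms(screw, flex)
  structure(list(flexion_angle = flexion_angle,
                 screw_home_deg = screw_home_deg,
                 internal_rotation_deg = ir,
                 transform = tf, source = "parametric"),
            class = "bone_pose")
}

#' @export
print.bone_pose <- function(x, ...) {
  cat(sprintf("Bone pose: flexion %g deg, internal rotation %g deg (%s)\n",
              x$flexion_angle, x$internal_rotation_deg, x$source))
  print(x$transform)
  invisible(x)
}

#' Register a bone pose from landmark correspondences
#'
#' Builds a `bone_pose` from observed landmark positions by least-squares
#' rigid registration of the reference landmarks onto the target set.
#'
#' @param geometry `knee_geometry`.
#' @param target_landmarks matrix of observed landmark positions, rows in
#'   the same order as `geometry$landmarks`.
#' @param flexion_angle nominal flexion angle tag for the pose, degrees.
#' @return `bone_pose` with `source = "landmark_registered"` and the
#'   registration `rms` attached.
#' @export
pose_from_landmarks <- function(geometry, target_landmarks, flexion_angle = NA_real_) {
  fit <- landmark_transform(geometry$landmarks, target_landmarks)
  structure(list(flexion_angle = flexion_angle,
                 internal_rotation_deg = NA_real_,
                 transform = fit$transform, rms = fit$rms,
                 source = "landmark_registered"),
            class = "bone_pose")
}

#' Mirror knee parameters about the sagittal midplane
#'
#' Flips the handedness of the knee: the geometry generated from the
#' mirrored parameters is the exact x -> -x reflection of the original
#' (the contralateral knee), with each meniscus occupying the reflected
#' position of its original.
#'
#' @param params `knee_params`.
#' @return `knee_params` of the mirrored (contralateral) knee.
#' @export
mirror_params <- function(params) {
  p <- unclass(params)
  p$handedness <- if (p$handedness == "right") "left" else "right"
  p$ligament_insertion_offsets <- p$ligament_insertion_offsets *
    matrix(rep(c(-1, 1, 1), each = 4), 4, 3)
  do.call(knee_params, p)
}
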
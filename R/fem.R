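## Static, geometrically linear FE core: constant-strain tetrahedra,
## tension-only ligament springs, penalty frictional contact, rigid-body
## boundary conditions (fixed tibia, femur with free DOFs), Newton solver
## with load ramping, step limiting and tangent-only Levenberg damping.

#' Stiffness matrix of a linear (constant-strain) tetrahedron
#'
#' K = V B' C B for the 4-node tetrahedron; DOF order
#' (n1x, n1y, n1z, n2x, ..., n4z).
#'
#' @param nodes 4 x 3 matrix of vertex coordinates, mm.
#' @param C 6x6 material stiffness, MPa, Voigt (11,22,33,23,13,12).
#' @return 12 x 12 element stiffness, N/mm.
#' @export
element_stiffness_tet <- function(nodes, C) {
  BV <- tet_B_matrix(nodes)
  BV$V * crossprod(BV$B, C %*% BV$B)
}

## B matrix (6 x 12) and volume of one tetrahedron.
tet_B_matrix <- function(nodes) {
  e1 <- nodes[2, ] - nodes[1, ]; e2 <- nodes[3, ] - nodes[1, ]; e3 <- nodes[4, ] - nodes[1, ]
  det <- sum(e1 * c(e2[2] * e3[3] - e2[3] * e3[2],
                    e2[3] * e3[1] - e2[1] * e3[3],
                    e2[1] * e3[2] - e2[2] * e3[1]))
  if (det <= 0) stop("inverted element: non-positive volume")
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  g2 <- cross(e2, e3) / det; g3 <- cross(e3, e1) / det; g4 <- cross(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  G <- rbind(g1, g2, g3, g4)
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cx <- 3 * a - 2; cy <- 3 * a - 1; cz <- 3 * a
    B[1, cx] <- G[a, 1]; B[2, cy] <- G[a, 2]; B[3, cz] <- G[a, 3]
    B[4, cy] <- G[a, 3]; B[4, cz] <- G[a, 2]
    B[5, cx] <- G[a, 3]; B[5, cz] <- G[a, 1]
    B[6, cx] <- G[a, 2]; B[6, cy] <- G[a, 1]
  }
  list(B = B, V = det / 6)
}

## Vectorised B rows for all elements of one part.
## Returns list(Brows = list of 6 (M x 12) matrices, V = volumes,
## dofmat = M x 12 global dof indices).
part_B_rows <- function(X, tets_g) {
  p1 <- X[tets_g[, 1], , drop = FALSE]
  e1 <- X[tets_g[, 2], , drop = FALSE] - p1
  e2 <- X[tets_g[, 3], , drop = FALSE] - p1
  e3 <- X[tets_g[, 4], , drop = FALSE] - p1
  crossM <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- crossM(e2, e3); c31 <- crossM(e3, e1); c12 <- crossM(e1, e2)
  det <- rowSums(e1 * c23)
  if (any(det <= 0)) stop("inverted element: non-positive volume")
  g <- list(NULL,
            c23 / det, c31 / det, c12 / det)
  g[[1]] <- -(g[[2]] + g[[3]] + g[[4]])
  M <- nrow(tets_g)
  Brows <- lapply(1:6, function(i) matrix(0, M, 12))
  for (a in 1:4) {
    cx <- 3 * a - 2; cy <- 3 * a - 1; cz <- 3 * a
    ga <- g[[a]]
    Brows[[1]][, cx] <- ga[, 1]
    Brows[[2]][, cy] <- ga[, 2]
    Brows[[3]][, cz] <- ga[, 3]
    Brows[[4]][, cy] <- ga[, 3]; Brows[[4]][, cz] <- ga[, 2]
    Brows[[5]][, cx] <- ga[, 3]; Brows[[5]][, cz] <- ga[, 1]
    Brows[[6]][, cx] <- ga[, 2]; Brows[[6]][, cy] <- ga[, 1]
  }
  dofmat <- matrix(0L, M, 12)
  for (a in 1:4) for (d in 1:3) dofmat[, 3L * (a - 1L) + d] <- 3L * (tets_g[, a] - 1L) + d
  list(Brows = Brows, V = det / 6, dofmat = dofmat)
}

## Unique material stiffnesses for a part: isotropic -> one matrix;
## fibered -> one matrix per distinct fiber direction.
part_material_Cs <- function(mesh, material) {
  M <- nrow(mesh$tets)
  if (inherits(material, "elastic_isotropic") || is.null(mesh$fiber)) {
    list(Cs = list(material_stiffness(material, c(1, 0, 0))), cid = rep(1L, M))
  } else {
    key <- paste(round(mesh$fiber[, 1], 9), round(mesh$fiber[, 2], 9),
                 round(mesh$fiber[, 3], 9))
    uk <- unique(key)
    cid <- match(key, uk)
    first <- match(uk, key)
    Cs <- lapply(first, function(e) {
      f <- mesh$fiber[e, ]
      stiffness_transverse_isotropic(material, f / sqrt(sum(f^2)))
    })
    list(Cs = Cs, cid = cid)
  }
}

## Elastic stiffness triplets for one part (vectorised over elements).
part_stiffness_triplets <- function(BV, Cs, cid) {
  M <- length(BV$V)
  Ke <- matrix(0, M, 144)
  iidx <- rep(1:12, times = 12)
  jidx <- rep(1:12, each = 12)
  for (g in seq_along(Cs)) {
    rows <- which(cid == g)
    C <- Cs[[g]]
    for (p in 1:6) for (q in 1:6) {
      if (abs(C[p, q]) < 1e-14) next
      w <- BV$V[rows] * C[p, q]
      Ke[rows, ] <- Ke[rows, ] +
        (BV$Brows[[p]][rows, iidx, drop = FALSE] *
           BV$Brows[[q]][rows, jidx, drop = FALSE]) * w
    }
  }
  list(i = as.integer(BV$dofmat[, iidx]), j = as.integer(BV$dofmat[, jidx]),
       x = as.numeric(Ke))
}

#' Assemble an FE model into a solvable system
#'
#' Combines part meshes into global numbering, assembles the elastic
#' stiffness, builds the constraint transformation (fixed DOFs, rigid-body
#' slaving with free rigid DOFs appended as unknowns) and precomputes the
#' reduced elastic stiffness and contact tributary areas.
#'
#' @param model `fe_model` (see [fe_model()]).
#' @param reuse optional `fe_system` of a closely related model: parts whose
#'   mesh and global offset are unchanged reuse their elastic triplets and
#'   stress-recovery tables instead of reassembling.
#' @return Object of class `fe_system`.
#' @export
fe_assemble <- function(model, reuse = NULL) {
  X <- model$X; N3 <- 3L * nrow(X)
  trip_i <- vector("list", length(model$parts))
  trip_j <- trip_i; trip_x <- trip_i
  recov <- vector("list", length(model$parts))
  for (p in seq_along(model$parts)) {
    prt <- model$parts[[p]]
    nm <- names(model$parts)[p]
    if (!is.null(reuse) &&
        identical(reuse$model$parts[[nm]]$mesh$uid, prt$mesh$uid) &&
        identical(reuse$model$offsets[[nm]], model$offsets[[p]]) &&
        !is.null(reuse$part_triplets[[nm]])) {
      tr <- reuse$part_triplets[[nm]]
      trip_i[[p]] <- tr$i; trip_j[[p]] <- tr$j; trip_x[[p]] <- tr$x
      recov[[p]] <- reuse$recovery[[which(names(reuse$model$parts) == nm)]]
      next
    }
    tets_g <- prt$mesh$tets + model$offsets[[p]]
    BV <- part_B_rows(X, tets_g)
    mc <- part_material_Cs(prt$mesh, prt$material)
    tr <- part_stiffness_triplets(BV, mc$Cs, mc$cid)
    trip_i[[p]] <- tr$i; trip_j[[p]] <- tr$j; trip_x[[p]] <- tr$x
    recov[[p]] <- list(BV = BV, Cs = mc$Cs, cid = mc$cid)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(N3, N3))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  ## constraint transformation u = T q + u0
  fixed_dof <- integer(0); fixed_val <- numeric(0)
  if (!is.null(model$fixed) && nrow(model$fixed)) {
    fixed_dof <- model$fixed$dof; fixed_val <- model$fixed$value
  }
  slave_dof <- integer(0)
  rb_cols <- list()
  n_rb <- 0L
  for (rb in model$rigid_bodies) n_rb <- n_rb + length(rb$free)
  is_fixed <- logical(N3); is_fixed[fixed_dof] <- TRUE
  is_slave <- logical(N3)
  for (rb in model$rigid_bodies) {
    dofs <- as.integer(outer(3L * (rb$nodes - 1L), 1:3, "+"))
    is_slave[dofs] <- TRUE
  }
  if (any(is_fixed & is_slave)) stop("DOF both fixed and rigid-slaved")
  free <- which(!is_fixed & !is_slave)
  nq <- length(free) + n_rb
  Ti <- free; Tj <- seq_along(free); Tx <- rep(1, length(free))
  col0 <- length(free)
  rb_col_names <- character(0)
  for (rb in model$rigid_bodies) {
    for (fd in rb$free) {
      col0 <- col0 + 1L
      rb_col_names <- c(rb_col_names, paste0(rb$name, ".", fd$name))
      if (fd$type == "trans") {
        for (d in 1:3) if (abs(fd$dir[d]) > 0) {
          Ti <- c(Ti, 3L * (rb$nodes - 1L) + d)
          Tj <- c(Tj, rep(col0, length(rb$nodes)))
          Tx <- c(Tx, rep(fd$dir[d], length(rb$nodes)))
        }
      } else {                     # rotation: u = axis x (Xn - point)
        dX <- sweep(X[rb$nodes, , drop = FALSE], 2L, fd$point)
        a <- fd$axis / sqrt(sum(fd$axis^2))
        w <- cbind(a[2] * dX[, 3] - a[3] * dX[, 2],
                   a[3] * dX[, 1] - a[1] * dX[, 3],
                   a[1] * dX[, 2] - a[2] * dX[, 1])
        for (d in 1:3) {
          nzr <- which(abs(w[, d]) > 1e-14)
          if (length(nzr)) {
            Ti <- c(Ti, 3L * (rb$nodes[nzr] - 1L) + d)
            Tj <- c(Tj, rep(col0, length(nzr)))
            Tx <- c(Tx, w[nzr, d])
          }
        }
      }
    }
  }
  T <- Matrix::sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(N3, nq))
  u0 <- numeric(N3); u0[fixed_dof] <- fixed_val
  K_red <- Matrix::forceSymmetric(Matrix::t(T) %*% K %*% T)

  areas <- lapply(model$contacts, function(cp) tributary_areas(cp, X))
  part_triplets <- stats::setNames(
    lapply(seq_along(model$parts), function(p)
      list(i = trip_i[[p]], j = trip_j[[p]], x = trip_x[[p]])),
    names(model$parts))
  structure(list(model = model, K = K, K_red = K_red, T = T, u0 = u0,
                 free = free, n_free = length(free), nq = nq,
                 rb_cols = rb_col_names, is_fixed = is_fixed,
                 recovery = recov, areas = areas,
                 part_triplets = part_triplets),
            class = "fe_system")
}

#' Construct an FE model
#'
#' @param parts named list; each element `list(mesh = <fe_mesh>,
#'   material = <elastic_material>)`.
#' @param fixed data.frame with columns `dof` (global DOF index) and
#'   `value` (prescribed displacement, mm), or NULL.
#' @param rigid_bodies list of rigid bodies: each
#'   `list(name =, nodes = <global node ids>, free = list(...))` where each
#'   free DOF is `list(name =, type = "trans", dir =)` or
#'   `list(name =, type = "rot", axis =, point =)`.
#' @param springs list of tension-only springs: each `list(name =, nodes =
#'   <global ids>, k = <N/mm>, ground = <point>, slack = <mm or NULL>)`;
#'   NULL slack means the reference length (zero force at reference).
#' @param contacts list of `contact_pair` (global node numbering).
#' @param loads list with optional `nodal` (full-length 3N force vector, N)
#'   and `rigid` (named vector of loads on rigid free DOFs, names
#'   "body.dof").
#' @return Object of class `fe_model`.
#' @export
fe_model <- function(parts, fixed = NULL, rigid_bodies = list(),
                     springs = list(), contacts = list(), loads = list()) {
  offs <- integer(length(parts)); names(offs) <- names(parts)
  tot <- 0L
  for (p in seq_along(parts)) {
    offs[p] <- tot
    tot <- tot + nrow(parts[[p]]$mesh$nodes)
  }
  X <- do.call(rbind, lapply(parts, function(pp) pp$mesh$nodes))
  rownames(X) <- NULL
  ## spring slack defaults to reference length
  for (s in seq_along(springs)) {
    sp <- springs[[s]]
    if (is.null(sp$slack)) {
      cen <- colMeans(X[sp$nodes, , drop = FALSE])
      springs[[s]]$slack <- sqrt(sum((cen - sp$ground)^2))
    }
  }
  structure(list(parts = parts, offsets = offs, X = X, fixed = fixed,
                 rigid_bodies = rigid_bodies, springs = springs,
                 contacts = contacts, loads = loads),
            class = "fe_model")
}

#' Global node ids of a part
#' @param model `fe_model`.
#' @param part part name.
#' @param local local node ids (default all).
#' @return Integer global node ids.
#' @export
global_nodes <- function(model, part, local = NULL) {
  off <- model$offsets[[part]]
  if (is.null(local)) local <- seq_len(nrow(model$parts[[part]]$mesh$nodes))
  as.integer(local + off)
}

#' Nodes of a facet set (local numbering)
#' @param mesh `fe_mesh`.
#' @param set facet set name.
#' @return Sorted unique node ids appearing in the facet set.
#' @export
facet_nodes <- function(mesh, set) {
  if (is.null(mesh$facets[[set]])) stop("no facet set named '", set, "'")
  sort(unique(as.integer(mesh$facets[[set]])))
}

#' Bonded rigid-bone constraints from a facet set
#'
#' Cartilage-bone interfaces permit no tangential motion: the bone-side
#' cartilage nodes move rigidly with their bone. For the fully constrained
#' tibia this returns a fixed-DOF table; for the femur a rigid-body slave
#' node set to attach to the femur's free DOFs.
#'
#' @param model `fe_model`.
#' @param part part name.
#' @param set facet set name (e.g. "bone").
#' @param kind "fixed" (tibial side) or "rigid" (femoral side).
#' @return For "fixed": data.frame(dof, value); for "rigid": global node ids.
#' @export
rigid_bone_constraints <- function(model, part, set = "bone", kind = c("fixed", "rigid")) {
  kind <- match.arg(kind)
  mesh <- model$parts[[part]]$mesh
  loc <- facet_nodes(mesh, set)
  if (!length(loc)) stop("empty facet set '", set, "' on part '", part, "'")
  gn <- global_nodes(model, part, loc)
  if (kind == "fixed")
    data.frame(dof = as.integer(outer(3L * (gn - 1L), 1:3, "+")), value = 0)
  else gn
}

## Tension-only spring forces: force distributed equally over the node set,
## elongation measured at the node-set centroid.
spring_forces <- function(model, u) {
  N3 <- 3L * nrow(model$X)
  f <- numeric(N3)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  report <- list()
  for (sp in model$springs) {
    nn <- length(sp$nodes)
    cen <- colMeans(model$X[sp$nodes, , drop = FALSE] + u[sp$nodes, , drop = FALSE])
    d <- sp$ground - cen
    L <- sqrt(sum(d^2))
    a <- d / max(L, 1e-12)
    ext <- L - sp$slack
    Fax <- if (ext > 0) sp$k * ext else 0
    fn <- Fax / nn
    dofs <- as.integer(outer(3L * (sp$nodes - 1L), 1:3, "+"))
    f[dofs] <- f[dofs] + rep(a * fn, each = nn)
    if (ext > 0) {
      ## tangent: d(-f)/du ~ (k/nn^2) a a' between every node pair
      S <- (sp$k / nn^2) * tcrossprod(a)
      if (L > 1e-9) S <- S + (Fax / L) * (diag(3) - tcrossprod(a)) / nn^2
      blk <- matrix(1, nn, nn) %x% S
      dd <- as.integer(t(outer(3L * (sp$nodes - 1L), 1:3, "+")))
      ti <- c(ti, rep(dd, times = 3L * nn))
      tj <- c(tj, rep(dd, each = 3L * nn))
      tx <- c(tx, as.numeric(blk))
    }
    report[[sp$name]] <- list(force = Fax, elongation = ext, axis = a,
                              k_eff = sp$k, on_ground = -a * Fax)
  }
  list(f = f, ti = ti, tj = tj, tx = tx, report = report)
}

## Evaluate full-space internal/external forces and contact state.
## Returns residual pieces used by the Newton loop.
evaluate_state <- function(sys, q, lambda, anchors, active_tol,
                           update_anchors = FALSE) {
  model <- sys$model
  N3 <- 3L * nrow(model$X)
  u_full <- as.numeric(sys$T %*% q) + sys$u0
  u <- matrix(u_full, ncol = 3L, byrow = TRUE)
  f_el <- as.numeric(sys$K %*% u_full)
  sp <- spring_forces(model, u)
  f_con <- numeric(N3)
  con_res <- vector("list", length(model$contacts))
  ti <- list(sp$ti); tj <- list(sp$tj); tx <- list(sp$tx)
  for (cc in seq_along(model$contacts)) {
    cr <- contact_forces(model$contacts[[cc]], model$X, u, sys$areas[[cc]],
                         anchors = anchors[[cc]], active_tol = active_tol,
                         update_anchors = update_anchors)
    con_res[[cc]] <- cr
    anchors[[cc]] <- cr$anchors
    f_con <- f_con + cr$f
    ti <- c(ti, list(cr$ti)); tj <- c(tj, list(cr$tj)); tx <- c(tx, list(cr$tx))
  }
  f_ext <- numeric(N3)
  if (!is.null(model$loads$nodal)) f_ext <- f_ext + lambda * model$loads$nodal
  r_full <- f_ext + f_con + sp$f - f_el
  r_red <- as.numeric(Matrix::t(sys$T) %*% r_full)
  ## total potential energy (friction treated as external, not potential):
  ## elastic strain energy - load potential + spring + contact penalty energy
  energy <- 0.5 * sum(u_full * f_el) - sum(f_ext * u_full) +
    sum(vapply(sp$report, function(s) 0.5 * s$k_eff * max(0, s$elongation)^2,
               numeric(1))) +
    sum(vapply(con_res, function(cr) cr$energy, numeric(1)))
  if (!is.null(model$loads$rigid) && length(model$loads$rigid)) {
    pos <- match(names(model$loads$rigid), sys$rb_cols)
    if (anyNA(pos)) stop("unknown rigid DOF in loads: ",
                         paste(names(model$loads$rigid)[is.na(pos)], collapse = ", "))
    r_red[sys$n_free + pos] <- r_red[sys$n_free + pos] + lambda * model$loads$rigid
    energy <- energy - sum(lambda * model$loads$rigid * q[sys$n_free + pos])
  }
  list(u = u, u_full = u_full, r_full = r_full, r_red = r_red, energy = energy,
       anchors = anchors, contacts = con_res, springs = sp, f_con = f_con,
       ti = unlist(ti), tj = unlist(tj), tx = unlist(tx))
}

#' Solve the static FE problem
#'
#' Newton iterations with penalty contact (active-set by gap), tension-only
#' springs, load ramping, step limiting and tangent-only Levenberg damping
#' (damping enters the iteration matrix only, never the converged residual).
#'
#' @param sys `fe_system` from [fe_assemble()].
#' @param rtol force-residual tolerance relative to the applied load.
#' @param max_iter maximum Newton iterations per load step.
#' @param load_steps number of proportional load increments (1 suffices for
#'   this load level; ramping is available for stiffer configurations).
#' @param step_limit maximum nodal displacement increment per iteration, mm.
#' @param active_tol gap activation tolerance for contact stiffness, mm.
#' @param penetration_tol allowed residual penetration, mm (reported).
#' @param state0 optional warm start: list with `q` (initial unknowns) and
#'   `anchors` (friction anchor list), e.g. mapped from a related solution.
#' @param verbose print per-iteration residuals.
#' @return Object of class `fe_solution`.
#' @export
solve_static <- function(sys, rtol = 2e-3, max_iter = 150, load_steps = 1,
                         step_limit = 1.0, active_tol = 0.5,
                         penetration_tol = 0.025, state0 = NULL,
                         verbose = FALSE) {
  model <- sys$model
  nq <- sys$nq
  if (nq == 0L) stop("structural singularity: no unknowns (everything constrained?)")
  q <- numeric(nq)
  ## a model without contacts or springs is linear: a singular stiffness is
  ## then a structural defect (missing constraints), not a solvable state
  if (!length(model$contacts) && !length(model$springs)) {
    probe <- rep(1, nq)
    x <- tryCatch(as.numeric(Matrix::solve(sys$K_red, probe)),
                  error = function(e) NULL)
    ok <- !is.null(x) && all(is.finite(x)) &&
      max(abs(as.numeric(sys$K_red %*% x) - probe)) < 1e-6 * max(1, max(abs(probe)))
    if (!ok) stop("structural singularity: stiffness not positive definite (insufficient constraint)")
  }
  anchors <- vector("list", length(model$contacts))
  if (!is.null(state0)) {
    if (!is.null(state0$q)) {
      stopifnot(length(state0$q) == nq)
      q <- state0$q
    }
    if (!is.null(state0$anchors)) anchors <- state0$anchors
  }
  fref <- 0
  if (!is.null(model$loads$nodal)) fref <- fref + sqrt(sum(model$loads$nodal^2))
  if (!is.null(model$loads$rigid)) fref <- fref + sqrt(sum(unlist(model$loads$rigid)^2))
  has_load <- fref > 0
  tol_base <- rtol * max(fref, 1)
  trace <- list()
  converged_all <- TRUE
  for (step in seq_len(load_steps)) {
    lambda <- step / load_steps
    damp <- 0
    st <- evaluate_state(sys, q, lambda, anchors,
                         min(active_tol, if (step > 1) 1e-3 else active_tol),
                         update_anchors = TRUE)
    anchors <- st$anchors              # friction history frozen between commits
    rn <- sqrt(sum(st$r_red^2))
    recommits <- 0L
    for (it in seq_len(max_iter)) {
      if (rn <= tol_base) break
      ## wide activation early (near-contact stiffness, no force) to keep
      ## the floating rigid body well-posed; tight once contact is seated
      act_now <- if (it <= 3L) active_tol else min(active_tol, 1e-3)
      Kc <- if (length(st$ti))
        Matrix::sparseMatrix(i = st$ti, j = st$tj, x = st$tx,
                             dims = rep(3L * nrow(model$X), 2L))
      else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = rep(3L * nrow(model$X), 2L))
      J <- sys$K_red + Matrix::forceSymmetric(Matrix::t(sys$T) %*% Kc %*% sys$T)
      accepted <- FALSE
      for (try_dir in 1:6) {
        repeat {
          Jd <- if (damp > 0) J + damp * Matrix::Diagonal(nq) else J
          dq <- tryCatch(as.numeric(Matrix::solve(Jd, st$r_red)),
                         error = function(e) NULL)
          ## an absurd step means the factorisation slid through a
          ## numerically singular pivot: damp and retry
          if (!is.null(dq) && all(is.finite(dq)) && max(abs(dq)) < 1e6) break
          damp <- if (damp == 0) 1e-2 * max(abs(J@x)) / nq else damp * 10
          if (damp > 1e12) stop("structural singularity: tangent not solvable (insufficient constraint)")
        }
        mstep <- max(abs(dq))
        if (mstep > step_limit) dq <- dq * (step_limit / mstep)
        slope <- sum(st$r_red * dq)          # descent rate of the energy
        if (slope <= 0) {                    # not a descent direction: damp more
          damp <- if (damp == 0) 1e-4 * max(Matrix::diag(J)) else damp * 10
          next
        }
        ## Globalisation: Armijo on the total potential energy while far
        ## from equilibrium; once the residual is small the energy
        ## difference drowns in roundoff, so accept on residual descent
        ## (the regularised system is smooth there and Newton is reliable).
        resid_mode <- rn < 2e-3 * max(fref, 1)
        alpha <- 1
        for (ls in 1:9) {
          st_try <- evaluate_state(sys, q + alpha * dq, lambda, anchors, act_now)
          ok <- if (resid_mode) sqrt(sum(st_try$r_red^2)) < rn
                else st_try$energy <= st$energy - 1e-4 * alpha * slope
          if (ok || sqrt(sum(st_try$r_red^2)) <= tol_base) { accepted <- TRUE; break }
          alpha <- alpha / 2
        }
        if (accepted) break
        damp <- if (damp == 0) 1e-4 * max(Matrix::diag(J)) else damp * 10
      }
      if (!accepted) {
        ## stagnation against stale friction anchors: commit the slip
        ## return map at the current state (a quasi-static history
        ## sub-increment) and continue; give up after several commits
        st2 <- evaluate_state(sys, q, lambda, anchors, act_now,
                              update_anchors = TRUE)
        anchors <- st2$anchors
        st <- evaluate_state(sys, q, lambda, anchors, act_now)
        rn_new <- sqrt(sum(st$r_red^2))
        recommits <- recommits + 1L
        damp <- 0
        if (recommits > 12L && rn_new >= rn) break
        rn <- rn_new
        next
      }
      q <- q + alpha * dq
      st <- st_try
      rn <- sqrt(sum(st$r_red^2))
      damp <- damp / 4; if (damp < 1e-8) damp <- 0
      trace[[length(trace) + 1L]] <- data.frame(step = step, iter = it,
                                                residual = rn, alpha = alpha,
                                                damping = damp)
      if (verbose) message(sprintf("step %d iter %d residual %.4g energy %.6g alpha %.3f damp %.2g",
                                   step, it, rn, st$energy, alpha, damp))
    }
    if (rn > tol_base) {
      converged_all <- FALSE
      warning(sprintf("load step %d did not converge: residual %.3g (tolerance %.3g)",
                      step, rn, tol_base))
    }
    ## commit friction history (slip return map) at the end of the load step
    st <- evaluate_state(sys, q, lambda, anchors, active_tol, update_anchors = TRUE)
    anchors <- st$anchors
  }
  st <- evaluate_state(sys, q, 1, anchors, active_tol)
  stresses <- recover_stresses(sys, st$u_full)
  rigid_dofs <- stats::setNames(if (length(sys$rb_cols)) q[sys$n_free + seq_along(sys$rb_cols)]
                                else numeric(0), sys$rb_cols)
  support <- -st$r_full
  support[!sys$is_fixed] <- 0
  pen <- vapply(st$contacts, function(cr) max(0, -min(cr$status$gap)), numeric(1))
  structure(list(model = model, system = sys, q = q,
                 u = st$u, rigid_dofs = rigid_dofs,
                 contact_force = matrix(st$f_con, ncol = 3L, byrow = TRUE),
                 stresses = stresses,
                 contacts = lapply(st$contacts, function(cr)
                   cr[c("status", "follower_force", "total_force_on_target")]),
                 springs = st$springs$report,
                 support_force = support,
                 residual_norm = sqrt(sum(st$r_red^2)),
                 tolerance = tol_base,
                 converged = converged_all && sqrt(sum(st$r_red^2)) <= tol_base,
                 max_penetration = if (length(pen)) max(pen) else 0,
                 penetration_tol = penetration_tol,
                 state = list(q = q, anchors = anchors),
                 trace = if (length(trace)) do.call(rbind, trace)
                 else data.frame(step = integer(), iter = integer(),
                                 residual = numeric(), alpha = numeric(),
                                 damping = numeric())),
            class = "fe_solution")
}

## Element stresses (Voigt M x 6, MPa) and principal values per part.
recover_stresses <- function(sys, u_full) {
  out <- list()
  for (p in seq_along(sys$model$parts)) {
    rec <- sys$recovery[[p]]
    dofu <- matrix(u_full[rec$BV$dofmat], ncol = 12L)
    eps <- vapply(1:6, function(r) rowSums(rec$BV$Brows[[r]] * dofu),
                  numeric(nrow(dofu)))
    sig <- matrix(0, nrow(eps), 6L)
    for (g in seq_along(rec$Cs)) {
      rows <- which(rec$cid == g)
      sig[rows, ] <- eps[rows, , drop = FALSE] %*% t(rec$Cs[[g]])
    }
    pcs <- principal_stresses_many(sig)
    out[[names(sys$model$parts)[p]]] <- list(voigt = sig, principal = pcs)
  }
  out
}

#' Consistent nodal forces for a uniform traction on a facet set
#'
#' @param mesh `fe_mesh`.
#' @param set facet set name.
#' @param traction length-3 traction vector, MPa (N/mm^2).
#' @return Matrix (n_nodes x 3) of nodal forces in local numbering, and the
#'   node ids, as a list.
#' @export
face_tractions <- function(mesh, set, traction) {
  faces <- mesh$facets[[set]]
  fa <- facet_areas_normals(mesh$nodes, faces)
  nn <- sort(unique(as.integer(faces)))
  f <- matrix(0, length(nn), 3L)
  for (c3 in 1:3) {
    tmp <- tapply(fa$area / 3, faces[, c3], sum)
    rows <- match(as.integer(names(tmp)), nn)
    f[rows, ] <- f[rows, ] + outer(as.numeric(tmp), traction)
  }
  list(nodes = nn, forces = f)
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution: %d nodes, %s, residual %.3g (tol %.3g), max penetration %.4f mm\n",
              nrow(x$u), if (x$converged) "converged" else "NOT converged",
              x$residual_norm, x$tolerance, x$max_penetration))
  if (length(x$rigid_dofs)) {
    cat("Rigid-body DOFs:\n")
    for (nm in names(x$rigid_dofs))
      cat(sprintf("  %s = %.5f\n", nm, x$rigid_dofs[[nm]]))
  }
  invisible(x)
}

#' @export
residuals.fe_solution <- function(object, ...) object$trace
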
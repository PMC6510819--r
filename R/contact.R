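## Node-to-surface penalty contact with regularised Coulomb friction.
##
## Followers are nodes; targets are deformed boundary triangle sets (with
## outward winding, as produced by the meshers) or analytic rigid surfaces
## (plane, sphere). Normal law: tension-free penalty p = kn * max(0, -gap);
## nodal normal force = p * tributary area. Friction: elastic-anchor
## (penalty) tangential force with return mapping, capped at mu * normal.
## Forces on mesh targets are distributed to the triangle nodes with
## barycentric weights, so contact transmits equal and opposite force and
## global equilibrium is preserved.

## Vectorised closest point on triangles (Ericson's region method).
## p, a, b, c: n x 3 matrices. Returns list(point, w) with barycentric
## weights (wa, wb, wc).
closest_point_triangle <- function(p, a, b, c) {
  dot <- function(u, v) rowSums(u * v)
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- dot(ab, ap); d2 <- dot(ac, ap)
  bp <- p - b; d3 <- dot(ab, bp); d4 <- dot(ac, bp)
  cp <- p - c; d5 <- dot(ab, cp); d6 <- dot(ac, cp)
  n <- nrow(p)
  wa <- numeric(n); wb <- numeric(n); wc <- numeric(n)
  done <- logical(n)
  setw <- function(idx, u, v, w) {
    wa[idx] <<- u; wb[idx] <<- v; wc[idx] <<- w; done[idx] <<- TRUE
  }
  r1 <- !done & d1 <= 0 & d2 <= 0                       # vertex a
  if (any(r1)) setw(r1, 1, 0, 0)
  r2 <- !done & d3 >= 0 & d4 <= d3                       # vertex b
  if (any(r2)) setw(r2, 0, 1, 0)
  r3 <- !done & d6 >= 0 & d5 <= d6                       # vertex c
  if (any(r3)) setw(r3, 0, 0, 1)
  vc <- d1 * d4 - d3 * d2
  r4 <- !done & vc <= 0 & d1 >= 0 & d3 <= 0              # edge ab
  if (any(r4)) {
    v <- d1[r4] / (d1[r4] - d3[r4]); setw(r4, 1 - v, v, 0)
  }
  vb <- d5 * d2 - d1 * d6
  r5 <- !done & vb <= 0 & d2 >= 0 & d6 <= 0              # edge ac
  if (any(r5)) {
    w <- d2[r5] / (d2[r5] - d6[r5]); setw(r5, 1 - w, 0, w)
  }
  va <- d3 * d6 - d5 * d4
  r6 <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0   # edge bc
  if (any(r6)) {
    w <- (d4[r6] - d3[r6]) / ((d4[r6] - d3[r6]) + (d5[r6] - d6[r6]))
    setw(r6, 0, 1 - w, w)
  }
  r7 <- !done                                            # interior
  if (any(r7)) {
    denom <- va[r7] + vb[r7] + vc[r7]
    v <- vb[r7] / denom; w <- vc[r7] / denom
    setw(r7, 1 - v - w, v, w)
  }
  point <- a * wa + b * wb + c * wc
  list(point = point, w = cbind(wa, wb, wc))
}

## Project follower points onto a deformed triangle set.
## pts: n x 3; faces: F x 3 (global node ids); coords: N x 3 deformed.
## Returns per point: best face index, projection, barycentric weights,
## smoothed outward normal, signed gap. Normals are barycentric
## interpolations of area-weighted vertex normals, so the gap varies
## continuously as a projection slides across facet boundaries (a faceted
## surface with per-face normals leaves gradient kinks that stall Newton).
project_on_faces <- function(pts, faces, coords, k_candidates = 8L) {
  A <- coords[faces[, 1], , drop = FALSE]
  B <- coords[faces[, 2], , drop = FALSE]
  C <- coords[faces[, 3], , drop = FALSE]
  cen <- (A + B + C) / 3
  n <- nrow(pts); Fn <- nrow(faces)
  k <- min(k_candidates, Fn)
  ## squared distances point -> face centroids
  d2 <- outer(rowSums(pts^2), rep(1, Fn)) + outer(rep(1, n), rowSums(cen^2)) -
    2 * pts %*% t(cen)
  ## k nearest centroids per point by repeated max.col (C fast path)
  ord <- matrix(0L, n, k)
  for (kk in seq_len(k)) {
    j <- max.col(-d2, ties.method = "first")
    ord[, kk] <- j
    d2[cbind(seq_len(n), j)] <- Inf
  }
  pi_rep <- rep(seq_len(n), each = k)
  fi <- as.integer(t(ord))
  cp <- closest_point_triangle(pts[pi_rep, , drop = FALSE],
                               A[fi, , drop = FALSE],
                               B[fi, , drop = FALSE],
                               C[fi, , drop = FALSE])
  dist2 <- rowSums((pts[pi_rep, , drop = FALSE] - cp$point)^2)
  dm <- matrix(dist2, nrow = n, byrow = TRUE)
  best <- max.col(-dm, ties.method = "first")
  pick <- (seq_len(n) - 1L) * k + best
  face_best <- fi[pick]
  proj <- cp$point[pick, , drop = FALSE]
  w <- cp$w[pick, , drop = FALSE]
  ## area-weighted vertex normals of the facet set (deformed configuration)
  fan_all <- facet_areas_normals(coords, faces)
  vn <- matrix(0, nrow(coords), 3L)
  wn <- fan_all$normal * fan_all$area
  for (c3 in 1:3) {
    acc <- rowsum(wn, group = faces[, c3])
    ids <- as.integer(rownames(acc))
    vn[ids, ] <- vn[ids, ] + acc
  }
  tri <- faces[face_best, , drop = FALSE]
  nrm <- w[, 1] * vn[tri[, 1], , drop = FALSE] +
    w[, 2] * vn[tri[, 2], , drop = FALSE] +
    w[, 3] * vn[tri[, 3], , drop = FALSE]
  nlen <- sqrt(rowSums(nrm^2))
  bad <- nlen < 1e-12
  if (any(bad)) nrm[bad, ] <- fan_all$normal[face_best[bad], , drop = FALSE]
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
  gap <- rowSums((pts - proj) * nrm)
  list(face = face_best, proj = proj, w = w, normal = nrm, gap = gap)
}

## Gap/normal against analytic rigid surfaces.
## surf: list(type = "plane", point, normal) with normal pointing towards
## the followers, or list(type = "sphere", centre, radius) contacted from
## outside.
project_on_analytic <- function(pts, surf) {
  if (surf$type == "plane") {
    nrm <- surf$normal / sqrt(sum(surf$normal^2))
    gap <- as.numeric(sweep(pts, 2L, surf$point) %*% nrm)
    proj <- pts - outer(gap, nrm)
    list(proj = proj, normal = matrix(nrm, nrow(pts), 3L, byrow = TRUE), gap = gap)
  } else if (surf$type == "sphere") {
    d <- sweep(pts, 2L, surf$centre)
    r <- sqrt(rowSums(d^2))
    nrm <- d / pmax(r, 1e-12)
    gap <- r - surf$radius
    proj <- sweep(nrm * surf$radius, 2L, surf$centre, "+")
    list(proj = proj, normal = nrm, gap = gap)
  } else stop("unknown analytic surface type: ", surf$type)
}

#' Define a contact pair
#'
#' @param follower_nodes integer global node ids of the follower surface.
#' @param follower_faces triangle matrix (global ids) of the follower
#'   surface, used to compute nodal tributary areas.
#' @param target_faces triangle matrix (global ids) of the target surface
#'   (outward winding), or `NULL` for an analytic target.
#' @param analytic optional analytic rigid surface:
#'   `list(type = "plane", point =, normal =)` (normal towards followers) or
#'   `list(type = "sphere", centre =, radius =)`.
#' @param friction_mu Coulomb friction coefficient (default 0.02).
#' @param penalty_normal normal penalty stiffness, N/mm^3 (pressure per
#'   penetration depth).
#' @param penalty_tangent tangential penalty stiffness, N/mm^3.
#' @param kind label: "deformable-deformable", "deformable-rigid" or
#'   "tear-face".
#' @param search_radius candidate search radius, mm.
#' @return Object of class `contact_pair`.
#' @export
contact_pair <- function(follower_nodes, follower_faces = NULL, target_faces = NULL,
                         analytic = NULL, friction_mu = 0.02,
                         penalty_normal = 300, penalty_tangent = 30,
                         kind = "deformable-deformable", search_radius = 6) {
  if (friction_mu < 0) stop("friction_mu must be >= 0")
  if (penalty_normal <= 0 || penalty_tangent <= 0) stop("contact penalties must be > 0")
  if (is.null(target_faces) && is.null(analytic))
    stop("contact pair needs target_faces or an analytic surface")
  structure(list(follower_nodes = as.integer(follower_nodes),
                 follower_faces = follower_faces,
                 target_faces = target_faces, analytic = analytic,
                 friction_mu = friction_mu,
                 penalty_normal = penalty_normal,
                 penalty_tangent = penalty_tangent,
                 kind = kind, search_radius = search_radius),
            class = "contact_pair")
}

## Tributary areas for follower nodes from their facet set (reference
## coords): one third of each adjacent follower triangle's area.
tributary_areas <- function(pair, X) {
  nf <- pair$follower_nodes
  if (is.null(pair$follower_faces)) return(rep(1, length(nf)))
  fa <- facet_areas_normals(X, pair$follower_faces)
  acc <- numeric(max(c(pair$follower_faces, nf)))
  for (c3 in 1:3) {
    tmp <- tapply(fa$area / 3, pair$follower_faces[, c3], sum)
    ids <- as.integer(names(tmp))
    acc[ids] <- acc[ids] + tmp
  }
  out <- acc[nf]
  if (any(out <= 0)) out[out <= 0] <- mean(out[out > 0])
  out
}

#' Evaluate contact forces for a displacement state
#'
#' Computes penalty normal and regularised Coulomb friction forces for one
#' contact pair, together with the per-follower status, and consistent
#' force distribution to the target facet nodes.
#'
#' @param pair `contact_pair`.
#' @param X reference node coordinates (N x 3, global numbering).
#' @param u displacement matrix (N x 3).
#' @param areas nodal tributary areas for the followers (from
#'   [tributary_areas()]).
#' @param anchors previous friction anchor points (n_f x 3 matrix or NULL).
#' @param active_tol gap below which a node contributes contact stiffness
#'   (force requires gap < 0), mm.
#' @return list with full-space force vector contributions (`f`, length 3N,
#'   force exerted ON the bodies), updated `anchors`, per-follower `status`
#'   data frame (gap mm, pressure MPa, state open/stick/slip), and tangent
#'   triplets (`ti`, `tj`, `tx`).
#' @export
contact_forces <- function(pair, X, u, areas, anchors = NULL, active_tol = 0.5,
                           update_anchors = TRUE) {
  nf <- pair$follower_nodes
  nF <- length(nf)
  xf <- X[nf, , drop = FALSE] + u[nf, , drop = FALSE]
  coords <- X + u
  if (is.null(pair$analytic)) {
    pr <- project_on_faces(xf, pair$target_faces, coords)
    tgt_nodes <- pair$target_faces[pr$face, , drop = FALSE]
  } else {
    pr <- project_on_analytic(xf, pair$analytic)
    tgt_nodes <- NULL
  }
  if (is.null(anchors)) anchors <- pr$proj
  gap <- pr$gap; nrm <- pr$normal
  kn <- pair$penalty_normal * areas
  kt <- pair$penalty_tangent * areas
  pen <- pmax(0, -gap)
  fn_mag <- kn * pen
  active <- gap < active_tol
  contactive <- pen > 0

  ## smooth regularised Coulomb friction from an elastic anchor:
  ## |f_t| = mu*fn * tanh(kt*|slip| / (mu*fn)), which asymptotes to the
  ## Coulomb cone with a C-infinity law (no stick/slip switch in the
  ## tangent). The pseudo-potential (anchor and normal force frozen) is
  ## (mu*fn)^2/kt * log cosh(kt*|slip|/(mu*fn)).
  ft <- matrix(0, nF, 3L)
  kt_tan <- numeric(nF)
  state <- ifelse(contactive, "stick", "open")
  fric_energy <- 0
  if (pair$friction_mu > 0 && any(contactive)) {
    idx <- which(contactive)
    slip_vec <- xf[idx, , drop = FALSE] - anchors[idx, , drop = FALSE]
    ndot <- rowSums(slip_vec * nrm[idx, , drop = FALSE])
    slip_t <- slip_vec - ndot * nrm[idx, , drop = FALSE]
    slipn <- sqrt(rowSums(slip_t^2))
    fscale <- pmax(pair$friction_mu * fn_mag[idx], 1e-12)
    arg <- kt[idx] * slipn / fscale
    tanh_a <- tanh(arg)
    fmag_t <- fscale * tanh_a
    dirn <- slip_t / pmax(slipn, 1e-14)
    ftt <- -fmag_t * dirn
    ftt[slipn < 1e-14, ] <- 0
    ft[idx, ] <- ftt
    kt_tan[idx] <- kt[idx] * (1 - tanh_a^2)       # consistent secant stiffness
    fric_energy <- sum(fscale^2 / pmax(kt[idx], 1e-14) * log(cosh(pmin(arg, 30))) +
                       ifelse(arg > 30, fscale * (slipn - 30 * fscale / kt[idx]), 0))
    state[idx][tanh_a > 0.95] <- "slip"
    ## commit (between load steps): pull far anchors back to the slip edge
    if (update_anchors) {
      sy <- 2 * fscale / kt[idx]
      far <- slipn > sy
      if (any(far)) {
        keep <- sy[far] / slipn[far]
        anchors[idx[far], ] <- xf[idx[far], , drop = FALSE] -
          slip_t[far, , drop = FALSE] * keep +
          (ndot[far]) * nrm[idx[far], , drop = FALSE] * 0
      }
    }
  }
  ## reset anchors where contact lost
  if (update_anchors) {
    lost <- !contactive
    anchors[lost, ] <- pr$proj[lost, , drop = FALSE]
  }

  ffoll <- nrm * fn_mag + ft            # force on follower nodes
  N3 <- 3L * nrow(X)
  f <- numeric(N3)
  dof3 <- function(nid) rbind(3L * (nid - 1L) + 1L, 3L * (nid - 1L) + 2L, 3L * (nid - 1L) + 3L)
  idxf <- which(fn_mag > 0 | rowSums(abs(ft)) > 0)
  if (length(idxf)) {
    dd <- dof3(nf[idxf])
    f[dd] <- f[dd] + t(ffoll[idxf, , drop = FALSE])
    if (!is.null(tgt_nodes)) {
      for (c3 in 1:3) {
        nid <- tgt_nodes[idxf, c3]
        w <- pr$w[idxf, c3]
        contrib <- -ffoll[idxf, , drop = FALSE] * w
        acc <- rowsum(contrib, group = nid)
        gid <- as.integer(rownames(acc))
        for (dim in 1:3) {
          gd <- 3L * (gid - 1L) + dim
          f[gd] <- f[gd] + acc[, dim]
        }
      }
    }
  }

  ## tangent triplets for active followers (vectorised over followers):
  ## block K[(a,d1),(b,d2)] = c_a c_b S[d1,d2] with c = (1, -w1, -w2, -w3)
  ## and S = kn n n' + kt_eff (I - n n').
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  idxa <- which(active)
  if (length(idxa)) {
    na <- length(idxa)
    kt_eff <- kt_tan[idxa]
    nv <- nrm[idxa, , drop = FALSE]
    if (is.null(tgt_nodes)) {
      nmat <- matrix(nf[idxa], na, 1L)
      cmat <- matrix(1, na, 1L)
    } else {
      nmat <- cbind(nf[idxa], tgt_nodes[idxa, , drop = FALSE])
      cmat <- cbind(1, -pr$w[idxa, , drop = FALSE])
    }
    nn <- ncol(nmat)
    nblk <- (3L * nn)^2
    TI <- matrix(0L, na, nblk); TJ <- matrix(0L, na, nblk); TX <- matrix(0, na, nblk)
    col <- 0L
    for (b in seq_len(nn)) for (d2 in 1:3) for (a in seq_len(nn)) for (d1 in 1:3) {
      col <- col + 1L
      S12 <- (kn[idxa] - kt_eff) * nv[, d1] * nv[, d2] + kt_eff * (d1 == d2)
      TI[, col] <- 3L * (nmat[, a] - 1L) + d1
      TJ[, col] <- 3L * (nmat[, b] - 1L) + d2
      TX[, col] <- cmat[, a] * cmat[, b] * S12
    }
    ti <- as.integer(TI); tj <- as.integer(TJ); tx <- as.numeric(TX)
  }
  status <- data.frame(node = nf, gap = gap, pressure = fn_mag / areas,
                       state = state, stringsAsFactors = FALSE)
  total_on_target <- -colSums(ffoll)
  list(f = f, anchors = anchors, status = status,
       energy = 0.5 * sum(fn_mag * pen) + fric_energy,
       ti = ti, tj = tj, tx = tx, follower_force = ffoll,
       total_force_on_target = total_on_target)
}
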
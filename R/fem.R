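# Reduced-order static FE trunk model.
#
# The spine is a chain of 3D space-frame (beam) elements representing the
# intervertebral disks, with quasi-rigid offset beams to the pedicles and to
# the pelvis.  The torso skin is a lattice of ring nodes tied to the skeleton
# by isotropic soft-tissue springs (with a rigid-offset coupling so that skin
# loads exert moments on the vertebrae) and to each other by membrane trusses.
# Contact with the brace (a cylindrical rho(z, phi) height-field) and the
# mattress (a unilateral plane foundation) uses node-to-surface penalty
# springs, updated per load increment.  All solves are linear small-increment
# solves; every node carries 6 DOFs, with skin rotations constrained.

dof_of <- function(node, comp) (node - 1L) * 6L + comp

skew3 <- function(r) matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)

# 12x12 global stiffness of a 3D frame element (Euler-Bernoulli, no shear).
# Local x runs p1 -> p2; `ref` seeds the local y direction.
frame_stiffness <- function(p1, p2, EA, EIy, EIz, GJ, ref = c(1, 0, 0)) {
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  ex <- d / L
  if (abs(sum(ref * ex)) > 0.99) ref <- c(0, 1, 0)
  ey <- normalize(ref - sum(ref * ex) * ex)
  ez <- cross3(ex, ey)
  lam <- rbind(ex, ey, ez)

  k <- matrix(0, 12, 12)
  add <- function(i, j, v) k[i, j] <<- k[i, j] + v
  # axial (local u_x: dofs 1, 7)
  ka <- EA / L
  k[c(1, 7), c(1, 7)] <- ka * matrix(c(1, -1, -1, 1), 2)
  # torsion (local r_x: dofs 4, 10)
  kt <- GJ / L
  k[c(4, 10), c(4, 10)] <- kt * matrix(c(1, -1, -1, 1), 2)
  # bending in local x-y plane (v: 2, 8; theta_z: 6, 12), stiffness EIz
  bz <- EIz / L^3 * matrix(c(
    12, 6 * L, -12, 6 * L,
    6 * L, 4 * L^2, -6 * L, 2 * L^2,
    -12, -6 * L, 12, -6 * L,
    6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  idx <- c(2, 6, 8, 12)
  k[idx, idx] <- k[idx, idx] + bz
  # bending in local x-z plane (w: 3, 9; theta_y: 5, 11), stiffness EIy
  by <- EIy / L^3 * matrix(c(
    12, -6 * L, -12, -6 * L,
    -6 * L, 4 * L^2, 6 * L, 2 * L^2,
    -12, 6 * L, 12, 6 * L,
    -6 * L, 2 * L^2, 6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  idx <- c(3, 5, 9, 11)
  k[idx, idx] <- k[idx, idx] + by

  T <- matrix(0, 12, 12)
  for (b in 0:3) T[b * 3 + 1:3, b * 3 + 1:3] <- lam
  list(K = t(T) %*% k %*% T, lam = lam, L = L, Kloc = k, T = T)
}

#' Model stiffness and material defaults
#'
#' Stiffness constants of the reduced-order trunk model, in load-deflection
#' form (the beam section constants are derived from these and the element
#' lengths).  Defaults are at the scale reported for human spinal functional
#' units: disk axial stiffness ~1.5 kN/mm, rotational stiffness ~2 N·m/deg.
#'
#' @param disk_k_axial Disk axial stiffness, N/mm.
#' @param disk_k_rot Disk bending stiffness, N·m/deg (also used for torsion).
#' @param rigid_factor Multiplier making vertebra/pedicle/pelvis links
#'   quasi-rigid relative to disks.
#' @param tissue_k_level Total radial soft-tissue stiffness per vertebral
#'   level, N/mm (shared across the ring nodes of that level).
#' @param tissue_shear_ratio Transverse/axial stiffness ratio of the
#'   soft-tissue springs.
#' @param rib_factor Extra skin-vertebra stiffness factor at thoracic levels
#'   (ribcage rigidity).
#' @param membrane_k_ring,membrane_k_vert Skin membrane truss stiffness
#'   between phi-neighbours and between rings, N/mm.
#' @param contact_k_per_area Penalty contact stiffness density, N/mm per mm^2
#'   of tributary node area (~10 N/mm per node at default skin resolution).
#' @param mattress_E,mattress_depth Mattress foam modulus (MPa) and reference
#'   depth (mm); foundation spring k = E * area / depth.
#' @param plate_a,plate_b Endplate ellipse semi-axes (anterior, lateral), mm.
#' @param gravity_mps2 Gravitational acceleration, m/s^2.
#' @return Named list of constants.
#' @export
model_params_default <- function(disk_k_axial = 300, disk_k_rot = 2,
                                 rigid_factor = 200,
                                 tissue_k_level = 30, tissue_shear_ratio = 0.3,
                                 rib_factor = 3,
                                 membrane_k_ring = 2, membrane_k_vert = 1,
                                 contact_k_per_area = 0.008,
                                 mattress_E = 0.3, mattress_depth = 100,
                                 plate_a = 15, plate_b = 20,
                                 gravity_mps2 = 9.81) {
  as.list(environment())
}

#' Assemble the reduced-order trunk model
#'
#' Builds nodes (vertebral centroids, pedicles, skin rings, pelvis), the
#' element set, lumped vertebral masses and tributary skin areas from a
#' generated anatomy.  Disk stiffness is divided by the patient's
#' `flexibility_factor`; thoracic soft-tissue springs are stiffened by the
#' ribcage factor.
#'
#' @param anatomy A `trunk_anatomy`.
#' @param flexibility_factor Dimensionless divisor on disk stiffness
#'   (defaults to the value in `anatomy$spec`).
#' @param params Constants from [model_params_default()].
#' @return An object of class `trunk_model`.
#' @export
assemble_model <- function(anatomy,
                           flexibility_factor = anatomy$spec$flexibility_factor,
                           params = model_params_default()) {
  stopifnot(flexibility_factor > 0)
  n <- length(anatomy$levels)
  np <- anatomy$skin$n_phi
  if (np < 8) stop("degenerate skin mesh: need >= 8 nodes per ring")
  if (!all(diff(anatomy$centroids[, 3]) < 0))
    stop("vertebral z-coordinates must decrease T1 -> L5")

  nodes <- rbind(anatomy$centroids, anatomy$ped_L, anatomy$ped_R,
                 anatomy$skin$verts, matrix(anatomy$pelvis$origin, 1))
  idx_cen <- 1:n
  idx_pedL <- n + (1:n)
  idx_pedR <- 2L * n + (1:n)
  idx_skin <- matrix(3L * n + seq_len(n * np), n, np, byrow = TRUE)
  idx_pelvis <- 3L * n + n * np + 1L
  nn <- nrow(nodes)

  krot <- params$disk_k_rot * 1000 * 180 / pi   # N*m/deg -> N*mm/rad
  elements <- list()
  add <- function(e) elements[[length(elements) + 1L]] <<- e

  # intervertebral disks, caudal node first (local x points cranially)
  for (k in 1:(n - 1)) {
    L <- sqrt(sum((anatomy$centroids[k, ] - anatomy$centroids[k + 1, ])^2))
    add(list(type = "frame", role = "disk", level = k,
             n1 = idx_cen[k + 1], n2 = idx_cen[k],
             EA = params$disk_k_axial * L / flexibility_factor,
             EI = krot * L / flexibility_factor,
             GJ = krot * L / flexibility_factor))
  }
  # lumbosacral junction pelvis -> L5 (disk-like so L5's inferior plate
  # stresses can be recovered from it)
  Lp <- sqrt(sum((anatomy$centroids[n, ] - anatomy$pelvis$origin)^2))
  add(list(type = "frame", role = "disk", level = n,
           n1 = idx_pelvis, n2 = idx_cen[n],
           EA = params$disk_k_axial * Lp / flexibility_factor,
           EI = krot * Lp / flexibility_factor,
           GJ = krot * Lp / flexibility_factor))
  # quasi-rigid pedicle offsets
  for (k in 1:n) for (side in c("L", "R")) {
    tgt <- if (side == "L") idx_pedL[k] else idx_pedR[k]
    L <- sqrt(sum((nodes[tgt, ] - anatomy$centroids[k, ])^2))
    add(list(type = "frame", role = "rigid", level = k,
             n1 = idx_cen[k], n2 = tgt,
             EA = params$rigid_factor * params$disk_k_axial * L,
             EI = params$rigid_factor * krot * L,
             GJ = params$rigid_factor * krot * L))
  }
  # soft tissue: skin node <-> vertebra rigid body (attachment halfway)
  for (k in 1:n) {
    ka <- params$tissue_k_level / np *
      (if (is_thoracic(k)) params$rib_factor else 1)
    for (j in 1:np) {
      add(list(type = "tissue", level = k, n_skin = idx_skin[k, j],
               n_vert = idx_cen[k], ka = ka,
               kt = params$tissue_shear_ratio * ka))
    }
  }
  # skin membrane trusses
  for (k in 1:n) for (j in 1:np) {
    jn <- if (j == np) 1L else j + 1L
    add(list(type = "truss", n1 = idx_skin[k, j], n2 = idx_skin[k, jn],
             k = params$membrane_k_ring))
    if (k < n)
      add(list(type = "truss", n1 = idx_skin[k, j], n2 = idx_skin[k + 1, j],
               k = params$membrane_k_vert))
  }

  masses <- numeric(nn)
  masses[idx_cen] <- anatomy$spec$trunk_mass_kg / n  # per-level fractions

  # tributary skin areas: ring arc length x vertical spacing
  zc <- anatomy$centroids[, 3]
  dz <- abs(c(diff(zc)[1], diff(zc)))
  area <- matrix(0, n, np)
  for (k in 1:n) {
    a <- anatomy$skin$a_ap[k]; b <- anatomy$skin$b_lat[k]
    per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    area[k, ] <- per / np * dz[k]
  }

  structure(list(
    nodes = nodes, n_nodes = nn, ndof = 6L * nn,
    idx_cen = idx_cen, idx_pedL = idx_pedL, idx_pedR = idx_pedR,
    idx_skin = idx_skin, idx_pelvis = idx_pelvis,
    elements = elements, masses = masses, skin_area = area,
    flexibility_factor = flexibility_factor,
    params = params, anatomy = anatomy,
    muscle_forces = NULL, calibrated = FALSE
  ), class = "trunk_model")
}

# Stiffness triplets of the full element set at the model's current
# (zero-stress) geometry.
model_triplets <- function(model) {
  X <- model$nodes
  cap <- length(model$elements) * 144L
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap)
  pos <- 0L
  put <- function(dofs, K) {
    m <- length(dofs)
    ii <- rep(dofs, times = m)
    jj <- rep(dofs, each = m)
    nz <- K != 0
    nadd <- sum(nz)
    if (pos + nadd > length(ti)) {
      ti <<- c(ti, integer(nadd + 1000L)); tj <<- c(tj, integer(nadd + 1000L))
      tx <<- c(tx, numeric(nadd + 1000L))
    }
    rng <- pos + seq_len(nadd)
    ti[rng] <<- ii[nz]; tj[rng] <<- jj[nz]; tx[rng] <<- as.vector(K)[nz]
    pos <<- pos + nadd
  }
  for (e in model$elements) {
    if (e$type == "frame") {
      fs <- frame_stiffness(X[e$n1, ], X[e$n2, ], e$EA, e$EI, e$EI, e$GJ)
      put(c(dof_of(e$n1, 1:6), dof_of(e$n2, 1:6)), fs$K)
    } else if (e$type == "truss") {
      d <- X[e$n2, ] - X[e$n1, ]
      dn <- normalize(d)
      S <- e$k * (dn %o% dn)
      K <- rbind(cbind(S, -S), cbind(-S, S))
      put(c(dof_of(e$n1, 1:3), dof_of(e$n2, 1:3)), K)
    } else if (e$type == "tissue") {
      ps <- X[e$n_skin, ]; pv <- X[e$n_vert, ]
      att <- pv + 0.5 * (ps - pv)
      r <- att - pv
      d <- normalize(ps - att)
      S <- e$ka * (d %o% d) + e$kt * (diag(3) - d %o% d)
      B <- cbind(diag(3), -diag(3), skew3(r))   # (u_skin, u_vert, theta_vert)
      K <- t(B) %*% S %*% B
      put(c(dof_of(e$n_skin, 1:3), dof_of(e$n_vert, 1:3), dof_of(e$n_vert, 4:6)),
          K)
    }
  }
  list(i = ti[seq_len(pos)], j = tj[seq_len(pos)], x = tx[seq_len(pos)])
}

model_stiffness <- function(model, extra = NULL) {
  tr <- model$base_triplets
  if (is.null(tr)) tr <- model_triplets(model)
  if (!is.null(extra)) {
    tr$i <- c(tr$i, extra$i); tr$j <- c(tr$j, extra$j); tr$x <- c(tr$x, extra$x)
  }
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(model$ndof, model$ndof))
}

# cache base triplets on the model (call after any geometry change)
cache_stiffness <- function(model) {
  model$base_triplets <- model_triplets(model)
  model
}

# default constraints: skin nodes carry no rotational stiffness
skin_rot_dofs <- function(model) {
  sk <- as.vector(model$idx_skin)
  as.vector(vapply(sk, function(nd) dof_of(nd, 4:6), integer(3)))
}

#' Define a load case
#'
#' @param forces Matrix `n_nodes x 3` of nodal forces (N), or `NULL`.
#' @param gravity Gravity vector (unit direction scaled by g is formed
#'   internally from `model$masses`), e.g. `c(0, 0, -1)` standing,
#'   `c(-1, 0, 0)` supine; `NULL` for no gravity.
#' @param fixed Data frame with columns `node`, `comp` (1:6), `value` (mm or
#'   rad) of prescribed DOFs.
#' @param contacts List of contact surfaces (see [contact_plane()],
#'   [contact_brace()]).
#' @return A `load_case` list.
#' @export
load_case <- function(forces = NULL, gravity = NULL, fixed = NULL,
                      contacts = list()) {
  if (!is.null(fixed) && nrow(fixed)) {
    key <- paste(fixed$node, fixed$comp)
    if (anyDuplicated(key)) stop("DOF constrained twice in load case")
  }
  structure(list(forces = forces, gravity = gravity, fixed = fixed,
                 contacts = contacts), class = "load_case")
}

#' Unilateral plane foundation (mattress) contact
#'
#' @param point A point on the plane (mm).
#' @param normal Outward normal (into the allowed half-space).
#' @param nodes Node indices checked against the plane.
#' @param k_per_area Penalty stiffness density N/mm/mm^2; multiplied by each
#'   node's tributary area.
#' @param areas Tributary areas (mm^2) aligned with `nodes`.
#' @return Contact descriptor.
#' @export
contact_plane <- function(point, normal, nodes, k_per_area, areas) {
  list(type = "plane", point = point, normal = normalize(normal),
       nodes = nodes, k = k_per_area * areas, areas = areas)
}

#' Brace surface contact (cylindrical height-field)
#'
#' @param rho_fun Function `(z, phi) -> rho` of the brace inner surface (mm),
#'   `NA` where the brace has been trimmed or opened.
#' @param axis `c(x0, y0)` of the vertical cylindrical axis.
#' @param nodes Skin node indices.
#' @param k_per_area Penalty stiffness density N/mm/mm^2.
#' @param areas Tributary areas (mm^2).
#' @return Contact descriptor.
#' @export
contact_brace <- function(rho_fun, axis, nodes, k_per_area, areas) {
  list(type = "brace", rho_fun = rho_fun, axis = axis, nodes = nodes,
       k = k_per_area * areas, areas = areas)
}

# gap (negative = penetration), outward normal and stiffness weight (shell
# edges fade out) for each contact node
contact_gaps <- function(contact, pos) {
  if (contact$type == "plane") {
    g <- as.vector((pos - matrix(contact$point, nrow(pos), 3, byrow = TRUE)) %*%
                     contact$normal)
    nrm <- matrix(contact$normal, nrow(pos), 3, byrow = TRUE)
    w <- rep(1, nrow(pos))
  } else {
    dx <- pos[, 1] - contact$axis[1]
    dy <- pos[, 2] - contact$axis[2]
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dy, dx)
    res <- contact$rho_fun(pos[, 3], phi)
    rb <- res$rho
    w <- res$w
    g <- rb - rho                       # inside the brace when positive
    g[is.na(g)] <- Inf
    nrm <- cbind(-dx / rho, -dy / rho, 0)  # inward push when penetrating
  }
  list(gap = g, normal = nrm, w = w)
}

#' Solve a static load case
#'
#' Loads (and prescribed displacements) are applied in linear increments; at
#' each increment the penalty contact set is relinearized at the current
#' configuration and iterated until the displacement field is self-consistent.
#'
#' @param model A `trunk_model`.
#' @param load A `load_case`.
#' @param increments Number of load increments.
#' @param donning_ramp If `TRUE`, brace contact surfaces are inflated by the
#'   initial interference and shrunk to their true position across the
#'   increments (smooth brace donning).
#' @param max_contact_iter Inner relinearization iterations per increment.
#' @param tol Relative residual tolerance.
#' @return A `solved_state`: displacements `u`, final `positions`, rotations,
#'   per-contact nodal forces, `residual_norm`, convergence diagnostics.
#' @export
solve_static <- function(model, load, increments = 10, donning_ramp = TRUE,
                         max_contact_iter = 25, tol = 1e-6) {
  ndof <- model$ndof
  f_ext <- numeric(ndof)
  if (!is.null(load$forces)) {
    for (c_ in 1:3) f_ext[dof_of(seq_len(model$n_nodes), c_)] <-
        f_ext[dof_of(seq_len(model$n_nodes), c_)] + load$forces[, c_]
  }
  if (!is.null(load$gravity)) {
    gv <- load$gravity * model$params$gravity_mps2
    for (c_ in 1:3) f_ext[dof_of(seq_len(model$n_nodes), c_)] <-
        f_ext[dof_of(seq_len(model$n_nodes), c_)] + model$masses * gv[c_]
  }

  fixed_idx <- skin_rot_dofs(model)
  fixed_val <- numeric(length(fixed_idx))
  if (!is.null(load$fixed) && nrow(load$fixed)) {
    fi <- dof_of(load$fixed$node, load$fixed$comp)
    keep <- !(fi %in% fixed_idx)
    fixed_idx <- c(fixed_idx, fi[keep])
    fixed_val <- c(fixed_val, load$fixed$value[keep])
  }
  free <- setdiff(seq_len(ndof), fixed_idx)

  K0 <- model_stiffness(model)
  u <- numeric(ndof)
  X0 <- model$nodes
  n_nodes <- model$n_nodes

  # initial interference per brace contact, for the donning ramp
  donning <- vapply(load$contacts, function(ct) {
    if (ct$type != "brace" || !donning_ramp) return(0)
    g <- contact_gaps(ct, X0[ct$nodes, , drop = FALSE])$gap
    max(0, -min(g[is.finite(g)], Inf))
  }, numeric(1))

  trans_of <- function(uv) {
    matrix(uv, ncol = 6, byrow = TRUE)[, 1:3, drop = FALSE]
  }

  contact_iters <- 0L
  for (inc in seq_len(increments)) {
    t_i <- inc / increments
    fv <- fixed_val * t_i
    omega <- 1
    dchg_prev <- Inf
    act_prev <- NULL
    for (it in seq_len(max_contact_iter)) {
      pos <- X0 + trans_of(u)
      extra <- list(i = integer(0), j = integer(0), x = numeric(0))
      f_c <- numeric(ndof)
      act_sig <- integer(0)
      for (ci in seq_along(load$contacts)) {
        ct <- load$contacts[[ci]]
        cg <- contact_gaps(ct, pos[ct$nodes, , drop = FALSE])
        g_eff <- cg$gap + donning[ci] * (1 - t_i)
        act <- which(is.finite(g_eff) & g_eff < 0)
        act_sig <- c(act_sig, ci * 100000L + act)
        for (aidx in act) {
          nd <- ct$nodes[aidx]
          nrm <- cg$normal[aidx, ]
          kc <- ct$k[aidx] * cg$w[aidx]
          dofs <- dof_of(nd, 1:3)
          Kc <- kc * (nrm %o% nrm)
          extra$i <- c(extra$i, rep(dofs, 3))
          extra$j <- c(extra$j, rep(dofs, each = 3))
          extra$x <- c(extra$x, as.vector(Kc))
          # restoring force at the current u: k * (-gap) along the stored
          # normal (which is oriented to push the node back to the surface)
          f_lin <- -kc * g_eff[aidx] * nrm
          f_c[dofs] <- f_c[dofs] + f_lin + as.vector(Kc %*% u[dofs])
        }
      }
      K <- model_stiffness(model, if (length(extra$i)) extra else NULL)
      rhs <- t_i * f_ext + f_c
      u_new <- u
      u_new[fixed_idx] <- fv
      b <- rhs[free] - as.vector(K[free, fixed_idx, drop = FALSE] %*% fv)
      # sparse Cholesky for the (frequent) contact iterations; LU for the
      # contact-free calibration solves, where its better accuracy on this
      # ill-conditioned system preserves the model's exact symmetries
      u_new[free] <- if (length(load$contacts))
        as.vector(Matrix::solve(Matrix::forceSymmetric(K[free, free]), b))
      else as.vector(Matrix::solve(K[free, free], b))
      dchg <- max(abs(u_new - u))
      # adaptive under-relaxation damps active-set limit cycles
      if (dchg > dchg_prev) omega <- max(omega / 2, 0.1)
      else omega <- min(1, omega * 1.25)
      u <- u + omega * (u_new - u)
      u[fixed_idx] <- fv
      dchg_prev <- dchg
      contact_iters <- contact_iters + 1L
      same_set <- identical(act_sig, act_prev)
      act_prev <- act_sig
      if (dchg * omega < 1e-6 * max(1, max(abs(u)))) break
      if (same_set && omega == 1 && dchg < 3e-4 * max(1, max(abs(u)))) {
        # stable active set and a consistent linearization: take the exact
        # solution of the linearized system and stop
        u <- u_new
        u[fixed_idx] <- fv
        break
      }
    }
  }

  # final contact forces and residual at the converged configuration
  pos <- X0 + trans_of(u)
  f_contact <- matrix(0, n_nodes, 3)
  pressures <- vector("list", length(load$contacts))
  for (ci in seq_along(load$contacts)) {
    ct <- load$contacts[[ci]]
    cg <- contact_gaps(ct, pos[ct$nodes, , drop = FALSE])
    pen <- pmax(0, -ifelse(is.finite(cg$gap), cg$gap, Inf))
    fmag <- ct$k * cg$w * pen
    f_contact[ct$nodes, ] <- f_contact[ct$nodes, ] + cg$normal * fmag
    pressures[[ci]] <- fmag / ct$areas * 1000   # N/mm^2 -> kPa
  }
  f_c_vec <- numeric(ndof)
  for (c_ in 1:3) f_c_vec[dof_of(seq_len(n_nodes), c_)] <- f_contact[, c_]
  r <- as.vector(K0 %*% u) - f_ext - f_c_vec
  load_norm <- max(sqrt(sum((f_ext + f_c_vec)^2)), 1e-9)
  res <- sqrt(sum(r[free]^2))

  structure(list(
    u = u, positions = pos, rotations = matrix(u, ncol = 6, byrow = TRUE)[, 4:6],
    f_contact = f_contact, contact_pressures_kpa = pressures,
    residual_norm = res, residual_rel = res / load_norm,
    contact_iterations = contact_iters, load = load
  ), class = "solved_state")
}

#' Nodal contact pressures of a solved state
#'
#' Penalty normal force divided by tributary node area, in kPa; zero for
#' non-contacting nodes.
#'
#' @param state A `solved_state` from [solve_static()].
#' @param contact_index Which contact surface of the load case (default: the
#'   brace surface if present, else the first).
#' @return Numeric vector of pressures (kPa), one per contact node.
#' @export
contact_pressures <- function(state, contact_index = NULL) {
  cts <- state$load$contacts
  if (!length(cts)) stop("state was solved without contact surfaces")
  if (is.null(contact_index)) {
    contact_index <- which(vapply(cts, function(ct) ct$type == "brace",
                                  logical(1)))[1]
    if (is.na(contact_index)) contact_index <- 1L
  }
  state$contact_pressures_kpa[[contact_index]]
}

# chord engineering strain of every two-node element
element_strains <- function(model, state) {
  X <- model$nodes
  P <- state$positions
  vapply(model$elements, function(e) {
    nn <- if (e$type == "tissue") c(e$n_skin, e$n_vert) else c(e$n1, e$n2)
    L0 <- sqrt(sum((X[nn[2], ] - X[nn[1], ])^2))
    L1 <- sqrt(sum((P[nn[2], ] - P[nn[1], ])^2))
    abs(L1 - L0) / L0
  }, numeric(1))
}

# Internal disk end forces -> left/right average compressive stresses on each
# growth plate of T2..L5 (superior & inferior), via sigma = N/A +/- M*c/I on
# an elliptical endplate section.  Compression is negative.
plate_stress_field <- function(model, state) {
  pr <- model$params
  hscale <- model$anatomy$spec$trunk_height_mm / 460
  a <- pr$plate_a * hscale; b <- pr$plate_b * hscale
  A <- pi * a * b
  I <- pi * a * b^3 / 4                 # about the anterior axis
  disk_sig <- list()
  for (e in model$elements) {
    if (e$type != "frame" || e$role != "disk") next
    fs <- frame_stiffness(model$nodes[e$n1, ], model$nodes[e$n2, ],
                          e$EA, e$EI, e$EI, e$GJ)
    ue <- c(state$u[dof_of(e$n1, 1:6)], state$u[dof_of(e$n2, 1:6)])
    floc <- fs$Kloc %*% (fs$T %*% ue)
    N <- floc[7]                        # axial at cranial end, tension +
    # coronal bending: moment about the local axis closest to global x
    m_loc <- floc[10:12]
    m_glob <- as.vector(t(fs$lam) %*% m_loc)
    M_cor <- m_glob[1]                  # about the anterior (x) axis
    sL <- (N / A + M_cor * b / I)
    sR <- (N / A - M_cor * b / I)
    disk_sig[[as.character(e$level)]] <- c(L = sL, R = sR)
  }
  lv <- model$anatomy$levels
  n <- length(lv)
  rows <- list()
  for (k in 2:n) {
    sup <- disk_sig[[as.character(k - 1)]]   # disk above vertebra k
    inf <- disk_sig[[as.character(k)]]       # disk below (or lumbosacral)
    rows[[length(rows) + 1]] <- data.frame(
      level = lv[k], plate = "superior", sigma_L = sup["L"], sigma_R = sup["R"])
    rows[[length(rows) + 1]] <- data.frame(
      level = lv[k], plate = "inferior", sigma_L = inf["L"], sigma_R = inf["R"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$sigma_m <- (out$sigma_L + out$sigma_R) / 2
  class(out) <- c("plate_stress_field", "data.frame")
  out
}

#' Calibrate the standing model against the presenting anatomy
#'
#' Finds the zero-stress (weightless) node positions and the stabilizing
#' muscle forces (antero-posterior and lateral, at T6, T10 and L3) such that
#' solving the model under gravity plus those forces reproduces the presenting
#' standing spine.  Muscle forces are fitted by bounded least squares on the
#' vertebral centroid displacements; the zero-stress state follows by
#' reverse-gravity fixed-point updates.
#'
#' @param model A `trunk_model` (zero-stress state initialized at the
#'   presenting anatomy).
#' @param target_positions Node positions to reproduce under load (defaults to
#'   the anatomy-derived positions).
#' @param tol_rms_mm Convergence tolerance on vertebral centroid RMS error.
#' @param max_iter Maximum fixed-point iterations.
#' @param muscle_bound_N Force bound per muscle component.
#' @return The calibrated `trunk_model` (fields `muscle_forces`, `calibrated`,
#'   `calibration_rms_mm`, `target_positions`).
#' @export
calibrate_standing <- function(model, target_positions = model$nodes,
                               tol_rms_mm = 2, max_iter = 50,
                               muscle_bound_N = 200) {
  mus_lv <- level_index(c("T6", "T10", "L3"))
  mus_nodes <- model$idx_cen[mus_lv]
  cen_dofs <- as.vector(vapply(model$idx_cen, function(nd) dof_of(nd, 1:3),
                               integer(3)))
  fixed <- data.frame(node = model$idx_pelvis, comp = 1:6, value = 0)
  no_gravity <- all(model$masses == 0)

  m <- numeric(6)
  D <- NULL
  for (iter in seq_len(max_iter)) {
    model <- cache_stiffness(model)
    base <- load_case(gravity = c(0, 0, -1), fixed = fixed)
    st_g <- solve_static(model, base, increments = 1)
    d_g <- st_g$u[cen_dofs]
    if (!no_gravity) {
      # influence of unit muscle forces on centroid displacements; the
      # geometry updates between iterations are small, so the matrix from
      # the first pass is reused
      if (is.null(D)) {
        D <- matrix(0, length(cen_dofs), 6)
        col <- 0
        for (nd in mus_nodes) for (cmp in 1:2) {
          col <- col + 1
          fm <- matrix(0, model$n_nodes, 3)
          fm[nd, cmp] <- 1
          stm <- solve_static(model, load_case(forces = fm, fixed = fixed),
                              increments = 1)
          D[, col] <- stm$u[cen_dofs]
        }
      }
      m_ls <- as.vector(qr.solve(D, -d_g))
      if (all(abs(m_ls) <= muscle_bound_N)) {
        m <- m_ls
      } else {
        qfun <- function(mm) sum((d_g + D %*% mm)^2)
        gfun <- function(mm) as.vector(2 * t(D) %*% (d_g + D %*% mm))
        opt <- stats::optim(pmin(pmax(m_ls, -muscle_bound_N), muscle_bound_N),
                            qfun, gfun, method = "L-BFGS-B",
                            lower = -muscle_bound_N, upper = muscle_bound_N,
                            control = list(factr = 1e4))
        m <- opt$par
      }
    }
    fm <- matrix(0, model$n_nodes, 3)
    col <- 0
    for (nd in mus_nodes) for (cmp in 1:2) {
      col <- col + 1
      fm[nd, cmp] <- m[col]
    }
    st <- solve_static(model, load_case(forces = fm, gravity = c(0, 0, -1),
                                        fixed = fixed), increments = 1)
    err <- target_positions - st$positions
    # reverse-gravity update of the zero-stress state
    model$nodes <- model$nodes + err
    model$base_triplets <- NULL
    cen_err <- err[model$idx_cen, , drop = FALSE]
    rms <- sqrt(mean(rowSums(cen_err^2)))
    if (rms <= tol_rms_mm * 0.25 || (iter > 2 && rms <= tol_rms_mm)) break
  }
  if (rms > tol_rms_mm)
    stop(sprintf("standing calibration did not converge (RMS %.2f mm)", rms))
  model <- cache_stiffness(model)
  model$muscle_forces <- data.frame(
    level = rep(c("T6", "T10", "L3"), each = 2),
    component = rep(c("x", "y"), 3), force_N = m)
  model$calibrated <- TRUE
  model$calibration_rms_mm <- rms
  model$target_positions <- target_positions
  model
}
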
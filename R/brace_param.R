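# Design space of the optimization: a cylindrical 6 x 6 patch grid over the
# brace surface, per-patch radial (rho) offsets bounded at +/- 25 mm, Gaussian
# smoothing of the resulting rho(z, phi) field, a 20-degree frontal opening,
# and automatic strap placement.

#' Build the cylindrical patch grid over a brace point cloud
#'
#' The grid axis is the vertical line through the point-cloud centroid;
#' `phi = 0` is the anterior (+x) direction.  Bin edges are uniform in z
#' between the retained points' extremes and uniform in phi over
#' `[-pi, pi)`.  Patches are indexed patch-major: z slow, phi fast
#' (patch 1 = lowest z band, first phi sector).
#'
#' @param brace Either a `brace_points` object or an `n x 3` point matrix.
#' @param nz,nphi Grid dimensions (default 6 x 6 = 36 patches).
#' @return A `patch_grid` with `z_edges`, `phi_edges`, `axis`, and
#'   `patch_index(points)`.
#' @export
build_patch_grid <- function(brace, nz = 6L, nphi = 6L) {
  pts <- if (inherits(brace, "brace_points")) brace_xyz(brace) else as.matrix(brace)
  if (nrow(pts) < 4) stop("degenerate point cloud")
  axis <- c(mean(pts[, 1]), mean(pts[, 2]))
  if (inherits(brace, "brace_points")) axis <- brace$axis
  zr <- range(pts[, 3])
  if (diff(zr) <= 0) stop("degenerate point cloud: zero z extent")
  z_edges <- seq(zr[1], zr[2], length.out = nz + 1)
  phi_edges <- seq(-pi, pi, length.out = nphi + 1)
  grid <- structure(list(axis = axis, nz = nz, nphi = nphi,
                         z_edges = z_edges, phi_edges = phi_edges),
                    class = "patch_grid")
  grid$patch_index <- function(points) {
    p <- as.matrix(points)
    phi <- atan2(p[, 2] - axis[2], p[, 1] - axis[1])
    iz <- pmin(pmax(findInterval(p[, 3], z_edges, rightmost.closed = TRUE), 1L), nz)
    ip <- pmin(pmax(findInterval(phi, phi_edges, rightmost.closed = TRUE), 1L), nphi)
    (iz - 1L) * nphi + ip
  }
  grid
}

#' Validate a rho-offset vector
#'
#' @param rho Numeric vector of per-patch radial offsets, mm.
#' @param grid The `patch_grid` it applies to.
#' @param bound Admissible magnitude, mm.
#' @return `rho`, invisibly, or an error.
#' @export
validate_rho <- function(rho, grid, bound = 25) {
  if (length(rho) != grid$nz * grid$nphi)
    stop("rho offset vector must have length ", grid$nz * grid$nphi)
  if (any(!is.finite(rho)) || any(abs(rho) > bound + 1e-9))
    stop("rho offsets must lie within [-", bound, ", +", bound, "] mm")
  invisible(rho)
}

#' Apply per-patch radial offsets to brace points
#'
#' Each retained point's radial coordinate is changed by its patch's offset;
#' z and phi are untouched.  Negative offsets move the patch toward the axis
#' (pressure area), positive away (relief area).
#'
#' @param brace A `brace_points` object.
#' @param grid A `patch_grid` over it.
#' @param rho Offset vector (patch-major: z slow, phi fast), mm.
#' @param bound Validation bound, mm.
#' @return The displaced `brace_points`.
#' @export
apply_offsets <- function(brace, grid, rho, bound = 25) {
  validate_rho(rho, grid, bound)
  pidx <- grid$patch_index(cbind(brace$verts[, 1], brace$verts[, 2], brace$z))
  out <- brace
  out$rho <- brace$rho + rho[pidx]
  out
}

#' Precompute the Gaussian smoothing operator for a brace lattice
#'
#' Smoothing acts on the polar height-field rho(z, phi) of the retained
#' points; the kernel is separable Gaussian in z and (wrapped) phi with
#' standard deviations of half a patch width by default.  Because the
#' points' (z, phi) sites do not move during optimization, the row-normalized
#' weight matrix can be reused across iterations.
#'
#' @param brace A `brace_points` object.
#' @param grid The `patch_grid` (sets the default bandwidths).
#' @param sigma_z,sigma_phi Kernel bandwidths (mm, rad).
#' @return A dense weight matrix over the retained points.
#' @export
smoothing_operator <- function(brace, grid,
                               sigma_z = diff(range(grid$z_edges)) / (2 * grid$nz),
                               sigma_phi = pi / grid$nphi) {
  z <- brace$z[brace$keep]
  ph <- brace$phi[brace$keep]
  dz <- outer(z, z, "-")
  dphi <- abs(outer(ph, ph, "-"))
  dphi <- pmin(dphi, 2 * pi - dphi)
  W <- exp(-0.5 * (dz / sigma_z)^2 - 0.5 * (dphi / sigma_phi)^2)
  W / rowSums(W)
}

#' Finalize a brace shape: smooth, open, strap
#'
#' Fuses the offset patches by Gaussian smoothing of the rho field, removes
#' the points falling in the frontal opening arc (default 20 degrees centered
#' on the anterior axis), and places the closure straps by picking the points
#' on each side of the opening closest to the proportional normalized heights
#' (`c(0.33, 0.66)` for 2 straps, `c(0.25, 0.5, 0.75)` for 3; 3 straps when
#' the brace spans more than 350 mm).
#'
#' @param brace Displaced `brace_points` (after [apply_offsets()]).
#' @param grid The `patch_grid`.
#' @param smoother Optional precomputed [smoothing_operator()] matrix.
#' @param opening_deg Full frontal opening arc, degrees.
#' @param n_straps 2, 3, or `NULL` to apply the height rule.
#' @param strap_tension_N Tension per strap, N.
#' @param thickness_mm,E_MPa,nu Shell properties carried as metadata
#'   (high-density polyethylene, 4 mm).
#' @return A `brace_shape`: final points, rho surface interpolator
#'   (`rho_fun(z, phi)` returning `list(rho =, w =)` with `rho = NA` and
#'   weight 0 off the shell, the weight fading at trim/opening edges),
#'   strap anchors and tension, opening arc, and material metadata.
#' @export
finalize_brace <- function(brace, grid, smoother = NULL, opening_deg = 20,
                           n_straps = NULL, strap_tension_N = 60,
                           thickness_mm = 4, E_MPa = 1000, nu = 0.4) {
  keep <- brace$keep
  if (is.null(smoother)) smoother <- smoothing_operator(brace, grid)
  rho_s <- as.vector(smoother %*% brace$rho[keep])
  rho_full <- brace$rho
  rho_full[keep] <- rho_s

  half <- deg2rad(opening_deg / 2)
  open_mask <- abs(brace$phi) < half
  final_keep <- keep & !open_mask
  if (!any(final_keep)) stop("empty shell: opening removed every brace point")

  zr <- range(brace$z[final_keep])
  if (is.null(n_straps)) n_straps <- if (diff(zr) > 350) 3L else 2L
  hts <- if (n_straps == 3L) c(0.25, 0.5, 0.75) else c(0.33, 0.66)
  z_t <- zr[1] + hts * diff(zr)
  pick_side <- function(side) {
    # points bordering the opening on one side
    cand <- which(final_keep & sign(brace$phi) == side &
                    abs(brace$phi) < half + 2 * pi / brace$n_phi * 1.5)
    if (!length(cand)) cand <- which(final_keep & sign(brace$phi) == side)
    vapply(z_t, function(zt) cand[which.min(abs(brace$z[cand] - zt))], integer(1))
  }
  iL <- pick_side(+1)
  iR <- pick_side(-1)
  xyz <- cbind(brace$axis[1] + rho_full * cos(brace$phi),
               brace$axis[2] + rho_full * sin(brace$phi), brace$z)
  straps <- data.frame(
    strap = seq_len(n_straps), target_height = z_t,
    left_x = xyz[iL, 1], left_y = xyz[iL, 2], left_z = xyz[iL, 3],
    right_x = xyz[iR, 1], right_y = xyz[iR, 2], right_z = xyz[iR, 3],
    tension_N = strap_tension_N)

  out <- brace
  out$rho <- rho_full
  out$keep <- final_keep
  shape <- structure(list(
    points = out, axis = brace$axis,
    straps = straps, opening_deg = opening_deg,
    thickness_mm = thickness_mm, E_MPa = E_MPa, nu = nu,
    rho_fun = brace_rho_fun(out)
  ), class = "brace_shape")
  shape
}

# Bilinear interpolator of the brace inner surface over the (ring-z, phi)
# lattice; NA outside the retained shell (trim or opening).
brace_rho_fun <- function(bp) {
  nr <- bp$n_ring; np <- bp$n_phi
  rho_m <- matrix(NA_real_, nr, np)
  z_ring <- numeric(nr)
  phi_g <- numeric(np)
  for (k in seq_len(nr)) {
    sel <- bp$ring == k
    z_ring[k] <- mean(bp$z[sel])
  }
  for (j in seq_len(np)) {
    sel <- bp$phi_idx == j
    phi_g[j] <- mean(bp$phi[sel])      # rings share the phi lattice
  }
  idx <- cbind(bp$ring, bp$phi_idx)
  rho_m[idx[bp$keep, , drop = FALSE]] <- bp$rho[bp$keep]
  ordp <- order(phi_g)
  phi_g <- phi_g[ordp]
  rho_m <- rho_m[, ordp, drop = FALSE]
  ordz <- order(z_ring)
  z_ring <- z_ring[ordz]
  rho_m <- rho_m[ordz, , drop = FALSE]

  function(z, phi) {
    n <- length(z)
    iz <- findInterval(z, z_ring)
    out <- rep(NA_real_, n)
    inside <- iz >= 1 & iz < length(z_ring)
    if (!any(inside)) return(list(rho = out, w = numeric(n)))
    iz1 <- iz[inside]; iz2 <- iz1 + 1L
    tz <- (z[inside] - z_ring[iz1]) / (z_ring[iz2] - z_ring[iz1])
    ph <- phi[inside]
    jp <- findInterval(ph, phi_g)
    j1 <- ifelse(jp < 1, length(phi_g), jp)       # wrap below first center
    j2 <- ifelse(j1 == length(phi_g), 1L, j1 + 1L)
    p1 <- phi_g[j1]
    dph <- (phi_g[j2] - p1) %% (2 * pi)
    tp <- ((ph - p1) %% (2 * pi)) / ifelse(dph == 0, 1, dph)
    v11 <- rho_m[cbind(iz1, j1)]; v12 <- rho_m[cbind(iz1, j2)]
    v21 <- rho_m[cbind(iz2, j1)]; v22 <- rho_m[cbind(iz2, j2)]
    w11 <- (1 - tz) * (1 - tp); w12 <- (1 - tz) * tp
    w21 <- tz * (1 - tp); w22 <- tz * tp
    # partial cells at trim/opening edges: renormalize over present corners
    # and fade the shell out with coverage, so the contact force is
    # continuous across the edge (no active-set chattering there)
    W <- cbind(w11, w12, w21, w22)
    Vm <- cbind(v11, v12, v21, v22)
    W[is.na(Vm)] <- 0
    sw <- rowSums(W)
    val <- ifelse(sw > 0.25, rowSums(W * Vm, na.rm = TRUE) / pmax(sw, 1e-12),
                  NA_real_)
    out[inside] <- val
    wout <- numeric(n)
    wout[inside] <- pmin(1, pmax(0, (sw - 0.25) / 0.5))
    list(rho = out, w = wout)
  }
}

#' Convert a brace shape or point lattice to a triangle mesh
#'
#' @param shape A `brace_shape` or `brace_points`.
#' @return List with `vertices` and `triangles` (retained lattice cells only).
#' @export
brace_mesh <- function(shape) {
  bp <- if (inherits(shape, "brace_shape")) shape$points else shape
  xyz <- cbind(bp$axis[1] + bp$rho * cos(bp$phi),
               bp$axis[2] + bp$rho * sin(bp$phi), bp$z)
  nr <- bp$n_ring; np <- bp$n_phi
  keep_m <- matrix(FALSE, nr, np)
  keep_m[cbind(bp$ring, bp$phi_idx)] <- bp$keep
  tris <- list()
  vid <- function(k, j) (k - 1L) * np + j
  for (k in seq_len(nr - 1)) for (j in seq_len(np)) {
    jn <- if (j == np) 1L else j + 1L
    if (keep_m[k, j] && keep_m[k, jn] && keep_m[k + 1, j] && keep_m[k + 1, jn]) {
      tris[[length(tris) + 1]] <- rbind(
        c(vid(k, j), vid(k + 1, j), vid(k, jn)),
        c(vid(k, jn), vid(k + 1, j), vid(k + 1, jn)))
    }
  }
  list(vertices = xyz,
       triangles = if (length(tris)) do.call(rbind, tris) else
         matrix(0L, 0, 3))
}
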
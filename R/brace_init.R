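# Initial over-corrected brace: pedicle mirroring about the sagittal plane,
# stepwise search for the maximal admissible over-correction weight, and
# extraction/trimming of the deformed skin.

#' Pedicle mirroring displacements
#'
#' Displacements that mirror the left/right pedicle coordinates of vertebrae
#' T2-L4 about the sagittal plane, scaled by the over-correction weight `W`:
#' `u_xL = W (x_R - x_L)`, `u_xR = W (x_L - x_R)`, `u_yL = -W (y_R + y_L)`,
#' `u_yR = -W (y_L + y_R)`, `u_zL = W (z_R - z_L)`, `u_zR = W (z_L - z_R)`.
#' `W = 0` leaves the spine unchanged, `W = 0.5` aligns it onto the sagittal
#' plane, `W = 1` inverts the deformity.
#'
#' @param anatomy A `trunk_anatomy`.
#' @param W Over-correction weight in \[0, 1\].
#' @return Data frame with one row per pedicle of T2-L4: `level`, `side`,
#'   `ux`, `uy`, `uz` (mm).
#' @export
mirror_displacements <- function(anatomy, W) {
  stopifnot(W >= 0, W <= 1)
  ks <- level_index("T2"):level_index("L4")
  L <- anatomy$ped_L[ks, , drop = FALSE]
  R <- anatomy$ped_R[ks, , drop = FALSE]
  out <- rbind(
    data.frame(level = anatomy$levels[ks], side = "L",
               ux = W * (R[, 1] - L[, 1]),
               uy = -W * (R[, 2] + L[, 2]),
               uz = W * (R[, 3] - L[, 3])),
    data.frame(level = anatomy$levels[ks], side = "R",
               ux = W * (L[, 1] - R[, 1]),
               uy = -W * (L[, 2] + R[, 2]),
               uz = W * (L[, 3] - R[, 3]))
  )
  rownames(out) <- NULL
  out
}

#' Find the maximal admissible over-correction
#'
#' Increases the over-correction weight `W` from 0 to 1 in steps of 0.1,
#' each time solving the model with the mirroring displacements imposed on
#' the T2-L4 pedicles (T1 centered over the superior endplate of L5 with its
#' x and y translations then fixed; pelvis fully fixed).  The search stops at
#' the last `W` whose solution keeps every element's chord strain below the
#' distortion threshold, and returns the deformed skin at that weight.
#'
#' @param model A `trunk_model` (calibrated or raw; the zero-stress geometry
#'   is used).
#' @param distortion_threshold Maximum admissible element engineering strain.
#' @param increments Load increments per solve.
#' @return An `overcorrection_result`: `W_max`, `deformed_skin` (point matrix
#'   plus ring structure and mesh), per-step `distortion` table, and the
#'   solved state at `W_max`.
#' @export
find_max_overcorrection <- function(model, distortion_threshold = 0.4,
                                    increments = 5) {
  anatomy <- model$anatomy
  n <- length(anatomy$levels)
  # the mirroring displacements are defined on the presenting geometry, so
  # the search runs on a model whose zero-stress state IS that geometry
  # (a calibrated model's zero-stress state is the weightless one)
  if (isTRUE(model$calibrated))
    model <- assemble_model(anatomy, model$flexibility_factor, model$params)
  model <- cache_stiffness(model)
  # center T1 over the superior endplate centroid of L5
  l5_sup <- anatomy$centroids[n, ] +
    anatomy$frames[[n]][, 3] * anatomy$body_height_mm[n] / 2
  t1_shift <- l5_sup[1:2] - anatomy$centroids[1, 1:2]

  ks <- level_index("T2"):level_index("L4")
  best <- NULL
  best_W <- 0
  steps <- list()
  for (W in seq(0, 1, by = 0.1)) {
    md <- mirror_displacements(anatomy, W)
    fixed <- data.frame(node = model$idx_pelvis, comp = 1:6, value = 0)
    fixed <- rbind(fixed, data.frame(node = 1L, comp = 1:2, value = t1_shift))
    for (side in c("L", "R")) {
      nodes <- if (side == "L") model$idx_pedL[ks] else model$idx_pedR[ks]
      mm <- md[md$side == side, ]
      fixed <- rbind(fixed,
                     data.frame(node = rep(nodes, 3),
                                comp = rep(1:3, each = length(nodes)),
                                value = c(mm$ux, mm$uy, mm$uz)))
    }
    st <- tryCatch(
      solve_static(model, load_case(fixed = fixed), increments = increments),
      error = function(e) if (W == 0) stop("model error at W = 0: ",
                                           conditionMessage(e)) else NULL)
    if (is.null(st)) break
    dist <- max(element_strains(model, st))
    steps[[length(steps) + 1]] <- data.frame(W = W, max_strain = dist)
    if (dist > distortion_threshold) break
    best <- st
    best_W <- W
  }
  if (is.null(best)) stop("no admissible over-correction weight (W = 0 failed)")

  verts <- matrix(0, n * anatomy$skin$n_phi, 3)
  for (k in 1:n) verts[(k - 1) * anatomy$skin$n_phi + seq_len(anatomy$skin$n_phi), ] <-
    best$positions[model$idx_skin[k, ], , drop = FALSE]

  structure(list(
    W_max = best_W,
    deformed_skin = list(verts = verts, tris = anatomy$skin$tris,
                         n_ring = n, n_phi = anatomy$skin$n_phi),
    distortion = do.call(rbind, steps),
    state = best
  ), class = "overcorrection_result")
}

#' Automatic trim profile from anatomical landmarks
#'
#' Piecewise-linear superior and inferior trim heights over the azimuth:
#' the superior limit reaches the axilla (95 % of skin height) on the convex
#' side of the thoracic curve and drops on the concave side; the inferior
#' limit covers the trochanter on the side ipsilateral to the
#' thoracolumbar/lumbar convexity and is raised to iliac-crest level on the
#' contralateral side.
#'
#' @param anatomy A `trunk_anatomy` (presenting deformity; determines the
#'   convex sides).
#' @return A `trim_profile` list: vectorized functions `h_top(phi)`,
#'   `h_bot(phi)` (mm) and `convex_side` (`"left"`/`"right"`).
#' @export
trim_profile_default <- function(anatomy) {
  zr <- range(anatomy$skin$verts[, 3])
  z0 <- zr[1]; z1 <- zr[2]; H <- z1 - z0
  mt_convex_left <- anatomy$spec$mt_dir > 0   # +y deviation = convex left
  tll_convex_left <- anatomy$spec$tll_dir > 0
  # phi = 0 anterior, +pi/2 patient left
  top_convex <- z0 + 0.95 * H
  top_concave <- z0 + 0.82 * H
  bot_trochanter <- z0
  bot_crest <- z0 + 0.12 * H
  mk <- function(v_left, v_right) {
    function(phi) {
      s <- sin(phi)                      # +1 left flank, -1 right flank
      w <- (s + 1) / 2                   # 0 at right flank, 1 at left flank
      v_right + (v_left - v_right) * w   # linear blend across azimuth
    }
  }
  h_top <- if (mt_convex_left) mk(top_convex, top_concave) else
    mk(top_concave, top_convex)
  h_bot <- if (tll_convex_left) mk(bot_trochanter, bot_crest) else
    mk(bot_crest, bot_trochanter)
  structure(list(h_top = h_top, h_bot = h_bot,
                 convex_side = if (mt_convex_left) "left" else "right"),
            class = "trim_profile")
}

#' Trim the deformed skin into the initial brace surface
#'
#' Retains the points of the over-corrected skin whose height lies between
#' the inferior and superior trim profiles at their azimuth; the result is
#' the inner surface of the initial brace.
#'
#' @param deformed_skin Deformed skin from [find_max_overcorrection()] (list
#'   with `verts`, `n_ring`, `n_phi`).
#' @param trim_profile A `trim_profile`.
#' @param axis Cylindrical axis `c(x0, y0)`; default: centroid of the points.
#' @return A `brace_points` object: retained points with cylindrical
#'   coordinates and the (ring, phi) grid mask used for surface
#'   interpolation.
#' @export
trim_initial_brace <- function(deformed_skin, trim_profile, axis = NULL) {
  V <- deformed_skin$verts
  if (is.null(axis)) axis <- c(mean(V[, 1]), mean(V[, 2]))
  keep_top <- trim_profile$h_top(atan2(V[, 2] - axis[2], V[, 1] - axis[1]))
  keep_bot <- trim_profile$h_bot(atan2(V[, 2] - axis[2], V[, 1] - axis[1]))
  if (any(keep_top <= keep_bot)) stop("trim profile inverted (h_top <= h_bot)")
  keep <- V[, 3] >= keep_bot & V[, 3] <= keep_top
  if (!any(keep)) stop("trim produced an empty brace surface")
  brace_points(V, keep = keep, axis = axis,
               n_ring = deformed_skin$n_ring, n_phi = deformed_skin$n_phi)
}

# Internal constructor: cylindrical representation of a brace point set that
# retains the (ring, phi) lattice of the skin it came from.
brace_points <- function(verts, keep = rep(TRUE, nrow(verts)), axis,
                         n_ring, n_phi) {
  dx <- verts[, 1] - axis[1]
  dy <- verts[, 2] - axis[2]
  structure(list(
    verts = verts, keep = keep, axis = axis,
    rho = sqrt(dx^2 + dy^2), phi = atan2(dy, dx), z = verts[, 3],
    n_ring = n_ring, n_phi = n_phi,
    ring = rep(seq_len(n_ring), each = n_phi),
    phi_idx = rep(seq_len(n_phi), n_ring)
  ), class = "brace_points")
}

# Cartesian points currently retained
brace_xyz <- function(bp) {
  cbind(bp$axis[1] + bp$rho * cos(bp$phi),
        bp$axis[2] + bp$rho * sin(bp$phi),
        bp$z)[bp$keep, , drop = FALSE]
}
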
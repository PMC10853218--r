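# The three simulated configurations: standing out-of-brace (OOB), supine
# in-brace (IB), and the two-year post-growth outcome (PG), linked by the
# Hueter-Volkmann growth-modulation law.

#' Growth-modulation parameters
#'
#' @param C Brace-wear compliance fraction (proportion of time in brace
#'   during sleep, 8 h/day = 0.33).
#' @param G_m_thoracic,G_m_lumbar Baseline vertebral growth rates, mm/year.
#' @param beta Stress sensitivity of growth, 1/MPa.
#' @param duration_years Treatment duration.
#' @param floor_zero If `TRUE`, negative local growth (resorption) is floored
#'   at zero; the printed law allows it, so the default keeps it.
#' @return A `growth_params` list.
#' @export
growth_params <- function(C = 0.33, G_m_thoracic = 0.8, G_m_lumbar = 1.1,
                          beta = 1.5, duration_years = 2, floor_zero = FALSE) {
  stopifnot(C >= 0, C <= 1, beta > 0, duration_years >= 0)
  structure(as.list(environment()), class = "growth_params")
}

# update anatomy frames/centroids/pedicles/skin from a solved state
update_anatomy <- function(model, state) {
  a <- model$anatomy
  n <- length(a$levels)
  out <- a
  out$centroids <- state$positions[model$idx_cen, , drop = FALSE]
  for (k in 1:n) {
    th <- state$rotations[model$idx_cen[k], ]
    ang <- sqrt(sum(th^2))
    Rr <- if (ang < 1e-12) diag(3) else {
      ax <- th / ang
      K <- skew3(ax)
      diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    }
    out$frames[[k]] <- Rr %*% a$frames[[k]]
    out$ped_L[k, ] <- state$positions[model$idx_pedL[k], ]
    out$ped_R[k, ] <- state$positions[model$idx_pedR[k], ]
  }
  tl <- vertebra_tilts(out)
  out$tilt_cor_deg <- tl$coronal
  out$tilt_sag_deg <- tl$sagittal
  out$axial_deg <- tl$axial
  for (k in 1:n) out$skin$verts[(k - 1) * a$skin$n_phi + seq_len(a$skin$n_phi), ] <-
    state$positions[model$idx_skin[k, ], , drop = FALSE]
  out$pelvis$origin <- state$positions[model$idx_pelvis, ]
  out
}

#' Simulate the standing out-of-brace configuration
#'
#' Solves the calibrated model under gravity and the tuned stabilizing muscle
#' forces; returns the standing geometry and the growth-plate stress field.
#'
#' @param model A calibrated `trunk_model`.
#' @return A `sim_result` with `configuration = "OOB"`, the solved state, the
#'   loaded anatomy, and `plate_stresses`.
#' @export
simulate_oob <- function(model) {
  if (!isTRUE(model$calibrated)) stop("model must be calibrated first")
  st <- solve_static(model, oob_load(model), increments = 1)
  structure(list(configuration = "OOB", state = st,
                 anatomy = update_anatomy(model, st),
                 plate_stresses = plate_stress_field(model, st)),
            class = "sim_result")
}

oob_load <- function(model) {
  fm <- matrix(0, model$n_nodes, 3)
  if (!is.null(model$muscle_forces)) {
    nodes <- model$idx_cen[level_index(model$muscle_forces$level)]
    comps <- match(model$muscle_forces$component, c("x", "y", "z"))
    for (i in seq_len(nrow(model$muscle_forces)))
      fm[nodes[i], comps[i]] <- fm[nodes[i], comps[i]] +
        model$muscle_forces$force_N[i]
  }
  load_case(forces = fm, gravity = c(0, 0, -1),
            fixed = data.frame(node = model$idx_pelvis, comp = 1:6, value = 0))
}

#' Simulate the supine nighttime in-brace configuration
#'
#' The weightless (zero-stress) patient lies supine: gravity acts posteriorly
#' (along -x), a unilateral foam-mattress foundation supports the posterior
#' skin, the brace inner surface contacts the skin through penalty springs,
#' and the closure straps pull the two opening edges together at their set
#' tension.  T1's lateral and craniocaudal translations and all pelvis DOFs
#' are blocked.
#'
#' @param model A calibrated `trunk_model`.
#' @param brace A `brace_shape` from [finalize_brace()].
#' @param increments Load increments (brace donning is ramped across them).
#' @return A `sim_result` with `configuration = "IB"`, the solved state, the
#'   in-brace anatomy, `plate_stresses` and `pressures_kpa`.
#' @export
simulate_inbrace <- function(model, brace, increments = 6) {
  if (!isTRUE(model$calibrated)) stop("model must be calibrated first")
  pr <- model$params
  skin_nodes <- as.vector(t(model$idx_skin))
  areas <- as.vector(t(model$skin_area))

  # mattress plane just touching the most posterior skin point
  x_plane <- min(model$nodes[skin_nodes, 1])
  mat_ct <- contact_plane(point = c(x_plane, 0, 0), normal = c(1, 0, 0),
                          nodes = skin_nodes,
                          k_per_area = pr$mattress_E / pr$mattress_depth,
                          areas = areas)
  br_ct <- contact_brace(brace$rho_fun, brace$axis, nodes = skin_nodes,
                         k_per_area = pr$contact_k_per_area, areas = areas)

  # straps: each tensioned band bridges the frontal opening between its two
  # anchors and presses the skin it crosses radially inward; the reaction is
  # carried by the shell (rigid and grounded here), so the edge-pull pair
  # reduces to this normal load on the anterior skin
  fm <- matrix(0, model$n_nodes, 3)
  skin_pos <- model$nodes[skin_nodes, , drop = FALSE]
  sphi <- atan2(skin_pos[, 2] - brace$axis[2], skin_pos[, 1] - brace$axis[1])
  arc <- deg2rad(brace$opening_deg / 2) + 2 * pi / model$anatomy$skin$n_phi
  zs <- model$nodes[skin_nodes, 3]
  dz_ring <- abs(diff(range(zs))) / (model$anatomy$skin$n_ring - 1)
  for (i in seq_len(nrow(brace$straps))) {
    s <- brace$straps[i, ]
    band <- which(abs(sphi) < arc & abs(zs - s$left_z) < dz_ring)
    if (!length(band)) next
    for (b in band) {
      nd <- skin_nodes[b]
      inward <- -normalize(c(skin_pos[b, 1] - brace$axis[1],
                             skin_pos[b, 2] - brace$axis[2], 0))
      fm[nd, ] <- fm[nd, ] + s$tension_N / length(band) * inward
    }
  }

  fixed <- rbind(
    data.frame(node = model$idx_pelvis, comp = 1:6, value = 0),
    data.frame(node = 1L, comp = c(2L, 3L), value = 0)  # T1 lateral + craniocaudal
  )
  lc <- load_case(forces = fm, gravity = c(-1, 0, 0), fixed = fixed,
                  contacts = list(mat_ct, br_ct))
  st <- solve_static(model, lc, increments = increments)
  structure(list(configuration = "IB", state = st,
                 anatomy = update_anatomy(model, st),
                 plate_stresses = plate_stress_field(model, st),
                 pressures_kpa = contact_pressures(st, 2)),
            class = "sim_result")
}

#' Combine out-of-brace and in-brace plate stresses
#'
#' Treatment-period average stress: `sigma = sigma_OOB + C (sigma_IB -
#' sigma_OOB)`, the affine combination weighted by the nightly brace-wear
#' compliance fraction.
#'
#' @param sigma_oob,sigma_ib `plate_stress_field` data frames over the same
#'   plates.
#' @param C Compliance fraction.
#' @return Combined `plate_stress_field`.
#' @export
combine_stresses <- function(sigma_oob, sigma_ib, C = 0.33) {
  stopifnot(nrow(sigma_oob) == nrow(sigma_ib),
            all(sigma_oob$level == sigma_ib$level),
            all(sigma_oob$plate == sigma_ib$plate))
  out <- sigma_oob
  out$sigma_L <- sigma_oob$sigma_L + C * (sigma_ib$sigma_L - sigma_oob$sigma_L)
  out$sigma_R <- sigma_oob$sigma_R + C * (sigma_ib$sigma_R - sigma_oob$sigma_R)
  out$sigma_m <- (out$sigma_L + out$sigma_R) / 2
  out
}

#' Local growth rates from plate stresses
#'
#' Hueter-Volkmann growth modulation: `G_side = G_m (1 + beta (sigma_side -
#' sigma_m))` per growth plate, with the thoracic/lumbar baseline rate and
#' compressive stress negative, so the more compressed side grows less.
#'
#' @param stress_field A `plate_stress_field` (typically the compliance-
#'   combined field).
#' @param params A `growth_params` list.
#' @return The field with `G_L`, `G_R` (mm/year) columns appended.
#' @export
plate_growth_rates <- function(stress_field, params = growth_params()) {
  thor <- is_thoracic(level_index(stress_field$level))
  G_m <- ifelse(thor, params$G_m_thoracic, params$G_m_lumbar)
  out <- stress_field
  out$G_L <- G_m * (1 + params$beta * (stress_field$sigma_L - stress_field$sigma_m))
  out$G_R <- G_m * (1 + params$beta * (stress_field$sigma_R - stress_field$sigma_m))
  if (isTRUE(params$floor_zero)) {
    out$G_L <- pmax(out$G_L, 0)
    out$G_R <- pmax(out$G_R, 0)
  }
  out
}

#' Simulate two years of growth-modulated evolution
#'
#' Applies the per-plate left/right growth increments to the vertebral bodies
#' (height gain plus coronal wedge rotation `atan(dG * duration / width)` per
#' plate), restacks the spine so the wedges accumulate along it, rebuilds the
#' anatomy, then recalibrates and re-solves the standing configuration on the
#' grown spine to obtain the post-growth geometry.
#'
#' @param model The calibrated presenting `trunk_model`.
#' @param rates Output of [plate_growth_rates()].
#' @param params A `growth_params` (supplies `duration_years`).
#' @param resolve If `TRUE` (default) recalibrate and gravity-solve the grown
#'   anatomy; if `FALSE` return the kinematically grown anatomy directly.
#' @return A `sim_result` with `configuration = "PG"`, the grown anatomy and
#'   (when `resolve`) its standing state and plate stresses.
#' @export
simulate_growth <- function(model, rates, params = growth_params(),
                            resolve = TRUE) {
  a0 <- model$anatomy
  n <- length(a0$levels)
  dur <- params$duration_years
  plate_w <- 2 * model$params$plate_b * (a0$spec$trunk_height_mm / 460)

  dG <- (rates$G_R - rates$G_L) * dur          # right-minus-left height gain
  gain <- (rates$G_L + rates$G_R) / 2 * dur    # mean height gain per plate
  wedge_deg <- numeric(n)                      # per-vertebra coronal wedge
  height_gain <- numeric(n)
  for (k in 2:n) {
    sel <- rates$level == a0$levels[k]
    wedge_deg[k] <- sum(rad2deg(atan(dG[sel] / plate_w)))
    height_gain[k] <- sum(gain[sel])
  }
  # a right-taller wedge rotates everything above toward +y (patient left)
  cum_wedge <- rev(cumsum(rev(wedge_deg))) - wedge_deg / 2
  tilt_cor <- a0$tilt_cor_deg + cum_wedge

  grown <- build_anatomy(a0$spec, tilt_cor, a0$tilt_sag_deg, a0$axial_deg,
                         n_phi = a0$skin$n_phi)
  grown$body_height_mm <- a0$body_height_mm + height_gain
  if (dur == 0) grown <- a0

  if (!resolve) {
    return(structure(list(configuration = "PG", anatomy = grown,
                          state = NULL, plate_stresses = NULL),
                     class = "sim_result"))
  }
  mg <- assemble_model(grown, model$flexibility_factor, model$params)
  mg <- calibrate_standing(mg, tol_rms_mm = 2, max_iter = 8)
  simulate_oob_as_pg(mg)
}

simulate_oob_as_pg <- function(model) {
  r <- simulate_oob(model)
  r$configuration <- "PG"
  r
}
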
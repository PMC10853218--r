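# 3D deformity metrics (Cobb, kyphosis/lordosis, apical axial rotation),
# the clinical objective function, and the contact-pressure safety check.

# Per-vertebra projected endplate tilts, degrees, from the stored frames.
# Coronal tilt: angle of the endplate normal projected onto the y-z plane
# (positive = normal tipped toward +y / patient left).  Sagittal: x-z plane.
vertebra_tilts <- function(anatomy) {
  n <- length(anatomy$levels)
  cor <- sag <- axl <- numeric(n)
  for (k in 1:n) {
    R <- anatomy$frames[[k]]
    nrm <- R[, 3]
    cor[k] <- rad2deg(atan2(nrm[2], nrm[3]))
    sag[k] <- rad2deg(atan2(nrm[1], nrm[3]))
    ex <- R[, 1]
    axl[k] <- rad2deg(atan2(ex[2], ex[1]))
  }
  list(coronal = cor, sagittal = sag, axial = axl)
}

#' Fix end vertebrae, apices and curve signs on the presenting deformity
#'
#' Selects, once per patient, the most-tilted (end) vertebrae of the main
#' thoracic and thoracolumbar/lumbar curves in the coronal projection, the
#' apical vertebra of each curve (largest lateral deviation), and the sign
#' convention that makes the presenting Cobb angles positive.  The same
#' context is reused for all simulated configurations of that patient so that
#' in-brace and post-growth angles are comparable (a negative value then means
#' an over-corrected curve).
#'
#' @param anatomy The presenting (baseline) `trunk_anatomy`.
#' @return A `metrics_context` list with end levels, apex levels and signs.
#' @export
baseline_context <- function(anatomy) {
  tl <- vertebra_tilts(anatomy)
  n <- length(anatomy$levels)
  mt_apex <- level_index(anatomy$spec$mt_apex_level)
  tll_apex <- level_index(anatomy$spec$tll_apex_level)

  # each curve's end vertebrae are sought on its own territory: the shared
  # boundary between the two curves lies between the apices (transitional
  # vertebra), so the windows are clipped there to avoid cross-talk when the
  # apices are adjacent
  pick_ends <- function(apex, up_lim = max(1, apex - 6),
                        lo_lim = min(n, apex + 6)) {
    up_rng <- up_lim:apex
    lo_rng <- apex:lo_lim
    # signed span is maximized by taking extreme tilts on each side
    up <- up_rng[which.max(tl$coronal[up_rng])]
    lo <- lo_rng[which.min(tl$coronal[lo_rng])]
    up2 <- up_rng[which.min(tl$coronal[up_rng])]
    lo2 <- lo_rng[which.max(tl$coronal[lo_rng])]
    # choose orientation with the larger magnitude
    if ((tl$coronal[up] - tl$coronal[lo]) >= (tl$coronal[lo2] - tl$coronal[up2]))
      list(upper = up, lower = lo, sign = 1)
    else list(upper = up2, lower = lo2, sign = -1)
  }
  mt <- pick_ends(mt_apex, lo_lim = tll_apex)
  tll <- pick_ends(tll_apex, up_lim = mt_apex)
  structure(list(
    mt = list(apex = mt_apex, upper = mt$upper, lower = mt$lower, sign = mt$sign),
    tll = list(apex = tll_apex, upper = tll$upper, lower = tll$lower, sign = tll$sign),
    avr_sign_mt = sign_or_one(mean_axial(tl$axial, mt_apex, n)),
    avr_sign_tll = sign_or_one(mean_axial(tl$axial, tll_apex, n))
  ), class = "metrics_context")
}

sign_or_one <- function(x) if (x < 0) -1 else 1
mean_axial <- function(axial, apex, n) {
  idx <- max(1, apex - 1):min(n, apex + 1)
  mean(axial[idx])
}

#' Coronal Cobb angle between two end vertebrae
#'
#' Angle between the superior-endplate normal of the upper end vertebra and
#' the inferior-endplate normal of the lower end vertebra, both projected onto
#' the coronal plane.
#'
#' @param anatomy A `trunk_anatomy` (presenting or simulated).
#' @param end_levels Length-2 character vector, e.g. `c("T5", "T11")`.
#' @param signed If `TRUE`, keep the signed angle (upper minus lower tilt);
#'   otherwise return the magnitude.
#' @return Angle in degrees.
#' @export
cobb_angle <- function(anatomy, end_levels, signed = FALSE) {
  tl <- vertebra_tilts(anatomy)
  i <- level_index(end_levels)
  a <- tl$coronal[i[1]] - tl$coronal[i[2]]
  if (signed) a else abs(a)
}

#' Sagittal spinal curves
#'
#' Thoracic kyphosis measured as the sagittal Cobb angle T4-T12 and lumbar
#' lordosis as L1-L5, both reported positive for the physiological curve
#' directions.
#'
#' @param anatomy A `trunk_anatomy`.
#' @return Named numeric `c(tk = , ll = )` in degrees.
#' @export
sagittal_angles <- function(anatomy) {
  tl <- vertebra_tilts(anatomy)
  tk <- tl$sagittal[level_index("T12")] - tl$sagittal[level_index("T4")]
  ll <- tl$sagittal[level_index("L1")] - tl$sagittal[level_index("L5")]
  c(tk = tk, ll = ll)
}

#' Apical axial vertebral rotation
#'
#' Mean transverse-plane rotation of the three most rotated vertebrae of a
#' curve (apex and its two neighbours), signed.
#'
#' @param anatomy A `trunk_anatomy`.
#' @param apex_level Apical vertebral level, e.g. `"T8"`.
#' @return Degrees (signed; direction of rotation toward the convexity).
#' @export
avr <- function(anatomy, apex_level) {
  tl <- vertebra_tilts(anatomy)
  mean_axial(tl$axial, level_index(apex_level), length(anatomy$levels))
}

#' Measure the six deformity metrics of a configuration
#'
#' @param anatomy A `trunk_anatomy`.
#' @param ctx A `metrics_context` from [baseline_context()] (end vertebrae and
#'   signs fixed on the presenting deformity).
#' @return A `deformity_metrics` list: `cobb_mt`, `cobb_tll`, `tk`, `ll`,
#'   `avr_mt`, `avr_tll`, all in degrees.  Cobb values are signed relative to
#'   the presenting curve direction (negative = over-corrected).
#' @export
measure_metrics <- function(anatomy, ctx) {
  tl <- vertebra_tilts(anatomy)
  lv <- anatomy$levels
  n <- length(lv)
  cobb <- function(cv) (tl$coronal[cv$upper] - tl$coronal[cv$lower]) * cv$sign
  sg <- sagittal_angles(anatomy)
  structure(list(
    cobb_mt = cobb(ctx$mt),
    cobb_tll = cobb(ctx$tll),
    tk = unname(sg["tk"]), ll = unname(sg["ll"]),
    avr_mt = mean_axial(tl$axial, ctx$mt$apex, n) * ctx$avr_sign_mt,
    avr_tll = mean_axial(tl$axial, ctx$tll$apex, n) * ctx$avr_sign_tll
  ), class = "deformity_metrics")
}

#' Objective-function weights and normal sagittal ranges
#'
#' Defaults follow the published design objective: configuration weights 5
#' (in-brace) and 10 (post-growth); plane weights 2 (coronal), 1 (sagittal),
#' 1 (transverse); normal thoracic kyphosis 20-40 degrees and lumbar lordosis
#' 30-60 degrees; denominators guarded at 1 degree.
#'
#' @param w_ib,w_pg Configuration weights.
#' @param w_c,w_s,w_t Coronal, sagittal, transverse plane weights.
#' @param tk_normal,ll_normal Normal ranges, degrees.
#' @param denom_floor_deg Lower guard for ratio denominators, degrees.
#' @return A list of class `objective_weights`.
#' @export
objective_weights <- function(w_ib = 5, w_pg = 10, w_c = 2, w_s = 1, w_t = 1,
                              tk_normal = c(20, 40), ll_normal = c(30, 60),
                              denom_floor_deg = 1) {
  stopifnot(w_ib > 0, w_pg > 0, w_c > 0, w_s > 0, w_t > 0,
            diff(tk_normal) > 0, diff(ll_normal) > 0, denom_floor_deg > 0)
  structure(as.list(environment()), class = "objective_weights")
}

#' Clamp a sagittal angle to its normal range
#'
#' Returns the normative reference used in the sagittal objective terms: the
#' nearer bound when the simulated value lies outside the documented normal
#' range, or the value itself when inside (making that term's numerator zero).
#'
#' @param value_deg Simulated angle, degrees.
#' @param normal_range `c(lo, hi)` degrees.
#' @return Reference angle, degrees.
#' @export
clamp_normal <- function(value_deg, normal_range) {
  stopifnot(length(normal_range) == 2, normal_range[1] < normal_range[2])
  pmin(pmax(value_deg, normal_range[1]), normal_range[2])
}

sagittal_term <- function(sim, ini, normal_range, floor_deg) {
  ref <- clamp_normal(sim, normal_range)
  num <- abs(abs(sim) - abs(ref))
  if (num == 0) return(0)              # simulated curve inside normal range
  den <- abs(abs(ini) - abs(ref))
  num / max(den, floor_deg)
}

#' Deformity score of one simulated configuration
#'
#' Weighted sum of coronal Cobb ratios, sagittal deviations from the normal
#' range (relative to the presenting deviation), and apical axial-rotation
#' ratios, as used for both the in-brace and the post-growth configurations.
#' Denominators are floored at `weights$denom_floor_deg` so that patients
#' presenting with normal sagittal alignment or zero apical rotation do not
#' produce degenerate ratios; a sagittal term whose simulated value is inside
#' the normal range contributes zero.
#'
#' @param metrics_sim,metrics_ini `deformity_metrics` of the simulated and the
#'   presenting configuration.
#' @param weights An `objective_weights` list.
#' @return The dimensionless score `phi`.
#' @export
deformity_term <- function(metrics_sim, metrics_ini, weights = objective_weights()) {
  fl <- weights$denom_floor_deg
  rat <- function(s, i) abs(s) / max(abs(i), fl)
  weights$w_c * (rat(metrics_sim$cobb_mt, metrics_ini$cobb_mt) +
                   rat(metrics_sim$cobb_tll, metrics_ini$cobb_tll)) +
    weights$w_s * (sagittal_term(metrics_sim$tk, metrics_ini$tk,
                                 weights$tk_normal, fl) +
                     sagittal_term(metrics_sim$ll, metrics_ini$ll,
                                   weights$ll_normal, fl)) +
    weights$w_t * (rat(metrics_sim$avr_mt, metrics_ini$avr_mt) +
                     rat(metrics_sim$avr_tll, metrics_ini$avr_tll))
}

#' Assemble the scalar brace objective
#'
#' `OF = w_ib * phi_ib + w_pg * phi_pg`: the weighted combination of the
#' in-brace and two-year post-growth deformity scores.
#'
#' @param phi_ib,phi_pg Deformity scores from [deformity_term()].
#' @param weights An `objective_weights` list.
#' @param max_pressure_kpa Optional peak skin contact pressure to carry along.
#' @param pressure_limit_kpa Feasibility threshold, kPa.
#' @return An `of_score` list: `value`, `phi_ib`, `phi_pg`, `feasible`,
#'   `max_pressure_kpa`.
#' @export
objective <- function(phi_ib, phi_pg, weights = objective_weights(),
                      max_pressure_kpa = NA_real_, pressure_limit_kpa = 450) {
  stopifnot(is.finite(phi_ib), is.finite(phi_pg))
  structure(list(
    value = weights$w_ib * phi_ib + weights$w_pg * phi_pg,
    phi_ib = phi_ib, phi_pg = phi_pg,
    feasible = if (is.na(max_pressure_kpa)) NA else max_pressure_kpa < pressure_limit_kpa,
    max_pressure_kpa = max_pressure_kpa
  ), class = "of_score")
}

#' Contact-pressure safety check
#'
#' A brace is feasible when its largest localized nodal skin contact pressure
#' stays below the pain-perception threshold (450 kPa by default).
#'
#' @param pressures_kpa Numeric vector of nodal pressures, kPa.
#' @param threshold_kpa Threshold, kPa.
#' @return List with `feasible` flag and `max_pressure_kpa`.
#' @export
check_pressure <- function(pressures_kpa, threshold_kpa = 450) {
  mx <- if (length(pressures_kpa)) max(pressures_kpa) else 0
  list(feasible = mx < threshold_kpa, max_pressure_kpa = mx)
}
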
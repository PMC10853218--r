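#' @keywords internal
"_PACKAGE"

# Global frame convention used throughout the package:
#   x anterior, y left lateral, z cranial.  Units: mm, N, MPa, degrees
# unless a function documents otherwise.

#' Vertebral level labels, T1 to L5
#'
#' @return Character vector of the 17 thoracolumbar levels in cranio-caudal
#'   order (`"T1" ... "T12", "L1" ... "L5"`).
#' @export
spine_levels <- function() c(paste0("T", 1:12), paste0("L", 1:5))

level_index <- function(level) {
  i <- match(level, spine_levels())
  if (anyNA(i)) stop("unknown vertebral level: ", paste(level[is.na(i)], collapse = ", "))
  i
}

is_thoracic <- function(idx) idx <= 12L

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize <- function(v) v / sqrt(sum(v^2))

# Orthonormal frame (columns = local x anterior-ish, y left-ish, z = tangent)
# from a cranial tangent direction plus an axial rotation about the tangent.
frame_from_tangent <- function(tangent, axial_deg = 0) {
  ez <- normalize(tangent)
  ex0 <- normalize(c(1, 0, 0) - sum(c(1, 0, 0) * ez) * ez)
  ey0 <- cross3(ez, ex0)
  a <- deg2rad(axial_deg)
  ex <- cos(a) * ex0 + sin(a) * ey0
  ey <- cross3(ez, ex)
  cbind(ex, ey, ez, deparse.level = 0)
}

# Compact-support C1 bump: cos^2(pi t / 2) on |t| < 1, 0 elsewhere.
bump <- function(t) ifelse(abs(t) < 1, cos(pi * t / 2)^2, 0)

#' Cohort ranges for synthetic patient sampling
#'
#' Default sampling ranges (and, where published, mean/sd) for the deformity
#' metrics of a moderate nighttime-brace AIS cohort: main-thoracic (MT) Cobb
#' 28 +/- 8 degrees over \[17, 44\], thoracolumbar/lumbar (TL/L) Cobb 31 +/- 9
#' over \[17, 48\], thoracic kyphosis 27 +/- 11 over \[13, 44\], lumbar
#' lordosis 42 +/- 19 over \[16, 77\], apical axial rotations 5 +/- 4 and
#' 8 +/- 7 degrees.  Trunk size, mass and spinal flexibility are not published
#' for the cohort; adolescent-plausible defaults are exposed here.
#'
#' @return Named list; each element is `c(lo, hi)` or
#'   `c(lo, hi, mean, sd)` for truncated-normal sampling.
#' @export
cohort_ranges_default <- function() {
  list(
    mt_cobb_deg      = c(17, 44, 28, 8),
    tll_cobb_deg     = c(17, 48, 31, 9),
    tk_deg           = c(13, 44, 27, 11),
    ll_deg           = c(16, 77, 42, 19),
    avr_mt_deg       = c(1, 16, 5, 4),
    avr_tll_deg      = c(0, 22, 8, 7),
    trunk_height_mm  = c(400, 500, 460, 30),
    trunk_mass_kg    = c(20, 34, 27.5, 4),
    flexibility_factor = c(0.7, 1.6, 1.1, 0.25),
    mt_apex_level    = c("T5", "T10"),
    tll_apex_level   = c("T11", "L3")
  )
}

rtrunc_norm <- function(n, lo, hi, mean, sd) {
  if (is.na(mean)) return(stats::runif(n, lo, hi))
  x <- stats::rnorm(n * 4 + 20, mean, sd)
  x <- x[x >= lo & x <= hi]
  while (length(x) < n) x <- c(x, stats::runif(n, lo, hi)) # pathological ranges
  x[seq_len(n)]
}

#' Sample a synthetic patient specification
#'
#' Draws one `patient_spec` from the cohort distribution.  Scalar metrics are
#' sampled from truncated normals (uniform where only a range is known); apex
#' levels uniformly over their admissible windows.  The main thoracic curve is
#' convex right and the thoracolumbar/lumbar curve convex left, the most common
#' presentation.
#'
#' @param cohort_ranges Ranges as returned by [cohort_ranges_default()].
#' @param seed Integer seed; identical seeds give identical specs.
#' @return An object of class `patient_spec`.
#' @export
sample_patient_spec <- function(cohort_ranges = cohort_ranges_default(), seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  for (nm in setdiff(names(cohort_ranges), c("mt_apex_level", "tll_apex_level"))) {
    r <- cohort_ranges[[nm]]
    if (length(r) < 2 || r[1] > r[2]) stop("empty or inverted range for ", nm)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  draw <- function(nm) {
    r <- cohort_ranges[[nm]]
    m <- if (length(r) >= 4) r[3] else NA_real_
    s <- if (length(r) >= 4) r[4] else NA_real_
    rtrunc_norm(1, r[1], r[2], m, s)
  }
  lv <- spine_levels()
  apex_window <- function(nm) {
    r <- cohort_ranges[[nm]]
    lv[seq(level_index(r[1]), level_index(r[2]))]
  }
  spec <- list(
    mt_cobb_deg  = draw("mt_cobb_deg"),
    tll_cobb_deg = draw("tll_cobb_deg"),
    mt_apex_level  = sample(apex_window("mt_apex_level"), 1),
    tll_apex_level = sample(apex_window("tll_apex_level"), 1),
    tk_deg = draw("tk_deg"),
    ll_deg = draw("ll_deg"),
    avr_mt_deg  = draw("avr_mt_deg"),
    avr_tll_deg = draw("avr_tll_deg"),
    trunk_height_mm = draw("trunk_height_mm"),
    trunk_mass_kg   = draw("trunk_mass_kg"),
    flexibility_factor = draw("flexibility_factor"),
    mt_dir  = -1,  # convex right (apex deviated toward -y)
    tll_dir = +1,  # convex left
    seed = as.integer(seed)
  )
  validate_patient_spec(structure(spec, class = "patient_spec"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Construct a patient specification directly
#'
#' @param mt_cobb_deg,tll_cobb_deg Coronal Cobb angles (degrees, >= 0).
#' @param mt_apex_level,tll_apex_level Apex levels (T5-T10, T11-L3).
#' @param tk_deg,ll_deg Thoracic kyphosis and lumbar lordosis (degrees).
#' @param avr_mt_deg,avr_tll_deg Apical axial rotations (degrees).
#' @param trunk_height_mm Spine length T1-L5 (mm).
#' @param trunk_mass_kg Trunk mass suspended on the spine (kg).
#' @param flexibility_factor Dimensionless divisor on disk stiffness (> 0).
#' @param mt_dir,tll_dir Curve convexity: -1 convex right, +1 convex left.
#' @param seed Integer seed recorded with the spec.
#' @return An object of class `patient_spec`.
#' @export
patient_spec <- function(mt_cobb_deg = 28, tll_cobb_deg = 31,
                         mt_apex_level = "T8", tll_apex_level = "L1",
                         tk_deg = 27, ll_deg = 42,
                         avr_mt_deg = 5, avr_tll_deg = 8,
                         trunk_height_mm = 460, trunk_mass_kg = 27.5,
                         flexibility_factor = 1.1,
                         mt_dir = -1, tll_dir = +1, seed = 1L) {
  spec <- structure(as.list(environment()), class = "patient_spec")
  spec$seed <- as.integer(seed)
  validate_patient_spec(spec)
}

validate_patient_spec <- function(spec) {
  stopifnot(
    spec$mt_cobb_deg >= 0, spec$tll_cobb_deg >= 0,
    spec$flexibility_factor > 0,
    spec$trunk_height_mm > 0, spec$trunk_mass_kg > 0,
    spec$mt_dir %in% c(-1, 1), spec$tll_dir %in% c(-1, 1)
  )
  mi <- level_index(spec$mt_apex_level)
  ti <- level_index(spec$tll_apex_level)
  if (mi < level_index("T5") || mi > level_index("T10"))
    stop("MT apex level must lie in T5-T10")
  if (ti < level_index("T11") || ti > level_index("L3"))
    stop("TL/L apex level must lie in T11-L3")
  spec
}

#' Mirror a patient specification about the sagittal plane
#'
#' @param spec A `patient_spec`.
#' @return The spec with both curve convexities and axial rotations flipped.
#' @export
mirror_spec <- function(spec) {
  spec$mt_dir <- -spec$mt_dir
  spec$tll_dir <- -spec$tll_dir
  spec
}

# Nominal (unscaled) vertebral body and disk heights, mm, T1..L5.
.body_heights0 <- c(rep(19, 12), rep(27, 5))
.disk_heights0 <- c(rep(4.5, 12), rep(8.5, 5))

# Internal: all deterministic geometry derived from centerline profiles.
# tilt_cor, tilt_sag, axial are per-level angles in degrees.
build_anatomy <- function(spec, tilt_cor, tilt_sag, axial, n_phi = 16L) {
  lv <- spine_levels()
  n <- length(lv)
  hscale <- spec$trunk_height_mm / sum(.body_heights0 + .disk_heights0)
  bh <- .body_heights0 * hscale
  dh <- .disk_heights0 * hscale
  seg <- bh + dh                       # centroid-to-centroid spacing

  # Stack centroids caudal -> cranial so vertebral tilts integrate into a
  # spine curve; z strictly increasing upwards, L5 inferior endplate at z = 0.
  cen <- matrix(0, n, 3)
  cen[n, 3] <- bh[n] / 2
  for (k in (n - 1):1) {
    tc <- deg2rad((tilt_cor[k] + tilt_cor[k + 1]) / 2)
    ts <- deg2rad((tilt_sag[k] + tilt_sag[k + 1]) / 2)
    d <- normalize(c(tan(ts), tan(tc), 1)) * seg[k]
    cen[k, ] <- cen[k + 1, ] + d
  }
  frames <- vector("list", n)
  for (k in 1:n) {
    tg <- c(tan(deg2rad(tilt_sag[k])), tan(deg2rad(tilt_cor[k])), 1)
    frames[[k]] <- frame_from_tangent(tg, axial[k])
  }
  # balanced (compensated) trunk: shear the centerline linearly in z so T1
  # sits plumb over the superior endplate centroid of L5, the usual
  # compensated presentation in moderate AIS
  l5_sup <- cen[n, ] + frames[[n]][, 3] * bh[n] / 2
  delta <- l5_sup[1:2] - cen[1, 1:2]
  wgt <- (cen[, 3] - cen[n, 3]) / (cen[1, 3] - cen[n, 3])
  cen[, 1] <- cen[, 1] + wgt * delta[1]
  cen[, 2] <- cen[, 2] + wgt * delta[2]
  cen[, 1] <- cen[, 1] - mean(cen[, 1])   # tidy frame origin
  cen[, 2] <- cen[, 2] - mean(cen[, 2])

  pedL <- pedR <- matrix(0, n, 3)
  ped_off <- 18 * hscale  # lateral pedicle half-spacing
  ped_post <- 26 * hscale # posterior offset of pedicles from body centroid
  for (k in 1:n) {
    R <- frames[[k]]
    pedL[k, ] <- cen[k, ] + as.vector(R %*% c(-ped_post, +ped_off, 0))
    pedR[k, ] <- cen[k, ] + as.vector(R %*% c(-ped_post, -ped_off, 0))
  }

  pelvis_origin <- c(cen[n, 1], cen[n, 2], cen[n, 3] - bh[n] / 2 - 35 * hscale)

  # Skin: swept elliptical rings centered near the trunk axis, drawn laterally
  # toward the spinal deviation (gain < 1) with level-dependent radii.
  sc <- spec$trunk_height_mm / 460
  a_ap  <- stats::approx(c(1, 7, 13, 17), c(90, 95, 88, 98) * sc, xout = 1:n)$y
  b_lat <- stats::approx(c(1, 7, 13, 17), c(132, 126, 116, 142) * sc, xout = 1:n)$y
  phi <- seq(-pi, pi, length.out = n_phi + 1)[seq_len(n_phi)]
  verts <- matrix(0, n * n_phi, 3)
  ring_center <- matrix(0, n, 3)
  for (k in 1:n) {
    cx <- 0.3 * cen[k, 1] + 52 * sc   # skin axis sits anterior to the spine
    cy <- 0.9 * cen[k, 2]
    ring_center[k, ] <- c(cx, cy, cen[k, 3])
    idx <- (k - 1) * n_phi + seq_len(n_phi)
    verts[idx, ] <- cbind(cx + a_ap[k] * cos(phi), cy + b_lat[k] * sin(phi),
                          rep(cen[k, 3], n_phi))
  }
  tris <- skin_triangles(n, n_phi)

  structure(list(
    spec = spec, levels = lv,
    centroids = cen, frames = frames,
    ped_L = pedL, ped_R = pedR,
    body_height_mm = bh, disk_height_mm = dh,
    tilt_cor_deg = tilt_cor, tilt_sag_deg = tilt_sag, axial_deg = axial,
    pelvis = list(origin = pelvis_origin, frame = diag(3)),
    skin = list(verts = verts, tris = tris, n_ring = n, n_phi = n_phi,
                ring_center = ring_center, a_ap = a_ap, b_lat = b_lat,
                phi = phi)
  ), class = "trunk_anatomy")
}

skin_triangles <- function(n_ring, n_phi) {
  tris <- matrix(0L, 0, 3)
  for (k in seq_len(n_ring - 1)) {
    i0 <- (k - 1) * n_phi
    i1 <- k * n_phi
    j <- seq_len(n_phi)
    jn <- c(seq_len(n_phi)[-1], 1L)
    tris <- rbind(tris,
                  cbind(i0 + j, i1 + j, i0 + jn),
                  cbind(i0 + jn, i1 + j, i1 + jn))
  }
  tris
}

#' Generate a synthetic scoliotic trunk anatomy
#'
#' Builds a full `trunk_anatomy` (vertebral frames T1-L5, pedicles, pelvis
#' frame, swept-ellipse skin mesh) whose measured deformity metrics match the
#' requested specification.  The coronal centerline is a superposition of two
#' compact-support bumps (one per curve); the sagittal profile is a
#' shape-preserving spline through kyphosis/lordosis control tilts; axial
#' rotation is coupled to each coronal bump and scaled to the requested apical
#' rotations.  Amplitudes are solved by fixed-point iteration against the
#' package's own metric measurements, so the round trip
#' `generate_patient() |> measure_metrics()` reproduces the spec within 1 degree.
#'
#' @param spec A `patient_spec`.
#' @param n_phi Number of skin nodes per ring (>= 8).
#' @return An object of class `trunk_anatomy`.
#' @export
generate_patient <- function(spec, n_phi = 16L) {
  validate_patient_spec(spec)
  # canonical orientation: solve for a convex-right main thoracic curve and
  # mirror the result, so reflection equivariance is exact by construction
  if (spec$mt_dir > 0)
    return(mirror_anatomy(generate_patient(mirror_spec(spec), n_phi)))
  lv <- spine_levels()
  n <- length(lv)
  hscale <- spec$trunk_height_mm / sum(.body_heights0 + .disk_heights0)
  seg <- (.body_heights0 + .disk_heights0) * hscale
  zc <- rev(cumsum(rev(seg)))          # nominal centroid heights, T1 first
  if (spec$mt_cobb_deg > 80 || spec$tll_cobb_deg > 80)
    stop("requested Cobb angle cannot be realized for this trunk height")

  mt_i <- level_index(spec$mt_apex_level)
  tl_i <- level_index(spec$tll_apex_level)
  w_mt <- 4.0 * mean(seg[1:12])
  w_tl <- 3.6 * mean(seg)
  b_mt <- bump((zc - zc[mt_i]) / w_mt)
  b_tl <- bump((zc - zc[tl_i]) / w_tl)

  # Coronal model: a C1 tilt profile with zero tilt at both apices and at
  # the curve edges, and three extreme tilts -- u above the MT apex, t at
  # the shared transitional vertebra between the apices, l below the TL/L
  # apex.  Sharing t between the curves is what couples their Cobb angles
  # (the clinical end vertebra between adjacent curves is common to both);
  # the asymmetric split keeps any cohort combination of MT and TL/L
  # magnitudes realizable (e.g. a small thoracic with a large lumbar).
  # Canonical orientation (MT convex right): u > 0, t < 0, l > 0, with
  # MT = u - t and TLL = l - t in magnitude.
  coronal_tilt <- function(u, t_, l) {
    z_trans <- (zc[mt_i] + zc[tl_i]) / 2
    kz <- c(zc[1] + 80,
            min(zc[mt_i] + w_mt, zc[1] + 40),
            zc[mt_i] + w_mt / 2,
            zc[mt_i], z_trans, zc[tl_i],
            max(zc[tl_i] - w_tl / 2, zc[17] - 20),
            max(zc[tl_i] - w_tl, zc[17] - 45),
            zc[17] - 80)
    kv <- c(0, 0, u, 0, t_, 0, l, 0, 0)
    ord <- order(kz)
    keep <- c(TRUE, diff(kz[ord]) > 1)   # drop collided knots (clamping)
    f <- stats::splinefun(kz[ord][keep], kv[ord][keep], method = "monoH.FC")
    f(zc)
  }

  # sagittal control tilts (degrees) at knot levels; shape-preserving spline
  sag_profile <- function(tk, ll) {
    kz <- zc[c(level_index("T1"), level_index("T4"), level_index("T12"),
               level_index("L1"), level_index("L5"))]
    kv <- c(-tk / 2, -tk / 2, tk / 2, ll / 2, -ll / 2)
    f <- stats::splinefun(rev(kz), rev(kv), method = "monoH.FC")
    f(zc)
  }

  # initial extreme tilts from the target Cobb angles (transitional tilt
  # shared equally with the smaller curve)
  t_share <- -min(spec$mt_cobb_deg, spec$tll_cobb_deg) / 2
  u_amp <- spec$mt_cobb_deg + t_share
  l_amp <- spec$tll_cobb_deg + t_share
  tk_amp <- spec$tk_deg
  ll_amp <- spec$ll_deg
  r_mt <- spec$avr_mt_deg * spec$mt_dir
  r_tl <- spec$avr_tll_deg * spec$tll_dir

  # the apical windows see both rotation bumps (curves may overlap when the
  # apices are adjacent), so the two axial gains solve a linear 2 x 2 system
  win <- function(apex) max(1, apex - 1):min(length(lv), apex + 1)
  bm1 <- b_mt / max(b_mt)
  bm2 <- b_tl / max(b_tl)
  Maxial <- rbind(c(mean(bm1[win(mt_i)]), mean(bm2[win(mt_i)])),
                  c(mean(bm1[win(tl_i)]), mean(bm2[win(tl_i)])))
  tgt_axial <- c(spec$avr_mt_deg * spec$mt_dir, spec$avr_tll_deg * spec$tll_dir)
  rax <- if (abs(det(Maxial)) > 1e-3) as.vector(solve(Maxial, tgt_axial)) else
    c(r_mt, r_tl)
  axial_prof <- function() rax[1] * bm1 + rax[2] * bm2

  build <- function() {
    build_anatomy(spec, coronal_tilt(u_amp, t_share, l_amp),
                  sag_profile(tk_amp, ll_amp), axial_prof(), n_phi)
  }

  # fixed-point refinement: the spline evaluated at vertebra positions
  # slightly undershoots the knot extremes, so the extreme tilts (and the
  # sagittal/axial amplitudes) are corrected against the package's own
  # measurements; the best iterate is kept
  target <- c(spec$mt_cobb_deg, spec$tll_cobb_deg)
  best <- NULL
  best_err <- Inf
  for (it in 1:20) {
    anatomy <- build()
    ctx <- baseline_context(anatomy)
    m <- measure_metrics(anatomy, ctx)
    errs <- c(abs(abs(m$cobb_mt) - target[1]), abs(abs(m$cobb_tll) - target[2]),
              abs(m$tk - spec$tk_deg), abs(m$ll - spec$ll_deg),
              abs(abs(m$avr_mt) - spec$avr_mt_deg),
              abs(abs(m$avr_tll) - spec$avr_tll_deg))
    if (max(errs) < best_err) {
      best <- anatomy
      best_err <- max(errs)
    }
    if (best_err < 0.2) break

    adj <- function(t_, got) if (abs(got) < 1e-6 || t_ == 0) 1 else
      pmin(pmax(t_ / abs(got), 0.5), 2)
    tk_amp <- tk_amp * adj(spec$tk_deg, m$tk)
    ll_amp <- ll_amp * adj(spec$ll_deg, m$ll)
    if (abs(det(Maxial)) > 1e-3) {
      raw <- c(m$avr_mt * ctx$avr_sign_mt, m$avr_tll * ctx$avr_sign_tll)
      rax <- rax + as.vector(solve(Maxial, tgt_axial - raw))
    }
    du <- target[1] - abs(m$cobb_mt)
    dl <- target[2] - abs(m$cobb_tll)
    u_amp <- max(u_amp + pmin(pmax(du, -10), 10), 0)
    l_amp <- max(l_amp + pmin(pmax(dl, -10), 10), 0)
  }
  best
}

#' Mirror an anatomy about the sagittal (x-z) plane
#'
#' @param anatomy A `trunk_anatomy`.
#' @return The y-mirrored anatomy (left/right pedicles swapped, frames and
#'   rotations reflected).
#' @export
mirror_anatomy <- function(anatomy) {
  M <- diag(c(1, -1, 1))
  refl <- function(m) m %*% M
  out <- anatomy
  out$centroids <- refl(anatomy$centroids)
  out$ped_L <- refl(anatomy$ped_R)   # left/right swap under the mirror
  out$ped_R <- refl(anatomy$ped_L)
  out$frames <- lapply(anatomy$frames, function(R) {
    Rm <- M %*% R %*% M               # proper rotation again
    Rm
  })
  out$tilt_cor_deg <- -anatomy$tilt_cor_deg
  out$axial_deg <- -anatomy$axial_deg
  out$pelvis$origin <- as.vector(M %*% anatomy$pelvis$origin)
  # reflect skin and restore the canonical phi ordering (phi -> -phi)
  sv <- refl(anatomy$skin$verts)
  np <- anatomy$skin$n_phi
  perm <- c(1L, np:2L)
  for (k in seq_len(anatomy$skin$n_ring)) {
    idx <- (k - 1L) * np + seq_len(np)
    sv[idx, ] <- sv[idx[perm], ]
  }
  out$skin$verts <- sv
  out$skin$ring_center <- refl(anatomy$skin$ring_center)
  if (!is.null(out$spec)) out$spec <- mirror_spec(out$spec)
  out
}

#' Write an anatomy description to plain text
#'
#' One record per vertebra (level, centroid, pedicles, tilts, rotation, body
#' height), tab-separated, mm and degrees in the global frame, preceded by
#' `#`-commented pelvis and trunk metadata.  The skin mesh is written
#' separately with [write_stl()].
#'
#' @param anatomy A `trunk_anatomy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anatomy <- function(anatomy, path) {
  df <- data.frame(
    level = anatomy$levels,
    cx = anatomy$centroids[, 1], cy = anatomy$centroids[, 2],
    cz = anatomy$centroids[, 3],
    pedLx = anatomy$ped_L[, 1], pedLy = anatomy$ped_L[, 2],
    pedLz = anatomy$ped_L[, 3],
    pedRx = anatomy$ped_R[, 1], pedRy = anatomy$ped_R[, 2],
    pedRz = anatomy$ped_R[, 3],
    tilt_cor_deg = anatomy$tilt_cor_deg, tilt_sag_deg = anatomy$tilt_sag_deg,
    axial_deg = anatomy$axial_deg, body_height_mm = anatomy$body_height_mm
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trunk_anatomy; frame: x anterior, y left, z cranial; units mm, deg"), con)
  writeLines(sprintf("# pelvis_origin\t%.6f\t%.6f\t%.6f", anatomy$pelvis$origin[1],
                     anatomy$pelvis$origin[2], anatomy$pelvis$origin[3]), con)
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
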
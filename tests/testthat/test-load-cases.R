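test_that("stress combination is the exact affine formula", {
  m <- calibrated_model()
  st <- solve_static(m, nightbrace:::oob_load(m), increments = 1)
  f <- nightbrace:::plate_stress_field(m, st)
  f2 <- f
  f2$sigma_L <- f$sigma_L + 0.1
  f2$sigma_R <- f$sigma_R - 0.05

  expect_equal(combine_stresses(f, f2, 0)$sigma_L, f$sigma_L)
  expect_equal(combine_stresses(f, f, 0.7)$sigma_L, f$sigma_L)
  c3 <- combine_stresses(f, f2, 0.33)
  expect_equal(c3$sigma_L, f$sigma_L + 0.33 * 0.1)
  expect_equal(c3$sigma_m, (c3$sigma_L + c3$sigma_R) / 2)

  # scalar hand check: 0.10 + 0.33 * (0.40 - 0.10) = 0.199
  one <- f[1, ]
  a <- one; a$sigma_L <- 0.10; a$sigma_R <- 0.10
  b <- one; b$sigma_L <- 0.40; b$sigma_R <- 0.40
  expect_equal(combine_stresses(a, b, 0.33)$sigma_L, 0.199)
})

test_that("growth law reproduces its printed baseline and hand values", {
  mk <- function(level, sL, sR) {
    d <- data.frame(level = level, plate = "superior",
                    sigma_L = sL, sigma_R = sR)
    d$sigma_m <- (sL + sR) / 2
    d
  }
  gp <- growth_params()
  # sides at the plate mean: baseline rates
  r <- plate_growth_rates(mk("T8", -0.2, -0.2), gp)
  expect_equal(r$G_L, 0.8)
  r <- plate_growth_rates(mk("L2", -0.2, -0.2), gp)
  expect_equal(r$G_L, 1.1)
  # sigma_side - sigma_m = -1/beta: growth fully inhibited
  r <- plate_growth_rates(mk("T8", -1 / 1.5, 1 / 1.5), gp)
  expect_equal(r$G_L[r$level == "T8"], 0)
  # lumbar, sigma_L - sigma_m = -0.2 MPa -> 1.1 * (1 - 0.3) = 0.77
  r <- plate_growth_rates(mk("L1", -0.2, 0.2), gp)
  expect_equal(r$G_L, 1.1 * (1 - 1.5 * 0.2))
  expect_equal(r$G_L, 0.77)
  # mean preservation: (G_L + G_R)/2 = G_m
  r <- plate_growth_rates(mk("T5", -0.31, -0.07), gp)
  expect_equal((r$G_L + r$G_R) / 2, 0.8)
  # resorption floor
  r <- plate_growth_rates(mk("T8", -2, 2), growth_params(floor_zero = TRUE))
  expect_equal(r$G_L, 0)
})

test_that("standing simulation compresses plates, concave side most", {
  m <- calibrated_model()            # MT convex right -> concave on the left
  r <- simulate_oob(m)
  expect_equal(r$configuration, "OOB")
  ps <- r$plate_stresses
  expect_true(all(ps$sigma_m < 0))   # all plates compressed under gravity
  apx <- ps[ps$level == m$anatomy$spec$mt_apex_level, ]
  expect_true(all(apx$sigma_L < apx$sigma_R))
  expect_lt(r$state$residual_rel, 1e-6)
})

test_that("massless trunk carries no standing stress", {
  a <- symmetric_patient()
  m0 <- assemble_model(a)
  m0$masses[] <- 0
  mc <- calibrate_standing(m0)
  r <- simulate_oob(mc)
  expect_lt(max(abs(r$plate_stresses$sigma_m)), 1e-9)
  expect_lt(max(abs(r$anatomy$centroids - a$centroids)), 1e-6)
})

test_that("a cleared brace exerts no influence on the spine", {
  fx <- initial_brace_fixture()
  m <- calibrated_model()
  sh_far <- finalize_brace(apply_offsets(fx$bp, fx$grid, rep(25, 36)),
                           fx$grid, smoother = fx$smoother,
                           strap_tension_N = 0)
  # weightless torso, slack straps, inflated shell: exact no-contact limit
  m0 <- m
  m0$masses[] <- 0
  ib0 <- simulate_inbrace(m0, sh_far)
  expect_equal(max(ib0$pressures_kpa), 0)
  expect_lt(max(abs(ib0$state$u)), 1e-9)

  # under gravity the sagging torso may graze the shell edges, but the
  # spine must track the unbraced supine solution closely
  ib_far <- simulate_inbrace(m, sh_far)
  pr <- m$params
  skin_nodes <- as.vector(t(m$idx_skin))
  areas <- as.vector(t(m$skin_area))
  mat <- contact_plane(c(min(m$nodes[skin_nodes, 1]), 0, 0), c(1, 0, 0),
                       skin_nodes, pr$mattress_E / pr$mattress_depth, areas)
  free <- solve_static(m, load_case(
    gravity = c(-1, 0, 0),
    fixed = rbind(data.frame(node = m$idx_pelvis, comp = 1:6, value = 0),
                  data.frame(node = 1L, comp = 2:3, value = 0)),
    contacts = list(mat)), increments = 6)
  dv <- ib_far$state$positions[m$idx_cen, ] - free$positions[m$idx_cen, ]
  expect_lt(max(abs(dv)), 5)
  expect_lt(max(ib_far$pressures_kpa), 20)
})

test_that("symmetric patient in a symmetric brace stays symmetric", {
  ms <- calibrated_symmetric_model()
  oc <- find_max_overcorrection(ms)
  bp <- trim_initial_brace(oc$deformed_skin, structure(list(
    h_top = function(phi) rep(max(oc$deformed_skin$verts[, 3]) - 20, length(phi)),
    h_bot = function(phi) rep(min(oc$deformed_skin$verts[, 3]) + 20, length(phi)),
    convex_side = "right"), class = "trim_profile"))
  g <- build_patch_grid(bp)
  sh <- finalize_brace(bp, g, smoother = smoothing_operator(bp, g))
  ib <- simulate_inbrace(ms, sh)
  uy <- ib$state$u[nightbrace:::dof_of(ms$idx_cen, 2)]
  expect_lt(max(abs(uy)), 1e-4)
})

test_that("tightening straps presses the torso into the shell monotonically", {
  # the strap band pushes the anterior skin posteriorly, so the maximum gap
  # between skin and the load-bearing (posterior/lateral) shell must be
  # non-increasing with tension
  fx <- initial_brace_fixture()
  m <- calibrated_model()
  gap_at <- function(tension) {
    sh <- finalize_brace(apply_offsets(fx$bp, fx$grid, rep(0, 36)), fx$grid,
                         smoother = fx$smoother, strap_tension_N = tension)
    ib <- simulate_inbrace(m, sh)
    pos <- ib$state$positions[as.vector(t(m$idx_skin)), ]
    phi <- atan2(pos[, 2] - sh$axis[2], pos[, 1] - sh$axis[1])
    rho <- sqrt((pos[, 1] - sh$axis[1])^2 + (pos[, 2] - sh$axis[2])^2)
    rr <- sh$rho_fun(pos[, 3], phi)
    post <- which(!is.na(rr$rho) & rr$w > 0.99 & cos(phi) < 0)
    max(rr$rho[post] - rho[post])
  }
  gaps <- vapply(c(0, 15, 30, 45, 60), gap_at, numeric(1))
  expect_true(all(diff(gaps) <= 1e-3))
})

test_that("growth simulation respects its limiting cases", {
  m <- calibrated_model()
  r <- simulate_oob(m)
  ctx <- baseline_context(m$anatomy)

  # zero duration: nothing changes
  rates <- plate_growth_rates(r$plate_stresses)
  pg0 <- simulate_growth(m, rates, growth_params(duration_years = 0),
                         resolve = FALSE)
  expect_equal(pg0$anatomy$centroids, m$anatomy$centroids)

  # uniform stresses: symmetric growth, Cobb essentially unchanged
  u <- r$plate_stresses
  u$sigma_L <- -0.2; u$sigma_R <- -0.2; u$sigma_m <- -0.2
  pg_u <- simulate_growth(m, plate_growth_rates(u), resolve = FALSE)
  d <- abs(measure_metrics(pg_u$anatomy, ctx)$cobb_mt -
             measure_metrics(m$anatomy, ctx)$cobb_mt)
  expect_lt(d, 0.5)
})

test_that("untreated curves progress; symmetrized stresses halt progression", {
  m <- calibrated_model()
  ctx <- baseline_context(m$anatomy)
  mt0 <- abs(measure_metrics(m$anatomy, ctx)$cobb_mt)
  oob <- simulate_oob(m)

  # no brace: sigma combination reduces to the OOB field (C * 0 = 0)
  untreated <- combine_stresses(oob$plate_stresses, oob$plate_stresses, 0.33)
  pg_u <- simulate_growth(m, plate_growth_rates(untreated))
  mt_u <- abs(measure_metrics(pg_u$anatomy, ctx)$cobb_mt)
  expect_gt(mt_u, mt0 + 0.5)           # vicious-cycle progression

  # perfectly symmetrizing stress field: no left/right growth difference
  sym <- oob$plate_stresses
  sym$sigma_L <- sym$sigma_m; sym$sigma_R <- sym$sigma_m
  pg_s <- simulate_growth(m, plate_growth_rates(combine_stresses(
    oob$plate_stresses, sym, 1)))
  mt_s <- abs(measure_metrics(pg_s$anatomy, ctx)$cobb_mt)
  expect_lt(abs(mt_s - mt0), 1.5)
  expect_lt(mt_s, mt_u)
})
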
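test_that("model assembly produces the expected node/element structure", {
  a <- default_patient()
  m <- assemble_model(a)
  expect_equal(m$n_nodes, 17 * 3 + 17 * 16 + 1)
  # one skin ring of >= 16 nodes per level
  expect_equal(dim(m$idx_skin), c(17, 16))
  expect_error(assemble_model(a, flexibility_factor = -1))
})

test_that("global stiffness is symmetric with six rigid-body modes", {
  m <- nightbrace:::cache_stiffness(assemble_model(symmetric_patient()))
  K <- nightbrace:::model_stiffness(m)
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
  sk <- nightbrace:::skin_rot_dofs(m)
  free <- setdiff(seq_len(m$ndof), sk)
  ev <- eigen(as.matrix(K[free, free]), symmetric = TRUE,
              only.values = TRUE)$values
  # six rigid modes (rotational ones scale with geometry^2, ~1e-4), clearly
  # separated from the softest elastic skin modes (~4e-2)
  expect_equal(sum(abs(ev) < 1e-3), 6)
  expect_true(all(ev > -1e-6))                 # positive semi-definite
})

test_that("flexibility factor divides disk stiffness", {
  a <- default_patient()
  m1 <- assemble_model(a, flexibility_factor = 1)
  m2 <- assemble_model(a, flexibility_factor = 2)
  d1 <- m1$elements[[1]]
  d2 <- m2$elements[[1]]
  expect_equal(d1$EI / d2$EI, 2)
  expect_equal(d1$EA / d2$EA, 2)
})

test_that("zero load gives zero displacement and tiny residual", {
  m <- nightbrace:::cache_stiffness(assemble_model(default_patient()))
  st <- solve_static(m, load_case(
    fixed = data.frame(node = m$idx_pelvis, comp = 1:6, value = 0)),
    increments = 1)
  expect_equal(max(abs(st$u)), 0)
})

test_that("tip-loaded cantilever matches the Euler-Bernoulli closed form", {
  nseg <- 10; L <- 300; EI <- 2.9e6
  mini <- nightbrace:::cache_stiffness(cantilever_model(nseg, L, EI = EI))
  f <- matrix(0, nseg + 1, 3)
  f[nseg + 1, 2] <- 10
  st <- solve_static(mini, load_case(
    forces = f, fixed = data.frame(node = 1, comp = 1:6, value = 0)),
    increments = 1)
  tip <- st$u[nightbrace:::dof_of(nseg + 1, 2)]
  expect_equal(tip, 10 * L^3 / (3 * EI), tolerance = 0.05)
  expect_lt(st$residual_rel, 1e-6)
})

test_that("symmetric patient under gravity stays in the sagittal plane", {
  m <- calibrated_symmetric_model()
  st <- solve_static(m, nightbrace:::oob_load(m), increments = 1)
  uy_vert <- st$u[nightbrace:::dof_of(m$idx_cen, 2)]
  expect_lt(max(abs(uy_vert)), 1e-6)
  expect_lt(max(abs(m$muscle_forces$force_N[m$muscle_forces$component == "y"])),
            1e-6)
  ps <- nightbrace:::plate_stress_field(m, st)
  expect_lt(max(abs(ps$sigma_L - ps$sigma_R)), 1e-6)
})

test_that("standing calibration reproduces the target anatomy", {
  m <- calibrated_model()
  expect_true(m$calibrated)
  expect_lte(m$calibration_rms_mm, 2)
  st <- solve_static(m, nightbrace:::oob_load(m), increments = 1)
  err <- st$positions[m$idx_cen, ] - m$target_positions[m$idx_cen, ]
  expect_lte(sqrt(mean(rowSums(err^2))), 2)
  expect_true(all(abs(m$muscle_forces$force_N) <= 200))
})

test_that("massless model calibrates to zero muscle forces", {
  a <- symmetric_patient()
  a$spec$trunk_mass_kg <- 1e-12
  m0 <- assemble_model(a)
  m0$masses[] <- 0
  mc <- calibrate_standing(m0)
  expect_lt(max(abs(mc$muscle_forces$force_N)), 1e-9)
  expect_lt(max(abs(mc$nodes - m0$nodes)), 1e-9)
})

test_that("penalty contact is consistent under stiffness refinement", {
  # plane squeezed against a cantilever: doubling the penalty stiffness
  # changes the total contact force by < 5 %
  nseg <- 6
  mini <- nightbrace:::cache_stiffness(cantilever_model(nseg, 300))
  f <- matrix(0, nseg + 1, 3)
  f[nseg + 1, 2] <- 50
  run <- function(kfac) {
    ct <- contact_plane(point = c(0, 5, 0), normal = c(0, -1, 0),
                        nodes = seq_len(nseg + 1),
                        k_per_area = 50 * kfac, areas = rep(1, nseg + 1))
    st <- solve_static(mini, load_case(
      forces = f, fixed = data.frame(node = 1, comp = 1:6, value = 0),
      contacts = list(ct)), increments = 4, donning_ramp = FALSE)
    sum(abs(st$f_contact[, 2]))
  }
  f1 <- run(1); f2 <- run(2)
  expect_gt(f1, 0)
  expect_lt(abs(f2 - f1) / f1, 0.05)
})

test_that("contact pressures are non-negative and zero without contact", {
  m <- calibrated_model()
  skin_nodes <- as.vector(t(m$idx_skin))
  areas <- as.vector(t(m$skin_area))
  # plane far away: no contact at all
  ct <- contact_plane(point = c(-1e4, 0, 0), normal = c(1, 0, 0),
                      nodes = skin_nodes, k_per_area = 0.01, areas = areas)
  st <- solve_static(m, load_case(
    gravity = c(0, 0, -1), forces = NULL,
    fixed = data.frame(node = m$idx_pelvis, comp = 1:6, value = 0),
    contacts = list(ct)), increments = 1)
  expect_true(all(contact_pressures(st, 1) == 0))
})

test_that("doubling skin ring resolution barely changes the simulated Cobb", {
  spec <- patient_spec()
  a16 <- generate_patient(spec, n_phi = 16L)
  a32 <- generate_patient(spec, n_phi = 32L)
  run <- function(a) {
    m <- calibrate_standing(assemble_model(a))
    r <- simulate_oob(m)
    measure_metrics(r$anatomy, baseline_context(a))$cobb_mt
  }
  expect_lt(abs(run(a16) - run(a32)), 2)
})
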
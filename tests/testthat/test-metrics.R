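test_that("Cobb angle matches the analytic arc oracle", {
  # circular coronal arc subtending 35 degrees between the end vertebrae:
  # per-vertebra tilt varies linearly from +17.5 to -17.5 degrees
  a <- symmetric_patient()
  n <- 17
  tilt <- seq(17.5, -17.5, length.out = n)
  b <- nightbrace:::build_anatomy(a$spec, tilt, rep(0, n), rep(0, n))
  expect_lt(abs(cobb_angle(b, c("T1", "L5")) - 35), 0.5)
  # straight spine
  expect_lt(cobb_angle(a, c("T5", "T11")), 1e-9)
})

test_that("sagittal angles decouple from coronal deformity", {
  a <- generate_patient(patient_spec(tk_deg = 27, ll_deg = 42))
  sg <- sagittal_angles(a)
  expect_equal(unname(sg["tk"]), 27, tolerance = 1)
  expect_equal(unname(sg["ll"]), 42, tolerance = 1)
  # pure coronal deformity, flat sagittal profile
  flat <- generate_patient(patient_spec(tk_deg = 0, ll_deg = 0))
  sgf <- sagittal_angles(flat)
  expect_lt(abs(sgf["tk"]), 0.5)
  expect_lt(abs(sgf["ll"]), 0.5)
})

test_that("apical rotation is the mean over apex +/- 1", {
  a <- symmetric_patient()
  n <- 17
  axial <- rep(0, n)
  axial[nightbrace:::level_index(c("T7", "T8", "T9"))] <- c(4, 6, 5)
  b <- nightbrace:::build_anatomy(a$spec, rep(0, n), rep(0, n), axial)
  expect_equal(avr(b, "T8"), 5, tolerance = 0.2)
  expect_equal(avr(a, "T8"), 0, tolerance = 1e-9)
})

test_that("normal-range clamping follows the documented branches", {
  expect_equal(clamp_normal(16, c(20, 40)), 20)
  expect_equal(clamp_normal(30, c(20, 40)), 30)
  expect_equal(clamp_normal(70, c(30, 60)), 60)
})

test_that("deformity score reproduces hand-evaluated cases", {
  w <- objective_weights()
  mk <- function(mt, tll, tk, ll, amt, atll)
    structure(list(cobb_mt = mt, cobb_tll = tll, tk = tk, ll = ll,
                   avr_mt = amt, avr_tll = atll), class = "deformity_metrics")
  ini <- mk(28, 31, 27, 42, 5, 8)     # sagittal values inside normal ranges

  # unchanged deformity: coronal 2*(1+1), sagittal 0 (both in range),
  # transverse 1*(1+1) -> 6
  expect_equal(deformity_term(ini, ini, w), 6)
  # perfect correction with in-range sagittal -> 0
  perfect <- mk(0, 0, 30, 45, 0, 0)
  expect_equal(deformity_term(perfect, ini, w), 0)
  # halving only the coronal ratios drops the coronal contribution 4 -> 2
  half <- mk(14, 15.5, 27, 42, 5, 8)
  expect_equal(deformity_term(half, ini, w), 4)
  # flattened kyphosis (16 deg, below the 20-40 range): numerator
  # |16 - 20| = 4, denominator |27 - 20| = 7, so phi = 6 + 4/7
  flat <- mk(28, 31, 16, 42, 5, 8)
  expect_equal(deformity_term(flat, ini, w), 6 + 4 / 7)
  # presenting sagittal value on the reference itself: denominator floored
  ini2 <- mk(28, 31, 20, 42, 5, 8)
  expect_equal(deformity_term(flat, ini2, w), 6 + 4 / 1)
})

test_that("objective assembles with the printed weights", {
  w <- objective_weights()
  expect_equal(w$w_ib, 5)
  expect_equal(w$w_pg, 10)
  sc <- objective(0, 0, w)
  expect_equal(sc$value, 0)
  sc <- objective(6, 6, w)
  expect_equal(sc$value, 90)
  sc2 <- objective(6, 6, objective_weights(w_pg = 20))
  expect_equal(sc2$value - sc$value, 60)  # doubling w_pg doubles only its term
})

test_that("pressure feasibility thresholds at 450 kPa", {
  expect_true(check_pressure(numeric(0))$feasible)
  expect_true(check_pressure(c(10, 449.9))$feasible)
  expect_false(check_pressure(c(10, 451))$feasible)
  sc <- objective(1, 1, max_pressure_kpa = 451)
  expect_false(sc$feasible)
})
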
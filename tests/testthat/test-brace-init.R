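test_that("mirroring displacements follow the sagittal-reflection formula", {
  a <- default_patient()
  ks <- nightbrace:::level_index("T2"):nightbrace:::level_index("L4")

  # W = 0: undeformed
  d0 <- mirror_displacements(a, 0)
  expect_true(all(abs(d0[, c("ux", "uy", "uz")]) == 0))

  # W = 0.5: displaced pedicles are symmetric about the sagittal plane
  d5 <- mirror_displacements(a, 0.5)
  L5d <- a$ped_L[ks, 2] + d5$uy[d5$side == "L"]
  R5d <- a$ped_R[ks, 2] + d5$uy[d5$side == "R"]
  expect_lt(max(abs(L5d + R5d)), 1e-9)

  # W = 1: coordinates fully swapped/mirrored
  d1 <- mirror_displacements(a, 1)
  expect_equal(a$ped_L[ks, 1] + d1$ux[d1$side == "L"], a$ped_R[ks, 1])
  expect_equal(a$ped_L[ks, 2] + d1$uy[d1$side == "L"], -a$ped_R[ks, 2])
  expect_equal(a$ped_L[ks, 3] + d1$uz[d1$side == "L"], a$ped_R[ks, 3])

  expect_error(mirror_displacements(a, 1.2))
})

test_that("mirroring at W = 1 is an involution", {
  a <- default_patient()
  ks <- nightbrace:::level_index("T2"):nightbrace:::level_index("L4")
  d1 <- mirror_displacements(a, 1)
  b <- a
  b$ped_L[ks, ] <- a$ped_L[ks, ] +
    cbind(d1$ux[d1$side == "L"], d1$uy[d1$side == "L"], d1$uz[d1$side == "L"])
  b$ped_R[ks, ] <- a$ped_R[ks, ] +
    cbind(d1$ux[d1$side == "R"], d1$uy[d1$side == "R"], d1$uz[d1$side == "R"])
  d2 <- mirror_displacements(b, 1)
  b$ped_L[ks, ] <- b$ped_L[ks, ] +
    cbind(d2$ux[d2$side == "L"], d2$uy[d2$side == "L"], d2$uz[d2$side == "L"])
  b$ped_R[ks, ] <- b$ped_R[ks, ] +
    cbind(d2$ux[d2$side == "R"], d2$uy[d2$side == "R"], d2$uz[d2$side == "R"])
  expect_lt(max(abs(b$ped_L[ks, ] - a$ped_L[ks, ])), 1e-9)
  expect_lt(max(abs(b$ped_R[ks, ] - a$ped_R[ks, ])), 1e-9)
})

test_that("over-correction search behaves at the extremes", {
  # already-straight spine: mirroring is the identity, skin unchanged
  ms <- calibrated_symmetric_model()
  oc <- find_max_overcorrection(ms)
  expect_equal(oc$W_max, 1)
  d0 <- max(abs(oc$deformed_skin$verts - ms$anatomy$skin$verts))
  expect_lt(d0, 0.1)

  # zero distortion threshold stops immediately
  m <- calibrated_model()
  oc0 <- find_max_overcorrection(m, distortion_threshold = 0)
  expect_equal(oc0$W_max, 0)
  expect_lt(max(abs(oc0$deformed_skin$verts - m$anatomy$skin$verts)), 1e-9)
})

test_that("over-correction reduces then inverts skin lateral asymmetry", {
  fx <- initial_brace_fixture()
  m <- calibrated_model()
  a <- m$anatomy
  np <- a$skin$n_phi
  apex <- nightbrace:::level_index(a$spec$mt_apex_level)
  ring_y <- function(verts, k) mean(verts[(k - 1) * np + seq_len(np), 2])
  y0 <- ring_y(a$skin$verts, apex)
  expect_lt(y0, 0)                      # convex right: skin drawn to -y
  dist <- fx$oc$distortion
  expect_true(all(diff(dist$max_strain) > 0))   # distortion grows with W
  yW <- ring_y(fx$oc$deformed_skin$verts, apex)
  expect_lt(abs(yW), abs(y0) + 0.5)     # asymmetry reduced (or inverted)
})

test_that("trimming respects the azimuthal height profiles", {
  fx <- initial_brace_fixture()
  skin <- fx$oc$deformed_skin
  zr <- range(skin$verts[, 3])

  const_prof <- structure(list(
    h_top = function(phi) rep(zr[1] + 0.8 * diff(zr), length(phi)),
    h_bot = function(phi) rep(zr[1] + 0.2 * diff(zr), length(phi)),
    convex_side = "right"), class = "trim_profile")
  bp <- trim_initial_brace(skin, const_prof)
  z <- bp$z[bp$keep]
  expect_gte(min(z), zr[1] + 0.2 * diff(zr))
  expect_lte(max(z), zr[1] + 0.8 * diff(zr))

  full_prof <- structure(list(
    h_top = function(phi) rep(zr[2] + 1, length(phi)),
    h_bot = function(phi) rep(zr[1] - 1, length(phi)),
    convex_side = "right"), class = "trim_profile")
  expect_true(all(trim_initial_brace(skin, full_prof)$keep))

  bad <- structure(list(
    h_top = function(phi) rep(zr[1], length(phi)),
    h_bot = function(phi) rep(zr[2], length(phi)),
    convex_side = "right"), class = "trim_profile")
  expect_error(trim_initial_brace(skin, bad), "inverted")
})

test_that("default trim is taller on the thoracic convex side", {
  m <- calibrated_model()
  a <- m$anatomy                        # MT convex right
  tp <- trim_profile_default(a)
  expect_equal(tp$convex_side, "right")
  expect_gt(tp$h_top(-pi / 2), tp$h_top(pi / 2))  # right flank taller
  fx <- initial_brace_fixture()
  right <- fx$bp$keep & sin(fx$bp$phi) < -0.5
  left <- fx$bp$keep & sin(fx$bp$phi) > 0.5
  expect_gt(max(fx$bp$z[right]), max(fx$bp$z[left]))
})
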
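make_cylinder <- function(n_ring = 30, n_phi = 60, R = 100, H = 300) {
  # offset keeps points off the patch-grid bin edges
  phi <- seq(-pi, pi, length.out = n_phi + 1)[seq_len(n_phi)] + 0.013
  z <- seq(0, H, length.out = n_ring)
  verts <- cbind(R * cos(rep(phi, n_ring)), R * sin(rep(phi, n_ring)),
                 rep(z, each = n_phi))
  nightbrace:::brace_points(verts, axis = c(0, 0),
                            n_ring = n_ring, n_phi = n_phi)
}

test_that("patch grid is a deterministic 6 x 6 partition", {
  cyl <- make_cylinder()
  g <- build_patch_grid(cyl)
  expect_equal(g$nz * g$nphi, 36)
  expect_length(g$z_edges, 7)
  expect_length(g$phi_edges, 7)
  pts <- nightbrace:::brace_xyz(cyl)
  idx <- g$patch_index(pts)
  expect_true(all(idx >= 1 & idx <= 36))
  # uniform cylinder: every patch holds 1/36 of points within 20 %
  counts <- tabulate(idx, 36)
  expect_true(all(abs(counts - nrow(pts) / 36) <= 0.2 * nrow(pts) / 36))
  g2 <- build_patch_grid(cyl)
  expect_identical(g$z_edges, g2$z_edges)
})

test_that("rotating the cloud by one sector shifts phi-bin membership", {
  cyl <- make_cylinder()
  g <- build_patch_grid(cyl)
  pts <- nightbrace:::brace_xyz(cyl)
  th <- 2 * pi / 6
  rot <- cbind(pts[, 1] * cos(th) - pts[, 2] * sin(th),
               pts[, 1] * sin(th) + pts[, 2] * cos(th), pts[, 3])
  i0 <- g$patch_index(pts)
  i1 <- g$patch_index(rot)
  ip0 <- (i0 - 1) %% 6
  ip1 <- (i1 - 1) %% 6
  expect_true(all((ip0 + 1) %% 6 == ip1 %% 6))
  expect_equal((i0 - 1) %/% 6, (i1 - 1) %/% 6)  # z band unchanged
})

test_that("rho offsets displace exactly their patch, radially", {
  cyl <- make_cylinder()
  g <- build_patch_grid(cyl)
  expect_identical(apply_offsets(cyl, g, rep(0, 36))$rho, cyl$rho)

  rho <- rep(0, 36); rho[14] <- -10
  out <- apply_offsets(cyl, g, rho)
  idx <- g$patch_index(cyl$verts)
  expect_true(all(out$rho[idx == 14] == cyl$rho[idx == 14] - 10))
  expect_true(all(out$rho[idx != 14] == cyl$rho[idx != 14]))
  expect_identical(out$phi, cyl$phi)
  expect_identical(out$z, cyl$z)

  infl <- apply_offsets(cyl, g, rep(25, 36))
  expect_true(all(infl$rho - cyl$rho == 25))

  expect_error(apply_offsets(cyl, g, rep(26, 36)), "within")
  expect_error(apply_offsets(cyl, g, rep(0, 35)), "length")
})

test_that("finalize smooths, opens 20 degrees and places straps", {
  cyl <- make_cylinder(H = 400)
  g <- build_patch_grid(cyl)
  sm <- smoothing_operator(cyl, g)

  # constant field is a fixed point of the smoother
  sh0 <- finalize_brace(cyl, g, smoother = sm)
  expect_lt(max(abs(sh0$points$rho[sh0$points$keep] - 100)), 1e-9)

  # opening removes exactly the |phi| < 10 degree points
  kept <- sh0$points$keep
  expect_true(all(abs(cyl$phi[kept]) >= nightbrace:::deg2rad(10) - 1e-12))
  removed <- cyl$keep & !kept
  expect_true(all(abs(cyl$phi[removed]) < nightbrace:::deg2rad(10)))

  # 400 mm tall -> 3 straps at 0.25 / 0.5 / 0.75 of the height
  expect_equal(nrow(sh0$straps), 3)
  zr <- range(cyl$z[kept])
  ring_dz <- diff(zr) / (cyl$n_ring - 1)
  expect_true(all(abs(sh0$straps$left_z - (zr[1] + c(.25, .5, .75) * diff(zr)))
                  <= ring_dz + 1e-9))
  # short brace -> 2 straps
  short <- make_cylinder(H = 300)
  gs <- build_patch_grid(short)
  sh2 <- finalize_brace(short, gs, smoother = smoothing_operator(short, gs))
  expect_equal(nrow(sh2$straps), 2)
  expect_equal(sh2$straps$tension_N, c(60, 60))

  # points already outside the arc: opening removes nothing
  side <- make_cylinder()
  side$keep <- abs(side$phi) >= nightbrace:::deg2rad(10)
  shs <- finalize_brace(side, build_patch_grid(side), )
  expect_equal(sum(shs$points$keep), sum(side$keep))
})

test_that("offsets and smoothing commute with vertical translation", {
  cyl <- make_cylinder()
  g <- build_patch_grid(cyl)
  rho <- sin(seq_len(36)) * 10
  a <- finalize_brace(apply_offsets(cyl, g, rho), g,
                      smoother = smoothing_operator(cyl, g))

  shifted <- cyl
  shifted$verts[, 3] <- shifted$verts[, 3] + 57
  shifted$z <- shifted$z + 57
  g2 <- build_patch_grid(shifted)
  b <- finalize_brace(apply_offsets(shifted, g2, rho), g2,
                      smoother = smoothing_operator(shifted, g2))
  expect_lt(max(abs(a$points$rho - b$points$rho)), 1e-9)
  expect_identical(a$points$keep, b$points$keep)
})

test_that("the brace surface interpolator tracks the points", {
  cyl <- make_cylinder()
  g <- build_patch_grid(cyl)
  rho <- rep(c(-10, 0, 10, 0, -5, 5), 6)
  sh <- finalize_brace(apply_offsets(cyl, g, rho), g,
                       smoother = smoothing_operator(cyl, g))
  bp <- sh$points
  sel <- which(bp$keep)[seq(1, sum(bp$keep), by = 17)]
  pred <- sh$rho_fun(bp$z[sel], bp$phi[sel])$rho
  expect_lt(max(abs(pred - bp$rho[sel]), na.rm = TRUE), 0.5)
  # off the shell (inside the opening) the surface carries no stiffness
  mid <- sh$rho_fun(mean(bp$z), 0)
  expect_equal(mid$w, 0)
})
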
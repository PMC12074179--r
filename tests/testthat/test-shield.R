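test_that("a zero coil source induces no shield response", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 9)
  panel <- shield_panel(c(0, 0, -1), c(0, 0, 1), 1.5, 11)
  sys <- shield_system(mesh, panel)
  s0 <- stream_function(numeric(nrow(mesh$vertices)), mesh)
  expect_equal(max(abs(solve_shield_response(sys, s0))), 0)
  expect_gte(sys$condition, 1)
})

test_that("the equipotential condition is satisfied after the solve", {
  th <- seq(0, 2 * pi, length.out = 121)
  loop <- list(cbind(0.25 * cos(th), 0.25 * sin(th), 0.3))
  panel <- shield_panel(c(0, 0, 0), c(0, 0, 1), 1.2, 21)
  sys <- shield_system(build_biplanar_mesh(1, 1, 5), panel)
  u_coil <- polyline_potential(loop, 1, sys$shield_points)
  s_sh <- solve_shield_response(sys, loop)
  resid <- u_coil + drop(sys$CU_shield %*% s_sh)
  expect_lt(max(abs(resid)), 1e-8 * max(abs(u_coil)))
})

test_that("a shield far away leaves the field unchanged", {
  th <- seq(0, 2 * pi, length.out = 101)
  loop <- list(cbind(0.3 * cos(th), 0.3 * sin(th), 0.2))
  panel <- shield_panel(c(0, 0, -100 * 0.5), c(0, 0, 1), 60, 9)
  sys <- shield_system(build_biplanar_mesh(1, 1, 5), panel)
  pts <- rbind(c(0, 0, 0.5), c(0.1, 0, 0.3))
  B0 <- polyline_field(loop, 1, pts)
  Bs <- shielded_field(sys, loop, pts, current = 1)
  expect_lt(max(abs(Bs - B0)) / max(sqrt(rowSums(B0^2))), 1e-3)
})

test_that("an infinite-permeability plane reproduces the method of images", {
  R_l <- 0.2; h <- 0.3
  th <- seq(0, 2 * pi, length.out = 181)
  loop <- list(cbind(R_l * cos(th), R_l * sin(th), h))
  image <- list(cbind(R_l * cos(th), R_l * sin(th), -h))  # co-rotating
  panel <- shield_panel(c(0, 0, 0), c(0, 0, 1), 1.5, 61)
  sys <- shield_system(build_biplanar_mesh(1, 1, 5), panel)
  pts <- rbind(c(0, 0, 0.5), c(0.15, 0, 0.45), c(0, 0.2, 0.6),
               c(-0.1, -0.1, 0.35), c(0.25, 0.1, 0.5))
  B_model <- shielded_field(sys, loop, pts, current = 1)
  B_images <- polyline_field(loop, 1, pts) + polyline_field(image, 1, pts)
  err <- sqrt(rowSums((B_model - B_images)^2)) / sqrt(rowSums(B_images^2))
  expect_lt(max(err), 0.03)
})

test_that("the shield response is linear in the coil source", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 17)
  panel <- shield_panel(c(0, -0.7, 0), c(0, 1, 0), 1.5, 17)
  sys <- shield_system(mesh, panel)
  s1 <- as.numeric(disk_stream(mesh, 0.3))
  s2 <- as.numeric(disk_stream(mesh, 0.2, current = -0.5))
  f1 <- solve_shield_response(sys, stream_function(s1, mesh))
  f2 <- solve_shield_response(sys, stream_function(s2, mesh))
  f12 <- solve_shield_response(sys, stream_function(s1 + s2, mesh))
  expect_equal(f12, f1 + f2, tolerance = 1e-10)
})

test_that("shielded efficiency reduces to free space without a shield and responds to distance", {
  d <- small_design("By")
  eff_free <- shielded_efficiency(d$coil, NULL, "By")
  expect_equal(as.numeric(eff_free), as.numeric(d$efficiency))

  deltas <- vapply(c(0.4, 0.2, 0.1), function(off) {
    p <- shield_panel(c(0, -d$mesh$plane_size / 2 - off, 0), c(0, 1, 0),
                      2.1, 21)
    sys <- shield_system(d$mesh, p)
    as.numeric(d$efficiency) -
      as.numeric(shielded_efficiency(d$coil, sys, "By"))
  }, 0)
  # a mu-metal floor below the coil lowers the y-field efficiency, more so
  # the closer it is
  expect_true(all(deltas > 0))
  expect_true(all(diff(deltas) > 0))
})

test_that("a symmetric shield box raises the z-coil efficiency", {
  d <- small_design("Bz")
  hs <- 1.2; ext <- 1.15; res <- 11
  panels <- list(
    shield_panel(c(0, -hs, 0), c(0, 1, 0), ext, res),
    shield_panel(c(0, hs, 0), c(0, -1, 0), ext, res),
    shield_panel(c(-hs, 0, 0), c(1, 0, 0), ext, res),
    shield_panel(c(hs, 0, 0), c(-1, 0, 0), ext, res),
    shield_panel(c(0, 0, -hs), c(0, 0, 1), ext, res),
    shield_panel(c(0, 0, hs), c(0, 0, -1), ext, res))
  sys <- shield_system(d$mesh, panels)
  eff_box <- shielded_efficiency(d$coil, sys, "Bz")
  expect_gt(as.numeric(eff_box), as.numeric(d$efficiency))
  # the symmetric enclosure preserves the even symmetry of Bz in z
  pts <- rbind(c(0, 0, 0.1), c(0, 0, -0.1))
  s_sh <- solve_shield_response(sys, d$coil, current = 1e-3)
  Bsh <- field_of_stream(field_coupling(sys$shield_mesh, pts), s_sh)
  expect_equal(Bsh[1, 3], Bsh[2, 3], tolerance = 0.05)
})
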
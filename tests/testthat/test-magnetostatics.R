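MU0 <- 4e-7 * pi

test_that("polyline Biot-Savart reproduces the square and circular loop closed forms", {
  a <- 0.8; I <- 2
  B <- polyline_field(list(square_loop(a)), I, c(0, 0, 0))
  expect_equal(B[3], 2 * sqrt(2) * MU0 * I / (pi * a), tolerance = 1e-12)

  R_l <- 0.3
  for (z in c(0, 0.1, 0.4)) {
    B <- polyline_field(list(circle_loop(R_l, 0, n = 361)), 1, c(0, 0, z))
    expect_equal(B[3], MU0 * R_l^2 / (2 * (R_l^2 + z^2)^1.5),
                 tolerance = 1e-4)
  }
  expect_equal(polyline_field(list(circle_loop(0.3)), 0, c(0, 0, 0.2)),
               matrix(0, 1, 3, dimnames = list(NULL, c("Bx", "By", "Bz"))))
})

test_that("polyline evaluation guards against open loops and on-segment points", {
  open_loop <- square_loop(0.5)[1:4, ]
  expect_error(polyline_field(list(open_loop), 1, c(0, 0, 1)), "not closed")
  expect_error(polyline_field(list(square_loop(0.5)), 1, c(0.25, 0, 0)),
               "singular")
})

test_that("a Helmholtz pair has a flat axial profile at the center", {
  R_l <- 0.4
  pair <- list(circle_loop(R_l, R_l / 2), circle_loop(R_l, -R_l / 2))
  h <- 1e-3
  Bz <- function(z) polyline_field(pair, 1, c(0, 0, z))[3]
  slope <- (Bz(h) - Bz(-h)) / (2 * h)
  expect_lt(abs(slope) / Bz(0), 1e-4)
})

test_that("stream-function field matches the equivalent-loop closed form", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 41)
  s <- disk_stream(mesh, 0.3)
  R_eq <- disk_equiv_radius(mesh, s)
  pts <- rbind(c(0, 0, 0.9), c(0, 0, 1.1), c(0, 0, 0.2))
  B <- field_of_stream(field_coupling(mesh, pts), s)
  zz <- pts[, 3] - 0.5
  exact <- MU0 * R_eq^2 / (2 * (R_eq^2 + zz^2)^1.5)
  expect_equal(B[, 3], exact, tolerance = 0.02)
  # zero stream function gives zero field
  s0 <- stream_function(numeric(nrow(mesh$vertices)), mesh)
  expect_equal(max(abs(field_of_stream(field_coupling(mesh, pts), s0))), 0)
})

test_that("the far field of a loop decays as r^-3", {
  mesh <- build_biplanar_mesh(0.5, 0.5, 21)
  s <- disk_stream(mesh, 0.15)
  r1 <- 20 * 0.5; r2 <- 40 * 0.5
  B1 <- field_of_stream(field_coupling(mesh, c(0, 0, r1)), s)
  B2 <- field_of_stream(field_coupling(mesh, c(0, 0, r2)), s)
  slope <- log(sqrt(sum(B1^2)) / sqrt(sum(B2^2))) / log(r2 / r1)
  expect_equal(slope, 3, tolerance = 0.05)
})

test_that("scalar potential matches the solid-angle closed form and -mu0 grad U = B", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 41)
  s <- disk_stream(mesh, 0.3)
  R_eq <- disk_equiv_radius(mesh, s)
  zz <- c(0.2, 0.45)
  pts <- cbind(0, 0, 0.5 + zz)
  U <- drop(potential_coupling(mesh, pts)$matrix %*% as.numeric(s))
  exact <- 2 * pi * (1 - zz / sqrt(R_eq^2 + zz^2)) / (4 * pi)
  expect_equal(U, exact, tolerance = 0.02)

  # numerical gradient of the potential vs the field kernel at random points
  set.seed(7)
  p <- cbind(stats::runif(10, -0.2, 0.2), stats::runif(10, -0.2, 0.2),
             stats::runif(10, 0.75, 1.0))
  h <- 1e-4
  B <- field_of_stream(field_coupling(mesh, p), s)
  for (comp in 1:3) {
    dp <- matrix(0, 1, 3); dp[comp] <- h
    Up <- drop(potential_coupling(mesh, sweep(p, 2, -dp))$matrix %*%
               as.numeric(s))
    Um <- drop(potential_coupling(mesh, sweep(p, 2, dp))$matrix %*%
               as.numeric(s))
    gradU <- (Up - Um) / (2 * h)
    expect_equal(-MU0 * gradU, B[, comp],
                 tolerance = 0.01 * max(abs(B)) / max(abs(B[, comp]), 1e-30))
  }
})

test_that("polyline potential agrees with the loop solid angle on and off axis", {
  R_l <- 0.3
  for (z in c(0.1, 0.3, 0.6)) {
    U <- polyline_potential(list(circle_loop(R_l, 0, n = 361)), 1,
                            c(0, 0, z))
    expect_equal(U, 2 * pi * (1 - z / sqrt(R_l^2 + z^2)) / (4 * pi),
                 tolerance = 1e-4)
  }
  # consistency with the quadrature kernel off axis
  mesh <- build_biplanar_mesh(1.0, 1.0, 41)
  s <- disk_stream(mesh, 0.3)
  p <- c(0.1, -0.05, 0.8)
  U1 <- drop(potential_coupling(mesh, p)$matrix %*% as.numeric(s))
  U2 <- polyline_potential(list(circle_loop(disk_equiv_radius(mesh, s),
                                            0.5, n = 361)), 1, p)
  expect_equal(U1, U2, tolerance = 0.02)
})

test_that("resistance matrix is a scaled stiffness with the right physics", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 41)
  R <- resistance_matrix(mesh, 1.72e-8, 70e-6)
  expect_equal(R$matrix, t(R$matrix))
  # constant per plane dissipates nothing
  s_const <- rep(1, nrow(mesh$vertices))
  expect_lt(abs(dissipated_power(R, s_const)), 1e-15)
  # doubling the thickness halves the dissipation
  R2 <- resistance_matrix(mesh, 1.72e-8, 140e-6)
  s <- as.numeric(disk_stream(mesh, 0.3))
  expect_equal(dissipated_power(R2, s), dissipated_power(R, s) / 2,
               tolerance = 1e-12)
  # thin annular turn: P = I^2 rho 2 pi r / (w t)
  rin <- 0.2; rout <- 0.32
  r <- sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2)
  ann <- ifelse(mesh$plane_side == 1,
                pmin(1, pmax(0, (rout - r) / (rout - rin))), 0)
  ann[mesh$boundary] <- 0
  expect_equal(dissipated_power(R, ann),
               1.72e-8 * 2 * pi * (rin + rout) / 2 / ((rout - rin) * 70e-6),
               tolerance = 0.10)
})

test_that("the computed field is divergence- and curl-free in the target region", {
  mesh <- build_biplanar_mesh(1.4, 1.4, 21)
  s <- disk_stream(mesh, 0.4)
  h <- 0.01
  probe <- rbind(c(h, 0, 0), c(-h, 0, 0), c(0, h, 0), c(0, -h, 0),
                 c(0, 0, h), c(0, 0, -h), c(0, 0, 0))
  B <- field_of_stream(field_coupling(mesh, probe), s)
  Bmag <- sqrt(sum(B[7, ]^2))
  divB <- (B[1, 1] - B[2, 1] + B[3, 2] - B[4, 2] + B[5, 3] - B[6, 3]) /
    (2 * h)
  expect_lt(abs(divB), 1e-3 * Bmag / h)
  curl <- c(
    (B[3, 3] - B[4, 3]) / (2 * h) - (B[5, 2] - B[6, 2]) / (2 * h),
    (B[5, 1] - B[6, 1]) / (2 * h) - (B[1, 3] - B[2, 3]) / (2 * h),
    (B[1, 2] - B[2, 2]) / (2 * h) - (B[3, 1] - B[4, 1]) / (2 * h)
  )
  dominant <- max(abs(B[1:6, ] - B[rep(7, 6), ])) / h
  expect_lt(max(abs(curl)), max(1e-3 * dominant, 1e-12))
})

test_that("matrix containers round-trip with units", {
  m <- matrix(rnorm(12), 3, 4)
  f <- tempfile()
  write_matrix_bin(m, f, units = "T/A")
  back <- read_matrix_bin(f)
  expect_identical(back$matrix, m)
  expect_identical(back$units, "T/A")
  writeBin(charToRaw("NOTMAGIC"), f)
  expect_error(read_matrix_bin(f), "container")
})
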
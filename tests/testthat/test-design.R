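test_that("target specifications populate the requested field pattern", {
  ctr <- matrix(0, 1, 3)
  t1 <- make_target("Bz", 1e-9, ctr)
  expect_equal(t1$b, matrix(c(0, 0, 1e-9), 1, 3,
                            dimnames = list(NULL, c("Bx", "By", "Bz"))))
  pts <- rbind(c(0, 0, -0.1), c(0, 0, 0.1))
  t2 <- make_target("Gzz", 1e-9, pts)
  expect_equal(t2$b[, 3], c(-1e-10, 1e-10))
  t3 <- make_target("Gxz", 1e-9, matrix(c(0, 0, 0.1), 1, 3))
  expect_equal(t3$b[1, ], c(Bx = 1e-10, By = 0, Bz = 0))
  expect_error(make_target("Bq", 1, ctr))
  expect_error(make_target("Bz", 0, ctr), "nonzero")
})

test_that("the stream-function optimizer solves the regularized problem", {
  mesh <- build_biplanar_mesh(1.4, 1.4, 15)
  spec <- trace_spec()
  R <- resistance_matrix(mesh, spec$resistivity, spec$thickness_um * 1e-6)
  pts <- rbind(c(0, 0, 0), sphere_surface_points(32, 0.25))
  A <- field_coupling(mesh, pts)

  # zero target -> zero stream function, zero objective
  t0 <- make_target("Bz", 1e-9, pts)
  t0$b[] <- 0
  sol0 <- optimize_stream_function(R, A, t0, residual = 0.02, mesh = mesh)
  expect_equal(max(abs(as.numeric(sol0$s))), 0)
  expect_equal(sol0$objective, 0)

  # residual decreases monotonically as lambda grows over four decades
  target <- make_target("Bz", 1e-9, pts)
  base <- optimize_stream_function(R, A, target, residual = 0.05,
                                   mesh = mesh)
  lams <- base$lambda * 10^(0:4)
  resids <- vapply(lams, function(l)
    optimize_stream_function(R, A, target, lambda = l, mesh = mesh)$residual,
    0)
  expect_true(all(diff(resids) < 0))

  # the solution satisfies the normal equations of the named component
  sol <- optimize_stream_function(R, A, target, residual = 0.05, mesh = mesh)
  interior <- !mesh$boundary
  keep <- rep(1:3, nrow(pts)) == 3
  Ai <- A$matrix[keep, interior]
  Ri <- R$matrix[interior, interior]
  s_int <- as.numeric(sol$s)[interior]
  b <- target$b[, 3]
  lhs <- (Ri + 2 * sol$lambda * crossprod(Ai)) %*% s_int
  rhs <- 2 * sol$lambda * crossprod(Ai, b)
  expect_equal(drop(lhs), drop(rhs), tolerance = 1e-8)
})

test_that("the default uniform-field design meets its residual target", {
  d <- small_design("Bz")
  expect_lte(d$solution$residual, 0.05)
  expect_equal(d$solution$residual, 0.02, tolerance = 1e-4)
  # achieved field is near-uniform over the sphere in the named component
  bz <- d$solution$achieved[, 3]
  expect_lt(stats::sd(bz) / mean(bz), 0.05)
})

test_that("discretization topology, polarity and current equivalence hold", {
  mesh <- build_biplanar_mesh(1.0, 1.0, 33)
  expect_error(discretize(stream_function(numeric(nrow(mesh$vertices)),
                                          mesh), 4),
               "degenerate")

  # radially symmetric dome: concentric anticlockwise loops on the +z plane
  r <- sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2)
  dome <- ifelse(mesh$plane_side == 1, pmax(0, 0.35 - r), 0)
  dome[mesh$boundary] <- 0
  coil <- discretize(stream_function(dome, mesh), 4)
  expect_true(all(vapply(coil$loops, `[[`, 0L, "polarity") == 1L))
  expect_true(all(vapply(coil$loops, `[[`, 0L, "plane") == 1L))
  areas <- vapply(coil$loops, `[[`, 0, "area")
  expect_true(all(diff(areas) < 0))   # sorted outermost first

  # discrete coil driven at the level step reproduces the continuous field
  d <- small_design("Bz")
  ctr <- matrix(0, 1, 3)
  B_cont <- field_of_stream(field_coupling(d$mesh, ctr),
                            as.numeric(d$solution$s))[1, 3]
  B_disc <- polyline_field(d$coil, d$coil$level_step, ctr)[1, 3]
  expect_equal(B_disc, B_cont, tolerance = 0.05)
})

test_that("fine rediscretization reproduces the continuous kernel field", {
  d <- small_design("Bz")
  fine <- discretize(d$solution, 200)
  ctr <- matrix(0, 1, 3)
  B_cont <- field_of_stream(field_coupling(d$mesh, ctr),
                            as.numeric(d$solution$s))[1, 3]
  B_fine <- polyline_field(fine, fine$level_step, ctr)[1, 3]
  expect_equal(B_fine, B_cont, tolerance = 0.01)
})

test_that("efficiency is a current-independent slope, zero for no turns", {
  expect_equal(as.numeric(coil_efficiency(list(), "Bz")), 0)
  d <- small_design("Bz")
  direct <- coil_efficiency(d$coil, "Bz")
  sweep <- coil_efficiency(d$coil, "Bz", mode = "sweep")
  sweep2 <- coil_efficiency(d$coil, "Bz", mode = "sweep",
                            currents = seq(0, 5e-3, length.out = 4))
  expect_equal(as.numeric(direct), as.numeric(sweep), tolerance = 1e-10)
  expect_equal(as.numeric(direct), as.numeric(sweep2), tolerance = 1e-10)
  expect_identical(attr(direct, "units"), "nT/mA")

  g <- small_design("Gzz")
  gd <- coil_efficiency(g$coil, "Gzz")
  gs <- coil_efficiency(g$coil, "Gzz", mode = "sweep")
  expect_equal(as.numeric(gd), as.numeric(gs), tolerance = 1e-10)
  expect_identical(attr(gd, "units"), "nT/m/mA")
})

test_that("the x and y uniform coils are rotated copies with equal efficiency", {
  ex <- small_design("Bx")$efficiency
  ey <- small_design("By")$efficiency
  expect_equal(as.numeric(ex), as.numeric(ey), tolerance = 0.02)
})

test_that("the uniform z coil approximates a Helmholtz profile at the center", {
  d <- small_design("Bz")
  h <- 0.05
  B <- polyline_field(d$coil, 1e-3, rbind(c(0, 0, -h), c(0, 0, 0),
                                          c(0, 0, h)))
  slope_per_10cm <- abs(B[3, 3] - B[1, 3])
  expect_lt(slope_per_10cm, 0.01 * B[2, 3])
})

test_that("the coil_design object supports the modelling-idiom methods", {
  d <- small_design("Bz")
  expect_s3_class(d, "coil_design")
  expect_length(coef(d), nrow(d$mesh$vertices))
  res <- residuals(d)
  expect_equal(dim(res), dim(d$target$b))
  expect_lt(sqrt(sum(res[, 3]^2)) / sqrt(sum(d$target$b[, 3]^2)), 0.021)
  pred <- predict(d, matrix(0, 1, 3), current = 1e-3)
  expect_equal(unname(pred[1, 3]) * 1e9, as.numeric(d$efficiency),
               tolerance = 1e-10)
  ps <- predict(d, matrix(0, 1, 3), current = 1e-3, type = "stream")
  expect_equal(ps[1, 3], pred[1, 3], tolerance = 0.05)
  s <- summary(d)
  expect_s3_class(s, "summary.coil_design")
  expect_gt(s$length_m, 0)
  expect_output(print(d), "Biplanar Bz")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(d))
  grDevices::dev.off()
})
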
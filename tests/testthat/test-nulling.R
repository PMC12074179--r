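test_that("coupling estimation does the activation arithmetic", {
  rd <- data.frame(sensor = c(1, 1), coil = c("baseline", "Bz"),
                   current_mA = c(0, 2), field_nT = c(0, 3))
  m <- estimate_coupling(rd)
  expect_equal(unname(m$M[1, 1]), 1.5)
  expect_error(estimate_coupling(rd, coils = c("Bz", "Bz")), "duplicate")
  bad <- rd; bad$current_mA[2] <- 0
  expect_error(estimate_coupling(bad), "zero activation")
})

test_that("a synthetic coupling matrix is recovered exactly from activations", {
  set.seed(42)
  M_true <- matrix(rnorm(16 * 6), 16, 6)
  baseline <- rnorm(16)
  rows <- data.frame(sensor = 1:16, coil = "baseline", current_mA = 0,
                     field_nT = baseline)
  for (k in 1:6) {
    I <- 5 + k
    rows <- rbind(rows, data.frame(
      sensor = 1:16, coil = paste0("c", k), current_mA = I,
      field_nT = baseline + M_true[, k] * I))
  }
  m <- estimate_coupling(rows)
  expect_lt(max(abs(m$M - M_true)) / max(abs(M_true)), 1e-10)

  # orthogonal columns give condition number one
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  rows2 <- data.frame(sensor = 1:6, coil = "baseline", current_mA = 0,
                      field_nT = 0)
  for (k in 1:6)
    rows2 <- rbind(rows2, data.frame(sensor = 1:6, coil = paste0("c", k),
                                     current_mA = 1, field_nT = Q[, k]))
  expect_equal(estimate_coupling(rows2)$condition, 1, tolerance = 1e-10)
})

test_that("nulling currents invert the coupling relation", {
  m <- structure(list(M = diag(3), sensors = 1:3, coils = c("a", "b", "c"),
                      condition = 1), class = "nulling_model")
  expect_equal(unname(nulling_currents(m, c(0, 0, 0))$currents), rep(0, 3))
  sol <- nulling_currents(m, c(2, -1, 3))
  expect_equal(unname(sol$currents), c(2, -1, 3))
  expect_equal(sol$residual_norm, 0)
  # applying minus the currents cancels the field exactly for square M
  set.seed(3)
  M <- matrix(rnorm(9), 3, 3)
  m2 <- structure(list(M = M, sensors = 1:3, coils = letters[1:3],
                       condition = kappa(M, exact = TRUE)),
                  class = "nulling_model")
  b <- drop(M %*% c(1, -2, 0.5))
  sol2 <- nulling_currents(m2, b)
  expect_lt(max(abs(b - drop(M %*% sol2$currents))), 1e-12)
  # ill conditioning warns but does not fail
  m3 <- m2; m3$condition <- 1e6
  expect_warning(nulling_currents(m3, b), "condition number")
})

test_that("least-squares currents recover the truth within noise bounds", {
  set.seed(11)
  M <- matrix(rnorm(16 * 3), 16, 3)
  model <- structure(list(M = M, sensors = 1:16, coils = c("x", "y", "z"),
                          condition = 1), class = "nulling_model")
  I_true <- c(1.2, -0.7, 2.5)
  sigma <- 0.05
  errs <- replicate(200, {
    b <- drop(M %*% I_true) + rnorm(16, sd = sigma)
    max(abs(nulling_currents(model, b)$currents - I_true))
  })
  # per-component standard error of the LS estimate
  se <- sqrt(max(diag(solve(crossprod(M))))) * sigma
  expect_lt(stats::quantile(errs, 0.99), 3.5 * se * sqrt(3))
  expect_lt(mean(errs), 3 * se)
})

test_that("nulling currents are equivariant under sensor reordering", {
  set.seed(5)
  M <- matrix(rnorm(8 * 3), 8, 3)
  b <- rnorm(8)
  model <- structure(list(M = M, sensors = 1:8, coils = c("x", "y", "z"),
                          condition = 1), class = "nulling_model")
  perm <- sample(8)
  model_p <- model
  model_p$M <- M[perm, ]
  expect_equal(nulling_currents(model, b)$currents,
               nulling_currents(model_p, b[perm])$currents,
               tolerance = 1e-12)
})

test_that("flip-and-average separates sensor bias from field", {
  field <- 3.2; bias <- -0.7
  out <- flip_bias_correct(field + bias, -field + bias)
  expect_equal(out$bias, bias)
  expect_equal(out$corrected, field)
})

test_that("a simulated session nulls a uniform background with real coils", {
  coils <- list(Bx = small_design("Bx")$coil,
                By = small_design("By")$coil,
                Bz = small_design("Bz")$coil)
  sens <- helmet_sensors(n = 16, seed = 2)

  # zero background -> zero residual
  s0 <- simulate_nulling_session(coils, sens,
                                 background = list(uniform = c(0, 0, 0)))
  expect_lt(s0$trace$max_residual_nT[1], 1e-9)

  # a 21 nT background along an arbitrary direction drops below 5%
  set.seed(9)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  s1 <- simulate_nulling_session(coils, sens,
                                 background = list(uniform = 21 * dir))
  expect_gt(s1$before, 5)
  expect_lt(s1$trace$max_residual_nT[1], 0.05 * s1$before)

  # frozen currents under a drifting background: residual grows with time
  s2 <- simulate_nulling_session(
    coils, sens,
    background = list(uniform = 21 * dir, drift = c(0.5, -0.2, 0.3)),
    times = c(0, 5, 10, 20))
  expect_true(all(diff(s2$trace$max_residual_nT) > 0))
})

test_that("activation tables and solved currents travel as delimited text", {
  rd <- data.frame(sensor = c(1, 1, 2, 2),
                   coil = c("baseline", "Bz", "baseline", "Bz"),
                   current_mA = c(0, 2, 0, 2),
                   field_nT = c(1, 4, -1, 2))
  f <- tempfile(fileext = ".tsv")
  write_readings(rd, f)
  back <- read_readings(f)
  expect_equal(back$field_nT, rd$field_nT)
  model <- estimate_coupling(back)
  sol <- nulling_currents(model, c(1, -1))
  cf <- tempfile(fileext = ".tsv")
  cy <- tempfile(fileext = ".yaml")
  write_currents(sol, cf, cy)
  cur <- utils::read.table(cf, header = TRUE)
  expect_equal(cur$current_mA, unname(sol$currents))
  expect_true(file.exists(cy))
})
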
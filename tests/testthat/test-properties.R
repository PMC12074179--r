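test_that("copper weight converts to thickness under both conventions", {
  expect_equal(copper_thickness(1), 35)
  expect_equal(copper_thickness(2), 70)
  expect_equal(copper_thickness(0.5), copper_thickness(1) / 2)
  expect_equal(copper_thickness(1, "density"),
               28.3495 / (8.96 * 929.0304) * 1e4, tolerance = 1e-12)
  expect_equal(round(copper_thickness(1, "density"), 1), 34.1)
  expect_error(copper_thickness(0), "> 0")
})

test_that("trace resistance follows rho L / (w t) with the right scalings", {
  spec <- trace_spec(5, 2)
  expect_equal(trace_resistance(0, spec), 0)
  expect_equal(trace_resistance(100, spec), 2 * trace_resistance(50, spec))
  wide <- trace_spec(10, 2)
  thick <- trace_spec(5, 4)
  expect_equal(trace_resistance(100, wide), trace_resistance(100, spec) / 2)
  expect_equal(trace_resistance(100, thick), trace_resistance(100, spec) / 2)
})

test_that("the default resistivity reproduces the published length-resistance pairs", {
  # published conducting-path lengths (m) and resistances (Ohm) for the six
  # coils, loops-only and connected-path variants
  lengths <- c(217.4, 236.5, 214.3, 232.2, 164.5, 170.6,
               159.3, 164.9, 155.8, 163.2, 110.1, 114.6)
  resist <- c(10.7, 11.6, 10.5, 11.4, 8.1, 8.4,
              7.8, 8.1, 7.7, 8.0, 5.4, 5.6)
  spec <- trace_spec(5, 2)
  computed <- trace_resistance(lengths, spec)
  expect_true(all(abs(round(computed, 1) - resist) <= 0.05 + 1e-9))
})

test_that("property reports assemble per-coil rows with sane relations", {
  expect_equal(nrow(properties_report(list())), 0)
  d <- small_design("Bz")
  set <- small_board_set("Bz")
  expect_warning(rep1 <- properties_report(list(Bz = d), list(Bz = set)),
                 "partial report")
  expect_equal(rep1$coil, "Bz")
  expect_gte(rep1$length_connected_m, rep1$length_loops_m)
  expect_equal(rep1$resistance_loops_ohm,
               trace_resistance(rep1$length_loops_m, trace_spec()))
  expect_equal(rep1$units, "nT/mA")
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  suppressWarnings(write_properties(rep1, csv, yml))
  back <- utils::read.csv(csv)
  expect_equal(back$length_loops_m, round(rep1$length_loops_m, 1))
  expect_true(file.exists(yml))
})
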
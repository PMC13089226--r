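test_that("the packaged equation table has the published structure", {
  eq <- packaged_equations()
  expect_equal(sum(eq$group == "missing_element"), 13)
  expect_equal(sum(eq$group == "mass_ols"), 14)
  expect_equal(sum(eq$group == "mass_pgls"), 14)
  t2 <- equation_record("table2_trunk")
  expect_equal(t2$slope, 2.9292)
  expect_equal(t2$intercept, 2.4367)
  expect_equal(t2$mean_abs_pe, 17.73)
  expect_equal(t2$sd_abs_pe, 13.94)
  e20 <- equation_record("eq20")
  expect_equal(e20$ll_numerator, 1.3067)
  expect_equal(e20$ll_scale, 1.5937)
  expect_equal(e20$ll_exponent, 10.2847)
  expect_equal(e20$ll_offset, -1.4684)
  # preferred estimators flagged per the published recommendation
  expect_true(all(eq$preferred[eq$id %in% c("eq9", "eq15", "eq20")]))
  expect_true(all(eq$preferred[eq$group == "mass_ols"]))
  expect_false(any(eq$preferred[eq$group == "mass_pgls"]))
})

test_that("every packaged coefficient round-trips through the table file", {
  eq <- packaged_equations()
  path <- withr::local_tempfile(fileext = ".csv")
  write_equation_table(path, eq)
  back <- read_equation_table(path)
  num <- c("slope", "intercept", "ll_numerator", "ll_scale", "ll_exponent",
           "ll_offset", "n", "r_squared", "aicc", "mean_abs_pe", "sd_abs_pe")
  for (col in num) expect_equal(back[[col]], eq[[col]])
  expect_equal(back$id, eq$id)
  # the shipped copy matches the in-code table
  shipped <- read_equation_table()
  for (col in num) expect_equal(shipped[[col]], eq[[col]])
})

test_that("missing-element predictions evaluate the published equations", {
  ral <- predict_missing_element("max_ral", list(trunk = 2000), units = "mm")
  expect_equal(ral$estimate, 10^(1.0123 * log10(2000) - 0.5068), tolerance = 1e-12)
  expect_equal(ral$estimate, 683.5, tolerance = 1e-3)
  tail <- predict_missing_element("tail", list(trunk = 2000), units = "mm")
  expect_equal(tail$estimate, 10^(0.8414 * log10(2000) + 0.4803), tolerance = 1e-12)
  expect_equal(tail$estimate, 1810.8, tolerance = 1e-3)
  # unit handling: meters in, meters out
  ral_m <- predict_missing_element("max_ral", list(trunk = 2))
  expect_equal(ral_m$estimate, ral$estimate / 1000, tolerance = 1e-12)
})

test_that("the skull solve inverts the log-logistic ratio exactly", {
  sk <- predict_missing_element("skull_length", list(neck = 2.0, cn = 13))
  expect_equal(sk$ratio, 0.6401, tolerance = 1e-4)
  expect_equal(sk$estimate, 3.557, tolerance = 1e-3)
  # plugging SKL back: SKL/(SKL + neck) = predicted ratio
  expect_equal(sk$estimate / (sk$estimate + 2.0), sk$ratio, tolerance = 1e-12)
  # an (artificial) curve with ratio >= 1 is infeasible
  eq <- packaged_equations()
  eq$ll_offset[eq$id == "eq20"] <- 0.5
  expect_error(
    predict_missing_element("skull_length", list(neck = 2, cn = 13), equations = eq),
    "infeasible")
})

test_that("limb-length prediction requires external coefficients", {
  expect_error(
    predict_missing_element("limb_length", list(propodial_distal_width = 0.2)),
    "external coefficients required")
  est <- predict_missing_element("limb_length", list(propodial_distal_width = 0.2),
                                 limb_coefficients = list(slope = 1, intercept = 0.5))
  expect_equal(est$estimate, 10^(log10(200) + 0.5) / 1000, tolerance = 1e-12)
})

test_that("body-mass prediction evaluates the OLS table with symmetric intervals", {
  m <- predict_body_mass("trunk", 1.0)
  expect_equal(m$mass, 10^2.4367, tolerance = 1e-12)
  expect_equal(m$mass, 273.3, tolerance = 1e-3)
  expect_equal(m$interval$lower, m$mass * (1 - 0.1773), tolerance = 1e-12)
  expect_equal(m$interval$lower, 224.9, tolerance = 1e-3)
  expect_equal(m$interval$upper, 321.8, tolerance = 1e-3)
  # the log10-mass difference over a decade of trunk length is the slope
  m10 <- predict_body_mass("trunk", 10)
  expect_equal(log10(m10$mass) - log10(m$mass), 2.9292, tolerance = 1e-12)
  # interval half-width fraction equals mean_abs_pe / 100 for every OLS row
  eq <- packaged_equations()
  for (id in eq$id[eq$group == "mass_ols"]) {
    row <- equation_record(id)
    est <- predict_body_mass(row$predictor, 0.8)
    expect_equal((est$interval$upper - est$mass) / est$mass,
                 row$mean_abs_pe / 100, tolerance = 1e-12)
  }
  expect_error(predict_body_mass("trunk", -1), "positive")
  expect_error(predict_body_mass("snout", 1), "unknown proxy")
})

test_that("composite proxies are assembled from their components", {
  sc <- predict_body_mass("skl_cn", components = list(skl = 0.5, cn = 30))
  expect_equal(sc$mass, 10^(2.8228 * log10(15) - 0.38), tolerance = 1e-12)
  vv <- predict_body_mass("vertebral_volume",
                          components = list(centrum_length = 0.06,
                                            centrum_width = 0.07,
                                            centrum_height = 0.05))
  expect_equal(vv$mass, 10^(1.0257 * log10(0.06 * 0.07 * 0.05) + 6.5333),
               tolerance = 1e-12)
  pg <- predict_body_mass("trunk", 1.0, table = "PGLS")
  expect_equal(pg$mass, 10^2.4871, tolerance = 1e-12)
  expect_null(pg$interval)
})
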
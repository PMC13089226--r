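make_measurement_table <- function(n = 27L, seed = 9L) {
  set.seed(seed)
  scale <- 10^runif(n, -0.3, 0.7)
  data.frame(taxon = sprintf("Taxon_%02d", seq_len(n)),
             specimen = sprintf("SPEC-%03d", seq_len(n)),
             cervical_count = sample(12:76, n, replace = TRUE),
             trunk_length = 1.2 * scale,
             neck_length = 1.5 * scale,
             skull_length = 0.35 * scale,
             max_rib_arc_length = 0.45 * scale,
             coracoid_width = 0.4 * scale,
             humerus_length = 0.5 * scale,
             femur_length = 0.48 * scale)
}

test_that("measurement tables round-trip through CSV to 1e-12", {
  df <- make_measurement_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(df, path)
  back <- load_measurements(path)
  expect_equal(nrow(back), 27)
  for (col in setdiff(names(df), c("taxon", "specimen"))) {
    expect_equal(back[[col]], df[[col]], tolerance = 1e-12)
  }
  expect_equal(back$taxon, df$taxon)
})

test_that("unit declarations convert on load", {
  df <- data.frame(taxon = "A", cervical_count = 30, trunk_length = 1.0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(df, path, units = "mm")
  expect_match(readLines(path, n = 1), "units: mm")
  raw <- utils::read.csv(path, skip = 1)
  expect_equal(raw$trunk_length, 1000) # written on the declared scale
  back <- load_measurements(path)
  expect_equal(back$trunk_length, 1.0) # converted back to meters
})

test_that("measurement loading enforces the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,trunk_length", "A,1.0"), path)
  expect_error(load_measurements(path), "mandatory")
  writeLines(c("taxon,cervical_count,trunk_length", "A,30,-1"), path)
  expect_error(load_measurements(path), "non-positive trunk_length in row 1")
  writeLines(c("taxon,cervical_count,trunk_length", "A,30,abc"), path)
  expect_error(load_measurements(path), "row 1, column 'trunk_length'")
  writeLines(c("taxon,cervical_count,mystery", "A,30,5"), path)
  expect_warning(load_measurements(path), "unknown column")
  expect_error(load_measurements(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("skeleton JSON round-trips a generated skeleton field-by-field", {
  sk <- gen_skeleton("elasmosaurid-like", 1.3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_skeleton(sk, path)
  back <- load_skeleton(path)
  expect_equal(back$taxon, sk$taxon)
  expect_equal(back$measurements[order(names(back$measurements))],
               sk$measurements[order(names(sk$measurements))], tolerance = 1e-12)
  expect_equal(back$vertebrae, sk$vertebrae, tolerance = 1e-12)
  expect_equal(back$rib_planes, sk$rib_planes, tolerance = 1e-12)
  expect_equal(back$rib_coefficient, sk$rib_coefficient, tolerance = 1e-12)
  for (nm in names(sk$limb_planforms)) {
    expect_equal(back$limb_planforms[[nm]]$chords,
                 sk$limb_planforms[[nm]]$chords, tolerance = 1e-12)
  }
  # and the reloaded spec reconstructs to the same mass
  expect_equal(run_reconstruct(back)$mass, run_reconstruct(sk)$mass,
               tolerance = 1e-9)
})

test_that("skeleton loading rejects version mismatch and region disorder", {
  sk <- gen_skeleton("pliosaurid-like", seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_skeleton(sk, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$schema_version <- "9.9"
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_skeleton(path), "schema-version mismatch")
  doc$schema_version <- "1.0"
  doc$vertebrae <- doc$vertebrae[rev(seq_len(nrow(doc$vertebrae))), ]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_skeleton(path), "out of order")
})

test_that("validation reports every violated invariant without stopping", {
  sk <- gen_skeleton("cryptoclidid-like", seed = 6)
  rep0 <- validate_skeleton(sk)
  expect_equal(nrow(rep0$errors), 0)
  sk$rib_coefficient <- 1.3
  rep1 <- validate_skeleton(sk)
  expect_match(rep1$errors$message, "rib coefficient must be in \\(0,1\\]", all = FALSE)
  sk$rib_coefficient <- 0.8
  sk$measurements$trunk_length <- -2
  rep2 <- validate_skeleton(sk)
  expect_match(rep2$errors$message, "trunk_length must be positive", all = FALSE)
})

test_that("validation warns with the named fallback for estimable elements", {
  sk <- gen_skeleton("cryptoclidid-like", seed = 6)
  sk$measurements$max_rib_arc_length <- NA_real_
  sk$measurements$tail_length <- NA_real_
  sk$vertebrae <- sk$vertebrae[sk$vertebrae$region != "caudal", ]
  rep <- validate_skeleton(sk)
  expect_equal(nrow(rep$errors), 0) # caudal removal breaks no invariant; CN intact
  expect_match(rep$warnings$message, "eq9", all = FALSE)
  expect_match(rep$warnings$message, "eq15", all = FALSE)
})

test_that("validation is order-independent over vertebral rows within regions", {
  sk <- gen_skeleton("elasmosaurid-like", seed = 7)
  v <- sk$vertebrae
  within_shuffled <- do.call(rbind, lapply(split(v, factor(v$region,
    levels = c("cervical", "pectoral", "dorsal", "sacral", "caudal"))),
    function(d) d[sample(nrow(d)), ]))
  sk2 <- sk
  sk2$vertebrae <- within_shuffled
  expect_equal(nrow(validate_skeleton(sk2)$errors), nrow(validate_skeleton(sk)$errors))
})
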
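test_that("rib projection reduces to the identity at zero angles", {
  p <- project_rib_plane(rib_plane(1, 0.4, 0, 0, 0))
  expect_equal(p$RPH_P1, 1)
  expect_equal(p$RPW_P1, 0.4)
  expect_equal(p$RPH_P2, 1)
  expect_equal(p$RPW_P2, 0.4)
  expect_equal(p$RPH_P3, 1)
  expect_equal(p$RPW_P3, 0.4)
})

test_that("rib projection matches the hand-evaluated composite rotation", {
  p <- project_rib_plane(rib_plane(1, 0.4, 30, 20, 10))
  expect_equal(p$RPH_P1, cos(pi / 6), tolerance = 1e-12)
  expect_equal(p$RPH_P1, 0.866025, tolerance = 1e-6)
  expect_equal(p$RPH_P2, 0.797621, tolerance = 1e-6)
  expect_equal(p$RPW_P2, 0.375877, tolerance = 1e-6)
  expect_equal(p$RPH_P3, 0.785503, tolerance = 1e-6)
  expect_equal(p$RPW_P3, p$RPW_P2)
})

test_that("edge-on bucket-handle rotation collapses the projected width", {
  p <- project_rib_plane(rib_plane(1, 0.4, 0, 90, 0))
  expect_equal(p$RPW_P2, 0, tolerance = 1e-15)
  expect_equal(p$RPH_P2, 1)
})

test_that("angles outside their stated ranges are rejected", {
  expect_error(rib_plane(1, 0.4, theta1 = 95), "theta1")
  expect_error(rib_plane(1, 0.4, theta2 = -5), "theta2")
  expect_error(rib_plane(1, 0.4, theta3 = 120), "theta3")
  expect_error(rib_plane(-1, 0.4), "positive")
})

test_that("projection equations agree with the rotation-matrix corner oracle", {
  grid <- expand.grid(t1 = seq(-60, 60, by = 15),
                      t2 = seq(0, 60, by = 15),
                      t3 = seq(-60, 60, by = 15))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    p <- project_rib_plane(rib_plane(1.3, 0.45, grid$t1[i], grid$t2[i], grid$t3[i]))
    o <- oracle_rib_projection(1.3, 0.45, grid$t1[i], grid$t2[i], grid$t3[i])
    worst <- max(worst, abs(p$RPH_P1 - o$RPH_P1), abs(p$RPW_P1 - o$RPW_P1),
                 abs(p$RPH_P2 - o$RPH_P2), abs(p$RPW_P2 - o$RPW_P2),
                 abs(p$RPH_P3 - o$RPH_P3), abs(p$RPW_P3 - o$RPW_P3))
  }
  expect_lt(worst, 1e-9)
})

test_that("projected height is monotone non-increasing in each angle magnitude", {
  base <- c(RPH = 1, RPW = 0.4)
  for (t1 in c(0, 20, 40)) {
    h <- vapply(seq(0, 80, by = 10), function(t3) {
      project_rib_plane(rib_plane(base[1], base[2], t1, 15, t3))$RPH_P3
    }, numeric(1))
    expect_true(all(diff(h) <= 1e-12))
  }
  h1 <- vapply(seq(0, 80, by = 10), function(t1) {
    project_rib_plane(rib_plane(base[1], base[2], t1, 15, 10))$RPH_P3
  }, numeric(1))
  expect_true(all(diff(h1) <= 1e-12))
})

test_that("rib coefficient is the arc ratio and rejects inverted inputs", {
  expect_equal(rib_coefficient(0.5, 0.5), 1.0)
  expect_equal(rib_coefficient(0.4, 0.5), 0.8)
  expect_error(rib_coefficient(0.6, 0.5), "exceeds")
})

test_that("Pythagorean ventral height treats the girdle as the hypotenuse", {
  expect_equal(ventral_height_from_girdle(0.5, 0.8), 0.3, tolerance = 1e-12)
  expect_equal(ventral_height_from_girdle(0.7, 0), 0.7)
  expect_error(ventral_height_from_girdle(0.3, 0.8), "infeasibility")
})

test_that("middle ventral height follows the rib-coefficient scaling", {
  expect_equal(middle_ventral_height(0.4, 0.4, 1), 0.4)
  expect_equal(middle_ventral_height(0.3, 0.5, 0.8), 0.5)
  expect_equal(middle_ventral_height(0.3, 0.5, 1.0), 0.4)
  expect_error(middle_ventral_height(0.3, 0.5, 1.3), "rib coefficient")
})

test_that("middle section width takes twice the widest projected rib half-width", {
  r1 <- rib_plane(1, 0.4, 0, 0, 0)
  expect_equal(middle_section_width(list(r1)), 0.8)
  r2 <- rib_plane(1, 0.4, 0, 20, 0)
  expect_equal(middle_section_width(list(r2)), 0.8 * cos(20 * pi / 180))
  expect_equal(middle_section_width(list(r2)), 0.751754, tolerance = 1e-6)
  ra <- rib_plane(1, 0.3, 0, 0, 0); rb <- rib_plane(1, 0.35, 0, 0, 0)
  expect_equal(middle_section_width(list(ra, rb)), 0.7)
  expect_error(middle_section_width(list()), "at least one")
})

test_that("cross-sections match analytic superellipse areas and symmetry", {
  cc <- build_cross_section(0.8, 0.2, 0.2, 2, 2, 512)
  expect_equal(contour_area(cc), pi * 0.4 * 0.2, tolerance = 1e-3)
  expect_lt(symmetry_residual(cc), 1e-9)
  # generic exponents against the closed-form superellipse area
  cc2 <- build_cross_section(0.9, 0.25, 0.18, 2.2, 2.5, 1024)
  expect_equal(contour_area(cc2), analytic_section_area(0.9, 0.25, 0.18, 2.2, 2.5),
               tolerance = 1e-3)
  # large exponents approach the bounding rectangle
  cc3 <- build_cross_section(0.8, 0.2, 0.2, 12, 12, 2048)
  expect_equal(contour_area(cc3), 0.8 * 0.4, tolerance = 0.02)
  # shoelace vs fan triangulation
  expect_equal(contour_area(cc2), triangulation_area(cc2), tolerance = 1e-12)
  expect_false(plesiomass:::self_intersects(cc2$x, cc2$y))
})

test_that("contour rescaling obeys the affine area law", {
  cc <- build_cross_section(0.8, 0.3, 0.2, 2.2, 2.5, 256)
  same <- rescale_contour(cc, contour_width(cc), contour_height(cc))
  expect_equal(same$x, cc$x, tolerance = 1e-12)
  expect_equal(same$y, cc$y, tolerance = 1e-12)
  for (tw in c(0.5, 1.6)) {
    for (th in c(0.2, 0.9)) {
      sc <- rescale_contour(cc, tw, th)
      expect_equal(contour_width(sc), tw, tolerance = 1e-9)
      expect_equal(contour_height(sc), th, tolerance = 1e-9)
      expect_equal(contour_area(sc),
                   contour_area(cc) * (tw / contour_width(cc)) * (th / contour_height(cc)),
                   tolerance = 1e-9)
    }
  }
})
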
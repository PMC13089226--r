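test_that("contour area is the shoelace area and rejects self-intersection", {
  sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(contour_area(sq), 1.0)
  circ <- circle_contour(1, 512)
  expect_equal(contour_area(circ), pi, tolerance = 1e-4)
  mirrored <- contour(-sq$x, sq$y)
  expect_equal(contour_area(mirrored), contour_area(sq))
  bowtie <- contour(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(contour_area(bowtie), "self-intersecting")
})

test_that("resampling is arc-length-uniform and idempotent", {
  cc <- build_cross_section(0.8, 0.25, 0.2, 2.2, 2.5, 300)
  r1 <- resample_contour(cc, 256)
  r2 <- resample_contour(r1, 256)
  expect_equal(r2$x, r1$x, tolerance = 1e-12)
  expect_equal(r2$y, r1$y, tolerance = 1e-12)
  circ <- resample_contour(circle_contour(1, 1024), 256)
  rad <- sqrt(circ$x^2 + (circ$y - 1)^2)
  expect_lt(diff(range(rad)), 1e-5)
  ell <- skull_section(0.4, 0.2, 512)
  expect_equal(contour_area(resample_contour(ell, 512)), contour_area(ell),
               tolerance = 1e-4)
})

test_that("contour blending is linear with exact endpoints", {
  a <- circle_contour(1, 256)
  b <- circle_contour(3, 256)
  f0 <- blend_contours(a, b, 0, 256)
  expect_equal(contour_area(f0), contour_area(resample_contour(a, 256)),
               tolerance = 1e-12)
  f1 <- blend_contours(a, b, 1, 256)
  expect_equal(contour_area(f1), contour_area(resample_contour(b, 256)),
               tolerance = 1e-12)
  mid <- blend_contours(a, b, 0.5, 256)
  expect_equal(contour_area(mid), pi * 4, tolerance = 1e-3)
  self <- blend_contours(a, a, 0.37, 256)
  expect_equal(contour_area(self), contour_area(resample_contour(a, 256)),
               tolerance = 1e-12)
})

test_that("slab integration reproduces analytic solids", {
  circ <- circle_contour(1, 512)
  # cylinder: exact against area x length
  cyl <- csm_slab(circ, circ, 2, 100)
  expect_equal(slab_volume(cyl), contour_area(circ) * 2, tolerance = 1e-12)
  # cone: within 0.01% of closed form at 100 subslabs
  cone <- csm_slab(circ, NULL, 3, 100)
  expect_equal(slab_volume(cone), pi, tolerance = 1e-4)
  # frustum r1=1 -> r2=2
  fr <- csm_slab(circ, circle_contour(2, 512), 3, 100)
  expect_equal(slab_volume(fr), 7 * pi, tolerance = 1e-4)
  # trapezoid error decays ~ n^-2
  err <- function(n) abs(slab_volume(csm_slab(circ, NULL, 3, n)) -
                           contour_area(circ))
  expect_gt(err(25) / err(100), 10)
  expect_lt(err(25) / err(100), 25)
})

test_that("volume is invariant under slab re-subdivision", {
  a <- circle_contour(0.6, 256)
  b <- circle_contour(1.4, 256)
  whole <- slab_volume(csm_slab(a, b, 2, 400))
  cut <- blend_contours(a, b, 0.3, 512)
  left <- slab_volume(csm_slab(a, cut, 0.6, 120))
  right <- slab_volume(csm_slab(cut, b, 1.4, 280))
  expect_equal(left + right, whole, tolerance = 1e-9)
})

test_that("limb volume integrates hydrofoil sections along the span", {
  p <- limb_planform(1, rep(0.2, 6), 0.2, 0.685)
  expect_equal(limb_volume(p), 0.685 * 0.2 * (0.2 * 0.2) * 1, tolerance = 1e-12)
  p2 <- limb_planform(1, rep(0.4, 6), 0.2, 0.685)
  expect_equal(limb_volume(p2), 4 * limb_volume(p), tolerance = 1e-12)
  expect_error(limb_planform(1, rep(0, 6)), NA) # zero chords allowed
  expect_equal(limb_volume(limb_planform(1, rep(0, 6))), 0)
})

test_that("soft-tissue staging enlarges sections by the linear scale and the tail by 5%", {
  sk <- gen_skeleton("cryptoclidid-like", seed = 2)
  cfg <- reconstruct_config()
  filled <- plesiomass:::fill_missing_elements(sk)
  sections <- plesiomass:::derive_sections(filled$spec, cfg)
  axis <- assemble_body_axis(filled$spec)
  model <- body_model(sections[c("skull", "glenoid", "middle", "acetabulum")],
                      unname(diff(axis$stations)), density = 1027)
  staged <- apply_soft_tissue(model, axis, soft_tissue_config(1.25, 0.05))
  for (nm in c("glenoid", "middle", "acetabulum")) {
    expect_equal(contour_width(staged$model$sections[[nm]]),
                 1.25 * contour_width(model$sections[[nm]]), tolerance = 1e-12)
    expect_equal(contour_area(staged$model$sections[[nm]]),
                 1.25^2 * contour_area(model$sections[[nm]]), tolerance = 1e-9)
  }
  expect_equal(contour_area(staged$model$sections$skull),
               contour_area(model$sections$skull))
  expect_equal(staged$model$slab_lengths[5], 1.05 * model$slab_lengths[5],
               tolerance = 1e-12)
  # identity configuration leaves the model unchanged
  ident <- apply_soft_tissue(model, axis, soft_tissue_config(1, 0))
  expect_equal(body_mass(ident$model)$volume, body_mass(model)$volume,
               tolerance = 1e-12)
})

test_that("mass equals volume times density and limbs add linearly", {
  g <- gen_parametric_body("cylinder", r = 0.5, L = 2)
  bm <- body_mass(g$model)
  expect_equal(bm$mass / bm$volume, 1027)
  withlimb <- g$model
  withlimb$limbs <- list(limb_planform(1, rep(0, 6)))
  expect_equal(body_mass(withlimb)$mass, bm$mass)
  model2 <- body_model_from_slabs(g$model$slabs, density = 1000)
  expect_equal(body_mass(model2)$mass / body_mass(model2)$volume, 1000)
})
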
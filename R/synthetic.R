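#' Seeded synthetic allometric dataset
#'
#' Draws predictor values log-uniformly over `x_range` and generates the
#' response on the log10 scale as `slope * log10(x) + intercept` plus
#' Normal(0, `noise_sigma`) noise (multiplicative lognormal on the antilog
#' scale, matching the log-transformed fitting space). Generating
#' parameters default to the packaged trunk-rib OLS coefficients so that
#' recovery tests double as equation-encoding checks.
#'
#' @param n Number of points (>= 3).
#' @param slope,intercept Generating log-linear coefficients.
#' @param noise_sigma Log10-scale residual SD (>= 0).
#' @param x_range Antilog predictor range (length 2, positive).
#' @param seed Integer seed.
#' @return A data frame with antilog columns `x`, `y` and their log10
#'   counterparts `log_x`, `log_y`.
#' @export
gen_allometric_dataset <- function(n = 30L, slope = 1.0123, intercept = -0.5068,
                                   noise_sigma = 0.05, x_range = c(200, 8000),
                                   seed = 1L) {
  stopifnot(n >= 3L, noise_sigma >= 0, length(x_range) == 2L, all(x_range > 0))
  set.seed(seed)
  lx <- stats::runif(n, log10(x_range[1L]), log10(x_range[2L]))
  ly <- slope * lx + intercept + stats::rnorm(n, 0, noise_sigma)
  data.frame(x = 10^lx, y = 10^ly, log_x = lx, log_y = ly)
}

#' Seeded synthetic skull-neck dataset over a cervical-count range
#'
#' Generates the log10 skull-to-(skull + neck) ratio from the packaged
#' log-logistic curve (`eq20` by default) over cervical counts, adds
#' Normal(0, `noise_sigma`) noise on the log10 scale (resampling the rare
#' draws with ratio >= 1), then materializes skull and neck lengths from a
#' lognormally drawn skull + neck total.
#'
#' @param cn_range Integer range of cervical counts within \[5, 80\].
#' @param n Number of specimens (sampled with replacement over `cn_range`;
#'   when `n` equals the range length each count appears once).
#' @param noise_sigma Log10-scale SD of ratio noise.
#' @param seed Integer seed.
#' @param equations Equation table holding the generating curve.
#' @return A data frame with columns `cn`, `ratio`, `skl`, `neck` (m).
#' @export
gen_skullneck_dataset <- function(cn_range = c(12L, 76L), n = NULL,
                                  noise_sigma = 0.05, seed = 1L,
                                  equations = packaged_equations()) {
  stopifnot(cn_range[1L] >= 5, cn_range[2L] <= 80, cn_range[1L] < cn_range[2L])
  counts <- seq(cn_range[1L], cn_range[2L])
  set.seed(seed)
  cn <- if (is.null(n) || n == length(counts)) counts else sample(counts, n, replace = TRUE)
  row <- equation_record("eq20", equations)
  log_ratio0 <- eval_log_logistic(row, log10(cn))
  log_ratio <- log_ratio0
  if (noise_sigma > 0) {
    for (i in seq_along(cn)) {
      for (try in 1:100) {
        cand <- log_ratio0[i] + stats::rnorm(1, 0, noise_sigma)
        if (cand < 0) { log_ratio[i] <- cand; break }
        if (try == 100) stop("could not draw a ratio < 1 after 100 retries")
      }
    }
  }
  ratio <- 10^log_ratio
  total <- 10^stats::rnorm(length(cn), log10(3), 0.2) # skull + neck totals ~ 3 m
  data.frame(cn = cn, ratio = ratio, skl = total * ratio,
             neck = total * (1 - ratio))
}

#' Seeded pure-birth tree with Brownian regression traits
#'
#' Simulates a pure-birth (Yule) tree, then a regression dataset whose
#' residuals follow Brownian motion on the tree: `x` is drawn uniformly,
#' `y = intercept + slope * x + eps` with `eps ~ N(0, sigma2 * C)` where C
#' is the tree's Brownian covariance.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param birth_rate Speciation rate of the pure-birth tree.
#' @param slope,intercept Generating line.
#' @param sigma2 Brownian rate of the residuals (0 gives exact collinearity).
#' @param seed Integer seed.
#' @return A list with `tree` (phylo), `data` (taxon, x, y), and `C`.
#' @export
gen_phylo_dataset <- function(n_taxa = 20L, birth_rate = 0.1, slope = 1,
                              intercept = 0, sigma2 = 0.01, seed = 1L) {
  stopifnot(n_taxa >= 4L, birth_rate > 0, sigma2 >= 0)
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  C <- brownian_covariance(tree)
  x <- stats::runif(n_taxa, 0, 2)
  eps <- if (sigma2 > 0) {
    drop(t(chol(sigma2 * C)) %*% stats::rnorm(n_taxa))
  } else {
    numeric(n_taxa)
  }
  list(tree = tree,
       data = data.frame(taxon = tree$tip.label, x = x,
                         y = intercept + slope * x + eps),
       C = C)
}

# clade templates: cervical counts and body proportions chosen to bracket
# the long-necked (elasmosaurid), intermediate (cryptoclidid) and
# short-necked large-headed (pliosaurid) morphotypes
skeleton_templates <- function() {
  list(
    "elasmosaurid-like" = list(
      cn = 40L, n_dorsal = 20L, n_caudal = 30L,
      skull_frac = 0.05, cervical_len = 0.06, dorsal_len = 0.075,
      caudal_len = 0.045, centrum_aspect = c(w = 1.2, h = 1.0),
      max_theta1 = 20, max_theta2 = 25, theta3_range = c(12, -12),
      ral_over_dorsal_len = 6.0, limb_span_frac = 0.22),
    "cryptoclidid-like" = list(
      cn = 28L, n_dorsal = 19L, n_caudal = 28L,
      skull_frac = 0.09, cervical_len = 0.05, dorsal_len = 0.07,
      caudal_len = 0.04, centrum_aspect = c(w = 1.25, h = 1.0),
      max_theta1 = 15, max_theta2 = 9, theta3_range = c(10, -10),
      ral_over_dorsal_len = 6.5, limb_span_frac = 0.25),
    "pliosaurid-like" = list(
      cn = 13L, n_dorsal = 22L, n_caudal = 26L,
      skull_frac = 0.22, cervical_len = 0.045, dorsal_len = 0.08,
      caudal_len = 0.05, centrum_aspect = c(w = 1.3, h = 1.0),
      max_theta1 = 18, max_theta2 = 20, theta3_range = c(10, -10),
      ral_over_dorsal_len = 5.5, limb_span_frac = 0.30))
}

#' Generate an internally consistent synthetic skeleton
#'
#' Builds a complete [skeleton_spec()] for one of three clade templates.
#' Vertebral counts, centrum dimensions, rib-plane angle gradients (both
#' pump-handle and bucket-handle angles increase gradually from 0 degrees in
#' the anterior dorsals to their template maxima in the mid-to-posterior
#' dorsal region), rib arc-length profiles (rising across the anterior half
#' of the dorsal series then shortening posteriorly), girdle widths
#' (feasible for the Pythagorean ventral-height construction), and limb
#' planforms are all generated jointly so every downstream stage runs
#' without error. Every geometric rule is homogeneous of degree 1 in
#' `size_scale`, so estimated mass scales as `size_scale^3`. Mild lognormal
#' jitter (seeded) individualizes centrum dimensions.
#'
#' @param template One of `"elasmosaurid-like"`, `"cryptoclidid-like"`,
#'   `"pliosaurid-like"`.
#' @param size_scale Linear size multiplier (1 gives a mid-sized animal).
#' @param seed Integer seed.
#' @return A [skeleton_spec()].
#' @export
gen_skeleton <- function(template = "cryptoclidid-like", size_scale = 1,
                         seed = 1L) {
  tpl <- skeleton_templates()[[template]]
  if (is.null(tpl)) {
    stop("unknown template '", template, "'; use one of: ",
         paste(names(skeleton_templates()), collapse = ", "))
  }
  stopifnot(size_scale > 0)
  set.seed(seed)
  s <- size_scale
  jitter <- function(n, sigma = 0.02) 10^stats::rnorm(n, 0, sigma)

  # vertebral column (lengths jittered, then scaled)
  mk_region <- function(region, n, len, w_ratio, h_ratio) {
    lens <- len * jitter(n) * s
    data.frame(region = region, position = seq_len(n), length = lens,
               width = lens * w_ratio, height = lens * h_ratio)
  }
  cerv <- mk_region("cervical", tpl$cn, tpl$cervical_len,
                    tpl$centrum_aspect[["w"]], tpl$centrum_aspect[["h"]])
  pect <- mk_region("pectoral", 3L, tpl$dorsal_len * 0.95,
                    tpl$centrum_aspect[["w"]], tpl$centrum_aspect[["h"]])
  dors <- mk_region("dorsal", tpl$n_dorsal, tpl$dorsal_len,
                    tpl$centrum_aspect[["w"]], tpl$centrum_aspect[["h"]])
  sacr <- mk_region("sacral", 3L, tpl$dorsal_len * 0.85,
                    tpl$centrum_aspect[["w"]], tpl$centrum_aspect[["h"]])
  caud <- mk_region("caudal", tpl$n_caudal, tpl$caudal_len,
                    tpl$centrum_aspect[["w"]], tpl$centrum_aspect[["h"]])
  vertebrae <- rbind(cerv, pect, dors, sacr, caud)

  cart <- 0.10
  neck <- sum(cerv$length) * (1 + cart)
  # trunk chord slightly shorter than the summed effective lengths -> gentle arch
  trunk_segments <- c(pect$length, dors$length, sacr$length[1L]) * (1 + cart)
  trunk <- 0.998 * sum(trunk_segments)
  tail <- sum(caud$length) * (1 + cart)
  skl <- max(tpl$skull_frac * (neck + trunk), 2.5 * tpl$dorsal_len * s)

  # rib arc-length profile: rises over the anterior half, shortens after
  nd <- tpl$n_dorsal
  pos <- seq_len(nd)
  peak <- ceiling(nd * 0.55)
  ral_profile <- ifelse(pos <= peak,
                        0.55 + 0.45 * (pos - 1) / (peak - 1),
                        1 - 0.45 * (pos - peak) / (nd - peak))
  max_ral <- tpl$ral_over_dorsal_len * tpl$dorsal_len * s
  ral <- ral_profile * max_ral
  ramp <- pmin((pos - 1) / (peak - 1), 1) # 0 in anterior dorsals -> 1 mid-dorsals
  theta3 <- tpl$theta3_range[1L] +
    (tpl$theta3_range[2L] - tpl$theta3_range[1L]) * (pos - 1) / (nd - 1)
  rib_planes <- data.frame(
    dorsal_position = pos,
    RPH = 0.82 * ral, RPW = 0.38 * ral,
    theta1 = tpl$max_theta1 * ramp, theta2 = tpl$max_theta2 * ramp,
    theta3 = theta3, arc_length = ral)

  glenoid_ral <- ral[1L]
  rib_coef <- glenoid_ral / max_ral

  # girdle widths sized against the glenoid section so the Pythagorean
  # ventral-height construction is always feasible
  glen_proj <- project_rib_plane(rib_plane(rib_planes$RPH[1L], rib_planes$RPW[1L],
                                           0, 0, rib_planes$theta3[1L]))
  glen_width <- mean(dors$width) + 2 * glen_proj$RPW_P3
  coracoid_width <- 0.72 * glen_width
  pubic_width <- 0.68 * glen_width

  mk_limb <- function(span) {
    limb_planform(span = span,
                  chords = 0.28 * span * c(1.0, 1.15, 1.05, 0.85, 0.55, 0.2),
                  thickness_fractions = c(0.30, 0.26, 0.22, 0.20, 0.18, 0.16))
  }
  fore_span <- tpl$limb_span_frac * (neck + trunk)
  hind_span <- 1.05 * fore_span
  hum_l <- 0.33 * fore_span; hum_w <- 0.45 * hum_l
  fem_l <- 0.33 * hind_span; fem_w <- 0.45 * fem_l

  measurements <- list(
    skull_length = skl,
    skull_width_at_quadrate = 0.52 * skl,
    skull_height_at_quadrate = 0.36 * skl,
    cervical_count = tpl$cn,
    neck_length = neck, trunk_length = trunk, tail_length = tail,
    max_rib_arc_length = max_ral, glenoid_rib_arc_length = glenoid_ral,
    coracoid_length = 0.55 * coracoid_width, coracoid_width = coracoid_width,
    pubic_length = 0.55 * pubic_width, pubic_width_max = pubic_width,
    ischium_length = 0.45 * pubic_width, ischium_width = 0.85 * pubic_width,
    humerus_length = hum_l, humerus_distal_width = hum_w,
    femur_length = fem_l, femur_distal_width = fem_w,
    forelimb_length = fore_span, hindlimb_length = hind_span,
    dorsal_centrum_mean_length = mean(dors$length),
    dorsal_centrum_mean_width = mean(dors$width),
    dorsal_centrum_mean_height = mean(dors$height))

  skeleton_spec(
    taxon = paste0("Synthetica ", gsub("-like", "", template)),
    specimen = sprintf("SYN-%s-%d", toupper(substr(template, 1, 3)), seed),
    clade = template,
    measurements = measurements, vertebrae = vertebrae,
    rib_planes = rib_planes, cartilage_fraction = cart,
    rib_coefficient = rib_coef,
    limb_planforms = list(fore_left = mk_limb(fore_span),
                          fore_right = mk_limb(fore_span),
                          hind_left = mk_limb(hind_span),
                          hind_right = mk_limb(hind_span)),
    maturity_flag = TRUE)
}

#' Parametric oracle bodies with closed-form volumes
#'
#' Builds body models whose exact volume is known analytically, for
#' validating the cross-sectional-method integrator: `"spheroid"` (axes
#' `a`, `b`, semi-length `c_len`, sectioned into `n_sections` elliptical
#' stations with point-tapered ends), `"cylinder"` (radius `r`, length
#' `L`), `"cone"` (base radius `r` tapering to a point over `L`),
#' `"frustum"` (radii `r1` to `r2`), and `"lofted_ellipse"` (semi-axes
#' interpolating linearly between stations, a closed form for the linear
#' loft).
#'
#' @param shape Shape family name.
#' @param a,b,c_len Spheroid semi-axes (m).
#' @param r,r1,r2,L Radii and length for the cylindrical families (m).
#' @param stations For `"lofted_ellipse"`: data frame with columns `a`,
#'   `b`, `length` (semi-axes at successive stations and inter-station
#'   distances; `length[1]` is ignored).
#' @param n_sections Number of axial sections for the spheroid.
#' @param n_subslabs Subslabs per slab.
#' @param n_points Contour vertex count.
#' @return A list with `model` (a `plesio_body_model` with no limbs) and
#'   `volume` (the closed-form volume, m^3).
#' @export
gen_parametric_body <- function(shape = c("spheroid", "cylinder", "cone",
                                          "frustum", "lofted_ellipse"),
                                a = 0.5, b = 0.5, c_len = 0.5,
                                r = 0.5, r1 = 1, r2 = 2, L = 2,
                                stations = NULL,
                                n_sections = 100L, n_subslabs = 100L,
                                n_points = 512L) {
  shape <- match.arg(shape)
  ell <- function(sa, sb) skull_section(2 * sa, 2 * sb, n_points = n_points)
  if (shape == "spheroid") {
    z <- seq(-c_len, c_len, length.out = n_sections + 1L)
    semi <- sqrt(pmax(1 - (z / c_len)^2, 0))
    slabs <- vector("list", n_sections)
    for (i in seq_len(n_sections)) {
      front <- if (semi[i] > 0) ell(a * semi[i], b * semi[i]) else NULL
      back <- if (semi[i + 1L] > 0) ell(a * semi[i + 1L], b * semi[i + 1L]) else NULL
      slabs[[i]] <- csm_slab(front, back, z[i + 1L] - z[i], n_subslabs)
    }
    return(list(model = body_model_from_slabs(slabs),
                volume = 4 / 3 * pi * a * b * c_len))
  }
  if (shape == "cylinder") {
    circ <- ell(r, r)
    return(list(model = body_model_from_slabs(list(csm_slab(circ, circ, L, n_subslabs))),
                volume = pi * r^2 * L))
  }
  if (shape == "cone") {
    return(list(model = body_model_from_slabs(
      list(csm_slab(ell(r, r), NULL, L, n_subslabs))),
      volume = pi * r^2 * L / 3))
  }
  if (shape == "frustum") {
    return(list(model = body_model_from_slabs(
      list(csm_slab(ell(r1, r1), ell(r2, r2), L, n_subslabs))),
      volume = pi * L * (r1^2 + r1 * r2 + r2^2) / 3))
  }
  # lofted_ellipse
  if (is.null(stations) || nrow(stations) < 2L) {
    stop("lofted_ellipse needs a stations data frame with >= 2 rows")
  }
  slabs <- list(); vol <- 0
  for (i in seq_len(nrow(stations) - 1L)) {
    a1 <- stations$a[i]; b1 <- stations$b[i]
    a2 <- stations$a[i + 1L]; b2 <- stations$b[i + 1L]
    len <- stations$length[i + 1L]
    slabs[[i]] <- csm_slab(ell(a1, b1), ell(a2, b2), len, n_subslabs)
    # exact integral of pi * a(t) b(t) with linear a, b
    vol <- vol + pi * len * (a1 * b1 + (a1 * b2 + a2 * b1) / 2 + a2 * b2) / 3
  }
  list(model = body_model_from_slabs(slabs), volume = vol)
}
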
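#' Reconstruction configuration
#'
#' Every default mirrors the published protocol constants: 100 subslabs per
#' slab, a 25% linear soft-tissue enlargement of the ribcage sections, a 5%
#' tail soft-tissue extension, and seawater density 1027 kg/m^3. The
#' superellipse exponents shape the cross-section family (dorsal 2.2 leaves
#' room for epaxial musculature; ventral 2.5 flattens the
#' gastralia-supported belly); a global intervertebral cartilage fraction of
#' 0.10 applies unless the skeleton carries per-region overrides.
#'
#' @param cartilage_fraction Global fallback cartilage fraction.
#' @param dorsal_exponent,ventral_exponent Cross-section superellipse
#'   exponents.
#' @param soft_tissue A [soft_tissue_config()].
#' @param n_subslabs Subslabs per slab.
#' @param density Body density (kg/m^3).
#' @param n_points Contour vertex count.
#' @param default_rib_coefficient Used (with a warning) when neither rib
#'   arc lengths nor an explicit rib coefficient are available.
#' @return A list of class `reconstruct_config`.
#' @export
reconstruct_config <- function(cartilage_fraction = 0.10,
                               dorsal_exponent = 2.2, ventral_exponent = 2.5,
                               soft_tissue = soft_tissue_config(),
                               n_subslabs = 100L, density = 1027,
                               n_points = 256L,
                               default_rib_coefficient = 0.8) {
  stopifnot(density > 0, n_subslabs >= 1)
  structure(list(cartilage_fraction = cartilage_fraction,
                 dorsal_exponent = dorsal_exponent,
                 ventral_exponent = ventral_exponent,
                 soft_tissue = soft_tissue, n_subslabs = n_subslabs,
                 density = density, n_points = n_points,
                 default_rib_coefficient = default_rib_coefficient),
            class = "reconstruct_config")
}

# fill unpreserved elements from the packaged regression equations,
# recording which fallback was used
fill_missing_elements <- function(spec, equations = packaged_equations()) {
  m <- spec$measurements
  fills <- list()
  has <- function(f) !is.null(m[[f]]) && !is.na(m[[f]])
  if (!has("trunk_length")) {
    stop("trunk length is required (measured); it cannot be estimated")
  }
  if (!has("max_rib_arc_length")) {
    est <- predict_missing_element("max_ral", list(trunk = m$trunk_length),
                                   equations = equations)
    m$max_rib_arc_length <- est$estimate
    fills$max_rib_arc_length <- est$equation_id
  }
  if (!has("tail_length") && !any(spec$vertebrae$region == "caudal")) {
    est <- predict_missing_element("tail", list(trunk = m$trunk_length),
                                   equations = equations)
    m$tail_length <- est$estimate
    fills$tail_length <- est$equation_id
  }
  if (!has("neck_length") && !any(spec$vertebrae$region == "cervical")) {
    stop("neither neck_length nor cervical vertebrae available")
  }
  if (!has("skull_length")) {
    neck <- m$neck_length
    if (is.null(neck) || is.na(neck)) {
      cerv <- spec$vertebrae[spec$vertebrae$region == "cervical", , drop = FALSE]
      neck <- sum(effective_segment_lengths(cerv, spec$cartilage_fraction))
    }
    est <- predict_missing_element("skull_length",
                                   list(neck = neck, cn = m$cervical_count),
                                   equations = equations)
    m$skull_length <- est$estimate
    fills$skull_length <- est$equation_id
  }
  spec$measurements <- m
  list(spec = spec, fills = fills)
}

# derive the four cross-section specifications from rib orientation,
# girdle widths and vertebral dimensions
derive_sections <- function(spec, config) {
  m <- spec$measurements
  rp <- spec$rib_planes
  if (is.null(rp) || nrow(rp) == 0L) stop("rib planes are required")
  dors <- spec$vertebrae[spec$vertebrae$region == "dorsal", , drop = FALSE]
  cw <- if (nrow(dors)) mean(dors$width) else m$dorsal_centrum_mean_width
  ch <- if (nrow(dors)) mean(dors$height) else m$dorsal_centrum_mean_height
  if (is.null(cw) || is.na(cw)) stop("dorsal centrum width unavailable")

  as_rib <- function(i, theta1 = rp$theta1[i], theta2 = rp$theta2[i],
                     theta3 = rp$theta3[i]) {
    rib_plane(rp$RPH[i], rp$RPW[i], theta1, theta2, theta3,
              rp$dorsal_position[i],
              arc_length = if ("arc_length" %in% names(rp)) rp$arc_length[i] else NULL)
  }

  # glenoid: most anterior dorsal rib; only theta3 applies there
  i_ant <- which.min(rp$dorsal_position)
  glen_proj <- project_rib_plane(as_rib(i_ant, theta1 = 0, theta2 = 0))
  glen_width <- cw + 2 * glen_proj$RPW_P3
  glen_dh <- ch + glen_proj$RPH_P3

  # rib coefficient
  rc <- spec$rib_coefficient
  if (is.null(rc) || is.na(rc)) {
    if (!is.null(m$glenoid_rib_arc_length) && !is.na(m$glenoid_rib_arc_length) &&
        !is.null(m$max_rib_arc_length) && !is.na(m$max_rib_arc_length)) {
      rc <- rib_coefficient(m$glenoid_rib_arc_length, m$max_rib_arc_length)
    } else {
      warning(sprintf("no rib coefficient derivable; using default %.2f",
                      config$default_rib_coefficient))
      rc <- config$default_rib_coefficient
    }
  }

  glen_vh <- ventral_height_from_girdle(m$coracoid_width, glen_width)
  acet_vh <- ventral_height_from_girdle(m$pubic_width_max, glen_width)

  # acetabulum: same width and common ventral line as the glenoid section;
  # dorsal profile is the glenoid profile rescaled by the posterior rib drop
  i_post <- which.max(rp$dorsal_position)
  post_proj <- project_rib_plane(as_rib(i_post, theta2 = 0))
  acet_dh <- ch + post_proj$RPH_P3
  acet_dh <- min(acet_dh, glen_dh) # posterior ribs shorten distally

  # middle: ribs around the middle of the dorsal series, standardized to
  # the maximum rib arc length, theta3 ~ 0; the section plane cuts each rib
  # plane closer to its edge the further the rib sits from the station
  nd <- nrow(rp)
  mid <- (min(rp$dorsal_position) + max(rp$dorsal_position)) / 2
  sel <- which(abs(rp$dorsal_position - mid) <= ceiling(nd / 6))
  ribs <- lapply(sel, function(i) {
    r <- as_rib(i, theta3 = 0)
    if (!is.null(r$arc_length) && !is.null(m$max_rib_arc_length) &&
        !is.na(m$max_rib_arc_length)) {
      r <- standardize_rib_plane(r, m$max_rib_arc_length)
    }
    r
  })
  span <- max(abs(rp$dorsal_position[sel] - mid), 1)
  fracs <- 1 - 0.7 * abs(rp$dorsal_position[sel] - mid) / span
  mid_width <- middle_section_width(ribs, fracs)
  mid_vh <- middle_ventral_height(glen_vh, acet_vh, rc)
  mid_dh <- ch + max(vapply(ribs, function(r) project_rib_plane(r)$RPH_P3, numeric(1)))

  skull_w <- m$skull_width_at_quadrate %||% (0.52 * m$skull_length)
  skull_h <- m$skull_height_at_quadrate %||% (0.36 * m$skull_length)

  list(
    skull = skull_section(skull_w, skull_h, config$n_points),
    glenoid = build_cross_section(glen_width, glen_dh, glen_vh,
                                  config$dorsal_exponent, config$ventral_exponent,
                                  config$n_points),
    middle = build_cross_section(mid_width, mid_dh, mid_vh,
                                 config$dorsal_exponent, config$ventral_exponent,
                                 config$n_points),
    acetabulum = build_cross_section(glen_width, acet_dh, acet_vh,
                                     config$dorsal_exponent, config$ventral_exponent,
                                     config$n_points),
    rib_coefficient = rc)
}

#' Run the full reconstruction pipeline on a skeleton
#'
#' Executes validate -> fill missing elements (packaged regressions) ->
#' body-axis assembly -> ribcage cross-section derivation -> soft-tissue
#' staging -> cross-sectional-method volume integration -> mass conversion.
#'
#' @param spec A [skeleton_spec()] or path to a skeleton JSON file.
#' @param config A [reconstruct_config()].
#' @param out_dir Optional directory for the per-slab CSV report and JSON
#'   summary.
#' @return A list of class `reconstruction`: `spec`, `fills` (fallback
#'   equations used), `axis` (post soft tissue), `sections`, `model`,
#'   `trunk_curve`, `volume` (m^3), `mass` (kg), `report` (per-slab data
#'   frame), `validation`.
#' @export
run_reconstruct <- function(spec, config = reconstruct_config(), out_dir = NULL) {
  if (is.character(spec)) spec <- load_skeleton(spec)
  stopifnot(inherits(spec, "plesio_skeleton"),
            inherits(config, "reconstruct_config"))
  report <- validate_skeleton(spec)
  if (nrow(report$errors)) {
    stop("skeleton fails validation:\n  ",
         paste(report$errors$message, collapse = "\n  "))
  }
  filled <- fill_missing_elements(spec)
  spec <- filled$spec

  axis <- assemble_body_axis(spec, spec$cartilage_fraction %||% config$cartilage_fraction)

  # trunk spinal curvature (reported; slab lengths follow the axial stations)
  trunk_curve <- NULL
  tr <- spec$vertebrae[spec$vertebrae$region %in% c("pectoral", "dorsal"), , drop = FALSE]
  sac1 <- spec$vertebrae[spec$vertebrae$region == "sacral", , drop = FALSE]
  if (nrow(sac1)) sac1 <- sac1[1L, , drop = FALSE]
  tr <- rbind(tr, sac1)
  if (nrow(tr) >= 2L) {
    segs <- effective_segment_lengths(tr, spec$cartilage_fraction %||%
                                        config$cartilage_fraction)
    if (sum(segs) >= spec$measurements$trunk_length) {
      trunk_curve <- tryCatch(
        solve_trunk_curve(spec$measurements$trunk_length, segs),
        error = function(e) {
          warning("trunk curve not solved: ", conditionMessage(e))
          NULL
        })
    }
  }

  sections <- derive_sections(spec, config)
  st <- axis$stations
  slab_lengths <- unname(diff(st))
  model <- body_model(sections[c("skull", "glenoid", "middle", "acetabulum")],
                      slab_lengths, limbs = spec$limb_planforms %||% list(),
                      density = config$density, n_subslabs = config$n_subslabs)
  staged <- apply_soft_tissue(model, axis, config$soft_tissue)
  masses <- body_mass(staged$model)

  out <- structure(list(spec = spec, fills = filled$fills,
                        axis = staged$axis, sections = staged$model$sections,
                        model = staged$model, trunk_curve = trunk_curve,
                        volume = masses$volume, mass = masses$mass,
                        report = masses$report, validation = report),
                   class = "reconstruction")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(masses$report,
                     file.path(out_dir, "volume_report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(taxon = spec$taxon, specimen = spec$specimen,
           total_length_m = staged$axis$total_length,
           volume_m3 = masses$volume, mass_kg = masses$mass,
           density_kg_m3 = config$density,
           fills = filled$fills,
           stations_m = as.list(staged$axis$stations)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> %s (%s)\n", x$spec$taxon, x$spec$specimen))
  cat(sprintf("  total length %.3f m, volume %.4g m^3, mass %.4g kg\n",
              x$axis$total_length, x$volume, x$mass))
  if (length(x$fills)) {
    cat("  filled elements:",
        paste(sprintf("%s (%s)", names(x$fills), unlist(x$fills)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Fit the regression model suite to an allometric dataset
#'
#' Fits the requested models to log10-transformed data and reports
#' coefficients, AICc, and leave-one-out percent prediction errors (mean
#' and SD) for each: OLS; PGLS under Brownian covariance on a supplied
#' dated tree; and the four-parameter log-logistic curve.
#'
#' @param x,y Predictor and response on the antilog scale (> 0); both are
#'   log10-transformed internally.
#' @param models Character subset of `c("ols", "pgls", "ll4")`.
#' @param tree Dated `phylo`, required for PGLS; tips aligned with `x`.
#' @param loo Compute leave-one-out percent prediction errors (default TRUE).
#' @return A list of class `fit_report` with one entry per fitted model:
#'   `fit` and `pe` (a `prediction_error_summary`).
#' @export
run_fit <- function(x, y, models = c("ols", "ll4"), tree = NULL, loo = TRUE) {
  stopifnot(all(x > 0), all(y > 0), length(x) == length(y))
  models <- match.arg(models, c("ols", "pgls", "ll4"), several.ok = TRUE)
  lx <- log10(x); ly <- log10(y)
  out <- list()
  if ("ols" %in% models) {
    fit <- fit_log_linear_ols(lx, ly)
    pe <- if (loo) loo_prediction_error(lx, ly) else NULL
    out$ols <- list(fit = fit, pe = pe)
  }
  if ("pgls" %in% models) {
    if (is.null(tree)) stop("PGLS requested but no tree supplied")
    if (length(tree$tip.label) != length(x)) {
      stop("tree/taxa mismatch: ", length(tree$tip.label), " tips vs ",
           length(x), " samples")
    }
    C <- brownian_covariance(tree)
    fit <- fit_pgls(lx, ly, C = C)
    pe <- if (loo) {
      loo_prediction_error(lx, ly, fitter = function(xt, yt) {
        keep <- match(xt, lx)
        fit_pgls(xt, yt, C = C[keep, keep, drop = FALSE])$predict
      })
    } else {
      NULL
    }
    out$pgls <- list(fit = fit, pe = pe)
  }
  if ("ll4" %in% models) {
    fit <- fit_log_logistic(lx, ly)
    pe <- if (loo) {
      loo_prediction_error(lx, ly,
                           fitter = function(xt, yt) fit_log_logistic(xt, yt)$predict)
    } else {
      NULL
    }
    out$ll4 <- list(fit = fit, pe = pe)
  }
  structure(out, class = "fit_report")
}

#' Predict body masses for a table of specimens
#'
#' Applies the packaged body-mass equations row-wise to a data frame of
#' proxy measurements (meters; any subset of the proxy columns named as in
#' [packaged_equations()]). When both the trunk-length and the
#' dorsal-centrum-volume proxies are available for a row, both estimates
#' are reported together with their bracketing range, following the
#' recommendation to apply the two best equations in tandem.
#'
#' @param proxies Data frame; recognized columns: `trunk`, `skl`, `cn`,
#'   `dorsal_centrum_mean_length`, `dorsal_centrum_mean_width`,
#'   `dorsal_centrum_mean_height`, `humerus_length`, `humerus_width`,
#'   `femur_length`, `femur_width`, `coracoid_length`, `coracoid_width`,
#'   `pubic_length`, `pubic_width`, `ischium_length`, `ischium_width`.
#' @param table `"OLS"` (default) or `"PGLS"`.
#' @return A data frame with one row per input row: per-proxy mass columns
#'   (`mass_<proxy>`), interval bounds for the preferred proxies, and
#'   `mass_bracket_low` / `mass_bracket_high` when at least two preferred
#'   proxies are available.
#' @export
run_predict <- function(proxies, table = "OLS") {
  stopifnot(is.data.frame(proxies))
  if (nrow(proxies) == 0L) {
    return(data.frame())
  }
  direct <- intersect(c("trunk", "humerus_length", "humerus_width",
                        "femur_length", "femur_width", "coracoid_length",
                        "coracoid_width", "pubic_length", "pubic_width",
                        "ischium_length", "ischium_width"),
                      names(proxies))
  out <- vector("list", nrow(proxies))
  for (i in seq_len(nrow(proxies))) {
    row <- proxies[i, , drop = FALSE]
    est <- list()
    for (p in direct) {
      v <- row[[p]]
      if (!is.na(v)) est[[p]] <- predict_body_mass(p, v, table)
    }
    if (all(c("skl", "cn") %in% names(row)) && !is.na(row$skl) && !is.na(row$cn)) {
      est$skl_cn <- predict_body_mass("skl_cn", table = table,
                                      components = list(skl = row$skl, cn = row$cn))
    }
    cd <- c("dorsal_centrum_mean_length", "dorsal_centrum_mean_width",
            "dorsal_centrum_mean_height")
    if (all(cd %in% names(row)) && !anyNA(row[cd])) {
      est$vertebral_volume <- predict_body_mass(
        "vertebral_volume", table = table,
        components = list(centrum_length = row[[cd[1L]]],
                          centrum_width = row[[cd[2L]]],
                          centrum_height = row[[cd[3L]]]))
    }
    rec <- list()
    for (p in names(est)) {
      rec[[paste0("mass_", p)]] <- est[[p]]$mass
      if (!is.null(est[[p]]$interval)) {
        rec[[paste0("mass_", p, "_lower")]] <- est[[p]]$interval$lower
        rec[[paste0("mass_", p, "_upper")]] <- est[[p]]$interval$upper
      }
    }
    pref <- intersect(c("trunk", "vertebral_volume"), names(est))
    if (length(pref) >= 2L) {
      masses <- vapply(est[pref], `[[`, numeric(1), "mass")
      rec$mass_bracket_low <- min(masses)
      rec$mass_bracket_high <- max(masses)
    }
    out[[i]] <- as.data.frame(rec)
  }
  nms <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) {
    for (nm in setdiff(nms, names(d))) d[[nm]] <- NA_real_
    d[, nms, drop = FALSE]
  })
  do.call(rbind, out)
}
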
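#' Published missing-element and body-mass equations
#'
#' Returns the full versioned table of published predictors as a data
#' frame: 13 missing-element equations (trunk-to-rib, tail, and skull-neck
#' models, ids `eq8`-`eq20`), 14 OLS body-mass rows (`table2_*`), and 14
#' PGLS body-mass rows (`table3_*`). Log-linear records carry `slope` and
#' `intercept`; log-logistic records carry `ll_numerator`, `ll_scale`,
#' `ll_exponent`, `ll_offset` for
#' `log10(response) = offset + numerator / (1 + (log10(predictor)/scale)^exponent)`.
#'
#' Units: the missing-element regressions (`eq8`-`eq15`) operate in
#' millimeters; the skull-neck models (`eq16`-`eq20`) are dimensionless
#' (length ratio vs. cervical count); the body-mass tables take meters in
#' and return kilograms. Every record declares its own units so scales
#' cannot be misapplied. `preferred` flags the recommended estimator for
#' each task: the trunk-rib OLS (`eq9`), trunk-tail OLS (`eq15`), the
#' full-dataset log-logistic skull-neck model (`eq20`), and the OLS mass
#' table over the PGLS one.
#'
#' @return A data frame with one row per equation record.
#' @export
packaged_equations <- function() {
  schema <- list(schema_version = "1.0")
  rec <- function(id, group, response, predictor, form, method,
                  slope = NA, intercept = NA,
                  ll_numerator = NA, ll_scale = NA, ll_exponent = NA,
                  ll_offset = NA, n = NA, r_squared = NA, aicc = NA,
                  mean_abs_pe = NA, sd_abs_pe = NA,
                  units_in = "m", units_out = "m", preferred = FALSE) {
    data.frame(id = id, group = group, response = response,
               predictor = predictor, form = form, method = method,
               slope = slope, intercept = intercept,
               ll_numerator = ll_numerator, ll_scale = ll_scale,
               ll_exponent = ll_exponent, ll_offset = ll_offset,
               n = n, r_squared = r_squared, aicc = aicc,
               mean_abs_pe = mean_abs_pe, sd_abs_pe = sd_abs_pe,
               units_in = units_in, units_out = units_out,
               preferred = preferred)
  }
  missing_el <- rbind(
    rec("eq8", "missing_element", "max_rib_arc_length", "trunk_length",
        "log-linear", "PGLS", slope = 1.0019, intercept = -0.4365, n = 24,
        aicc = -36.85, mean_abs_pe = 15.22, units_in = "mm", units_out = "mm"),
    rec("eq9", "missing_element", "max_rib_arc_length", "trunk_length",
        "log-linear", "OLS", slope = 1.0123, intercept = -0.5068, n = 24,
        r_squared = 0.9030, aicc = -54.88, mean_abs_pe = 14.29,
        units_in = "mm", units_out = "mm", preferred = TRUE),
    rec("eq10", "missing_element", "tail_length", "femur_length",
        "log-linear", "PGLS", slope = 0.9706, intercept = 0.6887, n = 22,
        aicc = -26.76, mean_abs_pe = 19.80, units_in = "mm", units_out = "mm"),
    rec("eq11", "missing_element", "tail_length", "femur_distal_width",
        "log-linear", "PGLS", slope = 0.7780, intercept = 1.4225, n = 22,
        aicc = -28.54, mean_abs_pe = 16.32, units_in = "mm", units_out = "mm"),
    rec("eq12", "missing_element", "tail_length", "trunk_length",
        "log-linear", "PGLS", slope = 0.8434, intercept = 0.4895, n = 22,
        aicc = -41.25, mean_abs_pe = 12.77, units_in = "mm", units_out = "mm"),
    rec("eq13", "missing_element", "tail_length", "femur_length",
        "log-linear", "OLS", slope = 0.8074, intercept = 1.0675, n = 22,
        r_squared = 0.6098, aicc = -34.94, mean_abs_pe = 19.56,
        units_in = "mm", units_out = "mm"),
    rec("eq14", "missing_element", "tail_length", "femur_distal_width",
        "log-linear", "OLS", slope = 0.8231, intercept = 1.2899, n = 22,
        r_squared = 0.7217, aicc = -42.38, mean_abs_pe = 17.42,
        units_in = "mm", units_out = "mm"),
    rec("eq15", "missing_element", "tail_length", "trunk_length",
        "log-linear", "OLS", slope = 0.8414, intercept = 0.4803, n = 22,
        r_squared = 0.8175, aicc = -51.66, mean_abs_pe = 13.43,
        units_in = "mm", units_out = "mm", preferred = TRUE),
    rec("eq16", "missing_element", "skull_neck_ratio", "cervical_count",
        "log-linear", "PGLS", slope = -1.4695, intercept = 1.5560, n = 37,
        aicc = -74.11, mean_abs_pe = 19.00, units_in = "", units_out = ""),
    rec("eq17", "missing_element", "skull_neck_ratio", "cervical_count",
        "log-linear", "OLS", slope = -1.4851, intercept = 1.5568, n = 37,
        aicc = -69.10, mean_abs_pe = 18.63, units_in = "", units_out = ""),
    rec("eq18", "missing_element", "skull_neck_ratio", "cervical_count",
        "log-logistic", "LL4", ll_numerator = 1.2808, ll_scale = 1.5844,
        ll_exponent = 10.2843, ll_offset = -1.4398, n = 37,
        aicc = -94.18, mean_abs_pe = 11.92, units_in = "", units_out = ""),
    rec("eq19", "missing_element", "skull_neck_ratio", "cervical_count",
        "log-linear", "OLS", slope = -1.5065, intercept = 1.5916, n = 40,
        aicc = -73.70, mean_abs_pe = 19.07, units_in = "", units_out = ""),
    rec("eq20", "missing_element", "skull_neck_ratio", "cervical_count",
        "log-logistic", "LL4", ll_numerator = 1.3067, ll_scale = 1.5937,
        ll_exponent = 10.2847, ll_offset = -1.4684, n = 40,
        aicc = -103.58, mean_abs_pe = 11.86, units_in = "", units_out = "",
        preferred = TRUE))

  t2 <- list( # proxy, slope, intercept, n, r2, pe, sd
    skl_cn = c(2.8228, -0.3800, 19, 0.9169, 50.76, 43.57),
    trunk = c(2.9292, 2.4367, 27, 0.9836, 17.73, 13.94),
    vertebral_volume = c(1.0257, 6.5333, 14, 0.9768, 22.65, 12.40),
    vertebral_area = c(1.4711, 6.2890, 14, 0.9657, 25.83, 25.16),
    humerus_length = c(2.9617, 4.2510, 26, 0.8314, 60.67, 79.48),
    humerus_width = c(3.4183, 5.3925, 26, 0.8230, 63.76, 67.39),
    femur_length = c(2.5684, 4.0469, 24, 0.8150, 73.21, 107.42),
    femur_width = c(3.1556, 5.2276, 24, 0.9055, 43.24, 47.89),
    coracoid_length = c(2.5219, 3.7767, 17, 0.9041, 47.03, 33.08),
    coracoid_width = c(2.7437, 4.6120, 24, 0.9144, 40.64, 31.44),
    pubic_length = c(2.3601, 4.1001, 19, 0.8559, 53.51, 53.45),
    pubic_width = c(2.9436, 4.4309, 20, 0.9076, 44.75, 35.66),
    ischium_length = c(2.0943, 3.9879, 21, 0.8305, 63.40, 74.11),
    ischium_width = c(2.9946, 4.8402, 23, 0.9455, 35.44, 41.75))
  t3 <- list( # proxy, slope, intercept, n, aicc_pgls
    skl_cn = c(4.1469, -1.8817, 18, 28.69),
    trunk = c(2.8160, 2.4871, 26, -34.70),
    vertebral_volume = c(0.9924, 6.3991, 13, 1.94),
    vertebral_area = c(1.4067, 6.1423, 13, 5.74),
    humerus_length = c(3.1155, 4.1540, 25, 30.76),
    humerus_width = c(3.0397, 5.1027, 25, 21.55),
    femur_length = c(3.3919, 4.2695, 23, 31.41),
    femur_width = c(2.6469, 4.8335, 23, 13.68),
    coracoid_length = c(2.1043, 3.6265, 16, 8.1),
    coracoid_width = c(2.8824, 4.6642, 23, -6.18),
    pubic_length = c(2.2077, 4.0294, 18, 17.35),
    pubic_width = c(3.0576, 4.4702, 19, 5.33),
    ischium_length = c(1.9700, 3.8969, 20, 19.48),
    ischium_width = c(3.0640, 4.8734, 22, -0.19))
  mass_ols <- do.call(rbind, lapply(names(t2), function(p) {
    v <- t2[[p]]
    rec(paste0("table2_", p), "mass_ols", "body_mass", p, "log-linear", "OLS",
        slope = v[1L], intercept = v[2L], n = v[3L], r_squared = v[4L],
        mean_abs_pe = v[5L], sd_abs_pe = v[6L],
        units_in = "m", units_out = "kg", preferred = TRUE)
  }))
  mass_pgls <- do.call(rbind, lapply(names(t3), function(p) {
    v <- t3[[p]]
    rec(paste0("table3_", p), "mass_pgls", "body_mass", p, "log-linear", "PGLS",
        slope = v[1L], intercept = v[2L], n = v[3L], aicc = v[4L],
        units_in = "m", units_out = "kg", preferred = FALSE)
  }))
  out <- rbind(missing_el, mass_ols, mass_pgls)
  attr(out, "schema_version") <- schema$schema_version
  out
}

#' Look up one equation record by id
#'
#' @param id Record id, e.g. `"eq9"` or `"table2_trunk"`.
#' @param equations Equation table (defaults to [packaged_equations()]).
#' @return A single-row data frame.
#' @export
equation_record <- function(id, equations = packaged_equations()) {
  row <- equations[equations$id == id, , drop = FALSE]
  if (nrow(row) != 1L) stop(sprintf("unknown equation id '%s'", id))
  row
}

eval_log_linear <- function(row, value_log10) {
  row$slope * value_log10 + row$intercept
}

eval_log_logistic <- function(row, x) {
  row$ll_offset + row$ll_numerator / (1 + (x / row$ll_scale)^row$ll_exponent)
}

#' Predict a missing skeletal element
#'
#' Applies the packaged missing-element equations: maximum rib arc length
#' from trunk length (`eq9`), tail length from trunk length (`eq15`), and
#' skull length from neck length and cervical count via the log-logistic
#' skull-to-neck ratio curve (`eq20`): with
#' `r = 10^f(log10 CN)` (the predicted SKL/(SKL + neck) ratio),
#' `SKL = neck * r / (1 - r)`. Total flipper length from propodial distal
#' width uses an external published equation whose coefficients are not
#' packaged; supply them via `limb_coefficients` (log-linear slope and
#' intercept on the mm scale).
#'
#' @param element One of `"max_ral"`, `"tail"`, `"skull_length"`,
#'   `"limb_length"`.
#' @param inputs Named list: `trunk` (m) for max_ral/tail; `neck` (m) and
#'   `cn` for skull_length; `propodial_distal_width` (m) for limb_length.
#' @param units Unit of the supplied inputs and of the returned estimate
#'   (`"m"`, `"cm"` or `"mm"`); conversion to each equation's native unit
#'   is handled internally.
#' @param limb_coefficients Optional list with `slope` and `intercept` for
#'   the limb-length equation (native mm scale).
#' @param equations Equation table override.
#' @return A list with `estimate`, `interval` (a [prediction_interval()]),
#'   `equation_id`, and `ratio` (skull solve only).
#' @export
predict_missing_element <- function(element, inputs, units = "m",
                                    limb_coefficients = NULL,
                                    equations = packaged_equations()) {
  element <- match.arg(element, c("max_ral", "tail", "skull_length", "limb_length"))
  to_m <- unit_scale(units)
  if (element %in% c("max_ral", "tail")) {
    trunk <- inputs$trunk
    if (is.null(trunk) || !is.finite(trunk) || trunk <= 0) {
      stop("a positive 'trunk' input is required")
    }
    row <- equation_record(if (element == "max_ral") "eq9" else "eq15", equations)
    trunk_mm <- trunk * to_m * 1000
    est_mm <- 10^eval_log_linear(row, log10(trunk_mm))
    est <- est_mm / 1000 / to_m
    return(list(estimate = est,
                interval = prediction_interval(est, row$mean_abs_pe),
                equation_id = row$id))
  }
  if (element == "skull_length") {
    neck <- inputs$neck; cn <- inputs$cn
    if (is.null(neck) || neck <= 0 || is.null(cn) || cn < 1) {
      stop("positive 'neck' and 'cn' inputs are required")
    }
    row <- equation_record("eq20", equations)
    ratio <- 10^eval_log_logistic(row, log10(cn))
    if (ratio >= 1) {
      stop(sprintf("infeasible skull solve: predicted SKL/(SKL+neck) ratio %.3f >= 1", ratio))
    }
    est <- neck * ratio / (1 - ratio)
    return(list(estimate = est,
                interval = prediction_interval(est, row$mean_abs_pe),
                equation_id = row$id, ratio = ratio))
  }
  # limb_length
  if (is.null(limb_coefficients)) {
    stop(paste0("external coefficients required: the propodial-width to ",
                "limb-length equation is published elsewhere; supply ",
                "limb_coefficients = list(slope =, intercept =)"))
  }
  w <- inputs$propodial_distal_width
  if (is.null(w) || w <= 0) stop("a positive 'propodial_distal_width' input is required")
  w_mm <- w * to_m * 1000
  est_mm <- 10^(limb_coefficients$slope * log10(w_mm) + limb_coefficients$intercept)
  est <- est_mm / 1000 / to_m
  list(estimate = est, interval = NULL, equation_id = "external_limb")
}

mass_proxies <- function() {
  c("skl_cn", "trunk", "vertebral_volume", "vertebral_area",
    "humerus_length", "humerus_width", "femur_length", "femur_width",
    "coracoid_length", "coracoid_width", "pubic_length", "pubic_width",
    "ischium_length", "ischium_width")
}

#' Predict body mass from a skeletal proxy
#'
#' Evaluates the packaged body-mass regressions:
#' `mass = 10^(slope * log10(value) + intercept)` kg with the proxy value in
#' meters (composite proxies are computed from their components first:
#' `skl_cn` = skull length x cervical count; `vertebral_volume` = mean
#' dorsal centrum length x width x height; `vertebral_area` = mean width x
#' height). The OLS table is the recommended default; the PGLS table is
#' retained for comparison (it publishes no percent prediction errors, so
#' its intervals are `NULL`).
#'
#' @param proxy Proxy name (see [packaged_equations()] `predictor` column).
#' @param value Proxy value in meters (or the composite product); ignored
#'   when `components` is given.
#' @param table `"OLS"` (Table of OLS fits, default) or `"PGLS"`.
#' @param components Optional named list to build composite proxies:
#'   `skl` and `cn`, or `centrum_length`/`centrum_width`/`centrum_height`.
#' @param equations Equation table override.
#' @return A list of class `mass_estimate`: `mass` (kg), `interval`,
#'   `proxy_used`, `equation_id`.
#' @export
predict_body_mass <- function(proxy, value = NULL, table = c("OLS", "PGLS"),
                              components = NULL,
                              equations = packaged_equations()) {
  table <- match.arg(table)
  if (!proxy %in% mass_proxies()) {
    stop("unknown proxy '", proxy, "'; available: ",
         paste(mass_proxies(), collapse = ", "))
  }
  if (!is.null(components)) {
    value <- switch(proxy,
      skl_cn = components$skl * components$cn,
      vertebral_volume = components$centrum_length * components$centrum_width *
        components$centrum_height,
      vertebral_area = components$centrum_width * components$centrum_height,
      stop("components are only used for composite proxies"))
  }
  if (is.null(value) || !is.finite(value) || value <= 0) {
    stop("proxy value must be positive")
  }
  id <- paste0(if (table == "OLS") "table2_" else "table3_", proxy)
  row <- equation_record(id, equations)
  mass <- 10^eval_log_linear(row, log10(value))
  interval <- if (is.finite(row$mean_abs_pe)) {
    prediction_interval(mass, row$mean_abs_pe)
  } else {
    NULL
  }
  structure(list(mass = mass, interval = interval, proxy_used = proxy,
                 equation_id = id),
            class = "mass_estimate")
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf("<mass_estimate> %.4g kg (proxy %s, %s)\n", x$mass,
              x$proxy_used, x$equation_id))
  if (!is.null(x$interval)) {
    cat(sprintf("  symmetric |%%PE| interval: [%.4g, %.4g] kg\n",
                x$interval$lower, x$interval$upper))
  }
  invisible(x)
}

#' Write or read the equation table as a documented CSV file
#'
#' The CSV round-trips every packaged coefficient unchanged; a copy ships
#' with the package under `inst/extdata/equation_table.csv`.
#'
#' @param path CSV path.
#' @param equations Table to write.
#' @return The table (read) or the path (write, invisibly).
#' @export
write_equation_table <- function(path, equations = packaged_equations()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plesiomass equation table, schema_version %s",
                     attr(equations, "schema_version") %||% "1.0"), con)
  utils::write.csv(equations, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_equation_table
#' @export
read_equation_table <- function(path = system.file("extdata", "equation_table.csv",
                                                   package = "plesiomass")) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^#", first)) 1L else 0L
  out <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
  ver <- regmatches(first, regexec("schema_version\\s+(\\S+)", first))[[1]]
  attr(out, "schema_version") <- if (length(ver) == 2L) ver[2L] else NA_character_
  out
}
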
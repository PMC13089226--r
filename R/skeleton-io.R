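#' @keywords internal
"_PACKAGE"

# Canonical measurement field names. Internal unit is meters everywhere;
# readers accept a per-file unit declaration (m | cm | mm) and convert on load.
measurement_fields <- function() {
  c("skull_length", "skull_width_at_quadrate", "skull_height_at_quadrate",
    "cervical_count", "neck_length", "trunk_length", "tail_length",
    "max_rib_arc_length", "glenoid_rib_arc_length",
    "coracoid_length", "coracoid_width", "pubic_length", "pubic_width_max",
    "ischium_length", "ischium_width",
    "humerus_length", "humerus_distal_width", "femur_length",
    "femur_distal_width", "forelimb_length", "hindlimb_length",
    "dorsal_centrum_mean_length", "dorsal_centrum_mean_width",
    "dorsal_centrum_mean_height")
}

unit_scale <- function(units) {
  switch(units, m = 1, cm = 0.01, mm = 0.001,
         stop(sprintf("unknown unit declaration '%s' (use m, cm or mm)", units)))
}

#' Read or write a per-specimen measurement table
#'
#' The measurement CSV holds one row per specimen with the documented header
#' names (`taxon`, `cervical_count`, and any subset of the linear
#' measurements, all in the declared unit). An optional first metadata line
#' `# units: mm` (or `cm`, `m`) declares the unit of every linear
#' measurement; the default is meters, the package-internal unit. Unknown
#' columns are ignored with a warning; missing values are `NA`.
#'
#' @param path CSV file path.
#' @return For `load_measurements()`, a data frame with one row per
#'   specimen, linear measurements converted to meters.
#' @export
load_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("measurement file not found: %s", path))
  first <- readLines(path, n = 1L)
  units <- "m"
  skip <- 0L
  if (grepl("^#", first)) {
    mt <- regmatches(first, regexec("units\\s*[:=]\\s*(m|cm|mm)", first))[[1]]
    if (length(mt) == 2L) units <- mt[2L] else stop("unparseable metadata line: ", first)
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = FALSE)
  mandatory <- c("taxon", "cervical_count")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known <- c("taxon", "specimen", "clade", measurement_fields())
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  numeric_cols <- intersect(measurement_fields(), names(df))
  s <- unit_scale(units)
  for (col in numeric_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric value '%s' in row %d, column '%s'",
                     v[bad[1L]], bad[1L], col))
      }
      v <- conv
    }
    neg <- which(!is.na(v) & v <= 0)
    if (length(neg)) {
      stop(sprintf("validation error: non-positive %s in row %d", col, neg[1L]))
    }
    if (col != "cervical_count") v <- v * s
    df[[col]] <- as.numeric(v)
  }
  if (any(!is.na(df$cervical_count) & df$cervical_count < 1)) {
    stop("validation error: cervical_count must be >= 1")
  }
  df
}

#' @rdname load_measurements
#' @param measurements Data frame as returned by `load_measurements()`
#'   (meters).
#' @param units Unit to declare and convert to on write.
#' @export
write_measurements <- function(measurements, path, units = "m") {
  s <- unit_scale(units)
  out <- measurements
  for (col in intersect(measurement_fields(), names(out))) {
    if (col != "cervical_count") out[[col]] <- out[[col]] / s
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", units), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Full per-specimen skeleton specification
#'
#' Bundles everything a reconstruction needs: the measurement set, the
#' ordered vertebral column (cervical, pectoral, dorsal, sacral, caudal;
#' 1-based positions within region), rib planes keyed to dorsal positions,
#' cartilage fractions, the rib coefficient, and per-limb planforms.
#'
#' @param taxon,specimen,clade Identification strings.
#' @param measurements Single-row data frame or named list of measurements
#'   (meters); must include `cervical_count`.
#' @param vertebrae Data frame with columns `region`, `position`, `length`,
#'   `width`, `height` (m).
#' @param rib_planes Data frame with columns `dorsal_position`, `RPH`,
#'   `RPW`, `theta1`, `theta2`, `theta3`, and optionally `arc_length`.
#' @param cartilage_fraction Scalar or named per-region vector (>= 0).
#' @param rib_coefficient Optional scalar in (0, 1].
#' @param limb_planforms Named list (`fore`, `hind`) of [limb_planform()]s.
#' @param maturity_flag TRUE for osteologically mature individuals.
#' @return A list of class `plesio_skeleton`.
#' @export
skeleton_spec <- function(taxon, specimen = "", clade = "",
                          measurements, vertebrae = NULL, rib_planes = NULL,
                          cartilage_fraction = 0.10, rib_coefficient = NULL,
                          limb_planforms = NULL, maturity_flag = TRUE) {
  if (is.data.frame(measurements)) measurements <- as.list(measurements[1L, ])
  stopifnot(is.list(measurements), !is.null(measurements$cervical_count))
  if (is.null(vertebrae)) {
    vertebrae <- data.frame(region = character(), position = integer(),
                            length = numeric(), width = numeric(),
                            height = numeric())
  }
  structure(list(taxon = taxon, specimen = specimen, clade = clade,
                 measurements = measurements, vertebrae = vertebrae,
                 rib_planes = rib_planes,
                 cartilage_fraction = cartilage_fraction,
                 rib_coefficient = rib_coefficient,
                 limb_planforms = limb_planforms,
                 maturity_flag = isTRUE(maturity_flag)),
            class = "plesio_skeleton")
}

#' @export
print.plesio_skeleton <- function(x, ...) {
  cat(sprintf("<plesio_skeleton> %s (%s), clade %s\n", x$taxon,
              x$specimen, x$clade))
  cat(sprintf("  %d vertebrae, %d rib planes, CN = %s\n",
              nrow(x$vertebrae),
              if (is.null(x$rib_planes)) 0L else nrow(x$rib_planes),
              x$measurements$cervical_count))
  invisible(x)
}

skeleton_schema_version <- "1.0"

#' Read or write a skeleton specification as versioned JSON
#'
#' The JSON document carries a `schema_version` field; loading a document
#' with a different major version is an explicit error. Nullable fields are
#' preserved as explicit nulls.
#'
#' @param path JSON file path.
#' @return For `load_skeleton()`, a [skeleton_spec()].
#' @export
load_skeleton <- function(path) {
  if (!file.exists(path)) stop(sprintf("skeleton file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) ||
      doc$schema_version != skeleton_schema_version) {
    stop(sprintf("schema-version mismatch: file has '%s', reader supports '%s'",
                 doc$schema_version %||% "<missing>", skeleton_schema_version))
  }
  meas <- lapply(doc$measurements, function(v) if (is.null(v)) NA_real_ else v)
  planforms <- NULL
  if (!is.null(doc$limb_planforms)) {
    planforms <- lapply(doc$limb_planforms, function(p) {
      limb_planform(span = p$span, chords = p$chords,
                    thickness_fractions = p$thickness_fractions,
                    section_area_coefficient = p$section_area_coefficient)
    })
  }
  spec <- skeleton_spec(
    taxon = doc$taxon, specimen = doc$specimen %||% "",
    clade = doc$clade %||% "", measurements = meas,
    vertebrae = as.data.frame(doc$vertebrae),
    rib_planes = if (is.null(doc$rib_planes)) NULL else as.data.frame(doc$rib_planes),
    cartilage_fraction = unlist(doc$cartilage_fraction),
    rib_coefficient = doc$rib_coefficient,
    limb_planforms = planforms,
    maturity_flag = doc$maturity_flag %||% TRUE)
  ord <- region_order_errors(spec$vertebrae)
  if (length(ord)) stop("validation error: ", ord[[1L]])
  spec
}

#' @rdname load_skeleton
#' @param spec A [skeleton_spec()].
#' @export
write_skeleton <- function(spec, path) {
  stopifnot(inherits(spec, "plesio_skeleton"))
  doc <- list(schema_version = skeleton_schema_version,
              taxon = spec$taxon, specimen = spec$specimen, clade = spec$clade,
              measurements = spec$measurements,
              vertebrae = spec$vertebrae, rib_planes = spec$rib_planes,
              cartilage_fraction = as.list(spec$cartilage_fraction),
              rib_coefficient = spec$rib_coefficient,
              limb_planforms = lapply(spec$limb_planforms, unclass),
              maturity_flag = spec$maturity_flag)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

region_levels <- c("cervical", "pectoral", "dorsal", "sacral", "caudal")

region_order_errors <- function(vertebrae) {
  if (nrow(vertebrae) == 0L) return(character())
  errs <- character()
  r <- as.character(vertebrae$region)
  bad <- setdiff(unique(r), region_levels)
  if (length(bad)) {
    errs <- c(errs, paste0("unknown vertebral region(s): ",
                           paste(bad, collapse = ", ")))
  }
  idx <- match(r, region_levels)
  if (any(diff(idx) < 0, na.rm = TRUE)) {
    errs <- c(errs, paste0("vertebral regions out of order ",
                           "(must run cervical -> pectoral -> dorsal -> sacral -> caudal)"))
  }
  errs
}

#' Validate a skeleton specification
#'
#' Checks every structural invariant and reports problems without stopping:
#' errors make the spec unusable for reconstruction, warnings flag nullable
#' fields a downstream stage will have to estimate (naming the fallback
#' equation that will be used).
#'
#' @param spec A [skeleton_spec()].
#' @return A list of class `validation_report` with data frames `errors` and
#'   `warnings` (columns `field`, `message`).
#' @export
validate_skeleton <- function(spec) {
  errs <- list(); warns <- list()
  add_err <- function(field, msg) errs[[length(errs) + 1L]] <<- c(field, msg)
  add_warn <- function(field, msg) warns[[length(warns) + 1L]] <<- c(field, msg)
  m <- spec$measurements

  cn <- m$cervical_count
  if (is.null(cn) || is.na(cn) || cn < 1) {
    add_err("cervical_count", "cervical count is required and must be >= 1")
  }
  for (f in setdiff(measurement_fields(), "cervical_count")) {
    v <- m[[f]]
    if (!is.null(v) && !is.na(v) && v <= 0) {
      add_err(f, sprintf("%s must be positive, got %g", f, v))
    }
  }
  if (nrow(spec$vertebrae)) {
    for (e in region_order_errors(spec$vertebrae)) add_err("vertebrae", e)
    bad <- with(spec$vertebrae, length <= 0 | width <= 0 | height <= 0)
    if (any(bad)) add_err("vertebrae", "centrum dimensions must be positive")
    if (any(spec$vertebrae$position < 1)) {
      add_err("vertebrae", "positions are 1-based within region")
    }
    ncerv <- sum(spec$vertebrae$region == "cervical")
    if (ncerv > 0 && !is.null(cn) && !is.na(cn) && ncerv != cn) {
      add_err("vertebrae", sprintf(
        "cervical vertebra count (%d) inconsistent with cervical_count (%d)",
        ncerv, cn))
    }
  }
  rc <- spec$rib_coefficient
  if (!is.null(rc) && !is.na(rc) && !(rc > 0 && rc <= 1)) {
    add_err("rib_coefficient", "rib coefficient must be in (0,1]")
  }
  if (!is.null(spec$rib_planes) && nrow(spec$rib_planes)) {
    rp <- spec$rib_planes
    if (any(rp$RPH <= 0 | rp$RPW <= 0)) {
      add_err("rib_planes", "RPH and RPW must be positive")
    }
    if (any(rp$theta1 < -90 | rp$theta1 > 90) ||
        any(rp$theta2 < 0 | rp$theta2 > 90) ||
        any(rp$theta3 < -90 | rp$theta3 > 90)) {
      add_err("rib_planes", "rib slant angles outside their stated ranges")
    }
  } else {
    add_warn("rib_planes", "no rib planes: ribcage sections cannot be derived")
  }
  if (any(region_fractions(spec$cartilage_fraction) < 0)) {
    add_err("cartilage_fraction", "cartilage fractions must be >= 0")
  }
  has <- function(f) !is.null(m[[f]]) && !is.na(m[[f]])
  if (!has("max_rib_arc_length") && has("trunk_length")) {
    add_warn("max_rib_arc_length",
             "missing: will be estimated from trunk length (trunk-rib OLS equation, eq9)")
  }
  no_caudals <- !any(spec$vertebrae$region == "caudal")
  if (!has("tail_length") && no_caudals && has("trunk_length")) {
    add_warn("tail_length",
             "missing: will be estimated from trunk length (trunk-tail OLS equation, eq15)")
  }
  if (!has("skull_length") && has("neck_length")) {
    add_warn("skull_length",
             "missing: will be estimated from neck length and cervical count (log-logistic equation, eq20)")
  }
  as_report <- function(lst) {
    if (!length(lst)) {
      return(data.frame(field = character(), message = character()))
    }
    m <- do.call(rbind, lst)
    data.frame(field = m[, 1L], message = m[, 2L], row.names = NULL)
  }
  structure(list(errors = as_report(errs), warnings = as_report(warns)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    cat("errors:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat(sprintf("  [%s] %s\n", x$errors$field[i], x$errors$message[i]))
    }
  }
  if (nrow(x$warnings)) {
    cat("warnings:\n")
    for (i in seq_len(nrow(x$warnings))) {
      cat(sprintf("  [%s] %s\n", x$warnings$field[i], x$warnings$message[i]))
    }
  }
  invisible(x)
}
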
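#' Cartilage-adjusted effective vertebral segment lengths
#'
#' Intervertebral cartilage thickness increases in proportion with vertebral
#' dimensions, so each vertebra contributes an effective axial length of
#' `centrum_length * (1 + fraction)`. The fraction may be a single global
#' value or a named vector of per-region overrides
#' (cervical/pectoral/dorsal/sacral/caudal).
#'
#' @param vertebrae Data frame with at least columns `region` and `length`
#'   (m), as held by a [skeleton_spec()].
#' @param cartilage_fraction Non-negative scalar, or named numeric vector of
#'   per-region fractions (unnamed element or `"default"` supplies the
#'   fallback).
#' @return Numeric vector of effective segment lengths (m), one per vertebra.
#' @export
effective_segment_lengths <- function(vertebrae, cartilage_fraction = 0.10) {
  stopifnot(is.data.frame(vertebrae), all(c("region", "length") %in% names(vertebrae)),
            all(cartilage_fraction >= 0))
  frac <- region_fractions(cartilage_fraction)[as.character(vertebrae$region)]
  unname(vertebrae$length * (1 + frac))
}

region_fractions <- function(cartilage_fraction) {
  regions <- c("cervical", "pectoral", "dorsal", "sacral", "caudal")
  if (is.null(names(cartilage_fraction))) {
    stopifnot(length(cartilage_fraction) == 1L)
    return(stats::setNames(rep(cartilage_fraction, 5L), regions))
  }
  default <- cartilage_fraction[["default"]] %||% 0.10
  out <- stats::setNames(rep(default, 5L), regions)
  known <- intersect(names(cartilage_fraction), regions)
  out[known] <- cartilage_fraction[known]
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Solve the trunk spinal curvature as an arc-constrained polyline
#'
#' Finds the circular arc through the two trunk endpoints (separated by the
#' trunk chord) such that a polyline whose vertices lie on the arc, with
#' chord lengths prescribed by the effective vertebral segment lengths, ends
#' exactly on the far endpoint. A circular arc is the minimal-assumption
#' smooth curve for the gentle dorsal arch of the plesiosaur trunk and makes
#' the solve a 1-D root-find on curvature.
#'
#' @param chord Trunk length (anterior scapula margin to acetabulum, m).
#' @param segment_lengths Effective per-vertebra segment lengths (m); their
#'   sum must be >= `chord` (and < (pi/2) * chord: gentle arch only).
#' @return A list of class `spinal_curve`: `chord`, `arc_length` (sum of
#'   segment lengths), `radius`, `subtended_angle` (radians), `sagitta`, and
#'   `vertices` (data frame x, y with the chord on the x-axis and the arch
#'   bulging to +y).
#' @export
solve_trunk_curve <- function(chord, segment_lengths) {
  stopifnot(chord > 0, all(segment_lengths > 0))
  S <- sum(segment_lengths)
  if (S < chord * (1 - 1e-12)) {
    stop(sprintf("infeasible: segment lengths sum to %.6g m < chord %.6g m", S, chord))
  }
  if (S >= (pi / 2) * chord) {
    stop("segment lengths imply an arch stronger than the gentle-arch limit")
  }
  n <- length(segment_lengths)
  if (abs(S - chord) <= 1e-12 * chord) {
    xs <- c(0, cumsum(segment_lengths)) * (chord / S)
    return(structure(list(chord = chord, arc_length = S, radius = Inf,
                          subtended_angle = 0, sagitta = 0,
                          vertices = data.frame(x = xs, y = rep(0, n + 1L))),
                     class = "spinal_curve"))
  }
  # endpoint separation of the polyline inscribed in a circle of curvature k
  endpoint_gap <- function(k) {
    R <- 1 / k
    2 * R * sin(sum(asin(pmin(segment_lengths * k / 2, 1))) ) - chord
  }
  k_hi <- 2 / max(segment_lengths) * (1 - 1e-9)
  k_lo <- 1e-12 / chord
  if (endpoint_gap(k_hi) > 0) {
    stop("no curvature in bracket closes the chord; check segment lengths")
  }
  root <- stats::uniroot(endpoint_gap, c(k_lo, k_hi), tol = 1e-15 * chord)
  k <- root$root
  R <- 1 / k
  delta <- 2 * asin(segment_lengths / (2 * R))
  theta <- sum(delta)
  yc <- -sqrt(max(R^2 - (chord / 2)^2, 0))
  alpha0 <- atan2(-yc, -chord / 2)
  alpha <- alpha0 - c(0, cumsum(delta))
  vx <- chord / 2 + R * cos(alpha)
  vy <- yc + R * sin(alpha)
  # pin the endpoints exactly onto the chord
  vx[1L] <- 0; vy[1L] <- 0
  miss <- sqrt((vx[n + 1L] - chord)^2 + vy[n + 1L]^2)
  if (miss > 1e-8 * chord) {
    stop(sprintf("trunk-curve solve did not converge: endpoint miss %.3g m", miss))
  }
  structure(list(chord = chord, arc_length = S, radius = R,
                 subtended_angle = theta, sagitta = R * (1 - cos(theta / 2)),
                 vertices = data.frame(x = vx, y = vy)),
            class = "spinal_curve")
}

#' Assemble the body axis of a skeleton
#'
#' Computes the axial stations (m from snout tip) of the anatomical
#' landmarks that bound the five cross-sectional-method slabs: snout tip,
#' quadrate (skull section), glenoid, middle (midway between glenoid and
#' acetabulum), acetabulum, and tail tip. Segment lengths come from the
#' skull length, cartilage-adjusted neck length, trunk chord, and tail
#' length; missing values must have been filled beforehand (see
#' [predict_missing_element()]).
#'
#' @param spec A validated [skeleton_spec()] whose `measurements` carry
#'   `skull_length`, `neck_length`, `trunk_length`, and `tail_length` (each
#'   either measured or filled), or with vertebrae from which neck/tail
#'   lengths can be summed.
#' @param cartilage_fraction Passed to [effective_segment_lengths()] when a
#'   length must be summed from vertebrae.
#' @return A list of class `body_axis`: `stations` (named numeric vector),
#'   `segment_lengths`, and `total_length` (m).
#' @export
assemble_body_axis <- function(spec, cartilage_fraction = NULL) {
  stopifnot(inherits(spec, "plesio_skeleton"))
  cf <- cartilage_fraction %||% spec$cartilage_fraction %||% 0.10
  m <- spec$measurements
  seg_from_vertebrae <- function(region) {
    v <- spec$vertebrae[spec$vertebrae$region == region, , drop = FALSE]
    if (nrow(v) == 0L) return(NULL)
    sum(effective_segment_lengths(v, cf))
  }
  skull <- m$skull_length
  neck <- m$neck_length %||% seg_from_vertebrae("cervical")
  trunk <- m$trunk_length %||% {
    tr <- spec$vertebrae[spec$vertebrae$region %in% c("pectoral", "dorsal", "sacral"), ,
                         drop = FALSE]
    if (nrow(tr) == 0L) NULL else sum(effective_segment_lengths(tr, cf))
  }
  tail <- m$tail_length %||% seg_from_vertebrae("caudal")
  for (nm in c("skull", "neck", "trunk", "tail")) {
    if (is.null(get(nm)) || is.na(get(nm))) {
      stop(sprintf("cannot assemble body axis: segment '%s' is unresolved", nm))
    }
  }
  glenoid <- skull + neck
  acetabulum <- glenoid + trunk
  stations <- c(snout_tip = 0, quadrate = skull, glenoid = glenoid,
                middle = (glenoid + acetabulum) / 2, acetabulum = acetabulum,
                tail_tip = acetabulum + tail)
  structure(list(stations = stations,
                 segment_lengths = c(skull = skull, neck = neck,
                                     trunk = trunk, tail = tail),
                 total_length = unname(stations[["tail_tip"]])),
            class = "body_axis")
}

#' Serialize a body axis to JSON
#'
#' @param axis A `body_axis`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_body_axis <- function(axis, path) {
  jsonlite::write_json(list(stations = as.list(axis$stations),
                            segment_lengths = as.list(axis$segment_lengths),
                            total_length = axis$total_length),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
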
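#' Rib plane descriptor
#'
#' A dorsal rib is simplified to a 2D structure lying in a vertical plane;
#' the minimum rectangle containing the rib has height `RPH` (rib plane
#' height) and width `RPW` (rib plane width). Three slant angles orient the
#' plane in 3D: `theta1` is the pump-handle rotation about a mediolateral
#' axis (deviation from vertical, degrees in \[-90, 90\]), `theta2` the
#' bucket-handle rotation about a dorsoventral axis (degrees in \[0, 90\]),
#' and `theta3` the tilt of the vertebral centrum from the horizontal plane
#' (degrees in \[-90, 90\]).
#'
#' @param RPH,RPW Rib plane height and width (m), both > 0.
#' @param theta1,theta2,theta3 Slant angles in degrees.
#' @param dorsal_position 1-based index of the supporting dorsal vertebra.
#' @param arc_length Optional rib arc length (m) used to standardize rib
#'   planes to the maximum rib arc length.
#' @return A list of class `rib_plane`.
#' @export
rib_plane <- function(RPH, RPW, theta1 = 0, theta2 = 0, theta3 = 0,
                      dorsal_position = 1L, arc_length = NULL) {
  if (!(RPH > 0 && RPW > 0)) stop("RPH and RPW must be positive")
  check_rib_angles(theta1, theta2, theta3)
  structure(list(RPH = RPH, RPW = RPW, theta1 = theta1, theta2 = theta2,
                 theta3 = theta3, dorsal_position = as.integer(dorsal_position),
                 arc_length = arc_length),
            class = "rib_plane")
}

check_rib_angles <- function(theta1, theta2, theta3) {
  if (theta1 < -90 || theta1 > 90) stop("theta1 must lie in [-90, 90] degrees")
  if (theta2 < 0 || theta2 > 90) stop("theta2 must lie in [0, 90] degrees")
  if (theta3 < -90 || theta3 > 90) stop("theta3 must lie in [-90, 90] degrees")
  invisible(TRUE)
}

deg2rad <- function(d) d * pi / 180

#' Project a rotated rib plane onto the transverse (vertical) plane
#'
#' Applies the three-step composite rotation of the rib plane and returns the
#' projected heights and widths after each step. With angles in radians
#' t1, t2, t3:
#' \deqn{RPH_{P1} = RPH \cos t_1, \quad RPW_{P1} = RPW}
#' \deqn{RPH_{P2} = RPH_{P1} - RPW \sin t_2 \sin t_1, \quad RPW_{P2} = RPW \cos t_2}
#' \deqn{RPH_{P3} = RPH_{P2} \cos t_3, \quad RPW_{P3} = RPW_{P2}}
#' The projected height is the vertical drop from the costovertebral
#' articulation to the distal rib corner; rotation order is fixed
#' (theta1, then theta2, then theta3) since 3D rotations do not commute.
#' Caliper rotation (about the anteroposterior axis) is not modeled.
#'
#' @param rib A [rib_plane()].
#' @return A list of class `rib_projection` with fields `RPH_P1`, `RPW_P1`,
#'   `RPH_P2`, `RPW_P2`, `RPH_P3`, `RPW_P3` (m).
#' @export
project_rib_plane <- function(rib) {
  stopifnot(inherits(rib, "rib_plane"))
  check_rib_angles(rib$theta1, rib$theta2, rib$theta3)
  t1 <- deg2rad(rib$theta1); t2 <- deg2rad(rib$theta2); t3 <- deg2rad(rib$theta3)
  RPH_P1 <- rib$RPH * cos(t1)
  RPW_P1 <- rib$RPW
  RPH_P2 <- RPH_P1 - rib$RPW * sin(t2) * sin(t1)
  RPW_P2 <- rib$RPW * cos(t2)
  RPH_P3 <- RPH_P2 * cos(t3)
  RPW_P3 <- RPW_P2
  structure(list(RPH_P1 = RPH_P1, RPW_P1 = RPW_P1, RPH_P2 = RPH_P2,
                 RPW_P2 = RPW_P2, RPH_P3 = RPH_P3, RPW_P3 = RPW_P3),
            class = "rib_projection")
}

#' Rib coefficient
#'
#' Ratio of the arc length of the rib dorsal to the glenoid cavity to the
#' maximum rib arc length observed in the specimen. Lies in (0, 1] by
#' definition; used to scale the middle ventral height (see
#' [middle_ventral_height()]).
#'
#' @param arc_glenoid Arc length of the rib dorsal to the glenoid (m).
#' @param arc_max Maximum rib arc length in the series (m).
#' @return Dimensionless scalar in (0, 1].
#' @export
rib_coefficient <- function(arc_glenoid, arc_max) {
  stopifnot(arc_glenoid > 0, arc_max > 0)
  if (arc_glenoid > arc_max) {
    stop("glenoid rib arc length exceeds the maximum rib arc length")
  }
  arc_glenoid / arc_max
}

#' Ventral section height from a girdle element width (Pythagoras)
#'
#' The girdle element (coracoid at the glenoid section, pubis at the
#' acetabulum section) spans from the ventral midline to the lateral
#' articulation and is treated as the hypotenuse of a right triangle whose
#' other leg is half the section width, so
#' `ventral_height = sqrt(girdle_width^2 - (section_width/2)^2)`.
#'
#' @param girdle_width Girdle element width (m).
#' @param section_width Full cross-section width (m).
#' @return Ventral height (m).
#' @export
ventral_height_from_girdle <- function(girdle_width, section_width) {
  stopifnot(girdle_width > 0, section_width >= 0)
  half <- section_width / 2
  if (girdle_width <= half) {
    stop(sprintf(paste0("geometric infeasibility: girdle width %.4g m does not ",
                        "exceed half the section width %.4g m"),
                 girdle_width, half))
  }
  sqrt(girdle_width^2 - half^2)
}

#' Middle-section ventral height
#'
#' The ventral height of the middle cross-section is the mean of the glenoid
#' and acetabulum ventral heights divided by the rib coefficient:
#' \deqn{h_{mid} = \frac{(h_{glen} + h_{acet})/2}{\mathrm{rib\ coefficient}}}
#'
#' @param glenoid_vh,acetabulum_vh Ventral heights of the bounding sections (m).
#' @param rib_coef Rib coefficient in (0, 1].
#' @return Middle ventral height (m).
#' @export
middle_ventral_height <- function(glenoid_vh, acetabulum_vh, rib_coef) {
  stopifnot(glenoid_vh > 0, acetabulum_vh > 0)
  if (!(rib_coef > 0 && rib_coef <= 1)) {
    stop("rib coefficient must be in (0, 1]")
  }
  ((glenoid_vh + acetabulum_vh) / 2) / rib_coef
}

#' Dorsal width of the middle cross-section from truncated ribs
#'
#' The middle cross-section transects several dorsal ribs, all standardized
#' to the maximum rib arc length and assumed to lie at a uniform
#' dorsoventral level with theta3 ~ 0 (the vertebral column arches gently, so
#' middle dorsal centra are near-horizontal). For each rib the section plane
#' cuts the rib plane at a fraction of its width; the cut width is projected
#' by cos(theta2), and the section width is twice the largest projected
#' half-width.
#'
#' @param ribs List of [rib_plane()] objects (already standardized).
#' @param intersect_fractions Fractions in `[0, 1]`, one per rib, locating the
#'   section plane within each rib plane's width. Defaults to 1 for all ribs.
#' @return Full middle-section width (m).
#' @export
middle_section_width <- function(ribs, intersect_fractions = NULL) {
  if (length(ribs) == 0L) stop("at least one rib plane is required")
  if (is.null(intersect_fractions)) intersect_fractions <- rep(1, length(ribs))
  stopifnot(length(intersect_fractions) == length(ribs),
            all(intersect_fractions >= 0), all(intersect_fractions <= 1))
  half_widths <- vapply(seq_along(ribs), function(i) {
    r <- ribs[[i]]
    stopifnot(inherits(r, "rib_plane"))
    intersect_fractions[i] * r$RPW * cos(deg2rad(r$theta2))
  }, numeric(1))
  2 * max(half_widths)
}

#' Standardize a rib plane to the maximum rib arc length
#'
#' Scales `RPH` and `RPW` isotropically so the rib's arc length equals
#' `arc_max`; used when building the middle cross-section, whose transected
#' ribs are assigned a standardized size equal to the maximum rib arc length.
#'
#' @param rib A [rib_plane()] with a non-null `arc_length`.
#' @param arc_max Target arc length (m).
#' @return A rescaled [rib_plane()].
#' @export
standardize_rib_plane <- function(rib, arc_max) {
  stopifnot(inherits(rib, "rib_plane"), arc_max > 0)
  if (is.null(rib$arc_length)) {
    stop("rib plane carries no arc_length; cannot standardize")
  }
  s <- arc_max / rib$arc_length
  rib_plane(rib$RPH * s, rib$RPW * s, rib$theta1, rib$theta2, rib$theta3,
            rib$dorsal_position, arc_length = arc_max)
}
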
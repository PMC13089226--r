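#' Axial slab for cross-sectional-method integration
#'
#' A slab is bounded by a front and a back cross-section; either end may be
#' a point (`NULL`), in which case the slab tapers as a generalized cone:
#' the bounding contour keeps a constant shape while its size shrinks
#' linearly to zero. Each slab is sliced into `n_subslabs` subslabs and
#' integrated by the trapezoid rule over cross-sectional areas, which
#' realizes the cross-sectional method's assumption of linear transitions in
#' shape and size at a small scale.
#'
#' @param front,back [contour()]s, or `NULL` for a point (at most one end).
#' @param length Slab length along the body axis (m), > 0.
#' @param n_subslabs Number of subslabs (default 100).
#' @return A list of class `csm_slab`.
#' @export
csm_slab <- function(front, back, length, n_subslabs = 100L) {
  stopifnot(length > 0, n_subslabs >= 1L)
  if (is.null(front) && is.null(back)) {
    stop("a slab needs a contour on at least one end")
  }
  structure(list(front = front, back = back, length = length,
                 n_subslabs = as.integer(n_subslabs)),
            class = "csm_slab")
}

#' Slab volume by subslab trapezoid integration
#'
#' Cross-sectional areas are evaluated at `n_subslabs + 1` stations: between
#' two contours the section is the pointwise linear blend
#' ([blend_contours()]), so the area is quadratic in the station parameter;
#' toward a point the area scales as `(1 - t)^2` (constant shape). The
#' trapezoid error decreases as `n^-2`.
#'
#' @param s A [csm_slab()].
#' @param n_resample Vertex count used for the blend correspondence.
#' @return Volume in m^3.
#' @export
slab_volume <- function(s, n_resample = 512L) {
  stopifnot(inherits(s, "csm_slab"))
  n <- s$n_subslabs
  t <- seq(0, 1, length.out = n + 1L)
  if (is.null(s$front) || is.null(s$back)) {
    base <- if (is.null(s$back)) s$front else s$back
    A0 <- contour_area(base)
    scale <- if (is.null(s$back)) 1 - t else t
    areas <- A0 * scale^2
  } else {
    f <- resample_contour(s$front, n_resample)
    b <- resample_contour(s$back, n_resample)
    areas <- vapply(t, function(ti) {
      shoelace((1 - ti) * f$x + ti * b$x, (1 - ti) * f$y + ti * b$y)
    }, numeric(1))
    if (any(areas < 0)) stop("negative blended section area; check orientations")
  }
  sum((areas[-1L] + areas[-(n + 1L)]) / 2) * (s$length / n)
}

#' Flipper planform treated as a single hydrofoil slab
#'
#' The limb is divided into equal spanwise segments; at each station the
#' cross-section is a streamlined hydrofoil of area
#' `section_area_coefficient * chord * (thickness_fraction * chord)`.
#' Volume is the trapezoid integral of section area along the span.
#'
#' @param span Limb length from body wall to tip (m).
#' @param chords Chord lengths (m) at `length(chords)` evenly spaced
#'   stations from limb base to tip.
#' @param thickness_fractions Max section thickness as a fraction of chord,
#'   recycled to the station count; in (0, 1).
#' @param section_area_coefficient Hydrofoil section area divided by
#'   (chord x thickness); 0.685 is typical of streamlined sections.
#' @return A list of class `limb_planform`.
#' @export
limb_planform <- function(span, chords, thickness_fractions = 0.20,
                          section_area_coefficient = 0.685) {
  stopifnot(span > 0, all(chords >= 0), length(chords) >= 2L,
            all(thickness_fractions > 0), all(thickness_fractions < 1),
            section_area_coefficient > 0)
  tf <- rep_len(thickness_fractions, length(chords))
  structure(list(span = span, chords = as.numeric(chords),
                 thickness_fractions = tf,
                 section_area_coefficient = section_area_coefficient),
            class = "limb_planform")
}

#' @rdname limb_planform
#' @param p A `limb_planform`.
#' @return For `limb_volume()`, the flipper volume in m^3.
#' @export
limb_volume <- function(p) {
  stopifnot(inherits(p, "limb_planform"))
  areas <- p$section_area_coefficient * p$chords * (p$thickness_fractions * p$chords)
  n <- length(areas)
  h <- p$span / (n - 1L)
  sum((areas[-1L] + areas[-n]) / 2) * h
}

#' Soft-tissue configuration
#'
#' Soft tissue around the ribcage is restored by scaling each of the three
#' ribcage cross-sections linearly (default 1.25 in both planar dimensions,
#' i.e. a 25% wider body outline than the ribcage), and by appending 5% to
#' the tail length. The skull section receives only minimal craniofacial
#' soft tissue and is left unscaled.
#'
#' @param section_linear_scale Linear enlargement of ribcage sections (>= 1).
#' @param tail_extension_fraction Fractional tail lengthening (>= 0).
#' @return A list of class `soft_tissue_config`.
#' @export
soft_tissue_config <- function(section_linear_scale = 1.25,
                               tail_extension_fraction = 0.05) {
  stopifnot(section_linear_scale >= 1, tail_extension_fraction >= 0)
  structure(list(section_linear_scale = section_linear_scale,
                 tail_extension_fraction = tail_extension_fraction),
            class = "soft_tissue_config")
}

#' Body model: ordered axial slabs, limb slabs, and density
#'
#' The section-based constructor holds the four named cross-sections
#' (skull, glenoid, middle, acetabulum) and the five slab lengths between
#' the six axial stations; the first and last slabs taper to a point at the
#' snout and tail tip. `body_model_from_slabs()` wraps an arbitrary slab
#' list (used by the parametric oracle solids). Default density is
#' 1027 kg/m^3, the density of surface seawater, reflecting near-neutral
#' buoyancy in marine tetrapods.
#'
#' @param sections Named list of [contour()]s: `skull`, `glenoid`, `middle`,
#'   `acetabulum`.
#' @param slab_lengths Numeric vector of 5 axial slab lengths (m): snout to
#'   quadrate, quadrate to glenoid, glenoid to middle, middle to acetabulum,
#'   acetabulum to tail tip.
#' @param limbs List of [limb_planform()]s (one entry per flipper).
#' @param density Body density in kg/m^3 (> 0).
#' @param n_subslabs Subslab count per slab.
#' @return A list of class `plesio_body_model`.
#' @export
body_model <- function(sections, slab_lengths, limbs = list(),
                       density = 1027, n_subslabs = 100L) {
  stopifnot(all(c("skull", "glenoid", "middle", "acetabulum") %in% names(sections)),
            length(slab_lengths) == 5L, all(slab_lengths > 0), density > 0)
  slabs <- list(
    csm_slab(NULL, sections$skull, slab_lengths[1L], n_subslabs),
    csm_slab(sections$skull, sections$glenoid, slab_lengths[2L], n_subslabs),
    csm_slab(sections$glenoid, sections$middle, slab_lengths[3L], n_subslabs),
    csm_slab(sections$middle, sections$acetabulum, slab_lengths[4L], n_subslabs),
    csm_slab(sections$acetabulum, NULL, slab_lengths[5L], n_subslabs))
  names(slabs) <- c("snout", "neck", "anterior_trunk", "posterior_trunk", "tail")
  structure(list(sections = sections, slab_lengths = slab_lengths,
                 slabs = slabs, limbs = limbs, density = density,
                 n_subslabs = as.integer(n_subslabs),
                 soft_tissue_applied = FALSE),
            class = "plesio_body_model")
}

#' @rdname body_model
#' @param slabs List of [csm_slab()]s.
#' @export
body_model_from_slabs <- function(slabs, limbs = list(), density = 1027) {
  stopifnot(length(slabs) >= 1L, all(vapply(slabs, inherits, logical(1), "csm_slab")),
            density > 0)
  structure(list(sections = NULL, slab_lengths = vapply(slabs, `[[`, numeric(1), "length"),
                 slabs = slabs, limbs = limbs, density = density,
                 n_subslabs = slabs[[1L]]$n_subslabs,
                 soft_tissue_applied = FALSE),
            class = "plesio_body_model")
}

#' Apply the soft-tissue stage to a body model
#'
#' Scales the glenoid, middle, and acetabulum contours linearly about their
#' ventral midline anchors by `cfg$section_linear_scale` (so each section
#' area grows by the scale squared), lengthens the tail slab by
#' `cfg$tail_extension_fraction`, and leaves the skull section unscaled.
#' The body axis tail-tip station moves accordingly.
#'
#' @param model A section-based [body_model()].
#' @param axis Optional `body_axis` to update alongside the model.
#' @param cfg A [soft_tissue_config()].
#' @return A list with elements `model` and `axis` (the latter `NULL` when
#'   not supplied).
#' @export
apply_soft_tissue <- function(model, axis = NULL, cfg = soft_tissue_config()) {
  stopifnot(inherits(model, "plesio_body_model"), inherits(cfg, "soft_tissue_config"))
  if (is.null(model$sections)) {
    stop("soft-tissue staging needs a section-based body model")
  }
  if (model$soft_tissue_applied) {
    warning("soft tissue already applied; applying again")
  }
  s <- cfg$section_linear_scale
  sections <- model$sections
  for (nm in c("glenoid", "middle", "acetabulum")) {
    sec <- sections[[nm]]
    sections[[nm]] <- rescale_contour(sec, contour_width(sec) * s,
                                      contour_height(sec) * s)
  }
  lengths <- model$slab_lengths
  extra <- lengths[5L] * cfg$tail_extension_fraction
  lengths[5L] <- lengths[5L] + extra
  out <- body_model(sections, lengths, model$limbs, model$density,
                    model$n_subslabs)
  out$soft_tissue_applied <- TRUE
  if (!is.null(axis)) {
    axis$stations[["tail_tip"]] <- axis$stations[["tail_tip"]] + extra
    axis$segment_lengths[["tail"]] <- axis$segment_lengths[["tail"]] + extra
    axis$total_length <- unname(axis$stations[["tail_tip"]])
  }
  list(model = out, axis = axis)
}

#' Total body volume and mass of a body model
#'
#' Volume is the sum of all axial slab volumes and limb volumes; mass is
#' volume times the assumed density.
#'
#' @param model A `plesio_body_model`.
#' @return A list with `volume` (m^3), `mass` (kg), and `report`, a data
#'   frame of per-slab lengths and volumes (limbs included).
#' @export
body_mass <- function(model) {
  stopifnot(inherits(model, "plesio_body_model"))
  sv <- vapply(model$slabs, slab_volume, numeric(1))
  lv <- if (length(model$limbs)) {
    vapply(model$limbs, limb_volume, numeric(1))
  } else {
    numeric()
  }
  volume <- sum(sv) + sum(lv)
  part <- c(names(model$slabs) %||% paste0("slab", seq_along(sv)),
            if (length(lv)) names(model$limbs) %||% paste0("limb", seq_along(lv)))
  report <- data.frame(
    part = part,
    kind = c(rep("axial", length(sv)), rep("limb", length(lv))),
    length_m = c(vapply(model$slabs, `[[`, numeric(1), "length"),
                 if (length(lv)) vapply(model$limbs, `[[`, numeric(1), "span")),
    volume_m3 = c(sv, lv))
  list(volume = volume, mass = volume * model$density, report = report)
}
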
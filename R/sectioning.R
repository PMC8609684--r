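# Virtual serial sectioning and systematic-uniform-random (SUR) selection.
# Sections are half-open z-intervals [z_i, z_i + t), indexed from 0, so every
# point of the reference volume belongs to exactly one section.

#' Serial section stack
#'
#' @param extent_z total depth to section, um (e.g. `region$extent["z"]`)
#' @param thickness_um nominal (final post-processing) section thickness t, um.
#'   Tissue shrinkage correction is not modelled; t is taken as configured.
#' @return object of class `section_stack` with fields `t`, `n_sections`,
#'   `extent_z`
#' @export
section_stack <- function(extent_z, thickness_um = 18) {
  check_positive(extent_z, "extent_z")
  check_positive(thickness_um, "thickness_um")
  n <- ceiling(extent_z / thickness_um)
  structure(
    list(t = thickness_um, n_sections = as.integer(n), extent_z = extent_z),
    class = "section_stack"
  )
}

#' Stereological sampling design
#'
#' Probe geometry for one virtual stereology run. The instrument-level
#' settings (grid spacings, counting-frame size, sphere radius) are not
#' dictated by the estimators; the defaults are chosen so that the default
#' synthetic cohort accumulates enough counts per compartment to keep
#' coefficients of error near 0.1 or below.
#'
#' @param interval_k section sampling interval k (every k-th section)
#' @param guard_um guard zone g at top and bottom of each section, um
#' @param point_spacing_um Cavalieri grid spacing (x, y), um; area per point
#'   a(p) is their product
#' @param frame_um disector counting-frame size (w, h), um
#' @param frame_spacing_um spacing of the frame lattice (x, y), um; equal to
#'   `frame_um` means frames tile the plane (area sampling fraction 1)
#' @param sphere_radius_um space-ball radius r_s, um
#' @param sphere_spacing_um sphere grid spacing, um: one value, or a named
#'   vector with one value per compartment (small compartments are usually
#'   probed with a denser sphere lattice, as region-wise sampling does)
#' @param allow_truncation allow spheres larger than the guarded disector
#'   height, truncating them at the guard planes with exact exposed-area
#'   accounting
#' @return object of class `sampling_design`
#' @export
sampling_design <- function(interval_k = 30L, guard_um = 1,
                            point_spacing_um = c(15, 15),
                            frame_um = c(60, 60),
                            frame_spacing_um = frame_um,
                            sphere_radius_um = 7,
                            sphere_spacing_um = c(DG = 15, CA1 = 15, CA23 = 15,
                                                  ML = 80, WM = 80),
                            allow_truncation = FALSE) {
  check_positive(interval_k, "interval_k")
  if (guard_um < 0) stopf("invalid parameter: `guard_um` must be >= 0")
  check_positive(point_spacing_um, "point_spacing_um")
  check_positive(frame_um, "frame_um")
  check_positive(frame_spacing_um, "frame_spacing_um")
  check_positive(sphere_radius_um, "sphere_radius_um")
  check_positive(sphere_spacing_um, "sphere_spacing_um")
  if (length(point_spacing_um) == 1L) point_spacing_um <- rep(point_spacing_um, 2)
  if (length(frame_um) == 1L) frame_um <- rep(frame_um, 2)
  if (length(frame_spacing_um) == 1L) frame_spacing_um <- rep(frame_spacing_um, 2)
  if (any(frame_spacing_um < frame_um)) {
    stopf("invalid design: frame spacing smaller than the frame would overlap frames")
  }
  structure(
    list(interval_k = as.integer(interval_k), guard_um = guard_um,
         point_spacing_um = point_spacing_um,
         area_per_point_um2 = prod(point_spacing_um),
         frame_um = frame_um, frame_spacing_um = frame_spacing_um,
         sphere_radius_um = sphere_radius_um,
         sphere_spacing_um = sphere_spacing_um,
         allow_truncation = allow_truncation),
    class = "sampling_design"
  )
}

# sphere spacing for one compartment (scalar design values apply everywhere)
.sphere_spacing_for <- function(design, compartment) {
  s <- design$sphere_spacing_um
  if (is.null(names(s))) return(s[[1]])
  if (!compartment %in% names(s)) {
    stopf("sampling design has no sphere spacing for compartment %s", compartment)
  }
  s[[compartment]]
}

.check_disector <- function(design, stack) {
  h <- stack$t - 2 * design$guard_um
  if (h <= 0) stopf("invalid design: disector height t - 2g must be > 0")
  h
}

#' Select a systematic-uniform-random sample of sections
#'
#' Every k-th section after a uniform random start: indices
#' `s0, s0 + k, s0 + 2k, ...` (0-based) with `s0` uniform on `0:(k-1)`.
#'
#' @param stack a `section_stack`
#' @param k sampling interval (defaults to the design's k)
#' @param seed integer seed used to draw the random start
#' @param random_start explicit start in `[0, k)`; overrides `seed`
#' @return integer vector of 0-based section indices
#' @export
select_sections <- function(stack, k = 30L, seed = NULL, random_start = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  k <- as.integer(k)
  if (k < 1L || k > stack$n_sections) {
    stopf("invalid design: sampling interval k = %d outside 1..%d",
          k, stack$n_sections)
  }
  if (is.null(random_start)) {
    if (is.null(seed)) stopf("either `seed` or `random_start` must be given")
    random_start <- with_stream_seed(seed, "sections",
                                     code = sample.int(k, 1L) - 1L)
  }
  random_start <- as.integer(random_start)
  if (random_start < 0L || random_start >= k) {
    stopf("invalid design: random start %d outside [0, k)", random_start)
  }
  seq.int(random_start, stack$n_sections - 1L, by = k)
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("Stereological sampling design\n")
  cat(sprintf("  every %d-th section, guard %g um\n", x$interval_k, x$guard_um))
  cat(sprintf("  point grid %g x %g um (a(p) = %g um^2)\n",
              x$point_spacing_um[1], x$point_spacing_um[2],
              x$area_per_point_um2))
  cat(sprintf("  frame %g x %g um on a %g x %g um lattice\n",
              x$frame_um[1], x$frame_um[2],
              x$frame_spacing_um[1], x$frame_spacing_um[2]))
  cat(sprintf("  sphere radius %g um, spacing: %s\n", x$sphere_radius_um,
              paste(sprintf("%s=%g", names(x$sphere_spacing_um),
                            x$sphere_spacing_um), collapse = " ")))
  invisible(x)
}
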
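#' Hippocampal compartment names understood by the region model
#'
#' DG, CA1 and CA23 are the principal cell layers (PCL); ML is the molecular
#' layer and WM white matter. Together they tile the reference volume.
#' @export
COMPARTMENTS <- c("DG", "CA1", "CA23", "ML", "WM")

#' Principal-cell-layer members aggregated as "PCL" in reports
#' @export
PCL_MEMBERS <- c("DG", "CA1", "CA23")

#' Build a layered reference volume of stacked slab compartments
#'
#' Idealises the laminar anatomy of the hippocampus as axis-aligned slabs.
#' Slabs are stacked along x, i.e. perpendicular to the sectioning axis (z),
#' so that every virtual section crosses all compartments side by side, as
#' hippocampal laminae do in horizontal histological sections. Analytic
#' compartment volumes are exact box volumes and serve as ground truth for
#' the Cavalieri estimator.
#'
#' @param layer_thicknesses named numeric vector of slab widths along x (um);
#'   names must be drawn from [COMPARTMENTS] without duplicates.
#' @param lateral_extent numeric of length 2: extent in y and z (um). z is the
#'   sectioning depth.
#' @return an object of class `region_model`: a list with `compartments`
#'   (data.frame of box bounds and analytic volumes), `extent` (x, y, z) and
#'   `pcl_members`.
#' @examples
#' build_region_model(c(DG = 100, CA1 = 100), lateral_extent = c(400, 540))
#' @export
build_region_model <- function(layer_thicknesses, lateral_extent) {
  if (is.null(names(layer_thicknesses)) || any(!nzchar(names(layer_thicknesses)))) {
    stopf("invalid parameter: `layer_thicknesses` must be a named vector")
  }
  if (!all(names(layer_thicknesses) %in% COMPARTMENTS)) {
    stopf("unknown compartment name(s): %s",
          paste(setdiff(names(layer_thicknesses), COMPARTMENTS), collapse = ", "))
  }
  if (anyDuplicated(names(layer_thicknesses))) {
    stopf("invalid parameter: duplicated compartment names")
  }
  check_positive(layer_thicknesses, "layer_thicknesses")
  if (length(lateral_extent) != 2) {
    stopf("invalid parameter: `lateral_extent` must have length 2 (y, z)")
  }
  check_positive(lateral_extent, "lateral_extent")

  x1 <- cumsum(as.double(layer_thicknesses))
  x0 <- c(0, x1[-length(x1)])
  comp <- data.frame(
    name = names(layer_thicknesses),
    x0 = x0, x1 = x1,
    y0 = 0, y1 = lateral_extent[[1]],
    z0 = 0, z1 = lateral_extent[[2]],
    stringsAsFactors = FALSE
  )
  comp$volume_um3 <- (comp$x1 - comp$x0) * (comp$y1 - comp$y0) * (comp$z1 - comp$z0)
  structure(
    list(
      compartments = comp,
      extent = c(x = sum(layer_thicknesses),
                 y = lateral_extent[[1]], z = lateral_extent[[2]]),
      pcl_members = intersect(PCL_MEMBERS, comp$name)
    ),
    class = "region_model"
  )
}

#' Analytic compartment volumes of a region model
#'
#' @param region a `region_model`
#' @param total also append the union volume under name `"total"`?
#' @return named numeric vector of volumes in um^3
#' @export
region_volumes <- function(region, total = FALSE) {
  v <- stats::setNames(region$compartments$volume_um3, region$compartments$name)
  if (total) v <- c(v, total = sum(v))
  v
}

#' Volume fraction of the principal cell layers
#'
#' @param region a `region_model`
#' @return PCL volume / total volume (dimensionless)
#' @export
pcl_volume_fraction <- function(region) {
  v <- region_volumes(region)
  sum(v[names(v) %in% region$pcl_members]) / sum(v)
}

# Row index of the compartment box containing each point, NA when outside.
# Boxes are half-open [lo, hi) so compartments are pairwise disjoint.
locate_compartment <- function(region, x, y, z) {
  comp <- region$compartments
  out <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(comp))) {
    hit <- x >= comp$x0[i] & x < comp$x1[i] &
      y >= comp$y0[i] & y < comp$y1[i] &
      z >= comp$z0[i] & z < comp$z1[i]
    out[hit & is.na(out)] <- i
  }
  out
}

#' @export
print.region_model <- function(x, ...) {
  cat("Layered reference volume (", nrow(x$compartments), " slab compartments)\n",
      sep = "")
  cat(sprintf("  extent: %.0f x %.0f x %.0f um (z = sectioning axis)\n",
              x$extent["x"], x$extent["y"], x$extent["z"]))
  v <- region_volumes(x)
  for (i in seq_along(v)) {
    cat(sprintf("  %-5s %10.3g um^3  (%.2f%%)\n",
                names(v)[i], v[i], 100 * v[i] / sum(v)))
  }
  cat(sprintf("  PCL fraction: %.2f%%\n", 100 * pcl_volume_fraction(x)))
  invisible(x)
}

#' Write / read a region model as JSON
#'
#' @param region a `region_model`
#' @param path file path
#' @return `read_region_json` returns a `region_model`
#' @export
write_region_json <- function(region, path) {
  payload <- list(
    compartments = region$compartments,
    extent = as.list(region$extent),
    pcl_members = region$pcl_members
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_region_json
#' @export
read_region_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- as.data.frame(payload$compartments, stringsAsFactors = FALSE)
  structure(
    list(
      compartments = comp,
      extent = unlist(payload$extent),
      pcl_members = as.character(payload$pcl_members)
    ),
    class = "region_model"
  )
}

#' Default reference volume used throughout the package
#'
#' A scaled-down hippocampus-like region: compartment volume fractions follow
#' published non-transgenic hippocampal morphometry (DG 4.43%, CA1 3.36%,
#' CA2/3 4.37%, i.e. PCL 12.16%; the remainder split ML 55% / WM 32.84%), and
#' the sectioning depth corresponds to 350 serial 18-um sections. The lateral
#' extent is chosen so that simulated cohorts run quickly while systematic
#' sampling still accumulates adequate probe counts per compartment.
#'
#' @param n_sections number of serial sections spanned by the z extent
#' @param section_thickness_um nominal section thickness t (um)
#' @param x_total_um total slab width along x (um)
#' @param y_um lateral extent in y (um)
#' @return a `region_model`
#' @export
default_region <- function(n_sections = 350, section_thickness_um = 18,
                           x_total_um = 1000, y_um = 250) {
  fractions <- c(DG = 0.0443, CA1 = 0.0336, CA23 = 0.0437,
                 ML = 0.5500, WM = 0.3284)
  build_region_model(
    layer_thicknesses = fractions * x_total_um,
    lateral_extent = c(y_um, n_sections * section_thickness_um)
  )
}
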
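# Stereological probes applied to one virtual section: Cavalieri point grid,
# optical disector with unbiased counting frames, and isotropic sphere probes
# ("space balls") for length.

# systematic 1D lattice from `from` to at most `to` (empty when from > to)
.grid_1d <- function(from, to, by) {
  if (from > to) return(numeric(0))
  seq(from, to, by = by)
}

.section_z <- function(stack, section) {
  if (any(section < 0L) || any(section >= stack$n_sections)) {
    stopf("section index outside 0..%d", stack$n_sections - 1L)
  }
  section * stack$t
}

#' Count Cavalieri grid points hitting each compartment
#'
#' Places a systematic point grid with a uniform random offset on the
#' section's mid-plane and counts points falling inside each compartment
#' (compartment boxes are half-open, so each point hits at most one).
#'
#' @param region a `region_model`
#' @param stack a `section_stack`
#' @param section 0-based section index
#' @param design a `sampling_design`
#' @param offset length-2 offset of the grid inside one cell, um; drawn
#'   uniformly from `seed` when NULL
#' @param seed integer seed (used when `offset` is NULL)
#' @return named integer vector: sum of points per compartment
#' @export
count_points <- function(region, stack, section, design,
                         offset = NULL, seed = NULL) {
  sp <- design$point_spacing_um
  if (is.null(offset)) {
    if (is.null(seed)) stopf("either `offset` or `seed` must be given")
    offset <- with_stream_seed(seed, "points", section,
                               code = stats::runif(2) * sp)
  }
  z_mid <- .section_z(stack, section) + stack$t / 2
  ext <- region$extent
  comp <- region$compartments
  out <- stats::setNames(integer(nrow(comp)), comp$name)
  if (z_mid >= max(comp$z1)) return(out)
  xs <- seq(offset[1], ext["x"], by = sp[1])
  ys <- seq(offset[2], ext["y"], by = sp[2])
  if (!length(xs) || !length(ys)) return(out)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  for (i in seq_len(nrow(comp))) {
    if (z_mid < comp$z0[i] || z_mid >= comp$z1[i]) next
    out[i] <- sum(px >= comp$x0[i] & px < comp$x1[i] &
                    py >= comp$y0[i] & py < comp$y1[i])
  }
  out
}

#' Count branch nodes (saddle points) in the optical disector
#'
#' Counts branch nodes whose z lies inside the guarded disector
#' `[z_i + g, z_i + t - g)` and whose (x, y) falls inside a counting frame.
#' Frames sit on a lattice with a random offset; the frame interval is
#' half-open in both axes, which implements the unbiased-counting-frame rule:
#' nodes on the left/bottom (inclusion) edges count, nodes on the right/top
#' (exclusion) edges do not, and with frames tiling the plane every node is
#' counted exactly once.
#'
#' @inheritParams count_points
#' @param net a `vascular_network`
#' @return named integer vector: saddle-point count per compartment present
#'   in the network
#' @export
count_saddle_points <- function(net, stack, section, design,
                                offset = NULL, seed = NULL) {
  h <- .check_disector(design, stack)
  fs <- design$frame_spacing_um
  fw <- design$frame_um
  if (is.null(offset)) {
    if (is.null(seed)) stopf("either `offset` or `seed` must be given")
    offset <- with_stream_seed(seed, "frames", section,
                               code = stats::runif(2) * fs)
  }
  z0 <- .section_z(stack, section) + design$guard_um
  nd <- net$nodes
  comps <- unique(net$truth$compartment)
  inz <- which(nd$kind == "branch" & nd$z >= z0 & nd$z < z0 + h)
  out <- stats::setNames(integer(length(comps)), comps)
  if (length(inz)) {
    u <- (nd$x[inz] - offset[1]) %% fs[1]
    v <- (nd$y[inz] - offset[2]) %% fs[2]
    hit <- inz[u < fw[1] & v < fw[2]]
    if (length(hit)) {
      tab <- table(nd$compartment[hit])
      out[names(tab)] <- as.integer(tab)
    }
  }
  out
}

# Transversal crossings between a set of polyline edges and one sphere
# surface. Roots of |p(s) - c|^2 = r^2 are counted on the half-open edge
# parameter (0, 1]; a positive discriminant guarantees a sign change
# (transversal crossing), tangency counts zero. Optionally restrict the
# crossing point's z to [zlo, zhi) (guard-plane truncation).
.sphere_edge_crossings <- function(e, idx, cx, cy, cz, r, zlo = -Inf, zhi = Inf) {
  if (!length(idx)) return(0L)
  ux <- e$x1[idx] - e$x0[idx]
  uy <- e$y1[idx] - e$y0[idx]
  uz <- e$z1[idx] - e$z0[idx]
  wx <- e$x0[idx] - cx
  wy <- e$y0[idx] - cy
  wz <- e$z0[idx] - cz
  a <- ux * ux + uy * uy + uz * uz
  b <- 2 * (ux * wx + uy * wy + uz * wz)
  cc <- wx * wx + wy * wy + wz * wz - r * r
  disc <- b * b - 4 * a * cc
  ok <- disc > 0 & a > 0
  if (!any(ok)) return(0L)
  sq <- sqrt(disc[ok])
  s1 <- (-b[ok] - sq) / (2 * a[ok])
  s2 <- (-b[ok] + sq) / (2 * a[ok])
  z1 <- e$z0[idx][ok] + s1 * uz[ok]
  z2 <- e$z0[idx][ok] + s2 * uz[ok]
  n1 <- s1 > 0 & s1 <= 1 & z1 >= zlo & z1 < zhi
  n2 <- s2 > 0 & s2 <= 1 & z2 >= zlo & z2 < zhi
  sum(n1) + sum(n2)
}

#' Count sphere-probe/centerline intersections in one section
#'
#' Places virtual spheres centred at the section's mid-depth on a systematic
#' x-y lattice per compartment (the lattice covers the compartment dilated by
#' the sphere radius, so capillaries near the compartment boundary are probed
#' without edge bias) and counts transversal crossings between segment
#' centerlines and each sphere surface. The summed exposed probe surface is
#' accounted analytically: expected sphere surface per lattice cell times the
#' compartment's sectional area, minus spherical caps beyond the guard planes
#' when truncation is enabled.
#'
#' @inheritParams count_saddle_points
#' @param net a `vascular_network`
#' @param region a `region_model`
#' @param edges optional precomputed `network_edges(net)` (reused across
#'   sections for speed)
#' @return data.frame with one row per compartment: `sum_i` (crossings) and
#'   `s_exposed_um2` (summed exposed sphere surface)
#' @export
count_sphere_intersections <- function(net, region, stack, section, design,
                                       offset = NULL, seed = NULL,
                                       edges = NULL) {
  h <- .check_disector(design, stack)
  r <- design$sphere_radius_um
  truncated <- r > h / 2
  if (truncated && !design$allow_truncation) {
    stopf(paste0("invalid design: sphere radius %.3g exceeds the half-height ",
                 "%.3g of the guarded disector and truncation is disabled"), r, h / 2)
  }
  if (is.null(edges)) edges <- network_edges(net)
  zbase <- .section_z(stack, section)
  z_mid <- zbase + stack$t / 2
  zlo <- zbase + design$guard_um
  zhi <- zbase + stack$t - design$guard_um
  # per-sphere exposed surface (identical for all spheres of the section)
  cap_h <- max(0, r - h / 2)
  sphere_area <- 4 * pi * r^2 - 2 * (2 * pi * r * cap_h)

  comp <- region$compartments
  e_zmin <- pmin(edges$z0, edges$z1)
  e_zmax <- pmax(edges$z0, edges$z1)
  zsel <- which(e_zmin <= z_mid + r & e_zmax >= z_mid - r)
  e_xmin <- pmin(edges$x0[zsel], edges$x1[zsel])
  e_xmax <- pmax(edges$x0[zsel], edges$x1[zsel])
  e_ymin <- pmin(edges$y0[zsel], edges$y1[zsel])
  e_ymax <- pmax(edges$y0[zsel], edges$y1[zsel])
  e_comp <- edges$compartment[zsel]

  out <- data.frame(compartment = comp$name, sum_i = 0L,
                    s_exposed_um2 = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(comp))) {
    if (z_mid < comp$z0[i] || z_mid >= comp$z1[i]) next
    spc <- .sphere_spacing_for(design, comp$name[i])
    off <- offset
    if (is.null(off)) {
      if (is.null(seed)) stopf("either `offset` or `seed` must be given")
      off <- with_stream_seed(seed, "spheres", section, comp$name[i],
                              code = stats::runif(2) * spc)
    }
    cxs <- .grid_1d(comp$x0[i] - r + off[1], comp$x1[i] + r, spc)
    cys <- .grid_1d(comp$y0[i] - r + off[2], comp$y1[i] + r, spc)
    n_i <- 0L
    csel <- which(e_comp == comp$name[i])
    for (cx in cxs) {
      bx <- csel[e_xmin[csel] <= cx + r & e_xmax[csel] >= cx - r]
      if (!length(bx)) next
      for (cy in cys) {
        bxy <- bx[e_ymin[bx] <= cy + r & e_ymax[bx] >= cy - r]
        if (!length(bxy)) next
        n_i <- n_i + .sphere_edge_crossings(edges, zsel[bxy], cx, cy, z_mid,
                                            r, zlo, zhi)
      }
    }
    area_c <- (comp$x1[i] - comp$x0[i]) * (comp$y1[i] - comp$y0[i])
    out$sum_i[i] <- n_i
    out$s_exposed_um2[i] <- sphere_area * area_c / spc^2
  }
  out
}

#' Apply all probes to the systematically sampled sections of one animal
#'
#' Selects every k-th section with a random start, then applies the point
#' grid, the optical disector and the sphere probes to each sampled section.
#' Each probe uses its own independent random offset per section, all derived
#' from `seed`.
#'
#' @param net a `vascular_network`
#' @param region a `region_model`
#' @param stack a `section_stack`
#' @param design a `sampling_design`
#' @param seed integer seed for all probe placements
#' @return a probe-count table: data.frame with columns section, compartment,
#'   sum_p, q_nodes, sum_i, s_exposed_um2, frame_area_um2
#' @export
probe_counts <- function(net, region, stack, design, seed = 1L) {
  sections <- select_sections(stack, design$interval_k, seed = seed)
  edges <- network_edges(net)
  comp_names <- region$compartments$name
  rows <- vector("list", length(sections))
  for (si in seq_along(sections)) {
    s <- sections[si]
    sp <- count_points(region, stack, s, design, seed = seed)
    sq <- count_saddle_points(net, stack, s, design, seed = seed)
    si_tab <- count_sphere_intersections(net, region, stack, s, design,
                                         seed = seed, edges = edges)
    rows[[si]] <- data.frame(
      section = s,
      compartment = comp_names,
      sum_p = as.integer(sp[comp_names]),
      q_nodes = as.integer(ifelse(comp_names %in% names(sq), sq[comp_names], 0L)),
      sum_i = si_tab$sum_i[match(comp_names, si_tab$compartment)],
      s_exposed_um2 = si_tab$s_exposed_um2[match(comp_names, si_tab$compartment)],
      frame_area_um2 = prod(design$frame_um),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sections") <- sections
  attr(out, "seed") <- seed
  out
}

#' Write / read a probe-count table as CSV
#'
#' The design seed is recorded in a `# seed:` header comment.
#'
#' @param counts a probe-count table from [probe_counts()]
#' @param path file path
#' @param animal_id optional id column value to prepend
#' @export
write_counts_csv <- function(counts, path, animal_id = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", attr(counts, "seed")), con)
  df <- cbind(animal_id = animal_id, counts)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
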
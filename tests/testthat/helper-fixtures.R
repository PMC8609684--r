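# Shared fixtures: tiny regions and hand-built networks with known geometry.

# single-slab region, defaults sized for fast tests
tiny_region <- function(w = 500, y = 400, z = 540, name = "DG") {
  thick <- stats::setNames(w, name)
  build_region_model(thick, lateral_extent = c(y, z))
}

# a small but non-trivial multi-compartment region (~10^7 um^3)
small_region <- function(z = 540) {
  build_region_model(c(DG = 60, CA1 = 45, CA23 = 59, ML = 740, WM = 442) * 0.5,
                     lateral_extent = c(150, z))
}

# Build a vascular_network from explicit polylines.
# `polylines`: list of n x 3 matrices; `kinds`: optional list of length-2
# character vectors giving the node kinds at each polyline's two ends.
manual_network <- function(polylines, compartment = "DG", kinds = NULL,
                           radius = 3) {
  n <- length(polylines)
  nodes_l <- list()
  segs_l <- list()
  verts <- do.call(rbind, polylines)
  nv <- vapply(polylines, nrow, 0L)
  v_end <- cumsum(nv)
  v_start <- v_end - nv + 1L
  comp <- if (length(compartment) == 1L) rep(compartment, n) else compartment
  for (i in seq_len(n)) {
    p <- polylines[[i]]
    kk <- if (is.null(kinds)) c("endpoint", "endpoint") else kinds[[i]]
    nodes_l[[i]] <- data.frame(
      id = c(2L * i - 1L, 2L * i),
      x = p[c(1, nrow(p)), 1], y = p[c(1, nrow(p)), 2],
      z = p[c(1, nrow(p)), 3],
      kind = kk, compartment = comp[i], stringsAsFactors = FALSE
    )
    segs_l[[i]] <- data.frame(
      id = i, node_start = 2L * i - 1L, node_end = 2L * i,
      compartment = comp[i], radius_um = radius, length_um = NA_real_,
      v_start = v_start[i], v_end = v_end[i], stringsAsFactors = FALSE
    )
  }
  colnames(verts) <- c("x", "y", "z")
  net <- structure(
    list(nodes = do.call(rbind, nodes_l), segments = do.call(rbind, segs_l),
         vertices = verts, truth = NULL),
    class = "vascular_network"
  )
  net$segments$length_um <- segment_lengths(net)
  net$truth <- network_truth(net)
  net
}

# straight polyline between two points with n_steps interior subdivisions
straight_poly <- function(a, b, n_steps = 1) {
  s <- seq(0, 1, length.out = n_steps + 1)
  cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]),
        a[3] + s * (b[3] - a[3]))
}

# quick default design scaled for tiny fixtures
tiny_design <- function(...) {
  sampling_design(interval_k = 3L, guard_um = 1,
                  point_spacing_um = c(50, 50),
                  frame_um = c(60, 60),
                  sphere_radius_um = 7,
                  sphere_spacing_um = 40, ...)
}
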
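# Transgenic (Tg) phenotype transformation: reduced dentate-gyrus capillary
# length (imposed by pruning whole segments) and thin hair-like capillaries
# in the vicinity of amyloid-like plaque spheres.

#' Parameters of the transgenic phenotype
#'
#' @param dg_length_multiplier fraction of the original DG capillary length
#'   retained; the default 0.51 imposes the 49% DG length reduction seen in
#'   12-month TgF344-AD hippocampus.
#' @param plaque_centers_density plaques per mm^3; the default 450/mm^3 with
#'   25-um plaques gives roughly 3% volume coverage, matching reported plaque
#'   load in 12-17-month animals.
#' @param plaque_radius plaque sphere radius, um
#' @param hairlike_radius radius (um) assigned to capillaries re-modelled near
#'   plaques ("thin hair-like capillaries")
#' @param hairlike_fraction fraction of capillaries near a plaque that become
#'   hair-like
#' @param plaque_centers optional n x 3 matrix of explicit plaque centres (um);
#'   overrides Poisson placement when given
#' @return a list of class `phenotype_params`
#' @export
phenotype_params <- function(dg_length_multiplier = 0.51,
                             plaque_centers_density = 450,
                             plaque_radius = 25,
                             hairlike_radius = 1.5,
                             hairlike_fraction = 0.8,
                             plaque_centers = NULL) {
  if (dg_length_multiplier <= 0 || dg_length_multiplier > 1) {
    stopf("invalid parameter: `dg_length_multiplier` must be in (0, 1]")
  }
  if (hairlike_fraction < 0 || hairlike_fraction > 1) {
    stopf("invalid parameter: `hairlike_fraction` must be in [0, 1]")
  }
  check_positive(plaque_radius, "plaque_radius")
  check_positive(hairlike_radius, "hairlike_radius")
  if (plaque_centers_density < 0) {
    stopf("invalid parameter: `plaque_centers_density` must be >= 0")
  }
  structure(
    list(dg_length_multiplier = dg_length_multiplier,
         plaque_centers_density = plaque_centers_density,
         plaque_radius = plaque_radius,
         hairlike_radius = hairlike_radius,
         hairlike_fraction = hairlike_fraction,
         plaque_centers = plaque_centers),
    class = "phenotype_params"
  )
}

# Segment polylines of one compartment as a list of coordinate matrices.
.segment_polylines <- function(net, idx) {
  lapply(idx, function(i) {
    net$vertices[net$segments$v_start[i]:net$segments$v_end[i], , drop = FALSE]
  })
}

# Prune whole leaf segments from a compartment subgraph until its total
# length lies in [0.98, 1.02] * target. Degree-2 remnants of former branch
# nodes are healed by merging their two incident segments, so node-kind
# bookkeeping stays exact.
.prune_to_target <- function(start, end, len, polys, kind_of, target) {
  alive <- rep(TRUE, length(start))
  total <- sum(len)
  dead_nodes <- integer(0)
  guard <- 0L
  nmax <- max(c(start, end))
  deg <- tabulate(c(start, end), nbins = nmax)
  while (total > target && guard < 10 * length(start)) {
    guard <- guard + 1L
    cand <- which(alive & (deg[start] == 1L | deg[end] == 1L))
    # never prune past the lower edge of the tolerance band
    cand <- cand[total - len[cand] >= 0.98 * target]
    if (!length(cand)) break
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    alive[s] <- FALSE
    total <- total - len[s]
    deg[start[s]] <- deg[start[s]] - 1L
    deg[end[s]] <- deg[end[s]] - 1L
    for (n in c(start[s], end[s])) {
      inc <- which(alive & (start == n | end == n))
      if (length(inc) == 0L) {
        dead_nodes <- c(dead_nodes, n)
      } else if (length(inc) == 2L && kind_of(n) == "branch") {
        s1 <- inc[1]; s2 <- inc[2]
        v1 <- polys[[s1]]
        if (start[s1] == n) {
          v1 <- v1[rev(seq_len(nrow(v1))), , drop = FALSE]
          a <- end[s1]
        } else {
          a <- start[s1]
        }
        v2 <- polys[[s2]]
        if (end[s2] == n) {
          v2 <- v2[rev(seq_len(nrow(v2))), , drop = FALSE]
          b <- start[s2]
        } else {
          b <- end[s2]
        }
        polys[[s1]] <- rbind(v1, v2[-1, , drop = FALSE])
        start[s1] <- a
        end[s1] <- b
        len[s1] <- len[s1] + len[s2]
        alive[s2] <- FALSE
        deg[n] <- 0L
        dead_nodes <- c(dead_nodes, n)
      }
    }
  }
  if (total > 1.02 * target || total < 0.98 * target) {
    stopf("pruning failure: could not reach %.4g um within 2%% (achieved %.4g)",
          target, total)
  }
  list(start = start, end = end, len = len, polys = polys,
       alive = alive, dead_nodes = dead_nodes, total = total)
}

# Segment ids with any polyline vertex within `radius` of any centre,
# found through a coarse cell hash on vertex coordinates.
.segments_near_centers <- function(net, centers, radius) {
  if (is.null(centers) || nrow(centers) == 0L) return(integer(0))
  v <- net$vertices
  seg_of_vertex <- rep(net$segments$id,
                       net$segments$v_end - net$segments$v_start + 1L)
  cs <- radius
  key <- function(ix, iy, iz) ix + 4096 * iy + 4096^2 * iz
  vkey <- key(floor(v[, 1] / cs), floor(v[, 2] / cs), floor(v[, 3] / cs))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  cb <- cbind(floor(centers[, 1] / cs), floor(centers[, 2] / cs),
              floor(centers[, 3] / cs))
  nbr_keys <- unique(as.vector(vapply(seq_len(nrow(offs)), function(j) {
    key(cb[, 1] + offs[j, 1], cb[, 2] + offs[j, 2], cb[, 3] + offs[j, 3])
  }, numeric(nrow(cb)))))
  cand <- which(!is.na(match(vkey, nbr_keys)))
  hit <- logical(nrow(net$segments))
  if (length(cand)) {
    # sort candidates by x so each plaque only scans an x-window
    ord <- cand[order(v[cand, 1])]
    vx <- v[ord, 1]; vy <- v[ord, 2]; vz <- v[ord, 3]
    for (i in seq_len(nrow(centers))) {
      i0 <- findInterval(centers[i, 1] - radius, vx) + 1L
      i1 <- findInterval(centers[i, 1] + radius, vx)
      if (i1 < i0) next
      rng <- i0:i1
      d2 <- (vx[rng] - centers[i, 1])^2 + (vy[rng] - centers[i, 2])^2 +
        (vz[rng] - centers[i, 3])^2
      hit[seg_of_vertex[ord[rng[d2 <= radius^2]]]] <- TRUE
    }
  }
  which(hit)
}

#' Apply the transgenic phenotype to a network
#'
#' Prunes whole dentate-gyrus segments until the DG truth length equals
#' `dg_length_multiplier` times the original (within 2%), then re-assigns a
#' thin "hair-like" radius to a fraction of the capillaries lying within
#' `plaque_radius` of Poisson-placed plaque centres. The truth table is
#' updated exactly from the transformed geometry; no compartment's length
#' ever increases.
#'
#' @param net a `vascular_network` containing a DG compartment
#' @param params a [phenotype_params()] object
#' @param seed integer seed
#' @return the transformed `vascular_network`
#' @export
apply_tg_phenotype <- function(net, params = phenotype_params(), seed = 1L) {
  stopifnot(inherits(net, "vascular_network"), inherits(params, "phenotype_params"))
  if (!"DG" %in% net$segments$compartment) {
    stopf("missing compartment: network has no DG compartment to transform")
  }

  if (params$dg_length_multiplier < 1) {
    dg_idx <- which(net$segments$compartment == "DG")
    seg <- net$segments
    polys <- .segment_polylines(net, dg_idx)
    kind_vec <- net$nodes$kind
    pr <- with_stream_seed(
      seed, "phenotype", "prune",
      code = .prune_to_target(
        start = seg$node_start[dg_idx], end = seg$node_end[dg_idx],
        len = seg$length_um[dg_idx], polys = polys,
        kind_of = function(n) kind_vec[n],
        target = params$dg_length_multiplier * sum(seg$length_um[dg_idx])
      )
    )
    net <- .rebuild_with_pruned_dg(net, dg_idx, pr)
  }

  centers <- params$plaque_centers
  if (is.null(centers) && params$plaque_centers_density > 0) {
    bbox_hi <- c(max(net$vertices[, 1]), max(net$vertices[, 2]),
                 max(net$vertices[, 3]))
    lambda <- params$plaque_centers_density * prod(bbox_hi) / 1e9
    centers <- with_stream_seed(seed, "phenotype", "plaques", code = {
      n <- stats::rpois(1, lambda)
      matrix(stats::runif(3 * n), ncol = 3) %*% diag(bbox_hi)
    })
  }
  if (!is.null(centers) && nrow(centers) > 0) {
    near <- .segments_near_centers(net, centers, params$plaque_radius)
    if (length(near)) {
      sel <- with_stream_seed(seed, "phenotype", "hairlike", code = {
        near[stats::runif(length(near)) < params$hairlike_fraction]
      })
      net$segments$radius_um[sel] <- params$hairlike_radius
    }
  }

  net$truth <- network_truth(net)
  net
}

# Reassemble the network after DG pruning: surviving DG polylines replace the
# original DG vertex block, dead DG nodes are dropped and ids renumbered.
.rebuild_with_pruned_dg <- function(net, dg_idx, pr) {
  keep_dg <- dg_idx[pr$alive]
  seg <- net$segments
  other_idx <- setdiff(seq_len(nrow(seg)), dg_idx)

  # new vertex matrix: other compartments first (original order), DG last
  other_nv <- seg$v_end[other_idx] - seg$v_start[other_idx] + 1L
  other_rows <- sequence(other_nv) + rep(seg$v_start[other_idx] - 1L, other_nv)
  dg_polys <- pr$polys[pr$alive]
  dg_nv <- vapply(dg_polys, nrow, 0L)
  vertices <- rbind(net$vertices[other_rows, , drop = FALSE],
                    do.call(rbind, dg_polys))

  other_vend <- cumsum(other_nv)
  dg_vend <- sum(other_nv) + cumsum(dg_nv)

  new_seg <- rbind(
    data.frame(
      id = seg$id[other_idx],
      node_start = seg$node_start[other_idx], node_end = seg$node_end[other_idx],
      compartment = seg$compartment[other_idx],
      radius_um = seg$radius_um[other_idx],
      length_um = seg$length_um[other_idx],
      v_start = other_vend - other_nv + 1L, v_end = other_vend,
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = seg$id[keep_dg],
      node_start = pr$start[pr$alive], node_end = pr$end[pr$alive],
      compartment = "DG",
      radius_um = seg$radius_um[keep_dg],
      length_um = pr$len[pr$alive],
      v_start = dg_vend - dg_nv + 1L, v_end = dg_vend,
      stringsAsFactors = FALSE
    )
  )

  node_alive <- rep(TRUE, nrow(net$nodes))
  node_alive[pr$dead_nodes] <- FALSE
  # DG nodes no longer touched by any surviving segment are dead too
  touched <- unique(c(new_seg$node_start, new_seg$node_end))
  dgn <- which(net$nodes$compartment == "DG")
  node_alive[setdiff(dgn, touched)] <- FALSE

  new_id <- cumsum(node_alive)
  nodes <- net$nodes[node_alive, , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  rownames(nodes) <- NULL
  new_seg$node_start <- new_id[new_seg$node_start]
  new_seg$node_end <- new_id[new_seg$node_end]
  new_seg$id <- seq_len(nrow(new_seg))
  rownames(new_seg) <- NULL
  colnames(vertices) <- c("x", "y", "z")

  out <- structure(
    list(nodes = nodes, segments = new_seg, vertices = vertices, truth = NULL),
    class = "vascular_network"
  )
  out$truth <- network_truth(out)
  out
}
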
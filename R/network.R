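# Synthetic 3D capillary networks with exactly known ground truth.
#
# The generative model is an isotropic persistent random walk: capillary
# segments (polylines) grow step-wise with direction jitter inside their
# compartment slab, reflecting at the walls; at the end of each segment the
# chain either branches (a degree-3 "saddle point" node) or terminates (a
# degree-1 endpoint). Trees are subcritical so they die out; residual length
# needed to hit the compartment target exactly is added as short unbranched
# filler chains. All truth quantities (per-compartment length, branch and
# endpoint counts) are recomputed from the emitted geometry.

.rownorm <- function(m) sqrt(rowSums(m * m))

.normalize_rows <- function(m) {
  n <- .rownorm(m)
  bad <- n < 1e-12
  if (any(bad)) {
    m[bad, ] <- matrix(stats::rnorm(3 * sum(bad)), ncol = 3)
    n[bad] <- .rownorm(m[bad, , drop = FALSE])
  }
  m / n
}

.random_dirs <- function(n) .normalize_rows(matrix(stats::rnorm(3 * n), ncol = 3))

# Fold coordinates into [lo, hi] by mirror reflection (triangle wave).
# Returns the folded value and whether the net parity flips the direction.
.fold <- function(v, lo, hi) {
  w <- hi - lo
  if (length(w) == 1L) w <- rep.int(w, length(v))
  u <- (v - lo) %% (2 * w)
  refl <- u > w
  u[refl] <- 2 * w[refl] - u[refl]
  list(x = lo + u, flip = refl)
}

# One growth step for all active tips: jitter direction, advance, reflect.
# `lo`/`hi` are n x 3 matrices of per-tip box bounds (tips of different
# compartments advance in lockstep).
.advance_tips <- function(p, d, len, lo, hi, dir_sd) {
  d <- .normalize_rows(d + matrix(stats::rnorm(length(d), sd = dir_sd), ncol = 3))
  praw <- p + d * len
  for (ax in 1:3) {
    f <- .fold(praw[, ax], lo[, ax], hi[, ax])
    praw[, ax] <- f$x
    d[f$flip, ax] <- -d[f$flip, ax]
  }
  list(p = praw, d = d, moved = .rownorm(praw - p))
}

# Exact-length unbranched chain grown with specular reflection (scalar code;
# only used for the few filler chains that square the length budget).
.exact_chain <- function(box, total_len, step_len) {
  lo <- c(box$x0, box$y0, box$z0)
  hi <- c(box$x1, box$y1, box$z1)
  p <- lo + stats::runif(3) * (hi - lo)
  d <- as.vector(.random_dirs(1))
  verts <- list(p)
  left <- total_len
  guard <- 0
  while (left > 1e-9 && guard < 10000) {
    guard <- guard + 1
    seg <- min(step_len, left)
    # distance to the first wall along d
    t_wall <- Inf
    ax_hit <- 0L
    for (ax in 1:3) {
      if (d[ax] > 1e-12) {
        t <- (hi[ax] - p[ax]) / d[ax]
      } else if (d[ax] < -1e-12) {
        t <- (lo[ax] - p[ax]) / d[ax]
      } else {
        t <- Inf
      }
      if (t < t_wall) {
        t_wall <- t
        ax_hit <- ax
      }
    }
    if (t_wall <= seg) {
      p <- p + d * t_wall
      d[ax_hit] <- -d[ax_hit]
      left <- left - t_wall
    } else {
      p <- p + d * seg
      left <- left - seg
    }
    verts[[length(verts) + 1L]] <- p
  }
  do.call(rbind, verts)
}

# Grow every compartment in one lockstep wave loop. Each compartment gets
# its own z-stratified tree roots and an exact total-length budget: whole
# trees are kept in spawn order up to the target, and the residue is added
# as exact-length unbranched filler chains. Returns the fields of a
# vascular_network (without class/truth).
.grow_all <- function(comp, targets, mean_seg, step_len, branch_prob,
                      dir_sd, branch_dir_sd = 0.8, max_waves = 60L) {
  nc <- nrow(comp)
  e_segs_per_tree <- 1 / (1 - 2 * branch_prob)
  n_roots <- pmax(1L, ceiling(targets * 1.08 / (mean_seg * e_segs_per_tree)))
  lo_mat <- as.matrix(comp[, c("x0", "y0", "z0")])
  hi_mat <- as.matrix(comp[, c("x1", "y1", "z1")])

  # roots: uniform in x/y, z-stratified in random order (capillary beds are
  # space-filling at tissue scale; free Poisson seeds clump along z)
  root_comp <- rep.int(seq_len(nc), n_roots)
  nr <- length(root_comp)
  u <- matrix(stats::runif(3 * nr), ncol = 3)
  strata <- unlist(lapply(n_roots, function(k) {
    (sample.int(k) - 1 + stats::runif(k)) / k
  }), use.names = FALSE)
  u[, 3] <- strata
  roots <- lo_mat[root_comp, , drop = FALSE] +
    u * (hi_mat[root_comp, , drop = FALSE] - lo_mat[root_comp, , drop = FALSE])

  node_pos <- list(roots)
  node_kind <- list(rep("endpoint", nr))
  node_tree <- list(seq_len(nr))
  n_nodes <- nr
  seg_chunks <- list()
  tree_comp <- root_comp
  tree_len <- numeric(nr)

  tips <- list(p = roots, d = .random_dirs(nr),
               parent = seq_len(nr), tree = seq_len(nr))
  wave <- 0L
  while (length(tips$parent) > 0L) {
    wave <- wave + 1L
    m <- length(tips$parent)
    tcomp <- tree_comp[tips$tree]
    seg_len <- pmin(pmax(stats::rexp(m, 1 / mean_seg), 5), 4 * mean_seg)
    n_steps <- ceiling(seg_len / step_len)
    maxs <- max(n_steps)
    verts <- array(NA_real_, c(m, maxs + 1L, 3L))
    verts[, 1L, ] <- tips$p
    p <- tips$p
    d <- tips$d
    moved <- numeric(m)
    lo_t <- lo_mat[tcomp, , drop = FALSE]
    hi_t <- hi_mat[tcomp, , drop = FALSE]
    for (j in seq_len(maxs)) {
      act <- which(n_steps >= j)
      lj <- ifelse(j < n_steps[act], step_len,
                   seg_len[act] - (n_steps[act] - 1) * step_len)
      st <- .advance_tips(p[act, , drop = FALSE], d[act, , drop = FALSE],
                          lj, lo_t[act, , drop = FALSE],
                          hi_t[act, , drop = FALSE], dir_sd)
      p[act, ] <- st$p
      d[act, ] <- st$d
      moved[act] <- moved[act] + st$moved
      verts[act, j + 1L, ] <- st$p
    }

    branch <- stats::runif(m) < branch_prob & wave < max_waves
    new_ids <- n_nodes + seq_len(m)
    node_pos[[length(node_pos) + 1L]] <- p
    node_kind[[length(node_kind) + 1L]] <- ifelse(branch, "branch", "endpoint")
    node_tree[[length(node_tree) + 1L]] <- tips$tree
    n_nodes <- n_nodes + m

    k <- n_steps + 1L
    idx_tip <- rep(seq_len(m), k)
    idx_step <- sequence(k)
    flat <- cbind(verts[cbind(idx_tip, idx_step, 1L)],
                  verts[cbind(idx_tip, idx_step, 2L)],
                  verts[cbind(idx_tip, idx_step, 3L)])
    seg_chunks[[length(seg_chunks) + 1L]] <- list(
      parent = tips$parent, end = new_ids, tree = tips$tree,
      length = moved, nvert = k, verts = flat
    )
    inc <- rowsum(moved, tips$tree)
    inc_tree <- as.integer(rownames(inc))
    tree_len[inc_tree] <- tree_len[inc_tree] + inc[, 1]

    if (any(branch)) {
      sel <- which(branch)
      reps <- rep(sel, each = 2L)
      child_d <- .normalize_rows(
        d[reps, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(reps), sd = branch_dir_sd), ncol = 3)
      )
      tips <- list(p = p[reps, , drop = FALSE], d = child_d,
                   parent = new_ids[reps], tree = tips$tree[reps])
    } else {
      tips <- list(p = matrix(numeric(0), ncol = 3), d = NULL,
                   parent = integer(0), tree = integer(0))
    }
  }

  # per-compartment prefix of whole trees not exceeding the target
  keep_tree <- logical(nr)
  remaining <- numeric(nc)
  for (ci in seq_len(nc)) {
    own <- which(tree_comp == ci)   # spawn order
    cum <- cumsum(tree_len[own])
    kmax <- sum(cum <= targets[ci] + 1e-9)
    keep_tree[own[seq_len(kmax)]] <- TRUE
    remaining[ci] <- targets[ci] - if (kmax > 0L) cum[kmax] else 0
  }

  all_kind <- unlist(node_kind)
  all_tree <- unlist(node_tree)
  all_pos <- do.call(rbind, node_pos)
  node_keep <- keep_tree[all_tree]
  node_comp <- tree_comp[all_tree]

  parent <- unlist(lapply(seg_chunks, `[[`, "parent"))
  endid <- unlist(lapply(seg_chunks, `[[`, "end"))
  segtree <- unlist(lapply(seg_chunks, `[[`, "tree"))
  seglen <- unlist(lapply(seg_chunks, `[[`, "length"))
  nvert <- unlist(lapply(seg_chunks, `[[`, "nvert"))
  vmat <- do.call(rbind, lapply(seg_chunks, `[[`, "verts"))
  seg_keep <- keep_tree[segtree]

  vmat <- vmat[rep(seg_keep, nvert), , drop = FALSE]
  parent <- parent[seg_keep]
  endid <- endid[seg_keep]
  segcomp <- tree_comp[segtree[seg_keep]]
  seglen <- seglen[seg_keep]
  nvert <- nvert[seg_keep]

  new_id <- cumsum(node_keep)
  parent <- new_id[parent]
  endid <- new_id[endid]
  all_pos <- all_pos[node_keep, , drop = FALSE]
  all_kind <- all_kind[node_keep]
  node_comp <- node_comp[node_keep]
  n_nodes <- sum(node_keep)

  # exact-length filler chains for each compartment's residual budget
  fpos <- list(); fkind <- character(0); fcomp_n <- integer(0)
  fparent <- integer(0); fend <- integer(0); fcomp_s <- integer(0)
  flen <- numeric(0); fnv <- integer(0); fverts <- list()
  for (ci in seq_len(nc)) {
    rem <- remaining[ci]
    box <- list(x0 = comp$x0[ci], x1 = comp$x1[ci], y0 = comp$y0[ci],
                y1 = comp$y1[ci], z0 = comp$z0[ci], z1 = comp$z1[ci])
    while (rem > 1e-6) {
      this_len <- if (rem < mean_seg + 5) rem else mean_seg
      ch <- .exact_chain(box, this_len, step_len)
      nv <- nrow(ch)
      fpos[[length(fpos) + 1L]] <- ch[c(1L, nv), , drop = FALSE]
      fkind <- c(fkind, "endpoint", "endpoint")
      fcomp_n <- c(fcomp_n, ci, ci)
      fparent <- c(fparent, n_nodes + 1L)
      fend <- c(fend, n_nodes + 2L)
      fcomp_s <- c(fcomp_s, ci)
      flen <- c(flen, this_len)
      fnv <- c(fnv, nv)
      fverts[[length(fverts) + 1L]] <- ch
      n_nodes <- n_nodes + 2L
      rem <- rem - this_len
    }
  }
  if (length(flen)) {
    all_pos <- rbind(all_pos, do.call(rbind, fpos))
    all_kind <- c(all_kind, fkind)
    node_comp <- c(node_comp, fcomp_n)
    parent <- c(parent, fparent)
    endid <- c(endid, fend)
    segcomp <- c(segcomp, fcomp_s)
    seglen <- c(seglen, flen)
    nvert <- c(nvert, fnv)
    vmat <- rbind(vmat, do.call(rbind, fverts))
  }

  list(node_pos = all_pos, node_kind = all_kind, node_comp = node_comp,
       seg_start = parent, seg_end = endid, seg_comp = segcomp,
       seg_length = seglen, seg_nvert = nvert, vertices = vmat)
}

#' Generate a seeded random vascular network with known ground truth
#'
#' Grows isotropically oriented branching capillary chains inside each
#' compartment of `region` until the compartment's total centerline length
#' matches `target_lv * volume` (exactly, via whole-tree bookkeeping plus
#' short unbranched filler chains). Identical `(parameters, seed)` give an
#' identical network.
#'
#' @param region a `region_model`
#' @param target_lv target length density in um^-2 (um per um^3); a single
#'   value or a named vector with one entry per compartment. Published
#'   hippocampal capillary values are around 1.7e-3 to 2.1e-3 um^-2
#'   (1.7-2.1 m/mm^3).
#' @param mean_segment_length mean capillary segment (node-to-node) length, um
#' @param seed integer seed
#' @param step_length polyline step, um (controls tortuosity resolution)
#' @param branch_prob probability that a chain branches (rather than ends) at
#'   a node; must be < 0.5 so trees are subcritical
#' @param dir_sd per-step direction jitter (sd of the isotropic perturbation)
#' @param radius_um capillary radius assigned to every segment, um
#' @param tol relative tolerance on achieved vs target length
#' @return an object of class `vascular_network` with `nodes`, `segments`,
#'   `vertices` and a recomputable `truth` table.
#' @export
generate_network <- function(region, target_lv, mean_segment_length = 62,
                             seed = 1L, step_length = 20, branch_prob = 0.4,
                             dir_sd = 0.35, radius_um = 3, tol = 0.01) {
  stopifnot(inherits(region, "region_model"))
  check_positive(target_lv, "target_lv")
  check_positive(mean_segment_length, "mean_segment_length")
  if (branch_prob < 0 || branch_prob >= 0.5) {
    stopf("invalid parameter: `branch_prob` must be in [0, 0.5)")
  }
  comp <- region$compartments
  if (length(target_lv) == 1L && is.null(names(target_lv))) {
    target_lv <- stats::setNames(rep(target_lv, nrow(comp)), comp$name)
  }
  if (!all(comp$name %in% names(target_lv))) {
    stopf("`target_lv` must name every compartment of the region")
  }
  targets <- target_lv[comp$name] * comp$volume_um3

  g <- with_stream_seed(
    seed, "generate",
    code = .grow_all(comp, targets, mean_segment_length, step_length,
                     branch_prob, dir_sd)
  )
  achieved <- rowsum(g$seg_length, comp$name[g$seg_comp])
  for (i in seq_len(nrow(comp))) {
    a <- achieved[comp$name[i], 1]
    if (abs(a - targets[i]) > tol * targets[i]) {
      stopf("generation failure in %s: achieved %.4g of target %.4g um",
            comp$name[i], a, targets[i])
    }
  }

  v_end <- cumsum(g$seg_nvert)
  nodes <- data.frame(
    id = seq_len(nrow(g$node_pos)),
    x = g$node_pos[, 1], y = g$node_pos[, 2], z = g$node_pos[, 3],
    kind = g$node_kind, compartment = comp$name[g$node_comp],
    stringsAsFactors = FALSE
  )
  segments <- data.frame(
    id = seq_along(g$seg_start),
    node_start = g$seg_start, node_end = g$seg_end,
    compartment = comp$name[g$seg_comp],
    radius_um = radius_um, length_um = g$seg_length,
    v_start = v_end - g$seg_nvert + 1L, v_end = v_end,
    stringsAsFactors = FALSE
  )
  vertices <- g$vertices
  colnames(vertices) <- c("x", "y", "z")
  net <- structure(
    list(nodes = nodes, segments = segments, vertices = vertices, truth = NULL),
    class = "vascular_network"
  )
  net$truth <- network_truth(net)
  net
}

#' Recompute the ground-truth table of a network from its geometry
#'
#' Sums polyline lengths and tallies node kinds per compartment. This is the
#' authoritative truth: the stored `$truth` table must always equal it.
#'
#' @param net a `vascular_network`
#' @return data.frame with columns compartment, length_um, n_branch,
#'   n_endpoint, n_segments
#' @export
network_truth <- function(net) {
  seg <- net$segments
  len <- segment_lengths(net)
  comps <- unique(c(seg$compartment, net$nodes$compartment))
  out <- data.frame(compartment = comps, stringsAsFactors = FALSE)
  out$length_um <- vapply(comps, function(cc) sum(len[seg$compartment == cc]), 0)
  out$n_branch <- vapply(
    comps, function(cc) {
      sum(net$nodes$kind == "branch" & net$nodes$compartment == cc)
    }, 0L)
  out$n_endpoint <- vapply(
    comps, function(cc) {
      sum(net$nodes$kind == "endpoint" & net$nodes$compartment == cc)
    }, 0L)
  out$n_segments <- vapply(comps, function(cc) sum(seg$compartment == cc), 0L)
  rownames(out) <- NULL
  out
}

#' Exact polyline length of every segment
#' @param net a `vascular_network`
#' @return numeric vector, um
#' @export
segment_lengths <- function(net) {
  v <- net$vertices
  seg <- net$segments
  nv <- seg$v_end - seg$v_start + 1L
  rows <- sequence(nv - 1L) + rep(seg$v_start - 1L, nv - 1L)
  d <- v[rows + 1L, , drop = FALSE] - v[rows, , drop = FALSE]
  el <- sqrt(rowSums(d * d))
  grp <- rep(seq_len(nrow(seg)), nv - 1L)
  as.numeric(rowsum(el, grp, reorder = TRUE))
}

# Flat edge table (one row per polyline edge) used by the probe code.
network_edges <- function(net) {
  v <- net$vertices
  seg <- net$segments
  nv <- seg$v_end - seg$v_start + 1L
  rows <- sequence(nv - 1L) + rep(seg$v_start - 1L, nv - 1L)
  a <- v[rows, , drop = FALSE]
  b <- v[rows + 1L, , drop = FALSE]
  list(
    x0 = a[, 1], y0 = a[, 2], z0 = a[, 3],
    x1 = b[, 1], y1 = b[, 2], z1 = b[, 3],
    compartment = rep(seg$compartment, nv - 1L),
    segment = rep(seg$id, nv - 1L)
  )
}

# Node degrees implied by segment incidences.
node_degrees <- function(net) {
  tab <- tabulate(c(net$segments$node_start, net$segments$node_end),
                  nbins = nrow(net$nodes))
  tab
}

#' Validate the structural invariants of a network
#'
#' Checks that every polyline has positive length, every node is referenced,
#' endpoint nodes have degree 1 and branch nodes degree >= 3, and that the
#' stored truth table matches a fresh recomputation from geometry.
#'
#' @param net a `vascular_network`
#' @return invisibly `TRUE`; errors otherwise
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  len <- segment_lengths(net)
  if (any(len <= 0)) stopf("invalid network: segment with non-positive length")
  deg <- node_degrees(net)
  if (any(deg == 0)) stopf("invalid network: unreferenced node")
  kind <- net$nodes$kind
  if (any(deg[kind == "endpoint"] != 1L)) {
    stopf("invalid network: endpoint node with degree != 1")
  }
  if (any(deg[kind == "branch"] < 3L)) {
    stopf("invalid network: branch node with degree < 3")
  }
  fresh <- network_truth(net)
  stored <- net$truth[match(fresh$compartment, net$truth$compartment), ]
  if (any(abs(fresh$length_um - stored$length_um) >
          1e-6 * pmax(fresh$length_um, 1))) {
    stopf("invalid network: stored truth lengths disagree with geometry")
  }
  if (any(fresh$n_branch != stored$n_branch) ||
      any(fresh$n_endpoint != stored$n_endpoint)) {
    stopf("invalid network: stored truth node counts disagree with geometry")
  }
  invisible(TRUE)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("Vascular network: %d segments, %d nodes (%d branch, %d endpoint)\n",
              nrow(x$segments), nrow(x$nodes),
              sum(x$nodes$kind == "branch"), sum(x$nodes$kind == "endpoint")))
  cat(sprintf("  total length %.4g um\n", sum(x$truth$length_um)))
  print(x$truth, row.names = FALSE)
  invisible(x)
}

#' Write / read a vascular network as JSON
#'
#' The JSON carries nodes (id, x, y, z, kind), segments (id, ends, polyline
#' vertices, radius, compartment) and the truth block, and round-trips
#' exactly enough that truth recomputation still matches.
#'
#' @param net a `vascular_network`
#' @param path file path
#' @export
write_network_json <- function(net, path) {
  seg <- net$segments
  nv <- seg$v_end - seg$v_start + 1L
  rows <- sequence(nv) + rep(seg$v_start - 1L, nv)
  v <- net$vertices[rows, , drop = FALSE]
  # pre-render each segment's vertex array as embedded JSON (much faster
  # than serialising tens of thousands of small nested matrices)
  row_str <- paste0("[", as.character(v[, 1]), ",", as.character(v[, 2]),
                    ",", as.character(v[, 3]), "]")
  grp <- factor(rep(seg$id, nv), levels = seg$id)
  vert_json <- vapply(split(row_str, grp), paste, "", collapse = ",")
  seg_json <- paste0(
    '{"id":', seg$id,
    ',"ends":[', seg$node_start, ",", seg$node_end,
    '],"compartment":"', seg$compartment,
    '","radius":', as.character(seg$radius_um),
    ',"vertices":[', vert_json, "]}"
  )
  nodes_json <- jsonlite::toJSON(net$nodes, dataframe = "rows", digits = NA,
                                 auto_unbox = TRUE)
  truth_json <- jsonlite::toJSON(net$truth, dataframe = "rows", digits = NA,
                                 auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0('{"nodes":', nodes_json, ',"segments":[',
                    paste(seg_json, collapse = ","), '],"truth":',
                    truth_json, "}"),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(payload$nodes, stringsAsFactors = FALSE)
  segs <- payload$segments
  nseg <- length(segs$id)
  vmats <- segs$vertices
  nvert <- vapply(vmats, nrow, 0L)
  v_end <- cumsum(nvert)
  v_start <- v_end - nvert + 1L
  ends <- do.call(rbind, segs$ends)
  segments <- data.frame(
    id = segs$id,
    node_start = ends[, 1], node_end = ends[, 2],
    compartment = segs$compartment,
    radius_um = segs$radius,
    length_um = NA_real_,
    v_start = v_start, v_end = v_end,
    stringsAsFactors = FALSE
  )
  vertices <- do.call(rbind, vmats)
  colnames(vertices) <- c("x", "y", "z")
  net <- structure(
    list(nodes = nodes, segments = segments, vertices = vertices,
         truth = as.data.frame(payload$truth, stringsAsFactors = FALSE)),
    class = "vascular_network"
  )
  net$segments$length_um <- segment_lengths(net)
  net
}

#' Export a network as CSV edge list (segment metadata + vertices)
#'
#' Writes `<stem>_segments.csv` and `<stem>_vertices.csv`.
#'
#' @param net a `vascular_network`
#' @param stem path stem without extension
#' @export
write_network_csv <- function(net, stem) {
  seg_path <- paste0(stem, "_segments.csv")
  vert_path <- paste0(stem, "_vertices.csv")
  utils::write.csv(net$segments, seg_path, row.names = FALSE)
  seg <- net$segments
  nv <- seg$v_end - seg$v_start + 1L
  vdf <- data.frame(
    segment_id = rep(seg$id, nv),
    net$vertices[sequence(nv) + rep(seg$v_start - 1L, nv), , drop = FALSE]
  )
  utils::write.csv(vdf, vert_path, row.names = FALSE)
  invisible(c(seg_path, vert_path))
}

#' Default generator length-density targets
#'
#' Per-compartment capillary length densities (um^-2) calibrated to published
#' non-transgenic hippocampal values: around 1.7-1.9 m/mm^3 in the principal
#' cell layers and slightly lower in molecular layer and white matter, giving
#' a volume-weighted whole-region density near 1.65e-3 um^-2 (1.65 m/mm^3).
#' @return named numeric vector
#' @export
default_lv_targets <- function() {
  c(DG = 1.70e-3, CA1 = 1.90e-3, CA23 = 1.87e-3, ML = 1.65e-3, WM = 1.55e-3)
}
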
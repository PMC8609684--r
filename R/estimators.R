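# Stereological estimators: Cavalieri volume, Euler-number capillary counts
# from disector saddle points, sphere-probe length, derived densities and
# Krogh-type diffusion distance, and the Gundersen coefficient of error.

#' Cavalieri volume estimate from systematic point counts
#'
#' `V = sum(P) * a(p) * k * t`: summed grid points times area per point,
#' section sampling interval and section thickness.
#'
#' @param sum_p per-section point counts (or their sum)
#' @param area_per_point_um2 a(p), um^2
#' @param k section sampling interval
#' @param t_um section thickness, um
#' @return volume in um^3
#' @export
cavalieri_volume <- function(sum_p, area_per_point_um2, k, t_um) {
  check_positive(area_per_point_um2, "area_per_point_um2")
  check_positive(k, "k")
  check_positive(t_um, "t_um")
  if (any(sum_p < 0)) stopf("invalid parameter: negative point counts")
  sum(sum_p) * area_per_point_um2 * k * t_um
}

#' Euler-number capillary and endpoint counts from disector saddle points
#'
#' Scales the summed saddle-point (branch node) count by the reciprocal
#' sampling fractions of the optical fractionator, then applies the Euler
#' relations for a capillary network: total capillary number is twice the
#' node number and the endpoint number is the node number plus one (the +1
#' is applied once, after scaling to the whole reference space, treating the
#' region's network as one connected structure).
#'
#' @param sum_q summed saddle-point count over all sampled disectors
#' @param ssf section sampling fraction (1/k)
#' @param asf area sampling fraction (frame area / frame lattice cell area)
#' @param hsf height sampling fraction ((t - 2g) / t)
#' @return list with `n_nodes`, `n_cap`, `n_endp`
#' @export
euler_counts <- function(sum_q, ssf, asf, hsf) {
  check_positive(ssf, "ssf")
  check_positive(asf, "asf")
  check_positive(hsf, "hsf")
  if (ssf > 1 || asf > 1 || hsf > 1) {
    stopf("invalid parameter: sampling fractions must be in (0, 1]")
  }
  if (sum_q < 0) stopf("invalid parameter: negative saddle-point count")
  n_nodes <- sum_q / (ssf * asf * hsf)
  list(n_nodes = n_nodes, n_cap = 2 * n_nodes, n_endp = n_nodes + 1)
}

#' Total capillary length from sphere-probe intersections
#'
#' The number of transversal intersections between isotropic sphere surfaces
#' and capillary centerlines is proportional to length density:
#' `Lv = 2 * sum(I) / S_exposed`, with `S_exposed` the summed exposed sphere
#' surface over the sampled sections (the section sampling fraction cancels
#' because the surface comes only from sampled sections). Total length is
#' `Lv * V_ref`.
#'
#' @param sum_i summed intersection count
#' @param s_exposed_um2 summed exposed sphere surface, um^2
#' @param v_ref_um3 reference volume, um^3 (typically the Cavalieri estimate)
#' @return list with `lv_um2` (um^-2) and `l_um` (um)
#' @export
sphere_length <- function(sum_i, s_exposed_um2, v_ref_um3) {
  if (sum_i < 0) stopf("invalid parameter: negative intersection count")
  if (s_exposed_um2 <= 0) {
    if (sum_i > 0) {
      stopf("inconsistent counts: intersections with zero exposed sphere surface")
    }
    return(list(lv_um2 = 0, l_um = 0))
  }
  lv <- 2 * sum_i / s_exposed_um2
  list(lv_um2 = lv, l_um = lv * v_ref_um3)
}

#' Densities, mean capillary length and potential diffusion distance
#'
#' Number and length densities are the totals divided by the reference
#' volume; mean capillary length is total length over total capillary
#' number. The potential diffusion distance derives from length density by
#' Krogh-cylinder geometry: each unit of capillary length supplies a
#' cylinder of tissue, so `r_diff = (4 * pi * Lv)^(-1/2)` with Lv in um^-2
#' (a configurable proportionality constant `c` generalises to
#' `r_diff = c * Lv^(-1/2)`; the default is `(4 pi)^(-1/2) = 0.2821`).
#'
#' @param v_um3 reference volume, um^3 (> 0)
#' @param n_cap total capillary number
#' @param n_endp total endpoint number
#' @param l_um total capillary length, um
#' @param diffusion_constant proportionality constant c of the diffusion
#'   distance
#' @return list with nv_um3, nv_endp_um3 (um^-3), lv_um2 (um^-2),
#'   mean_length_um (NA when `n_cap` is 0) and r_diff_um
#' @export
derive_densities <- function(v_um3, n_cap, n_endp, l_um,
                             diffusion_constant = 1 / sqrt(4 * pi)) {
  check_positive(v_um3, "v_um3")
  nv <- n_cap / v_um3
  nv_endp <- n_endp / v_um3
  lv <- l_um / v_um3
  mean_length <- if (n_cap > 0) l_um / n_cap else NA_real_
  r_diff <- if (lv > 0) diffusion_constant / sqrt(lv) else NA_real_
  list(nv_um3 = nv, nv_endp_um3 = nv_endp, lv_um2 = lv,
       mean_length_um = mean_length, r_diff_um = r_diff)
}

#' Gundersen coefficient of error for systematic samples
#'
#' Sampling-error estimate for a systematic-uniform-random series of
#' per-section counts `p_i`, after Gundersen's 1999 formulation. With
#' `A = sum(p_i^2)`, `B = sum(p_i p_{i+1})`, `C = sum(p_i p_{i+2})`,
#' the systematic variance is `(3(A - noise) - 4B + C) / 240` for smoothness
#' class 1 (smooth area profiles, e.g. Cavalieri point counts) or
#' `(3(A - noise) - 4B + C) / 12` for smoothness class 0 (object counts).
#' The nugget (noise) term is `0.0724 * b/sqrt(a) * sqrt(n * sum(p))` for
#' point counts and 0 for object counts.
#'
#' @param counts ordered per-section counts (>= 3 sections)
#' @param smoothness 0 or 1
#' @param count_type `"point"` (Cavalieri grid counts, with nugget) or
#'   `"object"` (disector / sphere intersection counts, nugget 0)
#' @param shape_coefficient profile shape coefficient b/sqrt(a) of the
#'   nugget term (default 5)
#' @return CE (dimensionless)
#' @export
ce_gundersen <- function(counts, smoothness = 1,
                         count_type = c("object", "point"),
                         shape_coefficient = 5) {
  count_type <- match.arg(count_type)
  n <- length(counts)
  if (n < 3) stopf("insufficient sections: CE needs >= 3 sampled sections")
  if (any(counts < 0)) stopf("invalid parameter: negative counts")
  total <- sum(counts)
  if (total <= 0) stopf("degenerate counts: CE undefined for all-zero series")
  if (!smoothness %in% c(0, 1)) stopf("invalid parameter: smoothness must be 0 or 1")
  noise <- if (count_type == "point") {
    0.0724 * shape_coefficient * sqrt(n * total)
  } else 0
  A <- sum(counts^2)
  B <- sum(counts[-n] * counts[-1])
  C <- if (n >= 3) sum(counts[seq_len(n - 2)] * counts[-(1:2)]) else 0
  denom <- if (smoothness == 1) 240 else 12
  var_srs <- max(0, (3 * (A - noise) - 4 * B + C) / denom)
  sqrt(noise + var_srs) / total
}

#' Full stereological estimate set for one animal
#'
#' Turns a probe-count table into per-compartment estimates, plus `PCL`
#' (DG + CA1 + CA2/3) and `total` aggregates formed by summing totals before
#' deriving densities. Reported units follow morphometric convention:
#' volumes in mm^3, lengths in m, densities per mm^3 and m/mm^3, mean length
#' and diffusion distance in um.
#'
#' @param counts probe-count table from [probe_counts()]
#' @param design the `sampling_design` used
#' @param stack the `section_stack` used
#' @param region the `region_model` (for PCL membership)
#' @param animal_id,group optional identifiers carried into the output
#' @return data.frame, one row per compartment/aggregate
#' @export
estimate_animal <- function(counts, design, stack, region,
                            animal_id = NA, group = NA) {
  hsf <- .check_disector(design, stack) / stack$t
  ssf <- 1 / design$interval_k
  asf <- prod(design$frame_um) / prod(design$frame_spacing_um)
  k <- design$interval_k
  t_um <- stack$t

  comps <- unique(counts$compartment)
  per <- lapply(comps, function(cc) {
    sub <- counts[counts$compartment == cc, ]
    sub <- sub[order(sub$section), ]
    v <- cavalieri_volume(sub$sum_p, design$area_per_point_um2, k, t_um)
    eu <- euler_counts(sum(sub$q_nodes), ssf, asf, hsf)
    sl <- sphere_length(sum(sub$sum_i), sum(sub$s_exposed_um2), v)
    list(compartment = cc, v_um3 = v, n_nodes = eu$n_nodes, l_um = sl$l_um,
         p_series = sub$sum_p, q_series = sub$q_nodes, i_series = sub$sum_i)
  })
  names(per) <- comps

  # Aggregates sum the estimated totals (V, nodes, L) of their member
  # compartments; pooling raw sphere counts across compartments would weight
  # them by sphere-lattice density rather than by volume and bias Lv.
  agg <- function(members, label) {
    sub <- per[members]
    list(compartment = label,
         v_um3 = sum(vapply(sub, `[[`, 0, "v_um3")),
         n_nodes = sum(vapply(sub, `[[`, 0, "n_nodes")),
         l_um = sum(vapply(sub, `[[`, 0, "l_um")),
         p_series = Reduce(`+`, lapply(sub, `[[`, "p_series")),
         q_series = Reduce(`+`, lapply(sub, `[[`, "q_series")),
         i_series = Reduce(`+`, lapply(sub, `[[`, "i_series")))
  }
  pcl <- intersect(region$pcl_members, comps)
  rows <- c(per,
            if (length(pcl) > 1) list(PCL = agg(pcl, "PCL")),
            list(total = agg(comps, "total")))

  out <- lapply(rows, function(r) {
    n_cap <- 2 * r$n_nodes
    n_endp <- r$n_nodes + 1
    dens <- if (r$v_um3 > 0) {
      derive_densities(r$v_um3, n_cap, n_endp, r$l_um)
    } else {
      list(nv_um3 = NA_real_, nv_endp_um3 = NA_real_, lv_um2 = NA_real_,
           mean_length_um = NA_real_, r_diff_um = NA_real_)
    }
    ce_v <- tryCatch(ce_gundersen(r$p_series, smoothness = 1, count_type = "point"),
                     error = function(e) NA_real_)
    ce_n <- tryCatch(ce_gundersen(r$q_series, smoothness = 0, count_type = "object"),
                     error = function(e) NA_real_)
    ce_l <- tryCatch(ce_gundersen(r$i_series, smoothness = 0, count_type = "object"),
                     error = function(e) NA_real_)
    data.frame(
      animal_id = animal_id, group = group, compartment = r$compartment,
      v_mm3 = r$v_um3 / UM3_PER_MM3,
      n_cap = n_cap, n_endp = n_endp,
      nv_per_mm3 = dens$nv_um3 * UM3_PER_MM3,
      nvendp_per_mm3 = dens$nv_endp_um3 * UM3_PER_MM3,
      l_m = r$l_um / UM_PER_M,
      lv_m_per_mm3 = lv_to_m_per_mm3(dens$lv_um2),
      mean_len_um = dens$mean_length_um,
      rdiff_um = dens$r_diff_um,
      ce_v = ce_v, ce_n = ce_n, ce_l = ce_l,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
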
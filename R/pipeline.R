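# End-to-end experiment orchestration: configuration, cohort simulation,
# probing, estimation and reporting, all reproducible from one master seed
# through named per-animal random streams.

#' Experiment configuration
#'
#' Bundles every tunable of a simulated stereology experiment. The defaults
#' reproduce the study conditions the package models: ~350 serial 18-um
#' sections sampled every 30th with 1-um guard zones, compartment volume
#' fractions and length densities matching published non-transgenic
#' hippocampal morphometry, a transgenic phenotype retaining 51% of DG
#' capillary length, and cohort sizes of 6 Tg vs 5 non-Tg animals.
#'
#' @param region a `region_model`
#' @param lv_targets named per-compartment length-density targets, um^-2
#' @param phenotype a [phenotype_params()] object for the Tg group
#' @param design a [sampling_design()]
#' @param section_thickness_um section thickness t, um
#' @param n_tg,n_nontg cohort sizes
#' @param mean_segment_length mean capillary segment length, um
#' @param master_seed master seed; every random draw in the experiment is
#'   derived from it through named streams
#' @return list of class `experiment_config`
#' @export
experiment_config <- function(region = default_region(),
                              lv_targets = default_lv_targets(),
                              phenotype = phenotype_params(),
                              design = sampling_design(),
                              section_thickness_um = 18,
                              n_tg = 6L, n_nontg = 5L,
                              mean_segment_length = 62,
                              master_seed = 1L) {
  stopifnot(inherits(region, "region_model"),
            inherits(phenotype, "phenotype_params"),
            inherits(design, "sampling_design"))
  if (n_tg < 0 || n_nontg < 0) stopf("invalid config: negative cohort size")
  cfg <- list(region = region, lv_targets = lv_targets, phenotype = phenotype,
              design = design, section_thickness_um = section_thickness_um,
              n_tg = as.integer(n_tg), n_nontg = as.integer(n_nontg),
              mean_segment_length = mean_segment_length,
              master_seed = as.integer(master_seed))
  class(cfg) <- "experiment_config"
  cfg
}

.animal_ids <- function(cfg) {
  data.frame(
    animal_id = c(sprintf("tg%02d", seq_len(cfg$n_tg)),
                  sprintf("wt%02d", seq_len(cfg$n_nontg))),
    group = c(rep("Tg", cfg$n_tg), rep("nonTg", cfg$n_nontg)),
    stringsAsFactors = FALSE
  )
}

#' Simulate one animal's vascular network
#'
#' Generates a network at the configured targets; animals in the `Tg` group
#' additionally receive the transgenic phenotype. Randomness comes from a
#' stream named by the animal id, so one animal's network is invariant to
#' cohort size or order.
#'
#' @param cfg an `experiment_config`
#' @param animal_id character id
#' @param group `"Tg"` or `"nonTg"`
#' @return a `vascular_network`
#' @export
simulate_animal <- function(cfg, animal_id, group = c("nonTg", "Tg")) {
  group <- match.arg(group)
  seed <- stream_seed(cfg$master_seed, "animal", animal_id)
  net <- generate_network(cfg$region, cfg$lv_targets,
                          mean_segment_length = cfg$mean_segment_length,
                          seed = seed)
  if (group == "Tg") {
    net <- apply_tg_phenotype(net, cfg$phenotype,
                              seed = stream_seed(seed, "tg"))
  }
  net
}

#' Simulate the whole cohort and write network/region files
#'
#' Writes one network JSON per animal plus the region JSON and a manifest
#' (CSV) listing files, groups and seeds.
#'
#' @param cfg an `experiment_config`
#' @param out_dir output directory (created if needed)
#' @return the manifest data.frame, invisibly
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- .animal_ids(cfg)
  write_region_json(cfg$region, file.path(out_dir, "region.json"))
  files <- character(nrow(ids))
  for (i in seq_len(nrow(ids))) {
    net <- simulate_animal(cfg, ids$animal_id[i], ids$group[i])
    files[i] <- file.path(out_dir, paste0(ids$animal_id[i], "_network.json"))
    write_network_json(net, files[i])
  }
  manifest <- cbind(ids,
                    file = files,
                    seed = vapply(ids$animal_id, function(a) {
                      stream_seed(cfg$master_seed, "animal", a)
                    }, 0L))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Run the full stereology pipeline on a (simulated) cohort
#'
#' Chains simulation, systematic sectioning and probing, estimation and the
#' group-comparison report for every animal of the configured cohort. Each
#' stage's outputs can be written as CSV/JSON under `out_dir`.
#'
#' @param cfg an `experiment_config`
#' @param out_dir optional output directory for stage outputs
#' @param networks optional named list of pre-simulated networks (by animal
#'   id); missing animals are simulated in-run
#' @param quiet suppress per-stage progress messages?
#' @return list with `counts` (probe-count table over all animals),
#'   `estimates` (per-animal estimate table), `report` (a `stereo_report`),
#'   and `truth` (per-animal, per-compartment ground truth)
#' @export
run_pipeline <- function(cfg, out_dir = NULL, networks = NULL, quiet = TRUE) {
  ids <- .animal_ids(cfg)
  stack <- section_stack(cfg$region$extent[["z"]], cfg$section_thickness_um)
  counts_l <- list()
  est_l <- list()
  truth_l <- list()
  for (i in seq_len(nrow(ids))) {
    aid <- ids$animal_id[i]
    if (!quiet) message("animal ", aid, " (", ids$group[i], ")")
    net <- if (!is.null(networks) && aid %in% names(networks)) {
      networks[[aid]]
    } else {
      simulate_animal(cfg, aid, ids$group[i])
    }
    probe_seed <- stream_seed(cfg$master_seed, "probe", aid)
    counts <- probe_counts(net, cfg$region, stack, cfg$design, seed = probe_seed)
    est <- estimate_animal(counts, cfg$design, stack, cfg$region,
                           animal_id = aid, group = ids$group[i])
    counts_l[[i]] <- cbind(animal_id = aid, group = ids$group[i], counts)
    est_l[[i]] <- est
    tr <- net$truth
    tr$animal_id <- aid
    tr$group <- ids$group[i]
    truth_l[[i]] <- tr
  }
  counts <- do.call(rbind, counts_l)
  estimates <- do.call(rbind, est_l)
  truth <- do.call(rbind, truth_l)
  report <- build_report(estimates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(counts, file.path(out_dir, "probe_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write_report(report, file.path(out_dir, "report"))
  }
  list(counts = counts, estimates = estimates, report = report, truth = truth)
}

#' Bundled reference group summary (published stereological table)
#'
#' Group means and SDs of the stereological microvascular parameters of
#' 12-month-old TgF344-AD (`Tg`, n = 6) and non-transgenic (`nonTg`, n = 5)
#' rat hippocampus, per compartment, as printed in the published table this
#' package's simulator is calibrated against. Used for desk-scale worked
#' examples (mean capillary length, headline percent changes) and for
#' generator defaults; not produced by this package's estimators.
#'
#' @return data.frame with columns compartment, group, parameter, mean, sd
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "tgf344ad_hippocampus_reference.csv",
                      package = "stereovasc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
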
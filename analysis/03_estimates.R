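#!/usr/bin/env Rscript
# Stage 3: stereological estimation.
#
# Turns the raw probe counts into per-animal, per-compartment estimates:
# Cavalieri volumes, Euler-number capillary and endpoint counts (2x nodes;
# nodes + 1), sphere-probe total length, densities, mean capillary length,
# Krogh-type diffusion distance, and Gundersen coefficients of error.
# Also joins the simulator's ground truth for an estimate/truth comparison
# no real study could make.

library(stereovasc)

seed <- as.integer(Sys.getenv("STEREOVASC_SEED", "1"))
cfg <- experiment_config(master_seed = seed)
region <- read_region_json("results/networks/region.json")
stack <- section_stack(region$extent[["z"]], cfg$section_thickness_um)
counts <- read.csv("results/probe_counts.csv")

est <- do.call(rbind, lapply(split(counts, counts$animal_id), function(sub) {
  estimate_animal(sub, cfg$design, stack, region,
                  animal_id = sub$animal_id[1], group = sub$group[1])
}))
rownames(est) <- NULL
write.csv(est, "results/estimates.csv", row.names = FALSE)

truth <- read.csv("results/networks/ground_truth.csv")
tot_truth <- aggregate(cbind(length_um, n_branch) ~ animal_id, truth, sum)
tot_est <- est[est$compartment == "total", ]
m <- match(tot_est$animal_id, tot_truth$animal_id)
cmp <- data.frame(
  animal_id = tot_est$animal_id, group = tot_est$group,
  l_ratio = tot_est$l_m * 1e6 / tot_truth$length_um[m],
  n_ratio = (tot_est$n_cap / 2) / tot_truth$n_branch[m],
  ce_v = tot_est$ce_v, ce_l = tot_est$ce_l
)
write.csv(cmp, "results/estimate_vs_truth.csv", row.names = FALSE)

message("Whole-region estimate/truth ratios across the cohort:")
message(sprintf("  L-hat / L-truth: mean %.3f (range %.3f-%.3f)",
                mean(cmp$l_ratio), min(cmp$l_ratio), max(cmp$l_ratio)))
message(sprintf("  N-hat / N-truth: mean %.3f (range %.3f-%.3f)",
                mean(cmp$n_ratio), min(cmp$n_ratio), max(cmp$n_ratio)))
message(sprintf("  CE(V) max %.3f, CE(L) max %.3f",
                max(cmp$ce_v), max(cmp$ce_l)))
message("Wrote results/estimates.csv and results/estimate_vs_truth.csv")
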
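#!/usr/bin/env Rscript
# Model-based inference of the chaperone expression distribution at
# 43 degC in both culture conditions (run 01_simulate_population.R first):
# per-cell single-free-parameter fits, the 2 % satisfactory-fit gate, the
# fit-success comparison with and without chaperone heterogeneity, and the
# population distribution assembled from per-cell likelihoods. Tables land
# under results/inference/.

suppressPackageStartupMessages(library(hsrdyn))

pop_dir <- "results/populations"
out_dir <- "results/inference"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
params <- hsr_params()
grid <- default_hsp0_grid(params, n = 60)

infer_condition <- function(tag) {
  traj <- read_trajectories(file.path(pop_dir,
                                      sprintf("traj_43C_%s.csv", tag)))
  protocol <- stress_protocol(43)
  ids <- unique(traj$cell_id)
  hsf1 <- fluorescence_to_hsf1(
    traj$total_fluorescence[!duplicated(traj$cell_id)])
  names(hsf1) <- ids
  cells <- split(traj, traj$cell_id)[ids]

  cmp <- fit_success_comparison(cells, hsf1[ids], protocol, params,
                                hsp0_grid = grid)
  fits <- cmp$fits
  fit_tab <- data.frame(
    cell_id = ids,
    best_hsp0 = vapply(fits, `[[`, 0, "best_hsp0"),
    best_error = vapply(fits, `[[`, 0, "best_error"),
    satisfactory = vapply(fits, `[[`, TRUE, "satisfactory"),
    coating = tag)
  lik_tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(cell_id = f$cell_id, hsp0 = f$hsp0_grid,
               weight = f$likelihood, coating = tag)
  }))
  dist <- population_distribution(fits)
  dist_tab <- data.frame(hsp0 = dist$grid, density = dist$density,
                         coating = tag)
  list(fit = fit_tab, lik = lik_tab, dist = dist_tab,
       pct_free = cmp$percent_free, pct_control = cmp$percent_control,
       median = distribution_median(dist))
}

res <- lapply(c("col-", "col+"), infer_condition)
names(res) <- c("col-", "col+")
write.csv(do.call(rbind, lapply(res, `[[`, "fit")),
          file.path(out_dir, "fits.csv"), row.names = FALSE)
write.csv(do.call(rbind, lapply(res, `[[`, "lik")),
          file.path(out_dir, "likelihoods.csv"), row.names = FALSE)
write.csv(do.call(rbind, lapply(res, `[[`, "dist")),
          file.path(out_dir, "expression_distribution.csv"),
          row.names = FALSE)

for (tag in names(res)) {
  r <- res[[tag]]
  truth <- read.csv(file.path(pop_dir, sprintf("truth_43C_%s.csv", tag)))
  message(sprintf(
    "%s: satisfactory fits %.0f %% (free chaperone) vs %.0f %% (fixed control); inferred median %.3f uM, generating sample median %.3f uM",
    tag, r$pct_free, r$pct_control, r$median,
    median(truth$true_hsp0_uM)))
}
message(sprintf(
  "inferred col+/col- median ratio: %.2f (generating shift was 1.50)",
  res[["col+"]]$median / res[["col-"]]$median))
message(paste(
  "note: the direction of the collagen shift is recovered, but its size is",
  "amplified: non-responding cells (many more in the col+ arm) constrain",
  "their chaperone level only from below, so their likelihood plateaus at",
  "high levels pull the summed distribution right. Point estimation is",
  "reliable only for responding cells."))
message("wrote inference tables to ", out_dir)
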
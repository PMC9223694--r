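#!/usr/bin/env Rscript
# Population-level descriptors of response heterogeneity from the
# simulated imaging campaign (run 01_simulate_population.R first):
# responder fractions vs. temperature with a Hill eye-guide, responder
# mean dynamics, amplitude distributions at 1 h and 3 h, relaxation-index
# histograms, and the ratio-binned activation function at 43 degC.
# Tables land under results/statistics/.

suppressPackageStartupMessages(library(hsrdyn))

pop_dir <- "results/populations"
out_dir <- "results/statistics"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
temps <- c(41, 42, 43, 44)

## responder fraction vs. temperature + Hill summary
resp <- do.call(rbind, lapply(temps, function(T) {
  traj <- read_trajectories(file.path(pop_dir,
                                      sprintf("traj_%dC_col-.csv", T)))
  calls <- call_responders(traj)
  data.frame(temperature_C = T, coating = "col-",
             n_cells = nrow(calls),
             responder_fraction = responder_fraction(calls))
}))
write.csv(resp, file.path(out_dir, "responders.csv"), row.names = FALSE)
hill <- fit_hill_curve(resp$temperature_C, resp$responder_fraction)
message(sprintf(
  "responder fraction rises from %.2f (41 degC) to %.2f (44 degC); Hill eye-guide: T50 = %.1f degC, h = %.1f, plateau = %.2f",
  resp$responder_fraction[1], resp$responder_fraction[4],
  hill$t50, hill$hill, hill$plateau))

## per-temperature dynamics and heterogeneity descriptors
mean_dyn <- list(); amps <- list(); relax <- list()
for (T in temps) {
  traj <- read_trajectories(file.path(pop_dir,
                                      sprintf("traj_%dC_col-.csv", T)))
  calls <- call_responders(traj)
  md <- mean_foci_dynamics(traj, calls)
  md$temperature_C <- T
  mean_dyn[[as.character(T)]] <- md

  am <- amplitude_distribution(traj, calls, time_points = c(1, 3))
  am$temperature_C <- T
  amps[[as.character(T)]] <- am

  cells <- split(traj, traj$cell_id)
  pos <- as.character(calls$cell_id[calls$is_positive])
  etas <- suppressMessages(
    vapply(cells[pos], relaxation_index, numeric(1)))
  h <- relaxation_histogram(etas)
  relax[[as.character(T)]] <- data.frame(
    temperature_C = T, bin_lo = h$breaks[-length(h$breaks)],
    bin_hi = h$breaks[-1L], count = h$counts, n_cells = h$n_cells)
}
write.csv(do.call(rbind, mean_dyn), file.path(out_dir, "mean_dynamics.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, amps), file.path(out_dir, "amplitudes.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, relax), file.path(out_dir, "relaxation.csv"),
          row.names = FALSE)
rl43 <- relax[["43"]]
message(sprintf(
  "43 degC relaxation shapes (n=%d responders): adaptation %d, imperfect %d, plateau %d, increase %d",
  rl43$n_cells[1], rl43$count[1], rl43$count[2], rl43$count[3],
  rl43$count[4]))

## activation function at 43 degC: F at 1 h vs. chaperone/HSF1 ratio
traj43 <- read_trajectories(file.path(pop_dir, "traj_43C_col-.csv"))
truth43 <- read.csv(file.path(pop_dir, "truth_43C_col-.csv"))
cells43 <- split(traj43, traj43$cell_id)
f_1h <- vapply(cells43, function(d) d$F[which.min(abs(d$time_h - 1))],
               numeric(1))
ord <- match(names(f_1h), truth43$cell_id)
act <- activation_function_by_ratio(
  f_1h, truth43$true_hsp0_uM[ord], truth43$true_hsf1_uM[ord],
  min_class_size = 15)
write.csv(act, file.path(out_dir, "activation_function.csv"),
          row.names = FALSE)
message(sprintf(
  "activation function: median F falls from %.3f to %.3f across the %d displayed ratio classes",
  act$p50[1], act$p50[nrow(act)], nrow(act)))
message("wrote statistics tables to ", out_dir)
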
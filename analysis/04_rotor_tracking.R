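#!/usr/bin/env Rscript
# Rotor-core tracking. Tracks the surrogate stable rotor (fast) and, with
# --full, the Courtemanche AF and 300% IK1 rotors on the 100 x 100 sheet at a
# 5 ms snapshot stride to compare meander between unstable and stabilized
# reentry. Writes results/rotors/.

suppressPackageStartupMessages(library(atriawave))
full <- "--full" %in% commandArgs(trailingOnly = TRUE)
out_dir <- file.path("results", "rotors")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

track_one <- function(label, rec, t_max) {
  trs <- track_cores(rec, t_max = t_max)
  if (!length(trs)) {
    message(sprintf("  %s: no trajectories", label))
    return(NULL)
  }
  main <- trs[[which.max(vapply(trs, function(x) x$lifetime, numeric(1)))]]
  message(sprintf(
    "  %s: %d trajectories; longest: lifetime %.0f ms, path %.2f cm, meander %.2f cm",
    label, length(trs), main$lifetime, main$path_length, main$meander_extent))
  pts <- cbind(label = label, trajectory = "longest", main$points)
  write.csv(pts, file.path(out_dir, paste0(label, "_core_track.csv")),
            row.names = FALSE)
  data.frame(label = label, n_trajectories = length(trs),
             lifetime = main$lifetime, path_length = main$path_length,
             meander_extent = main$meander_extent, chirality = main$chirality)
}

message("surrogate stable rotor (interval 200 ms) ...")
surrogate_model(140)
gs <- tissue_geometry(60, 60, 0.05, 1e-3)
rec <- run_s1s2("surrogate", NULL, gs, s1s2_interval = 200, duration = 2500,
                frame_dt = 5)
summ <- list(track_one("surrogate_stable", rec, 2500))

if (full) {
  message("Courtemanche rotors (AF transient vs IK1x3 stable) ...")
  cal <- calibrate_cv("courtemanche", dx = 0.04)
  gc_ <- tissue_geometry(100, 100, 0.04, cal$D)
  for (nm in c("AF", "IK1x3")) {
    sc <- if (nm == "AF") af_scaling() else scaling(IK1 = 3)
    recc <- run_s1s2("courtemanche", sc, gc_, s1s2_interval = 200,
                     duration = 3000, frame_dt = 5)
    summ[[nm]] <- track_one(paste0("courtemanche_", nm), recc, 3000)
  }
}
write.csv(do.call(rbind, summ), file.path(out_dir, "rotor_summary.csv"),
          row.names = FALSE)
message("done: ", out_dir)
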
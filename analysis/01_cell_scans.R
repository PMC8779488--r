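#!/usr/bin/env Rscript
# Single-cell characterization: quasi-steady-state biomarkers of the two
# atrial ionic models, per-current 50%-block sensitivity, the Grandi ICaL
# repolarization-failure scan, and the AF-remodeling variant.
# Writes results/cell/.

suppressPackageStartupMessages(library(atriawave))
out_dir <- file.path("results", "cell")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

bio <- function(model, sc = NULL) measure_biomarkers(pace(model, sc))

message("baseline and 50% Ito biomarkers ...")
rows <- list()
for (m in c("courtemanche", "grandi")) {
  for (lbl in c("baseline", "Ito50")) {
    sc <- if (lbl == "Ito50") scaling(Ito = 0.5) else scaling()
    rows[[paste(m, lbl)]] <- cbind(model = m, condition = lbl, bio(m, sc))
  }
}
write.csv(do.call(rbind, rows), file.path(out_dir, "baseline_biomarkers.csv"),
          row.names = FALSE)

message("per-current 50%-block sensitivity ...")
sens <- list()
for (m in c("courtemanche", "grandi")) {
  base <- bio(m)$apd90
  for (cur in CURRENT_IDS) {
    sc <- do.call(scaling, stats::setNames(list(0.5), cur))
    b <- bio(m, sc)
    sens[[paste(m, cur)]] <- data.frame(
      model = m, current = cur, scale = 0.5, apd90 = b$apd90,
      delta_apd90 = b$apd90 - base,
      repolarization_failure = b$repolarization_failure)
  }
}
write.csv(do.call(rbind, sens), file.path(out_dir, "block50_sensitivity.csv"),
          row.names = FALSE)

message("Grandi ICaL scan 100-400% ...")
scan <- conductance_scan("grandi", "ICaL", seq(1, 4, by = 0.25))
write.csv(scan, file.path(out_dir, "grandi_ical_scan.csv"), row.names = FALSE)
ok <- !scan$repolarization_failure & is.finite(scan$apd90)
message(sprintf("  largest fully-repolarizing ICaL scale: %g%%",
                100 * max(scan$scale[ok])))

message("AF-remodeling variant ...")
af <- rbind(cbind(model = "courtemanche", condition = "AF",
                  bio("courtemanche", af_scaling())),
            cbind(model = "grandi", condition = "AF",
                  bio("grandi", af_scaling())))
write.csv(af, file.path(out_dir, "af_variant.csv"), row.names = FALSE)
message("done: ", out_dir)
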
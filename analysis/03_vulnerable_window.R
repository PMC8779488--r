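#!/usr/bin/env Rscript
# Vulnerable-window scans. The surrogate scan (60 x 60, dx = 0.05 cm) runs in
# a couple of minutes; the Courtemanche scans on the 100 x 100 sheet cost a
# few minutes per interval, so by default only the matched interval (200 ms)
# is run per substrate. Pass --full for a 10 ms interval grid.
# Writes results/vulnerability/.

suppressPackageStartupMessages(library(atriawave))
full <- "--full" %in% commandArgs(trailingOnly = TRUE)
out_dir <- file.path("results", "vulnerability")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("surrogate window (apd90 = 140 ms) ...")
surrogate_model(140)
gs <- tissue_geometry(60, 60, 0.05, 1e-3)
vw <- scan_vulnerable_window("surrogate", NULL, gs,
                             seq(170, 230, by = 10), horizon = 2000)
print(vw)
write.csv(vw$records, file.path(out_dir, "surrogate_window.csv"),
          row.names = FALSE)

message("Courtemanche substrates on the 100 x 100 sheet (dx = 0.04 cm) ...")
cal <- calibrate_cv("courtemanche", dx = 0.04)
gc_ <- tissue_geometry(100, 100, 0.04, cal$D)
substrates <- list(SR = scaling(), AF = af_scaling(), IK1x3 = scaling(IK1 = 3))
grid <- if (full) seq(180, 260, by = 10) else 200
rows <- list()
for (nm in names(substrates)) {
  vwc <- scan_vulnerable_window("courtemanche", substrates[[nm]], gc_,
                                grid, horizon = 3000, frame_dt = 25)
  rows[[nm]] <- cbind(substrate = nm, vwc$records)
  message(sprintf("  %s: window [%s, %s]", nm,
                  format(vwc$window_start), format(vwc$window_end)))
}
write.csv(do.call(rbind, rows),
          file.path(out_dir, "courtemanche_windows.csv"), row.names = FALSE)
message("done: ", out_dir)
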
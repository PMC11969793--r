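#!/usr/bin/env Rscript
# Step 2: run the 7-plan rotation scan on every cohort phantom.
#
# For each phantom: reference montage (AP + LR pairs, 20/13 discs)
# centered on the tumor centroid, plus six trial montages rotated
# +/-15 and +/-30 degrees axially and +/-10 degrees sagittally; both
# pairs driven at 31 mA RMS/cm^2, fields combined as the duty-weighted
# mean of the two orientations. Per-phantom plan metrics go to
# results/scans/.

suppressPackageStartupMessages(library(ttfplan))

spec_files <- sort(list.files("results/phantoms", pattern = "\\.yaml$",
                              full.names = TRUE))
stopifnot(length(spec_files) > 0)
out_dir <- "results/scans"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (f in spec_files) {
  id <- sub("\\.yaml$", "", basename(f))
  g <- generate_phantom(read_phantom_spec(f))
  t0 <- Sys.time()
  scan <- run_protocol_scan(g)
  dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  write.csv(scan$metrics, file.path(out_dir, paste0(id, "_metrics.csv")),
            row.names = FALSE)
  imp <- data.frame(phantom = id, index = names(scan$improvement_pct),
                    best_plan = unname(scan$best[names(scan$improvement_pct)]),
                    improvement_pct = unname(scan$improvement_pct))
  write.csv(imp, file.path(out_dir, paste0(id, "_improvements.csv")),
            row.names = FALSE)
  cat(sprintf("%s: E_p %.3f V/cm, best mean-field plan %s (%+.2f%%) [%ss]\n",
              id, scan$E_p, scan$best[["E_mean"]],
              scan$improvement_pct[["E_mean"]], dt))
}
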
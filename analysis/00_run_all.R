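#!/usr/bin/env Rscript
# Runs every analysis stage in order. Equivalent to the in-memory
# run_pipeline(), but each stage reads the previous stage's files, so any
# stage can be re-run (or swapped for real data in the same formats).

for (script in c("01_simulate.R", "02_feature_tracks.R", "03_snp_screen.R",
                 "04_methylation.R", "05_dml.R", "06_annotate_enrich.R")) {
  message("==> analysis/", script)
  source(file.path("analysis", script), local = new.env())
}
message("done; see results/run and results/tables")
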
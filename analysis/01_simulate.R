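#!/usr/bin/env Rscript
# Generate the synthetic cohort: per-site tissue images with planted
# composition and spatial structure, unstained negative controls, collagen
# sections, and mass-cytometry samples. Writes the raw tables plus the
# planted ground truth under results/data/.
source("analysis/00_config.R")

for (site in sites) {
  tt <- gen_tissue(cfg, site)
  write_cell_table(tt$cells, res_dir("data", paste0("cells_", site, ".csv")))
  write_cell_table(tt$truth$cells, res_dir("data", paste0("truth_", site, ".csv")))
  cy <- gen_cytof(cfg, site)
  write_cell_table(cy$events, res_dir("data", paste0("events_", site, ".csv")))
  write_cell_table(cy$truth, res_dir("data", paste0("events_truth_", site, ".csv")))
  message(sprintf("%s: %d cells over %d images, %d CyTOF events",
                  site, nrow(tt$cells), length(unique(tt$cells$image_id)),
                  nrow(cy$events)))
}
controls <- gen_control(cfg, 20000)
write_cell_table(controls, res_dir("data", "controls.csv"))
message(sprintf("controls: %d background-only cells", nrow(controls)))
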
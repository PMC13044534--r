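#!/usr/bin/env Rscript
# Gate the imaging cohort. The composition/spatial layer uses the manual
# (visual-cutoff style) thresholds at the planted mixture midpoints; the
# CAF and macrophage panels use the adaptive control-calibrated gates.
# Writes gate tables, the QC exclusion log, and the in-sample control
# false-positive check.
source("analysis/00_config.R")

cells <- do.call(rbind, lapply(sites, function(s)
  read_cell_table(file.path("results/data", paste0("cells_", s, ".csv")))))
controls <- read_cell_table("results/data/controls.csv")

qc <- qc_filter(cells, 500)
write.csv(qc$exclusions, res_dir("gates", "qc_exclusions.csv"), row.names = FALSE)
message(sprintf("QC: %d/%d images retained (>= 500 cells)",
                length(qc$retained), nrow(qc$exclusions)))

gates_manual <- manual_gates(qc$retained, mixture_midpoint_thresholds(cfg))
gates_caf <- build_gates(cells, controls, caf_panel())
gates_mac <- build_gates(cells, controls, macrophage_panel())
write.csv(gates_manual, res_dir("gates", "gates_manual.csv"), row.names = FALSE)
write.csv(gates_caf, res_dir("gates", "gates_caf.csv"), row.names = FALSE)
write.csv(gates_mac, res_dir("gates", "gates_macrophage.csv"), row.names = FALSE)

# calibration check: gates built on the controls, applied back to them
gates_ctrl <- build_gates(controls, controls, caf_panel())
pos_ctrl <- call_positivity(controls, gates_ctrl)
fpr <- sapply(caf_panel()$markers, function(m) 100 * mean(pos_ctrl[[paste0("pos_", m)]]))
write.csv(data.frame(marker = names(fpr), control_fpr_pct = fpr),
          res_dir("gates", "control_fpr.csv"), row.names = FALSE)
message("in-sample control FPR (%): ",
        paste(sprintf("%s %.2f", names(fpr), fpr), collapse = ", "))
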
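#!/usr/bin/env Rscript
# Spatial layer: directional nearest-neighbor distance matrices per image,
# cohort-pooled heatmap matrices with target clustering, frequency/distance
# networks with seeded spinglass communities, and tumor-structure
# infiltration summaries.
source("analysis/00_config.R")

cells <- do.call(rbind, lapply(sites, function(s)
  read_cell_table(file.path("results/data", paste0("cells_", s, ".csv")))))
qc <- qc_filter(cells, 500)
pos <- call_positivity(cells, manual_gates(qc$retained,
                                           mixture_midpoint_thresholds(cfg)))
lab <- assign_lineage(pos, phenotype_scheme())
classes <- setdiff(scheme_classes(phenotype_scheme()), "other")
comp <- cohort_composition(lab, scheme_classes(phenotype_scheme()))

infil <- list()
for (st in sites) {
  sub <- lab[lab$site == st, ]
  summaries <- lapply(unique(sub$image_id), function(img)
    min_distance_matrix(sub[sub$image_id == img, ], classes))
  pooled <- pool_distance_summaries(summaries, "median")
  write.csv(distance_long(pooled, st),
            res_dir("spatial", paste0("distances_", st, ".csv")), row.names = FALSE)
  ord <- cluster_targets(pooled)
  message(st, " target dendrogram order: ", paste(ord$order, collapse = " > "))

  pct <- aggregate(pct_of_total ~ class, data = comp[comp$site == st, ], FUN = mean)
  net <- build_network(setNames(pct$pct_of_total, pct$class), pooled, min_pct = 0.5)
  net <- detect_communities(net, seed = 123)
  message(sprintf("%s communities (seed 123, Q = %.3f): %s", st, net$modularity,
                  paste(sprintf("%s=%d", names(net$membership), net$membership),
                        collapse = " ")))
  write.csv(data.frame(site = st, class = names(net$membership),
                       community = as.integer(net$membership),
                       modularity = net$modularity),
            res_dir("spatial", paste0("communities_", st, ".csv")), row.names = FALSE)

  for (img in unique(sub$image_id)) {
    one <- sub[sub$image_id == img, ]
    assn <- map_structures(one)
    if (!assn$eligible) {
      message(img, " excluded from infiltration: ", assn$eligibility_reason)
      next
    }
    inf <- infiltration_summary(assn, one)
    inf$site <- st; inf$image_id <- img
    infil[[img]] <- inf
  }
}
infil <- do.call(rbind, infil)
write.csv(infil, res_dir("spatial", "infiltration.csv"), row.names = FALSE)
cd3 <- infil[infil$class == "CD3", ]
message(sprintf("CD3 in stroma+external margin: %.1f%% of CD3 cells (pooled mean)",
                mean(aggregate(pct ~ image_id, FUN = sum,
                  data = cd3[cd3$region %in% c("stroma", "external_margin"), ])$pct)))
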
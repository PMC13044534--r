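#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end driver used by the analysis scripts and the determinism
#' tests: generates the synthetic cohort (tissue images, negative
#' controls, collagen sections, CyTOF samples), gates and phenotypes the
#' imaging data (manual mixture-midpoint thresholds for the
#' composition/spatial layer, adaptive control-calibrated gates for the
#' CAF and macrophage panels), runs the spatial layer (distance matrices,
#' pooled networks with seeded spinglass communities, tumor-structure
#' mapping with infiltration summaries), the CyTOF chain (cleanup, live
#' singlet gating, retention, hierarchical subsets, checkpoint
#' combinations, B-cell subsets), site comparisons, and assembles a
#' cohort report. Every random draw derives from `config$seed`, so
#' identical configurations reproduce identical results.
#'
#' @param config A [generator_config()].
#' @param community_seed Seed for spinglass community detection
#'   (default 123).
#' @param out_dir Optional directory for report CSVs.
#' @return List: `report` (a [cohort_report()]), plus the intermediate
#'   objects (`composition`, `gates`, `spatial`, `cytof`, `stats`,
#'   `collagen`, `truth`).
#' @export
run_pipeline <- function(config = generator_config(), community_seed = 123L,
                         out_dir = NULL) {
  sites <- names(config$site_profiles)

  ## --- generation -------------------------------------------------------
  tissues <- lapply(sites, function(st) gen_tissue(config, st))
  names(tissues) <- sites
  cells <- do.call(rbind, lapply(tissues, `[[`, "cells"))
  controls <- gen_control(config, 20000)
  cytof_raw <- lapply(sites, function(st) gen_cytof(config, st))
  names(cytof_raw) <- sites

  ## --- imaging QC + gating ---------------------------------------------
  qc <- qc_filter(cells, 500L)
  cells <- cells[cells$image_id %in% qc$retained, , drop = FALSE]

  thr <- mixture_midpoint_thresholds(config)
  gates_manual <- manual_gates(unique(cells$image_id), thr)
  posv <- call_positivity(cells, gates_manual)
  labeled <- assign_lineage(posv, phenotype_scheme())
  labeled_t <- assign_lineage(posv, tcell_scheme())

  gates_caf <- build_gates(cells, controls, caf_panel())
  gates_mac <- build_gates(cells, controls, macrophage_panel())

  ## --- composition -------------------------------------------------------
  comp <- cohort_composition(labeled, scheme_classes(phenotype_scheme()))
  comp_t <- cohort_composition(labeled_t, scheme_classes(tcell_scheme()))
  tf_tabs <- do.call(rbind, lapply(unique(labeled_t$sample_id), function(sid) {
    out <- tf_profile(labeled_t[labeled_t$sample_id == sid, ])
    out$sample_id <- sid
    out
  }))

  collagen <- do.call(rbind, lapply(sites, function(st) {
    do.call(rbind, lapply(seq_len(config$n_samples_per_site), function(s) {
      img <- gen_collagen_image(config, st, replicate = s)
      data.frame(site = st, sample_id = sprintf("%s_%02d", st, s),
                 truth_fraction = img$truth_fraction,
                 measured_pct = collagen_area_fraction(img$image),
                 stringsAsFactors = FALSE)
    }))
  }))

  ## --- spatial ------------------------------------------------------------
  classes <- setdiff(scheme_classes(phenotype_scheme()), "other")
  spatial_by_site <- list()
  infiltration <- list()
  for (st in sites) {
    sub <- labeled[labeled$site == st, , drop = FALSE]
    summaries <- lapply(unique(sub$image_id), function(img) {
      min_distance_matrix(sub[sub$image_id == img, ], classes)
    })
    pooled <- pool_distance_summaries(summaries, "median")
    pct <- stats::aggregate(pct_of_total ~ class, FUN = mean,
                            data = comp[comp$site == st, ])
    node_pct <- stats::setNames(pct$pct_of_total, pct$class)
    net <- build_network(node_pct, pooled, min_pct = 0.5)
    net <- detect_communities(net, seed = community_seed)
    ord <- cluster_targets(pooled)
    spatial_by_site[[st]] <- list(pooled_median = pooled, network = net,
                                  target_order = ord$order)
    for (img in unique(sub$image_id)) {
      one <- sub[sub$image_id == img, , drop = FALSE]
      assn <- tryCatch(map_structures(one), error = function(e) NULL)
      if (is.null(assn)) next
      inf <- tryCatch(infiltration_summary(assn, one), error = function(e) NULL)
      if (is.null(inf)) next
      inf$site <- st
      inf$image_id <- img
      infiltration[[img]] <- inf
    }
  }
  infiltration <- if (length(infiltration)) do.call(rbind, infiltration) else NULL

  community_tab <- do.call(rbind, lapply(sites, function(st) {
    net <- spatial_by_site[[st]]$network
    data.frame(site = st, class = names(net$membership),
               pct = net$nodes$pct[match(names(net$membership), net$nodes$class)],
               community = as.integer(net$membership),
               modularity = net$modularity, seed = net$seed,
               stringsAsFactors = FALSE)
  }))
  distance_tab <- do.call(rbind, lapply(sites, function(st) {
    distance_long(spatial_by_site[[st]]$pooled_median, st)
  }))

  ## --- CyTOF --------------------------------------------------------------
  gates_cy <- default_cytof_gates(config)
  cy_by_site <- list()
  combo_rows <- list()
  bcell_rows <- list()
  for (st in sites) {
    ev <- clean_events(cytof_raw[[st]]$events)
    live <- live_singlet_gate(ev, gates_cy$cisplatin_cut, gates_cy$dna_box)
    ret <- retain_samples(live_counts(live), 500L)
    live <- live[live$sample_id %in% ret$retained, , drop = FALSE]
    sc <- hierarchical_gate(live, gates_cy$marker_thresholds)
    elig_t <- min_parent_filter(sc, "CD3", 25L)
    elig_b <- min_parent_filter(sc, "CD19", 25L)
    for (sid in elig_t) {
      for (sub in c("CD4", "CD8")) {
        evs <- sc$events[sc$events$sample_id == sid & sc$events$subset == sub, ]
        if (!nrow(evs)) next
        cc <- checkpoint_combinations(evs, gates_cy$marker_thresholds)
        df <- cc$freq
        df$sample_id <- sid; df$site <- st; df$subset <- sub
        combo_rows[[paste(sid, sub)]] <- df
      }
    }
    for (sid in elig_b) {
      evs <- sc$events[sc$events$sample_id == sid & sc$events$subset == "CD19", ]
      bs <- b_cell_subsets(evs, gates_cy$marker_thresholds)
      bs$sample_id <- sid; bs$site <- st
      bcell_rows[[sid]] <- bs
    }
    counts <- sc$counts
    counts$site <- st
    cy_by_site[[st]] <- list(counts = counts, retention = ret$exclusions,
                             t_eligible = elig_t, b_eligible = elig_b)
  }
  cy_counts <- do.call(rbind, lapply(cy_by_site, `[[`, "counts"))
  rownames(cy_counts) <- NULL
  cy_combos <- if (length(combo_rows)) do.call(rbind, combo_rows) else NULL
  cy_bcells <- if (length(bcell_rows)) do.call(rbind, bcell_rows) else NULL

  ## --- site comparisons ---------------------------------------------------
  stat_rows <- list()
  if (length(sites) >= 2) {
    s1 <- sites[1]; s2 <- sites[2]
    for (cls in unique(comp$class)) {
      a <- comp$pct_of_total[comp$site == s1 & comp$class == cls]
      b <- comp$pct_of_total[comp$site == s2 & comp$class == cls]
      if (length(a) && length(b)) {
        mw <- mann_whitney(a, b)
        stat_rows[[paste0("comp_", cls)]] <- data.frame(
          analysis = "composition", contrast = paste(s1, "vs", s2),
          class = cls, method = mw$method, statistic = mw$statistic,
          p_value = mw$p_value, stringsAsFactors = FALSE)
      }
    }
    a <- collagen$measured_pct[collagen$site == s1]
    b <- collagen$measured_pct[collagen$site == s2]
    mw <- mann_whitney(a, b)
    stat_rows$collagen <- data.frame(
      analysis = "collagen_area", contrast = paste(s1, "vs", s2),
      class = "PicrosiriusRed", method = mw$method, statistic = mw$statistic,
      p_value = mw$p_value, stringsAsFactors = FALSE)
  }
  stats_tab <- if (length(stat_rows)) {
    out <- do.call(rbind, stat_rows)
    out$p_sidak <- adjust_p(out$p_value, "sidak")
    out$p_bonferroni <- adjust_p(out$p_value, "bonferroni")
    rownames(out) <- NULL
    out
  } else NULL

  report <- cohort_report(
    composition = comp,
    spatial = list(distances = distance_tab, communities = community_tab,
                   infiltration = infiltration),
    cytof = list(subsets = cy_counts, combos = cy_combos, bcells = cy_bcells),
    stats = stats_tab,
    exclusions = list(imaging_qc = qc$exclusions),
    config = config, seed = config$seed, out_dir = out_dir
  )

  list(report = report, composition = comp, composition_t = comp_t,
       tf_profiles = tf_tabs, collagen = collagen,
       gates = list(manual = gates_manual, caf = gates_caf, mac = gates_mac),
       spatial = spatial_by_site, infiltration = infiltration,
       cytof = list(by_site = cy_by_site, counts = cy_counts,
                    combos = cy_combos, bcells = cy_bcells),
       stats = stats_tab,
       truth = lapply(tissues, `[[`, "truth"))
}
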
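test_that("event cleanup drops beads and percentile-window outliers", {
  cfg <- small_config(seed = 51, n_events = 20000)
  cy <- gen_cytof(cfg, "primary")
  ev <- clean_events(cy$events)
  expect_true(all(ev$bead == 0))
  # planted merged ion clouds (extreme width) are almost all removed
  merged_ids <- cy$truth$event_id[cy$truth$qc_class == "merged"]
  removed <- setdiff(merged_ids, ev$event_id)
  expect_gte(length(removed) / length(merged_ids), 0.8)
  # all-bead input empties the table
  allbead <- cy$events
  allbead$bead <- 1L
  expect_equal(nrow(clean_events(allbead)), 0)
  # a full-range window is the identity apart from bead removal
  ev2 <- clean_events(ev, window = c(0, 1))
  expect_equal(ev2$event_id, ev$event_id)
  expect_error(clean_events(cy$events[, setdiff(names(cy$events), "width")]),
               "missing channels")
})

test_that("live singlet gate removes dead cells, debris and doublets", {
  cfg <- small_config(seed = 53, n_events = 20000)
  cy <- gen_cytof(cfg, "primary")
  g <- default_cytof_gates(cfg)
  live <- live_singlet_gate(cy$events, g$cisplatin_cut, g$dna_box)
  kept <- cy$truth[match(live$event_id, cy$truth$event_id), ]
  dead_ids <- cy$truth$event_id[cy$truth$qc_class == "dead"]
  dbl_ids <- cy$truth$event_id[cy$truth$qc_class == "doublet"]
  expect_lte(sum(dead_ids %in% live$event_id) / length(dead_ids), 0.01)
  expect_lte(sum(dbl_ids %in% live$event_id) / length(dbl_ids), 0.01)
  expect_error(live_singlet_gate(cy$events, 30, list(DNA1 = c(5, 1), DNA2 = c(1, 5))),
               "non-empty")
})

test_that("planted live-singlet fraction is recovered at cohort scale", {
  cm <- default_cytof_model()
  cm$qc_fractions <- c(bead = 0, debris = 0.08, doublet = 0.07,
                       dead = 0.15, merged = 0)
  cm$n_events_per_sample <- 50000L
  cfg <- generator_config(n_samples_per_site = 1, n_cells_per_image = 100,
                          cytof_model = cm, seed = 57)
  cy <- gen_cytof(cfg, "primary")
  g <- default_cytof_gates(cfg)
  live <- live_singlet_gate(cy$events, g$cisplatin_cut, g$dna_box)
  expect_lt(abs(nrow(live) / nrow(cy$events) - 0.70), 0.01)
})

test_that("sample retention applies the live-cell cutoff at the boundary", {
  lc <- data.frame(sample_id = c("s1", "s2"), n_live = c(499, 500))
  ret <- retain_samples(lc, 500)
  expect_equal(ret$retained, "s2")
  expect_equal(retain_samples(data.frame(sample_id = "s1", n_live = 10), 500)$retained,
               character(0))
  # monotone: raising the cutoff never adds samples
  lc2 <- data.frame(sample_id = letters[1:5], n_live = c(100, 400, 500, 800, 2000))
  r1 <- retain_samples(lc2, 400)$retained
  r2 <- retain_samples(lc2, 600)$retained
  expect_true(all(r2 %in% r1))
})

test_that("hierarchical gating partitions live singlets and recovers planted subsets", {
  # single constructed events walk the tree
  one <- function(CD45, CD3, CD4, CD8, CD19) {
    data.frame(sample_id = "s", CD45 = CD45, CD3 = CD3, CD4 = CD4,
               CD8 = CD8, CD19 = CD19, Ki67 = 0)
  }
  thr <- c(CD45 = 10, CD3 = 10, CD4 = 10, CD8 = 10, CD19 = 10, Ki67 = 10)
  expect_equal(hierarchical_gate(one(100, 100, 100, 0, 0), thr)$events$subset, "CD4")
  expect_equal(hierarchical_gate(one(0, 100, 100, 100, 100), thr)$events$subset,
               "CD45neg")  # the root gate dominates any lineage signal
  expect_equal(hierarchical_gate(one(100, 0, 0, 0, 100), thr)$events$subset, "CD19")
  expect_equal(hierarchical_gate(one(100, 100, 100, 100, 0), thr)$events$subset,
               "CD4CD8")
  expect_error(hierarchical_gate(one(1, 1, 1, 1, 1)[, -2], thr), "missing markers")

  cm <- default_cytof_model()
  cm$n_events_per_sample <- 50000L
  cfg <- generator_config(n_samples_per_site = 1, n_cells_per_image = 100,
                          cytof_model = cm, seed = 59)
  cy <- gen_cytof(cfg, "primary")
  g <- default_cytof_gates(cfg)
  live <- live_singlet_gate(clean_events(cy$events), g$cisplatin_cut, g$dna_box)
  sc <- hierarchical_gate(live, g$marker_thresholds)
  # exact partition
  expect_equal(sum(sc$counts$n), nrow(live))
  expect_equal(sum(sc$counts$pct), 100)
  planted <- cfg$cytof_model$subset_fractions$primary
  for (sub in names(planted)) {
    got <- sc$counts$pct[sc$counts$subset == sub] / 100
    expect_lt(abs(got - planted[[sub]]), 0.01, label = sub)
  }
})

test_that("minimum-parent filters are boundary-exact and independent across parents", {
  counts <- data.frame(
    sample_id = rep(c("s1", "s2"), each = 6),
    subset = rep(c("CD45neg", "CD45other", "CD4", "CD8", "CD4CD8", "CD19"), 2),
    n = c(100, 100, 10, 10, 4, 30,   100, 100, 20, 4, 1, 10))
  expect_equal(min_parent_filter(counts, "CD3", 25), "s2")  # 24 vs 25 T cells
  expect_equal(min_parent_filter(counts, "CD19", 25), "s1")
  expect_error(min_parent_filter(counts, "NKT"), "unknown parent")
  expect_length(min_parent_filter(counts[0, ], "CD19"), 0)
})

test_that("checkpoint combinations match the enumeration oracle and conserve mass", {
  thr <- setNames(rep(10, 5), checkpoint_markers())
  # all-negative cell
  ev0 <- as.data.frame(setNames(as.list(rep(0, 5)), checkpoint_markers()))
  cc0 <- checkpoint_combinations(ev0, thr)
  expect_equal(cc0$freq$freq[cc0$freq$combo == "CTLA4-LAG3-PD1-TIGIT-TIM3-"], 1)
  expect_equal(unname(cc0$histogram["0"]), 1)

  set.seed(61)
  n <- 32000
  pos <- matrix(runif(5 * n) < 0.5, n, 5, dimnames = list(NULL, checkpoint_markers()))
  ev <- as.data.frame(ifelse(pos, 100, 0))
  cc <- checkpoint_combinations(ev, thr)
  oracle <- oracle_combo_freq(pos, checkpoint_markers())
  for (k in names(oracle)) {
    expect_equal(cc$freq$freq[cc$freq$combo == k], unname(oracle[[k]]))
  }
  # independent 0.5 marginals: every combo near 1/32
  expect_true(all(abs(cc$freq$freq - 1 / 32) < 0.007))
  expect_equal(sum(cc$freq$freq), 1)
  expect_equal(sum(cc$histogram), 1)
  # count-k histogram equals the mass of size-k combos
  k_sizes <- rowSums(cc$freq[, checkpoint_markers()])
  for (k in 0:5) {
    expect_equal(unname(cc$histogram[as.character(k)]),
                 sum(cc$freq$freq[k_sizes == k]))
  }
  # sunburst root level aggregates to 1 and respects the fixed marker order
  lvl1 <- cc$sunburst[cc$sunburst$depth == 1, ]
  expect_equal(sum(lvl1$freq), 1)
  expect_true(all(grepl("^CTLA4", lvl1$path)))
})

test_that("checkpoint co-expression in generated T cells exceeds independence", {
  cfg <- small_config(seed = 63, n_events = 30000)
  cy <- gen_cytof(cfg, "primary")
  g <- default_cytof_gates(cfg)
  live <- live_singlet_gate(clean_events(cy$events), g$cisplatin_cut, g$dna_box)
  sc <- hierarchical_gate(live, g$marker_thresholds)
  cd4 <- sc$events[sc$events$subset == "CD4", ]
  cc <- checkpoint_combinations(cd4, g$marker_thresholds)
  p <- function(m) mean(cd4[[m]] > g$marker_thresholds[[m]])
  triple <- sum(cc$freq$freq[cc$freq$CTLA4 & cc$freq$LAG3 & cc$freq$PD1])
  expect_gt(triple, p("CTLA4") * p("LAG3") * p("PD1"))
})

test_that("B-cell subset rules evaluate marker logic and recover planted mixtures", {
  thr <- c(IgD = 10, CD27 = 10, PD1 = 10, PDL1 = 10, CD11b = 10, Ki67 = 10)
  ev <- data.frame(IgD = c(0, 0, 100), CD27 = c(100, 0, 0),
                   PD1 = c(0, 100, 0), PDL1 = c(0, 100, 0),
                   CD11b = 0, Ki67 = 0)
  bs <- b_cell_subsets(ev, thr)
  expect_equal(bs$n[bs$subset == "memory"], 1)
  # PD-1 and/or PD-L1: a double positive is counted once
  expect_equal(bs$n[bs$subset == "regulatory_potential"], 1)
  expect_error(b_cell_subsets(ev, thr, rules = c(x = "CD38")), "missing channels")

  cm <- default_cytof_model()
  cm$n_events_per_sample <- 50000L
  cm$subset_fractions$primary <- c(CD45neg = 0.2, CD45other = 0.2, CD4 = 0.2,
                                   CD8 = 0.2, CD19 = 0.2)
  cfg <- generator_config(n_samples_per_site = 1, n_cells_per_image = 100,
                          cytof_model = cm, seed = 67)
  cy <- gen_cytof(cfg, "primary")
  g <- default_cytof_gates(cfg)
  live <- live_singlet_gate(clean_events(cy$events), g$cisplatin_cut, g$dna_box)
  sc <- hierarchical_gate(live, g$marker_thresholds)
  bcells <- sc$events[sc$events$subset == "CD19", ]
  expect_gt(nrow(bcells), 5000)
  bs <- b_cell_subsets(bcells, g$marker_thresholds)
  planted_memory <- 100 * cfg$cytof_model$b_cell[["CD27"]]
  expect_lt(abs(bs$pct[bs$subset == "memory"] - planted_memory), 2)
})
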
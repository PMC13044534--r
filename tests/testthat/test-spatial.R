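cells_df <- function(xy, labels) {
  data.frame(cell_id = sprintf("c%03d", seq_len(nrow(xy))),
             x_um = xy[, 1], y_um = xy[, 2], label = labels,
             stringsAsFactors = FALSE)
}

test_that("distance matrices match hand geometry and are directional", {
  d <- min_distance_matrix(cells_df(rbind(c(0, 0), c(3, 4)), c("A", "B")),
                           c("A", "B"))
  expect_equal(d$min["A", "B"], 5)
  expect_equal(d$median["A", "B"], 5)
  d2 <- min_distance_matrix(
    cells_df(rbind(c(0, 0), c(10, 0), c(0, 1)), c("A", "A", "B")),
    c("A", "B"))
  expect_equal(d2$min["A", "B"], 1)
  expect_equal(d2$median["A", "B"], (1 + sqrt(101)) / 2)
  expect_equal(d2$median["B", "A"], 1)  # directional
  # absent class stays missing, never zero
  d3 <- min_distance_matrix(cells_df(rbind(c(0, 0)), "A"), c("A", "B"))
  expect_true(is.na(d3$min["A", "B"]))
  expect_true(is.na(d3$min["A", "A"]))  # single cell, self excluded
})

test_that("distance summaries equal the brute-force oracle on random maps", {
  set.seed(55)
  for (rep in 1:3) {
    n <- sample(100:500, 1)
    xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    labels <- sample(c("A", "B", "C"), n, replace = TRUE)
    ds <- min_distance_matrix(cells_df(xy, labels), c("A", "B", "C"))
    for (r in c("A", "B", "C")) for (t in c("A", "B", "C")) {
      ref <- xy[labels == r, , drop = FALSE]
      tgt <- xy[labels == t, , drop = FALSE]
      if (r == t) {
        o <- oracle_nn_summary(ref, ref, self = TRUE)
      } else {
        o <- oracle_nn_summary(ref, tgt)
      }
      expect_equal(ds$median[r, t], unname(o["median"]))
      expect_equal(ds$min[r, t], unname(o["min"]))
    }
  }
})

test_that("target clustering merges close columns first and ignores input order", {
  M <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cl <- cluster_targets(M)
  first_merge <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first_merge], c("A", "B"))
  # identical columns merge at height zero
  M2 <- cbind(A = c(0, 5, 7), B = c(0, 5, 7), C = c(9, 9, 9))
  rownames(M2) <- c("A", "B", "C")
  cl2 <- cluster_targets(M2)
  expect_equal(cl2$hclust$height[1], 0)
  # permutation of columns leaves merge heights unchanged
  perm <- c("C", "A", "B")
  cl3 <- cluster_targets(M[perm, perm])
  expect_equal(sort(cl3$hclust$height), sort(cl$hclust$height))
  M_na <- M; M_na[, "C"] <- NA; M_na["C", ] <- NA
  expect_warning(cluster_targets(M_na), "all-missing")
})

test_that("network edges decay with distance on the stated scale", {
  D <- matrix(c(5, 10, 10, 5), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  net <- build_network(c(A = 60, B = 40), D, min_pct = 0, lambda = 10)
  w <- igraph::E(net$graph)$weight
  expect_equal(w, exp(-1))  # d = lambda
  net0 <- build_network(c(A = 60, B = 40),
                        matrix(0, 2, 2, dimnames = dimnames(D)),
                        min_pct = 0, lambda = 10)
  expect_equal(igraph::E(net0$graph)$weight, 1)  # d = 0
  expect_equal(sum(net$nodes$pct), 100)
  expect_error(build_network(c(A = 0.1, B = 0.2), D, min_pct = 1),
               "fewer than 2 classes")
})

test_that("seeded spinglass recovers planted blocks and matches exhaustive modularity", {
  W <- matrix(0.05, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("n", 1:8)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cg <- structure(list(graph = g,
                       nodes = data.frame(class = rownames(W), pct = 12.5),
                       lambda = 1),
                  class = "community_graph")
  res <- detect_communities(cg, seed = 123)
  oracle <- oracle_best_partition(g)
  expect_equal(res$modularity, oracle$q)
  expect_true(same_partition(unname(res$membership), oracle$membership))
  expect_true(same_partition(unname(res$membership), rep(1:2, each = 4)))
  # determinism under the seed
  res2 <- detect_communities(cg, seed = 123)
  expect_identical(res$membership, res2$membership)
  # on a uniform complete graph no split beats the trivial partition
  Wu <- matrix(1, 6, 6); diag(Wu) <- 0
  rownames(Wu) <- colnames(Wu) <- paste0("u", 1:6)
  gu <- igraph::graph_from_adjacency_matrix(Wu, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  expect_equal(oracle_best_partition(gu)$q,
               igraph::modularity(gu, rep(1, 6), weights = igraph::E(gu)$weight))
})

test_that("structure mapping reproduces planted disk geometry", {
  set.seed(77)
  # dense tumor disk of radius 500 um centered in a 2 mm field
  n_t <- 3000
  r <- 500 * sqrt(runif(n_t)); a <- runif(n_t, 0, 2 * pi)
  tumor <- cbind(1000 + r * cos(a), 1000 + r * sin(a))
  n_s <- 3000
  stroma <- cbind(runif(n_s, 0, 2000), runif(n_s, 0, 2000))
  probes <- rbind(c(1450, 1000), c(1550, 1000), c(1100, 1000), c(1900, 1000))
  xy <- rbind(tumor, stroma, probes)
  labels <- c(rep("CK19", n_t), rep("other", n_s), rep("other", 4))
  df <- cells_df(xy, labels)
  # constructed map, one tissue piece by design: skip the component filter
  # so stray isolated occupancy bins cannot drop cells
  assn <- map_structures(df, margin_um = 100, grid_um = 50,
                         largest_component = FALSE)
  probe_regions <- assn$cells$region[match(df$cell_id[(n_t + n_s) + 1:4],
                                           assn$cells$cell_id)]
  expect_equal(probe_regions, c("internal_margin", "external_margin",
                                "intratumoral", "stroma"))
  # the four regions partition the cells
  expect_equal(nrow(assn$cells), nrow(df))
  expect_true(all(assn$cells$region %in%
    c("intratumoral", "internal_margin", "external_margin", "stroma")))
  expect_true(assn$eligible)
  # margin width 0 sends the margin populations to zero
  assn0 <- map_structures(df, margin_um = 0, grid_um = 50,
                          largest_component = FALSE)
  expect_equal(sum(assn0$cells$region %in% c("internal_margin", "external_margin")), 0)
  expect_error(map_structures(cells_df(stroma, rep("other", n_s))), "tumor class")
})

test_that("an all-tumor image has no stroma and fails the boundary-clarity rule", {
  set.seed(78)
  xy <- cbind(runif(4000, 0, 1000), runif(4000, 0, 1000))
  df <- cells_df(xy, rep("CK19", 4000))
  assn <- map_structures(df, margin_um = 100, grid_um = 50)
  expect_equal(sum(assn$cells$region %in% c("stroma", "external_margin")), 0)
  expect_false(assn$eligible)  # tumor mask covers all tissue bins
  expect_error(infiltration_summary(assn, df), "ineligible")
})

test_that("only the largest connected tissue piece is analyzed", {
  blob1 <- cbind(runif(800, 0, 500), runif(800, 0, 500))
  blob2 <- cbind(runif(100, 1500, 1700), runif(100, 1500, 1700))
  df <- cells_df(rbind(blob1, blob2), rep("CK19", 900))
  kept <- filter_largest_component(df, 50)
  expect_equal(nrow(kept), 800)
  expect_equal(attr(kept, "n_removed"), 100)
  expect_true(all(kept$x_um <= 500))
})

test_that("infiltration summaries recover the planted stromal immune gradient", {
  cfg <- small_config(seed = 41, n_cells = 8000)
  tt <- gen_tissue(cfg, "primary")
  pos <- call_positivity(tt$cells, manual_gates(unique(tt$cells$image_id),
                                                mixture_midpoint_thresholds(cfg)))
  lab <- assign_lineage(pos)
  assn <- map_structures(lab)
  expect_true(assn$eligible)
  inf <- infiltration_summary(assn, lab)
  cd3 <- inf[inf$class == "CD3", ]
  outer_share <- sum(cd3$pct[cd3$region %in% c("stroma", "external_margin")])
  inner_share <- sum(cd3$pct[cd3$region %in% c("intratumoral", "internal_margin")])
  expect_gt(outer_share, inner_share)
  # per-class percentages sum to 100 across the four regions
  for (cls in unique(inf$class)) {
    expect_equal(sum(inf$pct[inf$class == cls]), 100)
  }
})
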
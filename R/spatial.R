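#' Spatial analysis of labeled cell maps
#'
#' Directional nearest-neighbor distance summaries between phenotype
#' classes, hierarchical clustering of target profiles, frequency/distance
#' networks with seeded spinglass community detection, and four-region
#' tumor-structure mapping.
#'
#' @name spatial
NULL

# nearest-neighbor distances from each row of A to the rows of B (um),
# chunked so no n x n matrix is ever fully materialized. When self = TRUE,
# A and B are the same set and each point's own index is excluded.
.nn_dist <- function(A, B, self = FALSE, chunk = 512L) {
  nA <- nrow(A); nB <- nrow(B)
  if (nB == 0 || (self && nB == 1)) return(rep(NA_real_, nA))
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  out <- numeric(nA)
  for (start in seq(1L, nA, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nA)
    d2 <- outer(a2[idx], b2, "+") - 2 * (A[idx, , drop = FALSE] %*% t(B))
    if (self) d2[cbind(seq_along(idx), idx)] <- Inf
    mins <- d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))]
    out[idx] <- sqrt(pmax(mins, 0))
  }
  out
}

#' Directional nearest-neighbor distance matrices
#'
#' For every (reference, target) class pair, computes each reference cell's
#' Euclidean distance to its nearest target cell (self excluded on the
#' diagonal) and summarizes those per-reference distances by their median
#' and minimum. The matrices are directional: reference-to-target need not
#' equal target-to-reference.
#'
#' @param cells Labeled cell table for one image (`x_um`, `y_um`, `label`).
#' @param classes Classes to include (default: all observed labels).
#' @param label_col Column holding the class label.
#' @return List of class `distance_summary` with `median` and `min`
#'   matrices (reference rows, target columns; `NA` marks pairs with an
#'   absent class) and `n_per_class`.
#' @export
min_distance_matrix <- function(cells, classes = NULL, label_col = "label") {
  if (is.null(classes)) classes <- sort(unique(cells[[label_col]]))
  coords <- split(
    seq_len(nrow(cells)),
    factor(cells[[label_col]], levels = classes)
  )
  xy <- as.matrix(cells[, c("x_um", "y_um")])
  k <- length(classes)
  med <- mn <- matrix(NA_real_, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) {
    ref_idx <- coords[[i]]
    if (!length(ref_idx)) next
    A <- xy[ref_idx, , drop = FALSE]
    for (j in seq_len(k)) {
      tgt_idx <- coords[[j]]
      if (!length(tgt_idx)) next
      d <- .nn_dist(A, xy[tgt_idx, , drop = FALSE], self = i == j)
      if (all(is.na(d))) next
      med[i, j] <- stats::median(d, na.rm = TRUE)
      mn[i, j] <- min(d, na.rm = TRUE)
    }
  }
  structure(list(median = med, min = mn,
                 n_per_class = lengths(coords)),
            class = "distance_summary")
}

#' Pool per-image distance summaries across a cohort
#'
#' Elementwise median across images of the per-image summary matrices (the
#' pooling statistic is a package choice, stated once and used for both
#' heatmaps and network edges).
#'
#' @param summaries List of `distance_summary` objects on identical classes.
#' @param which Which per-image statistic to pool (`"median"` or `"min"`).
#' @return Pooled matrix.
#' @export
pool_distance_summaries <- function(summaries, which = c("median", "min")) {
  which <- match.arg(which)
  mats <- lapply(summaries, `[[`, which)
  arr <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  out <- apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  dimnames(out) <- dimnames(mats[[1]])
  out[is.nan(out)] <- NA_real_
  out
}

#' Hierarchical clustering of target classes
#'
#' Agglomerative clustering (complete linkage, Euclidean) of the target
#' columns of a median-distance matrix, as used to order distance-heatmap
#' columns. Columns that are entirely missing are excluded with a warning;
#' remaining missing entries are not allowed.
#'
#' @param summary A `distance_summary` or a median-distance matrix.
#' @return List with `order` (target classes in dendrogram order) and
#'   `hclust` (the tree).
#' @export
cluster_targets <- function(summary) {
  M <- if (inherits(summary, "distance_summary")) summary$median else summary
  all_na <- apply(M, 2, function(col) all(is.na(col)))
  if (any(all_na)) {
    warning("excluding all-missing target columns: ",
            paste(colnames(M)[all_na], collapse = ", "))
    M <- M[!all_na, !all_na, drop = FALSE]
  }
  if (ncol(M) < 2) stop("need at least 2 target classes with complete columns")
  hc <- stats::hclust(stats::dist(t(M)), method = "complete")
  list(order = colnames(M)[hc$order], hclust = hc)
}

#' Build a frequency/distance network over phenotype classes
#'
#' Nodes are phenotype classes weighted by their percentage of cells; edges
#' connect every retained pair with an attraction weight `exp(-d / lambda)`
#' where `d` is the symmetrized median-of-minimum-distance between the two
#' classes. The inversion from distance to attraction is needed because the
#' spinglass community objective expects affinity weights; `lambda`
#' defaults to the median of all pairwise symmetrized distances so that a
#' typical pair has weight `exp(-1)`. Classes below `min_pct` percent of
#' cells are excluded (tiny populations destabilize the spin model).
#'
#' @param node_pct Named percentages per class (e.g. cohort `pct_of_total`),
#'   or a [composition_summary()].
#' @param dist_matrix Median nearest-neighbor distance matrix (directional;
#'   it is symmetrized internally).
#' @param min_pct Minimum node percentage (default 1).
#' @param lambda Distance scale; default the median of pairwise distances.
#' @return List of class `community_graph` with `graph` (igraph), `nodes`
#'   (class, pct), and `lambda`.
#' @export
build_network <- function(node_pct, dist_matrix, min_pct = 1, lambda = NULL) {
  if (inherits(node_pct, "composition_summary")) {
    v <- node_pct$classes$pct_of_total
    names(v) <- node_pct$classes$class
    node_pct <- v
  }
  keep <- names(node_pct)[node_pct >= min_pct]
  keep <- intersect(keep, rownames(dist_matrix))
  D <- dist_matrix[keep, keep, drop = FALSE]
  D <- (D + t(D)) / 2
  complete <- rowSums(is.na(D)) <= 1  # allow missing diagonal only
  keep <- keep[complete[keep]]
  if (length(keep) < 2) stop("fewer than 2 classes retained for the network")
  D <- D[keep, keep, drop = FALSE]
  offdiag <- D[upper.tri(D)]
  if (is.null(lambda)) lambda <- stats::median(offdiag, na.rm = TRUE)
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  W <- exp(-D / lambda)
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$pct <- unname(node_pct[keep])
  structure(list(graph = g,
                 nodes = data.frame(class = keep, pct = unname(node_pct[keep]),
                                    stringsAsFactors = FALSE),
                 lambda = lambda),
            class = "community_graph")
}

#' Seeded spinglass community detection
#'
#' Partitions the class network by simulated-annealing spinglass modularity
#' optimization (25 spins, gamma 1), with the RNG seeded immediately before
#' the run so the partition is reproducible; the conventional seed is 123.
#' Disconnected graphs are handled by running each connected component
#' separately (singleton components become their own community).
#'
#' @param cg A `community_graph` from [build_network()].
#' @param seed RNG seed (default 123).
#' @param spins Maximum number of communities (default 25).
#' @param gamma Spinglass gamma parameter (default 1).
#' @return The input with `membership` (named integer vector),
#'   `modularity` (weighted modularity of the partition) and `seed` added.
#' @export
detect_communities <- function(cg, seed = 123L, spins = 25, gamma = 1) {
  stopifnot(inherits(cg, "community_graph"))
  g <- cg$graph
  set.seed(seed)
  comp <- igraph::components(g)
  membership <- integer(igraph::vcount(g))
  names(membership) <- igraph::V(g)$name
  offset <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1) {
      membership[vs] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    cl <- igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight,
                                    spins = spins, gamma = gamma)
    mem <- igraph::membership(cl)
    membership[vs] <- offset + as.integer(mem)
    offset <- offset + max(mem)
  }
  cg$membership <- membership
  cg$modularity <- igraph::modularity(g, membership,
                                      weights = igraph::E(g)$weight)
  cg$seed <- seed
  cg
}

# connected components of a set of occupied grid bins (4-neighborhood).
# bins: integer matrix with columns ix, iy. Returns component id per bin.
.grid_components <- function(bins) {
  n <- nrow(bins)
  key <- paste(bins[, 1], bins[, 2])
  idx <- stats::setNames(seq_len(n), key)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      b <- queue[[1]]
      queue <- queue[-1]
      nb_keys <- paste(bins[b, 1] + c(1, -1, 0, 0), bins[b, 2] + c(0, 0, 1, -1))
      nb <- idx[nb_keys]
      nb <- nb[!is.na(nb)]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Restrict an image to its largest connected tissue piece
#'
#' Rasterizes cell occupancy on a grid and keeps only cells falling in the
#' largest 4-connected component of occupied bins (fractured tissue: only
#' the largest intact piece is analyzed).
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param grid_um Occupancy bin size (default 50).
#' @return `cells` restricted to the largest component, with attribute
#'   `n_removed`.
#' @export
filter_largest_component <- function(cells, grid_um = 50) {
  ix <- floor(cells$x_um / grid_um)
  iy <- floor(cells$y_um / grid_um)
  key <- paste(ix, iy)
  bins <- unique(cbind(ix, iy))
  comp <- .grid_components(bins)
  largest <- which.max(tabulate(comp))
  keep_keys <- paste(bins[comp == largest, 1], bins[comp == largest, 2])
  keep <- key %in% keep_keys
  out <- cells[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Map cells to tumor-structure regions
#'
#' Rasterizes tumor-class density on a `grid_um` grid; the tumor mask is
#' the set of bins whose tumor-cell count exceeds `mask_frac` of the mean
#' non-zero tumor bin count; boundary bins are mask bins 4-adjacent to
#' non-mask bins (or the grid edge). Cells inside the mask within
#' `margin_um` of the boundary are the internal margin, cells outside
#' within `margin_um` the external margin, and the remainders are
#' intratumoral and stroma. Images are flagged eligible for infiltration
#' analysis when the mask occupies 5-95% of occupied tissue bins and the
#' boundary is at least 10 bins long (a deterministic surrogate for
#' manually judged "clear tumor-stroma boundaries").
#'
#' @param labeled Labeled cell table for one image.
#' @param tumor_class Tumor label (default `"CK19"`).
#' @param margin_um Margin half-width in um (default 100).
#' @param grid_um Raster bin size in um (default 50).
#' @param mask_frac Density threshold as a fraction of the mean non-zero
#'   tumor bin count (default 0.25).
#' @param largest_component Restrict to the largest connected tissue piece
#'   first (default TRUE).
#' @return List of class `structure_assignment`: `cells` (cell_id, region),
#'   `eligible`, `eligibility_reason`, `mask_share`, `boundary_bins`,
#'   parameters used.
#' @export
map_structures <- function(labeled, tumor_class = "CK19", margin_um = 100,
                           grid_um = 50, mask_frac = 0.25,
                           largest_component = TRUE) {
  if (largest_component) labeled <- filter_largest_component(labeled, grid_um)
  tumor <- labeled[labeled$label == tumor_class, , drop = FALSE]
  if (!nrow(tumor)) stop("no cells of tumor class '", tumor_class, "'")

  ix <- floor(labeled$x_um / grid_um)
  iy <- floor(labeled$y_um / grid_um)
  t_ix <- floor(tumor$x_um / grid_um)
  t_iy <- floor(tumor$y_um / grid_um)
  t_key <- paste(t_ix, t_iy)
  counts <- table(t_key)
  thr <- mask_frac * mean(counts)
  mask_keys <- names(counts)[as.vector(counts) > thr]

  mask_df <- do.call(rbind, strsplit(mask_keys, " "))
  mask_bins <- cbind(as.integer(mask_df[, 1]), as.integer(mask_df[, 2]))
  in_mask_key <- function(kx, ky) paste(kx, ky) %in% mask_keys
  # boundary: mask bins with a non-mask 4-neighbor
  nb_out <- !(in_mask_key(mask_bins[, 1] + 1, mask_bins[, 2]) &
              in_mask_key(mask_bins[, 1] - 1, mask_bins[, 2]) &
              in_mask_key(mask_bins[, 1], mask_bins[, 2] + 1) &
              in_mask_key(mask_bins[, 1], mask_bins[, 2] - 1))
  boundary <- mask_bins[nb_out, , drop = FALSE]

  cell_in_mask <- paste(ix, iy) %in% mask_keys
  if (nrow(boundary)) {
    bc <- cbind((boundary[, 1] + 0.5) * grid_um, (boundary[, 2] + 0.5) * grid_um)
    d_boundary <- .nn_dist(as.matrix(labeled[, c("x_um", "y_um")]), bc)
  } else {
    d_boundary <- rep(Inf, nrow(labeled))
  }
  region <- ifelse(
    cell_in_mask,
    ifelse(d_boundary <= margin_um, "internal_margin", "intratumoral"),
    ifelse(d_boundary <= margin_um, "external_margin", "stroma")
  )

  tissue_bins <- unique(paste(ix, iy))
  mask_share <- mean(tissue_bins %in% mask_keys)
  eligible <- mask_share >= 0.05 && mask_share <= 0.95 && nrow(boundary) >= 10
  reason <- if (eligible) "clear boundary" else if (nrow(boundary) < 10)
    "boundary too short" else "tumor mask share outside 5-95% of tissue"

  structure(
    list(cells = data.frame(cell_id = labeled$cell_id, region = region,
                            stringsAsFactors = FALSE),
         eligible = eligible, eligibility_reason = reason,
         mask_share = mask_share, boundary_bins = nrow(boundary),
         margin_um = margin_um, grid_um = grid_um, mask_frac = mask_frac),
    class = "structure_assignment"
  )
}

#' Per-region composition of non-tumor phenotyped cells
#'
#' For each phenotype class (tumor-negative), the percentage of its cells
#' falling in each of the four structure regions, plus the distribution of
#' all non-tumor phenotyped cells. Requires an eligible image (clear
#' tumor-stroma boundary); ineligible assignments raise an error carrying
#' the logged reason.
#'
#' @param assignment A `structure_assignment` from [map_structures()].
#' @param labeled The labeled cell table the assignment was computed from.
#' @param classes Non-tumor classes to summarize.
#' @return Data frame: class (including `"all_CK19neg"`), region, n, pct
#'   (per class, summing to 100 across regions).
#' @export
infiltration_summary <- function(assignment, labeled,
                                 classes = c("CD3", "CD19", "CD68", "aSMA")) {
  stopifnot(inherits(assignment, "structure_assignment"))
  if (!assignment$eligible) {
    stop("image ineligible for infiltration analysis: ",
         assignment$eligibility_reason)
  }
  regions <- c("intratumoral", "internal_margin", "external_margin", "stroma")
  reg <- assignment$cells$region[match(labeled$cell_id, assignment$cells$cell_id)]
  rows <- list()
  groups <- c(stats::setNames(as.list(classes), classes),
              list(all_CK19neg = classes))
  for (gname in names(groups)) {
    sel <- labeled$label %in% groups[[gname]]
    n_tot <- sum(sel)
    for (r in regions) {
      n <- sum(sel & reg == r, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        class = gname, region = r, n = n,
        pct = if (n_tot > 0) 100 * n / n_tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
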
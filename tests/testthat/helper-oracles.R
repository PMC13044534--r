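# Independent oracles used across the suite. Each deliberately recomputes
# its quantity by the most transparent route available (naive scans, full
# enumeration, brute-force double loops) so it shares no code path with the
# implementation it checks.

# exhaustive 1-D two-class split: recompute the within-class sum of squares
# of every contiguous cut with a naive per-cut evaluation
oracle_split_threshold <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  wss <- vapply(seq_len(n - 1), function(k) {
    left <- xs[1:k]; right <- xs[(k + 1):n]
    sum((left - mean(left))^2) + sum((right - mean(right))^2)
  }, numeric(1))
  k <- which.min(wss)
  (mean(xs[1:k]) + mean(xs[(k + 1):n])) / 2
}

# brute-force directional nearest-neighbor summaries (double loop)
oracle_nn_summary <- function(ref_xy, tgt_xy, self = FALSE) {
  d <- vapply(seq_len(nrow(ref_xy)), function(i) {
    dd <- sqrt((tgt_xy[, 1] - ref_xy[i, 1])^2 + (tgt_xy[, 2] - ref_xy[i, 2])^2)
    if (self) dd[i] <- Inf
    min(dd)
  }, numeric(1))
  d <- d[is.finite(d)]
  c(median = stats::median(d), min = min(d))
}

# full enumeration of the two-sided Mann-Whitney p value: all C(n, n_a)
# assignments of the pooled ranks
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (length(b)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# full enumeration of the two-sided Wilcoxon signed-rank p value over all
# 2^n sign patterns
oracle_wsr_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  vs <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
}

# all set partitions of n elements (Bell-number enumeration)
oracle_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in oracle_partitions(n - 1)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# exhaustive maximum-modularity partition of a small weighted graph
oracle_best_partition <- function(g) {
  n <- igraph::vcount(g)
  best_q <- -Inf; best_mem <- NULL
  for (p in oracle_partitions(n)) {
    mem <- integer(n)
    for (i in seq_along(p)) mem[p[[i]]] <- i
    q <- igraph::modularity(g, mem, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_mem <- mem }
  }
  list(q = best_q, membership = best_mem)
}

# per-cell enumeration of checkpoint combination frequencies via string keys
oracle_combo_freq <- function(pos_matrix, markers) {
  keys <- apply(pos_matrix, 1, function(r)
    paste0(markers, ifelse(r, "+", "-"), collapse = ""))
  table(keys) / nrow(pos_matrix)
}

# same community structure up to relabeling
same_partition <- function(m1, m2) {
  length(unique(paste(m1, m2))) == length(unique(m1)) &&
    length(unique(m1)) == length(unique(m2))
}

small_config <- function(seed = 7, n_cells = 2500, n_events = 5000,
                         n_samples = 1L) {
  cm <- default_cytof_model()
  cm$n_events_per_sample <- as.integer(n_events)
  generator_config(n_samples_per_site = n_samples,
                   n_cells_per_image = n_cells,
                   cytof_model = cm, seed = seed)
}
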
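#' Mass-cytometry analysis chain
#'
#' Event cleanup (beads, Gaussian discriminators, event length), viability
#' and DNA singlet gating, sample retention, hierarchical subset gating
#' with minimum-parent cutoffs, B-cell subsetting, and five-checkpoint
#' Boolean combination profiling.
#'
#' @name cytof
NULL

.gaussian_channels <- c("residual", "center", "offset", "width", "event_length")

#' Remove beads and abnormal events
#'
#' Drops bead-flagged events, then keeps only events whose Gaussian
#' discriminator channels (residual, center, offset, width) and event
#' length lie within per-sample percentile windows (default 1st-99th).
#'
#' @param events Event table with `bead` flag and the discriminator
#'   channels.
#' @param window Lower/upper percentile pair as fractions (default
#'   `c(0.01, 0.99)`), applied per channel within each sample.
#' @return Cleaned event table; attribute `removed` logs counts per stage.
#' @export
clean_events <- function(events, window = c(0.01, 0.99)) {
  missing_ch <- setdiff(c("bead", .gaussian_channels), names(events))
  if (length(missing_ch)) {
    stop("missing channels: ", paste(missing_ch, collapse = ", "))
  }
  n0 <- nrow(events)
  events <- events[events$bead == 0, , drop = FALSE]
  n_bead <- n0 - nrow(events)
  keep <- rep(TRUE, nrow(events))
  for (sid in unique(events$sample_id)) {
    si <- events$sample_id == sid
    for (ch in .gaussian_channels) {
      v <- events[[ch]][si]
      lo <- quantile7(v, window[1])
      hi <- quantile7(v, window[2])
      keep[si] <- keep[si] & events[[ch]][si] >= lo & events[[ch]][si] <= hi
    }
  }
  out <- events[keep, , drop = FALSE]
  attr(out, "removed") <- c(beads = n_bead, window = sum(!keep))
  out
}

#' Gate live intact singlets
#'
#' Retains events that are cisplatin-negative (viability) and fall inside
#' the DNA1/DNA2 intercalator box (intact singlet nucleated cells: debris
#' sits below the box, doublets above it).
#'
#' @param events Event table with `cisplatin`, `DNA1`, `DNA2`.
#' @param cisplatin_cut Events with cisplatin strictly above this are dead.
#' @param dna_box List with `DNA1` and `DNA2` elements, each `c(lo, hi)`.
#' @return Live-singlet event table.
#' @export
live_singlet_gate <- function(events, cisplatin_cut, dna_box) {
  for (ch in c("DNA1", "DNA2")) {
    box <- dna_box[[ch]]
    if (is.null(box) || length(box) != 2 || box[2] <= box[1]) {
      stop("dna_box must give a non-empty (lo, hi) interval for ", ch)
    }
  }
  keep <- events$cisplatin <= cisplatin_cut &
    events$DNA1 >= dna_box$DNA1[1] & events$DNA1 <= dna_box$DNA1[2] &
    events$DNA2 >= dna_box$DNA2[1] & events$DNA2 <= dna_box$DNA2[2]
  events[keep, , drop = FALSE]
}

#' Default synthetic-data gates
#'
#' Cuts derived from the generator's known mixtures: the cisplatin cut and
#' marker thresholds sit at the geometric midpoint (log-scale valley)
#' between the negative and positive component locations, and the DNA box
#' spans +/- 3.5 log-SD around the singlet DNA location (the doublet
#' population, at twice the singlet signal, lies ~7 log-SDs away). Real
#' data takes a manually specified threshold table instead.
#'
#' @param config A [generator_config()].
#' @return List with `cisplatin_cut`, `dna_box`, and `marker_thresholds`
#'   (named vector over the CyTOF channels).
#' @export
default_cytof_gates <- function(config) {
  ch <- config$cytof_model$channels
  gm <- function(a, b) exp((a[["meanlog"]] + b[["meanlog"]]) / 2)
  dna_lo <- exp(ch$dna_singlet[["meanlog"]] - 3.5 * ch$dna_singlet[["sdlog"]])
  dna_hi <- exp(ch$dna_singlet[["meanlog"]] + 3.5 * ch$dna_singlet[["sdlog"]])
  thr <- gm(ch$marker_negative, ch$marker_positive)
  markers <- c("CD45", "CD3", "CD4", "CD8", "CD19", "CD27", "IgD", "CD11b",
               "Ki67", "PDL1", checkpoint_markers())
  list(
    cisplatin_cut = gm(ch$cisplatin_live, ch$cisplatin_dead),
    dna_box = list(DNA1 = c(dna_lo, dna_hi), DNA2 = c(dna_lo, dna_hi)),
    marker_thresholds = stats::setNames(rep(thr, length(markers)), markers)
  )
}

#' Retain samples with enough live cells
#'
#' Samples with at least `min_live` live DNA2+ cells are retained
#' (the boundary count is retained).
#'
#' @param live_counts Data frame with `sample_id` and `n_live`, e.g. from
#'   counting rows per sample after [live_singlet_gate()].
#' @param min_live Minimum live-cell count (default 500).
#' @return List with `retained` sample ids and an `exclusions` log.
#' @export
retain_samples <- function(live_counts, min_live = 500L) {
  log <- data.frame(sample_id = live_counts$sample_id,
                    n_live = live_counts$n_live,
                    retained = live_counts$n_live >= min_live,
                    stringsAsFactors = FALSE)
  list(retained = log$sample_id[log$retained], exclusions = log)
}

#' Count live events per sample
#' @param events Gated event table.
#' @return Data frame `sample_id`, `n_live`.
#' @export
live_counts <- function(events) {
  tab <- table(events$sample_id)
  data.frame(sample_id = names(tab), n_live = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Hierarchical subset gating of live singlets
#'
#' Applies the gating tree CD45- / CD45+, then within CD45+CD3+ T cells
#' CD4 / CD8 / CD4CD8 double-positive (CD3+CD4-CD8- cells fall back to
#' other CD45+), within CD45+CD3- the CD19+ B cells, remainder
#' "other CD45+". The partition of live singlets is exhaustive and
#' exclusive. Also reports the Ki67+ fraction per subset.
#'
#' @param events Live-singlet event table.
#' @param thresholds Named per-marker cuts (strictly-greater positivity).
#' @return List of class `subset_counts` with `counts` (per sample x
#'   subset: n, pct of live, ki67_pct) and `events` (input plus `subset`).
#' @export
hierarchical_gate <- function(events, thresholds) {
  needed <- c("CD45", "CD3", "CD4", "CD8", "CD19", "Ki67")
  missing_m <- setdiff(needed, names(events))
  if (length(missing_m)) stop("missing markers: ", paste(missing_m, collapse = ", "))
  missing_t <- setdiff(needed, names(thresholds))
  if (length(missing_t)) stop("missing thresholds: ", paste(missing_t, collapse = ", "))
  pos <- function(m) events[[m]] > thresholds[[m]]
  cd45 <- pos("CD45"); cd3 <- pos("CD3"); cd4 <- pos("CD4")
  cd8 <- pos("CD8"); cd19 <- pos("CD19")
  subset <- rep("CD45other", nrow(events))
  subset[!cd45] <- "CD45neg"
  subset[cd45 & cd3 & cd4 & !cd8] <- "CD4"
  subset[cd45 & cd3 & !cd4 & cd8] <- "CD8"
  subset[cd45 & cd3 & cd4 & cd8] <- "CD4CD8"
  subset[cd45 & !cd3 & cd19] <- "CD19"
  events$subset <- subset

  ki67 <- pos("Ki67")
  levels <- c("CD45neg", "CD45other", "CD4", "CD8", "CD4CD8", "CD19")
  rows <- list()
  for (sid in unique(events$sample_id)) {
    si <- events$sample_id == sid
    n_tot <- sum(si)
    for (sub in levels) {
      sel <- si & subset == sub
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, subset = sub, n = n,
        pct = if (n_tot > 0) 100 * n / n_tot else NA_real_,
        ki67_pct = if (n > 0) 100 * mean(ki67[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = do.call(rbind, rows), events = events),
            class = "subset_counts")
}

#' Minimum-parent event filter
#'
#' Samples are eligible for downstream phenotyping of a parent population
#' only when the parent holds at least `min_events` events (default 25,
#' the robustness cutoff applied to CD3+ T cells and CD19+ B cells).
#' `parent = "CD3"` sums the CD4, CD8 and CD4CD8 leaves.
#'
#' @param counts A `subset_counts` or its `counts` data frame.
#' @param parent Parent population id (a subset leaf, or `"CD3"`).
#' @param min_events Minimum parent size (default 25).
#' @return Character vector of eligible sample ids.
#' @export
min_parent_filter <- function(counts, parent, min_events = 25L) {
  df <- if (inherits(counts, "subset_counts")) counts$counts else counts
  known <- c("CD45neg", "CD45other", "CD4", "CD8", "CD4CD8", "CD19", "CD3",
             unique(df$subset))
  if (!parent %in% known) stop("unknown parent population: ", parent)
  subsets <- if (parent == "CD3") c("CD4", "CD8", "CD4CD8") else parent
  sub <- df[df$subset %in% subsets, , drop = FALSE]
  if (!nrow(sub)) return(character(0))
  agg <- stats::aggregate(n ~ sample_id, data = sub, FUN = sum)
  agg$sample_id[agg$n >= min_events]
}

#' Boolean checkpoint-combination profiling
#'
#' Maps every cell of a T-cell subset to one of the 2^5 = 32 positivity
#' combinations of CTLA4, LAG3, PD1, TIGIT and TIM3 (fixed marker order),
#' and reports combination frequencies, the per-cell checkpoint-count
#' histogram (0-5), and a hierarchical (sunburst-ready) table cumulated in
#' the fixed marker order.
#'
#' @param events Event table already restricted to the subset of interest.
#' @param thresholds Named cuts for the five checkpoint channels.
#' @param markers Marker order (default [checkpoint_markers()]).
#' @return List of class `checkpoint_combos`: `freq` (32 rows: one logical
#'   column per marker, `combo` string, n, frequency), `histogram` (named
#'   vector over 0-5), `sunburst` (depth, path, freq), `n_cells`.
#' @export
checkpoint_combinations <- function(events, thresholds,
                                    markers = checkpoint_markers()) {
  missing_m <- setdiff(markers, names(events))
  if (length(missing_m)) stop("missing channels: ", paste(missing_m, collapse = ", "))
  pos <- sapply(markers, function(m) events[[m]] > thresholds[[m]])
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = nrow(events))
  colnames(pos) <- markers
  n <- nrow(events)

  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(markers)))[, length(markers):1]
  names(grid) <- markers
  combo_str <- function(m) {
    apply(m, 1, function(r) paste0(markers, ifelse(r, "+", "-"), collapse = ""))
  }
  grid_keys <- combo_str(as.matrix(grid))
  keys <- if (n > 0) combo_str(pos) else character(0)
  counts <- table(factor(keys, levels = grid_keys))
  freq <- data.frame(grid, combo = grid_keys,
                     n = as.integer(counts),
                     freq = if (n > 0) as.integer(counts) / n else NA_real_,
                     stringsAsFactors = FALSE)

  k <- rowSums(grid)
  histogram <- vapply(0:5, function(j) sum(freq$freq[k == j]), numeric(1))
  names(histogram) <- as.character(0:5)

  sun <- list()
  for (depth in seq_along(markers)) {
    sub <- markers[seq_len(depth)]
    path_keys <- apply(as.matrix(grid[, sub, drop = FALSE]), 1,
                       function(r) paste0(sub, ifelse(r, "+", "-"), collapse = ""))
    agg <- tapply(freq$freq, path_keys, sum)
    sun[[depth]] <- data.frame(depth = depth, path = names(agg),
                               freq = as.numeric(agg), stringsAsFactors = FALSE)
  }
  structure(list(freq = freq, histogram = histogram,
                 sunburst = do.call(rbind, sun), n_cells = n),
            class = "checkpoint_combos")
}

#' Default B-cell subset rule table
#'
#' Six conventionally defined, possibly overlapping subsets expressed as
#' Boolean rules over marker positivity. These definitions are package
#' conventions (naive IgD+CD27-; memory CD27+; regulatory potential PD-1
#' and/or PD-L1; extrafollicular IgD-CD27-CD11b+; plasmablast
#' Ki67+IgD-CD27+; unswitched IgD+CD27+), not a reconstruction of any
#' particular published rule set; supply your own table to change them.
#'
#' @return Named character vector of Boolean expressions over marker names.
#' @export
default_b_cell_rules <- function() {
  c(naive = "IgD & !CD27",
    memory = "CD27",
    regulatory_potential = "PD1 | PDL1",
    extrafollicular = "!IgD & !CD27 & CD11b",
    plasmablast = "Ki67 & !IgD & CD27",
    unswitched_memory = "IgD & CD27")
}

#' Fraction of CD19+ B cells in phenotypic subsets
#'
#' Evaluates a rule table (Boolean expressions over marker positivity) on
#' CD19+ events and reports the fraction of B cells in each subset. Rules
#' may overlap ("and/or" definitions count a double-positive cell once).
#'
#' @param events Event table restricted to CD19+ B cells.
#' @param thresholds Named cuts for every channel the rules mention.
#' @param rules Named Boolean expressions (default
#'   [default_b_cell_rules()]).
#' @return Data frame: subset, n, pct (of CD19+ cells).
#' @export
b_cell_subsets <- function(events, thresholds, rules = default_b_cell_rules()) {
  used <- unique(unlist(regmatches(rules, gregexpr("[A-Za-z][A-Za-z0-9]*", rules))))
  used <- setdiff(used, c("TRUE", "FALSE"))
  missing_ch <- setdiff(used, names(events))
  if (length(missing_ch)) {
    stop("rules reference missing channels: ", paste(missing_ch, collapse = ", "))
  }
  env <- new.env(parent = baseenv())
  for (m in used) assign(m, events[[m]] > thresholds[[m]], envir = env)
  n_b <- nrow(events)
  rows <- lapply(names(rules), function(rn) {
    sel <- eval(parse(text = rules[[rn]]), envir = env)
    data.frame(subset = rn, n = sum(sel),
               pct = if (n_b > 0) 100 * sum(sel) / n_b else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
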
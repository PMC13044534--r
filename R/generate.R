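#' Synthetic tissue, control, collagen and mass-cytometry generators
#'
#' These generators plant known ground truth (cell labels, modifier states,
#' composition vectors, collagen fractions, CyTOF subsets and checkpoint
#' states) so that every downstream analysis stage can be validated by
#' direct comparison against truth.
#'
#' @name synthgen
NULL

# lognormal parameters for one marker under the configured intensity model
.marker_params <- function(intensity_model, marker) {
  pm <- intensity_model$per_marker[[marker]]
  if (is.null(pm)) {
    list(negative = intensity_model$negative, positive = intensity_model$positive)
  } else {
    pm
  }
}

# draw raw intensities for one marker channel given per-cell truth positivity
.draw_intensities <- function(positive, params) {
  n <- length(positive)
  out <- numeric(n)
  npos <- sum(positive)
  if (npos > 0) {
    out[positive] <- stats::rlnorm(npos, params$positive[["meanlog"]],
                                   params$positive[["sdlog"]])
  }
  if (npos < n) {
    out[!positive] <- stats::rlnorm(n - npos, params$negative[["meanlog"]],
                                    params$negative[["sdlog"]])
  }
  out
}

# uniform points in a disk
.runif_disk <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(a), center[2] + r * sin(a))
}

.inside_any_nest <- function(xy, nests, radius) {
  inside <- rep(FALSE, nrow(xy))
  for (k in seq_len(nrow(nests))) {
    d2 <- (xy[, 1] - nests[k, 1])^2 + (xy[, 2] - nests[k, 2])^2
    inside <- inside | d2 <= radius^2
  }
  inside
}

# per-cell truth positivity matrix over the imaging marker channels
.truth_positivity <- function(truth) {
  lab <- truth$label
  cbind(
    CK19 = lab == "CK19",
    aSMA = lab == "aSMA",
    CD3 = lab %in% c("CD4T", "CD8T"),
    CD4 = lab == "CD4T",
    CD8 = lab == "CD8T",
    CD19 = lab == "CD19",
    CD68 = lab == "CD68",
    IL6 = truth$IL6,
    PDPLN = truth$PDPLN,
    PDGFRb = truth$PDGFRb,
    CCR2 = truth$CCR2,
    CD163 = truth$CD163,
    Tbet = truth$Tbet,
    FoxP3 = truth$FoxP3,
    RORgt = truth$RORgt
  )
}

#' Generate a synthetic tissue cohort for one disease site
#'
#' Draws `n_samples_per_site` images of `n_cells_per_image` cells each.
#' Cell classes are assigned by a multinomial draw from the site's planted
#' composition profile, so empirical truth composition is stochastic with
#' binomial sampling error. Tumor (CK19+) cells are concentrated in
#' circular nests, immune cells in clusters anchored preferentially outside
#' the nests, fibroblasts in the extranest stroma, and `other` cells
#' uniformly; marker intensities come from the positive log-normal component
#' for the channels implied by each cell's true label/modifiers and from the
#' background component otherwise.
#'
#' @param config A [generator_config()].
#' @param site Site id present in `config$site_profiles`.
#' @return List with `cells` (the cell table: `cell_id`, `image_id`,
#'   `sample_id`, `site`, `x_um`, `y_um`, one raw-intensity column per
#'   marker) and `truth` (list with per-cell `cells` truth and per-image
#'   `composition` fractions computed by direct counting of truth labels).
#' @export
gen_tissue <- function(config, site) {
  stopifnot(inherits(config, "generator_config"))
  profile <- config$site_profiles[[site]]
  if (is.null(profile)) stop("unknown site: ", site)
  sm <- config$spatial_model
  set.seed(derive_seed(config$seed, "tissue", site))

  classes <- names(profile$fractions)
  cell_list <- list()
  truth_list <- list()
  comp_list <- list()

  for (s in seq_len(config$n_samples_per_site)) {
    n <- config$n_cells_per_image
    sample_id <- sprintf("%s_%02d", site, s)
    label <- sample(classes, n, replace = TRUE, prob = profile$fractions)

    # nest centers fully inside the field
    W <- sm$field_um[1]; H <- sm$field_um[2]; R <- sm$nest_radius_um
    nests <- cbind(stats::runif(sm$n_nests, R, W - R),
                   stats::runif(sm$n_nests, R, H - R))

    xy <- cbind(stats::runif(n, 0, W), stats::runif(n, 0, H))

    idx_tumor <- which(label == "CK19")
    if (length(idx_tumor)) {
      which_nest <- sample.int(sm$n_nests, length(idx_tumor), replace = TRUE)
      for (k in seq_len(sm$n_nests)) {
        ii <- idx_tumor[which_nest == k]
        if (length(ii)) xy[ii, ] <- .runif_disk(length(ii), nests[k, ], R)
      }
    }

    for (cls in c("CD4T", "CD8T", "CD19", "CD68")) {
      ii <- which(label == cls)
      if (!length(ii)) next
      n_anchor <- max(1L, ceiling(length(ii) / sm$cells_per_anchor))
      anchors <- cbind(stats::runif(n_anchor, 0, W), stats::runif(n_anchor, 0, H))
      # anchors preferentially outside tumor nests (immune exclusion)
      for (tries in 1:50) {
        bad <- .inside_any_nest(anchors, nests, R)
        if (!any(bad)) break
        anchors[bad, ] <- cbind(stats::runif(sum(bad), 0, W),
                                stats::runif(sum(bad), 0, H))
      }
      a_idx <- sample.int(n_anchor, length(ii), replace = TRUE)
      r <- sm$attraction_radius_um * sqrt(stats::runif(length(ii)))
      ang <- stats::runif(length(ii), 0, 2 * pi)
      xy[ii, ] <- cbind(pmin(pmax(anchors[a_idx, 1] + r * cos(ang), 0), W),
                        pmin(pmax(anchors[a_idx, 2] + r * sin(ang), 0), H))
    }

    ii <- which(label == "aSMA")
    if (length(ii)) {
      for (tries in 1:20) {
        inside <- .inside_any_nest(xy[ii, , drop = FALSE], nests, R)
        redraw <- inside & stats::runif(length(ii)) < sm$stroma_bias
        if (!any(redraw)) break
        jj <- ii[redraw]
        xy[jj, ] <- cbind(stats::runif(length(jj), 0, W),
                          stats::runif(length(jj), 0, H))
      }
    }

    # modifier truth states
    p_il6 <- profile$il6[label]
    il6 <- stats::runif(n) < p_il6
    is_cd4 <- label == "CD4T"; is_cd8 <- label == "CD8T"
    tf <- sapply(c("Tbet", "FoxP3", "RORgt"), function(m) {
      p <- numeric(n)
      p[is_cd4] <- profile$tf_cd4[[m]]
      p[is_cd8] <- profile$tf_cd8[[m]]
      stats::runif(n) < p
    })
    is_caf <- label == "aSMA"; is_mac <- label == "CD68"
    pdpln <- stats::runif(n) < ifelse(is_caf, profile$caf_markers[["PDPLN"]], 0)
    pdgfrb <- stats::runif(n) < ifelse(is_caf, profile$caf_markers[["PDGFRb"]], 0)
    ccr2 <- stats::runif(n) < ifelse(is_mac, profile$mac_markers[["CCR2"]], 0)
    cd163 <- stats::runif(n) < ifelse(is_mac, profile$mac_markers[["CD163"]], 0)

    truth <- data.frame(
      cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
      image_id = sample_id, sample_id = sample_id, site = site,
      label = label, IL6 = il6,
      Tbet = tf[, "Tbet"], FoxP3 = tf[, "FoxP3"], RORgt = tf[, "RORgt"],
      PDPLN = pdpln, PDGFRb = pdgfrb, CCR2 = ccr2, CD163 = cd163,
      stringsAsFactors = FALSE
    )

    pos <- .truth_positivity(truth)
    intens <- sapply(colnames(pos), function(m) {
      .draw_intensities(pos[, m], .marker_params(config$intensity_model, m))
    })

    cells <- data.frame(
      cell_id = truth$cell_id, image_id = sample_id, sample_id = sample_id,
      site = site, x_um = xy[, 1], y_um = xy[, 2],
      stringsAsFactors = FALSE
    )
    cells <- cbind(cells, as.data.frame(intens))

    comp <- as.numeric(table(factor(label, levels = classes))) / n
    names(comp) <- classes

    cell_list[[s]] <- cells
    truth_list[[s]] <- truth
    comp_list[[sample_id]] <- comp
  }

  list(
    cells = do.call(rbind, cell_list),
    truth = list(cells = do.call(rbind, truth_list), composition = comp_list)
  )
}

#' Generate an unstained negative-control cell table
#'
#' All marker channels are drawn from the background (negative)
#' distributions only, emulating the unstained / negative-control images
#' used to calibrate gating floors.
#'
#' @param config A [generator_config()].
#' @param n_cells Number of control cells (>= 1).
#' @return Cell table with site `"control"`; all truth labels are negative.
#' @export
gen_control <- function(config, n_cells) {
  stopifnot(inherits(config, "generator_config"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  set.seed(derive_seed(config$seed, "control"))
  n <- as.integer(n_cells)
  markers <- imaging_markers()
  intens <- sapply(markers, function(m) {
    .draw_intensities(rep(FALSE, n), .marker_params(config$intensity_model, m))
  })
  cells <- data.frame(
    cell_id = sprintf("control_c%05d", seq_len(n)),
    image_id = "control_01", sample_id = "control_01", site = "control",
    x_um = stats::runif(n, 0, config$spatial_model$field_um[1]),
    y_um = stats::runif(n, 0, config$spatial_model$field_um[2]),
    stringsAsFactors = FALSE
  )
  cbind(cells, as.data.frame(intens))
}

#' Generate a synthetic collagen (Picrosirius-red-like) image
#'
#' Produces a single-channel grayscale pixel array with a circular tissue
#' region on a dark background. Within the tissue, an exact count of
#' `round(truth * n_tissue)` pixels is raised to the positive signal level,
#' so the recomputable positive-area fraction equals the returned truth
#' fraction by construction. Gray levels are separated so a fixed pair of
#' thresholds (tissue > 30, signal > 120 on a 0-255 scale) recovers the
#' masks exactly.
#'
#' @param config A [generator_config()].
#' @param site Site id present in `config$collagen_model`.
#' @param size Image dimensions in pixels (rows, cols).
#' @param replicate Replicate index (varies the RNG stream per sample).
#' @param truth_fraction Optional override of the planted positive-area
#'   fraction (in `[0, 1]`).
#' @return List with `image` (numeric matrix, 0-255) and `truth_fraction`
#'   (realized positive fraction of tissue pixels).
#' @export
gen_collagen_image <- function(config, site, size = c(512, 512),
                               replicate = 1L, truth_fraction = NULL) {
  stopifnot(inherits(config, "generator_config"))
  truth <- if (is.null(truth_fraction)) config$collagen_model[[site]] else truth_fraction
  if (is.null(truth)) stop("no collagen model for site: ", site)
  if (is.na(truth) || truth < 0 || truth > 1) {
    stop("collagen truth fraction must lie in [0, 1]")
  }
  set.seed(derive_seed(config$seed, "collagen", site, replicate))
  nr <- size[1]; nc <- size[2]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  rad <- 0.45 * min(nr, nc)
  d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
  tissue <- d2 <= rad^2
  n_tissue <- sum(tissue)
  img <- matrix(stats::runif(nr * nc, 0, 15), nr, nc)      # background
  img[tissue] <- stats::runif(n_tissue, 45, 75)            # tissue, signal-negative
  n_pos <- round(truth * n_tissue)
  if (n_pos > 0) {
    pos_idx <- sample(which(tissue), n_pos)
    img[pos_idx] <- stats::runif(n_pos, 150, 220)          # collagen signal
  }
  list(image = img, truth_fraction = n_pos / n_tissue)
}

.cytof_channels <- function() {
  c("CD45", "CD3", "CD4", "CD8", "CD19", "CD27", "IgD", "CD11b",
    "Ki67", "PDL1", "CTLA4", "LAG3", "PD1", "TIGIT", "TIM3")
}

#' Checkpoint marker order used for Boolean combination profiling
#' @return Character vector (fixed order CTLA4, LAG3, PD1, TIGIT, TIM3).
#' @export
checkpoint_markers <- function() c("CTLA4", "LAG3", "PD1", "TIGIT", "TIM3")

#' Generate synthetic mass-cytometry event tables for one site
#'
#' Events carry a bead flag, the four Gaussian discriminator channels
#' (residual, center, offset, width), event length, cisplatin (high for
#' planted dead events), DNA1/DNA2 (low for debris, doubled for planted
#' doublets), lineage channels and the five checkpoint channels. Checkpoint
#' positivity on T cells follows the latent-exhaustion Gaussian copula of
#' [default_cytof_model()], so co-expression exceeds independence when
#' `rho > 0` while the marginals are preserved exactly.
#'
#' @param config A [generator_config()].
#' @param site Site id with subset fractions in `config$cytof_model`.
#' @return List with `events` (one row per event) and `truth` (per-event
#'   QC class, subset and true checkpoint states).
#' @export
gen_cytof <- function(config, site) {
  stopifnot(inherits(config, "generator_config"))
  cm <- config$cytof_model
  sf <- cm$subset_fractions[[site]]
  if (is.null(sf)) stop("unknown site for CyTOF model: ", site)
  if (any(sf < 0)) stop("CyTOF subset fractions must be non-negative")
  set.seed(derive_seed(config$seed, "cytof", site))
  ch <- cm$channels
  ev_list <- list(); truth_list <- list()

  for (s in seq_len(config$n_samples_per_site)) {
    sample_id <- sprintf("%s_%02d", site, s)
    n <- cm$n_events_per_sample
    qf <- cm$qc_fractions
    qc_levels <- c(names(qf), "live")
    qc <- sample(qc_levels, n, replace = TRUE, prob = c(qf, 1 - sum(qf)))
    subset <- sample(names(sf), n, replace = TRUE, prob = sf)

    rln <- function(p, n_) stats::rlnorm(n_, p[["meanlog"]], p[["sdlog"]])
    residual <- rln(ch$gaussian, n)
    center <- rln(ch$gaussian, n)
    offset <- rln(ch$gaussian, n)
    width <- rln(ch$width, n)
    merged <- qc == "merged"
    width[merged] <- rln(ch$width_merged, sum(merged))
    event_length <- rln(ch$event_length, n)

    cisplatin <- rln(ch$cisplatin_live, n)
    dead <- qc == "dead"
    cisplatin[dead] <- rln(ch$cisplatin_dead, sum(dead))

    dna1 <- rln(ch$dna_singlet, n)
    dna2 <- rln(ch$dna_singlet, n)
    dbl <- qc == "doublet"
    dna1[dbl] <- 2 * rln(ch$dna_singlet, sum(dbl))
    dna2[dbl] <- 2 * rln(ch$dna_singlet, sum(dbl))
    debris <- qc == "debris"
    dna1[debris] <- rln(ch$dna_debris, sum(debris))
    dna2[debris] <- rln(ch$dna_debris, sum(debris))

    # lineage truth
    pos <- matrix(FALSE, n, length(.cytof_channels()),
                  dimnames = list(NULL, .cytof_channels()))
    pos[, "CD45"] <- subset != "CD45neg"
    pos[, "CD3"] <- subset %in% c("CD4", "CD8")
    pos[, "CD4"] <- subset == "CD4"
    pos[, "CD8"] <- subset == "CD8"
    pos[, "CD19"] <- subset == "CD19"
    pos[, "Ki67"] <- stats::runif(n) < cm$ki67[subset]

    is_b <- subset == "CD19"
    for (m in c("CD27", "IgD", "CD11b", "PDL1")) {
      p <- ifelse(is_b, cm$b_cell[[if (m == "PDL1") "PDL1" else m]], 0.02)
      pos[, m] <- stats::runif(n) < p
    }

    # checkpoint truth: Gaussian copula on T cells, background elsewhere
    cps <- checkpoint_markers()
    cp_truth <- matrix(FALSE, n, length(cps), dimnames = list(NULL, cps))
    z <- stats::rnorm(n)
    for (m in cps) {
      eps <- stats::rnorm(n)
      x <- cm$rho * z + sqrt(1 - cm$rho^2) * eps
      p <- rep(cm$checkpoint_background, n)
      for (tsub in c("CD4", "CD8")) {
        marg <- cm$checkpoint_marginals[[site]][[tsub]]
        p[subset == tsub] <- marg[[m]]
      }
      if (m == "PD1") p[is_b] <- cm$b_cell[["PD1"]]
      cp_truth[, m] <- x > stats::qnorm(1 - p)
    }
    pos[, cps] <- cp_truth
    # PD1 drives both the checkpoint channel and the B-cell modifier
    pos[, "PD1"] <- cp_truth[, "PD1"]

    intens <- sapply(colnames(pos), function(m) {
      v <- numeric(n)
      np <- sum(pos[, m])
      if (np > 0) v[pos[, m]] <- rln(ch$marker_positive, np)
      if (np < n) v[!pos[, m]] <- rln(ch$marker_negative, n - np)
      v
    })

    ev <- data.frame(
      sample_id = sample_id, event_id = sprintf("%s_e%05d", sample_id, seq_len(n)),
      site = site, bead = as.integer(qc == "bead"),
      residual = residual, center = center, offset = offset, width = width,
      event_length = event_length, cisplatin = cisplatin,
      DNA1 = dna1, DNA2 = dna2, stringsAsFactors = FALSE
    )
    ev <- cbind(ev, as.data.frame(intens))

    tr <- data.frame(
      sample_id = sample_id, event_id = ev$event_id, qc_class = qc,
      subset = subset, stringsAsFactors = FALSE
    )
    tr <- cbind(tr, as.data.frame(cp_truth))

    ev_list[[s]] <- ev; truth_list[[s]] <- tr
  }

  list(events = do.call(rbind, ev_list), truth = do.call(rbind, truth_list))
}
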
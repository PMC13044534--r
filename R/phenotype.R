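#' Phenotype scheme
#'
#' Maps per-cell marker positivity to one exclusive lineage label. Labels
#' are assigned by the first positive marker in precedence order, `"other"`
#' if none is positive; modifier markers (IL6, transcription factors) are
#' recorded independently of the lineage call. An optional double-positive
#' pair (e.g. CD4/CD8) is resolved to its own combined label before the
#' precedence rule.
#'
#' The default precedence CK19 > CD3 > CD19 > CD68 > aSMA puts epithelial
#' identity first (CK19 marks the malignant compartment) and immune
#' lineages before the stromal marker. Co-positivity resolution is a
#' package choice and fully configurable.
#'
#' @param precedence Lineage markers in decreasing precedence.
#' @param modifiers Modifier markers carried along (positivity columns must
#'   exist when summaries use them).
#' @param dp_pair Optional length-2 marker pair reported as a combined
#'   double-positive class (label `paste0(pair[1], pair[2])`).
#' @return List of class `phenotype_scheme`.
#' @export
phenotype_scheme <- function(precedence = c("CK19", "CD3", "CD19", "CD68", "aSMA"),
                             modifiers = "IL6", dp_pair = NULL) {
  if (anyDuplicated(precedence)) stop("precedence list has duplicates")
  if (!is.null(dp_pair)) stopifnot(length(dp_pair) == 2)
  structure(list(precedence = precedence, modifiers = modifiers,
                 dp_pair = dp_pair),
            class = "phenotype_scheme")
}

#' T-cell panel scheme
#'
#' CD4+, CD8+ and CD4+CD8+ double-positive T-cell lineages with
#' transcription-factor modifiers (T-bet, FoxP3, RORgt).
#' @return A [phenotype_scheme()].
#' @export
tcell_scheme <- function() {
  phenotype_scheme(precedence = c("CK19", "CD8", "CD4", "CD19", "CD68", "aSMA"),
                   modifiers = c("Tbet", "FoxP3", "RORgt"),
                   dp_pair = c("CD4", "CD8"))
}

#' Classes produced by a scheme (in reporting order)
#' @param scheme A [phenotype_scheme()].
#' @return Character vector of exclusive class labels including `"other"`.
#' @export
scheme_classes <- function(scheme) {
  cls <- scheme$precedence
  if (!is.null(scheme$dp_pair)) cls <- c(cls, paste0(scheme$dp_pair, collapse = ""))
  c(cls, "other")
}

#' Assign exclusive lineage labels
#'
#' @param positivity Cell table with logical `pos_<marker>` columns for all
#'   scheme markers.
#' @param scheme A [phenotype_scheme()].
#' @return The input with a `label` column (exclusive lineage) and, when
#'   aSMA and IL6 calls are present, a `caf_class` column splitting aSMA+
#'   cells into `"myCAF"` (aSMA+IL6-) and `"iCAF"` (aSMA+IL6+).
#' @export
assign_lineage <- function(positivity, scheme = phenotype_scheme()) {
  needed <- paste0("pos_", scheme$precedence)
  missing_m <- setdiff(needed, names(positivity))
  if (length(missing_m)) {
    stop("positivity columns missing for scheme markers: ",
         paste(sub("^pos_", "", missing_m), collapse = ", "))
  }
  n <- nrow(positivity)
  label <- rep("other", n)
  for (m in rev(scheme$precedence)) {
    label[positivity[[paste0("pos_", m)]]] <- m
  }
  if (!is.null(scheme$dp_pair)) {
    dp <- positivity[[paste0("pos_", scheme$dp_pair[1])]] &
      positivity[[paste0("pos_", scheme$dp_pair[2])]]
    label[dp] <- paste0(scheme$dp_pair, collapse = "")
  }
  positivity$label <- label
  if ("pos_aSMA" %in% names(positivity) && "pos_IL6" %in% names(positivity)) {
    positivity$caf_class <- ifelse(
      positivity$label == "aSMA",
      ifelse(positivity$pos_IL6, "iCAF", "myCAF"), NA_character_)
  }
  positivity
}

#' Occupancy-grid tissue area
#'
#' Reproducible surrogate for the imaged tissue area: the number of
#' `bin_um` x `bin_um` grid bins containing at least one cell, times the
#' bin area, in mm^2. The default 50 um bin is roughly two cell diameters.
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param bin_um Bin side length in um (default 50).
#' @return Area in mm^2.
#' @export
tissue_area <- function(cells, bin_um = 50) {
  if (!nrow(cells)) stop("empty cell table")
  stopifnot(bin_um > 0)
  bins <- unique(paste(floor(cells$x_um / bin_um), floor(cells$y_um / bin_um)))
  length(bins) * (bin_um / 1000)^2
}

#' Composition summary for one labeled sample
#'
#' Per-class counts, percentages of total cells, percentages of phenotyped
#' (non-`other`) cells, and densities per mm^2 of tissue; plus the
#' myCAF:iCAF ratio when CAF classes are present.
#'
#' @param labeled Output of [assign_lineage()] for a single sample.
#' @param area_mm2 Tissue area in mm^2 (> 0), e.g. from [tissue_area()].
#' @param classes Classes to report (default: observed labels, `"other"`
#'   last). Supplying the scheme's class list guarantees zero rows for
#'   absent classes.
#' @return List of class `composition_summary` with elements `classes`
#'   (data frame: class, count, pct_of_total, pct_of_phenotyped,
#'   density_mm2), `total_cells`, `area_mm2`, `mycaf_count`, `icaf_count`,
#'   and `mycaf_icaf_ratio` (`NA` when no iCAFs).
#' @export
composition_summary <- function(labeled, area_mm2, classes = NULL) {
  if (is.na(area_mm2) || area_mm2 <= 0) stop("tissue area must be > 0")
  if (is.null(classes)) {
    classes <- c(setdiff(sort(unique(labeled$label)), "other"), "other")
  }
  total <- nrow(labeled)
  counts <- as.integer(table(factor(labeled$label, levels = classes)))
  n_pheno <- total - sum(labeled$label == "other")
  df <- data.frame(
    class = classes, count = counts,
    pct_of_total = if (total > 0) 100 * counts / total else NA_real_,
    pct_of_phenotyped = if (n_pheno > 0)
      ifelse(classes == "other", NA_real_, 100 * counts / n_pheno)
    else NA_real_,
    density_mm2 = counts / area_mm2,
    stringsAsFactors = FALSE
  )
  mycaf <- icaf <- NA_integer_
  if (!is.null(labeled$caf_class)) {
    mycaf <- sum(labeled$caf_class == "myCAF", na.rm = TRUE)
    icaf <- sum(labeled$caf_class == "iCAF", na.rm = TRUE)
  }
  structure(
    list(classes = df, total_cells = total, area_mm2 = area_mm2,
         mycaf_count = mycaf, icaf_count = icaf,
         mycaf_icaf_ratio = if (!is.na(icaf) && icaf > 0) mycaf / icaf else NA_real_),
    class = "composition_summary"
  )
}

#' Cohort-wide composition in long format
#'
#' Applies [composition_summary()] per sample (tissue area from the
#' occupancy grid) and stacks the results for cohort-level statistics.
#'
#' @param labeled Labeled cell table for several samples (columns
#'   `sample_id`, `site`, coordinates, `label`).
#' @param classes Classes to report for every sample.
#' @param bin_um Occupancy-grid bin for [tissue_area()].
#' @return Long data frame: sample_id, site, class, count, pct_of_total,
#'   pct_of_phenotyped, density_mm2, plus per-sample myCAF/iCAF counts.
#' @export
cohort_composition <- function(labeled, classes, bin_um = 50) {
  out <- list()
  for (sid in unique(labeled$sample_id)) {
    sub <- labeled[labeled$sample_id == sid, , drop = FALSE]
    cs <- composition_summary(sub, tissue_area(sub, bin_um), classes)
    df <- cs$classes
    df$sample_id <- sid
    df$site <- sub$site[1]
    df$mycaf_count <- cs$mycaf_count
    df$icaf_count <- cs$icaf_count
    out[[sid]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample_id", "site", "class", "count", "pct_of_total",
          "pct_of_phenotyped", "density_mm2", "mycaf_count", "icaf_count")]
}

#' Collagen-positive area fraction of a stained section
#'
#' Percentage of tissue pixels above the signal threshold:
#' `100 * #(pixels > signal_threshold within tissue) / #(pixels > tissue_threshold)`.
#' Thresholds are fixed once per cohort and applied uniformly; the defaults
#' match the gray levels of the synthetic collagen generator.
#'
#' @param image Numeric pixel matrix.
#' @param signal_threshold Gray level above which a pixel counts as
#'   collagen-positive (default 120).
#' @param tissue_threshold Gray level above which a pixel counts as tissue
#'   (default 30).
#' @return Positive-area percentage of tissue (0-100).
#' @export
collagen_area_fraction <- function(image, signal_threshold = 120,
                                   tissue_threshold = 30) {
  tissue <- image > tissue_threshold
  n_tissue <- sum(tissue)
  if (n_tissue == 0) stop("no tissue pixels above the tissue threshold")
  100 * sum(image > signal_threshold & tissue) / n_tissue
}

#' Transcription-factor positivity per T-cell subset
#'
#' For each T-cell subset, the percentage of cells positive for each
#' transcription factor. Subsets with fewer than `min_count` cells are
#' reported as missing: small denominators (e.g. the scarce CD8
#' compartment of metastases) preclude a meaningful percentage.
#'
#' @param labeled Labeled cell table (T-cell scheme) with `pos_<tf>`
#'   columns.
#' @param tfs Transcription-factor markers.
#' @param subsets Subset labels to profile.
#' @param min_count Minimum subset size (default 25).
#' @return Data frame: subset, n, one percentage column per TF (`NA` when
#'   the subset is below `min_count`).
#' @export
tf_profile <- function(labeled, tfs = c("Tbet", "FoxP3", "RORgt"),
                       subsets = c("CD4", "CD8", "CD4CD8"), min_count = 25L) {
  rows <- lapply(subsets, function(sub) {
    cells <- labeled[labeled$label == sub, , drop = FALSE]
    n <- nrow(cells)
    pct <- vapply(tfs, function(tf) {
      col <- paste0("pos_", tf)
      if (n < min_count || !col %in% names(cells)) NA_real_
      else 100 * mean(cells[[col]])
    }, numeric(1))
    cbind(data.frame(subset = sub, n = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(pct)))
  })
  do.call(rbind, rows)
}
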
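#' Marker panel specification
#'
#' Describes how a multiplexed-imaging panel is gated: which markers it
#' carries, the intensity transform, an optional per-image percentile cap on
#' the gate, the control-based floor rule, and the minimum cell count per
#' image.
#'
#' @param name Panel name.
#' @param markers Character vector of marker ids.
#' @param transform `"none"` or `"arcsinh"`.
#' @param cofactor Arcsinh cofactor (default 150).
#' @param cap_percentile Optional percentile in (0, 100]; the final gate is
#'   capped at this percentile of each image's transformed intensities.
#' @param floor_rule See [floor_none()].
#' @param min_cells_per_image Images with fewer cells are excluded
#'   (default 500).
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(name, markers, transform = c("none", "arcsinh"),
                       cofactor = 150, cap_percentile = NULL,
                       floor_rule = floor_none(), min_cells_per_image = 500L) {
  transform <- match.arg(transform)
  stopifnot(length(markers) >= 1, cofactor > 0, min_cells_per_image >= 1)
  if (!is.null(cap_percentile)) {
    stopifnot(cap_percentile > 0, cap_percentile <= 100)
  }
  structure(list(name = name, markers = markers, transform = transform,
                 cofactor = cofactor, cap_percentile = cap_percentile,
                 floor_rule = floor_rule,
                 min_cells_per_image = as.integer(min_cells_per_image)),
            class = "panel_spec")
}

#' Built-in panels
#'
#' `caf_panel()`: the fibroblast panel (CK19, PDPLN, PDGFRb, aSMA).
#' Intensities are arcsinh-transformed (cofactor 150), gates are capped at
#' the 99th percentile of each image's transformed intensities and floored
#' by negative controls under per-marker false-positive-rate budgets
#' (PDPLN 5%, PDGFRb 10%, CK19 4%, aSMA 1%).
#'
#' `macrophage_panel()`: CD68, CCR2, CD163 on the raw intensity scale with a
#' background floor at the 99.5th percentile of unstained controls.
#'
#' @return A [panel_spec()].
#' @export
caf_panel <- function() {
  panel_spec(
    name = "caf",
    markers = c("CK19", "PDPLN", "PDGFRb", "aSMA"),
    transform = "arcsinh", cofactor = 150, cap_percentile = 99,
    floor_rule = floor_fpr_budget(
      c(PDPLN = 0.05, PDGFRb = 0.10, CK19 = 0.04, aSMA = 0.01))
  )
}

#' @rdname caf_panel
#' @export
macrophage_panel <- function() {
  panel_spec(
    name = "macrophage",
    markers = c("CD68", "CCR2", "CD163"),
    transform = "none",
    floor_rule = floor_fixed_percentile(99.5)
  )
}

.panel_transform <- function(panel) {
  if (panel$transform == "arcsinh") {
    cofactor <- panel$cofactor
    function(x) arcsinh_transform(x, cofactor)
  } else {
    identity
  }
}

#' Exclude images with too few cells
#'
#' Images with fewer than `min_cells` cells are excluded from gating and all
#' downstream analysis (the boundary count `min_cells` itself is retained).
#'
#' @param cells Cell table with an `image_id` column.
#' @param min_cells Minimum cell count (default 500).
#' @return List with `retained` (image ids) and `exclusions` (a log with
#'   one row per image: id, cell count, retained flag).
#' @export
qc_filter <- function(cells, min_cells = 500L) {
  stopifnot(min_cells >= 1)
  counts <- table(cells$image_id)
  log <- data.frame(image_id = names(counts),
                    n_cells = as.integer(counts),
                    retained = as.integer(counts) >= min_cells,
                    stringsAsFactors = FALSE)
  list(retained = log$image_id[log$retained], exclusions = log)
}

#' Build per-image, per-marker positivity gates
#'
#' For each retained image and panel marker: intensities are transformed per
#' the panel; the raw threshold is the exact two-class k-means threshold
#' unless the distribution is judged unimodal (see [is_unimodal()]), in
#' which case the median + 3 x MAD fallback is used; the cap is the panel's
#' percentile of the image's transformed intensities; the floor is
#' calibrated on the transformed controls; and the final threshold is
#' `min(max(raw, floor), cap)` with absent bounds ignored. Floors and caps
#' are the only control-based adjustment: there is no manual nudging (a
#' separate manual mode exists, see [manual_gates()]).
#'
#' @param cells Stained cell table (raw intensities, one column per marker).
#' @param controls Negative-control cell table; required when the panel has
#'   a floor rule.
#' @param panel A [panel_spec()].
#' @return Data frame of class `gate_set` with one row per retained image x
#'   marker: `image_id`, `marker`, `method` (kmeans / mad_fallback),
#'   `raw_threshold`, `floor_value`, `cap_value`, `final_threshold`.
#'   Attributes carry the transform, cofactor, panel name and the QC
#'   exclusion log.
#' @export
build_gates <- function(cells, controls = NULL, panel) {
  stopifnot(inherits(panel, "panel_spec"))
  if (panel$floor_rule$type != "none" && is.null(controls)) {
    stop("panel '", panel$name, "' requires negative controls for floor calibration")
  }
  missing_m <- setdiff(panel$markers, names(cells))
  if (length(missing_m)) stop("markers missing from cell table: ",
                              paste(missing_m, collapse = ", "))
  qc <- qc_filter(cells, panel$min_cells_per_image)
  cells <- cells[cells$image_id %in% qc$retained, , drop = FALSE]
  if (!nrow(cells)) stop("no image passed the cell-count filter")
  tf <- .panel_transform(panel)

  floors <- vapply(panel$markers, function(m) {
    if (panel$floor_rule$type == "none") return(NA_real_)
    calibrate_floor(tf(controls[[m]]), panel$floor_rule, m)
  }, numeric(1))

  rows <- list()
  for (img in unique(cells$image_id)) {
    idx <- cells$image_id == img
    if (sum(idx) < 2) stop("image ", img, " has fewer than 2 cells")
    for (m in panel$markers) {
      v <- tf(cells[[m]][idx])
      if (is_unimodal(v)) {
        raw <- mad_fallback_threshold(v)
        method <- "mad_fallback"
      } else {
        raw <- tryCatch(kmeans_threshold(v), tmequant_degenerate = function(e) NA_real_)
        method <- "kmeans"
        if (is.na(raw)) {
          raw <- mad_fallback_threshold(v)
          method <- "mad_fallback"
        }
      }
      cap <- if (is.null(panel$cap_percentile)) NA_real_ else
        quantile7(v, panel$cap_percentile / 100)
      fl <- floors[[m]]
      final <- raw
      if (!is.na(fl)) final <- max(final, fl)
      if (!is.na(cap)) final <- min(final, cap)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = img, marker = m, method = method,
        raw_threshold = raw, floor_value = fl, cap_value = cap,
        final_threshold = final, stringsAsFactors = FALSE)
    }
  }
  gates <- do.call(rbind, rows)
  structure(gates, class = c("gate_set", "data.frame"),
            transform = panel$transform, cofactor = panel$cofactor,
            panel = panel$name, qc = qc$exclusions)
}

#' Manual per-image gates (visual-cutoff workflow)
#'
#' Builds a gate set from fixed per-marker thresholds, reproducing the
#' multiplex-IHC workflow in which channel thresholds are set by visual
#' inspection and applied to every image.
#'
#' @param image_ids Images to gate.
#' @param thresholds Named numeric vector of per-marker thresholds, on the
#'   stated `transform` scale.
#' @param transform,cofactor Scale on which the thresholds are expressed.
#' @return A `gate_set` with method `"manual"`.
#' @export
manual_gates <- function(image_ids, thresholds,
                         transform = c("none", "arcsinh"), cofactor = 150) {
  transform <- match.arg(transform)
  if (is.null(names(thresholds))) stop("thresholds must be named by marker")
  g <- expand.grid(image_id = unique(image_ids), marker = names(thresholds),
                   stringsAsFactors = FALSE)
  g$method <- "manual"
  g$raw_threshold <- thresholds[g$marker]
  g$floor_value <- NA_real_
  g$cap_value <- NA_real_
  g$final_threshold <- g$raw_threshold
  structure(g, class = c("gate_set", "data.frame"),
            transform = transform, cofactor = cofactor,
            panel = "manual", qc = NULL)
}

#' Call per-cell marker positivity from a gate set
#'
#' A cell is positive for a marker iff its transformed intensity is strictly
#' greater than the image's final threshold; ties at the threshold are
#' negative, so in-sample control false-positive bounds hold exactly.
#'
#' @param cells Cell table (raw intensities).
#' @param gates A `gate_set` from [build_gates()] or [manual_gates()].
#' @param markers Markers to call (default: all markers in the gate set).
#' @return `cells` restricted to gated images, with one logical
#'   `pos_<marker>` column appended per marker.
#' @export
call_positivity <- function(cells, gates, markers = NULL) {
  stopifnot(inherits(gates, "gate_set"))
  if (is.null(markers)) markers <- unique(gates$marker)
  tf <- if (attr(gates, "transform") == "arcsinh") {
    cofactor <- attr(gates, "cofactor")
    function(x) arcsinh_transform(x, cofactor)
  } else identity

  cells <- cells[cells$image_id %in% unique(gates$image_id), , drop = FALSE]
  for (m in markers) {
    if (!m %in% names(cells)) stop("marker missing from cell table: ", m)
    thr_map <- gates$final_threshold[gates$marker == m]
    names(thr_map) <- gates$image_id[gates$marker == m]
    missing_img <- setdiff(unique(cells$image_id), names(thr_map))
    if (length(missing_img)) {
      stop("no gate for image ", missing_img[1], ", marker ", m)
    }
    cells[[paste0("pos_", m)]] <-
      tf(cells[[m]]) > unname(thr_map[cells$image_id])
  }
  cells
}

#' Manual thresholds matched to the generator's planted mixtures
#'
#' Convenience for synthetic cohorts: per-marker raw-scale thresholds at the
#' geometric midpoint between the negative and positive log-normal
#' locations, i.e. the log-scale valley of the planted mixture.
#'
#' @param config A [generator_config()].
#' @param markers Markers to threshold (default all imaging markers).
#' @return Named numeric vector of raw-intensity thresholds.
#' @export
mixture_midpoint_thresholds <- function(config, markers = imaging_markers()) {
  vapply(markers, function(m) {
    p <- .marker_params(config$intensity_model, m)
    exp((p$negative[["meanlog"]] + p$positive[["meanlog"]]) / 2)
  }, numeric(1))
}
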
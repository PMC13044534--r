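#' Assemble cohort report tables
#'
#' Collects the pipeline's per-figure-analog tables (composition by
#' sample, distance summaries, community memberships, structure
#' infiltration, CyTOF subsets and checkpoint combinations) and a run
#' manifest (configuration fingerprint, seed, exclusion logs). All outputs
#' are plain CSV plus a JSON manifest, written only when `out_dir` is
#' given. The manifest carries no timestamps so identical inputs produce
#' byte-identical reports.
#'
#' @param composition Long composition data frame ([cohort_composition()]).
#' @param spatial Optional list of spatial outputs (distance long table,
#'   community table, infiltration table).
#' @param cytof Optional list of CyTOF outputs (subset counts, combination
#'   frequencies, B-cell subsets).
#' @param stats Optional data frame of test results.
#' @param exclusions Optional named list of exclusion logs.
#' @param config Optional `generator_config` fingerprinted in the manifest.
#' @param seed Seed recorded in the manifest.
#' @param out_dir Output directory (created if needed); `NULL` = no files.
#' @return List of class `cohort_report` with `tables` and `manifest`.
#' @export
cohort_report <- function(composition = NULL, spatial = NULL, cytof = NULL,
                          stats = NULL, exclusions = NULL, config = NULL,
                          seed = NULL, out_dir = NULL) {
  tables <- list()
  if (!is.null(composition)) tables$composition <- composition
  for (nm in names(spatial)) tables[[paste0("spatial_", nm)]] <- spatial[[nm]]
  for (nm in names(cytof)) tables[[paste0("cytof_", nm)]] <- cytof[[nm]]
  if (!is.null(stats)) tables$stats <- stats
  if (!length(tables)) warning("empty report: no analysis outputs supplied")

  manifest <- list(
    package = "tmequant",
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else config_fingerprint(config),
    tables = lapply(tables, function(t) list(rows = nrow(t), cols = ncol(t))),
    exclusions = exclusions
  )
  manifest$manifest_hash <- config_fingerprint(manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(tables = tables, manifest = manifest), class = "cohort_report")
}

#' Deterministic content fingerprint
#'
#' Small polynomial rolling hash over the deparsed object, used to
#' fingerprint configurations and manifests. Not cryptographic; it only
#' needs to detect content changes deterministically.
#'
#' @param x Any R object.
#' @return Hex string.
#' @export
config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h1 <- 17; h2 <- 5381
  for (b in utf8ToInt(s)) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 33 + b) %% 1000000007
  }
  sprintf("%08x%08x", h1, h2)
}

#' Long-format distance table from a summary matrix
#' @param mat Distance matrix (reference rows, target columns).
#' @param site Site annotation.
#' @return Data frame: site, reference, target, distance_um.
#' @export
distance_long <- function(mat, site = NA_character_) {
  df <- expand.grid(reference = rownames(mat), target = colnames(mat),
                    stringsAsFactors = FALSE)
  df$distance_um <- mat[cbind(df$reference, df$target)]
  df$site <- site
  df[, c("site", "reference", "target", "distance_um")]
}
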
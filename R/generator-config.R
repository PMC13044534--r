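#' Default site composition profiles
#'
#' Phenotype composition profiles for primary and metastatic PDAC tissue used
#' by the synthetic-tissue generator. Each profile is a named fraction vector
#' over the seven planted cell classes (`CK19`, `aSMA`, `CD4T`, `CD8T`,
#' `CD19`, `CD68`, `other`) plus conditional modifier probabilities.
#'
#' The lineage fractions encode the central compositional contrast between
#' the two disease sites: a desmoplastic, fibroblast-rich primary tumor
#' (aSMA+ 25.5% of nucleated cells, CD8 T cells 7.99%, CD4 T cells 3.19%,
#' CD68+ macrophages 2.44%) versus a macrophage-rich, T-cell-poor metastasis
#' (aSMA+ 11.2%, CD8 0.90%, CD4 5.04%, CD68 8.29%). CD3 positivity is implied
#' by the two T-cell classes, so the planted CD3+ fraction is
#' `CD4T + CD8T`. Remaining mass is assigned to tumor cells (`CK19`) and
#' unphenotyped (`other`) cells at levels typical for tumor-rich sections.
#'
#' Modifier probabilities control IL6 co-expression (splitting aSMA+ CAFs
#' into myofibroblast-like aSMA+IL6- and inflammatory aSMA+IL6+ subsets,
#' with the myCAF:iCAF balance shifted toward myCAFs in metastases),
#' T-cell transcription factors (T-bet, FoxP3, RORgt; FoxP3/RORgt
#' predominant in primary CD4 T cells, T-bet elevated in metastatic ones),
#' and fibroblast/macrophage panel markers (PDPLN, PDGFRb, CCR2, CD163).
#'
#' @return Named list with elements `primary` and `metastatic`, each a list
#'   with `fractions` (sums to 1), `il6` (named by class, probability of
#'   IL6 positivity given the class), `tf_cd4`/`tf_cd8` (transcription-factor
#'   positivity given CD4/CD8 T-cell class), `caf_markers`
#'   (PDPLN/PDGFRb positivity given aSMA+), and `mac_markers`
#'   (CCR2/CD163 positivity given CD68+).
#' @export
default_site_profiles <- function() {
  list(
    primary = list(
      fractions = c(CK19 = 0.30, aSMA = 0.255, CD4T = 0.0319, CD8T = 0.0799,
                    CD19 = 0.005, CD68 = 0.0244, other = 0.3038),
      il6 = c(CK19 = 0.15, aSMA = 0.30, CD4T = 0.15, CD8T = 0.15,
              CD19 = 0.15, CD68 = 0.15, other = 0.10),
      tf_cd4 = c(Tbet = 0.25, FoxP3 = 0.35, RORgt = 0.30),
      tf_cd8 = c(Tbet = 0.50, FoxP3 = 0.05, RORgt = 0.05),
      caf_markers = c(PDPLN = 0.50, PDGFRb = 0.60),
      mac_markers = c(CCR2 = 0.50, CD163 = 0.40)
    ),
    metastatic = list(
      fractions = c(CK19 = 0.45, aSMA = 0.112, CD4T = 0.0504, CD8T = 0.009,
                    CD19 = 0.02, CD68 = 0.0829, other = 0.2757),
      il6 = c(CK19 = 0.15, aSMA = 0.15, CD4T = 0.15, CD8T = 0.15,
              CD19 = 0.15, CD68 = 0.15, other = 0.10),
      tf_cd4 = c(Tbet = 0.40, FoxP3 = 0.15, RORgt = 0.15),
      tf_cd8 = c(Tbet = 0.50, FoxP3 = 0.05, RORgt = 0.05),
      caf_markers = c(PDPLN = 0.50, PDGFRb = 0.60),
      mac_markers = c(CCR2 = 0.50, CD163 = 0.40)
    )
  )
}

#' Default two-component intensity model
#'
#' Per-marker fluorescence intensities are drawn from a two-component
#' log-normal mixture: a background (negative) component and a stained
#' (positive) component, in arbitrary fluorescence units. Log-normals are
#' used because fluorescence intensities are strictly positive and
#' right-skewed, which also makes the arcsinh compression used by the
#' gating layer meaningful.
#'
#' Defaults place the background at location `log(40)` (sdlog 0.35) and the
#' positive population at `log(600)` (sdlog 0.45), a separation of several
#' background SDs so that planted mixtures are resolvable by adaptive
#' thresholding.
#'
#' @param per_marker Optional named list of per-marker overrides, each a list
#'   with `negative` and `positive` components (`meanlog`, `sdlog`).
#' @return List with `negative`, `positive` (each `c(meanlog=, sdlog=)`) and
#'   `per_marker`.
#' @export
default_intensity_model <- function(per_marker = list()) {
  list(
    negative = c(meanlog = log(40), sdlog = 0.35),
    positive = c(meanlog = log(600), sdlog = 0.45),
    per_marker = per_marker
  )
}

#' Default spatial layout model
#'
#' Tumor (CK19+) cells are planted inside a small number of circular nests;
#' immune cells (T, B, macrophage) are placed in clusters around anchor
#' points preferentially located outside the nests, which plants both
#' detectable spatial communities and a stromal/marginal immune gradient.
#' Fibroblasts (aSMA+) are spread through the extranest stroma and `other`
#' cells uniformly across the field. Coordinates are micrometres with the
#' image convention: origin top-left, y increasing downward.
#'
#' @return List with `field_um` (width, height), `n_nests`,
#'   `nest_radius_um`, `attraction_radius_um` (immune community radius),
#'   `cells_per_anchor` (mean immune cluster size), and `stroma_bias`
#'   (probability that a fibroblast placed inside a nest is rejected and
#'   redrawn outside).
#' @export
default_spatial_model <- function() {
  list(
    field_um = c(2000, 2000),
    n_nests = 3L,
    nest_radius_um = 300,
    attraction_radius_um = 60,
    cells_per_anchor = 50,
    stroma_bias = 0.8
  )
}

#' Default mass-cytometry event model
#'
#' Events are a mixture of instrument/QC classes (normalization beads,
#' debris, doublets, cisplatin-high dead cells, merged ion clouds with
#' abnormal Gaussian width) and live intact singlets. Live cells are
#' assigned to one of five subsets (CD45-, other CD45+, CD4 T, CD8 T,
#' CD19 B). The five checkpoint channels (CTLA4, LAG3, PD1, TIGIT, TIM3)
#' on T cells follow a Gaussian-copula model: each cell carries a latent
#' "exhaustion" score and a marker is positive when its correlated normal
#' score exceeds the marginal quantile, so marginal positivities are
#' preserved exactly while co-expression exceeds independence whenever
#' `rho > 0`.
#'
#' Checkpoint marginals default to the site contrast observed on tumor
#' T cells: CD4 TIGIT 41.26%/38.38% and TIM3 31.98%/28.54%
#' (primary/metastatic), CD8 CTLA4 42.06%/60.07% and TIGIT 50.61%/62.84%.
#'
#' The merged-event fraction defaults to 1%: merged events are planted with
#' extreme Gaussian width, and the default 1st-99th percentile cleanup
#' window can only remove events above the empirical 99th percentile of a
#' channel, so the planted fraction is kept below that tail for the cleanup
#' stage to be able to remove essentially all of them.
#'
#' @return List describing event counts, QC-class fractions, subset
#'   fractions and checkpoint marginals per site, channel location/scale
#'   parameters, B-cell modifier probabilities, Ki67 rates and the copula
#'   co-expression strength `rho`.
#' @export
default_cytof_model <- function() {
  list(
    n_events_per_sample = 20000L,
    qc_fractions = c(bead = 0.02, debris = 0.04, doublet = 0.04,
                     dead = 0.10, merged = 0.01),
    subset_fractions = list(
      primary = c(CD45neg = 0.30, CD45other = 0.25, CD4 = 0.25,
                  CD8 = 0.15, CD19 = 0.05),
      metastatic = c(CD45neg = 0.35, CD45other = 0.30, CD4 = 0.20,
                     CD8 = 0.05, CD19 = 0.10)
    ),
    checkpoint_marginals = list(
      primary = list(
        CD4 = c(CTLA4 = 0.62, LAG3 = 0.55, PD1 = 0.60, TIGIT = 0.4126, TIM3 = 0.3198),
        CD8 = c(CTLA4 = 0.4206, LAG3 = 0.50, PD1 = 0.55, TIGIT = 0.5061, TIM3 = 0.25)
      ),
      metastatic = list(
        CD4 = c(CTLA4 = 0.65, LAG3 = 0.58, PD1 = 0.63, TIGIT = 0.3838, TIM3 = 0.2854),
        CD8 = c(CTLA4 = 0.6007, LAG3 = 0.45, PD1 = 0.60, TIGIT = 0.6284, TIM3 = 0.28)
      )
    ),
    checkpoint_background = 0.05,
    rho = 0.5,
    b_cell = c(CD27 = 0.15, IgD = 0.60, PD1 = 0.25, PDL1 = 0.20, CD11b = 0.05),
    ki67 = c(CD45neg = 0.10, CD45other = 0.10, CD4 = 0.20, CD8 = 0.25, CD19 = 0.15),
    channels = list(
      marker_negative = c(meanlog = log(2), sdlog = 0.5),
      marker_positive = c(meanlog = log(100), sdlog = 0.5),
      cisplatin_live = c(meanlog = log(5), sdlog = 0.5),
      cisplatin_dead = c(meanlog = log(200), sdlog = 0.4),
      dna_singlet = c(meanlog = log(300), sdlog = 0.10),
      dna_debris = c(meanlog = log(15), sdlog = 0.30),
      gaussian = c(meanlog = log(100), sdlog = 0.15),
      width = c(meanlog = log(50), sdlog = 0.15),
      width_merged = c(meanlog = log(150), sdlog = 0.10),
      event_length = c(meanlog = log(25), sdlog = 0.08)
    )
  )
}

#' Build a synthetic-cohort generator configuration
#'
#' Bundles and validates everything the synthetic-tissue and
#' mass-cytometry generators need: cohort sizes, per-site composition
#' profiles, the two-component intensity model, the spatial layout model,
#' per-site planted collagen area fractions, the CyTOF event model, and
#' the RNG seed. Defaults define the study conditions the rest of the
#' package is exercised under.
#'
#' @param n_samples_per_site Number of tissue samples (one image each) per
#'   disease site.
#' @param n_cells_per_image Cells per simulated image (default 10000).
#' @param site_profiles Named list of per-site composition profiles, see
#'   [default_site_profiles()].
#' @param intensity_model See [default_intensity_model()].
#' @param spatial_model See [default_spatial_model()].
#' @param collagen_model Named numeric, true collagen-positive area fraction
#'   of tissue per site. Primary PDAC is strongly desmoplastic, hence the
#'   higher default.
#' @param cytof_model See [default_cytof_model()].
#' @param seed Integer RNG seed; all generator draws derive from it.
#' @return Validated list of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_cells_per_image = 500, seed = 7)
#' names(cfg$site_profiles)
#' @export
generator_config <- function(n_samples_per_site = 2L,
                             n_cells_per_image = 10000L,
                             site_profiles = default_site_profiles(),
                             intensity_model = default_intensity_model(),
                             spatial_model = default_spatial_model(),
                             collagen_model = c(primary = 0.35, metastatic = 0.15),
                             cytof_model = default_cytof_model(),
                             seed = 1L) {
  stopifnot(n_samples_per_site >= 1, n_cells_per_image >= 1)
  if (!length(site_profiles) || is.null(names(site_profiles))) {
    stop("site_profiles must be a named list of site profiles")
  }
  for (site in names(site_profiles)) {
    pr <- site_profiles[[site]]
    f <- pr$fractions
    if (abs(sum(f) - 1) > 1e-9) {
      stop("phenotype fractions for site '", site, "' must sum to 1")
    }
    if (any(f < 0 | f > 1)) {
      stop("phenotype fractions for site '", site, "' must lie in [0, 1]")
    }
    probs <- c(pr$il6, pr$tf_cd4, pr$tf_cd8, pr$caf_markers, pr$mac_markers)
    if (any(probs < 0 | probs > 1)) {
      stop("modifier probabilities for site '", site, "' must lie in [0, 1]")
    }
  }
  im <- intensity_model
  if (im$negative[["meanlog"]] >= im$positive[["meanlog"]]) {
    stop("negative-population location must lie below positive-population location")
  }
  for (m in names(im$per_marker)) {
    pm <- im$per_marker[[m]]
    if (pm$negative[["meanlog"]] >= pm$positive[["meanlog"]]) {
      stop("negative-population location must lie below positive-population location (marker ", m, ")")
    }
  }
  sm <- spatial_model
  if (any(sm$field_um <= 0)) stop("field dimensions must be > 0")
  if (sm$nest_radius_um >= min(sm$field_um)) {
    stop("nest radius must be smaller than the field")
  }
  if (any(collagen_model < 0 | collagen_model > 1)) {
    stop("collagen area fractions must lie in [0, 1]")
  }
  for (site in names(cytof_model$subset_fractions)) {
    sf <- cytof_model$subset_fractions[[site]]
    if (any(sf < 0)) stop("CyTOF subset fractions must be non-negative")
    if (abs(sum(sf) - 1) > 1e-9) stop("CyTOF subset fractions must sum to 1")
  }
  if (any(cytof_model$qc_fractions < 0) || sum(cytof_model$qc_fractions) > 1) {
    stop("CyTOF QC-class fractions must be non-negative and sum to at most 1")
  }
  structure(
    list(
      n_samples_per_site = as.integer(n_samples_per_site),
      n_cells_per_image = as.integer(n_cells_per_image),
      site_profiles = site_profiles,
      intensity_model = intensity_model,
      spatial_model = spatial_model,
      collagen_model = collagen_model,
      cytof_model = cytof_model,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Deterministic sub-seed for a named generator operation: mixes the base
# seed with the operation/site tag so repeated calls with the same config
# reproduce byte-identical output while distinct operations decorrelate.
derive_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% 1999999973
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Imaging marker channels emitted by the tissue generator
#' @return Character vector of marker channel names.
#' @export
imaging_markers <- function() {
  c("CK19", "aSMA", "CD3", "CD4", "CD8", "CD19", "CD68", "IL6",
    "PDPLN", "PDGFRb", "CCR2", "CD163", "Tbet", "FoxP3", "RORgt")
}
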
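# Shared configuration for the analysis workflow. Sourced by every
# numbered script so the whole workflow runs under one set of study
# conditions and one seed.
library(tmequant)

cfg <- generator_config(
  n_samples_per_site = 3L,
  n_cells_per_image = 10000L,
  seed = 1234L
)
sites <- names(cfg$site_profiles)

res_dir <- function(...) {
  p <- file.path("results", ...)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  p
}
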
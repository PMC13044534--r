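test_that("degenerate all-tumor profile yields pure CK19 truth and positive intensities", {
  profiles <- default_site_profiles()
  profiles$pure <- profiles$primary
  profiles$pure$fractions <- c(CK19 = 1, aSMA = 0, CD4T = 0, CD8T = 0,
                               CD19 = 0, CD68 = 0, other = 0)
  cfg <- generator_config(n_cells_per_image = 300, n_samples_per_site = 1,
                          site_profiles = profiles, seed = 3)
  tt <- gen_tissue(cfg, "pure")
  expect_true(all(tt$truth$cells$label == "CK19"))
  expect_equal(unname(tt$truth$composition[[1]]), c(1, 0, 0, 0, 0, 0, 0))
  # every CK19 intensity from the positive component: all far above background
  neg_hi <- exp(cfg$intensity_model$negative[["meanlog"]] +
                  5 * cfg$intensity_model$negative[["sdlog"]])
  expect_gt(median(tt$cells$CK19), neg_hi)
})

test_that("empirical truth label frequencies track the planted profile", {
  cfg <- small_config(seed = 11, n_cells = 10000)
  for (site in c("primary", "metastatic")) {
    tt <- gen_tissue(cfg, site)
    planted <- cfg$site_profiles[[site]]$fractions
    emp <- table(factor(tt$truth$cells$label, levels = names(planted))) /
      nrow(tt$truth$cells)
    expect_true(all(abs(as.numeric(emp) - planted) <= 0.01),
                info = site)
    # truth composition equals empirical label frequencies exactly
    expect_equal(unname(tt$truth$composition[[1]]), as.numeric(emp))
  }
})

test_that("generator rejects unknown sites and impossible nest geometry", {
  cfg <- small_config()
  expect_error(gen_tissue(cfg, "liver"), "unknown site")
  sm <- default_spatial_model()
  sm$nest_radius_um <- 5000
  expect_error(generator_config(spatial_model = sm), "nest radius")
  expect_error(generator_config(collagen_model = c(primary = 1.2)), "collagen")
})

test_that("generation is deterministic for identical config and seed", {
  cfg <- small_config(seed = 21, n_cells = 800, n_events = 1500)
  expect_identical(gen_tissue(cfg, "primary"), gen_tissue(cfg, "primary"))
  expect_identical(gen_cytof(cfg, "metastatic"), gen_cytof(cfg, "metastatic"))
  expect_identical(gen_collagen_image(cfg, "primary"),
                   gen_collagen_image(cfg, "primary"))
  expect_identical(gen_control(cfg, 500), gen_control(cfg, 500))
})

test_that("negative controls are background-only and well separated from signal", {
  cfg <- small_config(seed = 5)
  expect_error(gen_control(cfg, 0), "n_cells")
  small <- gen_control(cfg, 5)
  expect_equal(nrow(small), 5)
  expect_true(all(small$site == "control"))
  ctrl <- gen_control(cfg, 20000)
  for (m in c("CD68", "aSMA", "CK19")) {
    q995 <- quantile(ctrl[[m]], 0.995, type = 7)
    expect_true(is.finite(q995))
    expect_gt(q995, median(ctrl[[m]]))
  }
  # stained positive population location sits above the control 99.9th pct
  q999 <- quantile(ctrl$CD68, 0.999, type = 7)
  expect_gt(exp(cfg$intensity_model$positive[["meanlog"]]), q999)
})

test_that("collagen images realize the planted positive-area fraction", {
  cfg <- small_config(seed = 9)
  img0 <- gen_collagen_image(cfg, "primary", truth_fraction = 0)
  tissue0 <- img0$image > 30
  expect_equal(sum(img0$image > 120 & tissue0), 0)
  img5 <- gen_collagen_image(cfg, "primary", truth_fraction = 0.5)
  frac <- sum(img5$image > 120 & img5$image > 30) / sum(img5$image > 30)
  expect_lt(abs(frac - 0.5), 0.005)
  img1 <- gen_collagen_image(cfg, "primary", truth_fraction = 1)
  tissue1 <- img1$image > 30
  expect_true(all(img1$image[tissue1] > 120))
  expect_error(gen_collagen_image(cfg, "primary", truth_fraction = 1.5),
               "\\[0, 1\\]")
})

test_that("planted tumor nests concentrate CK19 cells below the CSR expectation", {
  cfg <- small_config(seed = 13, n_cells = 10000)
  tt <- gen_tissue(cfg, "primary")
  ck <- tt$cells[tt$truth$cells$label == "CK19", ]
  ds <- min_distance_matrix(cbind(ck, label = "CK19"), "CK19")
  lambda <- nrow(ck) / prod(cfg$spatial_model$field_um)
  csr_mean_nn <- 0.5 / sqrt(lambda)
  expect_lt(ds$median["CK19", "CK19"], csr_mean_nn)
})

test_that("CyTOF generator plants viability, co-expression and marginals as configured", {
  cfg <- small_config(seed = 17, n_events = 50000)
  # all-dead sample: everything cisplatin-high, nothing survives the gate
  cm <- cfg$cytof_model
  cm$qc_fractions <- c(bead = 0, debris = 0, doublet = 0, dead = 1, merged = 0)
  cm$n_events_per_sample <- 2000L
  cfg_dead <- generator_config(n_samples_per_site = 1, n_cells_per_image = 100,
                               cytof_model = cm, seed = 17)
  cy_dead <- gen_cytof(cfg_dead, "primary")
  g <- default_cytof_gates(cfg_dead)
  expect_equal(nrow(live_singlet_gate(cy_dead$events, g$cisplatin_cut, g$dna_box)), 0)

  # zero co-expression strength: joint positivity factorizes
  cm0 <- cfg$cytof_model
  cm0$rho <- 0
  cm0$n_events_per_sample <- 50000L
  cfg0 <- generator_config(n_samples_per_site = 1, n_cells_per_image = 100,
                           cytof_model = cm0, seed = 19)
  cy0 <- gen_cytof(cfg0, "primary")
  t4 <- cy0$truth[cy0$truth$subset == "CD4", ]
  p_joint <- mean(t4$CTLA4 & t4$PD1)
  p_prod <- mean(t4$CTLA4) * mean(t4$PD1)
  expect_lt(abs(p_joint - p_prod), 0.012)

  # default rho > 0: positive dependence and preserved marginals
  cy <- gen_cytof(cfg, "primary")
  t4 <- cy$truth[cy$truth$subset == "CD4", ]
  expect_gt(mean(t4$CTLA4 & t4$LAG3 & t4$PD1),
            mean(t4$CTLA4) * mean(t4$LAG3) * mean(t4$PD1))
  marg <- cfg$cytof_model$checkpoint_marginals$primary$CD4
  for (m in checkpoint_markers()) {
    expect_lt(abs(mean(t4[[m]]) - marg[[m]]), 0.02)
  }
  expect_error(gen_cytof(cfg, "lung"), "unknown site")
})
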
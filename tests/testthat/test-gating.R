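test_that("arcsinh transform matches its closed form and is monotone", {
  expect_equal(arcsinh_transform(0, 150), 0)
  expect_equal(arcsinh_transform(150, 150), log(1 + sqrt(2)))
  set.seed(1)
  x <- sort(runif(50, 0, 5000))
  expect_true(all(diff(arcsinh_transform(x, 150)) > 0))
  expect_error(arcsinh_transform(1, 0), "cofactor")
  expect_error(arcsinh_transform(1, -3), "cofactor")
})

test_that("k-means threshold solves simple splits and errors on constants", {
  expect_equal(kmeans_threshold(c(0, 0, 0, 10, 10, 10)), 5)
  expect_equal(kmeans_threshold(c(1, 2)), 1.5)
  expect_error(kmeans_threshold(rep(4, 10)), class = "tmequant_degenerate")
})

test_that("k-means threshold equals the exhaustive variance-minimizing split", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(50:2000, 1)
    x <- switch(1 + i %% 3,
      c(rnorm(round(n / 2), 1, 0.2), rnorm(n - round(n / 2), 5, 0.5)),
      rlnorm(n, 1, 0.6),
      c(rexp(round(n * 0.9), 1), rnorm(n - round(n * 0.9), 12, 1)))
    expect_equal(kmeans_threshold(x), oracle_split_threshold(x))
  }
  # classification by threshold equals nearest-center classification
  x <- c(rnorm(500, 1, 0.2), rnorm(500, 5, 0.5))
  thr <- kmeans_threshold(x)
  xs <- sort(x)
  k <- sum(xs <= thr)
  m1 <- mean(xs[1:k]); m2 <- mean(xs[(k + 1):length(xs)])
  expect_identical(x > thr, abs(x - m2) < abs(x - m1))
})

test_that("MAD fallback threshold matches hand computations", {
  expect_equal(mad_fallback_threshold(1:9), 11)
  expect_equal(mad_fallback_threshold(rep(3.2, 5)), 3.2)
  # sparse positives: MAD collapses and the threshold equals the median
  expect_equal(mad_fallback_threshold(c(0, 0, 0, 0, 100)), 0)
  expect_error(mad_fallback_threshold(numeric(0)), "empty")
})

test_that("unimodality decision separates single-mode from well-split samples", {
  set.seed(7)
  expect_true(is_unimodal(rnorm(1000)))
  expect_true(is_unimodal(asinh(rlnorm(1000, log(40), 0.35) / 150)))
  expect_false(is_unimodal(c(rnorm(500, 0, 1), rnorm(500, 10, 1))))
  expect_false(is_unimodal(c(rnorm(500, 0, 1), rnorm(500, 4, 1))))
  expect_true(is_unimodal(rep(2, 50)))
  # minor-mode clause: sub-1% cluster is not trusted as a mode
  expect_true(is_unimodal(c(rnorm(2000, 0, 1), rnorm(10, 10, 0.5))))
})

test_that("floor calibration honors FPR budgets by order statistics", {
  ctrl <- 1:1000
  fl <- calibrate_floor(ctrl, floor_fpr_budget(c(PDPLN = 0.05)), "PDPLN")
  expect_equal(fl, 950)  # the 950th order statistic
  expect_equal(sum(ctrl > fl), 50)
  # type-7 interpolation on {1..200} at the 99.5th percentile
  expect_equal(calibrate_floor(1:200, floor_fixed_percentile(99.5)), 199.005)
  expect_equal(calibrate_floor(rep(7, 30), floor_fpr_budget(c(m = 0.01)), "m"), 7)
  expect_error(calibrate_floor(1:10, floor_fpr_budget(c(a = 0.05)), "b"),
               "no FPR budget")
  # the strict-exceedance fraction never exceeds the budget, for any n
  set.seed(3)
  for (q in c(0.01, 0.04, 0.05, 0.10)) {
    for (n in c(123, 777, 1000, 5000)) {
      x <- rlnorm(n, 0, 1)
      fl <- calibrate_floor(x, floor_fpr_budget(c(m = q)), "m")
      expect_lte(mean(x > fl), q)
    }
  }
})

test_that("image QC retains exactly the images at or above the cell cutoff", {
  cells <- data.frame(image_id = rep(c("a", "b", "c"), c(499, 500, 501)))
  qc <- qc_filter(cells, 500)
  expect_setequal(qc$retained, c("b", "c"))
  expect_equal(qc$exclusions$retained, c(FALSE, TRUE, TRUE))
  expect_length(qc_filter(data.frame(image_id = character(0)), 500)$retained, 0)
  all_big <- data.frame(image_id = rep(c("a", "b"), each = 600))
  expect_setequal(qc_filter(all_big, 500)$retained, c("a", "b"))
})

test_that("gate building composes threshold, floor and cap as specified", {
  cfg <- small_config(seed = 23, n_cells = 4000)
  tt <- gen_tissue(cfg, "primary")
  ctrl <- gen_control(cfg, 20000)
  gates <- build_gates(tt$cells, ctrl, caf_panel())
  expect_s3_class(gates, "gate_set")
  expect_equal(nrow(gates), length(caf_panel()$markers))

  # bimodal marker with floor below and cap above: clipping is a no-op
  g_ck <- gates[gates$marker == "CK19", ]
  expect_equal(g_ck$method, "kmeans")
  expect_gt(g_ck$raw_threshold, g_ck$floor_value)
  expect_lt(g_ck$raw_threshold, g_ck$cap_value)
  expect_equal(g_ck$final_threshold, g_ck$raw_threshold)

  # pure-background image: floors bound the in-sample false-positive rate
  ctrl_img <- ctrl
  gates_bg <- build_gates(ctrl_img, ctrl, caf_panel())
  pos <- call_positivity(ctrl_img, gates_bg)
  budgets <- caf_panel()$floor_rule$budgets
  for (m in names(budgets)) {
    expect_lte(mean(pos[[paste0("pos_", m)]]), budgets[[m]], label = m)
    g <- gates_bg[gates_bg$marker == m, ]
    expect_gte(g$final_threshold, min(g$floor_value, g$cap_value))
  }

  # a cap percentile below the k-means threshold forces final = cap
  low_cap <- panel_spec("lowcap", "CK19", transform = "arcsinh",
                        cap_percentile = 40)
  g_cap <- build_gates(tt$cells, panel = low_cap)
  expect_equal(g_cap$final_threshold, g_cap$cap_value)
  expect_gt(g_cap$raw_threshold, g_cap$cap_value)

  expect_error(build_gates(tt$cells, controls = NULL, caf_panel()),
               "requires negative controls")
})

test_that("positivity calls are strict, recover planted fractions, and name missing gates", {
  # tie at the threshold is negative
  cells <- data.frame(cell_id = "c1", image_id = "i1", m = 5)
  g <- manual_gates("i1", c(m = 5))
  expect_false(call_positivity(cells, g)$pos_m)

  cfg <- small_config(seed = 29, n_cells = 10000)
  tt <- gen_tissue(cfg, "metastatic")  # CD68 planted at 8.29%
  gates <- build_gates(tt$cells, gen_control(cfg, 20000), macrophage_panel())
  pos <- call_positivity(tt$cells, gates, "CD68")
  planted <- mean(tt$truth$cells$label == "CD68")
  expect_lt(abs(mean(pos$pos_CD68) - planted), 0.02)

  # gating is invariant to cell order
  perm <- sample(nrow(tt$cells))
  gates_perm <- build_gates(tt$cells[perm, ], gen_control(cfg, 20000),
                            macrophage_panel())
  expect_equal(gates$final_threshold, gates_perm$final_threshold)

  # a gate set that covers the image for one marker but not another
  # fails loudly, naming the image and marker
  partial <- manual_gates(unique(tt$cells$image_id), c(CD68 = 100))
  extra <- manual_gates("elsewhere", c(CD163 = 100))
  mixed <- rbind(partial, extra)
  attr(mixed, "transform") <- "none"; attr(mixed, "cofactor") <- 150
  class(mixed) <- c("gate_set", "data.frame")
  expect_error(call_positivity(tt$cells, mixed),
               "no gate for image metastatic_01, marker CD163")
})
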
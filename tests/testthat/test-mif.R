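# Binary single-channel classification, subset rules, per-core composition.

test_that("both ruleset versions are mutually exclusive by enumeration", {
  expect_true(ruleset_mutually_exclusive(caf_binary_ruleset("without_CD90")))
  expect_true(ruleset_mutually_exclusive(caf_binary_ruleset("with_CD90")))
  # a deliberately overlapping ruleset is caught
  bad <- structure(list(rules = list(A = c(FAP = TRUE),
                                     B = c(FAP = TRUE, PDPN = TRUE)),
                        version = "bad"), class = "binary_ruleset")
  expect_false(ruleset_mutually_exclusive(bad))
})

test_that("marker calls: threshold tie is ON, zeros are OFF", {
  cells <- data.frame(FAP = c(5, 10, 20), aSMA = c(0, 0, 0))
  calls <- call_markers(cells, c(FAP = 10, aSMA = 10))
  expect_equal(unname(calls[, "FAP"]), c(FALSE, TRUE, TRUE))
  expect_true(all(!calls[, "aSMA"]))
  expect_error(call_markers(cells, c(PDPN = 1)), "lacks column")
})

test_that("published binary definitions classify canonical call vectors", {
  rs <- caf_binary_ruleset("without_CD90")
  v_s1 <- c(FAP = TRUE, aSMA = TRUE, FSP1 = FALSE, PDPN = TRUE)
  v_s5 <- c(FAP = TRUE, aSMA = FALSE, FSP1 = FALSE, PDPN = TRUE)
  v_s4 <- c(FAP = FALSE, aSMA = TRUE, FSP1 = FALSE, PDPN = FALSE)
  v_other <- c(FAP = TRUE, aSMA = TRUE, FSP1 = TRUE, PDPN = TRUE)
  expect_equal(classify_subset(v_s1, rs), "CAF-S1")
  expect_equal(classify_subset(v_s5, rs), "CAF-S5")
  expect_equal(classify_subset(v_s4, rs), "CAF-S4")
  expect_equal(classify_subset(v_other, rs), "other")
})

test_that("synthetic core is called with >= 95% accuracy at Otsu thresholds", {
  core <- generate_mif_core(n_cells = 2000, seed = 31)
  classified <- classify_cells(core$cells)
  stroma <- classified$compartment == "stroma"
  truth <- core$truth$labels[core$truth$labels != "tumour"]
  expect_gte(mean(classified$subset[stroma] == truth), 0.95)
})

test_that("planted 60/30/10 subset mixture is recovered within 3 points", {
  core <- generate_mif_core(n_cells = 1000,
                            subset_mix = c("CAF-S1" = 0.6, "CAF-S4" = 0.3,
                                           "CAF-S5" = 0.1),
                            seed = 32)
  # FSP1 is OFF in every planted cell here, so the pooled FSP1 channel is
  # unimodal and Otsu has no valley: use the model's analytic thresholds
  classified <- classify_cells(core$cells,
                               thresholds = mif_thresholds_from_model())
  pct <- subset_percentages(classified)
  expect_lt(abs(pct[["CAF-S1"]] - 60), 3)
  expect_lt(abs(pct[["CAF-S4"]] - 30), 3)
  expect_lt(abs(pct[["CAF-S5"]] - 10), 3)
  # composition closure: subsets + other account for every classified CAF
  expect_equal(pct[["CAF-S1"]] + pct[["CAF-S4"]] + pct[["CAF-S5"]] +
                 pct[["other"]], 100, tolerance = 1e-9)
})

test_that("single-subset core gives 100% and zero for the others", {
  core <- generate_mif_core(n_cells = 300,
                            subset_mix = c("CAF-S1" = 1), seed = 33)
  classified <- classify_cells(core$cells,
                               thresholds = mif_thresholds_from_model())
  pct <- subset_percentages(classified)
  # ~1.5% of cells hit a false FSP1-positive tail call and fall to "other"
  expect_gte(pct[["CAF-S1"]], 98)
  expect_equal(pct[["CAF-S1"]] + pct[["other"]], 100, tolerance = 1e-9)
  expect_equal(pct[["CAF-S4"]], 0)
  expect_equal(pct[["CAF-S5"]], 0)
})

test_that("a core with no CAF-marker-positive stromal cell is excluded", {
  cells <- data.frame(cell_id = c("a", "b"), core_id = "c0",
                      x = c(1, 2), y = c(1, 2),
                      FAP = c(1, 1), aSMA = c(1, 1), PDPN = c(1, 1),
                      FSP1 = c(1, 1), CD90 = c(1, 1),
                      compartment = "stroma")
  classified <- classify_cells(cells, thresholds = c(FAP = 100, aSMA = 100,
                                                     PDPN = 100, FSP1 = 100))
  expect_warning(expect_error(subset_percentages(classified),
                              "no core with classifiable"),
                 "excluded")
})

test_that("cells without a compartment are dropped with a message", {
  core <- generate_mif_core(n_cells = 100, seed = 34)
  core$cells$compartment[1:5] <- NA
  expect_message(classified <- classify_cells(core$cells), "5 cell")
  expect_equal(nrow(classified), nrow(core$cells) - 5)
})

test_that("dropping CD90 never changes a CAF-S4 call when CD90 is ON", {
  with_cd90 <- caf_binary_ruleset("with_CD90")
  without <- caf_binary_ruleset("without_CD90")
  markers <- c("FAP", "aSMA", "FSP1", "PDPN")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(markers)))
  colnames(grid) <- markers
  for (i in seq_len(nrow(grid))) {
    v <- c(unlist(grid[i, ]), CD90 = TRUE)
    s_with <- classify_subset(v, with_cd90)
    s_without <- classify_subset(v, without)
    expect_equal(s_with == "CAF-S4", s_without == "CAF-S4")
  }
})

test_that("stromal positivity percentage detects a planted PDPN difference", {
  # two NSCLC classes with different PDPN-positive subset loads
  sq <- generate_mif_core(n_cells = 800,
                          subset_mix = c("CAF-S1" = 0.45, "CAF-S4" = 0.2,
                                         "CAF-S5" = 0.35),
                          seed = 35, core_id = "squamous")
  ad <- generate_mif_core(n_cells = 800,
                          subset_mix = c("CAF-S1" = 0.15, "CAF-S4" = 0.75,
                                         "CAF-S5" = 0.10),
                          seed = 36, core_id = "adeno")
  th <- default_mif_thresholds(rbind(sq$cells, ad$cells))
  p_sq <- percent_positive_stroma(sq$cells, "PDPN", th[["PDPN"]])
  p_ad <- percent_positive_stroma(ad$cells, "PDPN", th[["PDPN"]])
  expect_gt(p_sq, p_ad)
  expect_true(p_sq >= 0 && p_sq <= 100)
  # degenerate bounds
  none <- data.frame(PDPN = c(1, 1), compartment = "stroma")
  expect_equal(percent_positive_stroma(none, "PDPN", 10), 0)
  half <- data.frame(PDPN = c(1, 100), compartment = "stroma")
  expect_equal(percent_positive_stroma(half, "PDPN", 10), 50)
})

test_that("Otsu threshold separates a clear two-component mixture", {
  set.seed(1)
  x <- c(rlnorm(500, 3, 0.3), rlnorm(500, 7, 0.3))
  th <- otsu_threshold(x)
  expect_gt(th, exp(4))
  expect_lt(th, exp(6.5))
})
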
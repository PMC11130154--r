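# SOM training, metacluster selection, ordinal subset labelling,
# composition analysis.

model <- intensity_model()
cfg <- default_gate_config(model)

pooled_cohort <- function(n_per_tissue, n_events, seed, tissues = NULL) {
  cohort <- generate_flow_cohort(n_per_tissue = n_per_tissue,
                                 n_events = n_events, seed = seed)
  if (!is.null(tissues)) {
    cohort <- cohort[vapply(cohort, function(s) s$events$tissue[1],
                            character(1)) %in% tissues]
  }
  down <- lapply(cohort, function(s) {
    ev <- s$events
    ev$truth <- s$truth$labels
    downsample_events(gate_fibroblasts(ev, cfg), cfg, seed = seed)
  })
  concatenate_samples(down)
}

test_that("single-population SOM centres on the population mean and stays
           inside the data cloud", {
  s <- generate_flow_sample(c("CAF-S1" = 1), n_events = 1000, seed = 1)
  som <- train_som(s$events, grid_shape = c(4, 4), seed = 1)
  X <- cafsubtypes:::som_scale(s$events, som$markers, som$center, som$scale)
  mu <- colMeans(X)
  winners <- sort(unique(som$node_assignment))
  w_count <- as.vector(table(som$node_assignment))
  # the occupancy-weighted codebook centroid matches the population mean;
  # individual nodes tile the (unit-variance) cloud rather than collapse
  centroid <- colSums(som$codebook[winners, , drop = FALSE] * w_count) /
    sum(w_count)
  expect_lt(sqrt(sum((centroid - mu)^2)), 0.1)
  expect_true(all(abs(som$codebook[winners, ]) < 4))
})

test_that("two well-separated populations are split with >= 99% purity", {
  s <- generate_flow_sample(c("CAF-S1" = 0.5, "CAF-S2" = 0.5),
                            n_events = 2000, seed = 2)
  som <- train_som(s$events, seed = 2)
  truth <- s$truth$labels
  purity <- sum(vapply(unique(som$node_assignment), function(nd) {
    max(table(truth[som$node_assignment == nd]))
  }, numeric(1))) / length(truth)
  expect_gte(purity, 0.99)
})

test_that("training preconditions are enforced", {
  s <- generate_flow_sample(c("CAF-S1" = 1), n_events = 50, seed = 1)
  expect_error(train_som(s$events, epochs = 0, seed = 1), "epochs")
  expect_error(train_som(s$events, grid_shape = c(10, 10), seed = 1),
               "grid too large")
})

test_that("metacluster recovers a planted two-population structure", {
  s <- generate_flow_sample(c("CAF-S1" = 0.5, "CAF-S2" = 0.5),
                            n_events = 2000, seed = 4)
  som <- train_som(s$events, seed = 4)
  meta <- metacluster(som)
  expect_equal(meta$k, 2L)
  # partition property: every event gets exactly one finite label
  expect_equal(length(meta$event_labels), nrow(s$events))
  expect_false(anyNA(meta$event_labels))
})

test_that("degenerate identical codebook yields k = 1 with a warning", {
  fake <- structure(list(
    codebook = matrix(0, 9, 7,
                      dimnames = list(NULL, caf_markers())),
    node_assignment = rep(1:9, length.out = 50),
    grid_shape = c(3, 3), markers = caf_markers(),
    center = rep(0, 7), scale = rep(1, 7)), class = "caf_som")
  expect_warning(meta <- metacluster(fake), "degenerate")
  expect_equal(meta$k, 1L)
})

test_that("clusters are labelled by their ordinal profiles", {
  # three pure populations clustered and matched back to their profiles
  s <- generate_flow_sample(c("CAF-S1" = 0.4, "CAF-S2" = 0.3,
                              "CAF-S4" = 0.3), n_events = 3000, seed = 5)
  fit <- caf_flowsom(s$events, seed = 5)
  expect_equal(fit$meta$k, 3L)
  got <- sort(unname(fit$assignment$cluster_subset))
  expect_equal(got, c("CAF-S1", "CAF-S2", "CAF-S4"))
  # per-event labels agree with generator truth almost everywhere
  expect_gt(mean(fit$subset_labels == s$truth$labels), 0.95)
})

test_that("a cluster equidistant between two profiles is unassigned", {
  s <- generate_flow_sample(c("CAF-S1" = 1), n_events = 600, seed = 6)
  dup <- caf_marker_profiles()[c("CAF-S1", "CAF-S1")]
  names(dup) <- c("A", "B")
  fit <- caf_flowsom(s$events, profiles = dup, seed = 6)
  expect_true(all(fit$assignment$cluster_subset == "unassigned"))
})

test_that("normalised expression matrix is bounded [0, 1] per marker", {
  pooled <- pooled_cohort(4, 700, seed = 7, tissues = "tumour")
  fit <- caf_flowsom(pooled, seed = 7)
  nm <- fit$assignment$normalised
  for (m in colnames(nm)) {
    if (length(unique(fit$assignment$mfi[, m])) >= 2) {
      expect_equal(min(nm[, m]), 0)
      expect_equal(max(nm[, m]), 1)
    }
  }
})

test_that("assignments are invariant to channel rescaling with the model", {
  s <- generate_flow_sample(c("CAF-S1" = 0.5, "CAF-S4" = 0.5),
                            n_events = 1500, seed = 8)
  fit1 <- caf_flowsom(s$events, seed = 8)
  scaled <- s$events
  scaled$FAP <- scaled$FAP * 10
  off <- setNames(numeric(7), caf_markers())
  off["FAP"] <- log(10)
  model10 <- intensity_model(log_offset = off)
  fit2 <- caf_flowsom(scaled, model = model10, seed = 8)
  expect_identical(fit1$meta$event_labels, fit2$meta$event_labels)
  expect_identical(fit1$assignment$cluster_subset,
                   fit2$assignment$cluster_subset)
})

test_that("cluster-to-truth agreement stays high across seeds (ARI >= 0.8)", {
  aris <- vapply(1:10, function(sd) {
    pooled <- pooled_cohort(3, 700, seed = 100 + sd, tissues = "tumour")
    fit <- caf_flowsom(pooled, seed = sd)
    adjusted_rand_index(fit$meta$event_labels, pooled$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.8))
})

test_that("predict() labels new events like the training events", {
  s <- generate_flow_sample(c("CAF-S1" = 0.5, "CAF-S2" = 0.5),
                            n_events = 1500, seed = 9)
  fit <- caf_flowsom(s$events, seed = 9)
  self <- predict(fit, s$events)
  expect_identical(self, fit$subset_labels)
  new <- generate_flow_sample(c("CAF-S1" = 1), n_events = 200, seed = 10)
  expect_gt(mean(predict(fit, new$events) == "CAF-S1"), 0.95)
})

test_that("composition sums to 100 over assigned events and finds the
           planted tissue effect", {
  cohort <- generate_flow_cohort(n_per_tissue = 8, n_events = 600, seed = 11)
  labels <- unlist(lapply(cohort, function(s) s$truth$labels),
                   use.names = FALSE)
  sample_ids <- unlist(lapply(cohort, function(s) s$events$sample_id),
                       use.names = FALSE)
  tissue <- unlist(lapply(cohort, function(s) s$events$tissue),
                   use.names = FALSE)
  keep <- !labels %in% c("EpCAM+", "CD45+", "CD31+", "dead")
  res <- subset_composition(labels[keep], sample_ids[keep], tissue[keep])
  sums <- rowSums(res$composition[, paste0("CAF-S", 1:5)])
  expect_true(all(abs(sums - 100) < 1e-9))
  cmp <- res$comparison
  expect_lt(cmp$p[cmp$subset == "CAF-S3"], 0.05)
})

test_that("single-subset sample composes to 100% and empty samples warn", {
  res <- subset_composition(rep("CAF-S1", 10), rep("s1", 10))
  expect_equal(res$composition[["CAF-S1"]], 100)
  expect_warning(
    res2 <- subset_composition(c(rep("CAF-S1", 5), rep("unassigned", 3)),
                               c(rep("a", 5), rep("b", 3))),
    "no assigned events")
  expect_equal(nrow(res2$composition), 1)
})
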
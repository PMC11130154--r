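## Unbiased subset discovery: batch self-organizing map on the pooled gated
## events, Ward metaclustering of the codebook with automatic k selection,
## then ordinal-profile labelling of the metaclusters as CAF-S1..S5.

## squared-distance nearest codebook node for each row of X
nearest_code <- function(X, codes) {
  d2 <- outer(rowSums(X^2), rowSums(codes^2), "+") - 2 * X %*% t(codes)
  max.col(-d2, ties.method = "first")
}

som_scale <- function(events, markers, center, scale) {
  X <- log(as.matrix(events[, markers, drop = FALSE]))
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Train a self-organizing map on pooled fibroblast events
#'
#' Log-transforms and z-scales the phenotype markers, then batch-trains a
#' rectangular SOM (via `class::batchSOM`) with a linearly shrinking
#' neighbourhood radius, one pass per epoch. Each event is assigned to its
#' nearest codebook node in the scaled space.
#'
#' @param pooled Pooled event table (positive marker intensities).
#' @param markers Markers used for clustering; defaults to the seven
#'   phenotype markers (lineage markers are never clustered on).
#' @param grid_shape SOM grid rows and columns (default 10 x 10).
#' @param epochs Number of batch passes (>= 1).
#' @param seed Integer seed (codebook initialisation samples events).
#' @return An object of class `caf_som`: `codebook` (nodes x markers, scaled
#'   space), `node_assignment`, `grid_shape`, `markers` and the scaling
#'   parameters.
#' @export
train_som <- function(pooled, markers = caf_markers(),
                      grid_shape = c(10, 10), epochs = 20, seed = NULL) {
  check_markers(pooled, markers)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  n_nodes <- prod(grid_shape)
  if (nrow(pooled) < n_nodes) {
    stop("grid too large: ", n_nodes, " nodes for ", nrow(pooled), " events",
         call. = FALSE)
  }
  if (any(as.matrix(pooled[, markers]) <= 0)) {
    stop("marker intensities must be positive for log scaling", call. = FALSE)
  }
  Xl <- log(as.matrix(pooled[, markers, drop = FALSE]))
  center <- colMeans(Xl)
  scale <- apply(Xl, 2, sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(Xl, 2, center), 2, scale, "/")

  grid <- class::somgrid(xdim = grid_shape[1], ydim = grid_shape[2],
                         topo = "rectangular")
  radii <- seq(max(grid_shape) / 2, 0.5, length.out = max(epochs, 2))
  if (epochs == 1) radii <- radii[1]
  som <- with_seed(seed, class::batchSOM(X, grid, radii))
  codes <- unname(as.matrix(som$codes))
  colnames(codes) <- markers
  structure(list(codebook = codes,
                 node_assignment = nearest_code(X, codes),
                 grid_shape = grid_shape, markers = markers,
                 center = center, scale = scale),
            class = "caf_som")
}

#' Metacluster SOM nodes with automatic cluster-count selection
#'
#' Ward (ward.D2) hierarchical clustering of the occupied codebook nodes.
#' The cluster count k is chosen without user input as the maximiser of the
#' mean silhouette width over `2..k_max`; events inherit the label of their
#' node. A degenerate codebook (all occupied nodes identical) yields k = 1
#' with a warning.
#'
#' @param som A `caf_som` from [train_som()].
#' @param k_max Largest k considered (>= 2, <= number of occupied nodes).
#' @return An object of class `caf_metacluster`: `k`, `node_to_cluster`
#'   (NA for empty nodes), `event_labels` and `quality_curve` (named mean
#'   silhouette per candidate k).
#' @export
metacluster <- function(som, k_max = 15) {
  stopifnot(inherits(som, "caf_som"))
  occupied <- sort(unique(som$node_assignment))
  nodes <- som$codebook[occupied, , drop = FALSE]
  node_to_cluster <- rep(NA_integer_, nrow(som$codebook))
  if (k_max < 2) stop("k_max must be >= 2", call. = FALSE)

  dn <- dist(nodes)
  if (max(dn) < 1e-10 || nrow(nodes) < 2) {
    warning("degenerate codebook: all occupied nodes identical; k = 1")
    node_to_cluster[occupied] <- 1L
    return(structure(list(k = 1L, node_to_cluster = node_to_cluster,
                          event_labels = node_to_cluster[som$node_assignment],
                          quality_curve = numeric(0)),
                     class = "caf_metacluster"))
  }
  k_hi <- min(k_max, nrow(nodes) - 1)
  hc <- hclust(dn, method = "ward.D2")
  ks <- 2:k_hi
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k)
    mean(cluster::silhouette(cl, dn)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  k <- ks[which.max(sil)]
  node_to_cluster[occupied] <- cutree(hc, k)
  structure(list(k = as.integer(k), node_to_cluster = node_to_cluster,
                 event_labels = node_to_cluster[som$node_assignment],
                 quality_curve = sil),
            class = "caf_metacluster")
}

## discretise a log-scale geometric MFI to the nearest ordinal level
nearest_level <- function(log_mfi, model, marker) {
  off <- if (marker %in% names(model$log_offset)) {
    model$log_offset[[marker]]
  } else 0
  lv <- ordinal_levels()
  lv[which.min(abs(model$log_means + off - log_mfi))]
}

#' Label metaclusters as CAF subsets by ordinal profile matching
#'
#' Each cluster's per-marker geometric MFI is discretised to the nearest
#' ordinal level of the intensity model, and the resulting level vector is
#' matched to the reference subset profiles by minimal L1 distance on the
#' ordinal score scale. A cluster equidistant from two profiles is reported
#' as `"unassigned"`.
#'
#' @param meta A `caf_metacluster` from [metacluster()].
#' @param pooled The pooled event table the SOM was trained on.
#' @param profiles Reference profiles, as [caf_marker_profiles()].
#' @param model The [intensity_model()] whose level means anchor the
#'   discretisation.
#' @return An object of class `caf_subset_assignment`: `cluster_subset`
#'   (named character), `mfi` (clusters x markers geometric MFIs), `levels`
#'   (discretised ordinal levels) and `normalised` (per-marker min-max
#'   normalised MFI matrix, in `[0, 1]` per marker).
#' @export
assign_subsets <- function(meta, pooled, profiles = caf_marker_profiles(),
                           model = intensity_model()) {
  stopifnot(inherits(meta, "caf_metacluster"))
  if (length(meta$event_labels) != nrow(pooled)) {
    stop("metaclustering and pooled table are inconsistent", call. = FALSE)
  }
  markers <- caf_markers()
  check_markers(pooled, markers)
  clusters <- sort(unique(meta$event_labels))
  mfi <- t(vapply(clusters, function(cl) {
    vapply(markers,
           function(m) geometric_mfi(pooled[[m]][meta$event_labels == cl]),
           numeric(1))
  }, numeric(length(markers))))
  rownames(mfi) <- clusters

  lvl <- matrix(NA_character_, nrow(mfi), ncol(mfi),
                dimnames = dimnames(mfi))
  for (i in seq_along(clusters)) {
    for (m in markers) lvl[i, m] <- nearest_level(log(mfi[i, m]), model, m)
  }

  sc <- level_scores()
  prof_scores <- t(vapply(profiles,
                          function(p) unname(sc[p$levels]),
                          numeric(length(markers))))
  colnames(prof_scores) <- markers
  subset_of <- vapply(seq_along(clusters), function(i) {
    cost <- rowSums(abs(sweep(prof_scores, 2, sc[lvl[i, ]])))
    best <- min(cost)
    winners <- names(cost)[cost <= best + 1e-9]
    if (length(winners) > 1) "unassigned" else winners
  }, character(1))
  names(subset_of) <- clusters

  rng <- apply(mfi, 2, range)
  denom <- rng[2, ] - rng[1, ]
  denom[denom == 0] <- 1
  normalised <- sweep(sweep(mfi, 2, rng[1, ]), 2, denom, "/")

  structure(list(cluster_subset = subset_of, mfi = mfi, levels = lvl,
                 normalised = normalised),
            class = "caf_subset_assignment")
}

#' Fit the full SOM subtyping model
#'
#' One-call fit: trains the SOM on the pooled gated events, metaclusters the
#' codebook with automatic k selection, and labels the metaclusters against
#' the reference subset profiles.
#'
#' @inheritParams train_som
#' @inheritParams metacluster
#' @inheritParams assign_subsets
#' @param events Pooled gated event table (typically the concatenation of
#'   downsampled samples).
#' @return An object of class `caf_flowsom` with components `som`, `meta`,
#'   `assignment`, `subset_labels` (per-event subset name) and the call.
#'   Methods: `print`, `summary`, `plot`, `predict`.
#' @export
caf_flowsom <- function(events, markers = caf_markers(),
                        grid_shape = c(10, 10), epochs = 20, k_max = 15,
                        profiles = caf_marker_profiles(),
                        model = intensity_model(), seed = NULL) {
  som <- train_som(events, markers, grid_shape, epochs, seed)
  meta <- metacluster(som, k_max)
  assignment <- assign_subsets(meta, events, profiles, model)
  labels <- assignment$cluster_subset[as.character(meta$event_labels)]
  structure(list(som = som, meta = meta, assignment = assignment,
                 subset_labels = unname(labels),
                 n_events = nrow(events), call = match.call()),
            class = "caf_flowsom")
}

#' @export
print.caf_flowsom <- function(x, ...) {
  cat("CAF subtyping fit (SOM + Ward metaclustering)\n")
  cat(sprintf("  events: %d   grid: %dx%d   selected k: %d\n",
              x$n_events, x$som$grid_shape[1], x$som$grid_shape[2], x$meta$k))
  tab <- table(x$subset_labels)
  cat("  subset sizes:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.caf_flowsom <- function(object, ...) {
  out <- list(k = object$meta$k,
              cluster_subset = object$assignment$cluster_subset,
              mfi = object$assignment$mfi,
              levels = object$assignment$levels,
              quality_curve = object$meta$quality_curve,
              subset_counts = table(object$subset_labels))
  class(out) <- "summary.caf_flowsom"
  out
}

#' @export
print.summary.caf_flowsom <- function(x, ...) {
  cat(sprintf("Selected metacluster count: %d\n", x$k))
  cat("\nCluster -> subset assignment:\n")
  print(x$cluster_subset)
  cat("\nPer-cluster geometric MFIs:\n")
  print(round(x$mfi, 1))
  cat("\nDiscretised ordinal levels:\n")
  print(x$levels)
  invisible(x)
}

#' @export
plot.caf_flowsom <- function(x, ...) {
  nm <- x$assignment$normalised
  subs <- x$assignment$cluster_subset
  graphics::image(seq_len(ncol(nm)), seq_len(nrow(nm)), t(nm),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Relative marker expression (normalised per marker)",
                  ...)
  graphics::axis(1, seq_len(ncol(nm)), colnames(nm), las = 2)
  graphics::axis(2, seq_len(nrow(nm)),
                 paste0(rownames(nm), ": ", subs), las = 1)
  invisible(x)
}

#' Predict subset labels for new events
#'
#' Scales `newdata` with the training parameters, maps each event to its
#' nearest codebook node and returns the subset label of the node's
#' metacluster.
#'
#' @param object A `caf_flowsom` fit.
#' @param newdata Event table with the fit's marker columns.
#' @param ... Unused.
#' @return Character vector of subset labels.
#' @export
predict.caf_flowsom <- function(object, newdata, ...) {
  som <- object$som
  check_markers(newdata, som$markers)
  X <- som_scale(newdata, som$markers, som$center, som$scale)
  nodes <- nearest_code(X, som$codebook)
  cl <- object$meta$node_to_cluster[nodes]
  ## an empty training node can be hit at predict time: fall back to the
  ## nearest occupied node
  if (anyNA(cl)) {
    occ <- which(!is.na(object$meta$node_to_cluster))
    na_idx <- which(is.na(cl))
    alt <- nearest_code(X[na_idx, , drop = FALSE],
                        som$codebook[occ, , drop = FALSE])
    cl[na_idx] <- object$meta$node_to_cluster[occ[alt]]
  }
  unname(object$assignment$cluster_subset[as.character(cl)])
}

#' Per-sample subset composition and tissue comparison
#'
#' Computes, per sample, the percentage of assigned events in each subset
#' (percentages over assigned events sum to 100; unassigned events are
#' reported separately). If `tissue` is supplied, each subset's per-sample
#' percentages are compared between tissues with Welch tests.
#'
#' @param labels Per-event subset labels (may include `"unassigned"`).
#' @param sample_ids Per-event sample identifiers.
#' @param tissue Optional per-event tissue labels (`"tumour"`/`"NCL"`).
#' @return List with `composition` (data frame, one row per sample) and, if
#'   `tissue` was given, `comparison` (per-subset Welch t and p).
#' @export
subset_composition <- function(labels, sample_ids, tissue = NULL) {
  stopifnot(length(labels) == length(sample_ids))
  samples <- unique(sample_ids)
  subsets <- setdiff(sort(unique(labels)), "unassigned")
  rows <- list()
  for (s in samples) {
    sel <- sample_ids == s
    assigned <- labels[sel & labels != "unassigned"]
    if (!length(assigned)) {
      warning("sample ", s, " has no assigned events; excluded")
      next
    }
    pct <- 100 * table(factor(assigned, levels = subsets)) / length(assigned)
    row <- data.frame(sample_id = s,
                      tissue = if (is.null(tissue)) NA_character_ else
                        tissue[sel][1],
                      unassigned_pct = 100 * mean(labels[sel] == "unassigned"),
                      stringsAsFactors = FALSE)
    for (su in subsets) row[[su]] <- unname(pct[su])
    rows[[s]] <- row
  }
  comp <- do.call(rbind, rows)
  rownames(comp) <- NULL
  out <- list(composition = comp)
  if (!is.null(tissue) && length(unique(comp$tissue)) == 2) {
    tiss <- unique(comp$tissue)
    cmp <- do.call(rbind, lapply(subsets, function(su) {
      a <- comp[[su]][comp$tissue == tiss[1]]
      b <- comp[[su]][comp$tissue == tiss[2]]
      cg <- compare_groups(a, b)
      data.frame(subset = su, t = cg$statistic, p = cg$p.value)
    }))
    out$comparison <- cmp
  }
  out
}
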
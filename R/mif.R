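## Rule-based phenotyping of multiplex-immunofluorescence cell tables:
## binary single-channel classifiers composed into a mutually exclusive
## subset ruleset, and per-core subset composition.

#' Binary CAF subset ruleset
#'
#' Composite classifier built from single-channel ON/OFF calls. Two versions
#' are available: `"without_CD90"` (the default; CD90 is ignored because its
#' staining is typically too sparse to classify on) and `"with_CD90"` (CD90
#' ON required for CAF-S1/S4 and OFF for CAF-S5). Mutual exclusivity of the
#' subset rules is verified at construction by exhaustive enumeration of all
#' call vectors.
#'
#' @param version `"without_CD90"` or `"with_CD90"`.
#' @return An object of class `binary_ruleset`: list of per-subset named
#'   logical requirement vectors (markers absent from a rule are ignored).
#' @export
caf_binary_ruleset <- function(version = c("without_CD90", "with_CD90")) {
  version <- match.arg(version)
  rules <- if (version == "without_CD90") {
    list(
      "CAF-S1" = c(FAP = TRUE, aSMA = TRUE, FSP1 = FALSE, PDPN = TRUE),
      "CAF-S4" = c(FAP = FALSE, aSMA = TRUE, FSP1 = FALSE, PDPN = FALSE),
      "CAF-S5" = c(FAP = TRUE, aSMA = FALSE, FSP1 = FALSE, PDPN = TRUE))
  } else {
    list(
      "CAF-S1" = c(FAP = TRUE, aSMA = TRUE, FSP1 = FALSE, CD90 = TRUE,
                   PDPN = TRUE),
      "CAF-S4" = c(FAP = FALSE, aSMA = TRUE, FSP1 = FALSE, CD90 = TRUE,
                   PDPN = FALSE),
      "CAF-S5" = c(FAP = TRUE, aSMA = FALSE, FSP1 = FALSE, CD90 = FALSE,
                   PDPN = TRUE))
  }
  obj <- structure(list(rules = rules, version = version),
                   class = "binary_ruleset")
  if (!ruleset_mutually_exclusive(obj)) {
    stop("ruleset is not mutually exclusive", call. = FALSE)    # nocov
  }
  obj
}

#' Verify mutual exclusivity of a binary ruleset by enumeration
#'
#' Enumerates every possible ON/OFF call vector over the markers the ruleset
#' uses and checks that no vector satisfies two subset rules.
#'
#' @param ruleset A [caf_binary_ruleset()].
#' @return `TRUE` if no call vector satisfies more than one rule.
#' @export
ruleset_mutually_exclusive <- function(ruleset) {
  markers <- unique(unlist(lapply(ruleset$rules, names)))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(markers)))
  colnames(grid) <- markers
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, , drop = TRUE])
    n_hit <- sum(vapply(ruleset$rules,
                        function(r) all(v[names(r)] == r), logical(1)))
    if (n_hit > 1) return(FALSE)
  }
  TRUE
}

#' Otsu threshold of an intensity distribution
#'
#' Global two-class threshold maximising between-class variance, computed on
#' the log scale (fluorescence mixtures are near-symmetric there) and
#' returned on the intensity scale.
#'
#' @param x Positive intensities.
#' @param n_bins Histogram bins.
#' @return Threshold intensity.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  stopifnot(all(x > 0))
  lx <- log(x)
  br <- seq(min(lx), max(lx), length.out = n_bins + 1)
  h <- hist(lx, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  exp(mids[which.max(sigma_b)])
}

#' Global per-marker MIF thresholds
#'
#' One threshold per marker, estimated by Otsu's criterion on the pooled
#' intensity distribution across all cells/cores (a single threshold applies
#' to the whole collection, not per core).
#'
#' @param cells MIF cell table.
#' @param markers Markers to threshold.
#' @return Named numeric vector of thresholds.
#' @export
default_mif_thresholds <- function(cells,
                                   markers = c("FAP", "aSMA", "PDPN",
                                               "FSP1", "CD90")) {
  check_markers(cells, markers)
  vapply(markers, function(m) otsu_threshold(cells[[m]]), numeric(1))
}

#' Model-based MIF thresholds
#'
#' Analytic alternative to [default_mif_thresholds()] for data whose
#' intensity scale is known: uses the intensity model's positivity
#' threshold for every marker. Preferable when a channel is not bimodal
#' across the collection (e.g. a marker OFF in every cell), where Otsu's
#' criterion has no valley to find.
#'
#' @param model An [intensity_model()].
#' @param markers Markers to threshold.
#' @return Named numeric vector of thresholds.
#' @export
mif_thresholds_from_model <- function(model = intensity_model(),
                                      markers = c("FAP", "aSMA", "PDPN",
                                                  "FSP1", "CD90")) {
  setNames(rep(model$positivity_threshold, length(markers)), markers)
}

#' Per-cell binary marker calls
#'
#' A marker is ON iff its intensity is at or above the marker's global
#' threshold.
#'
#' @param cells MIF cell table with per-marker intensity columns.
#' @param thresholds Named thresholds, one per marker to call.
#' @return Logical matrix, cells x markers.
#' @export
call_markers <- function(cells, thresholds) {
  check_markers(cells, names(thresholds))
  calls <- vapply(names(thresholds),
                  function(m) cells[[m]] >= thresholds[[m]],
                  logical(nrow(cells)))
  if (nrow(cells) == 1) calls <- matrix(calls, nrow = 1,
                                        dimnames = list(NULL,
                                                        names(thresholds)))
  calls
}

#' Classify call vectors into CAF subsets
#'
#' Returns, per cell, the unique subset whose rule the call vector satisfies,
#' or `"other"` when no rule matches (a vector can never match two rules, by
#' construction of the ruleset).
#'
#' @param calls Logical matrix from [call_markers()] covering the ruleset's
#'   markers.
#' @param ruleset A [caf_binary_ruleset()].
#' @return Character vector of subset labels.
#' @export
classify_subset <- function(calls, ruleset) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list(NULL, names(calls)))
  used <- unique(unlist(lapply(ruleset$rules, names)))
  missing_mk <- setdiff(used, colnames(calls))
  if (length(missing_mk)) {
    stop("call matrix lacks marker(s): ", paste(missing_mk, collapse = ", "),
         call. = FALSE)
  }
  out <- rep("other", nrow(calls))
  for (s in names(ruleset$rules)) {
    r <- ruleset$rules[[s]]
    hit <- rep(TRUE, nrow(calls))
    for (m in names(r)) hit <- hit & (calls[, m] == r[[m]])
    out[hit] <- s
  }
  out
}

#' Classify a MIF cell table end to end
#'
#' Convenience wrapper: derives (or takes) global thresholds, calls markers
#' and classifies each cell. Cells lacking a compartment are excluded with a
#' message.
#'
#' @param cells MIF cell table.
#' @param ruleset A [caf_binary_ruleset()].
#' @param thresholds Named thresholds; defaults to Otsu on the pooled table.
#' @return The cell table with added columns `subset` and per-marker call
#'   columns (`<marker>_on`).
#' @export
classify_cells <- function(cells, ruleset = caf_binary_ruleset(),
                           thresholds = NULL) {
  if ("compartment" %in% colnames(cells)) {
    bad <- is.na(cells$compartment)
    if (any(bad)) {
      message(sum(bad), " cell(s) lack a compartment; excluded")
      cells <- cells[!bad, , drop = FALSE]
    }
  }
  used <- unique(unlist(lapply(ruleset$rules, names)))
  if (is.null(thresholds)) {
    thresholds <- default_mif_thresholds(cells, markers = used)
  }
  calls <- call_markers(cells, thresholds[used])
  cells$subset <- classify_subset(calls, ruleset)
  for (m in used) cells[[paste0(m, "_on")]] <- calls[, m]
  attr(cells, "thresholds") <- thresholds
  cells
}

#' Per-core CAF subset percentages
#'
#' Restricted to the stromal compartment. The denominator ("total CAFs") is
#' the number of stromal cells ON for at least one CAF marker; numerators
#' are the cells classified into each subset, with the remainder reported as
#' `"other"`. Cores without any total CAF are excluded with a warning.
#'
#' @param cells Classified cell table from [classify_cells()].
#' @param ruleset The ruleset used for classification.
#' @return Data frame, one row per core: `core_id`, `n_caf`, one percentage
#'   column per subset and `other`.
#' @export
subset_percentages <- function(cells, ruleset = caf_binary_ruleset()) {
  stopifnot("subset" %in% colnames(cells))
  used <- unique(unlist(lapply(ruleset$rules, names)))
  on_cols <- paste0(used, "_on")
  check_markers(cells, on_cols)
  stroma <- cells[cells$compartment == "stroma", , drop = FALSE]
  rows <- list()
  for (core in unique(stroma$core_id)) {
    cc <- stroma[stroma$core_id == core, , drop = FALSE]
    is_caf <- rowSums(as.matrix(cc[, on_cols, drop = FALSE])) >= 1
    if (!any(is_caf)) {
      warning("core ", core, " has no cells positive for any CAF marker; ",
              "excluded")
      next
    }
    cafs <- cc[is_caf, , drop = FALSE]
    row <- data.frame(core_id = core, n_caf = nrow(cafs),
                      stringsAsFactors = FALSE)
    for (s in names(ruleset$rules)) {
      row[[s]] <- 100 * mean(cafs$subset == s)
    }
    row[["other"]] <- 100 * mean(cafs$subset == "other")
    rows[[core]] <- row
  }
  if (!length(rows)) {
    stop("no core with classifiable CAFs", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of stromal cells positive for one marker
#'
#' @param cells MIF cell table with a `compartment` column.
#' @param marker Marker column name.
#' @param threshold Global intensity threshold for the marker.
#' @return Percentage of stromal cells at or above the threshold.
#' @export
percent_positive_stroma <- function(cells, marker, threshold) {
  check_markers(cells, c(marker, "compartment"))
  stroma <- cells[cells$compartment == "stroma", , drop = FALSE]
  if (!nrow(stroma)) stop("no stromal cells", call. = FALSE)
  100 * mean(stroma[[marker]] >= threshold)
}
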
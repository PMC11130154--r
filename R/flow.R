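## Flow-cytometry preprocessing: gating to fibroblasts, positivity and
## high-expression percentages, geometric MFI, downsampling, concatenation.

#' Gating configuration
#'
#' Numeric thresholds replacing the visual isotype-control gates of manual
#' analysis. Ties at a threshold count as positive (>=) throughout the
#' package. A sample retaining fewer than `min_fibroblasts` events after
#' gating is excluded; retained samples are downsampled to `downsample_n`
#' events.
#'
#' @param positivity Named per-marker positivity thresholds (covering at
#'   least the lineage and phenotype markers in use).
#' @param high Named per-marker high-expression thresholds; each must be >=
#'   the marker's positivity threshold.
#' @param viability Viability-dye threshold; events at or above it are dead.
#' @param downsample_n Events kept per sample (default 300).
#' @param min_fibroblasts Minimum gated events for a sample to be analysed
#'   (default 300).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(positivity, high, viability,
                        downsample_n = 300, min_fibroblasts = 300) {
  if (any(positivity <= 0) || any(high <= 0) || viability <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  common <- intersect(names(positivity), names(high))
  if (any(high[common] < positivity[common])) {
    stop("high threshold below positivity threshold for: ",
         paste(common[high[common] < positivity[common]], collapse = ", "),
         call. = FALSE)
  }
  if (downsample_n > min_fibroblasts) {
    stop("downsample_n must not exceed min_fibroblasts", call. = FALSE)
  }
  structure(list(positivity = positivity, high = high, viability = viability,
                 downsample_n = downsample_n,
                 min_fibroblasts = min_fibroblasts),
            class = "gate_config")
}

#' Default gate configuration from an intensity model
#'
#' Uses the model's analytic positivity/high/viability thresholds for every
#' marker.
#'
#' @param model An [intensity_model()].
#' @inheritParams gate_config
#' @return A [gate_config()].
#' @export
default_gate_config <- function(model = intensity_model(),
                                downsample_n = 300, min_fibroblasts = 300) {
  mk <- c(lineage_markers(), caf_markers())
  gate_config(
    positivity = setNames(rep(model$positivity_threshold, length(mk)), mk),
    high = setNames(rep(model$high_threshold, length(mk)), mk),
    viability = model$viability_threshold,
    downsample_n = downsample_n, min_fibroblasts = min_fibroblasts)
}

#' Derive gate thresholds from negative-control events
#'
#' The standard isotype-control surrogate: per marker, the positivity
#' threshold is the 99th percentile of a designated negative-control
#' population; the high threshold is placed `high_factor`-fold above it on
#' the intensity scale.
#'
#' @param controls Event table of negative-control events (marker columns).
#' @param markers Markers to derive thresholds for.
#' @param q Quantile of the control distribution (default 0.99).
#' @param high_factor Multiplier taking positivity to high thresholds.
#' @param viability Viability threshold to carry over.
#' @inheritParams gate_config
#' @return A [gate_config()].
#' @export
gate_config_from_controls <- function(controls,
                                      markers = c(lineage_markers(),
                                                  caf_markers()),
                                      q = 0.99, high_factor = 10,
                                      viability = exp(4),
                                      downsample_n = 300,
                                      min_fibroblasts = 300) {
  missing_mk <- setdiff(markers, colnames(controls))
  if (length(missing_mk)) {
    stop("control table lacks marker column(s): ",
         paste(missing_mk, collapse = ", "), call. = FALSE)
  }
  pos <- vapply(markers, function(m) quantile(controls[[m]], q, names = FALSE),
                numeric(1))
  gate_config(positivity = pos, high = pos * high_factor,
              viability = viability,
              downsample_n = downsample_n, min_fibroblasts = min_fibroblasts)
}

check_markers <- function(events, markers) {
  missing_mk <- setdiff(markers, colnames(events))
  if (length(missing_mk)) {
    stop("event table lacks column(s): ", paste(missing_mk, collapse = ", "),
         call. = FALSE)
  }
}

#' Gate events to viable lineage-negative fibroblasts
#'
#' Keeps events that are viable (viability dye below its threshold) and below
#' the positivity threshold on each of CD45, EpCAM and CD31, excluding
#' haematopoietic, epithelial and endothelial cells. Row order is preserved;
#' the operation is idempotent.
#'
#' @param events Event table with `viability` and lineage marker columns.
#' @param cfg A [gate_config()].
#' @return The gated event table.
#' @export
gate_fibroblasts <- function(events, cfg) {
  check_markers(events, c("viability", lineage_markers()))
  keep <- events$viability < cfg$viability
  for (m in lineage_markers()) {
    keep <- keep & events[[m]] < cfg$positivity[[m]]
  }
  events[keep, , drop = FALSE]
}

#' Percentage of events positive or high for a marker
#'
#' `percent_positive()` uses the marker's positivity threshold,
#' `percent_high()` its high-expression threshold; an intensity exactly at
#' the threshold counts as positive/high.
#'
#' @param events Non-empty event table.
#' @param marker Marker column name.
#' @param cfg A [gate_config()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(events, marker, cfg) {
  check_markers(events, marker)
  if (nrow(events) == 0) {
    stop("percentage undefined on an empty event table", call. = FALSE)
  }
  100 * mean(events[[marker]] >= cfg$positivity[[marker]])
}

#' @rdname percent_positive
#' @export
percent_high <- function(events, marker, cfg) {
  check_markers(events, marker)
  if (nrow(events) == 0) {
    stop("percentage undefined on an empty event table", call. = FALSE)
  }
  100 * mean(events[[marker]] >= cfg$high[[marker]])
}

#' Geometric mean fluorescence intensity
#'
#' @param values Positive intensities.
#' @return `exp(mean(log(values)))`.
#' @export
geometric_mfi <- function(values) {
  if (!length(values) || any(values <= 0)) {
    stop("geometric MFI requires a non-empty vector of positive values",
         call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Downsample a gated sample to a fixed number of events
#'
#' Uniform sampling without replacement to `cfg$downsample_n` rows. A sample
#' with fewer than `cfg$min_fibroblasts` events raises a condition of class
#' `caf_sample_excluded`, signalling that the caller should drop the sample.
#'
#' @param events Gated event table.
#' @param cfg A [gate_config()].
#' @param seed Integer seed making the draw reproducible.
#' @return Event table with exactly `cfg$downsample_n` rows.
#' @export
downsample_events <- function(events, cfg, seed = NULL) {
  n <- nrow(events)
  if (n < cfg$min_fibroblasts) {
    stop(structure(class = c("caf_sample_excluded", "error", "condition"),
                   list(message = sprintf(
                     "sample excluded: %d fibroblasts < required %d",
                     n, cfg$min_fibroblasts), call = sys.call(-1))))
  }
  if (n == cfg$downsample_n) return(events)
  with_seed(seed, events[sort(sample.int(n, cfg$downsample_n)), ,
                         drop = FALSE])
}

#' Concatenate per-sample event tables
#'
#' Row-stacks tables that share an identical column set, retaining sample and
#' tissue labels.
#'
#' @param samples List of event tables.
#' @return One combined event table.
#' @export
concatenate_samples <- function(samples) {
  if (!length(samples)) stop("no samples to concatenate", call. = FALSE)
  cols <- colnames(samples[[1]])
  for (s in samples) {
    if (!identical(colnames(s), cols)) {
      stop("samples have mismatched columns", call. = FALSE)
    }
  }
  out <- do.call(rbind, samples)
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparison
#'
#' Unpaired unequal-variance t-test, the default group comparison for
#' per-sample marker statistics.
#'
#' @param values_a,values_b Numeric vectors with >= 2 values each.
#' @return List with `statistic` (t) and `p.value` (two-sided).
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    ## degenerate: both groups constant, t.test cannot run
    if (mean(values_a) == mean(values_b)) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = sign(mean(values_a) - mean(values_b)) * Inf,
                p.value = 0))
  }
  ht <- t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
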
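#' @importFrom stats rlnorm rexp rnbinom rgamma runif rmultinom median quantile
#'   sd setNames aggregate hclust cutree dist p.adjust pnorm t.test wilcox.test
#'   complete.cases
NULL

## Marker vocabularies used across all modalities -----------------------------

#' Marker and level vocabularies
#'
#' `caf_markers()` returns the seven fibroblast-activation phenotyping markers;
#' `lineage_markers()` the exclusion markers used to gate out epithelial,
#' haematopoietic and endothelial cells; `ordinal_levels()` the six ordered
#' expression levels used in subset profiles, lowest first.
#'
#' @return A character vector.
#' @export
caf_markers <- function() {
  c("FAP", "CD29", "aSMA", "PDPN", "CD90", "FSP1", "PDGFRb")
}

#' @rdname caf_markers
#' @export
lineage_markers <- function() {
  c("EpCAM", "CD45", "CD31")
}

#' @rdname caf_markers
#' @export
ordinal_levels <- function() {
  c("Neg", "Neg-Low", "Low", "Med", "Med-High", "High")
}

## Numeric scores for ordinal levels. Hyphenated levels sit midway between
## their parent levels, so L1 profile distances treat "Neg-Low" as halfway
## between "Neg" and "Low".
level_scores <- function() {
  c("Neg" = 0, "Neg-Low" = 0.5, "Low" = 1,
    "Med" = 2, "Med-High" = 2.5, "High" = 3)
}

#' Construct an ordinal marker profile for one CAF subset
#'
#' A marker profile assigns exactly one ordinal expression level to each of
#' the seven CAF phenotyping markers. The five default subset profiles are
#' available from [caf_marker_profiles()].
#'
#' @param subset_name One of `"CAF-S1" ... "CAF-S5"` (other names are allowed
#'   for custom populations).
#' @param levels Named character vector mapping every marker in
#'   [caf_markers()] to a level in [ordinal_levels()].
#' @return An object of class `marker_profile`.
#' @export
marker_profile <- function(subset_name, levels) {
  mk <- caf_markers()
  if (!all(mk %in% names(levels)) || length(levels) != length(mk)) {
    stop("profile for ", subset_name, " must assign a level to each of: ",
         paste(mk, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(levels), mk)
  if (length(extra)) {
    stop("unknown marker(s) in profile: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unname(levels), ordinal_levels())
  if (length(bad)) {
    stop("unknown ordinal level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(subset_name = subset_name, levels = levels[mk]),
            class = "marker_profile")
}

#' Default CAF subset marker profiles
#'
#' The five CAF subsets are defined by ordinal expression levels of FAP, CD29,
#' alpha-SMA, PDPN, CD90, FSP1 and PDGFR-beta. CAF-S1 is the FAP-high
#' myofibroblast-like subset; CAF-S2 and CAF-S3 are quiescent-like, low-marker
#' populations; CAF-S4 is FAP-negative but contractile (alpha-SMA+); CAF-S5
#' expresses FAP and PDPN but lacks alpha-SMA.
#'
#' @return Named list of [marker_profile()] objects, one per subset.
#' @export
caf_marker_profiles <- function() {
  list(
    "CAF-S1" = marker_profile("CAF-S1", c(
      FAP = "High", CD29 = "Med-High", aSMA = "High", PDPN = "High",
      CD90 = "Med-High", FSP1 = "Low", PDGFRb = "Med")),
    "CAF-S2" = marker_profile("CAF-S2", c(
      FAP = "Neg", CD29 = "Neg-Low", aSMA = "Neg", PDPN = "Neg",
      CD90 = "Neg", FSP1 = "Neg", PDGFRb = "Neg")),
    "CAF-S3" = marker_profile("CAF-S3", c(
      FAP = "Low", CD29 = "Med", aSMA = "Neg-Low", PDPN = "Low",
      CD90 = "Low", FSP1 = "High", PDGFRb = "Low")),
    "CAF-S4" = marker_profile("CAF-S4", c(
      FAP = "Neg-Low", CD29 = "High", aSMA = "Med", PDPN = "Neg",
      CD90 = "Med-High", FSP1 = "Neg", PDGFRb = "Med-High")),
    "CAF-S5" = marker_profile("CAF-S5", c(
      FAP = "Med", CD29 = "Med", aSMA = "Neg-Low", PDPN = "Med",
      CD90 = "Low", FSP1 = "Low", PDGFRb = "Med"))
  )
}

## Intensity model -------------------------------------------------------------

#' Log-normal fluorescence intensity model
#'
#' Maps each ordinal expression level to a log-normal intensity distribution
#' (arbitrary fluorescence units). Log-means must increase strictly with the
#' level so that adjacent levels remain statistically separable; the default
#' spacing keeps the Bayes error between adjacent levels below 0.15 at
#' `log_sd = 0.3`.
#'
#' @param log_means Named numeric vector of log-scale means, one per ordinal
#'   level, strictly increasing from `"Neg"` to `"High"`.
#' @param log_sd Common log-scale standard deviation.
#' @param positivity_threshold Intensity above which a marker counts positive.
#' @param high_threshold Intensity above which expression counts high.
#' @param viability_threshold Intensity of the viability dye below which an
#'   event counts as live.
#' @param log_offset Optional named per-marker additive shift on the log scale
#'   (defaults to 0 for every marker); supports rescaled acquisition channels.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(log_means = c("Neg" = 3.0, "Neg-Low" = 3.65,
                                          "Low" = 4.3, "Med" = 5.6,
                                          "Med-High" = 6.25, "High" = 6.9),
                            log_sd = 0.3,
                            positivity_threshold = exp(3.65),
                            high_threshold = exp(6.25),
                            viability_threshold = exp(4.0),
                            log_offset = NULL) {
  lv <- ordinal_levels()
  if (!identical(sort(names(log_means)), sort(lv))) {
    stop("log_means must name every ordinal level", call. = FALSE)
  }
  log_means <- log_means[lv]
  if (any(diff(log_means) <= 0)) {
    stop("log_means must increase strictly from Neg to High", call. = FALSE)
  }
  if (log_sd <= 0) stop("log_sd must be positive", call. = FALSE)
  if (positivity_threshold <= 0 || high_threshold < positivity_threshold) {
    stop("need 0 < positivity_threshold <= high_threshold", call. = FALSE)
  }
  if (is.null(log_offset)) {
    log_offset <- setNames(numeric(length(caf_markers())), caf_markers())
  }
  structure(list(log_means = log_means, log_sd = log_sd,
                 positivity_threshold = positivity_threshold,
                 high_threshold = high_threshold,
                 viability_threshold = viability_threshold,
                 log_offset = log_offset),
            class = "intensity_model")
}

## Bayes error between two adjacent levels (equal priors, equal sd normals on
## the log scale): Phi(-delta / (2 sd)).
adjacent_level_bayes_error <- function(model) {
  d <- diff(model$log_means)
  stats::pnorm(-d / (2 * model$log_sd))
}

## Draw intensities for one marker at a given ordinal level.
draw_level_intensity <- function(n, level, model, marker = NULL) {
  off <- 0
  if (!is.null(marker) && marker %in% names(model$log_offset)) {
    off <- model$log_offset[[marker]]
  }
  rlnorm(n, meanlog = model$log_means[[level]] + off, sdlog = model$log_sd)
}
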
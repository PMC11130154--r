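## Synthetic inputs with planted ground truth for every pipeline stage.
## All randomness is routed through with_seed(): the global RNG state is
## saved and restored, so generators are pure functions of their arguments.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

## log-scale means of the viability dye for live and dead events
.VIABILITY_LIVE_LOGMEAN <- 2.0
.VIABILITY_DEAD_LOGMEAN <- 6.0

.CONTAMINANTS <- c("EpCAM+", "CD45+", "CD31+", "dead")

#' Simulate one flow-cytometry sample with planted subset labels
#'
#' Draws `n_events` single-cell events as a mixture of CAF subsets (each
#' marker sampled from the log-normal distribution of the subset's ordinal
#' level) plus optional lineage-positive contaminants and dead cells.
#' Fibroblast events are viable and negative for EpCAM/CD45/CD31; each
#' contaminant class is high for its lineage marker.
#'
#' @param mixture Named fractions over subset names in `profiles` (may be
#'   empty). Together with `contamination` the fractions must not exceed 1;
#'   they are renormalised to 1 if they fall short.
#' @param n_events Number of events to draw (>= 1).
#' @param contamination Named fractions over
#'   `"EpCAM+", "CD45+", "CD31+", "dead"`.
#' @param profiles List of [marker_profile()] objects, as
#'   [caf_marker_profiles()].
#' @param model [intensity_model()] translating ordinal levels to intensities.
#' @param sample_id,tissue Metadata stamped on every event; `tissue` is
#'   `"tumour"` or `"NCL"`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List with `events` (data.frame: `sample_id`, `tissue`, `viability`,
#'   lineage and phenotype marker intensities) and `truth` (per-event label
#'   plus requested proportions).
#' @export
generate_flow_sample <- function(mixture, n_events,
                                 contamination = numeric(),
                                 profiles = caf_marker_profiles(),
                                 model = intensity_model(),
                                 sample_id = "sample1", tissue = "tumour",
                                 seed = NULL) {
  stopifnot(n_events >= 1)
  mixture <- unlist(mixture)
  contamination <- unlist(contamination)
  if (length(mixture)) {
    unknown <- setdiff(names(mixture), names(profiles))
    if (length(unknown)) {
      stop("mixture names not found among profiles: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (length(contamination)) {
    unknown <- setdiff(names(contamination), .CONTAMINANTS)
    if (length(unknown)) {
      stop("unknown contaminant class(es): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  w <- c(mixture, contamination)
  if (!length(w) || any(w < 0)) {
    stop("mixture and contamination fractions must be non-negative and ",
         "non-empty", call. = FALSE)
  }
  if (sum(w) > 1 + 1e-8) {
    stop("invalid mixture: fractions sum to ", signif(sum(w), 4), " > 1",
         call. = FALSE)
  }
  w <- w / sum(w)

  with_seed(seed, {
    counts <- as.vector(rmultinom(1, n_events, w))
    names(counts) <- names(w)
    labels <- rep(names(counts), counts)

    mk <- caf_markers()
    lin <- lineage_markers()
    m <- matrix(NA_real_, nrow = n_events, ncol = 1 + length(lin) + length(mk),
                dimnames = list(NULL, c("viability", lin, mk)))
    row0 <- 0
    for (cls in names(counts)) {
      n <- counts[[cls]]
      if (n == 0) next
      idx <- row0 + seq_len(n)
      row0 <- row0 + n
      if (cls %in% names(profiles)) {
        prof <- profiles[[cls]]
        m[idx, "viability"] <- rlnorm(n, .VIABILITY_LIVE_LOGMEAN, model$log_sd)
        for (l in lin) m[idx, l] <- draw_level_intensity(n, "Neg", model)
        for (mkr in mk) {
          m[idx, mkr] <- draw_level_intensity(n, prof$levels[[mkr]], model, mkr)
        }
      } else if (cls == "dead") {
        m[idx, "viability"] <- rlnorm(n, .VIABILITY_DEAD_LOGMEAN, model$log_sd)
        for (l in lin) m[idx, l] <- draw_level_intensity(n, "Neg", model)
        for (mkr in mk) m[idx, mkr] <- draw_level_intensity(n, "Neg", model, mkr)
      } else {
        pos <- sub("\\+$", "", cls)
        m[idx, "viability"] <- rlnorm(n, .VIABILITY_LIVE_LOGMEAN, model$log_sd)
        for (l in lin) {
          m[idx, l] <- draw_level_intensity(n, if (l == pos) "High" else "Neg",
                                            model)
        }
        for (mkr in mk) m[idx, mkr] <- draw_level_intensity(n, "Neg", model, mkr)
      }
    }
    ord <- sample.int(n_events)
    events <- data.frame(sample_id = sample_id, tissue = tissue,
                         m[ord, , drop = FALSE],
                         stringsAsFactors = FALSE, check.names = FALSE)
    list(events = events,
         truth = list(labels = labels[ord], proportions = w))
  })
}

## Dirichlet draw via normalised gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a flow-cytometry cohort of tumour and adjacent-lung samples
#'
#' Generates paired tumour and non-cancerous lung (NCL) samples whose subset
#' mixtures vary around tissue-specific base compositions (Dirichlet
#' resampling). Defaults enrich CAF-S1/S4/S5 in tumour and CAF-S3 in NCL,
#' the compositional contrast the downstream comparison is designed to
#' detect.
#'
#' @param n_per_tissue Samples per tissue (default 14 each).
#' @param n_events Events per sample before gating.
#' @param base_tumour,base_ncl Named base subset fractions (summed to the
#'   fibroblast share of each sample).
#' @param concentration Dirichlet concentration controlling inter-sample
#'   variability (larger = less variable).
#' @param contamination Named contaminant fractions shared by all samples.
#' @param profiles,model,seed As in [generate_flow_sample()].
#' @return List of per-sample results as returned by
#'   [generate_flow_sample()]; names encode tissue and index.
#' @export
generate_flow_cohort <- function(n_per_tissue = 14, n_events = 2000,
                                 base_tumour = c("CAF-S1" = 0.28,
                                                 "CAF-S2" = 0.10,
                                                 "CAF-S3" = 0.07,
                                                 "CAF-S4" = 0.30,
                                                 "CAF-S5" = 0.25),
                                 base_ncl = c("CAF-S1" = 0.07,
                                              "CAF-S2" = 0.25,
                                              "CAF-S3" = 0.45,
                                              "CAF-S4" = 0.11,
                                              "CAF-S5" = 0.12),
                                 concentration = 60,
                                 contamination = c("EpCAM+" = 0.05,
                                                   "CD45+" = 0.10,
                                                   "CD31+" = 0.05,
                                                   "dead" = 0.05),
                                 profiles = caf_marker_profiles(),
                                 model = intensity_model(),
                                 seed = NULL) {
  stopifnot(n_per_tissue >= 1)
  fib_share <- 1 - sum(contamination)
  with_seed(seed, {
    out <- list()
    for (tis in c("tumour", "NCL")) {
      base <- if (tis == "tumour") base_tumour else base_ncl
      base <- base / sum(base)
      for (i in seq_len(n_per_tissue)) {
        mix <- rdirichlet1(concentration * base) * fib_share
        names(mix) <- names(base)
        id <- sprintf("%s_%02d", tis, i)
        out[[id]] <- generate_flow_sample(
          mixture = mix, n_events = n_events, contamination = contamination,
          profiles = profiles, model = model,
          sample_id = id, tissue = tis,
          seed = sample.int(.Machine$integer.max, 1))
      }
    }
    out
  })
}

## Binary ON/OFF staining profiles used on tissue sections (full five-marker
## version; CD90 is ON for CAF-S1/S4 and OFF for CAF-S5).
mif_truth_profiles <- function() {
  list(
    "CAF-S1" = c(FAP = TRUE, aSMA = TRUE, PDPN = TRUE, CD90 = TRUE,
                 FSP1 = FALSE),
    "CAF-S4" = c(FAP = FALSE, aSMA = TRUE, PDPN = FALSE, CD90 = TRUE,
                 FSP1 = FALSE),
    "CAF-S5" = c(FAP = TRUE, aSMA = FALSE, PDPN = TRUE, CD90 = FALSE,
                 FSP1 = FALSE),
    "other" = c(FAP = FALSE, aSMA = FALSE, PDPN = FALSE, CD90 = FALSE,
                FSP1 = TRUE)
  )
}

#' Regular polygon approximating a disc
#'
#' @param center Numeric length-2 centre (micrometres).
#' @param radius Radius in micrometres.
#' @param n Number of vertices.
#' @return A two-column matrix of vertex coordinates (open ring).
#' @export
disc_polygon <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

region_spec_to_polygons <- function(region_spec) {
  if (!length(region_spec)) stop("region list must be non-empty", call. = FALSE)
  lapply(region_spec, function(r) {
    if (is.matrix(r)) return(r)
    if (identical(r$type, "disc")) {
      return(disc_polygon(r$center, r$radius, if (is.null(r$n)) 64L else r$n))
    }
    if (identical(r$type, "polygon")) return(as.matrix(r$coords))
    stop("region must be a matrix, disc or polygon spec", call. = FALSE)
  })
}

default_region_spec <- function() {
  list(list(type = "disc", center = c(300, 300), radius = 150),
       list(type = "disc", center = c(700, 650), radius = 150))
}

#' Simulate a segmented multiplex-immunofluorescence tissue core
#'
#' Places tumour cells (PanCK+) uniformly inside the tumour regions and
#' stromal cells outside them, with each stromal subset's distance to the
#' nearest tumour region drawn from an exponential kernel. Kernel scales
#' follow `distance_order` (near to far), so median distances increase along
#' that list. ON markers draw from the model's "High" level and OFF markers
#' from "Neg".
#'
#' @param region_spec List of tumour regions: matrices of polygon vertices or
#'   `list(type = "disc", center =, radius =)` specs (micrometres).
#' @param n_cells Number of stromal cells (>= 1).
#' @param subset_mix Named fractions over `CAF-S1`, `CAF-S4`, `CAF-S5`,
#'   `other`.
#' @param distance_order Subset names ordered nearest-first.
#' @param distance_scales Exponential scale (micrometres) for each entry of
#'   `distance_order`; subsets not listed use `other_scale`.
#' @param other_scale Scale for subsets absent from `distance_order`.
#' @param n_tumour_cells Tumour-compartment cells to place inside regions.
#' @param frame Width and height of the core frame in micrometres.
#' @param model,seed As in [generate_flow_sample()].
#' @param core_id Identifier stamped on cells and regions.
#' @return List with `cells` (data.frame: `cell_id`, `core_id`, `x`, `y`,
#'   PanCK/FAP/aSMA/PDPN/FSP1/CD90 intensities, `compartment`), `regions`
#'   (list of polygon matrices) and `truth` (labels and exact distances).
#' @export
generate_mif_core <- function(region_spec = default_region_spec(),
                              n_cells = 3000,
                              subset_mix = c("CAF-S1" = 0.35, "CAF-S4" = 0.40,
                                             "CAF-S5" = 0.20, "other" = 0.05),
                              distance_order = c("CAF-S4", "CAF-S1", "CAF-S5"),
                              distance_scales = c(15, 40, 90),
                              other_scale = 60,
                              n_tumour_cells = round(0.3 * n_cells),
                              frame = c(1000, 1000),
                              model = intensity_model(),
                              seed = NULL, core_id = "core1") {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  regions <- region_spec_to_polygons(region_spec)
  subset_mix <- subset_mix / sum(subset_mix)
  profs <- mif_truth_profiles()
  unknown <- setdiff(names(subset_mix), names(profs))
  if (length(unknown)) {
    stop("unknown subset(s) in mix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  scales <- setNames(rep(other_scale, length(subset_mix)), names(subset_mix))
  scales[distance_order] <- distance_scales[seq_along(distance_order)]

  with_seed(seed, {
    ## quick coverage check: regions must leave stroma inside the frame
    px <- runif(2000, 0, frame[1]); py <- runif(2000, 0, frame[2])
    if (all(distance_to_nearest_tumour(px, py, regions) == 0)) {
      stop("tumour regions cover the whole frame: no stroma to populate",
           call. = FALSE)
    }

    counts <- as.vector(rmultinom(1, n_cells, subset_mix))
    names(counts) <- names(subset_mix)

    place_stromal <- function(n, scale) {
      xs <- numeric(0); ys <- numeric(0); ds <- numeric(0)
      tries <- 0
      while (length(xs) < n) {
        tries <- tries + 1
        if (tries > 400) {
          stop("unable to place stromal cells outside tumour regions",
               call. = FALSE)
        }
        m <- max(2000, 4 * (n - length(xs)))
        cx <- runif(m, 0, frame[1]); cy <- runif(m, 0, frame[2])
        d <- distance_to_nearest_tumour(cx, cy, regions)
        keep <- d > 0 & runif(m) < exp(-d / scale)
        xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep]); ds <- c(ds, d[keep])
      }
      list(x = xs[seq_len(n)], y = ys[seq_len(n)], d = ds[seq_len(n)])
    }

    lab <- character(0); X <- numeric(0); Y <- numeric(0); D <- numeric(0)
    for (s in names(counts)) {
      if (counts[[s]] == 0) next
      p <- place_stromal(counts[[s]], scales[[s]])
      lab <- c(lab, rep(s, counts[[s]]))
      X <- c(X, p$x); Y <- c(Y, p$y); D <- c(D, p$d)
    }

    ## tumour cells uniform inside regions
    tx <- numeric(0); ty <- numeric(0)
    while (length(tx) < n_tumour_cells) {
      m <- max(2000, 4 * (n_tumour_cells - length(tx)))
      cx <- runif(m, 0, frame[1]); cy <- runif(m, 0, frame[2])
      inside <- distance_to_nearest_tumour(cx, cy, regions) == 0
      tx <- c(tx, cx[inside]); ty <- c(ty, cy[inside])
    }
    tx <- tx[seq_len(n_tumour_cells)]; ty <- ty[seq_len(n_tumour_cells)]

    n_total <- length(lab) + n_tumour_cells
    mk <- c("PanCK", "FAP", "aSMA", "PDPN", "FSP1", "CD90")
    m <- matrix(NA_real_, n_total, length(mk), dimnames = list(NULL, mk))
    fill <- function(idx, on_markers) {
      for (mkr in mk) {
        lev <- if (mkr %in% on_markers) "High" else "Neg"
        m[idx, mkr] <<- draw_level_intensity(length(idx), lev, model)
      }
    }
    row0 <- 0
    for (s in names(counts)) {
      if (counts[[s]] == 0) next
      idx <- row0 + seq_len(counts[[s]]); row0 <- row0 + counts[[s]]
      on <- names(which(profs[[s]]))
      fill(idx, on)
    }
    if (n_tumour_cells > 0) {
      fill(length(lab) + seq_len(n_tumour_cells), "PanCK")
    }

    cells <- data.frame(
      cell_id = sprintf("%s_c%05d", core_id, seq_len(n_total)),
      core_id = core_id,
      x = c(X, tx), y = c(Y, ty),
      m, check.names = FALSE, stringsAsFactors = FALSE,
      compartment = rep(c("stroma", "tumour"),
                        c(length(lab), n_tumour_cells)))
    list(cells = cells, regions = regions,
         truth = list(labels = c(lab, rep("tumour", n_tumour_cells)),
                      distances = c(D, rep(0, n_tumour_cells)),
                      subset_mix = subset_mix,
                      distance_order = distance_order))
  })
}

#' Default planted log2 fold-changes for the CAF-S5 vs CAF-S1 comparison
#'
#' Contractility genes (TAGLN, TPM2, SPARC, MYL9) are planted down in CAF-S5
#' and inflammatory/complement genes (C3, SEPP1, C7, CLU) up, the directions
#' the differential-expression stage is expected to recover.
#'
#' @return Named numeric vector of signed log2 effects.
#' @export
default_planted_lfc <- function() {
  c(TAGLN = -2, TPM2 = -2, SPARC = -2, MYL9 = -2,
    C3 = 2, SEPP1 = 2, C7 = 2, CLU = 2)
}

scrna_marker_genes <- function() {
  c("ITGB1", "PDGFRB", "PDPN", "FAP", "S100A4", "ACTA2")
}

#' Simulate single-cell RNA counts for a CAF-S1 / CAF-S5 comparison
#'
#' Negative-binomial counts for two groups of fibroblasts constructed to pass
#' the marker filter of [filter_caf_s1_s5()]: every cell expresses ITGB1,
#' PDGFRB, PDPN and FAP, no cell expresses S100A4, CAF-S1 cells express ACTA2
#' and CAF-S5 cells do not. Genes named in `planted_lfc` have their CAF-S5
#' mean multiplied by `2^lfc`.
#'
#' @param n_cells_per_group Cells per group (scalar or length-2, S1 then S5).
#' @param n_genes Total gene count (must accommodate marker and planted
#'   genes).
#' @param planted_lfc Named signed log2 effects; names must be gene symbols
#'   present in the matrix.
#' @param nb_size Negative-binomial size (inverse dispersion).
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells integer matrix, dimnames set),
#'   `labels` (per-cell `"CAF-S1"`/`"CAF-S5"`) and `truth`.
#' @export
generate_scrna_counts <- function(n_cells_per_group = c(150, 150),
                                  n_genes = 600,
                                  planted_lfc = default_planted_lfc(),
                                  nb_size = 2, seed = NULL) {
  if (length(n_cells_per_group) == 1) {
    n_cells_per_group <- rep(n_cells_per_group, 2)
  }
  if (any(n_cells_per_group < 1)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  markers <- scrna_marker_genes()
  named <- union(markers, names(default_planted_lfc()))
  if (n_genes < length(named)) {
    stop("n_genes too small for marker and planted genes", call. = FALSE)
  }
  fillers <- setdiff(sprintf("gene%04d", seq_len(n_genes)), named)
  genes <- c(named, fillers[seq_len(n_genes - length(named))])
  unknown <- setdiff(names(planted_lfc), genes)
  if (length(unknown)) {
    stop("planted gene(s) not in matrix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  with_seed(seed, {
    n1 <- n_cells_per_group[1]; n5 <- n_cells_per_group[2]
    mu <- pmax(rgamma(n_genes, shape = 2, scale = 1.5), 0.05)
    names(mu) <- genes
    mu[markers] <- 4
    mu["ACTA2"] <- 5

    lfc_vec <- setNames(numeric(n_genes), genes)
    lfc_vec[names(planted_lfc)] <- planted_lfc

    draw_group <- function(n, mu_g) {
      matrix(rnbinom(n_genes * n, size = nb_size, mu = mu_g),
             nrow = n_genes, ncol = n)
    }
    c1 <- draw_group(n1, mu)
    c5 <- draw_group(n5, mu * 2 ^ lfc_vec)
    counts <- cbind(c1, c5)
    rownames(counts) <- genes
    colnames(counts) <- c(sprintf("S1_c%04d", seq_len(n1)),
                          sprintf("S5_c%04d", seq_len(n5)))

    ## enforce the marker construction exactly
    incl <- c("ITGB1", "PDGFRB", "PDPN", "FAP")
    counts[incl, ] <- pmax(counts[incl, , drop = FALSE], 1L)
    counts["S100A4", ] <- 0L
    counts["ACTA2", seq_len(n1)] <- pmax(counts["ACTA2", seq_len(n1)], 1L)
    counts["ACTA2", n1 + seq_len(n5)] <- 0L

    labels <- rep(c("CAF-S1", "CAF-S5"), c(n1, n5))
    list(counts = counts, labels = labels,
         truth = list(planted_lfc = planted_lfc, labels = labels))
  })
}

#' Simulate a survival cohort with a planted group hazard ratio
#'
#' Event times are exponential with the baseline hazard multiplied by
#' `hazard_ratio` for the high-risk group. For `covariate = "abundance"` the
#' high group is defined by a CAF-subset abundance above its cohort median;
#' for `covariate = "bulk"` a latent CAF-S5-dominant subgroup (prevalence
#' `bulk_prevalence`) carries the elevated hazard, and the three bulk marker
#' scores reflect it: FAP and PDPN are shifted up and aSMA down in that
#' subgroup, so marker-wise cutpoints are recoverable from the data.
#' Censoring times are independent exponentials calibrated so each patient is
#' censored with probability `censoring_rate`.
#'
#' @param n_patients Cohort size (>= 2).
#' @param covariate `"abundance"` or `"bulk"`.
#' @param hazard_ratio Multiplicative hazard for the high-risk group (> 0).
#' @param censoring_rate Fraction in `[0, 1)`.
#' @param base_hazard Baseline hazard per day.
#' @param bulk_prevalence Prevalence of the latent CAF-S5-dominant subgroup
#'   in the bulk design.
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `time` (days), `event` (1 = event,
#'   0 = censored) and covariate columns; the planted assignment is stored in
#'   `attr(, "truth")`.
#' @export
generate_survival_cohort <- function(n_patients = 200,
                                     covariate = c("abundance", "bulk"),
                                     hazard_ratio = 1,
                                     censoring_rate = 0.2,
                                     base_hazard = 1 / 1000,
                                     bulk_prevalence = 0.15,
                                     seed = NULL) {
  covariate <- match.arg(covariate)
  if (n_patients < 2) stop("need at least 2 patients", call. = FALSE)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    if (covariate == "abundance") {
      cov_df <- data.frame(caf_abundance = rlnorm(n_patients, log(10), 0.5))
      high <- cov_df$caf_abundance > median(cov_df$caf_abundance)
    } else {
      high <- runif(n_patients) < bulk_prevalence
      cov_df <- data.frame(
        FAP = rlnorm(n_patients, ifelse(high, 1.0, -0.3), 0.5),
        PDPN = rlnorm(n_patients, ifelse(high, 1.0, -0.3), 0.5),
        aSMA = rlnorm(n_patients, ifelse(high, -1.0, 0.3), 0.5))
    }
    rate <- base_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(n_patients, rate)
    if (censoring_rate > 0) {
      t_cens <- rexp(n_patients, rate * censoring_rate / (1 - censoring_rate))
    } else {
      t_cens <- rep(Inf, n_patients)
    }
    tab <- data.frame(patient_id = sprintf("p%04d", seq_len(n_patients)),
                      time = pmin(t_event, t_cens),
                      event = as.integer(t_event <= t_cens),
                      cov_df)
    attr(tab, "truth") <- list(high_group = high, hazard_ratio = hazard_ratio,
                               covariate = covariate)
    tab
  })
}
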
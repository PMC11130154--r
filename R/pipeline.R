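#' @keywords internal
#' @importFrom graphics hist
#' @importFrom grDevices hcl.colors
"_PACKAGE"

#' Run the full synthetic-to-results demonstration pipeline
#'
#' Generates every input modality with planted truth, then runs all analysis
#' stages: flow gating / downsampling / concatenation, SOM subtyping with
#' automatic metacluster selection, MIF classification, spatial
#' distance-to-tumour comparison, scRNA filtering with differential
#' expression, and survival stratification (median split and maximally
#' selected bulk cutpoints). Artifacts and a run manifest are written under
#' `out_dir` when given.
#'
#' @param seed Integer master seed; every stage derives its own seed from it.
#' @param out_dir Optional output directory for CSV/GeoJSON/MTX artifacts
#'   and `manifest.json`.
#' @param n_per_tissue,n_events Flow cohort size (samples per tissue, events
#'   per sample).
#' @param n_mif_cells Stromal cells in the simulated tissue core.
#' @param n_scrna_cells Cells per scRNA group.
#' @param n_patients Patients per simulated survival cohort.
#' @return List with per-stage results, invisibly when `out_dir` is given.
#' @export
caf_pipeline <- function(seed = 1, out_dir = NULL,
                         n_per_tissue = 14, n_events = 2000,
                         n_mif_cells = 3000, n_scrna_cells = 150,
                         n_patients = 200) {
  seeds <- with_seed(seed, sample.int(2^31 - 1, 6))
  model <- intensity_model()
  cfg <- default_gate_config(model)

  ## -- flow: simulate, gate, downsample, concatenate, cluster ------------
  cohort <- generate_flow_cohort(n_per_tissue = n_per_tissue,
                                 n_events = n_events, model = model,
                                 seed = seeds[1])
  gated <- lapply(cohort, function(s) gate_fibroblasts(s$events, cfg))
  kept <- list(); drop_log <- character(0)
  ds_seeds <- with_seed(seeds[2], sample.int(2^31 - 1, length(gated)))
  for (i in seq_along(gated)) {
    id <- names(gated)[i]
    res <- tryCatch(downsample_events(gated[[i]], cfg, seed = ds_seeds[i]),
                    caf_sample_excluded = function(e) {
                      drop_log <<- c(drop_log, paste0(id, ": ",
                                                      conditionMessage(e)))
                      NULL
                    })
    if (!is.null(res)) kept[[id]] <- res
  }
  pooled <- concatenate_samples(kept)
  fit <- caf_flowsom(pooled, model = model, seed = seeds[3])
  comp <- subset_composition(fit$subset_labels, pooled$sample_id,
                             pooled$tissue)

  ## -- MIF + spatial -----------------------------------------------------
  core <- generate_mif_core(n_cells = n_mif_cells, model = model,
                            seed = seeds[4])
  classified <- classify_cells(core$cells)
  pct <- subset_percentages(classified)
  stroma_caf <- classified$compartment == "stroma" &
    classified$subset != "other"
  records <- data.frame(cell_id = classified$cell_id[stroma_caf],
                        subset = classified$subset[stroma_caf],
                        distance = distance_to_nearest_tumour(
                          classified$x[stroma_caf], classified$y[stroma_caf],
                          core$regions))
  spatial <- subset_distance_comparison(records)

  ## -- scRNA -------------------------------------------------------------
  sc <- generate_scrna_counts(n_cells_per_group = n_scrna_cells,
                              seed = seeds[5])
  sc_labels <- filter_caf_s1_s5(sc$counts)
  de <- differential_expression(sc$counts, sc_labels)
  top <- top_genes(de, 50)

  ## -- survival ----------------------------------------------------------
  surv_seeds <- with_seed(seeds[6], sample.int(2^31 - 1, 2))
  cohort_abund <- generate_survival_cohort(n_patients = n_patients,
                                           covariate = "abundance",
                                           hazard_ratio = 3,
                                           seed = surv_seeds[1])
  ms <- median_split(cohort_abund, "caf_abundance")
  lr_abund <- logrank_test(list(ms$high, ms$low))
  cohort_bulk <- generate_survival_cohort(n_patients = max(n_patients, 300),
                                          covariate = "bulk",
                                          hazard_ratio = 2.5,
                                          seed = surv_seeds[2])
  cuts <- lapply(setNames(nm = c("FAP", "PDPN", "aSMA")), function(m) {
    max_selected_cutpoint(cohort_bulk, m)
  })
  pheno <- assign_bulk_phenotype(cohort_bulk, cuts)
  lr_bulk <- logrank_test(cohort_bulk, pheno)

  result <- list(
    flow = list(fit = fit, composition = comp, excluded = drop_log,
                n_pooled = nrow(pooled)),
    mif = list(percentages = pct, thresholds = attr(classified, "thresholds"),
               truth_mix = core$truth$subset_mix),
    spatial = spatial,
    scrna = list(de = de, top_genes = top, labels = sc_labels),
    survival = list(median_split_logrank = lr_abund, cutpoints = cuts,
                    phenotype_logrank = lr_bulk,
                    phenotype_n = sum(pheno == "CAF-S5")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(pooled, file.path(out_dir, "pooled_events.csv"))
    write_table_csv(comp$composition, file.path(out_dir, "composition.csv"))
    write_table_csv(classified, file.path(out_dir, "mif_cells.csv"))
    write_regions_geojson(core$regions,
                          file.path(out_dir, "tumour_regions.geojson"))
    write_table_csv(pct, file.path(out_dir, "mif_subset_percentages.csv"))
    write_table_csv(spatial$summary,
                    file.path(out_dir, "distance_summary.csv"))
    write_counts_mtx(sc$counts, file.path(out_dir, "scrna"))
    write_table_csv(de, file.path(out_dir, "de_results.csv"))
    write_table_csv(cohort_abund, file.path(out_dir, "cohort_abundance.csv"))
    write_table_csv(cohort_bulk, file.path(out_dir, "cohort_bulk.csv"))
    manifest <- list(
      seed = seed, stage_seeds = seeds,
      sizes = list(n_per_tissue = n_per_tissue, n_events = n_events,
                   n_mif_cells = n_mif_cells, n_scrna_cells = n_scrna_cells,
                   n_patients = n_patients),
      selected_k = fit$meta$k,
      n_pooled_events = nrow(pooled),
      excluded_samples = drop_log,
      n_mif_cores = length(unique(pct$core_id)),
      n_de_genes_tested = sum(!is.na(de$q)))
    atomic_write(file.path(out_dir, "manifest.json"), function(tmp) {
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), tmp)
    })
    return(invisible(result))
  }
  result
}
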
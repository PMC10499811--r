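#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline with the study's
#' defaults: 85% detectability, nominal p 0.05 and FDR q 0.05, elastic-net
#' grids (mixing 0.1..1, marker caps up to 21), 10-fold tuning CV, ridge
#' refit penalty 0.1, stability threshold 0.8, 100 bootstrap resamples and
#' 1000 repeats of 5-fold CV. Either a simulation design or input paths must
#' be supplied.
#'
#' @param design a [cohort_design], or `"default"` / `"panel"` for the
#'   shipped designs; `NULL` when reading from files.
#' @param npx_path,metadata_path,bridges_path input files (long NPX CSV/TSV,
#'   metadata CSV, optional bridge map CSV) when `design` is `NULL`.
#' @param detectability minimum detectable fraction (0, 1].
#' @param p_nominal,q_threshold significance thresholds in (0, 1].
#' @param alpha_grid,cap_grid,cv_k,nlambda elastic-net tuning grids.
#' @param stability_threshold minimum fold selection proportion for a marker
#'   to count as stable.
#' @param ridge_penalty penalty of the final refit.
#' @param bootstrap_B,cv_repeats,eval_k resampling sizes for evaluation.
#' @param panel_contrast the contrast the panel is trained on
#'   (`c(group_a, group_b)`, reference first).
#' @param seed master seed; every stage derives its own stream from it.
#' @param run_enrichment,gmt_path optional enrichment stage inputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(design = "default",
                       npx_path = NULL, metadata_path = NULL,
                       bridges_path = NULL,
                       detectability = 0.85,
                       p_nominal = 0.05, q_threshold = 0.05,
                       alpha_grid = seq(0.1, 1, by = 0.1),
                       cap_grid = c(3, 5, 7, 10, 15, 21),
                       cv_k = 10, nlambda = 100,
                       stability_threshold = 0.8,
                       ridge_penalty = 0.1,
                       bootstrap_B = 100, cv_repeats = 1000, eval_k = 5,
                       panel_contrast = c("AD", "DLB"),
                       seed = 1L,
                       run_enrichment = FALSE, gmt_path = NULL) {
  for (thr in list(detectability = detectability, p_nominal = p_nominal,
                   q_threshold = q_threshold,
                   stability_threshold = stability_threshold)) {
    if (!is.numeric(thr) || thr <= 0 || thr > 1)
      stopf("thresholds must lie in (0, 1]")
  }
  if (is.character(design))
    design <- switch(design, default = default_paper_design(),
                     panel = default_panel_design(),
                     stopf("unknown design '%s'", design))
  if (is.null(design) && (is.null(npx_path) || is.null(metadata_path)))
    stopf("either a design or npx_path + metadata_path is required")
  structure(list(design = design, npx_path = npx_path,
                 metadata_path = metadata_path, bridges_path = bridges_path,
                 detectability = detectability, p_nominal = p_nominal,
                 q_threshold = q_threshold, alpha_grid = alpha_grid,
                 cap_grid = cap_grid, cv_k = cv_k, nlambda = nlambda,
                 stability_threshold = stability_threshold,
                 ridge_penalty = ridge_penalty, bootstrap_B = bootstrap_B,
                 cv_repeats = cv_repeats, eval_k = eval_k,
                 panel_contrast = panel_contrast, seed = as.integer(seed),
                 run_enrichment = run_enrichment, gmt_path = gmt_path),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalars and vectors are passed to [run_config()] by name; a `design`
#' string of `"default"` or `"panel"` selects a shipped design.
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package; `.json`
#'   uses jsonlite).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the yaml package is required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate/ingest, QC (detectability filter + bridging
#' normalization), the three pairwise differential-abundance contrasts,
#' UpSet partitioning, panel selection (tuning, stability, ridge refit),
#' internal evaluation, and optionally enrichment; writes every stage output
#' plus a manifest into `out_dir`. A failed stage halts the run with the
#' stage name.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list of in-memory stage results (`npx`, `metadata`,
#'   `contrasts`, `partition`, `panel`, `evaluation`, paths in `files`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  stage <- "ingest"
  result <- tryCatch({
    if (!is.null(config$design)) {
      sim <- generate_cohort(config$design, seed = seeds[1])
      m <- sim$npx; meta <- sim$metadata; bridges <- sim$bridges
      write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
    } else {
      m <- read_npx_long(config$npx_path)
      meta <- utils::read.csv(config$metadata_path, stringsAsFactors = FALSE)
      bridges <- if (!is.null(config$bridges_path))
        utils::read.csv(config$bridges_path, stringsAsFactors = FALSE)
    }
    meta <- validate_metadata(meta, m)
    if (!"is_bridge" %in% names(meta)) meta$is_bridge <- FALSE

    stage <- "qc"
    filt <- filter_by_detectability(m, config$detectability)
    m <- filt$matrix
    if (length(unique(m$batch)) > 1 && !is.null(bridges) && nrow(bridges))
      m <- bridge_normalize(m, bridges, reference_batch = sort(unique(m$batch))[1])
    is_bridge <- if ("is_bridge" %in% names(meta))
      meta$is_bridge[match(sample_ids(m), meta$sample_id)] else
      rep(FALSE, nrow(m$values))
    m <- m[!is_bridge, ]
    writeLines(filt$dropped, file.path(out_dir, "dropped_assays.txt"))

    stage <- "diff_abundance"
    contrasts <- list(
      DLB_vs_CON = contrast_table(m, meta, "CON", "DLB"),
      DLB_vs_AD = contrast_table(m, meta, "AD", "DLB"),
      AD_vs_CON = contrast_table(m, meta, "CON", "AD"))
    for (nm in names(contrasts))
      write_tsv(contrasts[[nm]], file.path(out_dir, paste0("contrast_", nm, ".tsv")))

    stage <- "upset"
    partition <- upset_partition(contrasts$DLB_vs_CON, contrasts$DLB_vs_AD,
                                 contrasts$AD_vs_CON, config$p_nominal)
    write_tsv(partition, file.path(out_dir, "upset_partition.tsv"))
    write_tsv(upset_counts(partition), file.path(out_dir, "upset_counts.tsv"))
    write_tsv(upset_membership(partition), file.path(out_dir, "upset_membership.tsv"))
    dirsum <- subset_direction_summary(partition, contrasts$DLB_vs_CON,
                                       contrasts$AD_vs_CON, seed = seeds[2])
    if (!is.null(dirsum))
      write_tsv(dirsum, file.path(out_dir, "upset_direction_summary.tsv"))

    stage <- "panel_selection"
    ga <- config$panel_contrast[1]; gb <- config$panel_contrast[2]
    keep <- meta$sample_id[!meta$is_bridge & meta$diagnosis %in% c(ga, gb)]
    keep <- intersect(sample_ids(m), keep)
    X <- m$values[keep, , drop = FALSE]
    sub <- meta[match(keep, meta$sample_id), ]
    y <- as.numeric(sub$diagnosis == gb)
    covs <- build_covariates(sub, c("age", "sex"))
    tuned <- cv_tune(X, y, covs, alpha_grid = config$alpha_grid,
                     cap_grid = config$cap_grid, k = config$cv_k,
                     nlambda = config$nlambda, seed = seeds[3])
    write_tsv(tuning_summary(tuned), file.path(out_dir, "panel_grid.tsv"))
    chosen <- choose_model(tuned)
    props <- selection_proportions(X, y, covs, chosen, k = config$cv_k,
                                   seed = seeds[3])
    write_tsv(data.frame(assay_id = names(props), proportion = props),
              file.path(out_dir, "selection_proportions.tsv"))
    stable <- names(props)[props >= config$stability_threshold]
    if (length(stable) == 0) stable <- chosen$selected_assays
    panel <- ridge_refit(X, y, markers = stable, covariates = covs,
                         penalty = config$ridge_penalty,
                         contrast = paste(gb, "vs", ga, sep = "_"))
    panel_model_to_json(panel, file.path(out_dir, "panel_model.json"))

    stage <- "evaluation"
    cvres <- repeated_cv_auc(X[, stable, drop = FALSE], y, covs,
                             k = config$eval_k, repeats = config$cv_repeats,
                             penalty = config$ridge_penalty, seed = seeds[4])
    scores <- predict(panel, X, covariates = covs)
    boot <- bootstrap_auc_ci(scores, y, B = config$bootstrap_B,
                             seed = seeds[5])
    eval_out <- list(
      panel_markers = stable,
      repeated_cv = cvres[c("auc", "ci_low", "ci_high", "method",
                            "n_resamples", "seed")],
      training_bootstrap = boot[c("auc", "ci_low", "ci_high", "method",
                                  "n_resamples", "seed")])
    jsonlite::write_json(eval_out, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(boot$curve, file.path(out_dir, "roc_curve_training.tsv"))

    enrich <- NULL
    if (isTRUE(config$run_enrichment) && !is.null(config$gmt_path)) {
      stage <- "enrichment"
      sets <- read_gmt(config$gmt_path)
      background <- unique(sub("_Panel\\d+$", "", assay_ids(m)))
      query <- unique(sub("_Panel\\d+$", "",
                          partition$assay_id[partition$subset != "unclassified"]))
      query <- intersect(query, background)
      enrich <- hypergeom_enrich(query, background, sets)
      if (any(enrich$passes_filters))
        enrich <- kappa_cluster(enrich, sets, background)
      write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("lewypanel")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      master_seed = config$seed, stage_seeds = seeds,
      thresholds = config[c("detectability", "p_nominal", "q_threshold",
                            "stability_threshold", "ridge_penalty")],
      grids = config[c("alpha_grid", "cap_grid", "cv_k", "nlambda")],
      resampling = config[c("bootstrap_B", "cv_repeats", "eval_k")],
      panel_contrast = config$panel_contrast)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    list(npx = m, metadata = meta, contrasts = contrasts,
         partition = partition, tuning = tuned, panel = panel,
         evaluation = eval_out, enrichment = enrich, out_dir = out_dir)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(result)
}
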
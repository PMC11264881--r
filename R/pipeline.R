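#' Read a pipeline configuration file
#'
#' YAML configuration mirroring [run_pipeline()]'s `config` argument: a
#' `seed`, a `stages` list, and one block per stage (`sim`, `normalize`,
#' `process`, `mwas`, `enrich`, `pcorr`, `specmatch`, `gwas`, `phewas`).
#'
#' @param path Path to a YAML file.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

known_stages <- c("simulate", "normalize", "process", "mwas", "enrich",
                  "pcorr", "specmatch", "gwas", "phewas")

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order -- simulate (cohort + feature
#' matrix), normalize (QC LOESS drift correction), process (missingness
#' triage, imputation, batch correction, standardization), mwas (logistic
#' association scan with BH-FDR), enrich (class enrichment, if class
#' annotations are configured), pcorr (partial-correlation edges), specmatch
#' (spectral library search, if MGF paths are configured), gwas and phewas
#' (adult-cohort determinant scans, if an `adult` block is configured) --
#' writing result tables, a plain-text log and a manifest of all software
#' decisions into `out_dir`. The run is deterministic given `config$seed`:
#' the global seed is expanded into per-stage seeds with [stage_seed()], so
#' enabling or disabling one stage never reshuffles the randomness of others.
#'
#' @param config Configuration list (see [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir) {
  stages <- unlist(config$stages %||% c("simulate", "normalize", "process", "mwas"))
  bad <- setdiff(stages, known_stages)
  if (length(bad))
    config_error("unknown stage name(s): %s", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(...) writeLines(sprintf(...), log_con)

  state <- list()
  manifest <- list(seed = seed, stages = as.list(stages))
  run_stage <- function(name, fn) {
    say("stage %s: start", name)
    out <- tryCatch(fn(), error = function(e)
      nm_error("neometab_stage_error", "stage '%s' failed: %s",
               name, conditionMessage(e)))
    for (ln in processing_log(out)) say("%s", ln)
    say("stage %s: done", name)
    out
  }

  if ("simulate" %in% stages) {
    sim <- config$sim %||% list()
    sf <- if (!is.null(sim$signal_features))
      do.call(rbind, lapply(sim$signal_features, as.data.frame)) else NULL
    cfg <- sim_config(
      n_pairs = sim$n_pairs %||% 739L, n_features = sim$n_features %||% 865L,
      n_plates = sim$n_plates %||% 19L, qc_per_plate = sim$qc_per_plate %||% 6L,
      drift_amplitude = sim$drift_amplitude %||% 0.2,
      batch_sd = sim$batch_sd %||% 0.10,
      analytical_cv = sim$analytical_cv %||% 0.05,
      signal_features = sf, prs_auc = sim$prs_auc %||% 0.58,
      fh_rate_case = sim$fh_rate_case %||% 0.300,
      fh_rate_control = sim$fh_rate_control %||% 0.187,
      seed = seed
    )
    state$cohort <- run_stage("simulate", function() {
      coh <- generate_neonatal_cohort(cfg)
      coh$table <- generate_feature_matrix(coh$samples, coh$truth, cfg)
      coh
    })
    write_sample_records(state$cohort$samples, file.path(out_dir, "samples.tsv"))
    write_feature_table(state$cohort$table,
                        file.path(out_dir, "feature_table.tsv"),
                        file.path(out_dir, "feature_metadata.tsv"))
    utils::write.table(state$cohort$truth$features,
                       file.path(out_dir, "truth_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$sim <- cfg[setdiff(names(cfg), c("signal_features", "presence_targets"))]
  } else if (!is.null(config$paths$feature_table)) {
    state$cohort <- list(
      table = read_feature_table(config$paths$feature_table,
                                 config$paths$feature_metadata),
      samples = read_sample_records(config$paths$samples)
    )
  }

  tab <- state$cohort$table
  if ("normalize" %in% stages) {
    nz <- config$normalize %||% list()
    span <- nz$span %||% (2 / 3)
    degree <- nz$degree %||% 1L
    tab <- run_stage("normalize", function() {
      model <- fit_drift_model(tab, span = span, degree = degree)
      apply_drift_correction(tab, model)
    })
    manifest$normalize <- list(method = "QC-RLSC LOESS, per-plate, plate pools",
                               span = span, degree = degree,
                               reference = "median QC intensity",
                               extrapolation = "clamped to QC order range")
  }

  processed <- NULL
  if ("process" %in% stages) {
    pz <- config$process %||% list()
    processed <- run_stage("process", function()
      process_features(tab, low = pz$low %||% 0.25, high = pz$high %||% 0.75,
                       impute = pz$impute %||% "tree",
                       batch_method = pz$batch_method %||% "plate_median"))
    utils::write.table(processed$strata, file.path(out_dir, "feature_strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$process <- processed$meta
    manifest$process$boundary_rule <-
      "fraction < low dropped; < high binary; >= high continuous"
  }

  mwas_res <- NULL
  if ("mwas" %in% stages) {
    if (is.null(processed)) config_error("mwas requires the process stage")
    mz <- config$mwas %||% list()
    spec <- model_spec(mz$model %||% "model1")
    mwas_res <- run_stage("mwas", function()
      run_mwas(processed, state$cohort$samples, spec))
    write_assoc_results(mwas_res, file.path(out_dir, "assoc_results.tsv"))
    manifest$mwas <- list(model = spec$model, covariates = spec$covariates,
                          fdr = "Benjamini-Hochberg step-up",
                          failed_fits = "p = 1, kept in the BH family")
  }

  if ("enrich" %in% stages) {
    ez <- config$enrich %||% list()
    if (is.null(ez$class_file) || is.null(mwas_res)) {
      say("stage enrich: skipped (no class annotation file or no mwas results)")
    } else {
      ann <- utils::read.delim(ez$class_file, stringsAsFactors = FALSE)
      cls <- ann$class[match(mwas_res$feature_id, ann$feature_id)]
      enr <- run_stage("enrich", function()
        class_enrichment(mwas_res$p < (ez$alpha %||% 0.05), cls))
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("pcorr" %in% stages) {
    if (is.null(processed)) config_error("pcorr requires the process stage")
    cz <- config$pcorr %||% list()
    X <- cbind(processed$continuous, processed$binary)
    pc <- run_stage("pcorr", function() {
      meth <- cz$method %||% (if (nrow(X) > ncol(X)) "exact" else "ridge")
      partial_corr_matrix(X, method = meth, lambda = cz$lambda %||% 0.1)
    })
    ut <- upper.tri(pc$rho)
    edges <- data.frame(
      feature_i = rownames(pc$rho)[row(pc$rho)[ut]] %||% colnames(X)[row(pc$rho)[ut]],
      feature_j = colnames(pc$rho)[col(pc$rho)[ut]],
      rho = pc$rho[ut], p = pc$p[ut]
    )
    utils::write.table(edges, file.path(out_dir, "pcorr_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$pcorr <- list(method = pc$method, lambda = pc$lambda, df = pc$df)
  }

  if ("specmatch" %in% stages) {
    sz <- config$specmatch %||% list()
    if (is.null(sz$query) || is.null(sz$library)) {
      say("stage specmatch: skipped (no query/library MGF configured)")
    } else {
      thr <- match_thresholds(sz$min_cosine %||% 0.7, sz$min_peaks %||% 4L,
                              sz$parent_tol %||% 0.05, sz$frag_tol %||% 0.05)
      queries <- read_mgf(sz$query)
      lib <- read_mgf(sz$library)
      hits <- run_stage("specmatch", function()
        do.call(rbind, lapply(queries, library_search, lib, thr)))
      utils::write.table(hits, file.path(out_dir, "spectral_matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$specmatch <- unclass(thr)
    }
  }

  adult <- NULL
  if (any(c("gwas", "phewas") %in% stages)) {
    az <- config$adult %||% list()
    causal <- if (!is.null(az$causal))
      do.call(rbind, lapply(az$causal, as.data.frame)) else NULL
    adult <- generate_adult_cohort(az$n %||% 1000L, az$n_snps %||% 200L,
                                   causal = causal,
                                   diet_corr = az$diet_corr %||% 0,
                                   seed = seed)
  }
  if ("gwas" %in% stages) {
    gw <- run_stage("gwas", function()
      gwas_scan(adult$genotypes, adult$metabolite,
                cbind(age = adult$diet$age, sex = adult$diet$sex)))
    write_gwas_results(gw, file.path(out_dir, "gwas.assoc.tsv"))
    manifest$gwas <- list(model = "linear additive, age + sex adjusted",
                          lambda_gc = lambda_gc(gw$p))
  }
  if ("phewas" %in% stages) {
    preds <- cbind(adult$genotypes,
                   as.matrix(adult$diet[, c("age", "sex", "bmi", "dairy",
                                            "meat", "fish", "fruit_vegetables",
                                            "cereals", "potatoes")]))
    ph <- run_stage("phewas", function()
      lasso_phewas(adult$metabolite, preds, seed = stage_seed(seed, 9L)))
    utils::write.table(
      data.frame(predictor = names(ph$coefficients),
                 coefficient = ph$coefficients),
      file.path(out_dir, "phewas_top.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$phewas <- list(lambda_rule = "1-SE", cv_r2 = ph$cv_r2)
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(state = state, processed = processed, mwas = mwas_res,
                 out_dir = out_dir, manifest = manifest))
}
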
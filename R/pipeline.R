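# End-to-end pipeline: simulate/load -> preprocess -> swag -> diffmeth ->
# annotate -> overlap, driven by one validated config and one master seed.

pipeline_defaults <- function() {
  list(
    sim = list(n_early = 15, n_late = 16, n_probes = 1000, n_planted = 10,
               delta_beta = 0.115, beta_shape_a = 2, beta_shape_b = 8,
               noise_sd_logit = 0.25, intensity_scale = 10000,
               intensity_sd = 100, control_mean = 300, control_sd = 50,
               fail_fraction = 0, confound_strength = 0),
    qc = list(bead_min = 3, detection_max = 0.01, offset = 100),
    swag = list(alpha = 0.05, dmax = 3, m_per_dim = Inf, delta_aic = 2,
                covariate_mode = "pooled"),
    diff = list(variant = "welch", p_threshold = 0.001),
    input = list(beta = NULL, phenotypes = NULL, manifest = NULL,
                 group_col = "bedtime_group"),
    overlap = list(set_a = NULL, set_b = NULL, by_family = "triple",
                   gene_p_method = "min"),
    top_k = 10,
    seed = 1L,
    out_dir = NULL
  )
}

suggest_key <- function(key, known) {
  d <- utils::adist(key, known)
  hit <- known[which.min(d)]
  if (min(d) <= 2) sprintf(" (did you mean '%s'?)", hit) else ""
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, checks every key against the
#' known schema (unknown keys are errors, with a nearest-key suggestion),
#' fills in defaults, and verifies that referenced input files exist. All
#' validation errors are collected and reported together.
#'
#' When `input$beta` is unset the pipeline runs in synthetic mode and the
#' `sim` block configures the generator; otherwise `input$beta` and
#' `input$phenotypes` must name existing files (with `input$manifest`
#' optional but needed for annotation).
#'
#' @param config YAML path or nested list.
#' @return A resolved list of class `"pipeline_config"`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML file path")
  defaults <- pipeline_defaults()
  errors <- character(0)

  unknown_top <- setdiff(names(config), names(defaults))
  for (k in unknown_top)
    errors <- c(errors, sprintf("unknown config key '%s'%s", k,
                                suggest_key(k, names(defaults))))
  resolved <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]])) {
      block <- config[[k]]
      if (!is.list(block)) {
        errors <- c(errors, sprintf("config block '%s' must be a mapping", k))
        next
      }
      unknown <- setdiff(names(block), names(defaults[[k]]))
      for (u in unknown)
        errors <- c(errors, sprintf("unknown key '%s.%s'%s", k, u,
                                    suggest_key(u, names(defaults[[k]]))))
      for (u in intersect(names(block), names(defaults[[k]])))
        resolved[[k]][[u]] <- block[[u]]
    } else {
      resolved[[k]] <- config[[k]]
    }
  }

  simulate_mode <- is.null(resolved$input$beta)
  if (!simulate_mode) {
    for (f in c("beta", "phenotypes")) {
      path <- resolved$input[[f]]
      if (is.null(path))
        errors <- c(errors,
                    sprintf("input.%s is required when input.beta is set", f))
      else if (!file.exists(path))
        errors <- c(errors, sprintf("input.%s file not found: %s", f, path))
    }
  }
  for (f in c("set_a", "set_b")) {
    path <- resolved$overlap[[f]]
    if (!is.null(path) && !file.exists(path))
      errors <- c(errors, sprintf("overlap.%s file not found: %s", f, path))
  }
  if (length(errors))
    stop(paste(c("invalid pipeline config:", paste0("  - ", errors)),
               collapse = "\n"), call. = FALSE)
  resolved$simulate_mode <- simulate_mode
  class(resolved) <- "pipeline_config"
  resolved
}

#' Run the full analysis pipeline
#'
#' Executes every stage under a single master seed (each stage derives its
#' own deterministic sub-stream): synthetic data generation or file loading,
#' intensity preprocessing, per-probe differential methylation, SWAG model
#' selection with variable importance, top-hit reporting, manifest
#' annotation of the significant probes, context distributions, and
#' (when reference gene sets are configured) the gene-set cross-comparison
#' with Benjamini-Yekutieli correction. When `out_dir` is set, all stage
#' outputs and a machine-readable `summary.json` are written; re-running
#' with the same config reproduces them byte-identically. A stage failure
#' leaves a `FAILED` marker file in `out_dir` alongside any partial output.
#'
#' @param config a `"pipeline_config"` (or anything [validate_config()]
#'   accepts).
#' @return A list of class `"run_summary"` with per-stage counts, key
#'   parameters, the top-k table, distribution reports and overlap counts.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    unlink(file.path(out_dir, "FAILED"))
  }
  tryCatch(
    run_pipeline_stages(config, out_dir),
    error = function(e) {
      if (!is.null(out_dir))
        writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
      stop(e)
    })
}

run_pipeline_stages <- function(config, out_dir) {
  log_stage <- function(stage, fmt, ...)
    message(sprintf("[%s seed=%d] %s", stage, config$seed, sprintf(fmt, ...)))

  # --- stage: data ---------------------------------------------------------
  if (config$simulate_mode) {
    cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    ds <- simulate_dataset(cfg)
    phenotypes <- ds$phenotypes
    pp <- preprocess_panel(ds$panel, bead_min = config$qc$bead_min,
                           detection_max = config$qc$detection_max,
                           offset = config$qc$offset)
    beta <- pp$beta
    qc <- pp$qc
    manifest <- load_manifest_df(ds$manifest)
    truth <- ds$truth
    log_stage("simulate", "%d probes x %d samples, %d planted",
              nrow(beta), ncol(beta), length(truth$planted_probe_ids))
  } else {
    beta <- read_beta_tsv(config$input$beta)
    phenotypes <- read_phenotypes(config$input$phenotypes,
                                  config$input$group_col)
    manifest <- if (!is.null(config$input$manifest))
      load_manifest(config$input$manifest)
    qc <- NULL; truth <- NULL
    log_stage("load", "%d probes x %d samples from %s",
              nrow(beta), ncol(beta), config$input$beta)
  }
  groups <- stats::setNames(as.character(phenotypes$bedtime_group),
                            phenotypes$sample_id)

  # --- stage: differential methylation ------------------------------------
  diff <- per_probe_ttest(beta, groups, variant = config$diff$variant)
  counts <- classify_counts(diff, config$diff$p_threshold)
  log_stage("diffmeth", "%d significant probes at p < %g (%d hyper / %d hypo in early)",
            counts$n_significant, config$diff$p_threshold,
            counts$n_hyper_in_early, counts$n_hypo_in_early)

  # --- stage: SWAG ---------------------------------------------------------
  covs <- phenotypes[, intersect(c("age_years", "sex", "bmi_z", "wc_z",
                                   "whtr_z"), names(phenotypes)),
                     drop = FALSE]
  fit <- swag(t(beta), phenotypes$bedtime_group,
              alpha = config$swag$alpha, dmax = config$swag$dmax,
              m_per_dim = config$swag$m_per_dim,
              delta_aic = config$swag$delta_aic,
              covariates = if (ncol(covs)) covs else NULL,
              covariate_mode = config$swag$covariate_mode,
              seed = derive_seed(config$seed, "swag"))
  log_stage("swag", "library of %d models over %d screened variables",
            sum(vapply(fit$library, length, integer(1))),
            length(fit$screened))

  # --- stage: top hits + annotation ---------------------------------------
  sig_probes <- diff$probe_id[diff$p_value < config$diff$p_threshold]
  ann <- if (!is.null(manifest)) annotate_probes(sig_probes, manifest)
  top <- top_table(diff, fit$importance,
                   k = min(config$top_k, nrow(fit$importance)),
                   annotation = ann$table)
  dists <- if (!is.null(ann) && length(sig_probes))
    lapply(stats::setNames(nm = c("refgene_group", "island_relation",
                                  "regulatory_feature")),
           function(f) context_distribution(ann$table, f))
  if (!is.null(ann))
    log_stage("annotate", "%d significant probes -> %d unique genes",
              length(sig_probes), length(ann$genes))

  # --- stage: gene-set overlap --------------------------------------------
  overlap <- NULL
  if (!is.null(config$overlap$set_a) && !is.null(config$overlap$set_b) &&
      !is.null(ann) && length(ann$genes)) {
    set_a <- load_gene_set(config$overlap$set_a, "set_a")
    set_b <- load_gene_set(config$overlap$set_b, "set_b")
    gp <- gene_level_p(diff, ann$table,
                       method = config$overlap$gene_p_method)
    overlap <- intersect_sets(gene_set(ann$genes, "study"), set_a, set_b,
                              gene_pvals = gp,
                              by_family = config$overlap$by_family)
    log_stage("overlap", "%d / %d / %d genes in A / B / both",
              overlap$n_a, overlap$n_b, overlap$n_triple)
  }

  summary <- structure(list(
    seed = config$seed,
    params = list(qc = config$qc, swag = config$swag, diff = config$diff,
                  top_k = config$top_k),
    n_probes = nrow(beta), n_samples = ncol(beta),
    qc = if (!is.null(qc)) unclass(qc)[c("n_input_probes", "n_excluded_beads",
                                         "n_excluded_detection",
                                         "n_retained")],
    n_significant = counts$n_significant,
    n_hyper_in_early = counts$n_hyper_in_early,
    n_hypo_in_early = counts$n_hypo_in_early,
    n_unique_genes = if (!is.null(ann)) length(ann$genes),
    swag_models_per_dimension = vapply(fit$library, length, integer(1)),
    swag_min_aic = fit$best$aic,
    top_table = top,
    distributions = dists,
    overlap = if (!is.null(overlap))
      overlap[c("n_a", "n_b", "n_triple", "in_both")],
    truth_recall_top_k = if (!is.null(truth) &&
                             length(truth$planted_probe_ids))
      sum(utils::head(fit$importance$variable, config$top_k) %in%
            truth$planted_probe_ids) / config$top_k
  ), class = "run_summary")

  if (!is.null(out_dir)) {
    write_beta_tsv(beta, file.path(out_dir, "beta.tsv"))
    utils::write.csv(phenotypes, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    utils::write.table(as.data.frame(diff), file.path(out_dir, "diff_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_swag_library(unlist(fit$library, recursive = FALSE,
                              use.names = FALSE),
                       file.path(out_dir, "swag_library.jsonl"),
                       file.path(out_dir, "swag_summary.json"))
    utils::write.table(fit$importance, file.path(out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top_flat <- top
    if (!is.null(top_flat$genes))
      top_flat$genes <- vapply(top_flat$genes, paste, character(1),
                               collapse = ";")
    utils::write.table(top_flat, file.path(out_dir, "top_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sm <- rapply(unclass(summary),
                 function(x) if (is.data.frame(x)) {
                   if (!is.null(x$genes))
                     x$genes <- vapply(x$genes, paste, character(1),
                                       collapse = ";")
                   x
                 } else x,
                 classes = "data.frame", how = "replace")
    jsonlite::write_json(sm, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows", na = "null")
  }
  summary
}

# Accept an in-memory raw manifest data.frame (generator output) and
# normalise it through the same path as load_manifest().
load_manifest_df <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  load_manifest(tmp)
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Pipeline run summary\n")
  cat(sprintf("  seed %d; %d probes x %d samples\n", x$seed, x$n_probes,
              x$n_samples))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %d/%d probes retained\n", x$qc$n_retained,
                x$qc$n_input_probes))
  cat(sprintf("  significant probes (p < %g): %d (%d hyper / %d hypo in early)\n",
              x$params$diff$p_threshold, x$n_significant,
              x$n_hyper_in_early, x$n_hypo_in_early))
  cat(sprintf("  SWAG models per dimension: %s; min AIC %.3f\n",
              paste(x$swag_models_per_dimension, collapse = "/"),
              x$swag_min_aic))
  if (!is.null(x$n_unique_genes))
    cat(sprintf("  unique genes among significant probes: %d\n",
                x$n_unique_genes))
  if (!is.null(x$overlap))
    cat(sprintf("  gene-set overlap: %d / %d / %d (A / B / both)\n",
                x$overlap$n_a, x$overlap$n_b, x$overlap$n_triple))
  if (!is.null(x$truth_recall_top_k))
    cat(sprintf("  planted-probe recall in top-%d importance: %.2f\n",
                x$params$top_k, x$truth_recall_top_k))
  invisible(x)
}
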
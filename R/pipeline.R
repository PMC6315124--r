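#' Pipeline run configuration
#'
#' One serialisable object holding every knob of an end-to-end run:
#' synthetic dataset size, preprocessing thresholds, selection-frequency
#' settings, and QTL/eQTL scan parameters. A run is reproducible from the
#' configuration alone.
#'
#' @param seed master seed for the whole run.
#' @param n_lines,n_genes,n_rnaseq_lines synthetic dataset dimensions.
#' @param min_mean_fpkm,pseudocount preprocessing (see
#'   [preprocess_config()]).
#' @param subset_fraction,n_trials,model_size,frequency_threshold,penalty_rule
#'   selection-frequency settings (see [selection_config()]).
#' @param n_permutations,alpha,window_cm,step_cm,entry_p,exit_p,max_cofactors
#'   QTL scan settings.
#' @param reselect_cofactors re-select cofactors inside each permutation
#'   replicate (slower, accounts for selection)?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_lines = 104, n_genes = 5000,
                            n_rnaseq_lines = 20,
                            min_mean_fpkm = 0.01, pseudocount = 0.01,
                            subset_fraction = 0.10, n_trials = 10000,
                            model_size = 8, frequency_threshold = 0.01,
                            penalty_rule = "fixed_size",
                            n_permutations = 1000, alpha = 0.05,
                            window_cm = 10, step_cm = 1,
                            entry_p = 0.05, exit_p = 0.10, max_cofactors = 5,
                            reselect_cofactors = TRUE) {
  cfg <- list(seed = seed, n_lines = n_lines, n_genes = n_genes,
              n_rnaseq_lines = n_rnaseq_lines,
              min_mean_fpkm = min_mean_fpkm, pseudocount = pseudocount,
              subset_fraction = subset_fraction, n_trials = n_trials,
              model_size = model_size,
              frequency_threshold = frequency_threshold,
              penalty_rule = penalty_rule,
              n_permutations = n_permutations, alpha = alpha,
              window_cm = window_cm, step_cm = step_cm,
              entry_p = entry_p, exit_p = exit_p,
              max_cofactors = max_cofactors,
              reselect_cofactors = reselect_cofactors)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (cfg$n_lines < 3) stop("`n_lines` must be >= 3", call. = FALSE)
  if (cfg$n_genes < 1) stop("`n_genes` must be >= 1", call. = FALSE)
  if (cfg$n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  # constructor-level checks shared with the stage configs
  preprocess_config(cfg$min_mean_fpkm, cfg$pseudocount)
  selection_config(cfg$subset_fraction, cfg$n_trials, cfg$model_size,
                   cfg$frequency_threshold, cfg$penalty_rule, cfg$seed)
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

.hash_string <- function(s) {
  h <- 2166136261
  for (k in utf8ToInt(s)) h <- ((h * 16777619) + k) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes simulate -> write -> preprocess -> selection frequency ->
#' QTL scan -> qPCR/eQTL in order, writing each stage's outputs as TSV/JSON
#' under `out_dir` and returning a machine-readable summary. Re-running
#' with the same configuration reproduces the numeric artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return a `run_summary`: list with `version`, `config`, `config_hash`,
#'   `counts`, `artifacts` (file paths), `elapsed` (seconds per stage) and
#'   `results` (in-memory stage outputs, including the dataset and its
#'   ground truth).
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  elapsed <- numeric(0)
  artifacts <- list()
  results <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      stop("pipeline failed at stage '", name, "' (completed: ",
           if (length(completed)) paste(completed, collapse = ", ") else "none",
           "): ", conditionMessage(e), call. = FALSE)
    })
    completed <<- c(completed, name)
    elapsed[name] <<- proc.time()[["elapsed"]] - t0
    out
  }

  ds <- stage("simulate", function() {
    d <- simulate_bil_dataset(n_lines = config$n_lines,
                              n_genes = config$n_genes,
                              n_rnaseq_lines = config$n_rnaseq_lines,
                              seed = config$seed)
    write_dataset(d, file.path(out_dir, "data"))
    d
  })
  results$dataset <- ds
  artifacts$data_dir <- file.path(out_dir, "data")

  pp <- stage("preprocess", function() {
    pc <- preprocess_config(config$min_mean_fpkm, config$pseudocount)
    expr <- filter_low_expression(ds$expression, pc)
    expr_log <- log_transform(expr, pc)
    df <- data.frame(gene_id = rownames(expr_log), expr_log,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(df, file.path(out_dir, "expression.log2.tsv"))
    expr_log
  })
  results$expr_log <- pp
  artifacts$expression_log2 <- file.path(out_dir, "expression.log2.tsv")

  sel <- stage("selection_frequency", function() {
    sc <- selection_config(config$subset_fraction, config$n_trials,
                           config$model_size, config$frequency_threshold,
                           config$penalty_rule,
                           seed = rng_substream(config$seed, "selection"))
    tab <- run_selection_frequency(pp, ds$trait, sc)
    rep <- report_selected_genes(tab, pp, ds$trait, sc)
    .write_tsv(as.data.frame(tab), file.path(out_dir, "freq.tsv"))
    .write_tsv(rep, file.path(out_dir, "selected_genes.tsv"))
    list(table = tab, report = rep)
  })
  results$selection <- sel
  artifacts$freq <- file.path(out_dir, "freq.tsv")
  artifacts$selected_genes <- file.path(out_dir, "selected_genes.tsv")

  qtl <- stage("qtl_scan", function() {
    geno <- ds$genotypes
    y <- ds$trait$means[rownames(geno)]
    grid <- impute_pseudomarker_genotypes(geno, ds$map, config$step_cm)
    rule <- list(entry_p = config$entry_p, exit_p = config$exit_p,
                 max_cofactors = config$max_cofactors)
    cof <- do.call(select_cofactors, c(list(geno, y), rule))
    thr <- permutation_threshold(
      geno, ds$map, y, n_permutations = config$n_permutations,
      alpha = config$alpha, seed = rng_substream(config$seed, "qtl-perm"),
      cofactor_rule = if (config$reselect_cofactors) rule else NULL,
      cofactors = if (config$reselect_cofactors) character(0) else cof,
      window_cm = config$window_cm, grid = grid)
    prof <- cim_scan(geno, ds$map, y, cofactors = cof,
                     window_cm = config$window_cm, grid = grid,
                     trait_name = "SW")
    calls <- call_qtl(prof, ds$map, thr, "SW")
    .write_tsv(as.data.frame(prof), file.path(out_dir, "profile.tsv"))
    .write_tsv(as.data.frame(calls), file.path(out_dir, "qtl.tsv"))
    list(profile = prof, threshold = thr, calls = calls, grid = grid,
         cofactors = cof)
  })
  results$qtl <- qtl
  artifacts$profile <- file.path(out_dir, "profile.tsv")
  artifacts$qtl <- file.path(out_dir, "qtl.tsv")

  eq <- stage("eqtl_scan", function() {
    sim <- simulate_qpcr(ds$genotypes, ds$map, ds$trait, ds$truth,
                         seed = rng_substream(config$seed, "qpcr"))
    curve <- fit_standard_curve(sim$standards)
    quant <- quantify_samples(curve, sim$cq_table)
    res <- eqtl_scan(ds$genotypes, ds$map, quant$line_means,
                     gene = ds$truth$focal_gene,
                     n_permutations = config$n_permutations,
                     alpha = config$alpha,
                     seed = rng_substream(config$seed, "eqtl-perm"),
                     window_cm = config$window_cm, grid = qtl$grid)
    .write_tsv(as.data.frame(res$profile), file.path(out_dir, "eqtl_profile.tsv"))
    .write_tsv(as.data.frame(res$calls), file.path(out_dir, "eqtl.tsv"))
    c(res, list(quantification = quant, curve = curve))
  })
  results$eqtl <- eq
  artifacts$eqtl_profile <- file.path(out_dir, "eqtl_profile.tsv")
  artifacts$eqtl <- file.path(out_dir, "eqtl.tsv")

  counts <- list(
    genes_total = nrow(ds$expression),
    genes_after_filter = nrow(pp),
    genes_above_threshold = nrow(sel$report),
    n_qtl = nrow(qtl$calls),
    n_eqtl = nrow(eq$calls)
  )
  summary <- list(
    version = as.character(utils::packageVersion("bilfreqsel")),
    config = unclass(config),
    config_hash = .hash_string(jsonlite::toJSON(unclass(config), auto_unbox = TRUE)),
    counts = counts,
    artifacts = lapply(artifacts, normalizePath),
    elapsed = as.list(elapsed)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary$results <- results
  class(summary) <- "run_summary"
  summary
}

#' Evaluate a pipeline run against its planted ground truth
#'
#' @param summary a `run_summary` from [run_pipeline()] (must carry the
#'   synthetic dataset and its truth).
#' @param truth optional `synthetic_truth`; defaults to the one stored in
#'   the run.
#' @return a `truth_evaluation` list:
#'   \describe{
#'     \item{gene_recovery}{fraction of planted causal genes whose
#'       selection frequency exceeds the 95th percentile of null-gene
#'       frequencies, plus planted/null frequency summaries.}
#'     \item{qtl}{per planted QTL: whether it was called on its
#'       chromosome, localisation error (cM) and additive-effect bias at
#'       the nearest call.}
#'   }
#' @export
compare_to_truth <- function(summary, truth = NULL) {
  if (is.null(truth)) truth <- summary$results$dataset$truth
  if (is.null(truth)) stop("no ground truth available for this run", call. = FALSE)
  tab <- summary$results$selection$table
  planted <- intersect(truth$causal_genes$gene_id, tab$gene_id)
  is_planted <- tab$gene_id %in% planted
  null_q95 <- quantile(tab$frequency[!is_planted], 0.95, names = FALSE)
  gene_recovery <- list(
    n_planted = length(planted),
    fraction_above_null_q95 = mean(tab$frequency[is_planted] > null_q95),
    median_planted_frequency = stats::median(tab$frequency[is_planted]),
    null_q95 = null_q95
  )
  calls <- summary$results$qtl$calls
  qtl <- truth$qtl
  rows <- lapply(seq_len(nrow(qtl)), function(i) {
    on_chr <- calls[calls$chromosome == qtl$chromosome[i], , drop = FALSE]
    if (!nrow(on_chr)) {
      return(data.frame(chromosome = qtl$chromosome[i],
                        true_position_cm = qtl$position_cm[i],
                        true_effect = qtl$effect[i], called = FALSE,
                        localization_error_cm = NA_real_,
                        effect_estimate = NA_real_, effect_bias = NA_real_))
    }
    j <- which.min(abs(on_chr$position_cm - qtl$position_cm[i]))
    data.frame(chromosome = qtl$chromosome[i],
               true_position_cm = qtl$position_cm[i],
               true_effect = qtl$effect[i], called = TRUE,
               localization_error_cm = abs(on_chr$position_cm[j] - qtl$position_cm[i]),
               effect_estimate = on_chr$additive_effect[j],
               effect_bias = on_chr$additive_effect[j] - qtl$effect[i])
  })
  structure(list(gene_recovery = gene_recovery, qtl = do.call(rbind, rows)),
            class = "truth_evaluation")
}
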
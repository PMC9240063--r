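#' Read a pipeline configuration
#'
#' Accepts either a YAML file path or a list. Defaults mirror the method's
#' standard settings: score threshold 700, top 200 proximal genes, damping
#' 0.85, selection alpha 0.01, ssGSEA weight 0.25, C grid 0.1-1.0, 100
#' Monte-Carlo iterations at 80% training fraction, 365-day survival horizon.
#'
#' @param config YAML path or named list. Recognized fields: `network`,
#'   `aliases`, `seeds` (character vector or comma string), `gmt`,
#'   `expression`, `clinical`, `expression_test`, `clinical_test`,
#'   `mutations`, `external_scores`, `out_dir`, `score_threshold`, `top_k`,
#'   `damping`, `alpha`, `universe`, `ssgsea_alpha`, `C_grid`, `n_iter`,
#'   `train_frac`, `year_days`, `rng_seed`.
#' @return A validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(score_threshold = 700, top_k = 200, damping = 0.85,
                   alpha = 0.01, universe = "intersection", ssgsea_alpha = 0.25,
                   C_grid = seq(0.1, 1, by = 0.1), n_iter = 100,
                   train_frac = 0.8, year_days = 365, rng_seed = 1L,
                   aliases = NULL, mutations = NULL, external_scores = NULL,
                   expression_test = NULL, clinical_test = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("network", "gmt", "expression", "clinical", "seeds", "out_dir")) {
    assert_that(!is.null(config[[nm]]), sprintf("pipeline config lacks required field '%s'", nm))
  }
  if (is.character(config$seeds) && length(config$seeds) == 1L && grepl(",", config$seeds)) {
    config$seeds <- trimws(strsplit(config$seeds, ",")[[1L]])
  }
  for (nm in c("network", "gmt", "expression", "clinical", "aliases",
               "mutations", "external_scores", "expression_test", "clinical_test")) {
    p <- config[[nm]]
    if (!is.null(p)) assert_that(file.exists(p), sprintf("config file '%s' does not exist: %s", nm, p))
  }
  config
}

score_features <- function(expr, collection, enrichment, ssgsea_alpha) {
  selected <- enrichment$pathway[enrichment$selected]
  assert_that(length(selected) > 0, "no pathway was selected; cannot build features")
  es <- suppressWarnings(ssgsea_es(expr, collection[selected], alpha = ssgsea_alpha))
  nes <- normalize_es(es)
  suppressWarnings(zscore_standardize(nes))
}

#' Run the pipeline end to end from one configuration
#'
#' Executes the full chain — network loading and largest-component
#' extraction, propagation from the drug targets, pathway selection, ssGSEA
#' scoring with cohort z-standardization, and the evaluation stage chosen by
#' `mode` — writing every intermediate artifact plus a machine-readable run
#' manifest (embedded config, seed, per-stage row counts, md5 per file) to
#' the output directory. Reruns with the same config produce byte-identical
#' metrics output.
#'
#' @param config A [pipeline_config()] list or YAML path.
#' @param mode One of `"loocv"`, `"mccv"`, `"across_study"`, `"survival"`,
#'   `"combine"`. `"across_study"` requires `expression_test` /
#'   `clinical_test`; `"combine"` requires `mutations`.
#' @return The manifest list, invisibly; artifacts are on disk under
#'   `config$out_dir`.
#' @export
run_end_to_end <- function(config,
                           mode = c("loocv", "mccv", "across_study", "survival", "combine")) {
  mode <- match.arg(mode)
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_counts <- list()
  artifacts <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs under %s)",
                   name, conditionMessage(e), out), call. = FALSE)
    })
  }

  net <- run_stage("network", {
    g <- load_string_network(cfg$network, cfg$score_threshold, aliases = cfg$aliases)
    largest_connected_component(g)
  })
  stage_counts$network <- c(nodes = igraph::vcount(net), edges = igraph::ecount(net))

  proximal <- run_stage("propagation", {
    pr <- propagate(net, cfg$seeds, damping = cfg$damping)
    select_proximal_genes(pr, k = cfg$top_k)
  })
  f <- file.path(out, "proximal_genes.txt")
  writeLines(proximal, f); artifacts <- c(artifacts, f)
  stage_counts$propagation <- c(proximal_genes = length(proximal))

  enrichment <- run_stage("selection", {
    collection <- read_gmt(cfg$gmt)
    universe <- netbio_universe(net, collection, cfg$universe)
    list(collection = collection,
         table = select_netbio_pathways(proximal, collection, universe, alpha = cfg$alpha))
  })
  f <- file.path(out, "enrichment.tsv")
  write.table(enrichment$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
  artifacts <- c(artifacts, f)
  stage_counts$selection <- c(tested = nrow(enrichment$table),
                              selected = sum(enrichment$table$selected))

  expr <- run_stage("expression", read_expression_tsv(cfg$expression))
  clinical <- run_stage("expression", read_clinical_tsv(cfg$clinical))
  activity <- run_stage("activity", {
    score_features(expr, enrichment$collection, enrichment$table, cfg$ssgsea_alpha)
  })
  f <- file.path(out, "activity.tsv")
  write_expression_tsv(activity, f, id_col = "pathway"); artifacts <- c(artifacts, f)
  stage_counts$activity <- c(pathways = nrow(activity), samples = ncol(activity))

  samples <- intersect(colnames(activity), clinical$sample)
  y <- setNames(clinical$response, clinical$sample)[samples]
  X <- t(activity[, samples, drop = FALSE])
  spec <- model_spec(C_grid = cfg$C_grid, rng_seed = cfg$rng_seed)

  eval_out <- run_stage(mode, switch(mode,
    loocv = {
      res <- loocv(X, y, spec)
      list(predictions = res$predictions,
           metrics = res$metrics[setdiff(names(res$metrics), "confusion")],
           confusion = res$metrics$confusion)
    },
    mccv = {
      res <- monte_carlo_cv(X, y, spec, n_iter = cfg$n_iter, train_frac = cfg$train_frac)
      list(per_iteration = res$per_iteration, metrics = as.list(setNames(res$summary$mean,
           paste0("mean_", res$summary$metric))))
    },
    across_study = {
      expr_b <- read_expression_tsv(cfg$expression_test)
      clin_b <- read_clinical_tsv(cfg$clinical_test)
      act_b <- score_features(expr_b, enrichment$collection, enrichment$table, cfg$ssgsea_alpha)
      res <- across_study_predict(X, y, t(act_b), spec)
      y_b <- setNames(clin_b$response, clin_b$sample)[res$predictions$sample]
      mt <- compute_metrics(y_b, res$predictions$probability)
      list(predictions = res$predictions,
           metrics = mt[setdiff(names(mt), "confusion")], confusion = mt$confusion)
    },
    survival = {
      res <- loocv(X, y, spec)
      strat <- survival_stratify(res$predictions, clinical, year_days = cfg$year_days)
      list(predictions = res$predictions,
           metrics = c(res$metrics[setdiff(names(res$metrics), "confusion")],
                       list(logrank_p = strat$logrank$p,
                            survival_difference = strat$survival_at_horizon$difference)))
    },
    combine = {
      mut <- data.table::fread(cfg$mutations, data.table = FALSE)
      tmb <- setNames(compute_tmb(mut$T, mut$NT), mut$sample)
      res_nb <- loocv(X, y, spec)
      res_tmb <- combined_tmb_netbio(NULL, tmb, y, spec)
      res_comb <- combined_tmb_netbio(activity[, samples, drop = FALSE], tmb, y, spec)
      recl <- reclassification_sets(res_tmb$predictions, res_comb$predictions)
      list(predictions = res_comb$predictions,
           metrics = list(auc_netbio = res_nb$metrics$auc_roc,
                          auc_tmb = res_tmb$metrics$auc_roc,
                          auc_combined = res_comb$metrics$auc_roc,
                          n_R2NR = length(recl$R2NR), n_NR2R = length(recl$NR2R)))
    }
  ))

  if (!is.null(eval_out$predictions)) {
    f <- file.path(out, "predictions.tsv")
    write.table(eval_out$predictions, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f)
  }
  if (!is.null(eval_out$per_iteration)) {
    f <- file.path(out, "mc_iterations.tsv")
    write.table(eval_out$per_iteration, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f)
  }
  f <- file.path(out, "metrics.json")
  jsonlite::write_json(eval_out$metrics, f, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, f)
  stage_counts[[mode]] <- c(samples = length(y))

  manifest <- list(
    mode = mode,
    config = cfg[setdiff(names(cfg), "out_dir")],
    rng_seed = cfg$rng_seed,
    stage_counts = stage_counts,
    artifacts = setNames(as.list(unname(tools::md5sum(artifacts))), basename(artifacts))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
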
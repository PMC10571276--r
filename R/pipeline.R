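# End-to-end orchestration: curation -> descriptors -> ionization -> set
# assembly -> statistics -> rule baselines -> Super Learner, with per-stage
# CSV outputs and a JSON report. All randomness flows from one master seed
# split into fixed per-stage offsets.

#' Pipeline configuration
#'
#' @param input named list of input tables: either `simulate` (a
#'   [benchmark_spec()]) or file paths per source, e.g.
#'   `list(hmdb_gut = "gut.csv", drugbank = "drugs.csv")`.
#' @param outdir output directory (created if needed).
#' @param ph environment pH for ionization (default 7.4).
#' @param outer_folds outer stratified folds; the first is the external test
#'   fold (default 8).
#' @param cv_folds cross-validation folds for the meta-features (default 7).
#' @param split `"random"` (stratified folds) or `"butina"`
#'   (structure-disjoint cluster split for the external test side).
#' @param butina_threshold Tanimoto threshold for the butina split.
#' @param alpha significance level for the statistical battery.
#' @param seed master seed.
#' @return config list of class `gutperm_config`.
#' @export
pipeline_config <- function(input, outdir = tempfile("gutperm_run_"),
                            ph = 7.4, outer_folds = 8L, cv_folds = 7L,
                            split = c("random", "butina"),
                            butina_threshold = 0.8, alpha = 0.05, seed = 1L) {
  split <- match.arg(split)
  structure(list(input = input, outdir = outdir, ph = ph,
                 outer_folds = outer_folds, cv_folds = cv_folds,
                 split = split, butina_threshold = butina_threshold,
                 alpha = alpha, seed = seed),
            class = "gutperm_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; fields as in [pipeline_config()], with an optional
#'   `simulate` block holding [benchmark_spec()] arguments.
#' @return config list of class `gutperm_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (!is.null(y$simulate)) {
    input <- list(simulate = do.call(benchmark_spec, y$simulate))
  }
  pipeline_config(input = input,
                  outdir = y$outdir %||% tempfile("gutperm_run_"),
                  ph = y$ph %||% 7.4,
                  outer_folds = y$outer_folds %||% 8L,
                  cv_folds = y$cv_folds %||% 7L,
                  split = y$split %||% "random",
                  butina_threshold = y$butina_threshold %||% 0.8,
                  alpha = y$alpha %||% 0.05,
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_msg <- function(...) message("[gutperm] ", ...)

#' Run the full analysis pipeline
#'
#' Executes curation, descriptor computation, ionization, set assembly, the
#' statistical battery (class enrichment, scaffold statistics, property
#' comparisons), the reversed-rule baselines and the Super Learner
#' train/evaluate protocol, writing per-stage CSVs and a JSON report to the
#' output directory.
#'
#' @param config a [pipeline_config()] or a YAML path.
#' @return (invisibly) the report list; files are written under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "gutperm_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed)
  t0 <- Sys.time()

  # --- curate --------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$input$simulate)) {
    stage_msg("simulating benchmark")
    bm <- generate_benchmark(config$input$simulate)
    records <- bm$compounds
    truth <- bm$truth
    utils::write.csv(truth, file.path(config$outdir, "truth.csv"),
                     row.names = FALSE)
  } else {
    stage_msg("reading compound tables")
    tabs <- lapply(names(config$input), function(src) {
      p <- config$input[[src]]
      if (!file.exists(p)) stop("input path does not exist: ", p)
      read_compound_table(p, source = src)
    })
    records <- do.call(rbind, tabs)
    records$smiles <- normalize_structures(records$smiles)
    records <- records[!is.na(records$smiles), , drop = FALSE]
    records <- deduplicate_across_sets(records)
  }
  write_compound_table(records, file.path(config$outdir, "curated.csv"))
  report$n_records <- nrow(records)

  # --- descriptors / ionization / assembly ---------------------------------
  stage_msg("computing descriptors for ", nrow(records), " molecules")
  records <- descriptor_table(records)
  records <- ionize_table(records, ph = config$ph)
  records <- assemble_sets(records)
  if (!is.null(truth)) {
    records$permanence_label <- factor(
      truth$label_observed[match(records$id, truth$id)],
      levels = PERMANENCE_LABELS)
  }
  write_compound_table(records, file.path(config$outdir, "master.csv"))
  report$assembly <- lapply(attr(records, "assembly"), function(x)
    if (is.table(x)) as.list(x) else x)

  # --- statistics ----------------------------------------------------------
  stage_msg("statistical battery")
  lab <- droplevels(records$permanence_label)
  if (nlevels(lab) == 2L) {
    tab <- table(records$permanence_label, normalize_chem_class(records$chem_class))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    enr <- contingency_posthoc(unclass(tab), alpha = config$alpha)
    utils::write.csv(tidy_contingency(enr),
                     file.path(config$outdir, "class_enrichment.csv"),
                     row.names = FALSE)
    mw <- mannwhitney_bh(records, DESCRIPTOR_NAMES, alpha = config$alpha)
    utils::write.csv(mw, file.path(config$outdir, "property_tests.csv"),
                     row.names = FALSE)
  }
  ion_dist <- ionization_distribution(records, ph = config$ph,
                                      by = "permanence_label")
  utils::write.csv(as.data.frame(ion_dist),
                   file.path(config$outdir, "ionization_distribution.csv"))
  sc <- scaffold_set_stats(records)
  utils::write.csv(as.data.frame(sc),
                   file.path(config$outdir, "scaffold_stats.csv"),
                   row.names = FALSE)
  report$scaffolds <- as.list(as.data.frame(sc))

  # --- modeling ------------------------------------------------------------
  model_rows <- !is.na(records$permanence_label)
  mdl <- records[model_rows, , drop = FALSE]
  stage_msg("train/test split (", config$split, ")")
  if (config$split == "butina") {
    fps <- fingerprint_matrix(mdl$smiles)
    sp <- butina_split(fps, threshold = config$butina_threshold,
                       test_fraction = 1 / config$outer_folds,
                       seed = config$seed + 11L)
    test_idx <- sp$test
  } else {
    folds <- stratified_folds(mdl$chem_class, k = config$outer_folds,
                              seed = config$seed + 11L)
    test_idx <- which(folds == 1L)
  }
  train_idx <- setdiff(seq_len(nrow(mdl)), test_idx)
  Xtr <- build_feature_matrix(mdl[train_idx, , drop = FALSE])
  Xte <- build_feature_matrix(mdl[test_idx, , drop = FALSE],
                              training_stats = attr(Xtr, "feature_stats"))
  ytr <- mdl$permanence_label[train_idx]
  yte <- mdl$permanence_label[test_idx]
  fl_te <- mdl$fl_flag[test_idx]

  stage_msg("rule baselines")
  lip <- reversed_lipinski(mdl[test_idx, , drop = FALSE])
  veb <- reversed_veber(mdl[test_idx, , drop = FALSE])
  rules_eval <- list(
    lipinski = evaluate_predictions(yte, lip$label, fl_mask = fl_te),
    veber = evaluate_predictions(yte, veb$label, fl_mask = fl_te))
  utils::write.csv(cbind(id = mdl$id[test_idx], lipinski = as.character(lip$label),
                         lipinski_violations = lip$violations,
                         veber = as.character(veb$label)),
                   file.path(config$outdir, "rule_predictions.csv"),
                   row.names = FALSE)

  stage_msg("fitting Super Learner (", length(train_idx), " training rows)")
  sl <- fit_superlearner(Xtr, ytr, cv_folds = config$cv_folds,
                         seed = config$seed + 23L,
                         strata = mdl$chem_class[train_idx])
  proba <- predict(sl, Xte, type = "prob")
  sl_eval <- evaluate_predictions(yte, proba, fl_mask = fl_te)
  utils::write.csv(data.frame(id = mdl$id[test_idx], proba = proba,
                              truth = as.character(yte)),
                   file.path(config$outdir, "superlearner_predictions.csv"),
                   row.names = FALSE)

  report$evaluation <- list(
    superlearner = as.list(as.data.frame(t(as.matrix(sl_eval)))),
    lipinski = as.list(as.data.frame(t(as.matrix(rules_eval$lipinski)))),
    veber = as.list(as.data.frame(t(as.matrix(rules_eval$veber)))))
  report$n_train <- length(train_idx)
  report$n_test <- length(test_idx)
  report$elapsed_s <- round(as.numeric(Sys.time() - t0, units = "secs"), 1)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_msg("done in ", report$elapsed_s, " s -> ", config$outdir)
  invisible(report)
}
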
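#' Workflow configuration
#'
#' Defaults reproduce the method's standard choices: logistic family,
#' co-methylated-locus feature only, 5-fold cross-validation, the
#' super-high and high accuracy categories for downstream analysis, and
#' DML thresholds delta 0.1 / q 0.05.
#'
#' @param ... configuration fields overriding the defaults. Recognized
#'   fields: `family`, `feature_mode`, `k_folds`, `seed`, `categories`,
#'   `delta_threshold`, `q_threshold`, `min_samples`, `min_fit_samples`,
#'   `nn_max_distance`, `normalize_input`, and the paths `betas`,
#'   `manifest`, `fasta`, `models`, `out_dir`, `input`, `reference`,
#'   `groups`.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  config <- list(
    family = "logistic", feature_mode = "cometh", k_folds = 5L, seed = 1L,
    categories = c("super_high", "high"),
    delta_threshold = 0.1, q_threshold = 0.05,
    min_samples = 30L, min_fit_samples = 30L, nn_max_distance = Inf,
    normalize_input = TRUE, normalize_training = TRUE,
    betas = NULL, manifest = NULL, fasta = NULL, models = NULL,
    out_dir = NULL, input = NULL, reference = NULL, groups = NULL)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(config, overrides, keep.null = TRUE)
  if (!config$family %in% c("logistic", "ols"))
    stop("family must be 'logistic' or 'ols'")
  if (!config$feature_mode %in% c("cometh", "cometh+nn", "cometh+nn+seq"))
    stop("feature_mode must be one of cometh, cometh+nn, cometh+nn+seq")
  if (length(config$categories) == 0 ||
      !all(config$categories %in% MODEL_CATEGORIES))
    stop("categories must be a non-empty subset of: ",
         paste(MODEL_CATEGORIES, collapse = ", "))
  if (config$k_folds < 2) stop("k_folds must be >= 2")
  config$k_folds <- as.integer(config$k_folds)
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

#' Read a workflow configuration from a YAML file
#'
#' @param path YAML file of `field: value` pairs.
#' @param ... overrides applied on top of the file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  fields <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(fields, list(...), keep.null = TRUE))
}

# Semantic fields (everything except output locations) hashed into the
# run log so outputs can be traced to a configuration.
#' Hash of the semantic configuration fields
#' @param config a [run_config()].
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  semantic <- config[setdiff(names(unclass(config)), c("out_dir"))]
  semantic <- semantic[order(names(semantic))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(semantic, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

.load_betas <- function(x) {
  if (is.character(x)) read_beta_matrix(x) else { validate_beta_matrix(x); x }
}
.load_manifest <- function(x) {
  if (is.character(x)) read_manifest(x) else { validate_manifest(x); x }
}

.run_log <- function(config, stage, extra = list()) {
  c(list(stage = stage,
         package_version = as.character(utils::packageVersion("pretimeth")),
         seed = config$seed, config_hash = config_hash(config)), extra)
}

.write_outputs <- function(config, stage, objects, log) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    path <- file.path(config$out_dir, nm)
    if (is.matrix(obj)) write_beta_matrix(obj, path)
    else utils::write.table(obj, path, sep = "\t", quote = FALSE,
                            row.names = FALSE, na = "NA")
  }
  jsonlite::write_json(log, file.path(config$out_dir,
                                      paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Build per-locus models from a training beta matrix
#'
#' Orchestrates locus partition, quantile normalization, feature
#' assignment, per-locus cross-validation and model persistence. When
#' `config$models` is set the fitted models are saved there (JSON lines);
#' when `config$out_dir` is set the assignment table, per-category CV
#' report and a machine-readable run log are written too.
#'
#' @param config a [run_config()].
#' @param betas,manifest,seqs optional in-memory inputs overriding the
#'   configured paths.
#' @return invisible list with `models`, `assignments`, `excluded`,
#'   `report`, `category_counts` and `config_hash`.
#' @export
cmd_build <- function(config, betas = NULL, manifest = NULL, seqs = NULL) {
  stopifnot(inherits(config, "run_config"))
  needs_seq <- config$feature_mode == "cometh+nn+seq"
  if (needs_seq && is.null(seqs) && is.null(config$fasta))
    stop("configuration error: feature mode '", config$feature_mode,
         "' requires a FASTA (config$fasta) or in-memory sequences")
  if (is.null(betas)) betas <- .load_betas(config$betas)
  if (is.null(manifest)) manifest <- .load_manifest(config$manifest)
  if (is.null(seqs) && needs_seq) seqs <- read_genome(config$fasta)

  parts <- partition_loci(manifest)
  # synthetic fixtures are generated on the post-normalization beta
  # scale; set normalize_training = FALSE to train on them as-is
  norm <- if (isTRUE(config$normalize_training)) quantile_normalize(betas)
  else betas
  asg <- build_assignments(manifest, norm,
                           model_loci = parts$model_loci,
                           feature_loci = parts$feature_loci,
                           seqs = if (needs_seq) seqs else NULL,
                           min_samples = config$min_samples,
                           nn_max_distance = config$nn_max_distance)
  models <- list()
  excluded <- asg$excluded
  for (i in seq_len(nrow(asg$assignments))) {
    row <- asg$assignments[i, , drop = FALSE]
    cv <- cross_validate(row$model_probe, row, norm,
                         family = config$family,
                         feature_mode = config$feature_mode,
                         k_folds = config$k_folds, seed = config$seed,
                         min_fit_samples = config$min_fit_samples)
    if (is.null(cv)) {
      excluded <- rbind(excluded, data.frame(
        model_probe = row$model_probe,
        reason = "insufficient_complete_samples_or_missing_feature",
        stringsAsFactors = FALSE))
      next
    }
    models[[length(models) + 1L]] <- cv$model
  }
  if (length(models) == 0) stop("zero modelable loci")
  report <- summarize_models(models)
  counts <- table(factor(vapply(models, function(m) m$category, character(1)),
                         levels = MODEL_CATEGORIES))
  message(sprintf("built %d locus models (%s); excluded %d",
                  length(models),
                  paste(sprintf("%s: %d", names(counts), counts),
                        collapse = ", "),
                  nrow(excluded)))
  if (!is.null(config$models)) save_models(models, config$models)
  log <- .run_log(config, "build",
                  list(n_models = length(models),
                       n_excluded = nrow(excluded),
                       category_counts = as.list(counts)))
  .write_outputs(config, "build",
                 list(assignments.tsv = asg$assignments,
                      cv_report.tsv = report), log)
  invisible(list(models = models, assignments = asg$assignments,
                 excluded = excluded, report = report,
                 category_counts = counts, config_hash = config_hash(config)))
}

#' Expand a 450K-style beta matrix with stored models
#'
#' Quantile-normalizes the input (unless `config$normalize_input` is
#' `FALSE`), applies every stored model, filters by the configured
#' accuracy categories, and optionally writes the expanded matrix plus a
#' per-probe sidecar of category and missingness counts.
#'
#' @param config a [run_config()].
#' @param models,input optional in-memory inputs overriding the
#'   configured paths.
#' @return invisible list with `results` (long prediction table),
#'   `expanded` (probes x samples matrix) and `sidecar`.
#' @export
cmd_predict <- function(config, models = NULL, input = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(models)) models <- load_models(config$models)
  if (is.null(input)) input <- .load_betas(config$input)
  if (isTRUE(config$normalize_input) && ncol(input) >= 2)
    input <- quantile_normalize(input)
  results <- predict_matrix(models, input)
  filtered <- filter_by_category(results, config$categories)
  expanded <- predictions_to_matrix(filtered)
  sidecar <- do.call(rbind, lapply(split(filtered, filtered$model_probe),
                                   function(d) data.frame(
    model_probe = d$model_probe[1], category = d$category[1],
    n_predicted = sum(!is.na(d$predicted_beta)),
    n_missing = sum(is.na(d$predicted_beta)), stringsAsFactors = FALSE)))
  rownames(sidecar) <- NULL
  log <- .run_log(config, "predict",
                  list(n_models = length(models),
                       n_predicted_cells = sum(!is.na(expanded))))
  .write_outputs(config, "predict",
                 list(expanded.tsv = expanded, probe_summary.tsv = sidecar),
                 log)
  invisible(list(results = results, filtered = filtered,
                 expanded = expanded, sidecar = sidecar))
}

#' Evaluate stored models against reference measurements
#'
#' Predicts with [cmd_predict()] semantics and scores the non-missing
#' predictions against a reference matrix, optionally per accuracy
#' category.
#'
#' @param config a [run_config()].
#' @param models,input,reference optional in-memory inputs.
#' @param group_by `"none"` or `"category"`.
#' @return invisible metrics data.frame.
#' @export
cmd_evaluate <- function(config, models = NULL, input = NULL,
                         reference = NULL, group_by = "category") {
  stopifnot(inherits(config, "run_config"))
  if (is.null(reference)) reference <- .load_betas(config$reference)
  pred <- cmd_predict(config, models = models, input = input)
  metrics <- evaluate_predictions(pred$filtered, reference,
                                  group_by = group_by)
  log <- .run_log(config, "evaluate", list(groups = metrics$group))
  .write_outputs(config, "evaluate", list(metrics.tsv = metrics), log)
  invisible(metrics)
}

#' Differential methylation on an expanded matrix
#'
#' Welch's t-test per probe, Benjamini-Hochberg correction, the DML
#' conjunction rule (q and delta-beta thresholds from the config), DMG
#' aggregation over promoter annotations, and region summaries.
#'
#' @param config a [run_config()].
#' @param predictions beta matrix (probes x samples), e.g. the expanded
#'   matrix written by [cmd_predict()]; a path or matrix.
#' @param group_labels named group labels (see [call_dml()]); read from
#'   `config$groups` (two-column TSV `sample_id`, `group`) when `NULL`.
#' @param manifest manifest path or data.frame.
#' @return invisible list with `dml`, `dmg` and `regions`.
#' @export
cmd_dml <- function(config, predictions = NULL, group_labels = NULL,
                    manifest = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(predictions)) predictions <- .load_betas(config$input)
  if (is.character(predictions)) predictions <- read_beta_matrix(predictions)
  if (is.null(manifest)) manifest <- .load_manifest(config$manifest)
  if (is.null(group_labels)) {
    gl <- utils::read.table(config$groups, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    group_labels <- stats::setNames(gl$group, gl$sample_id)
  }
  dml <- call_dml(predictions, group_labels,
                  delta_threshold = config$delta_threshold,
                  q_threshold = config$q_threshold)
  dmg <- call_dmg(dml, manifest)
  regions <- if (any(dml$is_dml))
    summarize_dml_regions(dml, annotate_region(dml$probe_id, manifest))
  else NULL
  message(sprintf("%d DMLs, %d DMGs (%d probe(s) skipped)",
                  sum(dml$is_dml), nrow(dmg), attr(dml, "n_skipped")))
  log <- .run_log(config, "dml",
                  list(n_dml = sum(dml$is_dml), n_dmg = nrow(dmg),
                       n_skipped = attr(dml, "n_skipped")))
  .write_outputs(config, "dml", list(dml.tsv = dml, dmg.tsv = dmg), log)
  invisible(list(dml = dml, dmg = dmg, regions = regions))
}
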
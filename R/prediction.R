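#' Apply stored locus models to a new beta matrix
#'
#' For every model x sample, the predicted beta is the model output when
#' all feature loci are present in the input with non-missing values;
#' otherwise the cell is missing with a reason
#' (`feature_absent_from_platform`, `feature_value_missing`, or
#' `model_flagged`). Prediction is a pure function of the model table and
#' input matrix.
#'
#' @param models list of `locus_model` objects.
#' @param input beta matrix (e.g. 450K-style) with feature probes in rows.
#' @return data.frame with columns `model_probe`, `sample_id`,
#'   `predicted_beta`, `category`, `reason` (`NA` where predicted).
#' @export
predict_matrix <- function(models, input) {
  if (length(models) == 0) stop("empty model table")
  validate_beta_matrix(input)
  samples <- colnames(input)
  n_s <- length(samples)
  blocks <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    pred <- rep(NA_real_, n_s)
    reason <- rep(NA_character_, n_s)
    if (isTRUE(m$flagged)) {
      reason[] <- "model_flagged"
    } else if (!all(m$features %in% rownames(input))) {
      reason[] <- "feature_absent_from_platform"
    } else {
      X <- t(input[m$features, , drop = FALSE])
      ok <- stats::complete.cases(X)
      reason[!ok] <- "feature_value_missing"
      if (any(ok))
        pred[ok] <- predict_locus(m$family, m$coefficients, m$intercept,
                                  X[ok, , drop = FALSE])
    }
    blocks[[i]] <- data.frame(
      model_probe = m$model_probe, sample_id = samples,
      predicted_beta = pred, category = m$category, reason = reason,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Filter prediction results by model accuracy category
#'
#' @param results data.frame from [predict_matrix()].
#' @param allowed non-empty subset of
#'   `c("super_high", "high", "medium", "low")`.
#' @return filtered data.frame; the per-category row counts of the input
#'   are attached as attribute `"category_counts"`.
#' @export
filter_by_category <- function(results, allowed) {
  if (length(allowed) == 0) stop("allowed category set must be non-empty")
  bad <- setdiff(allowed, MODEL_CATEGORIES)
  if (length(bad) > 0)
    stop("unknown categories: ", paste(bad, collapse = ", "))
  counts <- table(factor(results$category, levels = MODEL_CATEGORIES))
  out <- results[results$category %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "category_counts") <- counts
  out
}

#' Pivot prediction results to a beta matrix
#'
#' @param results data.frame from [predict_matrix()].
#' @return numeric matrix (model probes x samples) with missing
#'   predictions as `NA`.
#' @export
predictions_to_matrix <- function(results) {
  probes <- unique(results$model_probe)
  samples <- unique(results$sample_id)
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(results$model_probe, probes),
          match(results$sample_id, samples))] <- results$predicted_beta
  m
}

#' Evaluate predictions against reference measurements
#'
#' Pairs each non-missing prediction with the matching reference value
#' and delegates to [compute_metrics()], optionally stratified by model
#' accuracy category.
#'
#' @param results data.frame from [predict_matrix()].
#' @param reference beta matrix of measured values covering the predicted
#'   probes and samples.
#' @param group_by `"none"` (one pooled row) or `"category"`.
#' @return data.frame with columns `group`, `n_pairs` and the eight
#'   metrics.
#' @export
evaluate_predictions <- function(results, reference,
                                 group_by = c("none", "category")) {
  group_by <- match.arg(group_by)
  validate_beta_matrix(reference)
  ok <- !is.na(results$predicted_beta) &
    results$model_probe %in% rownames(reference) &
    results$sample_id %in% colnames(reference)
  res <- results[ok, , drop = FALSE]
  obs <- reference[cbind(match(res$model_probe, rownames(reference)),
                         match(res$sample_id, colnames(reference)))]
  keep <- !is.na(obs)
  res <- res[keep, , drop = FALSE]
  obs <- obs[keep]
  if (nrow(res) == 0) stop("zero overlapping prediction/reference pairs")
  groups <- if (group_by == "none") list(all = seq_len(nrow(res)))
  else split(seq_len(nrow(res)),
             factor(res$category, levels = MODEL_CATEGORIES), drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    data.frame(group = g, n_pairs = length(idx),
               t(compute_metrics(res$predicted_beta[idx], obs[idx])),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
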
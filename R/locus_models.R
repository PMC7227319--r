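#' Fit a fractional-response logistic regression for one locus
#'
#' Beta values are treated as fractional responses: the fit minimizes the
#' binomial deviance sum(-(y log p + (1 - y) log(1 - p))) with
#' p = sigmoid(w . x + b), by iteratively reweighted least squares. The
#' objective is convex, so the solution does not depend on starting
#' values. Responses are clipped to `[eps, 1 - eps]` before fitting.
#'
#' @param y numeric response vector of beta values in \[0, 1\].
#' @param X numeric feature vector or matrix (samples x features).
#' @param eps response clipping bound (default 1e-6).
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @param maxit maximum IRLS iterations (default 100).
#' @param start optional numeric starting coefficients
#'   `(intercept, weights)`.
#' @return list with `coefficients` (one weight per feature), `intercept`,
#'   `converged` and `flagged` (`TRUE` for degenerate feature columns or
#'   non-convergence).
#' @export
fit_logistic <- function(y, X, eps = 1e-6, tol = 1e-8, maxit = 100,
                         start = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("y and X have incompatible dimensions")
  if (any(apply(X, 2, stats::sd) == 0))
    return(list(coefficients = rep(NA_real_, ncol(X)), intercept = NA_real_,
                converged = FALSE, flagged = TRUE))
  yc <- pmin(pmax(y, eps), 1 - eps)
  design <- cbind(`(Intercept)` = 1, X)
  coefs <- if (!is.null(start)) as.numeric(start) else numeric(ncol(design))
  deviance <- function(cf) {
    mu <- sigmoid(as.vector(design %*% cf))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(yc * log(mu) + (1 - yc) * log(1 - mu))
  }
  dev_old <- deviance(coefs)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- as.vector(design %*% coefs)
    mu <- sigmoid(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yc - mu) / wts
    step <- stats::lm.wfit(design, z, wts)$coefficients
    if (!all(is.finite(step))) break
    # step-halving keeps the Newton update inside the convex bowl
    dev_new <- deviance(step)
    halvings <- 0L
    while (dev_new > dev_old + 1e-12 && halvings < 30L) {
      step <- (step + coefs) / 2
      dev_new <- deviance(step)
      halvings <- halvings + 1L
    }
    delta <- max(abs(step - coefs))
    coefs <- step
    dev_old <- dev_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coefficients = unname(coefs[-1]), intercept = unname(coefs[1]),
       converged = converged,
       flagged = !converged || anyNA(coefs))
}

#' Fit an ordinary least squares model for one locus
#'
#' Predictions from this family are clipped to \[0, 1\] at predict time;
#' the fit itself is the unconstrained least-squares solution.
#'
#' @inheritParams fit_logistic
#' @return list with `coefficients`, `intercept`, `converged`, `flagged`
#'   (`TRUE` for a rank-deficient design).
#' @export
fit_ols <- function(y, X) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("y and X have incompatible dimensions")
  design <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(design, y)
  flagged <- fit$rank < ncol(design) || anyNA(fit$coefficients)
  list(coefficients = unname(fit$coefficients[-1]),
       intercept = unname(fit$coefficients[1]),
       converged = !flagged, flagged = flagged)
}

#' Predict beta values from fitted per-locus parameters
#'
#' @param family `"logistic"` or `"ols"`.
#' @param coefficients numeric weights, one per feature.
#' @param intercept numeric intercept.
#' @param X feature vector or matrix (samples x features).
#' @return predicted beta values in \[0, 1\] (logistic by range of the
#'   sigmoid, OLS by clipping).
#' @export
predict_locus <- function(family, coefficients, intercept, X) {
  X <- as.matrix(X)
  eta <- as.vector(X %*% coefficients + intercept)
  if (family == "logistic") sigmoid(eta) else pmin(pmax(eta, 0), 1)
}

#' Eight prediction performance metrics
#'
#' R (Pearson), RMSE and MAE are computed on the continuous values.
#' Values are binarized at 0.5 (status +1 when beta > 0.5, -1 otherwise;
#' observed status is truth, predicted status is the call) to obtain the
#' confusion counts for SE = TP/(TP+FN), SP = TN/(TN+FP), ACC and MCC.
#' AUC is the Mann-Whitney rank statistic of the continuous predictions
#' against the binarized observed status, with midrank tie handling.
#' When the observed statuses are all one class, SE or SP and AUC are
#' reported as missing, never silently 0.
#'
#' @param predicted,observed equal-length numeric vectors in \[0, 1\].
#' @return named numeric vector `r`, `rmse`, `mae`, `se`, `sp`, `mcc`,
#'   `acc`, `auc` (entries may be `NA` when undefined).
#' @export
compute_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) == 0) stop("empty vectors")
  if (anyNA(predicted) || anyNA(observed))
    stop("compute_metrics expects complete vectors")
  err <- predicted - observed
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  r <- if (stats::sd(predicted) > 0 && stats::sd(observed) > 0)
    stats::cor(predicted, observed) else NA_real_
  obs_pos <- observed > 0.5
  pred_pos <- predicted > 0.5
  tp <- sum(pred_pos & obs_pos)
  tn <- sum(!pred_pos & !obs_pos)
  fp <- sum(pred_pos & !obs_pos)
  fn <- sum(!pred_pos & obs_pos)
  n_pos <- tp + fn
  n_neg <- tn + fp
  se <- if (n_pos > 0) tp / n_pos else NA_real_
  sp <- if (n_neg > 0) tn / n_neg else NA_real_
  acc <- (tp + tn) / length(observed)
  denom <- sqrt(prod(c(tn + fn, tn + fp, tp + fn, tp + fp)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  auc <- if (n_pos > 0 && n_neg > 0) {
    ranks <- rank(predicted)  # midranks for ties
    (sum(ranks[obs_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else NA_real_
  c(r = r, rmse = rmse, mae = mae, se = se, sp = sp, mcc = mcc,
    acc = acc, auc = auc)
}

#' Map cross-validated RMSE to an accuracy category
#'
#' Super high accurate: RMSE < 0.05; high: 0.05 <= RMSE < 0.1; medium:
#' 0.1 <= RMSE < 0.15; low: RMSE >= 0.15.
#'
#' @param rmse numeric vector of non-negative RMSE values.
#' @return character vector over `c("super_high", "high", "medium",
#'   "low")`.
#' @export
categorize <- function(rmse) {
  if (any(!is.na(rmse) & rmse < 0)) stop("RMSE must be non-negative")
  out <- MODEL_CATEGORIES[findInterval(rmse, c(0.05, 0.1, 0.15)) + 1L]
  out[is.na(rmse)] <- NA_character_
  out
}

# Feature probes of an assignment row for a given feature mode, in the
# fixed order co-methylated, nearest-neighbour, sequence-match. Returns
# NULL when a required feature is absent.
.assignment_features <- function(assignment, feature_mode = "cometh") {
  cols <- switch(feature_mode,
                 "cometh" = "cometh_probe",
                 "cometh+nn" = c("cometh_probe", "nn_probe"),
                 "cometh+nn+seq" = c("cometh_probe", "nn_probe", "seq_probe"),
                 stop("unknown feature mode: ", feature_mode))
  feats <- unlist(assignment[1, cols], use.names = FALSE)
  if (anyNA(feats)) return(NULL)
  unique_feats <- feats[!duplicated(feats)]
  unique_feats
}

#' Cross-validate a single-locus model
#'
#' Training samples with complete response and features are partitioned
#' into `k_folds` seeded folds; each fold is predicted by a model fitted
#' on the remaining folds, the eight metrics are computed on the pooled
#' out-of-fold predictions, and the returned coefficients are refitted on
#' all complete training samples. The accuracy category is assigned from
#' the pooled cross-validated RMSE.
#'
#' @param model_probe model probe ID.
#' @param assignment one-row data.frame from [build_assignments()].
#' @param training beta matrix of training samples.
#' @param family `"logistic"` (default) or `"ols"`.
#' @param feature_mode `"cometh"`, `"cometh+nn"` or `"cometh+nn+seq"`.
#' @param k_folds number of folds (default 5).
#' @param seed fold-assignment seed (default 1).
#' @param min_fit_samples minimum complete samples (default 30).
#' @return list with `model` (a `locus_model`: probe, features, family,
#'   coefficients, intercept, `cv_metrics`, `category`, `n_train`,
#'   `flagged`) and `oof` (named out-of-fold predictions), or `NULL` when
#'   the locus has too few complete samples or a required feature is
#'   absent.
#' @export
cross_validate <- function(model_probe, assignment, training,
                           family = c("logistic", "ols"),
                           feature_mode = "cometh", k_folds = 5, seed = 1,
                           min_fit_samples = 30) {
  family <- match.arg(family)
  feats <- .assignment_features(assignment, feature_mode)
  if (is.null(feats)) return(NULL)
  if (!all(c(model_probe, feats) %in% rownames(training)))
    stop("probe rows missing from training matrix for ", model_probe)
  y <- training[model_probe, ]
  X <- t(training[feats, , drop = FALSE])
  ok <- !is.na(y) & stats::complete.cases(X)
  n <- sum(ok)
  if (n < max(k_folds, min_fit_samples)) return(NULL)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  folds <- with_local_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  oof <- rep(NA_real_, n)
  names(oof) <- rownames(X)
  flagged <- FALSE
  fitter <- if (family == "logistic") fit_logistic else fit_ols
  for (f in seq_len(k_folds)) {
    train_idx <- folds != f
    fit <- fitter(y[train_idx], X[train_idx, , drop = FALSE])
    if (fit$flagged) { flagged <- TRUE; break }
    oof[!train_idx] <- predict_locus(family, fit$coefficients,
                                     fit$intercept, X[!train_idx, , drop = FALSE])
  }
  if (flagged || anyNA(oof)) {
    model <- list(model_probe = model_probe, features = feats,
                  family = family, coefficients = rep(NA_real_, length(feats)),
                  intercept = NA_real_,
                  cv_metrics = stats::setNames(rep(NA_real_, 8),
                                               c("r", "rmse", "mae", "se", "sp",
                                                 "mcc", "acc", "auc")),
                  category = NA_character_, n_train = n, flagged = TRUE)
    class(model) <- "locus_model"
    return(list(model = model, oof = oof))
  }
  metrics <- compute_metrics(oof, y)
  full <- fitter(y, X)
  model <- list(model_probe = model_probe, features = feats, family = family,
                coefficients = full$coefficients, intercept = full$intercept,
                cv_metrics = metrics,
                category = categorize(metrics[["rmse"]]),
                n_train = n, flagged = full$flagged)
  class(model) <- "locus_model"
  list(model = model, oof = oof)
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model %s: %s on %s; CV RMSE %.4f (%s), n = %d>\n",
              x$model_probe, x$family, paste(x$features, collapse = "+"),
              x$cv_metrics[["rmse"]],
              ifelse(is.na(x$category), "flagged", x$category), x$n_train))
  invisible(x)
}

MODEL_SCHEMA_VERSION <- 1L

#' Save fitted locus models as JSON lines
#'
#' One JSON object per model with a `schema_version` field; coefficients
#' are written at full double precision, so save/load round-trips are
#' lossless.
#'
#' @param models list of `locus_model` objects.
#' @param path output path.
#' @export
save_models <- function(models, path) {
  lines <- vapply(models, function(m) {
    rec <- list(schema_version = MODEL_SCHEMA_VERSION,
                model_probe = m$model_probe,
                features = as.list(m$features),
                family = m$family,
                coefficients = as.list(m$coefficients),
                intercept = m$intercept,
                cv_metrics = as.list(m$cv_metrics),
                category = m$category,
                n_train = m$n_train,
                flagged = m$flagged)
    # 17 significant digits make double round-trips lossless
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                                  na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Load locus models saved by [save_models()]
#'
#' @param path JSON-lines model file.
#' @return list of `locus_model` objects.
#' @export
load_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(line) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    if (is.null(rec$schema_version) ||
        rec$schema_version != MODEL_SCHEMA_VERSION)
      stop("unsupported model file schema version: ",
           if (is.null(rec$schema_version)) "<missing>" else rec$schema_version)
    cv <- unlist(rec$cv_metrics)
    cv <- stats::setNames(as.numeric(cv), names(cv))
    m <- list(model_probe = rec$model_probe,
              features = as.character(unlist(rec$features)),
              family = rec$family,
              coefficients = as.numeric(unlist(rec$coefficients)),
              intercept = if (is.null(rec$intercept)) NA_real_ else rec$intercept,
              cv_metrics = cv,
              category = if (is.null(rec$category)) NA_character_ else rec$category,
              n_train = rec$n_train,
              flagged = isTRUE(rec$flagged))
    class(m) <- "locus_model"
    m
  })
}

#' Summarize fitted models per accuracy category
#'
#' Mirrors the per-category metrics report: one row per category (plus an
#' `all` row) with the locus count and the mean of each cross-validation
#' metric.
#'
#' @param models list of `locus_model` objects.
#' @return data.frame with columns `category`, `n`, and the mean of the
#'   eight metrics.
#' @export
summarize_models <- function(models) {
  keep <- !vapply(models, function(m) isTRUE(m$flagged), logical(1))
  models <- models[keep]
  cats <- vapply(models, function(m) m$category, character(1))
  metrics <- do.call(rbind, lapply(models, function(m) m$cv_metrics))
  groups <- c(list(all = seq_along(models)),
              lapply(stats::setNames(MODEL_CATEGORIES, MODEL_CATEGORIES),
                     function(cat) which(cats == cat)))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    means <- if (length(idx) > 0)
      colMeans(metrics[idx, , drop = FALSE], na.rm = TRUE)
    else stats::setNames(rep(NA_real_, 8), colnames(metrics))
    data.frame(category = g, n = length(idx), t(means),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
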
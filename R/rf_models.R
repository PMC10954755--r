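# Random forest models of readthrough efficiency.
#
# Regression models predict log2 readthrough efficiency directly;
# classification models separate extreme "high" from "low" readthrough
# transcripts. mtry is tuned by k-fold cross-validation over a small grid;
# the final forest is refit on all data with out-of-bag permutation
# importance (the %IncMSE / mean-decrease-accuracy convention: mean
# across-tree increase in OOB error after permuting a feature, divided by
# its standard error). Fits are delegated to ranger with a fixed seed and
# one thread, so results are fully reproducible.

#' Model specification for readthrough forests
#'
#' @param task `"regression"` or `"classification"`.
#' @param n_trees Number of trees (default 100).
#' @param cv_folds Cross-validation folds for mtry tuning (default 5).
#' @param mtry_grid Integer candidates for mtry; `NULL` for the default
#'   grid of [default_mtry_grid()].
#' @param seed Integer seed driving fold assignment and all forest fits.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(task = c("regression", "classification"),
                       n_trees = 100L, cv_folds = 5L, mtry_grid = NULL,
                       seed = 1L) {
  task <- match.arg(task)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(task = task, n_trees = as.integer(n_trees),
                 cv_folds = as.integer(cv_folds),
                 mtry_grid = mtry_grid, seed = as.integer(seed)),
            class = "model_spec")
}

#' Default mtry candidate grid
#'
#' Candidates `{1, ceiling(p/10), ceiling(sqrt(p)), ceiling(p/3)}`
#' (deduplicated, clipped to `[1, p]`), covering both the classification
#' (`sqrt(p)`) and regression (`p/3`) heuristics.
#'
#' @param p Number of features.
#' @return Sorted integer vector.
#' @export
default_mtry_grid <- function(p) {
  g <- c(1L, ceiling(p / 10), ceiling(sqrt(p)), ceiling(p / 3))
  sort(unique(pmin(as.integer(p), pmax(1L, as.integer(g)))))
}

# Convert a feature data frame to a ranger-ready data frame. Character
# columns become factors with a fixed level registry (alphabetical at
# training time); numeric columns pass through. At prediction time values
# absent from the registry map to "NA_short" when that level exists,
# otherwise to the first registered level, with a warning.
encode_features <- function(features, feature_names, registry = NULL) {
  missing_cols <- setdiff(feature_names, names(features))
  if (length(missing_cols)) {
    stop("feature table is missing model features: ",
         paste(head(missing_cols, 5), collapse = ", "))
  }
  x <- features[, feature_names, drop = FALSE]
  build <- is.null(registry)
  if (build) registry <- list()
  for (cn in feature_names) {
    v <- x[[cn]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      if (build) {
        registry[[cn]] <- sort(unique(v))
      } else {
        lev <- registry[[cn]]
        unseen <- !(v %in% lev) & !is.na(v)
        if (any(unseen)) {
          fallback <- if ("NA_short" %in% lev) "NA_short" else lev[1]
          warning(sum(unseen), " unseen level(s) in feature '", cn,
                  "' mapped to '", fallback, "'")
          v[unseen] <- fallback
        }
      }
      x[[cn]] <- factor(v, levels = registry[[cn]])
    } else {
      if (build) registry[[cn]] <- NULL
      x[[cn]] <- as.numeric(v)
    }
  }
  list(data = x, registry = registry)
}

rt_ranger <- function(x, y, n_trees, mtry, seed, importance = "none",
                      classification = FALSE) {
  ranger::ranger(x = x, y = y, num.trees = n_trees, mtry = mtry,
                 seed = seed, num.threads = 1L,
                 importance = importance,
                 scale.permutation.importance = importance == "permutation",
                 respect.unordered.factors = "order",
                 probability = FALSE)
}

cv_fold_ids <- function(n, k, seed, strata = NULL) {
  with_rt_seed(seed, {
    if (is.null(strata)) {
      sample(rep_len(seq_len(k), n))
    } else {
      ids <- integer(n)
      for (s in unique(strata)) {
        idx <- which(strata == s)
        ids[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      ids
    }
  })
}

# Shared CV + final-fit engine for both tasks.
train_forest <- function(features, y, spec, schema, tune) {
  feature_names <- if (!is.null(schema)) {
    intersect(schema$feature_names, names(features))
  } else {
    setdiff(names(features), "transcript_id")
  }
  enc <- encode_features(features, feature_names)
  x <- enc$data
  n <- nrow(x)
  p <- length(feature_names)
  grid <- spec$mtry_grid
  if (is.null(grid)) grid <- default_mtry_grid(p)
  grid <- sort(unique(pmin(p, pmax(1L, as.integer(grid)))))
  classification <- spec$task == "classification"
  strata <- if (classification) y else NULL
  cv_table <- NULL
  if (tune) {
    folds <- cv_fold_ids(n, spec$cv_folds, substream_seed(spec$seed, "cv_folds"),
                         strata = strata)
    metric <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      pred <- if (classification) numeric(n) else numeric(n)
      for (f in seq_len(spec$cv_folds)) {
        test <- folds == f
        fit <- rt_ranger(x[!test, , drop = FALSE], y[!test], spec$n_trees,
                         grid[gi],
                         substream_seed(spec$seed, sprintf("cv_%d_%d", gi, f)))
        pred[test] <- forest_scores(fit, x[test, , drop = FALSE],
                                    classification)
      }
      metric[gi] <- if (classification) auroc(pred, y) else nrmse(y, pred)
    }
    cv_table <- data.frame(mtry = grid, metric = metric)
    best <- if (classification) which.max(metric) else which.min(metric)
    mtry <- grid[best]
    cv_metric <- metric[best]
  } else {
    # tuning disabled: the backend's default mtry heuristic
    mtry <- NULL
    cv_metric <- NA_real_
  }
  fit <- rt_ranger(x, y, spec$n_trees,
                   if (is.null(mtry)) NULL else mtry,
                   substream_seed(spec$seed, "final_fit"),
                   importance = "permutation",
                   classification = classification)
  structure(list(task = spec$task, fit = fit,
                 schema_name = if (!is.null(schema)) schema$name else "custom",
                 groups = if (!is.null(schema)) schema$groups else NULL,
                 feature_names = feature_names,
                 registry = enc$registry,
                 mtry = fit$mtry, cv_metric = cv_metric,
                 cv_table = cv_table, spec = spec,
                 y_range = if (!classification) range(y) else NULL,
                 training_ids = features$transcript_id,
                 x = x, y = y),
            class = "rt_model")
}

# Out-of-fold scores: numeric predictions for regression, "high"-vote
# fractions for classification.
forest_scores <- function(fit, newdata, classification) {
  if (!classification) {
    return(predict(fit, data = newdata, num.threads = 1L)$predictions)
  }
  all_pred <- predict(fit, data = newdata, num.threads = 1L,
                      predict.all = TRUE)$predictions
  idx_high <- which(fit$forest$levels == "high")
  rowMeans(all_pred == idx_high)
}

#' Train a random forest regressor of readthrough efficiency
#'
#' mtry is chosen to minimize cross-validated NRMSE (RMSE divided by the
#' range of the response); the final forest is refit on all data at the
#' chosen mtry with permutation importance.
#'
#' @param features Feature data frame (`transcript_id` plus feature
#'   columns), e.g. from [extract_features()] +
#'   [attach_negative_controls()].
#' @param target Numeric log2 readthrough efficiencies, aligned with
#'   `features` rows.
#' @param spec A [model_spec()] with `task = "regression"`.
#' @param schema Optional [feature_schema()] restricting/ordering the
#'   feature columns.
#' @param tune Tune mtry by CV (`TRUE`, default) or keep the backend
#'   default heuristic (`FALSE`, used for schema-variant models).
#' @return Object of class `rt_model`.
#' @export
train_regressor <- function(features, target, spec = model_spec("regression"),
                            schema = NULL, tune = TRUE) {
  if (spec$task != "regression") stop("spec$task must be 'regression'")
  if (length(target) != nrow(features)) {
    stop("target length must match feature rows")
  }
  if (any(!is.finite(target))) stop("targets must be finite")
  if (nrow(features) < 50) stop("need at least 50 training records")
  if (diff(range(target)) == 0) {
    stop("constant target: NRMSE undefined")
  }
  train_forest(features, target, spec, schema, tune)
}

#' Train a random forest classifier of extreme readthrough groups
#'
#' mtry is chosen to maximize cross-validated AUROC computed from
#' out-of-fold tree-vote fractions.
#'
#' @param labels Character or factor with levels `"high"` and `"low"`.
#' @inheritParams train_regressor
#' @return Object of class `rt_model`.
#' @export
train_classifier <- function(features, labels,
                             spec = model_spec("classification"),
                             schema = NULL, tune = TRUE) {
  if (spec$task != "classification") stop("spec$task must be 'classification'")
  labels <- factor(as.character(labels), levels = c("low", "high"))
  if (anyNA(labels)) stop("labels must be 'high' or 'low'")
  counts <- table(labels)
  if (any(counts == 0)) stop("both classes must be present")
  if (min(counts) < spec$cv_folds) {
    stop("cv_folds (", spec$cv_folds, ") exceeds the smaller class count (",
         min(counts), ")")
  }
  train_forest(features, labels, spec, schema, tune)
}

#' @export
print.rt_model <- function(x, ...) {
  cat("rt_model (", x$task, "), schema '", x$schema_name, "', ",
      length(x$feature_names), " features, ntree=", x$fit$num.trees,
      ", mtry=", x$mtry,
      if (!is.na(x$cv_metric))
        paste0(", CV ", if (x$task == "regression") "NRMSE" else "AUROC",
               "=", signif(x$cv_metric, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Out-of-bag permutation importance table
#'
#' Per feature, the across-tree mean increase in out-of-bag error after
#' permuting that feature's OOB values, divided by its standard error
#' (the %IncMSE convention for regression, mean decrease accuracy for
#' classification). Set `scaled = FALSE` for the unscaled mean difference
#' (recomputed on an identically seeded refit).
#'
#' @param model An `rt_model`.
#' @param scaled Divide by the standard error (default `TRUE`).
#' @return Data frame `feature`, `score`, `rank` (1 = most important),
#'   `group`.
#' @export
permutation_importance <- function(model, scaled = TRUE) {
  if (scaled) {
    imp <- ranger::importance(model$fit)
  } else {
    # identically seeded refit reproduces the same forest, differing only
    # in the importance scaling
    refit <- ranger::ranger(
      x = model$x, y = model$y, num.trees = model$spec$n_trees,
      mtry = model$mtry, seed = substream_seed(model$spec$seed, "final_fit"),
      num.threads = 1L, importance = "permutation",
      scale.permutation.importance = FALSE,
      respect.unordered.factors = "order")
    imp <- ranger::importance(refit)
  }
  out <- data.frame(feature = names(imp), score = unname(imp),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$score, ties.method = "min")
  out$group <- if (!is.null(model$groups)) {
    unname(model$groups[out$feature])
  } else {
    NA_character_
  }
  out[order(out$rank), , drop = FALSE]
}

#' Predict readthrough from a trained model
#'
#' Regression models return predicted log2 readthrough efficiency;
#' classification models return the fraction of trees voting `"high"`.
#' Unseen categorical levels are mapped to the explicit `"NA_short"`
#' bucket (with a warning), never an error.
#'
#' @param model An `rt_model`.
#' @param features Feature data frame conforming to the model's schema.
#' @return Numeric vector, one prediction per row of `features`.
#' @export
predict_readthrough <- function(model, features) {
  enc <- encode_features(features, model$feature_names, model$registry)
  forest_scores(model$fit, enc$data, model$task == "classification")
}

#' Root mean squared error normalized to the response range
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return `sqrt(mean((y - yhat)^2)) / (max(y) - min(y))`.
#' @export
nrmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  r <- diff(range(y))
  if (r == 0) stop("zero response range: NRMSE undefined")
  sqrt(mean((y - yhat)^2)) / r
}

#' Area under the ROC curve (rank / concordance formulation)
#'
#' Equals the probability that a random `"high"` record outscores a random
#' `"low"` record, ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels `"high"`/`"low"` labels (character or factor).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "high"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
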
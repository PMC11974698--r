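#' Run the shuffle test: evaluate a predictor at every disruption level
#'
#' The central experiment of the package: the test set is shuffled at each
#' requested level (the identity level is always evaluated first as the
#' baseline), the predictor is applied to each shuffled copy, and task
#' metrics are computed per level. A drop in performance at the first level
#' that destroys a given statistic localizes which data feature the predictor
#' exploits; shuffles are applied to test data only — the predictor is never
#' re-fit.
#'
#' @param dataset a `hap_dataset` (classification or regression).
#' @param predictor one of: an [fit_oracle()] `oracle_classifier`; a function
#'   taking a list of matrices and returning either a list with `labels` and
#'   optionally `scores` (classification) or a numeric vector (regression);
#'   or a named list mapping each level token to precomputed predictions of
#'   those same shapes (for external models evaluated offline, e.g. published
#'   networks — predictions are produced elsewhere on archives written by
#'   [shuffle_battery()]).
#' @param levels shuffle levels to test; defaults to all six.
#' @param master_seed integer seed driving all per-matrix shuffle seeds.
#' @return object of class `degradation_report`: list with `task`, `levels`,
#'   `metrics` (named per-level list as returned by [evaluate_classifier()] /
#'   [evaluate_regressor()]) and `provenance`.
#' @export
run_shuffle_test <- function(dataset, predictor, levels = shuffle_levels(),
                             master_seed = 1L) {
  if (!inherits(dataset, "hap_dataset")) {
    stop("dataset must be a hap_dataset", call. = FALSE)
  }
  levels <- unique(c("identity", vapply(levels, check_level, character(1),
                                        USE.NAMES = FALSE)))
  shuffled <- shuffle_battery(dataset$matrices, levels, master_seed)
  n <- length(dataset$matrices)
  metrics <- vector("list", length(levels))
  names(metrics) <- levels
  positive <- if (inherits(predictor, "oracle_classifier")) {
    predictor$high_class
  } else {
    NULL
  }
  for (lv in levels) {
    pred <- get_predictions(predictor, shuffled[[lv]], lv)
    if (dataset$task == "classification") {
      if (is.null(pred$labels) || length(pred$labels) != n) {
        stop(sprintf("predictor contract violated at level `%s`: expected %d labels",
                     lv, n), call. = FALSE)
      }
      metrics[[lv]] <- evaluate_classifier(dataset$labels, pred$labels,
                                           scores = pred$scores,
                                           positive = positive)
    } else {
      values <- if (is.list(pred)) pred$values %||% pred$labels else pred
      values <- as.numeric(values)
      if (length(values) != n) {
        stop(sprintf("predictor contract violated at level `%s`: expected %d predictions",
                     lv, n), call. = FALSE)
      }
      metrics[[lv]] <- evaluate_regressor(dataset$labels, values)
    }
  }
  structure(
    list(task = dataset$task,
         levels = levels,
         metrics = metrics,
         provenance = list(master_seed = as.integer(master_seed),
                           n_matrices = n,
                           dataset_metadata = dataset$metadata,
                           predictor = describe_predictor(predictor))),
    class = "degradation_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_predictions <- function(predictor, matrices, level) {
  if (inherits(predictor, "oracle_classifier")) {
    predict(predictor, matrices)
  } else if (is.function(predictor)) {
    predictor(matrices)
  } else if (is.list(predictor)) {
    if (is.null(predictor[[level]])) {
      stop(sprintf("no precomputed predictions supplied for level `%s`", level),
           call. = FALSE)
    }
    predictor[[level]]
  } else {
    stop("unsupported predictor type", call. = FALSE)
  }
}

describe_predictor <- function(predictor) {
  if (inherits(predictor, "oracle_classifier")) {
    sprintf("oracle_classifier(%s)", predictor$statistic)
  } else if (is.function(predictor)) {
    "function"
  } else {
    "precomputed predictions"
  }
}

#' @export
print.degradation_report <- function(x, ...) {
  cat(sprintf("<degradation_report> task: %s, %d matrices\n",
              x$task, x$provenance$n_matrices %||% NA))
  if (!is.null(x$aggregate)) {
    cat(sprintf("  aggregated over %d predictor instances (mean [95%% CI]):\n",
                x$n_instances))
    for (lv in x$levels) {
      ag <- x$aggregate[[lv]]
      parts <- vapply(names(ag), function(metric) {
        sprintf("%s %.3f [%.3f, %.3f]", metric, ag[[metric]]$mean,
                ag[[metric]]$ci[1L], ag[[metric]]$ci[2L])
      }, character(1))
      cat(sprintf("  %-20s %s\n", lv, paste(parts, collapse = "  ")))
    }
    return(invisible(x))
  }
  for (lv in x$levels) {
    mt <- x$metrics[[lv]]
    line <- if (x$task == "classification") {
      sprintf("accuracy %.3f (NIR %.3f)%s", mt$accuracy, mt$no_information_rate,
              if (!is.null(mt$auc)) sprintf("  AUC %.3f", mt$auc) else "")
    } else {
      sprintf("Spearman r %.3f  RMSE %.4f%s", mt$spearman_r, mt$rmse,
              if (isTRUE(mt$degenerate)) "  (degenerate)" else "")
    }
    cat(sprintf("  %-20s %s\n", lv, line))
  }
  invisible(x)
}

#' Aggregate degradation reports across predictor instances
#'
#' Independently trained instances of the same architecture vary; aggregating
#' their shuffle-test reports shows whether the degradation pattern is a
#' property of the architecture rather than one training run. Per level and
#' scalar metric this computes the mean and an empirical 95% percentile
#' interval (2.5/97.5 percentiles, linear interpolation) across instances.
#'
#' @param reports list of >= 2 `degradation_report`s over the same task and
#'   levels.
#' @return a `degradation_report` with `aggregate` (per level, per metric:
#'   `mean`, `ci`, `values`), `n_instances`, and the per-instance metrics
#'   retained under `instances`.
#' @export
aggregate_instances <- function(reports) {
  if (!is.list(reports) || length(reports) < 2L ||
      !all(vapply(reports, inherits, logical(1), "degradation_report"))) {
    stop("need a list of >= 2 degradation_report objects", call. = FALSE)
  }
  base <- reports[[1L]]
  for (r in reports[-1L]) {
    if (!identical(r$levels, base$levels) || !identical(r$task, base$task)) {
      stop("reports differ in levels or task; cannot aggregate", call. = FALSE)
    }
  }
  metric_names <- if (base$task == "classification") {
    intersect(c("accuracy", "no_information_rate", "auc"),
              names(base$metrics[[1L]]))
  } else {
    c("spearman_r", "rmse")
  }
  aggregate <- lapply(base$levels, function(lv) {
    per_metric <- lapply(metric_names, function(metric) {
      v <- vapply(reports, function(r) as.numeric(r$metrics[[lv]][[metric]]),
                  numeric(1))
      list(mean = mean(v),
           ci = stats::quantile(v, c(0.025, 0.975), type = 7, names = FALSE),
           values = v)
    })
    names(per_metric) <- metric_names
    per_metric
  })
  names(aggregate) <- base$levels
  structure(
    list(task = base$task,
         levels = base$levels,
         metrics = base$metrics,
         instances = lapply(reports, `[[`, "metrics"),
         aggregate = aggregate,
         n_instances = length(reports),
         provenance = base$provenance),
    class = "degradation_report"
  )
}
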
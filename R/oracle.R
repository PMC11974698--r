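#' Statistic functions usable by oracle classifiers
#'
#' Each oracle predicts through exactly one scalar summary statistic of the
#' input matrix. `oracle_statistics()` lists the supported names;
#' `oracle_statistic_fun()` returns the corresponding function. For
#' `last_informative_column` an all-zero matrix (no informative column) is
#' scored as 0 so thresholding stays well defined.
#'
#' @return `oracle_statistics()`: character vector of statistic names.
#' @export
oracle_statistics <- function() {
  c("pi", "h1", "singleton_fraction", "seg_sites", "last_informative_column")
}

#' @rdname oracle_statistics
#' @param statistic one of [oracle_statistics()].
#' @export
oracle_statistic_fun <- function(statistic) {
  switch(statistic,
    pi = pairwise_pi,
    h1 = garud_h1,
    singleton_fraction = function(m) {
      s <- afs(m)
      seg <- sum(s$counts)
      if (seg == 0L) return(0)
      unname(s$counts["1"]) / seg
    },
    seg_sites = function(m) sum(afs(m)$counts),
    last_informative_column = function(m) {
      lic <- last_informative_column(m)
      if (is.na(lic)) 0 else as.numeric(lic)
    },
    stop("unknown oracle statistic: ", toString(statistic),
         " (expected one of: ", paste(oracle_statistics(), collapse = ", "), ")",
         call. = FALSE)
  )
}

#' Fit a single-statistic threshold classifier
#'
#' An interpretable stand-in predictor whose decision depends on the input
#' matrix only through one named summary statistic: the threshold maximizing
#' training accuracy is chosen over the midpoints of adjacent sorted distinct
#' statistic values (plus the two outer extremes), ties broken toward the
#' lower threshold, and each side of the threshold is assigned the
#' majority class of the training points on that side. Because the predictor
#' is a pure function of its statistic, its performance under a shuffle level
#' is bit-identical to baseline exactly when that level preserves the
#' statistic — which is what makes these oracles useful probes of the shuffle
#' battery.
#'
#' @param dataset a binary-classification `hap_dataset`.
#' @param statistic one of [oracle_statistics()].
#' @return object of class `oracle_classifier`: list with `statistic`,
#'   `threshold`, `high_class`, `low_class`, `classes` and
#'   `training_accuracy`.
#' @export
fit_oracle <- function(dataset, statistic) {
  if (!inherits(dataset, "hap_dataset") || dataset$task != "classification") {
    stop("fit_oracle requires a classification hap_dataset", call. = FALSE)
  }
  classes <- sort(unique(dataset$labels))
  if (length(classes) != 2L) {
    stop("fit_oracle requires exactly 2 classes; got ", length(classes),
         call. = FALSE)
  }
  f <- oracle_statistic_fun(statistic)
  values <- vapply(dataset$matrices, f, numeric(1))
  if (anyNA(values)) {
    stop("statistic `", statistic, "` is undefined (NA) for some matrix",
         call. = FALSE)
  }
  sv <- sort(unique(values))
  candidates <- if (length(sv) == 1L) {
    sv
  } else {
    c(sv[1L] - 1, (sv[-length(sv)] + sv[-1L]) / 2)
  }
  best <- NULL
  for (thr in candidates) {
    high <- values > thr
    for (hc in classes) {
      lc <- setdiff(classes, hc)
      pred <- ifelse(high, hc, lc)
      acc <- mean(pred == dataset$labels)
      if (is.null(best) || acc > best$acc) {
        best <- list(thr = thr, hc = hc, lc = lc, acc = acc)
      }
    }
  }
  structure(
    list(statistic = statistic,
         threshold = best$thr,
         high_class = best$hc,
         low_class = best$lc,
         classes = classes,
         training_accuracy = best$acc),
    class = "oracle_classifier"
  )
}

#' Predict with an oracle classifier
#'
#' @param object an `oracle_classifier` from [fit_oracle()].
#' @param matrices list of `hap_matrix` objects (or a `hap_dataset`).
#' @param ... unused.
#' @return list with `labels` (character) and `scores` (the raw statistic
#'   values; larger score means the `high_class` side).
#' @export
predict.oracle_classifier <- function(object, matrices, ...) {
  if (inherits(matrices, "hap_dataset")) matrices <- matrices$matrices
  f <- oracle_statistic_fun(object$statistic)
  scores <- vapply(matrices, f, numeric(1))
  labels <- ifelse(scores > object$threshold, object$high_class, object$low_class)
  list(labels = labels, scores = scores)
}

#' @export
print.oracle_classifier <- function(x, ...) {
  cat(sprintf("<oracle_classifier> %s > %s -> %s, else %s (train acc %.3f)\n",
              x$statistic, format(x$threshold, digits = 4),
              x$high_class, x$low_class, x$training_accuracy))
  invisible(x)
}
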
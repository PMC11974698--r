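#' Write a degradation report to JSON and/or TSV
#'
#' JSON carries the full nested structure (per-level metrics including
#' confusion matrices and ROC points, instance and aggregate blocks,
#' provenance) and round-trips through [read_report()] exactly. TSV is a flat
#' view — one row per level x metric x instance plus aggregate rows with the
#' percentile interval — convenient for plotting metric-vs-level curves.
#'
#' @param r a `degradation_report`.
#' @param path output stem; `.json` / `.tsv` are appended.
#' @param format `"json"`, `"tsv"` or `"both"`.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(r, path, format = c("both", "json", "tsv")) {
  if (!inherits(r, "degradation_report")) {
    stop("expected a degradation_report", call. = FALSE)
  }
  format <- match.arg(format)
  written <- character(0)
  if (format %in% c("json", "both")) {
    f <- paste0(path, ".json")
    # digits = I(17): significant digits, enough for exact double round-trips
    jsonlite::write_json(report_to_list(r), f, auto_unbox = TRUE,
                         digits = I(17), null = "null", pretty = TRUE)
    written <- c(written, f)
  }
  if (format %in% c("tsv", "both")) {
    f <- paste0(path, ".tsv")
    utils::write.table(report_to_tsv(r), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' @rdname write_report
#' @param json_path path to a JSON file written by `write_report`.
#' @export
read_report <- function(json_path) {
  x <- jsonlite::read_json(json_path)
  list_to_report(x)
}

scalar_metric_names <- function(task, metric_list) {
  if (task == "classification") {
    intersect(c("accuracy", "no_information_rate", "auc"), names(metric_list))
  } else {
    c("spearman_r", "rmse")
  }
}

report_to_tsv <- function(r) {
  rows <- list()
  add <- function(level, metric, instance, value, lo = NA_real_, hi = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, metric = metric, instance = instance,
      value = value, ci_lo = lo, ci_hi = hi, stringsAsFactors = FALSE)
  }
  for (lv in r$levels) {
    metric_names <- scalar_metric_names(r$task, r$metrics[[lv]])
    if (is.null(r$aggregate)) {
      for (metric in metric_names) {
        add(lv, metric, "point", as.numeric(r$metrics[[lv]][[metric]]))
      }
    } else {
      for (metric in metric_names) {
        ag <- r$aggregate[[lv]][[metric]]
        for (i in seq_along(ag$values)) {
          add(lv, metric, as.character(i), ag$values[i])
        }
        add(lv, metric, "aggregate", ag$mean, ag$ci[1L], ag$ci[2L])
      }
    }
  }
  do.call(rbind, rows)
}

metrics_to_list <- function(mt, task) {
  out <- list()
  for (nm in names(mt)) {
    v <- mt[[nm]]
    out[[nm]] <- if (nm == "confusion") {
      list(classes = rownames(v),
           counts = unname(apply(v, 1L, function(row) as.list(row),
                                 simplify = FALSE)))
    } else if (nm == "roc") {
      list(threshold = sprintf("%.17g", v$threshold),
           fpr = v$fpr, tpr = v$tpr)
    } else {
      v
    }
  }
  out
}

metrics_from_list <- function(x, task) {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    out[[nm]] <- switch(nm,
      confusion = {
        classes <- unlist(v$classes)
        counts <- matrix(as.integer(unlist(v$counts)),
                         nrow = length(classes), byrow = TRUE,
                         dimnames = list(true = classes, predicted = classes))
        counts
      },
      roc = data.frame(threshold = as.numeric(unlist(v$threshold)),
                       fpr = as.numeric(unlist(v$fpr)),
                       tpr = as.numeric(unlist(v$tpr))),
      accuracy = ,
      no_information_rate = ,
      auc = ,
      spearman_r = ,
      rmse = as.numeric(v),
      degenerate = as.logical(v),
      positive = as.character(v),
      v
    )
  }
  out
}

report_to_list <- function(r) {
  out <- list(
    task = r$task,
    levels = as.list(r$levels),
    metrics = lapply(r$metrics, metrics_to_list, task = r$task),
    provenance = r$provenance
  )
  if (!is.null(r$aggregate)) {
    out$n_instances <- r$n_instances
    out$instances <- lapply(r$instances, function(inst) {
      lapply(inst, metrics_to_list, task = r$task)
    })
    out$aggregate <- r$aggregate
  }
  out
}

list_to_report <- function(x) {
  r <- list(
    task = x$task,
    levels = unlist(x$levels),
    metrics = lapply(x$metrics, metrics_from_list, task = x$task)
  )
  if (!is.null(x$aggregate)) {
    # field order mirrors aggregate_instances()
    r$instances <- lapply(x$instances, function(inst) {
      lapply(inst, metrics_from_list, task = x$task)
    })
    r$aggregate <- lapply(x$aggregate, function(per_level) {
      lapply(per_level, function(ag) {
        list(mean = as.numeric(ag$mean),
             ci = as.numeric(unlist(ag$ci)),
             values = as.numeric(unlist(ag$values)))
      })
    })
    r$n_instances <- as.integer(x$n_instances)
  }
  r$provenance <- restore_provenance(x$provenance)
  structure(r, class = "degradation_report")
}

restore_provenance <- function(p) {
  if (is.null(p)) return(NULL)
  p <- simplify_tree(p)
  if (!is.null(p$master_seed)) p$master_seed <- as.integer(p$master_seed)
  if (!is.null(p$n_matrices)) p$n_matrices <- as.integer(p$n_matrices)
  p
}

# read_json (simplifyVector = FALSE) returns every JSON array as a list;
# collapse unnamed lists of atomic scalars back into the vectors they were
# written from (numeric arrays mixing integer-looking and fractional values
# become doubles, as in R).
simplify_tree <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, simplify_tree)
  scalar <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, logical(1))
  if (length(x) && is.null(names(x)) && all(scalar)) {
    types <- unique(vapply(x, typeof, character(1)))
    if (all(types %in% c("integer", "double"))) {
      v <- unlist(x, use.names = FALSE)
      return(if (length(types) == 1L) v else as.numeric(v))
    }
    if (length(types) == 1L && types %in% c("character", "logical")) {
      return(unlist(x, use.names = FALSE))
    }
  }
  x
}

#' Write / read a labeled dataset as a directory of archives
#'
#' Writes each matrix as a [write_archive()] file (`matrix_0001.txt`, ...)
#' plus a `metadata.json` sidecar carrying labels, task and generation
#' metadata. `read_dataset` reconstructs the `hap_dataset`. This is the
#' on-disk interchange point for external predictors: shuffle, write, predict
#' elsewhere, feed the prediction files back to [run_shuffle_test()].
#'
#' @param dataset a `hap_dataset`.
#' @param dir directory to create/fill.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns
#'   the `hap_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "hap_dataset")) {
    stop("expected a hap_dataset", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("matrix_%04d.txt", seq_along(dataset$matrices))
  for (i in seq_along(dataset$matrices)) {
    write_archive(dataset$matrices[[i]], file.path(dir, files[i]))
  }
  meta <- list(task = dataset$task,
               labels = dataset$labels,
               files = files,
               metadata = dataset$metadata)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) {
    stop("no metadata.json in ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path)
  files <- unlist(meta$files)
  labels <- unlist(meta$labels)
  if (identical(meta$task, "regression")) labels <- as.numeric(labels)
  structure(
    list(matrices = lapply(file.path(dir, files), read_archive),
         labels = labels,
         task = meta$task,
         metadata = meta$metadata),
    class = "hap_dataset"
  )
}
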
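test_that("classifier metrics: accuracy, confusion layout, ROC endpoints", {
  truth <- c("A", "A", "B", "B")
  perfect <- evaluate_classifier(truth, truth, scores = c(0, 0, 1, 1))
  expect_identical(perfect$accuracy, 1)
  expect_identical(diag(perfect$confusion), c(A = 2L, B = 2L))
  expect_identical(perfect$auc, 1)

  flipped <- evaluate_classifier(truth, c("B", "B", "A", "A"))
  expect_identical(flipped$accuracy, 0)
  expect_identical(unname(diag(flipped$confusion)), c(0L, 0L))
  expect_identical(unname(flipped$confusion[1L, 2L]), 2L)

  # confusion row sums equal per-class true counts
  pred <- c("A", "B", "B", "B")
  cm <- evaluate_classifier(truth, pred)$confusion
  expect_identical(unname(rowSums(cm)), c(2, 2))
  expect_error(evaluate_classifier(c("A", "A"), c("A", "A")), ">= 2 classes")
})

test_that("trapezoidal AUC equals the all-pairs ranking probability", {
  auc_brute <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  for (s in 1:10) {
    n <- 40L + 7L * s
    dat <- hapshuffle:::with_seed(1000L + s, {
      list(scores = round(stats::rnorm(n), 1),  # rounding induces score ties
           pos = stats::runif(n) < 0.4)
    })
    if (!any(dat$pos) || all(dat$pos)) next
    truth <- ifelse(dat$pos, "case", "control")
    got <- evaluate_classifier(truth, truth, scores = dat$scores,
                               positive = "case")$auc
    expect_equal(got, auc_brute(dat$scores, dat$pos), tolerance = 1e-12)
  }
  # random scores independent of truth give AUC near 0.5
  dat <- hapshuffle:::with_seed(99L, list(scores = stats::rnorm(2000),
                                          pos = rep(c(TRUE, FALSE), 1000)))
  truth <- ifelse(dat$pos, "case", "control")
  auc <- evaluate_classifier(truth, truth, scores = dat$scores,
                             positive = "case")$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("regressor metrics handle ties, reversals and degenerate inputs", {
  perfect <- evaluate_regressor(c(1, 2, 3), c(1, 2, 3))
  expect_identical(perfect$spearman_r, 1)
  expect_identical(perfect$rmse, 0)
  expect_identical(evaluate_regressor(c(1, 2, 3), c(5, 4, 3))$spearman_r, -1)
  shifted <- evaluate_regressor(c(1, 2, 3), c(2, 3, 4))
  expect_identical(shifted$spearman_r, 1)
  expect_identical(shifted$rmse, 1)
  flat <- evaluate_regressor(c(1, 2, 3), c(2, 2, 2))
  expect_identical(flat$spearman_r, 0)
  expect_true(flat$degenerate)
})

test_that("shuffle-test metrics are bit-identical exactly where the oracle's
           statistic is preserved", {
  ds <- make_classification_dataset(50L, master_seed = 301L)
  # preservation sets per statistic: the boundary statistic is only
  # guaranteed by the boundary-keeping block level (column shuffles can move
  # an all-zero trailing data column, shifting the apparent width)
  preserved <- list(
    pi = c("columns", "within_columns"),
    h1 = "columns",
    singleton_fraction = c("columns", "within_columns"),
    seg_sites = c("columns", "within_columns"),
    last_informative_column = "block_keep_padding")
  for (stat in names(preserved)) {
    o <- fit_oracle(ds, stat)
    rep <- run_shuffle_test(ds, o, master_seed = 17L)
    base <- rep$metrics$identity
    for (lv in preserved[[stat]]) {
      expect_identical(rep$metrics[[lv]], base)
    }
    # the two block levels collapse pi, h1, singleton_fraction and seg_sites
    # to class-independent values: accuracy must leave the separable baseline
    if (stat %in% c("pi", "h1", "singleton_fraction", "seg_sites")) {
      expect_false(identical(rep$metrics$block_break_padding, base))
    }
    if (stat == "last_informative_column") {
      expect_false(identical(rep$metrics$block_break_padding, base))
    }
  }
})

test_that("a multi-statistic predictor degrades monotonically down the ladder", {
  ds <- make_classification_dataset(40L, master_seed = 88L)
  # logistic combination of pi, H1 and singleton fraction, fit on identity data
  feats <- function(ms) {
    t(vapply(ms, function(m) {
      s <- summarize_matrix(m)
      c(pi = s$pi, h1 = s$h1,
        sf = if (is.na(s$singleton_fraction)) 0 else s$singleton_fraction)
    }, numeric(3)))
  }
  x <- feats(ds$matrices)
  y <- as.integer(ds$labels == "sweep")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  predictor <- function(ms) {
    p <- stats::plogis(cbind(1, feats(ms)) %*% stats::coef(fit))[, 1L]
    list(labels = ifelse(p > 0.5, "sweep", "neutral"), scores = p)
  }
  accs <- vapply(1:20, function(ms_seed) {
    r <- run_shuffle_test(ds, predictor,
                          levels = c("columns", "within_columns", "all_pixels"),
                          master_seed = ms_seed)
    vapply(r$metrics, `[[`, numeric(1), "accuracy")
  }, numeric(4))
  mean_acc <- rowMeans(accs)
  # non-increasing along identity -> columns -> within_columns -> all_pixels
  # within simulation tolerance
  expect_true(all(diff(mean_acc) <= 0.02))
})

test_that("prediction-count violations and precomputed per-level predictions", {
  ds <- make_classification_dataset(5L, master_seed = 41L)
  bad <- function(ms) list(labels = rep("neutral", 3L))
  expect_error(run_shuffle_test(ds, bad, levels = "columns", master_seed = 1L),
               "contract violated at level `identity`")
  pre <- list(
    identity = list(labels = ds$labels),
    columns = list(labels = rev(ds$labels)))
  r <- run_shuffle_test(ds, pre, levels = "columns", master_seed = 1L)
  expect_identical(r$metrics$identity$accuracy, 1)
  expect_identical(r$metrics$columns$accuracy, 0)
  expect_error(run_shuffle_test(ds, pre, levels = c("columns", "all_pixels"),
                                master_seed = 1L),
               "no precomputed predictions")
})

test_that("aggregation over instances gives percentile intervals", {
  ds <- make_classification_dataset(10L, master_seed = 7L)
  o <- fit_oracle(ds, "h1")
  r1 <- run_shuffle_test(ds, o, levels = "columns", master_seed = 1L)
  expect_error(aggregate_instances(list(r1)), ">= 2")
  # identical reports: zero-width interval at the common value
  agg_same <- aggregate_instances(list(r1, r1))
  a <- agg_same$aggregate$identity$accuracy
  expect_identical(a$ci[1L], a$ci[2L])
  expect_identical(a$mean, r1$metrics$identity$accuracy)
  # reference percentile check: accuracies 0.4 / 0.6 -> [0.405, 0.595]
  r2 <- r1
  r1$metrics$identity$accuracy <- 0.4
  r2$metrics$identity$accuracy <- 0.6
  agg <- aggregate_instances(list(r1, r2))
  expect_identical(agg$aggregate$identity$accuracy$mean, 0.5)
  expect_equal(agg$aggregate$identity$accuracy$ci, c(0.405, 0.595),
               tolerance = 1e-12)
  r3 <- run_shuffle_test(ds, o, levels = "within_columns", master_seed = 1L)
  expect_error(aggregate_instances(list(r1, r3)), "differ in levels")
})

test_that("reports round-trip through JSON and flatten to TSV", {
  ds <- make_classification_dataset(8L, master_seed = 15L)
  o <- fit_oracle(ds, "pi")
  r <- run_shuffle_test(ds, o, master_seed = 5L)
  stem <- withr::local_tempfile()
  files <- write_report(r, stem, format = "both")
  expect_identical(read_report(paste0(stem, ".json")), r)

  tsv <- utils::read.delim(paste0(stem, ".tsv"))
  expect_identical(nrow(tsv), length(r$levels) * 3L)  # accuracy, NIR, auc
  expect_setequal(unique(tsv$level), r$levels)

  agg <- aggregate_instances(list(r, run_shuffle_test(ds, o, master_seed = 6L)))
  files2 <- write_report(agg, stem, format = "both")
  expect_identical(read_report(paste0(stem, ".json")), agg)
  tsv2 <- utils::read.delim(paste0(stem, ".tsv"))
  # one row per level x metric x instance plus one aggregate row
  expect_identical(nrow(tsv2), length(agg$levels) * 3L * (2L + 1L))

  # regression reports round-trip too
  rds <- make_regression_dataset(12L, master_seed = 4L)
  rr <- run_shuffle_test(rds, function(ms) vapply(ms, garud_h1, numeric(1)),
                         levels = "columns", master_seed = 2L)
  write_report(rr, stem, format = "json")
  expect_identical(read_report(paste0(stem, ".json")), rr)
})

test_that("dataset directories round-trip and the CLI drives the pipeline", {
  dir <- withr::local_tempdir()
  ds <- make_classification_dataset(4L, master_seed = 9L)
  write_dataset(ds, file.path(dir, "ds"))
  back <- read_dataset(file.path(dir, "ds"))
  expect_identical(back$matrices, ds$matrices)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$task, ds$task)

  arc <- file.path(dir, "sim.txt")
  hapshuffle_cli(c("simulate", "--generator", "neutral", "--n-hap", "8",
                   "--n-sites", "12", "--seed", "3", "--out", arc))
  m <- read_archive(arc)
  expect_identical(m, simulate_neutral(8L, 12L, seed = 3L))

  shuf <- file.path(dir, "shuf.txt")
  hapshuffle_cli(c("shuffle", "--in", arc, "--level", "columns",
                   "--seed", "5", "--out", shuf))
  expect_identical(read_archive(shuf), shuffle_columns(m, 5L))

  stats_out <- file.path(dir, "stats.tsv")
  hapshuffle_cli(c("stats", "--in", arc, "--out", stats_out))
  tab <- utils::read.delim(stats_out)
  expect_identical(tab$seg_sites, sum(afs(m)$counts))
  expect_equal(tab$pi, pairwise_pi(m))

  hapshuffle_cli(c("evaluate", "--dataset", file.path(dir, "ds"),
                   "--oracle", "h1", "--levels", "columns,within_columns",
                   "--seed", "7", "--out", file.path(dir, "rep")))
  rep <- read_report(file.path(dir, "rep.json"))
  expect_identical(rep$levels, c("identity", "columns", "within_columns"))
})
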
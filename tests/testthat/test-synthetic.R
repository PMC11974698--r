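test_that("neutral generator follows the 1/k frequency law with exchangeable sites", {
  # P(k = 1) for n_hap = 4 is (1/1) / (1 + 1/2 + 1/3) = 6/11; check the whole
  # law by chi-square against the empirical class counts over many sites
  m <- simulate_neutral(4L, 10000L, seed = 101L)
  d <- colSums(m$alleles)
  expect_true(all(d >= 1L & d <= 3L))
  expected <- (1 / 1:3) / sum(1 / 1:3)
  expect_equal(expected[1L], 6 / 11)
  counts <- tabulate(d, nbins = 3L)
  expect_gt(stats::chisq.test(counts, p = expected)$p.value, 0.001)
  expect_identical(length(m$positions), 10000L)
  expect_false(is.unsorted(m$positions))

  # exchangeable columns: distance-r2 correlation centered on 0 across seeds
  rho <- vapply(1:40, function(s) {
    r2_distance_corr(simulate_neutral(12L, 30L, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(rho)), 0.05)
})

test_that("mosaic generator produces tunable LD and founder-limited diversity", {
  frozen <- simulate_ld_mosaic(10L, 30L, n_founders = 3L, switch_rate = 0,
                               seed = 5L)
  expect_gte(garud_h1(frozen), 1 / 3)  # at most 3 haplotype classes

  # stronger linkage at low switch rate, in the mean over seed pairs
  r2_at <- function(rate, s) {
    suppressMessages(
      ld_r2(simulate_ld_mosaic(16L, 40L, 4L, rate, seed = s))$mean_r2)
  }
  lo <- vapply(1:30, function(s) r2_at(0.01, s), numeric(1))
  hi <- vapply(1:30, function(s) r2_at(0.5, s + 1000L), numeric(1))
  expect_gt(mean(lo, na.rm = TRUE), mean(hi, na.rm = TRUE))
})

test_that("sweep generator reduces diversity relative to matched neutral draws", {
  hard <- simulate_sweep_like(8L, 20L, sweep_freq = 1, flip_rate = 0,
                              seed = 31L)
  expect_identical(garud_h1(hard), 1)

  h1_sweep <- seg_sweep <- h1_neut <- seg_neut <- numeric(60)
  for (s in 1:60) {
    sw <- simulate_sweep_like(16L, 40L, sweep_freq = 0.8, seed = s)
    ne <- simulate_neutral(16L, 40L, seed = s + 5000L)
    h1_sweep[s] <- garud_h1(sw); h1_neut[s] <- garud_h1(ne)
    seg_sweep[s] <- sum(afs(sw)$counts); seg_neut[s] <- sum(afs(ne)$counts)
  }
  expect_gt(mean(h1_sweep), mean(h1_neut))
  expect_lt(mean(seg_sweep), mean(seg_neut))
})

test_that("classification datasets are balanced, padded and regenerable", {
  ds <- make_classification_dataset(10L, master_seed = 77L)
  expect_length(ds$matrices, 20L)
  expect_identical(as.integer(table(ds$labels)), c(10L, 10L))
  expect_true(all(vapply(ds$matrices, function(m) ncol(m$alleles), integer(1)) == 64L))
  # bit-exact regeneration from metadata
  again <- do.call(make_classification_dataset,
                   ds$metadata[c("n_per_class", "class_specs", "pad_to",
                                 "master_seed")])
  expect_identical(again, ds)

  # three-way class structure (neutral / moderate / strong sweep)
  specs3 <- list(
    neutral = list(generator = "neutral", n_hap = 12L, n_sites = 40L),
    moderate = list(generator = "sweep", n_hap = 12L, n_sites = 40L,
                    sweep_freq = 0.5),
    strong = list(generator = "sweep", n_hap = 12L, n_sites = 40L,
                  sweep_freq = 0.9))
  ds3 <- make_classification_dataset(5L, specs3, pad_to = 40L, master_seed = 3L)
  expect_identical(sort(unique(ds3$labels)), c("moderate", "neutral", "strong"))
  expect_identical(as.integer(table(ds3$labels)), c(5L, 5L, 5L))
  expect_error(
    make_classification_dataset(2L, specs3, pad_to = 10L, master_seed = 1L),
    "pad_to")
})

test_that("oracle fitting finds separating thresholds and degrades to chance", {
  ds <- make_classification_dataset(30L, master_seed = 19L)
  for (stat in c("h1", "seg_sites", "pi")) {
    o <- fit_oracle(ds, stat)
    expect_identical(o$training_accuracy, 1)
  }
  # labels independent of the statistic: accuracy near 0.5 plus optimism
  specs_same <- list(
    a = list(generator = "neutral", n_hap = 12L, n_sites = 40L),
    b = list(generator = "neutral", n_hap = 12L, n_sites = 40L))
  ds_null <- make_classification_dataset(100L, specs_same, pad_to = 40L,
                                         master_seed = 11L)
  o_null <- fit_oracle(ds_null, "pi")
  expect_lt(o_null$training_accuracy, 0.65)
  expect_gte(o_null$training_accuracy, 0.5)

  # single example per class: threshold at the midpoint of the two values
  tiny <- structure(
    list(matrices = list(simulate_sweep_like(8L, 30L, 0.9, seed = 1L),
                         simulate_neutral(8L, 30L, seed = 2L)),
         labels = c("sweep", "neutral"),
         task = "classification", metadata = list()),
    class = "hap_dataset")
  o2 <- fit_oracle(tiny, "h1")
  vals <- sort(vapply(tiny$matrices, garud_h1, numeric(1)))
  expect_identical(o2$threshold, mean(vals))
})

test_that("oracle predictions are deterministic pure functions of the statistic", {
  ds <- make_classification_dataset(10L, master_seed = 23L)
  o <- fit_oracle(ds, "pi")
  p1 <- predict(o, ds)
  expect_identical(p1, predict(o, ds))
  expect_identical(length(p1$labels), 20L)
  # pi is invariant under within-column shuffling, so predictions match exactly
  for (s in c(2L, 9L)) {
    shuffled <- lapply(ds$matrices, shuffle_within_columns, seed = s)
    expect_identical(predict(o, shuffled), p1)
  }
  # an h1 oracle sends all-identical-haplotype matrices to the high side
  o_h1 <- fit_oracle(ds, "h1")
  mono <- list(hap_matrix(matrix(1L, 6L, 8L)), hap_matrix(matrix(1L, 6L, 8L)))
  expect_identical(unique(predict(o_h1, mono)$labels), o_h1$high_class)
})
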
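#' Exchangeable-site neutral-like haplotype matrix
#'
#' Each column independently draws a derived-allele count k in 1..n_hap-1
#' with probability proportional to 1/k — the classic neutral-equilibrium
#' frequency-spectrum shape — and assigns the k derived alleles to uniformly
#' chosen rows. Columns are exchangeable by construction, so the matrix has
#' no linkage structure (expected distance–r2 correlation 0). Positions are
#' uniform sorted draws in `[0, 1)`, as in ms-style output.
#'
#' This is a feature-level stand-in for coalescent output: it reproduces the
#' 1/k AFS shape and per-site exchangeability, not genealogical correlations.
#'
#' @param n_hap number of haplotypes (>= 2).
#' @param n_sites number of segregating sites (>= 1).
#' @param seed integer seed.
#' @return a [hap_matrix()] with `padding_width` 0 and positions.
#' @export
simulate_neutral <- function(n_hap, n_sites, seed) {
  n_hap <- check_scalar_count(n_hap, "n_hap", min = 2L)
  n_sites <- check_scalar_count(n_sites, "n_sites", min = 1L)
  with_seed(seed, {
    kprob <- 1 / seq_len(n_hap - 1L)
    k <- sample.int(n_hap - 1L, n_sites, replace = TRUE, prob = kprob)
    a <- matrix(0L, nrow = n_hap, ncol = n_sites)
    for (j in seq_len(n_sites)) {
      a[sample.int(n_hap, k[j]), j] <- 1L
    }
    hap_matrix(a, padding_width = 0L, positions = sort(stats::runif(n_sites)))
  })
}

#' Founder-mosaic haplotype matrix with tunable linkage structure
#'
#' Draws `n_founders` founder haplotypes from the neutral generator, then
#' builds each output haplotype as a left-to-right copying mosaic: start from
#' a uniformly chosen founder and, between adjacent sites, switch to a
#' uniformly chosen founder with probability `switch_rate`. Low switch rates
#' give long shared founder tracts — high LD, LD decay with distance, and
#' high haplotype homozygosity; `switch_rate = 1` destroys adjacency
#' structure entirely.
#'
#' @param n_hap number of output haplotypes (>= 2).
#' @param n_sites number of site columns drawn; columns left without any
#'   derived allele by the copying process are dropped, so the realized width
#'   can be lower.
#' @param n_founders number of founder haplotypes, between 2 and `n_hap`.
#' @param switch_rate per-interval probability of re-drawing the founder,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return a [hap_matrix()] with `padding_width` 0 and positions (taken from
#'   the founder draw).
#' @export
simulate_ld_mosaic <- function(n_hap, n_sites, n_founders = 4L,
                               switch_rate = 0.05, seed = 1L) {
  n_hap <- check_scalar_count(n_hap, "n_hap", min = 2L)
  n_founders <- check_scalar_count(n_founders, "n_founders", min = 2L)
  if (n_founders > n_hap) stop("n_founders must be <= n_hap", call. = FALSE)
  if (switch_rate < 0 || switch_rate > 1) {
    stop("switch_rate must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    founders <- simulate_neutral(n_founders, n_sites,
                                 seed = sample.int(.Machine$integer.max, 1L))
    fa <- founders$alleles
    a <- matrix(0L, nrow = n_hap, ncol = n_sites)
    for (i in seq_len(n_hap)) {
      f <- sample.int(n_founders, 1L)
      a[i, 1L] <- fa[f, 1L]
      if (n_sites > 1L) {
        switches <- stats::runif(n_sites - 1L) < switch_rate
        for (j in 2L:n_sites) {
          if (switches[j - 1L]) f <- sample.int(n_founders, 1L)
          a[i, j] <- fa[f, j]
        }
      }
    }
    drop_empty_sites(a, founders$positions)
  })
}

# A haplotype matrix holds sites segregating in the sample; copying mosaics
# and sweep overwriting can zero a column out entirely, so such columns are
# dropped (with their positions) rather than emitted as fake sites. This also
# keeps the last data column informative, the property real variable-width
# inputs have and the padding-boundary analyses rely on.
drop_empty_sites <- function(a, positions) {
  keep <- colSums(a) > 0L
  if (!any(keep)) {
    stop("degenerate draw: no site carries a derived allele; change the seed ",
         "or parameters", call. = FALSE)
  }
  new_hap_matrix(a[, keep, drop = FALSE], padding_width = 0L,
                 positions = positions[keep])
}

#' Sweep-like haplotype matrix with reduced haplotype diversity
#'
#' Emulates the footprint of a selective sweep: a fraction `sweep_freq` of the
#' haplotypes are near-copies of one core haplotype (each site flipped
#' independently at rate `flip_rate`, emulating mutations on the sweeping
#' background), while the remainder are neutral-like draws. Relative to a
#' matched neutral matrix this reduces realized segregating sites and raises
#' Garud's H1 — a dramatic reduction of haplotype diversity.
#'
#' @param n_hap number of haplotypes (>= 2).
#' @param n_sites number of site columns drawn (the realized polymorphic
#'   count is typically lower: sites can become monomorphic).
#' @param sweep_freq fraction of haplotypes carrying the swept background, in
#'   `(0, 1]`.
#' @param flip_rate per-site flip probability on swept haplotypes.
#' @param seed integer seed.
#' @return a [hap_matrix()] with `padding_width` 0 and positions.
#' @export
simulate_sweep_like <- function(n_hap, n_sites, sweep_freq = 0.8,
                                flip_rate = 0.02, seed = 1L) {
  n_hap <- check_scalar_count(n_hap, "n_hap", min = 2L)
  n_sites <- check_scalar_count(n_sites, "n_sites", min = 1L)
  if (sweep_freq <= 0 || sweep_freq > 1) {
    stop("sweep_freq must be in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    base <- simulate_neutral(n_hap, n_sites,
                             seed = sample.int(.Machine$integer.max, 1L))
    a <- base$alleles
    n_sweep <- max(1L, round(sweep_freq * n_hap))
    core <- a[1L, ]
    for (i in seq_len(n_sweep)) {
      flips <- stats::runif(n_sites) < flip_rate
      a[i, ] <- ifelse(flips, 1L - core, core)
    }
    drop_empty_sites(a, base$positions)
  })
}

generator_registry <- function() {
  list(
    neutral = function(n_hap, n_sites, seed, ...) {
      simulate_neutral(n_hap, n_sites, seed)
    },
    ld_mosaic = function(n_hap, n_sites, seed, n_founders = 4L,
                         switch_rate = 0.05, ...) {
      simulate_ld_mosaic(n_hap, n_sites, n_founders, switch_rate, seed)
    },
    sweep = function(n_hap, n_sites, seed, sweep_freq = 0.8,
                     flip_rate = 0.02, ...) {
      simulate_sweep_like(n_hap, n_sites, sweep_freq, flip_rate, seed)
    }
  )
}

#' Build a balanced labeled classification dataset
#'
#' Generates `n_per_class` matrices for each class from its generator spec,
#' derives each matrix's seed deterministically from
#' `(master_seed, class index, matrix index)` so the dataset regenerates
#' bit-exactly from its metadata, and optionally right-pads everything to a
#' common width (as fixed-input-width networks require).
#'
#' The default two-class task contrasts `neutral` (64 sites) against `sweep`
#' (32 sites, sweep frequency 0.8), both with 20 haplotypes, padded to
#' width 64 — so diversity, haplotype homozygosity and the padding boundary
#' all carry class signal, as in published sweep-detection setups.
#'
#' @param n_per_class matrices per class.
#' @param class_specs named list; each element a list with `generator`
#'   (`"neutral"`, `"ld_mosaic"` or `"sweep"`) plus that generator's
#'   parameters (`n_hap`, `n_sites`, ...). Names are the class labels.
#' @param pad_to optional common width for [pad_to_width()]; must be at least
#'   the widest generated matrix.
#' @param master_seed integer master seed recorded in the metadata.
#' @return object of class `hap_dataset`: list with `matrices`, `labels`
#'   (character), `task = "classification"` and `metadata` sufficient to
#'   regenerate the dataset.
#' @export
make_classification_dataset <- function(n_per_class = 100L,
                                        class_specs = default_class_specs(),
                                        pad_to = 64L,
                                        master_seed = 1L) {
  n_per_class <- check_scalar_count(n_per_class, "n_per_class", min = 1L)
  if (length(class_specs) < 2L || is.null(names(class_specs))) {
    stop("class_specs must be a named list with >= 2 classes", call. = FALSE)
  }
  gens <- generator_registry()
  matrices <- list()
  labels <- character(0)
  for (ci in seq_along(class_specs)) {
    spec <- class_specs[[ci]]
    gname <- spec$generator
    if (is.null(gens[[gname]])) {
      stop("unknown generator: ", toString(gname), call. = FALSE)
    }
    for (i in seq_len(n_per_class)) {
      args <- spec
      args$generator <- NULL
      args$seed <- derive_seed(master_seed, ci, i)
      matrices[[length(matrices) + 1L]] <- do.call(gens[[gname]], args)
      labels <- c(labels, names(class_specs)[ci])
    }
  }
  if (!is.null(pad_to)) {
    widths <- vapply(matrices, function(m) ncol(m$alleles), integer(1))
    if (pad_to < max(widths)) {
      stop(sprintf("pad_to = %d smaller than widest matrix (%d)",
                   pad_to, max(widths)), call. = FALSE)
    }
    matrices <- lapply(matrices, pad_to_width, target_width = pad_to)
  }
  structure(
    list(matrices = matrices,
         labels = labels,
         task = "classification",
         metadata = list(generator = "make_classification_dataset",
                         n_per_class = n_per_class,
                         class_specs = class_specs,
                         pad_to = pad_to,
                         master_seed = as.integer(master_seed))),
    class = "hap_dataset"
  )
}

#' @rdname make_classification_dataset
#' @export
default_class_specs <- function() {
  list(
    neutral = list(generator = "neutral", n_hap = 20L, n_sites = 64L),
    sweep = list(generator = "sweep", n_hap = 20L, n_sites = 32L,
                 sweep_freq = 0.8, flip_rate = 0.02)
  )
}

#' Build a regression dataset over sweep intensity
#'
#' Draws `n` sweep-like matrices whose target is the sweep frequency, sampled
#' uniformly over `freq_range`. Useful for exercising the regression side of
#' the harness (Spearman's r, RMSE) with a continuously varying signal.
#'
#' @param n number of matrices.
#' @param freq_range range of sweep frequencies sampled uniformly.
#' @param n_hap,n_sites matrix dimensions.
#' @param pad_to optional common width.
#' @param master_seed integer master seed.
#' @return a `hap_dataset` with numeric `labels` and `task = "regression"`.
#' @export
make_regression_dataset <- function(n = 100L, freq_range = c(0.2, 0.95),
                                    n_hap = 20L, n_sites = 48L,
                                    pad_to = NULL, master_seed = 1L) {
  n <- check_scalar_count(n, "n", min = 3L)
  targets <- with_seed(derive_seed(master_seed, 0L, 0L),
                       stats::runif(n, freq_range[1L], freq_range[2L]))
  matrices <- lapply(seq_len(n), function(i) {
    simulate_sweep_like(n_hap, n_sites, sweep_freq = targets[i],
                        flip_rate = 0.02, seed = derive_seed(master_seed, 1L, i))
  })
  if (!is.null(pad_to)) matrices <- lapply(matrices, pad_to_width, target_width = pad_to)
  structure(
    list(matrices = matrices,
         labels = targets,
         task = "regression",
         metadata = list(generator = "make_regression_dataset", n = n,
                         freq_range = freq_range, n_hap = n_hap,
                         n_sites = n_sites, pad_to = pad_to,
                         master_seed = as.integer(master_seed))),
    class = "hap_dataset"
  )
}

#' @export
print.hap_dataset <- function(x, ...) {
  cat(sprintf("<hap_dataset> %d matrices, task: %s\n",
              length(x$matrices), x$task))
  if (x$task == "classification") {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat(sprintf("  targets in [%g, %g]\n", min(x$labels), max(x$labels)))
  }
  invisible(x)
}
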
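#' Allele frequency spectrum
#'
#' Counts of non-padding sites by derived-allele count class k = 1..n_hap-1
#' (the polymorphic classes of the unfolded SFS). Monomorphic-ancestral and
#' fixed-derived columns are tallied separately; `sum(counts)` equals the
#' segregating-site count. `folded = TRUE` collapses classes k and n-k (minor
#' allele counts), for data whose ancestral/derived polarization is unknown.
#'
#' @param m a valid `hap_matrix`.
#' @param folded fold the spectrum to minor-allele counts.
#' @return list with `counts` (named integer vector over the frequency
#'   classes), `n_monomorphic_zero` and `n_fixed_derived`.
#' @export
afs <- function(m, folded = FALSE) {
  stop_if_invalid(m)
  region <- data_region(m)
  n <- nrow(region)
  d <- colSums(region)
  poly <- d[d > 0L & d < n]
  if (folded) {
    kmax <- n %/% 2L
    counts <- tabulate(pmin(poly, n - poly), nbins = kmax)
    names(counts) <- as.character(seq_len(kmax))
  } else {
    counts <- tabulate(poly, nbins = max(n - 1L, 0L))
    names(counts) <- as.character(seq_len(max(n - 1L, 0L)))
  }
  list(counts = counts,
       n_monomorphic_zero = sum(d == 0L),
       n_fixed_derived = sum(d == n))
}

#' Pairwise heterozygosity (nucleotide diversity, pi)
#'
#' Mean number of differences between two randomly drawn haplotypes:
#' `sum_j d_j (n - d_j) / choose(n, 2)` over non-padding columns j, where d_j
#' is the derived count and n the number of haplotypes. Fixed columns
#' contribute 0.
#'
#' @param m a valid `hap_matrix` with at least 2 haplotypes.
#' @return non-negative numeric.
#' @export
pairwise_pi <- function(m) {
  stop_if_invalid(m)
  region <- data_region(m)
  n <- nrow(region)
  d <- colSums(region)
  sum(d * (n - d)) / choose(n, 2)
}

#' Garud's H1 haplotype homozygosity
#'
#' `H1 = sum_i p_i^2` over haplotype identity classes (distinct full-row
#' strings of the non-padding region), p_i the class frequency. H1 is 1 when
#' all haplotypes are identical (the hard-sweep limit) and 1/n when all n are
#' distinct; high values signal reduced haplotype diversity, the classic
#' selective-sweep signature.
#'
#' @param m a valid `hap_matrix`.
#' @return numeric in `[1/n_hap, 1]`.
#' @export
garud_h1 <- function(m) {
  stop_if_invalid(m)
  region <- data_region(m)
  keys <- apply(region, 1L, paste, collapse = "")
  if (!length(keys)) keys <- rep("", nrow(m$alleles))
  # summing over sorted class counts keeps H1 bit-identical under column
  # permutation (key order would otherwise permute the float summation)
  p <- sort(as.vector(table(keys))) / length(keys)
  sum(p^2)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' The squared allelic correlation
#' `r2(j,k) = (P11 - p_j p_k)^2 / (p_j(1-p_j) p_k(1-p_k))` computed from
#' haplotype frequencies over all pairs of polymorphic non-padding columns.
#' Monomorphic columns are excluded (r2 undefined there).
#'
#' @param m a valid `hap_matrix`.
#' @return list with `r2` (symmetric matrix over polymorphic columns, unit
#'   diagonal), `poly_columns` (their 1-based column indices) and `mean_r2`
#'   (mean of the off-diagonal values, `NA` with a message when fewer than two
#'   polymorphic columns exist).
#' @export
ld_r2 <- function(m) {
  stop_if_invalid(m)
  region <- data_region(m)
  n <- nrow(region)
  d <- colSums(region)
  poly <- which(d > 0L & d < n)
  if (length(poly) < 2L) {
    message("ld_r2: fewer than 2 polymorphic columns; no pairs to report")
    return(list(r2 = matrix(numeric(0), 0L, 0L), poly_columns = poly,
                mean_r2 = NA_real_))
  }
  x <- region[, poly, drop = FALSE]
  p <- colMeans(x)
  p11 <- crossprod(x) / n
  dis <- p11 - outer(p, p)
  denom <- outer(p * (1 - p), p * (1 - p))
  r2 <- dis^2 / denom
  diag(r2) <- 1
  dimnames(r2) <- NULL
  off <- r2[upper.tri(r2)]
  list(r2 = r2, poly_columns = poly, mean_r2 = mean(off))
}

#' Rank correlation between inter-site distance and r-squared
#'
#' Spearman correlation (average-rank ties) between `|pos_j - pos_k|` and
#' `r2(j, k)` over all pairs of polymorphic columns — an operational measure
#' of short-scale LD decay: strongly negative when LD decays with distance,
#' centered on 0 once column order is randomized. When either vector is
#' entirely tied (e.g. all r2 equal) the correlation is reported as 0 by
#' convention.
#'
#' @param m a valid `hap_matrix` with positions and >= 3 polymorphic columns.
#' @return numeric in `[-1, 1]`.
#' @export
r2_distance_corr <- function(m) {
  stop_if_invalid(m)
  if (is.null(m$positions)) {
    stop("r2_distance_corr requires positions", call. = FALSE)
  }
  ld <- ld_r2(m)
  if (length(ld$poly_columns) < 3L) {
    stop("r2_distance_corr requires >= 3 polymorphic columns", call. = FALSE)
  }
  pos <- m$positions[ld$poly_columns]
  dists <- as.vector(stats::dist(pos))
  r2v <- ld$r2[lower.tri(ld$r2)]
  if (stats::sd(dists) == 0 || stats::sd(r2v) == 0) return(0)
  stats::cor(dists, r2v, method = "spearman")
}

#' Bundle of summary statistics for one matrix
#'
#' Computes every statistic targeted by the shuffle levels: the unfolded AFS,
#' pi, segregating-site count S, total derived count, singleton fraction,
#' Garud's H1, mean pairwise r2, and (when positions are present and usable)
#' the distance–r2 rank correlation.
#'
#' @param m a valid `hap_matrix`.
#' @return object of class `hap_sumstats`, a list with fields `afs`,
#'   `n_monomorphic_zero`, `n_fixed_derived`, `pi`, `seg_sites`,
#'   `total_derived`, `singleton_fraction`, `h1`, `mean_r2`,
#'   `r2_distance_corr` (`NA` when positions are absent or too few
#'   polymorphic columns exist).
#' @export
summarize_matrix <- function(m) {
  stop_if_invalid(m)
  region <- data_region(m)
  n <- nrow(region)
  d <- colSums(region)
  spectrum <- afs(m)
  seg <- sum(spectrum$counts)
  singleton_fraction <- if (seg > 0L) unname(spectrum$counts["1"]) / seg else NA_real_
  ld <- suppressMessages(ld_r2(m))
  rdc <- NA_real_
  if (!is.null(m$positions) &&
      length(m$positions) == ncol(region) &&
      length(ld$poly_columns) >= 3L) {
    rdc <- r2_distance_corr(m)
  }
  structure(
    list(afs = spectrum$counts,
         n_monomorphic_zero = spectrum$n_monomorphic_zero,
         n_fixed_derived = spectrum$n_fixed_derived,
         pi = pairwise_pi(m),
         seg_sites = seg,
         total_derived = as.integer(sum(d)),
         singleton_fraction = singleton_fraction,
         h1 = garud_h1(m),
         mean_r2 = ld$mean_r2,
         r2_distance_corr = rdc),
    class = "hap_sumstats"
  )
}

#' @export
print.hap_sumstats <- function(x, ...) {
  cat("<hap_sumstats>\n")
  cat(sprintf("  S = %d  total_derived = %d  singletons = %s\n",
              x$seg_sites, x$total_derived,
              format(x$singleton_fraction, digits = 3)))
  cat(sprintf("  pi = %s  H1 = %s  mean_r2 = %s  r2~dist rho = %s\n",
              format(x$pi, digits = 4), format(x$h1, digits = 4),
              format(x$mean_r2, digits = 4),
              format(x$r2_distance_corr, digits = 3)))
  invisible(x)
}
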
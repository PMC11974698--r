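#' The shuffle levels, in order of disruption depth
#'
#' Six tokens forming a strict total order used for reporting:
#' `identity` (no change), `columns` (permute whole site columns, destroying
#' short-scale LD while preserving every column-permutation-invariant
#' statistic), `within_columns` (column shuffle plus an independent permutation
#' of entries within each column, additionally destroying haplotype identity
#' and long-scale LD), `all_pixels` (uniform permutation of every entry in the
#' data region, additionally destroying the allele frequency spectrum),
#' `block_keep_padding` and `block_break_padding` (deterministic grouping of
#' all derived alleles into a contiguous block, preserving or destroying the
#' zero-padding boundary). Padding columns never participate in any level
#' except `block_break_padding`, the only level defined to disrupt the
#' boundary.
#'
#' @return character vector of the six level tokens in disruption order.
#' @export
shuffle_levels <- function() {
  c("identity", "columns", "within_columns", "all_pixels",
    "block_keep_padding", "block_break_padding")
}

check_level <- function(level) {
  if (length(level) != 1L || !level %in% shuffle_levels()) {
    stop("unknown shuffle level: ", toString(level),
         " (expected one of: ", paste(shuffle_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  level
}

warn_zero_width <- function(fn) {
  warning(sprintf("%s: data width is 0; returning the input unchanged", fn),
          call. = FALSE)
}

#' Shuffle whole columns of segregating sites
#'
#' Permutes the non-padding columns uniformly at random. The multiset of
#' columns is preserved, so every column-permutation-invariant statistic (AFS,
#' pi, S, Garud's H1, the multiset of pairwise r-squared values) is unchanged;
#' only the association between genomic position and site content — i.e.
#' short-scale LD decay — is destroyed. Padding columns, `padding_width` and
#' `positions` are untouched.
#'
#' @param m a valid `hap_matrix`.
#' @param seed integer seed; identical `(m, seed)` give identical output.
#' @return the shuffled [hap_matrix()].
#' @export
shuffle_columns <- function(m, seed) {
  stop_if_invalid(m)
  w <- data_width(m)
  if (w == 0L) {
    warn_zero_width("shuffle_columns")
    return(m)
  }
  a <- m$alleles
  perm <- with_seed(seed, sample.int(w))
  a[, seq_len(w)] <- a[, perm, drop = FALSE]
  new_hap_matrix(a, m$padding_width, m$positions)
}

#' Shuffle columns, then entries within each column
#'
#' The composite level: first a uniform column permutation, then an
#' independent uniform permutation of the entries within each non-padding
#' column. Per-column allele counts are preserved (so AFS, pi, S and the
#' singleton fraction survive) but rows are no longer coherent haplotypes:
#' haplotype homozygosity (H1) and between-site correlations (long-scale LD)
#' are destroyed.
#'
#' @inheritParams shuffle_columns
#' @return the shuffled [hap_matrix()].
#' @export
shuffle_within_columns <- function(m, seed) {
  stop_if_invalid(m)
  w <- data_width(m)
  if (w == 0L) {
    warn_zero_width("shuffle_within_columns")
    return(m)
  }
  a <- m$alleles
  n <- nrow(a)
  a[, seq_len(w)] <- with_seed(seed, {
    shuffled <- a[, sample.int(w), drop = FALSE]
    for (j in seq_len(w)) {
      shuffled[, j] <- shuffled[sample.int(n), j]
    }
    shuffled
  })
  new_hap_matrix(a, m$padding_width, m$positions)
}

#' Shuffle all entries of the data region
#'
#' A single uniform permutation of every entry in the non-padding region,
#' destroying the allele frequency spectrum on top of everything the lighter
#' levels destroy; only the total derived-allele count survives.
#'
#' @inheritParams shuffle_columns
#' @return the shuffled [hap_matrix()].
#' @export
shuffle_all <- function(m, seed) {
  stop_if_invalid(m)
  w <- data_width(m)
  if (w == 0L) {
    warn_zero_width("shuffle_all")
    return(m)
  }
  a <- m$alleles
  idx <- seq_len(w)
  region <- a[, idx, drop = FALSE]
  v <- as.vector(region)
  a[, idx] <- with_seed(seed, matrix(v[sample.int(length(v))],
                                     nrow = nrow(a), ncol = w))
  new_hap_matrix(a, m$padding_width, m$positions)
}

#' Group derived alleles into a block, keeping the padding boundary
#'
#' Deterministic (no randomness): all T derived alleles of the data region are
#' packed into a contiguous block anchored at the padding boundary — columns
#' filled right-to-left starting at the last non-padding column, top-to-bottom
#' within each column. Total derived count, `data_width` and (for T > 0) the
#' last informative column are preserved; every other feature is destroyed.
#' This is the strongest disruption that still leaves the segregating-sites
#' boundary where a padding-aware consumer expects it.
#'
#' @param m a valid `hap_matrix`.
#' @return the block-grouped [hap_matrix()].
#' @export
block_group_keep_padding <- function(m) {
  stop_if_invalid(m)
  w <- data_width(m)
  a <- m$alleles
  n <- nrow(a)
  if (w == 0L) return(m)
  idx <- seq_len(w)
  total <- sum(a[, idx])
  a[, idx] <- 0L
  remaining <- total
  j <- w
  while (remaining > 0L) {
    k <- min(n, remaining)
    a[seq_len(k), j] <- 1L
    remaining <- remaining - k
    j <- j - 1L
  }
  new_hap_matrix(a, m$padding_width, m$positions)
}

#' Group derived alleles into a block, breaking the padding boundary
#'
#' Deterministic: the T derived alleles are packed left-to-right from column 1
#' across the FULL matrix width, padding region included, top-to-bottom within
#' each column. The zero-padding boundary no longer exists, so the output
#' carries `padding_width` 0; the apparent width collapses to
#' `ceiling(T / n_hap)`. Only the total derived count survives. Positions are
#' carried through unchanged (they are never modified by any level), which for
#' a padded positioned input means the output no longer satisfies the
#' positions-length invariant — by construction, this level may produce a
#' matrix that [validate_hap_matrix()] rejects.
#'
#' @param m a valid `hap_matrix`.
#' @return the block-grouped [hap_matrix()] with `padding_width` 0.
#' @export
block_group_break_padding <- function(m) {
  stop_if_invalid(m)
  a <- m$alleles
  n <- nrow(a)
  w_full <- ncol(a)
  total <- sum(a[, seq_len(data_width(m)), drop = FALSE])
  a[] <- 0L
  remaining <- total
  j <- 1L
  while (remaining > 0L) {
    k <- min(n, remaining)
    a[seq_len(k), j] <- 1L
    remaining <- remaining - k
    j <- j + 1L
  }
  new_hap_matrix(a, padding_width = 0L, positions = m$positions)
}

#' Apply one shuffle level
#'
#' Dispatches a level token to its operation. The two block levels are
#' deterministic and ignore `seed`; `identity` returns the input unchanged.
#' Positions are always carried through untouched.
#'
#' @param m a valid `hap_matrix`.
#' @param level one token from [shuffle_levels()].
#' @param seed integer seed for the randomized levels.
#' @return the transformed [hap_matrix()].
#' @export
apply_level <- function(m, level, seed = 1L) {
  check_level(level)
  switch(level,
    identity            = { stop_if_invalid(m); m },
    columns             = shuffle_columns(m, seed),
    within_columns      = shuffle_within_columns(m, seed),
    all_pixels          = shuffle_all(m, seed),
    block_keep_padding  = block_group_keep_padding(m),
    block_break_padding = block_group_break_padding(m)
  )
}

#' Apply a battery of shuffle levels across a dataset
#'
#' Applies each requested level to every matrix, with per-matrix seeds derived
#' deterministically from `(master_seed, matrix index, level)`. The derivation
#' is counter-based, so the output at one level is invariant to which other
#' levels are requested, and the same call reproduces bit-exactly.
#'
#' @param matrices list of valid `hap_matrix` objects (or a `hap_dataset`,
#'   whose matrices are used).
#' @param levels character vector of tokens from [shuffle_levels()].
#' @param master_seed integer master seed.
#' @return named list mapping each level to a list of shuffled matrices.
#' @export
shuffle_battery <- function(matrices, levels, master_seed) {
  if (inherits(matrices, "hap_dataset")) matrices <- matrices$matrices
  if (!length(matrices)) stop("empty dataset", call. = FALSE)
  levels <- unique(vapply(levels, check_level, character(1), USE.NAMES = FALSE))
  out <- vector("list", length(levels))
  names(out) <- levels
  for (lv in levels) {
    ord <- match(lv, shuffle_levels())
    out[[lv]] <- lapply(seq_along(matrices), function(i) {
      apply_level(matrices[[i]], lv, derive_seed(master_seed, i, ord))
    })
  }
  out
}
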
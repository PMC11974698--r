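#' Binary haplotype-by-site matrix with zero-padding metadata
#'
#' The central container of the package: a matrix with one row per sampled
#' haplotype and one column per segregating site, entries coded 0 (ancestral)
#' or 1 (derived). Population-genetic neural networks consume exactly this
#' "image"; variable-width inputs are commonly right-padded with all-zero
#' columns to a fixed width, and the padding boundary itself encodes the total
#' number of segregating sites. `padding_width` records how many trailing
#' columns are padding; since padding shares the ancestral colour, it is
#' distinguishable from data only through this metadata — mirroring what a
#' network actually sees.
#'
#' @param alleles matrix coercible to integer, every entry 0 or 1; rows are
#'   haplotypes, columns are sites (data columns first, padding columns last).
#' @param padding_width number of trailing all-zero padding columns (>= 0).
#' @param positions optional numeric vector of genomic coordinates for the
#'   data (non-padding) columns, sorted non-decreasing. Base pairs or the
#'   scaled `[0, 1)` coordinates of ms-style simulators; the package treats
#'   them as opaque metadata and no operation ever reorders or rescales them.
#'
#' @return an object of class `hap_matrix`: a list with elements `alleles`,
#'   `padding_width` and `positions` (`NULL` when absent).
#' @examples
#' m <- hap_matrix(rbind(c(0, 1), c(1, 1)))
#' data_width(m)
#' @seealso [validate_hap_matrix()], [data_width()], [last_informative_column()]
#' @export
hap_matrix <- function(alleles, padding_width = 0L, positions = NULL) {
  m <- new_hap_matrix(alleles, padding_width, positions)
  problems <- validate_hap_matrix(m)
  if (length(problems)) {
    stop("invalid hap_matrix:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }
  m
}

# Unvalidated constructor; internal producers (shuffles, parsers) use it and
# guarantee validity themselves, except block_break_padding whose output may
# legitimately break the positions-length invariant.
new_hap_matrix <- function(alleles, padding_width = 0L, positions = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  if (!is.null(positions)) positions <- as.numeric(positions)
  structure(
    list(alleles = alleles,
         padding_width = as.integer(padding_width),
         positions = positions),
    class = "hap_matrix"
  )
}

#' Validate a haplotype matrix
#'
#' Checks every structural invariant and returns a verdict rather than
#' throwing: binary entries, at least 2 haplotypes and 1 column,
#' `0 <= padding_width <= n_col`, trailing padding columns entirely zero, and
#' positions (when present) of length `n_col - padding_width` and sorted
#' non-decreasing.
#'
#' @param m a `hap_matrix` (or list shaped like one).
#' @return character vector of human-readable violations, `character(0)` when
#'   the matrix is valid. Each violation names the offending row/column.
#' @examples
#' validate_hap_matrix(hap_matrix(rbind(c(0, 1), c(1, 1))))  # character(0)
#' @export
validate_hap_matrix <- function(m) {
  problems <- character(0)
  a <- m$alleles
  if (!is.matrix(a)) {
    return("`alleles` is not a matrix")
  }
  n <- nrow(a)
  w <- ncol(a)
  if (n < 2L) problems <- c(problems, sprintf("n_hap is %d; need >= 2", n))
  if (w < 1L) problems <- c(problems, sprintf("n_col is %d; need >= 1", w))
  bad <- which(!(a == 0L | a == 1L), arr.ind = TRUE)
  if (nrow(bad)) {
    problems <- c(problems, sprintf(
      "non-binary entry at (%d,%d)", bad[, 1L], bad[, 2L]))
  }
  pw <- m$padding_width
  if (length(pw) != 1L || is.na(pw) || pw < 0L || pw > w) {
    problems <- c(problems, sprintf(
      "padding_width %s outside [0, n_col = %d]", toString(pw), w))
    pw <- 0L
  }
  if (pw > 0L) {
    pad_cols <- seq.int(w - pw + 1L, w)
    dirty <- pad_cols[colSums(a[, pad_cols, drop = FALSE] != 0L) > 0L]
    if (length(dirty)) {
      problems <- c(problems, sprintf(
        "padding column %d contains a derived allele", dirty))
    }
  }
  pos <- m$positions
  if (!is.null(pos)) {
    if (length(pos) != w - pw) {
      problems <- c(problems, sprintf(
        "positions length %d != n_col - padding_width = %d",
        length(pos), w - pw))
    }
    if (anyNA(pos)) {
      problems <- c(problems, "positions contain NA")
    } else if (is.unsorted(pos)) {
      problems <- c(problems, "positions are not sorted non-decreasing")
    }
  }
  problems
}

#' @export
print.hap_matrix <- function(x, ...) {
  n <- nrow(x$alleles)
  w <- ncol(x$alleles)
  cat(sprintf("<hap_matrix> %d haplotypes x %d columns (%d data + %d padding)\n",
              n, w, w - x$padding_width, x$padding_width))
  cat(sprintf("  derived alleles: %d; positions: %s\n",
              sum(x$alleles),
              if (is.null(x$positions)) "absent" else
                sprintf("%d coordinates in [%g, %g]",
                        length(x$positions), min(x$positions), max(x$positions))))
  invisible(x)
}

#' Width of the data (non-padding) region
#'
#' @param m a valid `hap_matrix`.
#' @return integer, `n_col - padding_width`; 0 for an all-padding matrix.
#' @export
data_width <- function(m) {
  stop_if_invalid(m)
  ncol(m$alleles) - m$padding_width
}

#' Last column carrying a derived allele
#'
#' The largest (1-based) column index holding at least one derived allele —
#' the "apparent width" perceived by a consumer blind to the padding metadata,
#' i.e. the position of the segregating-sites boundary in the image. For a
#' valid matrix this never exceeds [data_width()].
#'
#' @param m a valid `hap_matrix`.
#' @return integer column index, or `NA_integer_` for an all-zero matrix.
#' @export
last_informative_column <- function(m) {
  stop_if_invalid(m)
  informative <- which(colSums(m$alleles) > 0L)
  if (!length(informative)) NA_integer_ else informative[length(informative)]
}

# Internal validity gate. The padding-breaking block shuffle legitimately
# yields positions of length != n_col - padding_width (the boundary is gone,
# positions are carried verbatim); since positions are opaque metadata to
# every operation except r2_distance_corr (which checks for itself), that one
# violation is tolerated here while validate_hap_matrix() still reports it.
stop_if_invalid <- function(m) {
  if (!inherits(m, "hap_matrix")) {
    stop("expected a `hap_matrix` object", call. = FALSE)
  }
  problems <- validate_hap_matrix(m)
  problems <- problems[!grepl("^positions length", problems)]
  if (length(problems)) {
    stop("invalid hap_matrix:\n", paste0("  - ", problems, collapse = "\n"),
         call. = FALSE)
  }
  invisible(m)
}

# Data-region view used throughout: the first data_width columns.
data_region <- function(m) {
  w <- ncol(m$alleles) - m$padding_width
  m$alleles[, seq_len(w), drop = FALSE]
}
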
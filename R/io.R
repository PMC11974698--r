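#' Read ms-style simulator output
#'
#' Parses the de facto text format of coalescent simulators: replicates
#' delimited by `//`, each with a `segsites: <k>` line, a
#' `positions: <k floats>` line, then one 0/1 string per haplotype. Positions
#' are stored as given (typically scaled `[0, 1)`); no rescaling is applied.
#'
#' @param file path to an ms output file, or a character vector holding the
#'   text itself (a single string may contain newlines).
#' @return list of [hap_matrix()] objects, one per replicate, each with
#'   `padding_width` 0. A `segsites: 0` replicate yields a degenerate
#'   zero-column matrix (flagged with a warning) for the caller to handle.
#' @examples
#' txt <- c("ms 2 1", "//", "segsites: 2", "positions: 0.10 0.50", "01", "11")
#' read_ms(txt)[[1]]
#' @export
read_ms <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
  starts <- which(trimws(lines) == "//")
  if (!length(starts)) {
    stop("no replicate delimiter `//` found in ms input", call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[seq.int(starts[r], ends[r])]
    seg_line <- grep("^segsites:", trimws(block))
    if (!length(seg_line)) {
      stop(sprintf("replicate %d: missing `segsites:` line", r), call. = FALSE)
    }
    k <- as.integer(sub("^segsites:\\s*", "", trimws(block[seg_line[1L]])))
    if (is.na(k)) {
      stop(sprintf("replicate %d: unparseable segsites count", r), call. = FALSE)
    }
    if (k == 0L) {
      warning(sprintf("replicate %d has segsites 0; returning a zero-column matrix", r))
      out[[r]] <- new_hap_matrix(matrix(integer(0), nrow = 0L, ncol = 0L),
                                 padding_width = 0L, positions = NULL)
      next
    }
    pos_line <- grep("^positions:", trimws(block))
    positions <- NULL
    if (length(pos_line)) {
      positions <- as.numeric(strsplit(
        trimws(sub("^positions:", "", trimws(block[pos_line[1L]]))), "\\s+")[[1L]])
      if (length(positions) != k) {
        stop(sprintf("replicate %d: %d positions for %d segsites",
                     r, length(positions), k), call. = FALSE)
      }
    }
    body_start <- max(seg_line[1L], if (length(pos_line)) pos_line[1L] else 0L) + 1L
    rows <- character(0)
    for (i in seq.int(body_start, length(block))) {
      ln <- trimws(block[i])
      if (ln == "") {
        if (length(rows)) break else next
      }
      if (!grepl("^[01]+$", ln)) {
        stop(sprintf("replicate %d, line %d: haplotype row contains non-0/1 character",
                     r, i), call. = FALSE)
      }
      if (nchar(ln) != k) {
        stop(sprintf("replicate %d, line %d: row length %d != segsites %d",
                     r, i, nchar(ln), k), call. = FALSE)
      }
      rows <- c(rows, ln)
    }
    if (length(rows) < 2L) {
      stop(sprintf("replicate %d: found %d haplotype rows; need >= 2",
                   r, length(rows)), call. = FALSE)
    }
    alleles <- matrix(
      as.integer(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE)),
      nrow = length(rows), ncol = k, byrow = TRUE)
    out[[r]] <- hap_matrix(alleles, padding_width = 0L, positions = positions)
  }
  out
}

#' Read phased haplotypes from a VCF
#'
#' Converts biallelic SNP records with phased genotypes into a haplotype
#' matrix: each diploid sample contributes two rows (haploid samples one),
#' columns ordered by `POS`, positions stored as the 1-based `POS` values
#' verbatim. Non-SNP or multiallelic records are skipped with a message.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param samples optional character vector restricting to these sample names.
#' @param allow_unphased treat `/`-separated genotypes as if phased. Off by
#'   default: the shuffles operate strictly on haplotypes, and silently
#'   pseudo-phasing genotypes would fabricate haplotype structure.
#' @return a [hap_matrix()] with `padding_width` 0.
#' @export
read_vcf <- function(path, samples = NULL, allow_unphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skipped))
  }
  if (!any(keep)) stop("no biallelic SNP records in VCF", call. = FALSE)
  if (length(unique(fix[keep, "CHROM"])) > 1L) {
    stop("VCF spans multiple chromosomes; supply one region at a time", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) {
      stop("sample(s) not in VCF: ", toString(missing_s), call. = FALSE)
    }
    gt <- gt[, samples, drop = FALSE]
  }
  if (anyNA(gt) || any(grepl(".", gt, fixed = TRUE))) {
    stop("missing allele ('.') in GT; cannot build haplotypes", call. = FALSE)
  }
  if (any(grepl("/", gt, fixed = TRUE))) {
    if (!allow_unphased) {
      stop("unphased genotype separator '/' found; set allow_unphased = TRUE ",
           "to treat genotypes as phased", call. = FALSE)
    }
    gt[] <- gsub("/", "|", gt, fixed = TRUE)
  }
  pos <- as.numeric(fix[keep, "POS"])
  ord <- order(pos)
  gt <- gt[ord, , drop = FALSE]
  pos <- pos[ord]
  rows <- list()
  for (s in colnames(gt)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    ploidy <- unique(lengths(parts))
    if (length(ploidy) != 1L) {
      stop(sprintf("sample %s has inconsistent ploidy across records", s),
           call. = FALSE)
    }
    al <- matrix(as.integer(unlist(parts, use.names = FALSE)),
                 nrow = ploidy, ncol = length(parts))
    if (anyNA(al) || any(al > 1L)) {
      stop(sprintf("sample %s has a non-biallelic or unparseable allele", s),
           call. = FALSE)
    }
    for (h in seq_len(ploidy)) rows[[length(rows) + 1L]] <- al[h, ]
  }
  hap_matrix(do.call(rbind, rows), padding_width = 0L, positions = pos)
}

ARCHIVE_MAGIC <- "#hapshuffle v1"

#' Write / read the plain-text matrix archive
#'
#' A minimal self-describing text format for haplotype matrices: a header
#' line `#hapshuffle v1 n_hap=<i> n_col=<i> padding_width=<i>`, an optional
#' `#positions <numbers>` line, then one contiguous 0/1 string per haplotype.
#' The round trip is bit-exact, positions included (written with 17
#' significant digits).
#'
#' @param m a valid `hap_matrix`.
#' @param path file path to write to / read from.
#' @return `write_archive` returns `path` invisibly; `read_archive` returns
#'   the reconstructed [hap_matrix()].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' m <- hap_matrix(rbind(c(0, 1), c(1, 1)), positions = c(0.1, 0.5))
#' write_archive(m, f)
#' identical(read_archive(f), m)
#' @export
write_archive <- function(m, path) {
  stop_if_invalid(m)
  a <- m$alleles
  header <- sprintf("%s n_hap=%d n_col=%d padding_width=%d",
                    ARCHIVE_MAGIC, nrow(a), ncol(a), m$padding_width)
  lines <- header
  if (!is.null(m$positions)) {
    lines <- c(lines, paste("#positions",
                            paste(sprintf("%.17g", m$positions), collapse = " ")))
  }
  lines <- c(lines, apply(a, 1L, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], ARCHIVE_MAGIC)) {
    stop("not a hapshuffle v1 archive: bad or missing header", call. = FALSE)
  }
  get_field <- function(name) {
    pat <- sprintf(".*\\b%s=(\\d+).*", name)
    if (!grepl(sprintf("\\b%s=\\d+", name), lines[1L])) {
      stop(sprintf("archive header missing field `%s`", name), call. = FALSE)
    }
    as.integer(sub(pat, "\\1", lines[1L]))
  }
  n_hap <- get_field("n_hap")
  n_col <- get_field("n_col")
  padding_width <- get_field("padding_width")
  cursor <- 2L
  positions <- NULL
  if (cursor <= length(lines) && startsWith(lines[cursor], "#positions")) {
    body <- trimws(sub("^#positions", "", lines[cursor]))
    positions <- if (nzchar(body)) as.numeric(strsplit(body, "\\s+")[[1L]]) else numeric(0)
    cursor <- cursor + 1L
  }
  rows <- lines[seq.int(cursor, length.out = length(lines) - cursor + 1L)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != n_hap) {
    stop(sprintf("archive declares n_hap=%d but has %d row(s)", n_hap, length(rows)),
         call. = FALSE)
  }
  if (any(nchar(rows) != n_col)) {
    stop(sprintf("archive declares n_col=%d but a row has %d character(s)",
                 n_col, nchar(rows[which(nchar(rows) != n_col)[1L]])), call. = FALSE)
  }
  if (any(!grepl("^[01]*$", rows))) {
    stop("archive row contains a non-0/1 character", call. = FALSE)
  }
  alleles <- matrix(
    as.integer(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE)),
    nrow = n_hap, ncol = n_col, byrow = TRUE)
  hap_matrix(alleles, padding_width = padding_width, positions = positions)
}

#' Right-pad a matrix with all-zero columns to a target width
#'
#' Emulates the zero-padding preprocessing of fixed-input-width networks:
#' all-zero columns are appended on the right and recorded in
#' `padding_width`. Positions are unchanged (they describe data columns only).
#'
#' @param m a valid `hap_matrix` with `padding_width` 0.
#' @param target_width total column count after padding; must be >= `n_col`.
#' @return the padded [hap_matrix()].
#' @export
pad_to_width <- function(m, target_width) {
  stop_if_invalid(m)
  if (m$padding_width != 0L) {
    stop("pad_to_width expects an unpadded matrix (padding_width 0)", call. = FALSE)
  }
  target_width <- check_scalar_count(target_width, "target_width", min = 1L)
  w <- ncol(m$alleles)
  if (target_width < w) {
    stop(sprintf("target_width %d smaller than matrix width %d", target_width, w),
         call. = FALSE)
  }
  if (target_width == w) return(m)
  pad <- matrix(0L, nrow = nrow(m$alleles), ncol = target_width - w)
  new_hap_matrix(cbind(m$alleles, pad),
                 padding_width = target_width - w,
                 positions = m$positions)
}
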
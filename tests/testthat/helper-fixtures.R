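# Fixture builders shared across test files. Everything is generated in code
# from fixed seeds; no data files.

# A mixed bag of matrices from all three generators, varied dimensions, some
# right-padded — the standard corpus for property tests.
random_matrix_corpus <- function(n, master_seed = 424242L,
                                 max_hap = 32L, max_sites = 128L) {
  lapply(seq_len(n), function(i) {
    cfg <- hapshuffle:::with_seed(hapshuffle:::derive_seed(master_seed, i, 1L), {
      list(gen = sample(c("neutral", "ld_mosaic", "sweep"), 1L),
           n_hap = sample(4:max_hap, 1L),
           n_sites = sample(8:max_sites, 1L),
           pad = sample(c(0L, sample(1:16, 1L)), 1L))
    })
    seed <- hapshuffle:::derive_seed(master_seed, i, 2L)
    m <- switch(cfg$gen,
      neutral = simulate_neutral(cfg$n_hap, cfg$n_sites, seed),
      ld_mosaic = simulate_ld_mosaic(cfg$n_hap, cfg$n_sites,
                                     n_founders = min(4L, cfg$n_hap),
                                     switch_rate = 0.1, seed = seed),
      sweep = simulate_sweep_like(cfg$n_hap, cfg$n_sites, sweep_freq = 0.8,
                                  seed = seed))
    if (cfg$pad > 0L) m <- pad_to_width(m, ncol(m$alleles) + cfg$pad)
    m
  })
}

ms_fixture_text <- function() {
  c("ms 3 2 -t 5", "1234 5678 91011", "",
    "//",
    "segsites: 2",
    "positions: 0.10 0.50",
    "01",
    "11",
    "00",
    "",
    "//",
    "segsites: 3",
    "positions: 0.20 0.40 0.90",
    "010",
    "110",
    "001")
}

write_vcf_fixture <- function(path, gts = c("0|1", "1|1"),
                              extra_record = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"))
  records <- c(
    paste(c("1", "100", ".", "A", "T", ".", "PASS", ".", "GT", gts[1L]),
          collapse = "\t"),
    paste(c("1", "200", ".", "G", "C", ".", "PASS", ".", "GT", gts[2L]),
          collapse = "\t"))
  writeLines(c(header, records, extra_record), path)
  path
}

# Scalar statistics bundle used by the preservation-matrix checks; the r2
# multiset is sorted so column permutations compare equal.
stat_bundle <- function(m) {
  s <- summarize_matrix(m)
  ld <- suppressMessages(ld_r2(m))
  list(afs = s$afs,
       pi = s$pi,
       seg_sites = s$seg_sites,
       total_derived = s$total_derived,
       singleton_fraction = s$singleton_fraction,
       h1 = s$h1,
       r2_multiset = sort(round(ld$r2[upper.tri(ld$r2)], 12)),
       data_width = data_width(m),
       lic = last_informative_column(m))
}
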
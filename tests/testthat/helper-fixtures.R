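# Shared in-code fixtures for the test suite. Everything is generated,
# nothing is read from disk except through the package's own writers.

# a log2-ratio profile over evenly spaced 150 bp targets
make_profile <- function(ratios, chrom = "chr1", start0 = 10000L,
                         spacing = 5150L) {
  n <- length(ratios)
  start <- start0 + (seq_len(n) - 1L) * spacing
  data.frame(chrom = rep(chrom, length.out = n), start = start,
             end = start + 150L, name = sprintf("T%04d", seq_len(n)),
             log2_ratio = ratios, stringsAsFactors = FALSE)
}

# histogram rows for one marker with given length -> count pairs
make_hist <- function(marker_id, lengths, counts) {
  data.frame(marker_id = marker_id, repeat_length = lengths,
             read_count = counts, stringsAsFactors = FALSE)
}

# a minimal variant row with sane defaults, overridable by name
make_variant <- function(...) {
  v <- data.frame(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                  gene = "GENE1", effect = "missense", vaf = 0.3,
                  depth = 200, popmax_af = NA_real_,
                  internal_db_status = "none",
                  functional_class = "unclassified",
                  protein_change = NA_character_,
                  priority = "prioritized", deprioritization_reasons = "",
                  stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

# n distinct variant rows (unique positions)
make_variants <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(pos = 1000L + i, ...)
  }))
}

# write a small VCF from raw lines
write_vcf_lines <- function(body, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", sep = "\t"))
  writeLines(c(hdr, body), path)
  path
}
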
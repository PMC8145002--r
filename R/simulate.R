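#' Generate a synthetic panel target layout
#'
#' Evenly spaced fixed-width targets across a set of chromosomes, named
#' and grouped into genes, emulating the exon-level probe layout of a
#' hybrid-capture panel.
#'
#' @param n_targets Number of targets (default 200).
#' @param n_chrom Number of chromosomes the targets spread over
#'   (default 4).
#' @param target_bp Target width in bp (default 150).
#' @param gap_bp Gap between adjacent targets (default 5000).
#' @param targets_per_gene Targets grouped under one gene label
#'   (default 10).
#' @return A target table in [read_targets()] layout.
#' @export
gen_targets <- function(n_targets = 200L, n_chrom = 4L, target_bp = 150L,
                        gap_bp = 5000L, targets_per_gene = 10L) {
  per_chrom <- ceiling(n_targets / n_chrom)
  chrom <- paste0("chr", rep(seq_len(n_chrom), each = per_chrom))[
    seq_len(n_targets)]
  idx_on_chrom <- unlist(lapply(rle(chrom)$lengths, seq_len)) - 1L
  start <- 10000L + idx_on_chrom * (target_bp + gap_bp)
  data.frame(
    chrom = chrom, start = start, end = start + target_bp,
    name = sprintf("T%04d", seq_len(n_targets)),
    gene = sprintf("GENE%03d",
                   (seq_len(n_targets) - 1L) %/% targets_per_gene + 1L),
    kind = "on_target", stringsAsFactors = FALSE
  )
}

#' Simulate tumor + panel-of-normals coverage with injected CNVs
#'
#' Per-target depth is `coverage_mean * 2^(r + e)` where `r` is the
#' expected log2 ratio of the target's true copy-number state at the given
#' purity ([expected_log2_ratio()]) and `e` is Gaussian log2-scale noise —
#' a log-normal multiplicative noise model. References are generated at
#' CN = 2. Ground-truth events are recorded exactly.
#'
#' @param targets Target table (e.g. [gen_targets()]).
#' @param cnv_spec data.frame `(chrom, start, end, cn)` of injected events
#'   (0-based half-open, non-overlapping).
#' @param purity Tumor cellularity in (0, 1].
#' @param coverage_mean Mean on-target depth (default 300, the assay's
#'   working range).
#' @param log2_noise_sd Per-target log2 noise sd (default 0.05).
#' @param n_references Panel-of-normals size (default 4).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list: `tumor` (coverage profile), `references` (list of
#'   profiles), `truth` (data.frame `chrom`, `start`, `end`, `cn`,
#'   `direction`).
#' @export
gen_coverage <- function(targets, cnv_spec = NULL, purity = 1,
                         coverage_mean = 300, log2_noise_sd = 0.05,
                         n_references = 4L, seed = 1L) {
  if (!is.null(cnv_spec) && nrow(cnv_spec) > 1L) {
    for (i in seq_len(nrow(cnv_spec) - 1L)) {
      for (j in (i + 1L):nrow(cnv_spec)) {
        if (cnv_spec$chrom[i] == cnv_spec$chrom[j] &&
            cnv_spec$start[i] < cnv_spec$end[j] &&
            cnv_spec$end[i] > cnv_spec$start[j]) {
          stop("overlapping cnv_spec regions")
        }
      }
    }
  }
  set.seed(seed)
  cn <- rep(2, nrow(targets))
  if (!is.null(cnv_spec)) {
    for (i in seq_len(nrow(cnv_spec))) {
      hit <- targets$chrom == cnv_spec$chrom[i] &
        targets$start >= cnv_spec$start[i] &
        targets$end <= cnv_spec$end[i]
      cn[hit] <- cnv_spec$cn[i]
    }
  }
  exp_r <- expected_log2_ratio(cn, purity)
  noise <- function() {
    if (log2_noise_sd > 0) stats::rnorm(nrow(targets), 0, log2_noise_sd)
    else rep(0, nrow(targets))
  }
  tumor <- coverage_profile(coverage_mean * 2^(exp_r + noise()), targets,
                            sample_id = "tumor")
  references <- lapply(seq_len(n_references), function(i) {
    coverage_profile(coverage_mean * 2^noise(), targets,
                     sample_id = paste0("normal", i))
  })
  truth <- if (is.null(cnv_spec) || nrow(cnv_spec) == 0L) {
    data.frame(chrom = character(), start = integer(), end = integer(),
               cn = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cnv_spec,
               direction = ifelse(cnv_spec$cn > 2, "gain", "loss"),
               stringsAsFactors = FALSE)
  }
  list(tumor = tumor, references = references, truth = truth)
}

# stable per-marker repeat-length distribution: unimodal around the
# reference length with stutter one and two units away
stable_shape <- function(reference_length) {
  lens <- reference_length + (-2:2)
  probs <- c(0.05, 0.2, 0.5, 0.2, 0.05)
  keep <- lens >= 1
  data.frame(repeat_length = lens[keep], prob = probs[keep] /
               sum(probs[keep]))
}

sample_hist <- function(marker_id, shape, n_reads) {
  counts <- as.integer(stats::rmultinom(1, n_reads, shape$prob))
  data.frame(marker_id = marker_id,
             repeat_length = shape$repeat_length,
             read_count = counts, stringsAsFactors = FALSE)
}

#' Simulate microsatellite marker histograms with known MSI status
#'
#' Stable markers draw reads (multinomially) from a unimodal stutter
#' distribution centered on the marker's reference repeat length; unstable
#' markers draw from the same shape shifted by `length_shift` repeat units
#' (the typical somatic slippage signal). Three MSS reference samples are
#' generated from the unshifted shapes. The truth class applies the
#' classification bands to the specified unstable fraction.
#'
#' @param markers Marker definition table (default the packaged 110).
#' @param fraction_unstable Fraction of markers simulated unstable.
#' @param length_shift Repeat-unit shift of unstable markers (default 2).
#' @param reads_per_marker Reads per marker (default 200); values below
#'   the validity threshold intentionally generate invalid markers (a
#'   warning is raised).
#' @param n_references Number of MSS reference samples (default 3).
#' @param min_coverage Validity threshold used for the warning and the
#'   truth class (default 30).
#' @param min_valid Minimum valid markers for the truth class (default 99).
#' @param seed Integer seed.
#' @return A list: `sample` (histograms), `references` (list of
#'   histograms), `truth_class`, `unstable_markers`.
#' @export
gen_msi <- function(markers = oncopanel_msi_markers(),
                    fraction_unstable = 0, length_shift = 2L,
                    reads_per_marker = 200L, n_references = 3L,
                    min_coverage = 30L, min_valid = 99L, seed = 1L) {
  stopifnot(fraction_unstable >= 0, fraction_unstable <= 1)
  if (reads_per_marker < min_coverage) {
    warning("reads_per_marker below the validity threshold: ",
            "all markers will be invalid")
  }
  set.seed(seed)
  n <- nrow(markers)
  n_unstable <- round(fraction_unstable * n)
  unstable_ids <- if (n_unstable > 0L) {
    sample(markers$marker_id, n_unstable)
  } else character(0)
  gen_sample <- function(shift_ids) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      shape <- stable_shape(markers$reference_length[i] +
                              if (markers$marker_id[i] %in% shift_ids)
                                length_shift else 0L)
      sample_hist(markers$marker_id[i], shape, reads_per_marker)
    }))
  }
  references <- lapply(seq_len(n_references),
                       function(i) gen_sample(character(0)))
  sample_h <- gen_sample(unstable_ids)
  n_valid_truth <- if (reads_per_marker >= min_coverage) n else 0L
  truth_class <- if (n_valid_truth < min_valid) "no_call"
                 else classify_msi(n_unstable / n_valid_truth,
                                   n_valid_truth, min_valid)
  list(sample = sample_h, references = references,
       truth_class = truth_class, unstable_markers = unstable_ids)
}

#' Simulate an annotated somatic variant table (and VCF) with known truth
#'
#' Observed alt-read counts are Binomial(depth, true VAF); the observed
#' VAF is alt/depth. A dilution factor scales all true VAFs (emulating
#' mixing a positive sample into a negative background, e.g. 1:1 dilution
#' halves every VAF). Truth records carry the pre-noise VAFs.
#'
#' @param spec data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `effect`, `true_vaf`, `depth` and optionally
#'   `functional_class`, `protein_change`, `popmax_af`.
#' @param dilution Multiplicative dilution factor on true VAFs
#'   (default 1 = undiluted).
#' @param seed Integer seed.
#' @param vcf_path Optional path; when given, an annotated VCF is written
#'   there.
#' @return A list: `variants` (table in [read_variants()] layout with
#'   observed VAFs), `truth` (spec with diluted true VAFs), `vcf_path`.
#' @export
gen_variants <- function(spec, dilution = 1, seed = 1L,
                         vcf_path = NULL) {
  stopifnot(all(spec$depth > 0))
  set.seed(seed)
  true_vaf <- pmin(1, spec$true_vaf * dilution)
  alt_reads <- stats::rbinom(nrow(spec), spec$depth, true_vaf)
  variants <- data.frame(
    chrom = spec$chrom, pos = spec$pos, ref = spec$ref, alt = spec$alt,
    gene = spec$gene, effect = spec$effect,
    vaf = alt_reads / spec$depth, depth = spec$depth,
    popmax_af = if ("popmax_af" %in% names(spec)) spec$popmax_af
                else NA_real_,
    internal_db_status = "none",
    functional_class = if ("functional_class" %in% names(spec))
      spec$functional_class else "unclassified",
    protein_change = if ("protein_change" %in% names(spec))
      spec$protein_change else NA_character_,
    priority = "prioritized", deprioritization_reasons = "",
    stringsAsFactors = FALSE
  )
  truth <- spec
  truth$true_vaf <- true_vaf
  if (!is.null(vcf_path)) write_variant_vcf(variants, vcf_path)
  list(variants = variants, truth = truth, vcf_path = vcf_path)
}

# minimal single-sample VCF emitter for generated fixtures
write_variant_vcf <- function(variants, path, sample_id = "TUMOR") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Protein effect\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population popmax AF\">",
    "##INFO=<ID=DB,Number=1,Type=String,Description=\"Internal DB status\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- c(paste0("GENE=", variants$gene[i]),
               paste0("EFFECT=", variants$effect[i]))
    if (!is.na(variants$popmax_af[i])) {
      parts <- c(parts, paste0("POPAF=", variants$popmax_af[i]))
    }
    if (variants$internal_db_status[i] != "none") {
      parts <- c(parts, paste0("DB=", variants$internal_db_status[i]))
    }
    if (!is.na(variants$protein_change[i])) {
      parts <- c(parts, paste0("PCHANGE=", variants$protein_change[i]))
    }
    paste(parts, collapse = ";")
  }, character(1))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT:AF:DP",
                paste("0/1", sprintf("%.6g", variants$vaf),
                      variants$depth, sep = ":"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate replicate input sets with shared truth
#'
#' Calls `gen` once per replicate with a seed derived from the master seed
#' plus the replicate index, so replicates carry independent noise around
#' the same truth and the whole set is reproducible from the master seed.
#'
#' @param gen A function of a single `seed` argument returning one
#'   generated input set.
#' @param n Number of replicates (>= 2).
#' @param seed Master seed.
#' @return A list of `n` generated sets.
#' @export
gen_replicates <- function(gen, n, seed = 1L) {
  if (n < 2L) stop("need n >= 2 replicates")
  lapply(seq_len(n), function(i) gen(seed + i))
}
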
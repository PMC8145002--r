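#' Run and sample QC gates
#'
#' Default gates: Q30 strictly greater than 80%, clusters passing filter
#' strictly greater than 70%, DNA Integrity Number strictly greater than 2,
#' at least 26 million reads, and a DP100 target of 96.2% of bases at
#' >= 100x depth.
#'
#' @param min_q30_pct,min_pf_pct,min_din,min_reads,dp100_target_pct Gate
#'   values.
#' @return A list of class `qc_gates`.
#' @export
qc_gates <- function(min_q30_pct = 80, min_pf_pct = 70, min_din = 2,
                     min_reads = 26e6, dp100_target_pct = 96.2) {
  stopifnot(min_q30_pct > 0, min_pf_pct > 0, min_din > 0, min_reads > 0)
  structure(list(min_q30_pct = min_q30_pct, min_pf_pct = min_pf_pct,
                 min_din = min_din, min_reads = min_reads,
                 dp100_target_pct = dp100_target_pct),
            class = "qc_gates")
}

#' Evaluate run/sample QC gates
#'
#' Q30, cluster-PF and DIN are strict inequalities (a run at exactly 80%
#' Q30 fails; a sample at exactly DIN 2 fails); the read-count gate is
#' inclusive. Overall pass requires every gate to pass.
#'
#' @param metrics A list or one-row data.frame with `q30_pct`,
#'   `clusters_pf_pct`, `n_reads` (percentages in \[0, 100\]).
#' @param meta A list with `din` (and optionally `sample_id`).
#' @param gates [qc_gates()].
#' @return A data.frame `(gate, value, threshold, pass)` with attribute
#'   `overall_pass`.
#' @export
run_qc <- function(metrics, meta, gates = qc_gates()) {
  out <- data.frame(
    gate = c("q30", "clusters_pf", "din", "n_reads"),
    value = c(metrics$q30_pct, metrics$clusters_pf_pct, meta$din,
              metrics$n_reads),
    threshold = c(gates$min_q30_pct, gates$min_pf_pct, gates$min_din,
                  gates$min_reads),
    pass = c(metrics$q30_pct > gates$min_q30_pct,
             metrics$clusters_pf_pct > gates$min_pf_pct,
             meta$din > gates$min_din,
             metrics$n_reads >= gates$min_reads),
    stringsAsFactors = FALSE
  )
  attr(out, "overall_pass") <- all(out$pass)
  attr(out, "failures") <- out$gate[!out$pass]
  out
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

pos_in_targets <- function(chrom, pos, targets) {
  # VCF pos is 1-based; targets are 0-based half-open
  vapply(seq_along(pos), function(i) {
    any(targets$chrom == chrom[i] & targets$start < pos[i] &
          targets$end >= pos[i])
  }, logical(1))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Accuracy of a call set against a truth set
#'
#' Scores calls against truth within the assay's stated evaluation scope:
#' truth variants below the VAF limit of detection or outside the panel's
#' target regions are excluded from the denominator before scoring.
#' Matching rules per analyte: sequence variants match on
#' chrom/pos/ref/alt; CNV events match on direction plus reciprocal
#' overlap >= `min_overlap`; MSI matches on class per sample. Specificity
#' is computed only when an interrogated-negative space is supplied
#' (`n_interrogated_negatives`), otherwise reported as `NA` — never 0.
#'
#' @param calls Call set (data.frame; columns depend on `analyte`).
#' @param truth Truth set (same layout; variant truth may carry `vaf`).
#' @param analyte `"variant"`, `"cnv"` or `"msi"`.
#' @param lod_vaf Truth variants with VAF strictly below this are excluded
#'   (default 0.05).
#' @param targets Optional panel target table restricting the variant
#'   evaluation space.
#' @param n_interrogated_negatives Optional count of interrogated negative
#'   positions/markers (specificity denominator is this minus nothing:
#'   TN = n - FP).
#' @param min_overlap Reciprocal-overlap threshold for CNV matching
#'   (default 0.5).
#' @return A list: `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `n_truth_evaluated`, `n_truth_excluded`.
#' @export
accuracy <- function(calls, truth, analyte = c("variant", "cnv", "msi"),
                     lod_vaf = 0.05, targets = NULL,
                     n_interrogated_negatives = NULL,
                     min_overlap = 0.5) {
  analyte <- match.arg(analyte)
  excluded <- 0L
  if (analyte == "variant") {
    if (!is.null(truth$vaf)) {
      drop <- truth$vaf < lod_vaf
      excluded <- excluded + sum(drop)
      truth <- truth[!drop, , drop = FALSE]
    }
    if (!is.null(targets)) {
      keep_t <- pos_in_targets(truth$chrom, truth$pos, targets)
      excluded <- excluded + sum(!keep_t)
      truth <- truth[keep_t, , drop = FALSE]
      calls <- calls[pos_in_targets(calls$chrom, calls$pos, targets), ,
                     drop = FALSE]
    }
    tk <- variant_key(truth); ck <- variant_key(calls)
    tp <- sum(tk %in% ck); fn <- sum(!tk %in% ck)
    fp <- sum(!ck %in% tk)
  } else if (analyte == "cnv") {
    matched_truth <- logical(nrow(truth))
    matched_call <- logical(nrow(calls))
    for (i in seq_len(nrow(truth))) {
      for (j in seq_len(nrow(calls))) {
        if (truth$chrom[i] == calls$chrom[j] &&
            truth$direction[i] == calls$direction[j] &&
            reciprocal_overlap(truth$start[i], truth$end[i],
                               calls$start[j], calls$end[j]) >=
              min_overlap) {
          matched_truth[i] <- TRUE
          matched_call[j] <- TRUE
        }
      }
    }
    tp <- sum(matched_truth); fn <- sum(!matched_truth)
    fp <- sum(!matched_call)
  } else {
    stopifnot(nrow(calls) == nrow(truth))
    ok <- calls$msi_class == truth$msi_class
    tp <- sum(ok); fn <- sum(!ok); fp <- sum(!ok)
  }
  tn <- if (is.null(n_interrogated_negatives)) NA_integer_
        else n_interrogated_negatives - fp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (!is.na(tn) && tn + fp > 0) tn / (tn + fp) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn, sensitivity = sens,
       specificity = spec, n_truth_evaluated = nrow(truth),
       n_truth_excluded = excluded)
}

#' Per-analyte exclusion rules for replicate comparisons
#'
#' Mirrors the repeatability/reproducibility scope: SNVs require VAF
#' strictly above 5%, PASS filter status and no homopolymer proximity;
#' CNVs require size >= 0.5 kb, score strictly above 8 and autosomal
#' location; fusions require supporting coverage >= 10.
#'
#' @param snv_min_vaf,snv_require_pass,snv_exclude_homopolymer SNV rules.
#' @param cnv_min_size_bp,cnv_min_score,cnv_exclude_sex_chroms CNV rules.
#' @param fusion_min_coverage Fusion rule.
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(snv_min_vaf = 0.05, snv_require_pass = TRUE,
                            snv_exclude_homopolymer = TRUE,
                            cnv_min_size_bp = 500, cnv_min_score = 8,
                            cnv_exclude_sex_chroms = TRUE,
                            fusion_min_coverage = 10) {
  structure(list(snv_min_vaf = snv_min_vaf,
                 snv_require_pass = snv_require_pass,
                 snv_exclude_homopolymer = snv_exclude_homopolymer,
                 cnv_min_size_bp = cnv_min_size_bp,
                 cnv_min_score = cnv_min_score,
                 cnv_exclude_sex_chroms = cnv_exclude_sex_chroms,
                 fusion_min_coverage = fusion_min_coverage),
            class = "exclusion_rules")
}

apply_exclusions <- function(df, analyte, rules) {
  reason <- rep(NA_character_, nrow(df))
  if (analyte == "snv") {
    if (!is.null(df$vaf)) {
      reason[is.na(reason) & df$vaf <= rules$snv_min_vaf] <- "LOW_VAF"
    }
    if (rules$snv_require_pass && !is.null(df$filter)) {
      reason[is.na(reason) & df$filter != "PASS"] <- "NOT_PASS"
    }
    if (rules$snv_exclude_homopolymer &&
        !is.null(df$homopolymer_proximal)) {
      reason[is.na(reason) & df$homopolymer_proximal] <- "HOMOPOLYMER"
    }
  } else if (analyte == "cnv") {
    reason[is.na(reason) & df$size_bp < rules$cnv_min_size_bp] <-
      "SMALL_EVENT"
    reason[is.na(reason) & df$score <= rules$cnv_min_score] <-
      "LOW_SCORE"
    if (rules$cnv_exclude_sex_chroms && !is.null(df$sex_chromosome)) {
      reason[is.na(reason) & df$sex_chromosome] <- "SEX_CHROMOSOME"
    }
  } else if (analyte == "fusion") {
    reason[is.na(reason) & df$coverage < rules$fusion_min_coverage] <-
      "LOW_COVERAGE"
  }
  list(kept = df[is.na(reason), , drop = FALSE],
       excluded = data.frame(key = item_key(df, analyte),
                             rule = reason,
                             stringsAsFactors = FALSE)[!is.na(reason), ,
                                                       drop = FALSE])
}

item_key <- function(df, analyte) {
  switch(analyte,
    snv = variant_key(df),
    cnv = paste(df$chrom, df$start, df$end, df$direction, sep = ":"),
    fusion = df$name,
    msi = df$msi_class,
    pgx = paste(df$rsid, df$genotype, sep = ":"))
}

#' Replicate concordance with per-analyte exclusion rules
#'
#' Concordance is the percentage of post-exclusion items present in
#' *every* replicate among items present in *any* replicate. Exclusions
#' are applied per replicate before forming the union/intersection and
#' every excluded item is recorded with the rule that removed it.
#' Symmetric under permutation of the replicates; 100% when all replicates
#' are identical.
#'
#' @param replicates List (>= 2) of call-set data.frames from the same
#'   material.
#' @param analyte `"snv"`, `"cnv"`, `"fusion"`, `"msi"` or `"pgx"`.
#' @param rules [exclusion_rules()].
#' @return A list: `concordance_pct`, `n_union`, `n_in_all`, `excluded`
#'   (data.frame `replicate`, `key`, `rule`).
#' @export
replicate_concordance <- function(replicates,
                                  analyte = c("snv", "cnv", "fusion",
                                              "msi", "pgx"),
                                  rules = exclusion_rules()) {
  analyte <- match.arg(analyte)
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  ledgers <- list()
  keys <- lapply(seq_along(replicates), function(i) {
    res <- apply_exclusions(replicates[[i]], analyte, rules)
    if (nrow(res$excluded) > 0L) {
      res$excluded$replicate <- i
      ledgers[[length(ledgers) + 1L]] <<- res$excluded
    }
    unique(item_key(res$kept, analyte))
  })
  all_union <- Reduce(union, keys)
  in_all <- Reduce(intersect, keys)
  conc <- if (length(all_union) == 0L) NA_real_
          else 100 * length(in_all) / length(all_union)
  excluded <- if (length(ledgers) > 0L) do.call(rbind, ledgers)
              else data.frame(key = character(), rule = character(),
                              replicate = integer(),
                              stringsAsFactors = FALSE)
  list(concordance_pct = conc, n_union = length(all_union),
       n_in_all = length(in_all), excluded = excluded)
}

#' Coefficient of variation of replicate VAF measurements
#'
#' `CV = 100 * sd / mean` with the sample (n - 1) standard deviation;
#' passes when strictly below `max_cv_pct`. Scale-invariant.
#'
#' @param vafs Numeric vector (>= 2 finite values) of replicate VAFs for
#'   one variant.
#' @param max_cv_pct Acceptance bound (default 25).
#' @return A list `(cv_pct, mean, sd, pass)`.
#' @export
vaf_cv <- function(vafs, max_cv_pct = 25) {
  vafs <- vafs[is.finite(vafs)]
  if (length(vafs) < 2L) stop("need at least 2 finite VAFs")
  m <- mean(vafs)
  if (m == 0) stop("mean VAF is 0; CV undefined")
  cv <- 100 * stats::sd(vafs) / m
  list(cv_pct = cv, mean = m, sd = stats::sd(vafs),
       pass = cv < max_cv_pct)
}

#' Read-saturation (plateau) analysis of DP100 versus read count
#'
#' For each sample, successive DP100 gains are normalized to percentage
#' points per `per_reads` additional reads; the plateau is the smallest
#' grid read count after which every subsequent increment gains strictly
#' less than `plateau_delta`. Samples whose final increment still gains at
#' least `plateau_delta` never plateau and are flagged. The recommended
#' minimum read count is the largest plateau among plateauing samples.
#'
#' @param observations data.frame `(sample_id, n_reads, dp100_pct)`; each
#'   sample needs >= 3 grid points with strictly increasing `n_reads`.
#' @param plateau_delta Gain threshold in percentage points (default 0.5).
#' @param per_reads Read increment the gains are normalized to
#'   (default 2e6).
#' @return A list: `per_sample` (data.frame `sample_id`, `plateau_reads`,
#'   `plateaued`), `recommended_min_reads`, `non_plateauing`.
#' @export
saturation_analysis <- function(observations, plateau_delta = 0.5,
                                per_reads = 2e6) {
  one <- function(df) {
    if (nrow(df) < 3L) stop("sample '", df$sample_id[1L],
                            "': need >= 3 grid points")
    if (is.unsorted(df$n_reads, strictly = TRUE)) {
      stop("sample '", df$sample_id[1L],
           "': n_reads must be strictly increasing")
    }
    gain <- diff(df$dp100_pct) / diff(df$n_reads) * per_reads
    plateau <- NA_real_
    for (j in seq_len(nrow(df) - 1L)) {
      if (all(gain[j:length(gain)] < plateau_delta)) {
        plateau <- df$n_reads[j]
        break
      }
    }
    data.frame(sample_id = df$sample_id[1L], plateau_reads = plateau,
               plateaued = !is.na(plateau), stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, lapply(split(observations,
                                            observations$sample_id), one))
  rownames(per_sample) <- NULL
  plat <- per_sample$plateau_reads[per_sample$plateaued]
  list(per_sample = per_sample,
       recommended_min_reads = if (length(plat)) max(plat) else NA_real_,
       non_plateauing = per_sample$sample_id[!per_sample$plateaued])
}

#' Samples per sequencing run from cluster capacity
#'
#' `floor(capacity / per_sample_clusters)`: the guaranteed minimum of
#' roughly 13 million PF clusters per sample yields 13 samples on a
#' mid-output kit and 32 on a high-output kit at the default capacities.
#'
#' @param kit_cluster_capacity Total PF cluster capacity of the kit.
#' @param per_sample_clusters Guaranteed clusters per sample
#'   (default 13e6, i.e. 26 million reads paired-end).
#' @return Integer number of samples; 0 triggers a warning.
#' @export
samples_per_run <- function(kit_cluster_capacity,
                            per_sample_clusters = 13e6) {
  if (kit_cluster_capacity <= 0 || per_sample_clusters <= 0) {
    stop("capacities must be positive")
  }
  n <- as.integer(floor(kit_cluster_capacity / per_sample_clusters))
  if (n == 0L) {
    warning("kit capacity below one sample's cluster requirement")
  }
  n
}

#' Default kit cluster capacities
#'
#' Config constants reproducing 13 samples (mid output) and 32 samples
#' (high output) at 13e6 clusters per sample.
#'
#' @return Named numeric vector.
#' @export
kit_capacities <- function() {
  c(mid_output = 169e6, high_output = 416e6)
}

#' Cohort alteration-frequency table
#'
#' Percentage of cases in each tumor-type cohort carrying at least one
#' alteration of each gene x class combination (a case counts once per
#' combination regardless of multiplicity), optionally with deltas against
#' a static reference frequency table.
#'
#' @param cases data.frame `(case_id, tumor_type)` — one row per case.
#' @param alterations data.frame `(case_id, gene, class)` — one row per
#'   detected alteration (`class` e.g. `"SNV"`, `"CNV"`).
#' @param reference Optional data.frame `(tumor_type, gene, class,
#'   reference_pct)`.
#' @return data.frame `(tumor_type, gene, class, n_cases, n_affected,
#'   pct)` (+ `reference_pct`, `delta_pct` when a reference is supplied),
#'   percentages rounded to 2 decimals.
#' @export
cohort_frequencies <- function(cases, alterations, reference = NULL) {
  if (nrow(cases) == 0L) stop("empty cohort")
  alt <- merge(alterations, cases, by = "case_id")
  alt <- unique(alt[, c("case_id", "tumor_type", "gene", "class")])
  sizes <- table(cases$tumor_type)
  agg <- stats::aggregate(case_id ~ tumor_type + gene + class, alt,
                          function(x) length(unique(x)))
  names(agg)[names(agg) == "case_id"] <- "n_affected"
  agg$n_cases <- as.integer(sizes[agg$tumor_type])
  agg$pct <- round(100 * agg$n_affected / agg$n_cases, 2)
  if (!is.null(reference)) {
    agg <- merge(agg, reference, by = c("tumor_type", "gene", "class"),
                 all = TRUE)
    # combinations the reference names but the cohort lacks are 0%
    zero <- is.na(agg$n_affected)
    agg$n_affected[zero] <- 0L
    agg$n_cases[zero] <- as.integer(sizes[agg$tumor_type[zero]])
    agg$pct[zero] <- 0
    agg$delta_pct <- round(agg$pct - agg$reference_pct, 2)
  }
  agg <- agg[order(agg$tumor_type, agg$gene, agg$class),
             , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
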
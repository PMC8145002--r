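test_that("QC gates use the printed strict inequalities", {
  good <- list(q30_pct = 90.7, clusters_pf_pct = 88.4, n_reads = 30e6)
  qc <- run_qc(good, list(din = 3.1))
  expect_true(attr(qc, "overall_pass"))

  # DIN must be strictly above 2
  qc_din <- run_qc(good, list(din = 2.0))
  expect_false(attr(qc_din, "overall_pass"))
  expect_equal(attr(qc_din, "failures"), "din")

  # Q30 must be strictly greater than 80
  qc_q30 <- run_qc(list(q30_pct = 80.0, clusters_pf_pct = 88.4,
                        n_reads = 30e6), list(din = 3.1))
  expect_equal(attr(qc_q30, "failures"), "q30")

  qc_reads <- run_qc(list(q30_pct = 90, clusters_pf_pct = 80,
                          n_reads = 25e6), list(din = 3))
  expect_equal(attr(qc_reads, "failures"), "n_reads")
})

test_that("accuracy scopes truth to the LOD and panel regions", {
  truth <- data.frame(chrom = "chr1", pos = 1:10, ref = "A", alt = "T",
                      vaf = c(rep(0.2, 9), 0.03))
  calls <- truth[1:9, ]
  # the 0.03 VAF truth item is below the 5% LOD: excluded, sensitivity 1
  acc <- accuracy(calls, truth, "variant")
  expect_equal(acc$sensitivity, 1)
  expect_equal(acc$fp, 0L)
  expect_equal(acc$n_truth_excluded, 1L)
  # calls == truth gives perfect sensitivity, no false positives
  acc2 <- accuracy(truth, truth, "variant", lod_vaf = 0)
  expect_equal(acc2$sensitivity, 1)
  expect_equal(acc2$fp, 0L)
  # specificity only with an interrogated-negative space, else missing
  expect_true(is.na(acc$specificity))
  acc3 <- accuracy(calls, truth, "variant",
                   n_interrogated_negatives = 1000)
  expect_equal(acc3$specificity, 1)

  # truth outside the panel regions is excluded from the denominator
  tg <- data.frame(chrom = "chr1", start = 0L, end = 5L, name = "T1",
                   gene = "", kind = "on_target")
  acc4 <- accuracy(calls, truth, "variant", lod_vaf = 0, targets = tg)
  expect_equal(acc4$n_truth_evaluated, 5L)
  expect_equal(acc4$sensitivity, 1)

  # CNV: reciprocal overlap >= 0.5 with matching direction
  cnv_truth <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                          direction = "gain")
  cnv_hit <- data.frame(chrom = "chr1", start = 1200L, end = 2100L,
                        direction = "gain")
  expect_equal(accuracy(cnv_hit, cnv_truth, "cnv")$sensitivity, 1)
  cnv_wrong <- data.frame(chrom = "chr1", start = 1200L, end = 2100L,
                          direction = "loss")
  expect_equal(accuracy(cnv_wrong, cnv_truth, "cnv")$sensitivity, 0)

  # MSI: per-sample class concordance
  msi_acc <- accuracy(data.frame(msi_class = c("MSS", "MSI_H", "MSS")),
                      data.frame(msi_class = c("MSS", "MSI_H", "MSI_L")),
                      "msi")
  expect_equal(msi_acc$tp, 2L)
})

test_that("replicate concordance is intersection over union after exclusions", {
  snv <- function(n) data.frame(chrom = "chr1", pos = seq_len(n),
                                ref = "A", alt = "T", vaf = 0.3,
                                filter = "PASS",
                                homopolymer_proximal = FALSE)
  # identical triplicates: 100%
  expect_equal(replicate_concordance(list(snv(10), snv(10), snv(10)),
                                     "snv")$concordance_pct, 100)
  # 118 union variants, 117 in all three
  r <- replicate_concordance(list(snv(118), snv(117), snv(118)), "snv")
  expect_equal(r$n_union, 118L)
  expect_equal(r$n_in_all, 117L)
  expect_equal(round(r$concordance_pct, 2), 99.15)
  # permutation symmetry
  r2 <- replicate_concordance(list(snv(117), snv(118), snv(118)), "snv")
  expect_equal(r2$concordance_pct, r$concordance_pct)
  expect_error(replicate_concordance(list(snv(5)), "snv"), "at least 2")

  # exclusion rules: low-VAF, non-PASS and homopolymer-proximal SNVs
  s <- snv(10)
  s$vaf[1] <- 0.04; s$filter[2] <- "q20"; s$homopolymer_proximal[3] <- TRUE
  r3 <- replicate_concordance(list(s, snv(10)[4:10, ], snv(10)[4:10, ]),
                              "snv")
  expect_equal(r3$concordance_pct, 100)
  expect_setequal(r3$excluded$rule, c("LOW_VAF", "NOT_PASS",
                                      "HOMOPOLYMER"))

  # CNV exclusions: sub-0.5 kb events don't count against concordance
  cnv <- data.frame(chrom = "chr1", start = c(1000L, 50000L),
                    end = c(1400L, 80000L), direction = "gain",
                    size_bp = c(400L, 30000L), score = c(9.5, 9.5),
                    sex_chromosome = FALSE)
  reps <- list(cnv, cnv[2, ], cnv[2, ])
  rc <- replicate_concordance(reps, "cnv")
  expect_equal(rc$concordance_pct, 100)
  expect_equal(rc$excluded$rule, "SMALL_EVENT")
  # score <= 8 excluded (the high-confidence bound is strict)
  cnv8 <- cnv; cnv8$score <- c(8.0, 9.0); cnv8$size_bp <- 30000L
  rc8 <- replicate_concordance(list(cnv8, cnv8, cnv8), "cnv")
  expect_equal(rc8$excluded$rule, rep("LOW_SCORE", 3))
  # fusions need supporting coverage >= 10
  fus <- data.frame(name = c("EML4-ALK", "weak"), coverage = c(50, 9))
  rf <- replicate_concordance(list(fus, fus[1, , drop = FALSE]),
                              "fusion")
  expect_equal(rf$concordance_pct, 100)
  expect_equal(rf$excluded$rule, "LOW_COVERAGE")
})

test_that("VAF coefficient of variation uses the sample sd", {
  expect_equal(vaf_cv(c(0.05, 0.05, 0.05))$cv_pct, 0)
  cv <- vaf_cv(c(0.04, 0.05, 0.06))
  expect_equal(cv$cv_pct, 20)      # sd 0.01 / mean 0.05
  expect_true(cv$pass)
  cv2 <- vaf_cv(c(0.02, 0.05, 0.08))
  expect_equal(cv2$cv_pct, 60)
  expect_false(cv2$pass)
  # scale invariance
  expect_equal(vaf_cv(3 * c(0.02, 0.05, 0.08))$cv_pct, 60)
  expect_error(vaf_cv(c(0, 0, 0)), "mean")
  expect_error(vaf_cv(0.05), "at least 2")
})

test_that("saturation analysis finds the DP100 plateau", {
  grid <- seq(20e6, 34e6, by = 2e6)
  # flat curve plateaus at the first grid point
  flat <- data.frame(sample_id = "f", n_reads = grid, dp100_pct = 96)
  expect_equal(saturation_analysis(flat)$per_sample$plateau_reads, 20e6)
  # strong gains up to 26e6, then < 0.5 pp per 2e6 reads
  sat <- data.frame(sample_id = "s", n_reads = grid,
                    dp100_pct = c(80, 85, 90, 95, 95.2, 95.4, 95.6, 95.8))
  res <- saturation_analysis(sat)
  expect_equal(res$per_sample$plateau_reads, 26e6)
  expect_equal(res$recommended_min_reads, 26e6)
  # strictly rising 1 pp per step: never plateaus, flagged
  rise <- data.frame(sample_id = "r", n_reads = grid,
                     dp100_pct = seq(80, by = 1, length.out = 8))
  expect_equal(saturation_analysis(rise)$non_plateauing, "r")
  # unsorted grid rejected
  expect_error(saturation_analysis(sat[c(2, 1, 3:8), ]), "increasing")
})

test_that("samples per run is floor division of cluster capacity", {
  expect_equal(samples_per_run(kit_capacities()[["mid_output"]]), 13L)
  expect_equal(samples_per_run(kit_capacities()[["high_output"]]), 32L)
  expect_warning(n0 <- samples_per_run(12e6), "below")
  expect_equal(n0, 0L)
  expect_error(samples_per_run(0), "positive")
  # monotone in capacity, anti-monotone in per-sample clusters
  caps <- seq(10e6, 500e6, by = 10e6)
  expect_true(all(diff(suppressWarnings(
    vapply(caps, samples_per_run, integer(1)))) >= 0))
  per <- seq(5e6, 30e6, by = 1e6)
  expect_true(all(diff(vapply(per, function(p)
    samples_per_run(400e6, p), integer(1))) <= 0))
})

test_that("cohort frequencies count each case once per gene and class", {
  cases <- data.frame(case_id = sprintf("b%02d", 1:14),
                      tumor_type = "breast")
  alts <- data.frame(case_id = c(sprintf("b%02d", 1:5), "b01"),
                     gene = "PIK3CA", class = "SNV")  # b01 twice
  fr <- cohort_frequencies(cases, alts)
  expect_equal(fr$n_affected, 5L)
  expect_equal(fr$pct, 35.71)

  mel <- data.frame(case_id = sprintf("m%02d", 1:19),
                    tumor_type = "melanoma")
  mel_alts <- data.frame(case_id = sprintf("m%02d", 1:10), gene = "BRAF",
                         class = "SNV")
  expect_equal(cohort_frequencies(mel, mel_alts)$pct, 52.63)

  # reference comparison fills unobserved combinations with 0%
  ref <- data.frame(tumor_type = "breast", gene = c("PIK3CA", "TP53"),
                    class = "SNV", reference_pct = c(34.35, 36.47))
  fr2 <- cohort_frequencies(cases, alts, reference = ref)
  tp53 <- fr2[fr2$gene == "TP53", ]
  expect_equal(tp53$pct, 0)
  expect_equal(tp53$delta_pct, -36.47)
  expect_equal(fr2$delta_pct[fr2$gene == "PIK3CA"], 35.71 - 34.35)
  expect_error(cohort_frequencies(cases[0, ], alts), "empty")
})
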
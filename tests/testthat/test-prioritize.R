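test_that("deprioritization rules fire on the printed boundaries", {
  v <- rbind(
    make_variant(pos = 1L, vaf = 0.04, depth = 300),             # LOW_VAF
    make_variant(pos = 2L, vaf = 0.30, depth = 20),              # LOW_DEPTH at equality
    make_variant(pos = 3L, vaf = 0.30, depth = 21,
                 popmax_af = 0.02, effect = "synonymous"),       # two rules
    make_variant(pos = 4L, vaf = 0.051, depth = 150)             # clean
  )
  f <- apply_filters(v)
  expect_equal(f$priority, c("deprioritized", "deprioritized",
                             "deprioritized", "prioritized"))
  expect_equal(f$deprioritization_reasons[1], "LOW_VAF")
  expect_equal(f$deprioritization_reasons[2], "LOW_DEPTH")
  expect_setequal(strsplit(f$deprioritization_reasons[3], ";")[[1]],
                  c("POP_FREQUENT", "BENIGN_EFFECT"))
  expect_equal(f$deprioritization_reasons[4], "")

  # VAF boundary inclusive: 0.05 fires, 0.051 does not
  expect_equal(apply_filters(make_variant(vaf = 0.05))$priority,
               "deprioritized")
  # popmax boundary inclusive at 0.02; missing popmax never fires
  expect_equal(apply_filters(make_variant(popmax_af = 0.02))$priority,
               "deprioritized")
  expect_equal(apply_filters(make_variant(popmax_af = NA_real_))$priority,
               "prioritized")
  # internal database evidence
  expect_equal(
    apply_filters(make_variant(internal_db_status = "artifact")
                  )$deprioritization_reasons, "DB_ARTIFACT")
  expect_equal(
    apply_filters(make_variant(internal_db_status = "benign")
                  )$deprioritization_reasons, "DB_BENIGN")
})

test_that("filtering is idempotent, order-independent and flag-only", {
  set.seed(9)
  v <- make_variants(50)
  v$vaf <- round(runif(50, 0, 0.2), 3)
  v$depth <- sample(5:300, 50, replace = TRUE)
  v$popmax_af <- ifelse(runif(50) < 0.3, round(runif(50), 3), NA)
  v$effect <- sample(c("missense", "synonymous", "intronic_nonsplicing"),
                     50, replace = TRUE)
  f1 <- apply_filters(v)
  expect_equal(apply_filters(f1), f1)               # idempotent
  perm <- sample(nrow(v))
  f2 <- apply_filters(v[perm, ])
  expect_equal(f2$priority, f1$priority[perm])      # order-independent
  expect_equal(nrow(f1), nrow(v))                   # nothing deleted
  # bijection: deprioritized iff reasons non-empty
  expect_equal(f1$priority == "deprioritized",
               nzchar(f1$deprioritization_reasons))
})

test_that("tightening thresholds never rescues a deprioritized variant", {
  set.seed(10)
  v <- make_variants(80)
  v$vaf <- round(runif(80, 0, 0.15), 3)
  v$depth <- sample(5:100, 80, replace = TRUE)
  v$popmax_af <- ifelse(runif(80) < 0.5, round(runif(80, 0, 0.05), 4), NA)
  base <- apply_filters(v, filter_config())
  tighter <- apply_filters(v, filter_config(min_depth_exclusive = 30,
                                            max_vaf_exclusive = 0.08,
                                            popmax_benign_af = 0.01))
  was_dep <- base$priority == "deprioritized"
  expect_true(all(tighter$priority[was_dep] == "deprioritized"))
})

test_that("tier assignment matches gene, hotspot and tumor type", {
  kb <- oncopanel_kb()
  braf <- make_variant(gene = "BRAF", functional_class = "pathogenic",
                       protein_change = "V600E")
  expect_equal(assign_tiers(braf, "melanoma", kb),
               data.frame(category = "T", level = "I"))
  # hotspot prefix: G12 covers G12D
  kras <- make_variant(gene = "KRAS", functional_class = "pathogenic",
                       protein_change = "G12D")
  expect_equal(assign_tiers(kras, "colorectal", kb),
               data.frame(category = "R", level = "I"))
  # same alteration, different tumor type, different implication
  expect_equal(assign_tiers(kras, "pancreatic", kb)$category, c("D", "P"))
  # VUS never receives tiers
  vus <- make_variant(gene = "BRAF", functional_class = "VUS",
                      protein_change = "V600E")
  expect_equal(nrow(assign_tiers(vus, "melanoma", kb)), 0L)
  # wrong tumor type: no match
  expect_equal(nrow(assign_tiers(braf, "lung", kb)), 0L)
  # duplicate categories collapse to the best level
  kb2 <- data.frame(gene = "BRAF", match_kind = "hotspot_aa",
                    match_value = "V600", tumor_type = "any",
                    tiers = c("T:II", "T:I"))
  expect_equal(assign_tiers(braf, "melanoma", kb2),
               data.frame(category = "T", level = "I"))
})

test_that("malformed knowledge rows are rejected at load time", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tmatch_kind\tmatch_value\ttumor_type\ttiers",
               "BRAF\thotspot_aa\tV600E\tmelanoma\tT:I",
               "KRAS\thotspot_aa\tG12\tcolorectal\tZ:9"), f)
  expect_error(read_knowledge_base(f), "row 2")
})

test_that("PGx positions are each reported once with banded genotypes", {
  defs <- oncopanel_pgx()
  expect_equal(nrow(defs), 10L)
  v <- rbind(
    make_variant(chrom = defs$chrom[1], pos = defs$pos[1],
                 ref = defs$ref[1], alt = defs$alt[1], vaf = 0.48),
    make_variant(chrom = defs$chrom[2], pos = defs$pos[2],
                 ref = defs$ref[2], alt = defs$alt[2], vaf = 1.00),
    make_variant(chrom = defs$chrom[3], pos = defs$pos[3],
                 ref = defs$ref[3], alt = defs$alt[3], vaf = 0.05)
  )
  cov <- data.frame(chrom = defs$chrom[4], pos = defs$pos[4], depth = 80)
  g <- pgx_genotypes(v, defs, coverage = cov)
  expect_equal(nrow(g), 10L)
  expect_equal(g$genotype[1], "ref/alt")
  expect_equal(g$genotype[2], "alt/alt")
  expect_equal(g$genotype[3], "ref/ref")   # below het band
  expect_equal(g$genotype[4], "ref/ref")   # absent but covered
  expect_true(all(g$genotype[5:10] == "no_call"))  # no evidence

  bad <- defs[1:9, ]
  expect_error(pgx_genotypes(v, bad), "exactly 10")
})

test_that("case summaries flag pathogenic-positive and actionable cases", {
  kb <- oncopanel_kb()
  vus_case <- summarize_case(make_variant(functional_class = "VUS"),
                             tumor_type = "melanoma", kb = kb)
  expect_false(vus_case$pathogenic_positive)
  expect_false(vus_case$actionable)

  braf_case <- summarize_case(
    make_variant(gene = "BRAF", functional_class = "pathogenic",
                 protein_change = "V600E"),
    tumor_type = "melanoma", kb = kb)
  expect_true(braf_case$pathogenic_positive)
  expect_true(braf_case$actionable)
  expect_equal(braf_case$tiers, data.frame(category = "T", level = "I"))

  # a deprioritized pathogenic variant does not make a case positive
  dep_case <- summarize_case(
    apply_filters(make_variant(gene = "BRAF",
                               functional_class = "pathogenic",
                               protein_change = "V600E", vaf = 0.01)),
    tumor_type = "melanoma", kb = kb)
  expect_false(dep_case$pathogenic_positive)

  # fusion and MSI-H knowledge entries confer actionability
  fus_case <- summarize_case(
    make_variant(functional_class = "VUS"),
    fusions = data.frame(name = "EML4-ALK"),
    tumor_type = "lung", kb = kb)
  expect_true(fus_case$actionable)
  expect_equal(sort(fus_case$tiers$category), c("R", "T"))
})

test_that("cohort rates equal hand-computed ratios", {
  kb <- oncopanel_kb()
  path_case <- function() summarize_case(
    make_variant(functional_class = "pathogenic"), tumor_type = "other",
    kb = kb)
  act_case <- function() summarize_case(
    make_variant(gene = "BRAF", functional_class = "pathogenic",
                 protein_change = "V600E"), tumor_type = "melanoma",
    kb = kb)
  vus_case <- function() summarize_case(
    make_variant(functional_class = "VUS"), tumor_type = "other", kb = kb)
  cohort <- c(replicate(86, act_case(), simplify = FALSE),
              replicate(15, path_case(), simplify = FALSE),
              replicate(3, vus_case(), simplify = FALSE))
  r <- cohort_rates(cohort)
  expect_equal(r$n_cases, 104L)
  expect_equal(r$n_pathogenic_positive, 101L)
  expect_equal(r$n_actionable, 86L)
  expect_equal(round(r$pathogenic_positive_pct), 97)
  expect_equal(round(r$actionable_pct, 1), 82.7)
})
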
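#' Variant deprioritization rule configuration
#'
#' Boundary semantics follow the printed operators literally: a variant is
#' deprioritized when depth <= `min_depth_exclusive`, VAF <=
#' `max_vaf_exclusive`, or population AF >= `popmax_benign_af` — all
#' inclusive at the boundary. A missing population AF never fires the
#' population rule.
#'
#' @param min_depth_exclusive Deprioritize when depth <= this (default 20).
#' @param max_vaf_exclusive Deprioritize when VAF <= this (default 0.05).
#' @param popmax_benign_af Deprioritize when population AF >= this
#'   (default 0.02).
#' @param benign_effects Effects treated as likely benign (default
#'   synonymous and non-splicing intronic).
#' @param honor_internal_db Fire DB_ARTIFACT/DB_BENIGN on internal-database
#'   status (default TRUE).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth_exclusive = 20,
                          max_vaf_exclusive = 0.05,
                          popmax_benign_af = 0.02,
                          benign_effects = c("synonymous",
                                             "intronic_nonsplicing"),
                          honor_internal_db = TRUE) {
  stopifnot(min_depth_exclusive >= 0, max_vaf_exclusive >= 0,
            max_vaf_exclusive <= 1, popmax_benign_af >= 0,
            popmax_benign_af <= 1,
            all(benign_effects %in% variant_effects))
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 max_vaf_exclusive = max_vaf_exclusive,
                 popmax_benign_af = popmax_benign_af,
                 benign_effects = benign_effects,
                 honor_internal_db = honor_internal_db),
            class = "filter_config")
}

#' Apply deprioritization rules to a variant table
#'
#' Flags (never deletes) variants failing quality or benignity rules, so
#' the full call set survives for manual review. A record is deprioritized
#' iff at least one rule fires; every firing rule id is recorded in
#' `deprioritization_reasons` (semicolon-joined). Rule ids: `LOW_DEPTH`
#' (depth <= 20), `LOW_VAF` (VAF <= 0.05), `DB_ARTIFACT` / `DB_BENIGN`
#' (internal database), `POP_FREQUENT` (population AF >= 0.02),
#' `BENIGN_EFFECT` (synonymous / non-splicing intronic). Evaluation order
#' never affects the outcome, and the function is idempotent.
#'
#' @param variants Variant table from [read_variants()].
#' @param cfg [filter_config()].
#' @return The same table with `priority` and `deprioritization_reasons`
#'   set.
#' @export
apply_filters <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0L) return(variants)
  reasons <- vector("list", nrow(variants))
  add <- function(hit, id) {
    hit[is.na(hit)] <- FALSE
    for (i in which(hit)) reasons[[i]] <<- c(reasons[[i]], id)
  }
  add(variants$depth <= cfg$min_depth_exclusive, "LOW_DEPTH")
  add(variants$vaf <= cfg$max_vaf_exclusive, "LOW_VAF")
  if (isTRUE(cfg$honor_internal_db)) {
    add(variants$internal_db_status == "artifact", "DB_ARTIFACT")
    add(variants$internal_db_status == "benign", "DB_BENIGN")
  }
  add(!is.na(variants$popmax_af) &
        variants$popmax_af >= cfg$popmax_benign_af, "POP_FREQUENT")
  add(variants$effect %in% cfg$benign_effects, "BENIGN_EFFECT")
  variants$deprioritization_reasons <- vapply(
    reasons, function(r) paste(r, collapse = ";"), character(1))
  variants$priority <- ifelse(
    nzchar(variants$deprioritization_reasons), "deprioritized",
    "prioritized")
  variants
}

tier_categories <- c("T", "D", "P", "R")
tier_levels <- c("I", "II")

#' Parse / format tier annotation strings
#'
#' Tier annotations travel as compact strings like `"T:I;P:II"` (category
#' in T/D/P/R, level I or II).
#'
#' @param s A single tier string (may be empty).
#' @return `parse_tiers()`: data.frame `(category, level)`;
#'   `format_tiers()`: the compact string.
#' @export
parse_tiers <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(category = character(), level = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  out <- data.frame(category = vapply(parts, `[`, character(1), 1L),
                    level = vapply(parts, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  if (!all(out$category %in% tier_categories) ||
      !all(out$level %in% tier_levels)) {
    stop("malformed tier string: ", s)
  }
  out
}

#' @rdname parse_tiers
#' @param tiers data.frame `(category, level)`.
#' @export
format_tiers <- function(tiers) {
  if (nrow(tiers) == 0L) return("")
  paste(paste(tiers$category, tiers$level, sep = ":"), collapse = ";")
}

#' Read the actionability knowledge table
#'
#' TSV columns: `gene`, `match_kind` (`hotspot_aa`, `exon_region`,
#' `gene_level`, `fusion`, `msi_status`), `match_value`, `tumor_type`
#' (or `any`), `tiers` (e.g. `"T:I;P:II"`).
#'
#' @param path TSV path.
#' @return A validated data.frame.
#' @export
read_knowledge_base <- function(path) {
  kb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene", "match_kind", "match_value", "tumor_type", "tiers")
  if (!all(need %in% names(kb))) {
    stop("knowledge table must have columns: ",
         paste(need, collapse = ", "))
  }
  kinds <- c("hotspot_aa", "exon_region", "gene_level", "fusion",
             "msi_status")
  for (i in seq_len(nrow(kb))) {
    if (!kb$match_kind[i] %in% kinds) {
      stop("knowledge table row ", i, ": unknown match_kind '",
           kb$match_kind[i], "'")
    }
    t <- tryCatch(parse_tiers(kb$tiers[i]), error = function(e) NULL)
    if (is.null(t) || nrow(t) == 0L) {
      stop("knowledge table row ", i, ": malformed or empty tiers '",
           kb$tiers[i], "'")
    }
  }
  kb
}

#' The packaged actionability knowledge table
#'
#' Seeded with guideline-backed (level I) and literature-backed (level II)
#' associations across therapy/diagnosis/prognosis/resistance for the
#' panel's headline alterations (BRAF V600E/K, KRAS G12, EGFR exon 19 del,
#' EML4-ALK, NCOA4-RET, BRCA2 loss, NRAS G13/Q61, KIT L576P, PIK3CA
#' hotspots, MSI-H). Editable: users extend the TSV.
#'
#' @return A data.frame knowledge table.
#' @export
oncopanel_kb <- function() {
  read_knowledge_base(system.file("extdata", "kb.tsv",
                                  package = "oncopanel"))
}

# best (lowest) level per category
collapse_tiers <- function(tiers) {
  if (nrow(tiers) == 0L) return(tiers)
  tiers$rank <- match(tiers$level, tier_levels)
  keep <- stats::aggregate(rank ~ category, tiers, min)
  out <- merge(keep, unique(tiers), by = c("category", "rank"))
  out <- out[order(match(out$category, tier_categories)),
             c("category", "level")]
  rownames(out) <- NULL
  out
}

#' Assign clinical tier annotations to one variant
#'
#' Only pathogenic / likely pathogenic variants receive tiers; everything
#' else returns an empty annotation. Knowledge entries match on gene plus
#' tumor type (`"any"` matches every tumor type) plus kind-specific value:
#' `hotspot_aa` matches when the variant's protein change starts with the
#' entry's value (so `G12` covers `G12D`, `G12V`, ...); `exon_region`
#' matches an optional `region` field on the variant; `gene_level` matches
#' any qualifying variant in the gene. Duplicate categories collapse to the
#' best (lowest) level.
#'
#' @param variant One-row variant data.frame (needs `gene`,
#'   `functional_class`; `protein_change` and `region` are used when
#'   present).
#' @param tumor_type Tumor type of the case.
#' @param kb Knowledge table from [read_knowledge_base()].
#' @return data.frame `(category, level)` (possibly empty).
#' @export
assign_tiers <- function(variant, tumor_type, kb = oncopanel_kb()) {
  no_tiers <- data.frame(category = character(), level = character(),
                         stringsAsFactors = FALSE)
  if (!variant$functional_class %in% c("pathogenic",
                                       "likely_pathogenic")) {
    return(no_tiers)
  }
  hits <- kb[kb$gene == variant$gene &
               kb$tumor_type %in% c(tumor_type, "any") &
               kb$match_kind %in% c("hotspot_aa", "exon_region",
                                    "gene_level"), , drop = FALSE]
  if (nrow(hits) == 0L) return(no_tiers)
  pch <- if ("protein_change" %in% names(variant))
    variant$protein_change else NA_character_
  reg <- if ("region" %in% names(variant)) variant$region
         else NA_character_
  match_row <- vapply(seq_len(nrow(hits)), function(i) {
    switch(hits$match_kind[i],
      hotspot_aa = !is.na(pch) && startsWith(pch, hits$match_value[i]),
      exon_region = !is.na(reg) && reg == hits$match_value[i],
      gene_level = TRUE)
  }, logical(1))
  if (!any(match_row)) return(no_tiers)
  tiers <- do.call(rbind, lapply(hits$tiers[match_row], parse_tiers))
  collapse_tiers(tiers)
}

#' Annotate a variant table with tier strings
#'
#' Vectorized convenience over [assign_tiers()]; adds a `tiers` column of
#' compact strings.
#'
#' @param variants Variant table.
#' @param tumor_type Tumor type of the case.
#' @param kb Knowledge table.
#' @return `variants` with a `tiers` column.
#' @export
annotate_tiers <- function(variants, tumor_type, kb = oncopanel_kb()) {
  variants$tiers <- vapply(seq_len(nrow(variants)), function(i) {
    format_tiers(assign_tiers(variants[i, ], tumor_type, kb))
  }, character(1))
  variants
}

#' Read the pharmacogenetic SNP definition table
#'
#' @param path TSV with columns `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `drug`, `evidence_level`; must contain exactly 10 rows (the panel's
#'   PGx design).
#' @return A validated data.frame.
#' @export
read_pgx_defs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "ref", "alt", "drug",
            "evidence_level")
  if (!all(need %in% names(d))) {
    stop("PGx table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d) != 10L) {
    stop("PGx definition table must have exactly 10 rows (got ",
         nrow(d), ")")
  }
  d
}

#' The packaged 10-SNP pharmacogenetic panel
#'
#' A representative set of ten high-evidence (PharmGKB level <= 2A)
#' oncology pharmacogenetic SNPs (DPYD, TPMT, NUDT15, UGT1A1, GSTP1) with
#' approximate GRCh37 coordinates; the assay's exact list is proprietary,
#' so this table is a documented, editable default.
#'
#' @return A data.frame of 10 PGx SNP definitions.
#' @export
oncopanel_pgx <- function() {
  read_pgx_defs(system.file("extdata", "pgx_snps.tsv",
                            package = "oncopanel"))
}

#' Genotype the pharmacogenetic SNP panel
#'
#' Reports each of the 10 PGx positions exactly once. A position present in
#' the variant table is genotyped from its VAF: `alt/alt` when VAF >=
#' `hom_min`, `ref/alt` when `het_min` <= VAF < `hom_min`, `ref/ref`
#' below `het_min`. A position absent from the variants but covered to at
#' least `min_depth` in the supplied coverage evidence is `ref/ref`;
#' absent without coverage evidence it is `no_call`.
#'
#' @param variants Variant table (ideally from the germline control).
#' @param defs PGx definitions from [read_pgx_defs()].
#' @param coverage Optional data.frame `(chrom, pos, depth)` of per-position
#'   depth evidence.
#' @param min_depth Minimum depth counting as coverage evidence
#'   (default 20).
#' @param het_min,hom_min VAF band edges (defaults 0.15 / 0.85).
#' @return data.frame `(rsid, drug, evidence_level, genotype, vaf)`.
#' @export
pgx_genotypes <- function(variants, defs = oncopanel_pgx(),
                          coverage = NULL, min_depth = 20,
                          het_min = 0.15, hom_min = 0.85) {
  if (nrow(defs) != 10L) {
    stop("PGx definition table must have exactly 10 rows (got ",
         nrow(defs), ")")
  }
  one <- function(i) {
    hit <- which(variants$chrom == defs$chrom[i] &
                   variants$pos == defs$pos[i] &
                   variants$ref == defs$ref[i] &
                   variants$alt == defs$alt[i])
    if (length(hit) > 0L) {
      vaf <- variants$vaf[hit[1L]]
      gt <- if (vaf >= hom_min) "alt/alt"
            else if (vaf >= het_min) "ref/alt"
            else "ref/ref"
      return(data.frame(rsid = defs$rsid[i], drug = defs$drug[i],
                        evidence_level = defs$evidence_level[i],
                        genotype = gt, vaf = vaf,
                        stringsAsFactors = FALSE))
    }
    covered <- !is.null(coverage) &&
      any(coverage$chrom == defs$chrom[i] & coverage$pos == defs$pos[i] &
            coverage$depth >= min_depth)
    data.frame(rsid = defs$rsid[i], drug = defs$drug[i],
               evidence_level = defs$evidence_level[i],
               genotype = if (covered) "ref/ref" else "no_call",
               vaf = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(defs)), one))
  rownames(out) <- NULL
  out
}

#' Summarize one patient case
#'
#' Collapses a case's prioritized variants, CNV events, MSI result, fusion
#' calls and PGx genotypes into the per-case flags the cohort analyses
#' consume: a case is pathogenic-positive when at least one prioritized
#' pathogenic / likely pathogenic finding exists, and actionable when at
#' least one finding carries a tier annotation (including fusion and MSI-H
#' knowledge entries).
#'
#' @param variants Variant table, filtered ([apply_filters()]) and tier
#'   annotated ([annotate_tiers()]); a missing `tiers` column is computed
#'   when `tumor_type` is given.
#' @param cnv_events Optional CNV event table.
#' @param msi Optional `msi_result`.
#' @param fusions Optional data.frame of externally-called fusions with a
#'   `name` column (e.g. `"EML4-ALK"`).
#' @param pgx Optional PGx genotype table.
#' @param tumor_type Tumor type (for knowledge-table matching).
#' @param kb Knowledge table.
#' @return A list of class `case_summary` with counts and flags.
#' @export
summarize_case <- function(variants, cnv_events = NULL, msi = NULL,
                           fusions = NULL, pgx = NULL, tumor_type = "any",
                           kb = oncopanel_kb()) {
  if (!"priority" %in% names(variants)) {
    variants <- apply_filters(variants)
  }
  if (!"tiers" %in% names(variants)) {
    variants <- annotate_tiers(variants, tumor_type, kb)
  }
  keep <- variants$priority == "prioritized"
  pathogenic <- keep & variants$functional_class %in%
    c("pathogenic", "likely_pathogenic")
  tier_strings <- variants$tiers[keep]

  if (!is.null(fusions) && nrow(fusions) > 0L) {
    fkb <- kb[kb$match_kind == "fusion" &
                kb$tumor_type %in% c(tumor_type, "any"), , drop = FALSE]
    for (f in fusions$name) {
      hit <- fkb$tiers[fkb$match_value == f]
      if (length(hit) > 0L) tier_strings <- c(tier_strings, hit)
    }
  }
  if (!is.null(msi) && identical(msi$msi_class, "MSI_H")) {
    mkb <- kb[kb$match_kind == "msi_status" & kb$match_value == "MSI_H" &
                kb$tumor_type %in% c(tumor_type, "any"), , drop = FALSE]
    if (nrow(mkb) > 0L) tier_strings <- c(tier_strings, mkb$tiers)
  }
  tier_strings <- tier_strings[nzchar(tier_strings)]
  tiers <- if (length(tier_strings) > 0L) {
    collapse_tiers(do.call(rbind, lapply(tier_strings, parse_tiers)))
  } else {
    data.frame(category = character(), level = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(
    tumor_type = tumor_type,
    n_prioritized = sum(keep),
    n_pathogenic = sum(pathogenic),
    pathogenic_positive = any(pathogenic),
    n_actionable_findings = length(tier_strings),
    actionable = length(tier_strings) > 0L,
    tiers = tiers,
    n_cnv = if (is.null(cnv_events)) 0L else nrow(cnv_events),
    msi_class = if (is.null(msi)) NA_character_ else msi$msi_class,
    n_pgx_calls = if (is.null(pgx)) 0L
                  else sum(pgx$genotype != "no_call")
  ), class = "case_summary")
}

#' Cohort-level rates from case summaries
#'
#' @param summaries A list of `case_summary` objects.
#' @return A list: `n_cases`, `n_pathogenic_positive`, `n_actionable`,
#'   `pathogenic_positive_pct`, `actionable_pct` (percent of cases).
#' @export
cohort_rates <- function(summaries) {
  n <- length(summaries)
  if (n == 0L) stop("empty cohort")
  np <- sum(vapply(summaries, `[[`, logical(1), "pathogenic_positive"))
  na <- sum(vapply(summaries, `[[`, logical(1), "actionable"))
  list(n_cases = n, n_pathogenic_positive = np, n_actionable = na,
       pathogenic_positive_pct = 100 * np / n,
       actionable_pct = 100 * na / n)
}
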
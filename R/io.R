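#' Read panel target regions from a BED file
#'
#' Parses a 3--6 column BED file into the target-region table used throughout
#' the package. Coordinates stay in BED convention: 0-based, half-open
#' `[start, end)`. Columns beyond the first three are interpreted as
#' `name`, `gene` and `kind`; missing columns are filled with defaults.
#' Overlapping regions are kept as-is (no merging), and file order is
#' preserved.
#'
#' @param path Path to a BED file (plain text, tab-separated).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`, `gene`,
#'   `kind`. `kind` is one of `"on_target"`, `"off_target_bin"`,
#'   `"snp_probe"`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr7\t55241700\t55241800\tEGFR_ex19\tEGFR", bed)
#' read_targets(bed)
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_targets())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("BED line ", which(ncols < 3L)[1L], " has fewer than 3 columns")
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  }
  out <- data.frame(
    chrom = get_col(1L),
    start = suppressWarnings(as.integer(get_col(2L))),
    end   = suppressWarnings(as.integer(get_col(3L))),
    name  = get_col(4L),
    gene  = get_col(5L),
    kind  = get_col(6L),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1L]
    stop("BED line ", bad, ": non-integer coordinates")
  }
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1L]
    stop("BED line ", bad, ": end must be greater than start (",
         out$chrom[bad], ":", out$start[bad], "-", out$end[bad], ")")
  }
  out$name[is.na(out$name)] <- paste0(
    out$chrom[is.na(out$name)], ":", out$start[is.na(out$name)], "-",
    out$end[is.na(out$name)])
  out$gene[is.na(out$gene)] <- ""
  out$kind[is.na(out$kind) | !nzchar(out$kind)] <- "on_target"
  valid_kinds <- c("on_target", "off_target_bin", "snp_probe")
  if (!all(out$kind %in% valid_kinds)) {
    stop("BED column 6 (kind) must be one of: ",
         paste(valid_kinds, collapse = ", "))
  }
  out
}

empty_targets <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), gene = character(), kind = character(),
             stringsAsFactors = FALSE)
}

#' Write target regions back out as BED
#'
#' @param targets Target table from [read_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  utils::write.table(
    targets[, c("chrom", "start", "end", "name", "gene", "kind")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-target mean-depth table for one sample
#'
#' The TSV must carry columns `sample_id`, `name` (target name matching the
#' panel BED) and `depth`. Every panel target must appear exactly once; the
#' returned profile is re-ordered to the panel's target order.
#'
#' @param path Path to a tab-separated coverage table with a header row.
#' @param targets Panel target table from [read_targets()].
#' @return A data.frame `(sample_id, name, depth)` aligned to `targets`.
#' @export
read_coverage <- function(path, targets) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "name", "depth")
  if (!all(need %in% names(tab))) {
    stop("coverage TSV must have columns: ", paste(need, collapse = ", "))
  }
  coverage_profile(tab$depth, targets, names = tab$name,
                   sample_id = unique(tab$sample_id)[1L])
}

#' Construct a coverage profile aligned to the panel targets
#'
#' @param depths Numeric vector of mean depths, one per target.
#' @param targets Panel target table.
#' @param names Target names paired with `depths` (defaults to panel order).
#' @param sample_id Sample identifier.
#' @return A data.frame `(sample_id, name, depth)` in panel target order.
#' @export
coverage_profile <- function(depths, targets, names = targets$name,
                             sample_id = "sample") {
  if (any(duplicated(names))) {
    stop("duplicate target in coverage table: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  missing <- setdiff(targets$name, names)
  if (length(missing) > 0L) {
    stop("coverage table missing target(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names, targets$name)
  if (length(extra) > 0L) {
    stop("coverage table has unknown target(s): ",
         paste(extra, collapse = ", "))
  }
  if (any(!is.finite(depths)) || any(depths < 0)) {
    stop("depths must be finite and >= 0")
  }
  ord <- match(targets$name, names)
  data.frame(sample_id = sample_id, name = targets$name,
             depth = as.numeric(depths[ord]), stringsAsFactors = FALSE)
}

#' Default column mapping for annotated VCFs
#'
#' Names the FORMAT/INFO fields that carry the quantities the prioritizer
#' needs. The upstream annotator is deliberately unconstrained: any VCF
#' whose fields can be mapped here is accepted.
#'
#' @param vaf_field FORMAT field holding the per-sample allele fraction.
#' @param depth_field FORMAT field holding the per-sample depth.
#' @param ad_field FORMAT field holding allelic depths (fallback VAF source:
#'   alt / (ref + alt) when `vaf_field` is absent).
#' @param sample Sample column to read genotype fields from (index or name);
#'   for tumor/normal VCFs this should be the tumor sample.
#' @param gene_info,effect_info,popmax_info,db_info INFO keys for gene
#'   symbol, protein effect, population (popmax) allele frequency, and
#'   internal-database status.
#' @param protein_info INFO key for the protein change (e.g. `V600E`),
#'   used for hotspot tier matching; optional.
#' @return A list of class `variant_config`.
#' @export
variant_config <- function(vaf_field = "AF", depth_field = "DP",
                           ad_field = "AD", sample = 1L,
                           gene_info = "GENE", effect_info = "EFFECT",
                           popmax_info = "POPAF", db_info = "DB",
                           protein_info = "PCHANGE") {
  structure(list(vaf_field = vaf_field, depth_field = depth_field,
                 ad_field = ad_field, sample = sample,
                 gene_info = gene_info, effect_info = effect_info,
                 popmax_info = popmax_info, db_info = db_info,
                 protein_info = protein_info),
            class = "variant_config")
}

variant_effects <- c("missense", "nonsense", "synonymous", "splicing",
                     "intronic_nonsplicing", "frameshift", "inframe_indel",
                     "promoter", "other")

#' Read an annotated VCF into a variant table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into one row per ALT allele.
#' Multiallelic sites are decomposed; positions stay 1-based (VCF
#' convention). VAF is taken from the configured FORMAT field of the chosen
#' sample, falling back to `AD`-derived alt/(ref+alt) when absent; the
#' source used is reported with a message. A missing population AF is kept
#' as `NA`, never coerced to 0.
#'
#' @param path Path to a VCF file.
#' @param config Column mapping from [variant_config()].
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `effect`, `vaf`, `depth`, `popmax_af`, `internal_db_status`,
#'   `functional_class`, `protein_change`, `priority`,
#'   `deprioritization_reasons`.
#' @export
read_variants <- function(path, config = variant_config()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  body <- sum(!grepl("^#", readLines(path)) & nzchar(readLines(path)))
  if (body == 0L) {
    return(empty_variants())
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    # single-record VCFs collapse to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  n_sites <- nrow(fix)

  info_get <- function(key) {
    if (is.null(key)) return(rep(NA_character_, n_sites))
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n_sites) else as.character(v)
  }
  gt_get <- function(key) {
    if (is.null(key) || nrow(vcf@gt) == 0L || ncol(vcf@gt) < 2L) {
      return(rep(NA_character_, n_sites))
    }
    m <- tryCatch(vcfR::extract.gt(vcf, element = key),
                  error = function(e) NULL)
    if (is.null(m)) return(rep(NA_character_, n_sites))
    idx <- config$sample
    if (is.character(idx)) {
      if (!idx %in% colnames(m)) stop("sample '", idx, "' not in VCF")
    } else if (idx > ncol(m)) {
      stop("sample index ", idx, " out of range for VCF with ",
           ncol(m), " sample(s)")
    }
    as.character(m[, idx])
  }

  alts_per_site <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alts_per_site)
  site_of <- rep(seq_len(n_sites), n_alt)
  alt_ix <- unlist(lapply(n_alt, seq_len))

  pick_allele <- function(values) {
    # per-site comma lists (Number=A fields): pick the entry for each ALT
    split_vals <- strsplit(values, ",", fixed = TRUE)
    vapply(seq_along(site_of), function(i) {
      v <- split_vals[[site_of[i]]]
      if (length(v) == 0L || all(is.na(v))) return(NA_character_)
      if (length(v) >= alt_ix[i]) v[[alt_ix[i]]] else v[[1L]]
    }, character(1))
  }

  raw_af <- gt_get(config$vaf_field)
  raw_dp <- gt_get(config$depth_field)
  raw_ad <- gt_get(config$ad_field)

  vaf <- suppressWarnings(as.numeric(pick_allele(raw_af)))
  vaf_source <- "FORMAT/AF"
  if (all(is.na(vaf))) {
    # fall back to allelic depths: AD = ref,alt1[,alt2...]
    ad_split <- strsplit(raw_ad, ",", fixed = TRUE)
    vaf <- vapply(seq_along(site_of), function(i) {
      ad <- suppressWarnings(as.numeric(ad_split[[site_of[i]]]))
      if (length(ad) < 2L || anyNA(ad) || sum(ad) == 0) return(NA_real_)
      ad[alt_ix[i] + 1L] / sum(ad)
    }, numeric(1))
    vaf_source <- "FORMAT/AD"
  }
  if (all(is.na(vaf))) {
    stop("cannot derive VAF: neither FORMAT/", config$vaf_field,
         " nor FORMAT/", config$ad_field, " present in ", path)
  }
  message("read_variants: VAF taken from ", vaf_source, " for ", path)

  depth <- suppressWarnings(as.numeric(raw_dp))[site_of]
  if (all(is.na(depth))) {
    stop("cannot derive depth: FORMAT/", config$depth_field,
         " missing in ", path)
  }

  effect <- info_get(config$effect_info)[site_of]
  effect[is.na(effect)] <- "other"
  if (!all(effect %in% variant_effects)) {
    bad <- setdiff(unique(effect), variant_effects)
    stop("unknown effect value(s) in INFO/", config$effect_info, ": ",
         paste(bad, collapse = ", "))
  }
  db <- info_get(config$db_info)[site_of]
  db[is.na(db)] <- "none"

  out <- data.frame(
    chrom = as.character(fix[, "CHROM"])[site_of],
    pos = as.integer(fix[, "POS"])[site_of],
    ref = as.character(fix[, "REF"])[site_of],
    alt = unlist(alts_per_site),
    gene = info_get(config$gene_info)[site_of],
    effect = effect,
    vaf = vaf,
    depth = depth,
    popmax_af = suppressWarnings(as.numeric(info_get(config$popmax_info)))[site_of],
    internal_db_status = db,
    functional_class = "unclassified",
    protein_change = info_get(config$protein_info)[site_of],
    priority = "prioritized",
    deprioritization_reasons = "",
    stringsAsFactors = FALSE
  )
  if (any(!is.na(out$vaf) & (out$vaf < 0 | out$vaf > 1))) {
    stop("VAF outside [0,1] in ", path)
  }
  out
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), effect = character(),
             vaf = numeric(), depth = numeric(), popmax_af = numeric(),
             internal_db_status = character(),
             functional_class = character(), protein_change = character(),
             priority = character(), deprioritization_reasons = character(),
             stringsAsFactors = FALSE)
}

#' Write a stage result to disk
#'
#' Tabular results (data.frames: CNV events, variant tables, coverage
#' profiles) serialize to TSV or JSON; list-shaped results (MSI results,
#' validation reports) to JSON. Round-trip stable with [read_report()].
#'
#' @param x A data.frame or list produced by a pipeline stage.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (`"tsv"` only for data.frames).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(x)) stop("tsv format requires a data.frame")
    df <- x
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (inherits(x, "msi_result")) {
      x <- list(n_valid = x$n_valid, n_unstable = x$n_unstable,
                fraction = x$instability_fraction, class = x$msi_class,
                per_marker = x$per_marker)
    } else if (!is.data.frame(x)) {
      x <- unclass(x)
    }
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Path written by [write_report()].
#' @param format `"json"` or `"tsv"`.
#' @param as_data_frame For JSON: simplify to a data.frame where possible.
#' @return The deserialized object.
#' @export
read_report <- function(path, format = c("json", "tsv"),
                        as_data_frame = TRUE) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = as_data_frame)
  }
}

#' Validate a set of pipeline input files
#'
#' Attempts to parse each file by extension (`.bed`, `.vcf`, coverage
#' `.tsv`) and reports, per file, whether it conforms and the number of
#' records read.
#'
#' @param paths Character vector of file paths.
#' @param targets Optional target table (needed to validate coverage TSVs).
#' @return A data.frame `(path, kind, ok, n_records, message)`.
#' @export
validate_inputs <- function(paths, targets = NULL) {
  one <- function(p) {
    kind <- if (grepl("\\.bed$", p)) "bed"
            else if (grepl("\\.vcf$", p)) "vcf"
            else "coverage_tsv"
    res <- tryCatch({
      n <- switch(kind,
        bed = nrow(read_targets(p)),
        vcf = nrow(suppressMessages(read_variants(p))),
        coverage_tsv = {
          if (is.null(targets)) stop("targets required for coverage TSV")
          nrow(read_coverage(p, targets))
        })
      list(ok = TRUE, n = n, msg = "")
    }, error = function(e) list(ok = FALSE, n = NA_integer_,
                                msg = conditionMessage(e)))
    data.frame(path = p, kind = kind, ok = res$ok, n_records = res$n,
               message = res$msg, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(paths, one))
}
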
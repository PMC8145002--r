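#' CNV calling thresholds
#'
#' Default log2-ratio thresholds for gain and loss detection. Calls are made
#' on strict inequalities: a target participates in a gain only when its
#' ratio is strictly greater than `gain_log2`, and in a loss only when
#' strictly below `loss_log2`.
#'
#' @param gain_log2 Gain threshold (default 0.3).
#' @param loss_log2 Loss threshold (default -0.4).
#' @return A list of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(gain_log2 = 0.3, loss_log2 = -0.4) {
  stopifnot(is.numeric(gain_log2), is.numeric(loss_log2))
  if (!(gain_log2 > 0 && loss_log2 < 0)) {
    stop("need gain_log2 > 0 > loss_log2")
  }
  structure(list(gain_log2 = gain_log2, loss_log2 = loss_log2),
            class = "cnv_thresholds")
}

#' Normalize a coverage profile against a panel of normals
#'
#' Converts per-target mean depths into log2 ratios by median-of-ratios:
#' each profile is first scaled to fractional coverage (depth divided by the
#' sample's median depth), then the sample's fractional coverage is divided
#' by the per-target median fractional coverage across the reference set.
#' Targets whose reference median fractional coverage is zero cannot be
#' normalized; they are dropped with a warning rather than emitted as NaN.
#'
#' @param sample Coverage profile data.frame `(sample_id, name, depth)` from
#'   [coverage_profile()] or [read_coverage()].
#' @param references List of at least two reference coverage profiles from
#'   diploid/normal samples, sharing the panel target set.
#' @param targets Panel target table from [read_targets()].
#' @return A data.frame `(chrom, start, end, name, log2_ratio)` in panel
#'   order, with attribute `sample_id`.
#' @export
normalize_coverage <- function(sample, references, targets) {
  if (length(references) < 2L) {
    stop("at least 2 reference profiles are required")
  }
  stopifnot(identical(sample$name, targets$name))
  for (r in references) stopifnot(identical(r$name, targets$name))
  med <- stats::median(sample$depth)
  if (med <= 0) stop("sample median depth is 0; cannot normalize")
  frac <- sample$depth / med
  ref_frac <- vapply(references, function(r) {
    m <- stats::median(r$depth)
    if (m <= 0) stop("reference '", r$sample_id[1L],
                     "' has median depth 0")
    r$depth / m
  }, numeric(nrow(targets)))
  ref_med <- apply(ref_frac, 1L, stats::median)
  keep <- ref_med > 0
  if (any(!keep)) {
    warning(sum(!keep), " target(s) dropped (reference median fractional ",
            "coverage 0): ", paste(targets$name[!keep], collapse = ", "))
  }
  out <- data.frame(
    chrom = targets$chrom[keep], start = targets$start[keep],
    end = targets$end[keep], name = targets$name[keep],
    log2_ratio = log2(frac[keep] / ref_med[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "sample_id") <- sample$sample_id[1L]
  out
}

#' Expected log2 ratio of a copy-number state at a given tumor purity
#'
#' Two-population mixture: a specimen with tumor cellularity `c` carrying
#' `CN` copies in the tumor compartment and 2 copies in the admixed normal
#' compartment has mean relative coverage `(c * CN + (1 - c) * 2) / 2`, so
#' the expected log2 ratio is `log2((c * CN + (1 - c) * 2) / 2)`. Diploid
#' regions give 0 at every purity.
#'
#' @param copy_number Total copy number in the tumor compartment (>= 0).
#' @param tumor_cellularity Tumor cell fraction in (0, 1]; non-tumor
#'   infiltration is `1 - tumor_cellularity`.
#' @return Expected log2 ratio (vectorized over both arguments).
#' @examples
#' expected_log2_ratio(4, 1)    # 1
#' expected_log2_ratio(3, 0.5)  # log2(2.5/2)
#' @export
expected_log2_ratio <- function(copy_number, tumor_cellularity) {
  if (any(tumor_cellularity <= 0) || any(tumor_cellularity > 1)) {
    stop("tumor_cellularity must be in (0, 1]")
  }
  if (any(copy_number < 0)) stop("copy_number must be >= 0")
  log2((tumor_cellularity * copy_number +
          (1 - tumor_cellularity) * 2) / 2)
}

#' Purity-corrected copy number from an observed log2 ratio
#'
#' Exact inverse of [expected_log2_ratio()]:
#' `CN = (2^(r + 1) - 2 * (1 - c)) / c`, floored at 0 (heavy losses in
#' impure samples can otherwise invert to slightly negative values).
#'
#' @param event_log2 Observed event log2 ratio.
#' @param tumor_cellularity Tumor cell fraction in (0, 1].
#' @return Estimated copy number (float, >= 0).
#' @export
estimate_copy_number <- function(event_log2, tumor_cellularity) {
  if (any(tumor_cellularity <= 0) || any(tumor_cellularity > 1)) {
    stop("tumor_cellularity must be in (0, 1]")
  }
  pmax(0, (2^(event_log2 + 1) - 2 * (1 - tumor_cellularity)) /
         tumor_cellularity)
}

sex_chroms <- c("chrX", "chrY", "X", "Y")

#' Call CNV events from a log2-ratio profile
#'
#' Forms maximal runs of adjacent same-chromosome targets whose ratios all
#' strictly exceed the gain threshold (gains) or fall strictly below the
#' loss threshold (losses). Each run becomes one event whose `event_log2`
#' is the median of the member-target ratios; the event is kept only if
#' that median itself clears the threshold. Copy number is estimated from
#' `event_log2` and the sample's tumor cellularity, and each event receives
#' a credibility score via [score_event()]. Targets sitting exactly on a
#' threshold never trigger a call. Events on chrX/chrY are called but
#' flagged `sex_chromosome = TRUE` so downstream concordance analyses can
#' exclude them.
#'
#' @param profile Log2-ratio profile from [normalize_coverage()] (rows in
#'   genomic/panel order).
#' @param tumor_cellularity Tumor cell fraction in (0, 1].
#' @param thresholds [cnv_thresholds()].
#' @return A data.frame of events: `chrom`, `start`, `end`, `direction`,
#'   `n_targets`, `size_bp`, `event_log2`, `copy_number`, `score`,
#'   `score_class`, `sex_chromosome`. Zero rows is a valid result.
#' @export
call_events <- function(profile, tumor_cellularity,
                        thresholds = cnv_thresholds()) {
  if (nrow(profile) == 0L) stop("empty log2-ratio profile")
  state <- ifelse(profile$log2_ratio > thresholds$gain_log2, "gain",
           ifelse(profile$log2_ratio < thresholds$loss_log2, "loss",
                  "neutral"))
  run_id <- cumsum(c(TRUE, state[-1L] != state[-length(state)] |
                       profile$chrom[-1L] != profile$chrom[-nrow(profile)]))
  events <- list()
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    dir <- state[idx[1L]]
    if (dir == "neutral") next
    ev_log2 <- stats::median(profile$log2_ratio[idx])
    ok <- if (dir == "gain") ev_log2 > thresholds$gain_log2
          else ev_log2 < thresholds$loss_log2
    if (!ok) next
    chrom <- profile$chrom[idx[1L]]
    start <- min(profile$start[idx]); end <- max(profile$end[idx])
    events[[length(events) + 1L]] <- data.frame(
      chrom = chrom, start = start, end = end, direction = dir,
      n_targets = length(idx), size_bp = end - start,
      event_log2 = ev_log2,
      copy_number = estimate_copy_number(ev_log2, tumor_cellularity),
      member_first = idx[1L], member_last = idx[length(idx)],
      sex_chromosome = chrom %in% sex_chroms,
      stringsAsFactors = FALSE
    )
  }
  if (length(events) == 0L) return(empty_cnv_events())
  ev <- do.call(rbind, events)
  sc <- vapply(seq_len(nrow(ev)), function(i) {
    score_event(ev[i, ], profile, thresholds, other_events = ev[-i, ])
  }, numeric(1))
  ev$score <- sc
  ev$score_class <- score_class(sc)
  ev$member_first <- ev$member_last <- NULL
  rownames(ev) <- NULL
  ev[, c("chrom", "start", "end", "direction", "n_targets", "size_bp",
         "event_log2", "copy_number", "score", "score_class",
         "sex_chromosome")]
}

empty_cnv_events <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             direction = character(), n_targets = integer(),
             size_bp = integer(), event_log2 = numeric(),
             copy_number = numeric(), score = numeric(),
             score_class = character(), sex_chromosome = logical(),
             stringsAsFactors = FALSE)
}

score_class <- function(score) {
  ifelse(score > 8, "high", ifelse(score > 4, "medium", "low"))
}

#' Credibility score of a CNV event
#'
#' Weighted combination of four ingredients, each in \[0, 1\]:
#' \describe{
#'   \item{A (weight 0.4)}{ratio magnitude: `min(|event_log2| /
#'     (2 * |threshold|), 1)` for the event's direction.}
#'   \item{B (weight 0.3)}{event size: `log10(size_bp / 500) / 3` clipped to
#'     \[0, 1\] — saturating at 0.5 Mb, zero at or below 500 bp.}
#'   \item{C (weight 0.2)}{member consistency: fraction of member targets
#'     individually clearing the threshold.}
#'   \item{D (weight 0.1)}{neighborhood: 1 when no opposite-direction event
#'     lies within 1 Mb on the same chromosome, else 0.}
#' }
#' `score = 10 * (0.4 A + 0.3 B + 0.2 C + 0.1 D)`; class `high` requires
#' score strictly greater than 8, `medium` covers (4, 8\], `low` the rest.
#' High-confidence analyses downstream exclude events with score <= 8.
#'
#' @param event One event row (as produced within [call_events()]).
#' @param profile The log2-ratio profile the event was called on.
#' @param thresholds [cnv_thresholds()].
#' @param other_events Remaining events on the sample (for ingredient D).
#' @return Numeric score in \[0, 10\].
#' @export
score_event <- function(event, profile, thresholds = cnv_thresholds(),
                        other_events = NULL) {
  members <- which(profile$chrom == event$chrom &
                     profile$start >= event$start &
                     profile$end <= event$end)
  if (length(members) == 0L) {
    stop("event does not overlap the supplied profile")
  }
  thr <- if (event$direction == "gain") thresholds$gain_log2
         else thresholds$loss_log2
  if (event$direction == "cnloh") {
    a <- min(event$baf_dev / 0.5, 1)
    c_comp <- 1
  } else {
    a <- min(abs(event$event_log2) / (2 * abs(thr)), 1)
    exceeds <- if (event$direction == "gain") {
      profile$log2_ratio[members] > thr
    } else {
      profile$log2_ratio[members] < thr
    }
    c_comp <- mean(exceeds)
  }
  b <- min(max(log10(event$size_bp / 500) / 3, 0), 1)
  d <- 1
  if (!is.null(other_events) && nrow(other_events) > 0L &&
      event$direction != "cnloh") {
    opp <- if (event$direction == "gain") "loss" else "gain"
    near <- other_events$direction == opp &
      other_events$chrom == event$chrom &
      other_events$start <= event$end + 1e6 &
      other_events$end >= event$start - 1e6
    if (any(near)) d <- 0
  }
  10 * (0.4 * a + 0.3 * b + 0.2 * c_comp + 0.1 * d)
}

#' Detect copy-neutral loss of heterozygosity from SNP B-allele fractions
#'
#' Scans genome-distributed SNP probes (restricted by the caller to SNPs
#' heterozygous in the matched control) for maximal runs of at least
#' `min_run` consecutive SNPs whose B-allele fraction deviates from 0.5 by
#' more than `baf_dev`, in regions where every overlapping target's log2
#' ratio stays within the copy-neutral band `|r| <= neutral_band`. Allele
#' imbalance over a gained or lost region is not cnLOH and is not flagged.
#'
#' @param snp_bafs data.frame `(chrom, pos, baf)` with 1-based positions,
#'   sorted by chromosome and position.
#' @param profile Log2-ratio profile from [normalize_coverage()].
#' @param min_run Minimum run length in SNPs (default 10).
#' @param baf_dev Minimum |BAF - 0.5| deviation (default 0.15).
#' @param neutral_band Maximum |log2 ratio| of overlapping targets
#'   (default 0.1).
#' @param thresholds [cnv_thresholds()] (for scoring).
#' @return A data.frame of events with `direction = "cnloh"` and
#'   `copy_number = 2`; scoring ingredient A is the mean |BAF - 0.5| / 0.5.
#' @export
detect_cnloh <- function(snp_bafs, profile, min_run = 10L, baf_dev = 0.15,
                         neutral_band = 0.1,
                         thresholds = cnv_thresholds()) {
  if (nrow(snp_bafs) == 0L) return(empty_cnv_events())
  dev <- abs(snp_bafs$baf - 0.5) > baf_dev
  run_id <- cumsum(c(TRUE, dev[-1L] != dev[-length(dev)] |
                       snp_bafs$chrom[-1L] != snp_bafs$chrom[-nrow(snp_bafs)]))
  events <- list()
  for (id in unique(run_id)) {
    idx <- which(run_id == id)
    if (!dev[idx[1L]] || length(idx) < min_run) next
    chrom <- snp_bafs$chrom[idx[1L]]
    start <- min(snp_bafs$pos[idx]) - 1L  # back to 0-based half-open
    end <- max(snp_bafs$pos[idx])
    over <- which(profile$chrom == chrom & profile$start < end &
                    profile$end > start)
    if (length(over) > 0L &&
        any(abs(profile$log2_ratio[over]) > neutral_band)) next
    mean_dev <- mean(abs(snp_bafs$baf[idx] - 0.5))
    ev <- data.frame(
      chrom = chrom, start = start, end = end, direction = "cnloh",
      n_targets = length(idx), size_bp = end - start,
      event_log2 = if (length(over) > 0L)
        stats::median(profile$log2_ratio[over]) else 0,
      copy_number = 2, baf_dev = mean_dev,
      sex_chromosome = chrom %in% sex_chroms,
      stringsAsFactors = FALSE
    )
    b <- min(max(log10(ev$size_bp / 500) / 3, 0), 1)
    a <- min(mean_dev / 0.5, 1)
    ev$score <- 10 * (0.4 * a + 0.3 * b + 0.2 * 1 + 0.1 * 1)
    ev$score_class <- score_class(ev$score)
    events[[length(events) + 1L]] <- ev
  }
  if (length(events) == 0L) return(empty_cnv_events())
  ev <- do.call(rbind, events)
  ev$baf_dev <- NULL
  rownames(ev) <- NULL
  ev[, c("chrom", "start", "end", "direction", "n_targets", "size_bp",
         "event_log2", "copy_number", "score", "score_class",
         "sex_chromosome")]
}

#' Copy-number limit of detection across non-tumor infiltration levels
#'
#' For each infiltration fraction `f` (tumor cellularity `c = 1 - f`),
#' reports the smallest integer gain copy number whose expected log2 ratio
#' strictly exceeds the gain threshold, and the largest integer copy number
#' below 2 whose expected ratio falls strictly below the loss threshold
#' (`NA` when not even a homozygous deletion would be called). At 50%
#' infiltration with the default thresholds this gives 3 copies for gains
#' and 1 copy for deletions.
#'
#' @param thresholds [cnv_thresholds()].
#' @param infiltration Numeric vector of non-tumor infiltration fractions
#'   in \[0, 1).
#' @param max_cn Upper search bound for gains (default 100).
#' @return data.frame `(infiltration, min_gain_cn, max_deletion_cn)`;
#'   `min_gain_cn` is `NA` when no CN up to `max_cn` is detectable.
#' @export
lod_curve <- function(thresholds = cnv_thresholds(),
                      infiltration = c(0, 0.25, 0.5, 0.75),
                      max_cn = 100L) {
  if (any(infiltration < 0) || any(infiltration >= 1)) {
    stop("infiltration must be in [0, 1)")
  }
  one <- function(f) {
    c_ <- 1 - f
    gains <- 3:max_cn
    hit <- gains[expected_log2_ratio(gains, c_) > thresholds$gain_log2]
    min_gain <- if (length(hit)) min(hit) else NA_integer_
    dels <- c(1L, 0L)
    hit_d <- dels[expected_log2_ratio(dels, c_) < thresholds$loss_log2]
    max_del <- if (length(hit_d)) max(hit_d) else NA_integer_
    data.frame(infiltration = f, min_gain_cn = min_gain,
               max_deletion_cn = max_del)
  }
  out <- do.call(rbind, lapply(infiltration, one))
  rownames(out) <- NULL
  out
}
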
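#' Read microsatellite marker definitions
#'
#' @param path TSV with columns `marker_id`, `chrom`, `start`, `end`,
#'   `repeat_unit`, `reference_length` (0-based half-open coordinates).
#' @return A data.frame of marker definitions.
#' @export
read_msi_markers <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "start", "end", "repeat_unit",
            "reference_length")
  if (!all(need %in% names(m))) {
    stop("marker TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(m$reference_length < 1)) stop("reference_length must be >= 1")
  m
}

#' The packaged 110-marker microsatellite panel definition
#'
#' A synthetic stand-in for the assay's proprietary marker list: 110
#' genome-distributed mono- and dinucleotide repeat loci with plausible
#' reference repeat lengths, sufficient to exercise every MSI operation.
#'
#' @return A data.frame of 110 marker definitions.
#' @export
oncopanel_msi_markers <- function() {
  read_msi_markers(system.file("extdata", "msi_markers.tsv",
                               package = "oncopanel"))
}

#' Read per-marker repeat-length read histograms for one sample
#'
#' @param path TSV with columns `sample_id`, `marker_id`, `repeat_length`,
#'   `read_count`.
#' @return A data.frame (long format) of marker histograms.
#' @export
read_marker_histograms <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "marker_id", "repeat_length", "read_count")
  if (!all(need %in% names(h))) {
    stop("histogram TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(h$read_count < 0) || any(h$repeat_length < 0)) {
    stop("repeat_length and read_count must be >= 0")
  }
  h
}

# normalized length distribution of one marker's histogram rows
normalize_hist <- function(lengths, counts) {
  total <- sum(counts)
  if (total <= 0) return(NULL)
  tapply(counts, lengths, sum) / total
}

# total-variation distance between two named probability vectors
tv_distance <- function(p, q) {
  lens <- union(names(p), names(q))
  pv <- ifelse(lens %in% names(p), p[lens], 0)
  qv <- ifelse(lens %in% names(q), q[lens], 0)
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  sum(abs(pv - qv)) / 2
}

#' Build a per-marker stability baseline from MSS reference samples
#'
#' For each marker, the baseline length distribution is the mean of the
#' normalized reference histograms, and the marker's instability threshold
#' is the largest deviation statistic (total-variation distance to the
#' baseline) observed among the reference samples themselves, plus a safety
#' margin, capped at 1. A marker in a test sample is later called unstable
#' only when it deviates from the baseline more than any stable reference
#' did, by more than the margin.
#'
#' @param references Named list (>= 3) of per-sample histogram data.frames
#'   as returned by [read_marker_histograms()].
#' @param margin Safety margin added to the per-marker maximum reference
#'   deviation (default 0.05).
#' @param min_coverage Coverage every reference marker must reach
#'   (default 30).
#' @return A list of class `msi_baseline`: `distributions` (named list of
#'   `(repeat_length, prob)` data.frames), `thresholds` (named numeric),
#'   `n_reference_samples`, `margin`.
#' @export
build_baseline <- function(references, margin = 0.05, min_coverage = 30L) {
  if (length(references) < 3L) {
    stop("at least 3 MSS reference samples are required (got ",
         length(references), ")")
  }
  markers <- unique(references[[1L]]$marker_id)
  per_ref <- lapply(references, function(h) {
    split(h, h$marker_id)
  })
  dists <- list(); thresholds <- numeric(0)
  for (m in markers) {
    ref_dists <- lapply(seq_along(per_ref), function(i) {
      rows <- per_ref[[i]][[m]]
      if (is.null(rows)) {
        stop("marker '", m, "' missing from reference sample ",
             if (!is.null(names(references))) names(references)[i] else i)
      }
      if (sum(rows$read_count) < min_coverage) {
        stop("marker '", m, "' under-covered (",
             sum(rows$read_count), " < ", min_coverage,
             ") in reference sample ", i)
      }
      normalize_hist(rows$repeat_length, rows$read_count)
    })
    lens <- sort(unique(unlist(lapply(ref_dists, names))))
    mat <- vapply(ref_dists, function(d) {
      v <- rep(0, length(lens)); names(v) <- lens
      v[names(d)] <- d
      v
    }, numeric(length(lens)))
    mat <- matrix(mat, nrow = length(lens), dimnames = list(lens, NULL))
    base <- rowMeans(mat)
    max_dev <- max(vapply(seq_len(ncol(mat)), function(j) {
      sum(abs(mat[, j] - base)) / 2
    }, numeric(1)))
    dists[[m]] <- data.frame(repeat_length = as.integer(lens),
                             prob = as.numeric(base))
    thresholds[m] <- min(max_dev + margin, 1)
  }
  structure(list(distributions = dists, thresholds = thresholds,
                 n_reference_samples = length(references),
                 margin = margin),
            class = "msi_baseline")
}

#' Serialize / restore an MSI baseline as JSON
#'
#' @param baseline An `msi_baseline` from [build_baseline()].
#' @param path Output path.
#' @return `path` invisibly; `read_msi_baseline()` returns the baseline.
#' @export
write_msi_baseline <- function(baseline, path) {
  x <- unclass(baseline)
  x$thresholds <- as.list(x$thresholds)  # keep marker names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_msi_baseline
#' @export
read_msi_baseline <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  b$distributions <- lapply(b$distributions, as.data.frame)
  b$thresholds <- unlist(b$thresholds)
  structure(b, class = "msi_baseline")
}

#' Evaluate one marker's stability against the baseline
#'
#' The deviation statistic is the total-variation distance between the
#' observed normalized length distribution and the marker's baseline
#' distribution (bounded in \[0, 1\], 0 for identical distributions). The
#' marker is valid only when its coverage reaches `min_coverage`; invalid
#' markers are never unstable and are excluded from instability-fraction
#' denominators.
#'
#' @param observed Histogram rows for one marker: data.frame with
#'   `marker_id`, `repeat_length`, `read_count`.
#' @param baseline [build_baseline()] result.
#' @param min_coverage Validity coverage threshold (default 30 reads).
#' @return A list `(marker_id, coverage, valid, statistic, unstable)`.
#' @export
marker_stability <- function(observed, baseline, min_coverage = 30L) {
  m <- unique(observed$marker_id)
  stopifnot(length(m) == 1L)
  if (!m %in% names(baseline$distributions)) {
    stop("unknown marker_id: ", m)
  }
  coverage <- sum(observed$read_count)
  valid <- coverage >= min_coverage
  statistic <- NA_real_
  unstable <- FALSE
  if (coverage > 0) {
    obs <- normalize_hist(observed$repeat_length, observed$read_count)
    ref <- baseline$distributions[[m]]
    refv <- ref$prob; names(refv) <- ref$repeat_length
    statistic <- tv_distance(obs, refv)
    unstable <- valid && statistic > baseline$thresholds[[m]]
  }
  list(marker_id = m, coverage = coverage, valid = valid,
       statistic = statistic, unstable = unstable)
}

#' Instability fraction over valid markers
#'
#' The proportion of unstable markers among valid markers. The exact
#' rational is preserved in attributes `n_unstable` and `n_valid`.
#'
#' @param calls Per-marker call table with logical columns `valid` and
#'   `unstable` (from [call_msi()]).
#' @return The fraction as a numeric scalar with attributes `n_unstable`
#'   and `n_valid`.
#' @export
instability_fraction <- function(calls) {
  n_valid <- sum(calls$valid)
  if (n_valid == 0L) stop("no valid markers; fraction undefined")
  n_unstable <- sum(calls$unstable & calls$valid)
  structure(n_unstable / n_valid, n_unstable = n_unstable,
            n_valid = n_valid)
}

#' Classify MSI status from the instability fraction
#'
#' Band boundaries (inclusive lower bounds, half-open above):
#' MSS \[0, 0.18), inconclusive \[0.18, 0.21), MSI-L \[0.21, 0.31),
#' MSI-H \[0.31, 1\]. A sample with fewer than `min_valid` valid markers
#' (default 99) gets no call regardless of its fraction.
#'
#' @param fraction Instability fraction(s) in \[0, 1\].
#' @param n_valid Number of valid markers (recycled against `fraction`).
#' @param min_valid Minimum valid markers for a classification (default 99).
#' @return Character vector: `"MSS"`, `"inconclusive"`, `"MSI_L"`,
#'   `"MSI_H"` or `"no_call"`.
#' @export
classify_msi <- function(fraction, n_valid, min_valid = 99L) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    stop("fraction must be in [0, 1]")
  }
  n <- max(length(fraction), length(n_valid))
  fraction <- rep_len(fraction, n); n_valid <- rep_len(n_valid, n)
  out <- ifelse(n_valid < min_valid, "no_call",
         ifelse(fraction < 0.18, "MSS",
         ifelse(fraction < 0.21, "inconclusive",
         ifelse(fraction < 0.31, "MSI_L", "MSI_H"))))
  out
}

#' Call MSI status for one sample
#'
#' Runs [marker_stability()] on every baseline marker present in the
#' sample, computes the instability fraction over valid markers, and
#' classifies the sample.
#'
#' @param sample Histogram data.frame for one sample
#'   ([read_marker_histograms()] layout).
#' @param baseline [build_baseline()] result.
#' @param min_coverage Marker validity threshold (default 30 reads).
#' @param min_valid Minimum valid markers for a classification (default 99).
#' @return A list of class `msi_result`: `per_marker` (data.frame),
#'   `n_valid`, `n_unstable`, `instability_fraction`, `msi_class`.
#' @export
call_msi <- function(sample, baseline, min_coverage = 30L,
                     min_valid = 99L) {
  by_marker <- split(sample, sample$marker_id)
  unknown <- setdiff(names(by_marker), names(baseline$distributions))
  if (length(unknown) > 0L) {
    stop("unknown marker_id: ", paste(unknown, collapse = ", "))
  }
  calls <- do.call(rbind, lapply(by_marker, function(rows) {
    s <- marker_stability(rows, baseline, min_coverage)
    data.frame(marker_id = s$marker_id, coverage = s$coverage,
               valid = s$valid, statistic = s$statistic,
               unstable = s$unstable, stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  n_valid <- sum(calls$valid)
  n_unstable <- sum(calls$unstable & calls$valid)
  frac <- if (n_valid > 0L) n_unstable / n_valid else NA_real_
  cls <- if (n_valid == 0L) "no_call" else
    classify_msi(frac, n_valid, min_valid)
  structure(list(per_marker = calls, n_valid = n_valid,
                 n_unstable = n_unstable, instability_fraction = frac,
                 msi_class = cls),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat("MSI result: class", x$msi_class, "\n")
  cat("  valid markers:   ", x$n_valid, "\n")
  cat("  unstable markers:", x$n_unstable, "\n")
  cat("  instability fraction:",
      if (is.na(x$instability_fraction)) "NA"
      else sprintf("%.4f (%d/%d)", x$instability_fraction, x$n_unstable,
                   x$n_valid), "\n")
  invisible(x)
}
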
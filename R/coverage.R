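#' Per-base depth over the panel targets
#'
#' Full depth accounting (including zero-depth bases) for every target
#' interval, computed from an alignment table.
#'
#' @param alignments alignment data frame from [align_reads()].
#' @param panel an [amplicon_panel()].
#' @return Object of class `depth_profile`: list with `intervals` (the
#'   target intervals) and `depth` (one integer vector per interval).
#' @export
depth_profile <- function(alignments, panel) {
  full <- pileup_full(alignments, panel)
  targets <- full$targets
  depth <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    sel <- full$columns$chrom == t$chrom &
      full$columns$pos >= t$start & full$columns$pos < t$end
    full$columns$depth[sel]
  })
  structure(list(intervals = targets, depth = depth),
            class = "depth_profile")
}

#' Low-coverage regions
#'
#' Maximal runs of consecutive target bases whose depth is strictly below
#' the threshold, reported as 0-based half-open intervals. Such regions
#' need re-sequencing by another technique when complete target coverage
#' is required.
#'
#' @param profile a [depth_profile()].
#' @param threshold minimum acceptable depth (default 30).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
low_coverage_regions <- function(profile, threshold = 30L) {
  stopifnot(threshold >= 0L)
  out <- lapply(seq_len(nrow(profile$intervals)), function(i) {
    t <- profile$intervals[i, ]
    low <- profile$depth[[i]] < threshold
    if (!any(low)) return(NULL)
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values
    data.frame(chrom = t$chrom, start = t$start + starts[sel],
               end = t$start + ends[sel], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based
#'   half-open, which is the BED convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  con <- open_out(path)
  on.exit(close(con))
  if (nrow(intervals) > 0L) {
    writeLines(paste(intervals$chrom, intervals$start, intervals$end,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Per-sample input statistics
#'
#' Read count, mean base quality and uncovered-region count for a sample,
#' as consumed by [qc_gate()].
#'
#' @param sample_id sample name.
#' @param pairs read-pair data frame.
#' @param profile optional [depth_profile()] for the uncovered-region
#'   count.
#' @param threshold depth threshold for "uncovered".
#' @return One-row data frame: `sample_id`, `total_reads`,
#'   `mean_base_quality`, `uncovered_region_count`.
#' @export
sample_stats <- function(sample_id, pairs, profile = NULL,
                         threshold = 30L) {
  uncovered <- if (is.null(profile)) {
    NA_integer_
  } else {
    nrow(low_coverage_regions(profile, threshold))
  }
  data.frame(
    sample_id = sample_id,
    total_reads = 2L * nrow(pairs),
    mean_base_quality = mean_phred(c(pairs$qual1, pairs$qual2)),
    uncovered_region_count = uncovered,
    stringsAsFactors = FALSE)
}

#' Sample quality-control gate
#'
#' The reference quality and read count are the means over the best 20 %
#' of samples (fewest uncovered regions, ties broken by sample id,
#' `ceiling(0.2 n)` samples). A sample is excluded when its mean base
#' quality is lower than `quality_frac` of the reference quality or its
#' total read count is lower than `reads_frac` of the reference count.
#' The thresholds are read literally as fractions *of* the reference
#' (`interpretation = "of_reference"`); the alternative reading — a drop
#' *below* the reference by that fraction — is available as
#' `"below_reference"`.
#'
#' @param stats data frame of [sample_stats()] rows.
#' @param quality_frac quality threshold fraction (default 0.30).
#' @param reads_frac read-count threshold fraction (default 0.10).
#' @param reference_top_frac fraction of samples defining the reference
#'   (default 0.20).
#' @param interpretation threshold arithmetic, see above.
#' @return List with `included` and `excluded` (the latter with a
#'   `reason` column), plus `reference_quality` and `reference_reads`.
#' @export
qc_gate <- function(stats, quality_frac = 0.30, reads_frac = 0.10,
                    reference_top_frac = 0.20,
                    interpretation = c("of_reference", "below_reference")) {
  interpretation <- match.arg(interpretation)
  if (nrow(stats) == 0L) {
    ado_error("qc_gate needs at least one sample", "ado_qc_error")
  }
  n_ref <- ceiling(reference_top_frac * nrow(stats))
  ord <- order(stats$uncovered_region_count, stats$sample_id)
  ref <- stats[ord[seq_len(n_ref)], , drop = FALSE]
  ref_quality <- mean(ref$mean_base_quality)
  ref_reads <- mean(ref$total_reads)
  mult <- if (interpretation == "of_reference") c(quality_frac, reads_frac)
          else c(1 - quality_frac, 1 - reads_frac)
  bad_q <- stats$mean_base_quality < mult[1L] * ref_quality
  bad_r <- stats$total_reads < mult[2L] * ref_reads
  reason <- ifelse(bad_q & bad_r, "quality+reads",
                   ifelse(bad_q, "quality", ifelse(bad_r, "reads", "")))
  excluded <- stats[bad_q | bad_r, , drop = FALSE]
  excluded$reason <- reason[bad_q | bad_r]
  rownames(excluded) <- NULL
  included <- stats[!(bad_q | bad_r), , drop = FALSE]
  rownames(included) <- NULL
  list(included = included, excluded = excluded,
       reference_quality = ref_quality, reference_reads = ref_reads)
}

#' Cohort-level variant sharing
#'
#' For each distinct variant key across a cohort, the fraction of samples
#' carrying it, bucketed as `<50%` (candidate unique variants), `50-80%`
#' and `>=80%` (highly shared variants, candidate panel artifacts).
#'
#' @param sets named list of per-sample [variant_set()] objects.
#' @return List with `variants` (key columns, `n_samples`, `fraction`,
#'   `bucket`) and `summary` (bucket counts and percentages).
#' @export
cohort_sharing <- function(sets) {
  if (length(sets) == 0L) {
    ado_error("cohort_sharing needs at least one sample", "ado_qc_error")
  }
  keys <- lapply(sets, variant_key)
  all_keys <- unique(unlist(keys, use.names = FALSE))
  n <- length(sets)
  count <- vapply(all_keys, function(k) {
    sum(vapply(keys, function(kk) k %in% kk, logical(1L)))
  }, integer(1L))
  fraction <- count / n
  bucket <- ifelse(fraction >= 0.8, ">=80%",
                   ifelse(fraction >= 0.5, "50-80%", "<50%"))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  variants <- data.frame(chrom = parts[, 1L],
                         pos = as.integer(parts[, 2L]),
                         ref = parts[, 3L], alt = parts[, 4L],
                         n_samples = count, fraction = fraction,
                         bucket = bucket, stringsAsFactors = FALSE)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  lev <- c("<50%", "50-80%", ">=80%")
  tab <- table(factor(variants$bucket, levels = lev))
  summary <- data.frame(bucket = lev, n = as.integer(tab),
                        pct = if (nrow(variants) > 0L) {
                          100 * as.integer(tab) / nrow(variants)
                        } else rep(0, 3L),
                        stringsAsFactors = FALSE)
  list(variants = variants, summary = summary)
}
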
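#' Test a primer against a read prefix
#'
#' A primer matches iff the read is at least as long as the primer and the
#' Hamming distance between the primer and the read's first `len(primer)`
#' bases is at most one. No gapped comparison is ever attempted, so a
#' single-base insertion or deletion inside the primer-matching prefix
#' shifts the remaining bases and (for non-repetitive primers) fails the
#' match. `N` on either side matches anything without counting as a
#' mismatch.
#'
#' @param read_seq read sequence.
#' @param primer primer sequence (same orientation as the read prefix).
#' @return List with `matched` (logical) and `mismatches` (integer; `NA`
#'   when the read is shorter than the primer).
#' @examples
#' match_primer_prefix("ACCTTTTT", "ACGT")  # one mismatch: matched
#' match_primer_prefix("ATCATTTT", "ACGT")  # two mismatches: not matched
#' @export
match_primer_prefix <- function(read_seq, primer) {
  mm <- prefix_mismatches(read_seq, primer)
  list(matched = !is.na(mm) && mm <= 1L, mismatches = mm)
}

# mismatch matrices (pairs x amplicons) for read 1 vs ULSO, read 2 vs DLSO
assign_matrix <- function(pairs, panel) {
  amp <- panel$amplicons
  n <- nrow(pairs)
  k <- nrow(amp)
  mm1 <- matrix(NA_integer_, n, k)
  mm2 <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    mm1[, j] <- prefix_mismatches(pairs$seq1, amp$ulso[j])
    mm2[, j] <- prefix_mismatches(pairs$seq2, amp$dlso[j])
  }
  total <- mm1 + mm2
  total[is.na(total) | mm1 > 1L | mm2 > 1L] <- NA_integer_
  list(mm1 = mm1, mm2 = mm2, total = total)
}

# amplicon index per pair (NA = discard): smallest total mismatch count,
# ties broken by manifest order
assign_index <- function(total) {
  if (ncol(total) == 0L) return(rep(NA_integer_, nrow(total)))
  filled <- total
  filled[is.na(filled)] <- 1000L
  best <- max.col(-filled, ties.method = "first")
  best[filled[cbind(seq_len(nrow(total)), best)] >= 1000L] <- NA_integer_
  best
}

#' Assign a read pair to an amplicon and trim its primers
#'
#' Read 1's prefix is tested against each amplicon's ULSO and read 2's
#' against the same amplicon's DLSO; both must match (at most one mismatch
#' each, no gaps) for assignment. When several primer pairs match, the
#' assignment with the smallest total mismatch count wins, ties broken by
#' manifest order. Matched primers are trimmed off sequence and quality in
#' lockstep; unassignable pairs get a discard verdict.
#'
#' @param pair one-row data frame (or list) with `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @param panel an [amplicon_panel()].
#' @return A one-row trimmed-pair data frame (columns `id`, `amplicon_id`,
#'   `seq1`, `qual1`, `seq2`, `qual2`, `mismatches1`, `mismatches2`), or
#'   `NULL` for a discard verdict.
#' @export
assign_and_trim <- function(pair, panel) {
  pairs <- as.data.frame(pair, stringsAsFactors = FALSE)
  res <- trim_pairs(pairs, panel)
  if (res$stats$assigned_pairs == 0L) NULL else res$pairs
}

#' Trim primers from a set of read pairs
#'
#' Vectorised primer assignment and trimming for a whole read-pair table.
#' Every input pair is exactly one of assigned or discarded; output order
#' follows input order.
#'
#' @param pairs read-pair data frame (see [read_fastq_pair()]).
#' @param panel an [amplicon_panel()].
#' @return List with `pairs` (trimmed pairs, as in [assign_and_trim()]),
#'   `rejects` (the discarded input pairs) and `stats` (a `trim_stats`
#'   object: `total_pairs`, `assigned_pairs`, `discarded_pairs` and
#'   per-amplicon assigned counts).
#' @export
trim_pairs <- function(pairs, panel) {
  amp <- panel$amplicons
  mm <- assign_matrix(pairs, panel)
  idx <- assign_index(mm$total)
  keep <- !is.na(idx)
  kept <- pairs[keep, , drop = FALSE]
  ki <- idx[keep]
  ulen <- nchar(amp$ulso)[ki]
  dlen <- nchar(amp$dlso)[ki]
  trimmed <- data.frame(
    id = kept$id,
    amplicon_id = amp$amplicon_id[ki],
    seq1 = substring(kept$seq1, ulen + 1L),
    qual1 = substring(kept$qual1, ulen + 1L),
    seq2 = substring(kept$seq2, dlen + 1L),
    qual2 = substring(kept$qual2, dlen + 1L),
    mismatches1 = mm$mm1[cbind(which(keep), ki)],
    mismatches2 = mm$mm2[cbind(which(keep), ki)],
    stringsAsFactors = FALSE)
  rownames(trimmed) <- NULL
  per_amp <- table(factor(trimmed$amplicon_id, levels = amp$amplicon_id))
  stats <- structure(list(
    total_pairs = nrow(pairs),
    assigned_pairs = nrow(trimmed),
    discarded_pairs = nrow(pairs) - nrow(trimmed),
    per_amplicon = stats::setNames(as.integer(per_amp), names(per_amp))),
    class = "trim_stats")
  list(pairs = trimmed, rejects = pairs[!keep, , drop = FALSE],
       stats = stats)
}

#' Trim a FASTQ pair on disk
#'
#' File-level wrapper around [trim_pairs()]: reads a paired FASTQ, assigns
#' and trims, and optionally writes the trimmed pairs, the rejected pairs
#' and a stats TSV.
#'
#' @param fastq1,fastq2 input FASTQ paths.
#' @param panel an [amplicon_panel()].
#' @param out1,out2 optional output paths for the trimmed FASTQ pair.
#' @param rejects1,rejects2 optional output paths for discarded pairs.
#' @param stats_path optional output path for the stats TSV.
#' @return As [trim_pairs()], invisibly.
#' @export
trim_fastq <- function(fastq1, fastq2, panel, out1 = NULL, out2 = NULL,
                       rejects1 = NULL, rejects2 = NULL, stats_path = NULL) {
  pairs <- read_fastq_pair(fastq1, fastq2)
  res <- trim_pairs(pairs, panel)
  if (!is.null(out1) && !is.null(out2)) {
    write_fastq_pair(res$pairs, out1, out2)
  }
  if (!is.null(rejects1) && !is.null(rejects2)) {
    write_fastq_pair(res$rejects, rejects1, rejects2)
  }
  if (!is.null(stats_path)) write_trim_stats(res$stats, stats_path)
  invisible(res)
}

#' Write trimming statistics as TSV
#'
#' @param stats a `trim_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trim_stats <- function(stats, path) {
  df <- data.frame(
    metric = c("total_pairs", "assigned_pairs", "discarded_pairs",
               paste0("assigned_", names(stats$per_amplicon))),
    value = c(stats$total_pairs, stats$assigned_pairs,
              stats$discarded_pairs, unname(stats$per_amplicon)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.trim_stats <- function(x, ...) {
  cat(sprintf("Read pairs: %d total, %d assigned, %d discarded\n",
              x$total_pairs, x$assigned_pairs, x$discarded_pairs))
  if (length(x$per_amplicon) > 0L) {
    cat(sprintf("  %s: %d\n", names(x$per_amplicon), x$per_amplicon),
        sep = "")
  }
  invisible(x)
}
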
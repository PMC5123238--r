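#' Alignment parameters
#'
#' Scoring for the local aligner and the gap budget. The defaults (+2
#' match, -2 mismatch, -4 gap open, -1 gap extend) only matter for tie
#' cases at amplicon scale; `max_gap_fraction` caps the cumulative
#' inserted-plus-deleted length of an alignment at
#' `floor(max_gap_fraction * read_length)` — reads whose best alignment
#' needs more gap than that are reported unaligned. The default of one
#' third mirrors the vendor amplicon workflow.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores (mismatch
#'   and gap penalties must be negative).
#' @param max_gap_fraction maximum cumulative gap length as a fraction of
#'   read length, in (0, 1].
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -2, gap_open = -4,
                         gap_extend = -1, max_gap_fraction = 1 / 3) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            max_gap_fraction > 0, max_gap_fraction <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 max_gap_fraction = max_gap_fraction),
            class = "align_params")
}

OP_CODES <- c("M", "I", "D", "S")

ops_to_cigar <- function(ops, lens) {
  if (length(ops) == 0L) return("*")
  paste0(lens, OP_CODES[ops + 1L], collapse = "")
}

cigar_to_ops <- function(cigar) {
  if (cigar == "*") return(list(ops = integer(0), lens = integer(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- match(regmatches(cigar, gregexpr("[MIDS]", cigar))[[1L]],
               OP_CODES) - 1L
  list(ops = ops, lens = lens)
}

# target sequence and genomic offset of its first base for a given mode
align_target <- function(panel, amplicon_id, mode) {
  amp <- panel$amplicons
  i <- match(amplicon_id, amp$amplicon_id)
  if (is.na(i)) {
    ado_error(sprintf("unknown amplicon id '%s'", amplicon_id),
              "ado_unknown_amplicon_error")
  }
  a <- amp[i, ]
  if (mode == "trimmed") {
    list(seq = a$insert_seq, offset = a$insert_start, chrom = a$chrom,
         insert_start = a$insert_start, insert_end = a$insert_end)
  } else {
    ext <- paste0(a$ulso, a$insert_seq,
                  revcomp(a$dlso))
    list(seq = ext, offset = a$insert_start - nchar(a$ulso),
         chrom = a$chrom, insert_start = a$insert_start,
         insert_end = a$insert_end)
  }
}

# convert aligned bases falling outside the insert interval into soft
# clips (softclip mode): walk ops left to right tracking genomic position
clip_primer_ops <- function(ops, lens, ref_start, insert_start, insert_end) {
  out_ops <- integer(0)
  out_lens <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    k <- length(out_ops)
    if (k > 0L && out_ops[k] == op) {
      out_lens[k] <<- out_lens[k] + len
    } else {
      out_ops[k + 1L] <<- op
      out_lens[k + 1L] <<- len
    }
  }
  g <- ref_start
  new_start <- NA_integer_
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op == 3L || op == 1L) {        # S or I: no reference consumed
      if (op == 1L && g > insert_start && g <= insert_end &&
          !is.na(new_start)) {
        push(1L, len)                  # insertion inside the insert
      } else {
        push(3L, len)                  # primer-region insertion -> clip
      }
    } else {                           # M or D consume reference
      lo <- g; hi <- g + len
      seg_lo <- max(lo, insert_start)
      seg_hi <- min(hi, insert_end)
      if (seg_hi > seg_lo) {
        if (op == 0L) push(3L, seg_lo - lo) else NULL  # leading primer M -> S
        if (is.na(new_start)) new_start <- seg_lo
        push(op, seg_hi - seg_lo)
        if (op == 0L) push(3L, hi - seg_hi)
      } else {
        if (op == 0L) push(3L, len)    # fully in primer region
        # a D fully in the primer region consumes no read bases: drop it
      }
      g <- hi
    }
  }
  list(ops = out_ops, lens = out_lens, ref_start = new_start)
}

align_one <- function(seq, target, params) {
  sw_align_cpp(seq, target$seq, as.integer(params$match),
               as.integer(params$mismatch), as.integer(params$gap_open),
               as.integer(params$gap_extend))
}

# core single-read alignment; seq must already be in plus-strand
# orientation. Returns NULL for an unaligned verdict.
align_seq <- function(seq, target, params, mode) {
  res <- align_one(seq, target, params)
  if (res$score <= 0L || length(res$ops) == 0L) return(NULL)
  gap_total <- sum(res$lens[res$ops %in% c(1L, 2L)])
  if (gap_total > floor(params$max_gap_fraction * nchar(seq))) return(NULL)
  ops <- res$ops
  lens <- res$lens
  if (res$read_start > 0L) {
    ops <- c(3L, ops); lens <- c(res$read_start, lens)
  }
  tail_clip <- nchar(seq) - res$read_end
  if (tail_clip > 0L) {
    ops <- c(ops, 3L); lens <- c(lens, tail_clip)
  }
  ref_start <- target$offset + res$target_start
  if (mode == "softclip") {
    cl <- clip_primer_ops(ops, lens, ref_start, target$insert_start,
                          target$insert_end)
    if (is.na(cl$ref_start)) return(NULL)  # nothing left inside the insert
    ops <- cl$ops; lens <- cl$lens; ref_start <- cl$ref_start
  }
  list(ref_start = ref_start, cigar = ops_to_cigar(ops, lens),
       score = res$score)
}

#' Align one assigned read to its amplicon
#'
#' Places a read on the reference through its assigned amplicon by local
#' alignment with affine gaps. In `trimmed` mode the target is the
#' expected insert sequence; in `softclip` and `untrimmed` modes it is
#' ULSO + insert + reverse-complemented DLSO. In `softclip` mode aligned
#' bases falling on the primer footprints are converted to soft clips so
#' they are excluded from the pileup; in `untrimmed` mode primer bases
#' stay aligned and contribute to the pileup. Alignments whose cumulative
#' gap length exceeds the budget (see [align_params()]) get an unaligned
#' verdict.
#'
#' @param seq read sequence, plus-strand orientation (reverse-complement
#'   read 2 before calling; [align_reads()] does this for you).
#' @param amplicon_id assigned amplicon.
#' @param panel an [amplicon_panel()].
#' @param params an [align_params()] object.
#' @param mode one of `"trimmed"`, `"softclip"`, `"untrimmed"`.
#' @return List with `chrom`, `ref_start` (0-based genomic position of the
#'   first aligned base), `cigar` (M/I/D/S), `score`; or `NULL` if
#'   unaligned.
#' @export
align_to_amplicon <- function(seq, amplicon_id, panel,
                              params = align_params(),
                              mode = c("trimmed", "softclip", "untrimmed")) {
  mode <- match.arg(mode)
  target <- align_target(panel, amplicon_id, mode)
  res <- align_seq(seq, target, params, mode)
  if (is.null(res)) return(NULL)
  c(list(chrom = target$chrom), res)
}

#' Align a table of assigned read pairs
#'
#' Batch version of [align_to_amplicon()] over a trimmed (or merely
#' assigned) pair table. Read 2 is reverse-complemented onto the plus
#' strand before alignment. Alignments are memoised per distinct
#' (amplicon, sequence), which makes repeated simulated reads cheap.
#'
#' @param pairs trimmed-pair data frame (from [trim_pairs()]); in
#'   `softclip`/`untrimmed` mode the untrimmed sequences are expected.
#' @param panel an [amplicon_panel()].
#' @param params an [align_params()].
#' @param mode alignment mode, see [align_to_amplicon()].
#' @return List with `alignments` (data frame: `id`, `mate`,
#'   `amplicon_id`, `chrom`, `ref_start`, `cigar`, `seq`, `qual`) and
#'   `unaligned` (count of reads with an unaligned verdict).
#' @export
align_reads <- function(pairs, panel, params = align_params(),
                        mode = c("trimmed", "softclip", "untrimmed")) {
  mode <- match.arg(mode)
  n <- nrow(pairs)
  seq2p <- revcomp(pairs$seq2)
  qual2p <- vapply(pairs$qual2, function(q) {
    paste(rev(seq_chars(q)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  long <- data.frame(
    id = rep(pairs$id, 2L),
    mate = rep(c(1L, 2L), each = n),
    amplicon_id = rep(pairs$amplicon_id, 2L),
    seq = c(pairs$seq1, seq2p),
    qual = c(pairs$qual1, qual2p),
    stringsAsFactors = FALSE)
  key <- paste(long$amplicon_id, long$seq, sep = "\r")
  uniq <- !duplicated(key)
  memo <- lapply(which(uniq), function(i) {
    target <- align_target(panel, long$amplicon_id[i], mode)
    align_seq(long$seq[i], target, params, mode)
  })
  names(memo) <- key[uniq]
  hit <- memo[key]
  ok <- !vapply(hit, is.null, logical(1L))
  amp <- panel$amplicons
  chrom <- amp$chrom[match(long$amplicon_id, amp$amplicon_id)]
  alignments <- data.frame(
    id = long$id[ok],
    mate = long$mate[ok],
    amplicon_id = long$amplicon_id[ok],
    chrom = chrom[ok],
    ref_start = vapply(hit[ok], `[[`, integer(1L), "ref_start"),
    cigar = vapply(hit[ok], `[[`, character(1L), "cigar"),
    seq = long$seq[ok],
    qual = long$qual[ok],
    stringsAsFactors = FALSE)
  rownames(alignments) <- NULL
  list(alignments = alignments, unaligned = sum(!ok))
}

#' Write alignments as a SAM file
#'
#' Minimal well-formed SAM: `@HD`/`@SQ` header from the panel reference,
#' one record per aligned read, CIGAR restricted to M/I/D/S. Mate-2 reads
#' (aligned on the plus strand after reverse complementing) carry flag 16.
#'
#' @param alignments alignment data frame from [align_reads()].
#' @param panel an [amplicon_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, panel, path) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(panel$reference),
                     nchar(panel$reference)), con)
  if (nrow(alignments) > 0L) {
    writeLines(paste(alignments$id,
                     ifelse(alignments$mate == 2L, 16L, 0L),
                     alignments$chrom,
                     alignments$ref_start + 1L,
                     60L,
                     alignments$cigar,
                     "*", 0L, 0L,
                     alignments$seq,
                     alignments$qual,
                     sep = "\t"), con)
  }
  invisible(path)
}
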
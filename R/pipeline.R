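#' Variants intersecting primer footprints
#'
#' A variant affects an amplicon when its reference span intersects that
#' amplicon's upstream or downstream primer footprint (half-open
#' intersection). The span of an SNV is its base; an insertion counts
#' through its anchor base; a deletion through its deleted bases. These
#' are the variants capable of causing allele drop-out on the amplicons
#' they affect.
#'
#' @param vs a [variant_set()].
#' @param panel an [amplicon_panel()].
#' @return Data frame mapping variants to affected amplicons: the variant
#'   key columns plus `amplicon_id` and `primer` (one row per
#'   variant/footprint hit; zero rows when nothing is affected).
#' @export
variants_in_primer_regions <- function(vs, panel) {
  fp <- primer_footprints(panel)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      amplicon_id = character(0), primer = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(vs) == 0L || nrow(fp) == 0L) return(empty)
  span_start <- ifelse(vs$kind == "DEL", vs$pos + 1L, vs$pos)
  span_end <- ifelse(vs$kind == "DEL",
                     vs$pos + nchar(vs$ref),        # deleted bases
                     vs$pos + 1L)                   # SNV base / INS anchor
  hits <- lapply(seq_len(nrow(vs)), function(i) {
    j <- which(fp$chrom == vs$chrom[i] &
                 intervals_overlap(span_start[i], span_end[i],
                                   fp$start, fp$end))
    if (length(j) == 0L) return(NULL)
    data.frame(chrom = vs$chrom[i], pos = vs$pos[i], ref = vs$ref[i],
               alt = vs$alt[i], amplicon_id = fp$amplicon_id[j],
               primer = fp$primer[j], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) empty else hits
}

#' Remove read pairs of ADO-affected amplicons
#'
#' Drops every pair assigned to an amplicon whose primer footprint
#' carries a round-one variant, so the remaining (unbiased) amplicons
#' drive the second calling round.
#'
#' @param pairs trimmed-pair data frame (with `amplicon_id`).
#' @param affected character vector of affected amplicon ids.
#' @return List with `pairs` (the retained pairs) and `removed` (count).
#' @export
remove_affected_reads <- function(pairs, affected) {
  keep <- !(pairs$amplicon_id %in% affected)
  list(pairs = pairs[keep, , drop = FALSE], removed = sum(!keep))
}

resolve_dataset <- function(pairs, panel) {
  if (inherits(pairs, "ado_dataset")) {
    if (missing(panel) || is.null(panel)) panel <- pairs$fixture$panel
    pairs <- pairs$pairs
  }
  list(pairs = pairs, panel = panel)
}

#' Run the two-round ADO trimming pipeline
#'
#' Round one trims primers, aligns each pair to its assigned amplicon
#' insert, and calls variants. If any round-one variant falls in a primer
#' footprint, the pairs of every affected amplicon are removed and a
#' second round of pileup and calling is run over all target regions
#' (exactly one removal round); otherwise round two is skipped. The
#' rounds are merged with round-one precedence on key collisions.
#'
#' @param pairs read-pair data frame, or an `ado_dataset` (its panel is
#'   then used by default).
#' @param panel an [amplicon_panel()].
#' @param align_params an [align_params()].
#' @param call_params a [call_params()].
#' @return Object of class `ado_result`: `step1`, `step2`, `merged`
#'   (variant sets), `affected_amplicons`, `removed_pairs`, and `stats`
#'   (trim stats, unaligned count, per-step mean depths, uncovered-target
#'   flag when removal leaves target bases without any amplicon).
#' @export
run_two_step <- function(pairs, panel = NULL,
                         align_params = adotrim::align_params(),
                         call_params = adotrim::call_params()) {
  d <- resolve_dataset(pairs, panel)
  trim <- trim_pairs(d$pairs, d$panel)
  aln <- align_reads(trim$pairs, d$panel, align_params, mode = "trimmed")
  pile1 <- build_pileup(aln$alignments, d$panel)
  step1 <- call_variants(pile1, call_params, step = 1L, panel = d$panel)
  affected_map <- variants_in_primer_regions(step1, d$panel)
  affected <- unique(affected_map$amplicon_id)
  removed <- 0L
  step2 <- variant_set()
  depth2 <- NA_real_
  lost_target <- 0L
  if (length(affected) > 0L) {
    filtered <- remove_affected_reads(trim$pairs, affected)
    removed <- filtered$removed
    keep_ids <- filtered$pairs$id
    aln2 <- aln$alignments[aln$alignments$id %in% keep_ids, , drop = FALSE]
    pile2 <- pileup_full(aln2, d$panel)
    step2 <- call_variants(build_pileup(aln2, d$panel), call_params,
                           step = 2L, panel = d$panel)
    depth2 <- mean(pile2$columns$depth)
    lost_target <- sum(pile2$columns$depth == 0L)
  }
  merged <- merge_variant_sets(step1, step2)
  structure(list(
    step1 = step1, step2 = step2, merged = merged,
    affected_amplicons = affected,
    affected_map = affected_map,
    removed_pairs = removed,
    stats = list(trim = trim$stats, unaligned = aln$unaligned,
                 mean_depth_step1 = mean(pileup_full(aln$alignments,
                                                     d$panel)$columns$depth),
                 mean_depth_step2 = depth2,
                 uncovered_after_removal = lost_target)),
    class = "ado_result")
}

#' Run a single-round pipeline
#'
#' Three baselines against the two-round pipeline. `softclip` emulates
#' the vendor amplicon workflow: primer identification (one mismatch),
#' alignment of the raw reads to ULSO + insert + DLSO with
#' primer-overlapping bases soft-clipped out of the pileup, one calling
#' pass. `trimmed` is round one of the two-round pipeline alone.
#' `untrimmed` aligns the raw reads with primer bases contributing to the
#' pileup — the naive alignment that lets ADO-biased primer bases mask a
#' true heterozygote.
#'
#' @inheritParams run_two_step
#' @param mode `"softclip"`, `"trimmed"` or `"untrimmed"`.
#' @return A [variant_set()]; trimming/alignment statistics are attached
#'   as attribute `"stats"` and the pileup the calls were made from as
#'   attribute `"pileup"`.
#' @export
run_single_round <- function(pairs, panel = NULL,
                             align_params = adotrim::align_params(),
                             call_params = adotrim::call_params(),
                             mode = c("softclip", "trimmed", "untrimmed")) {
  mode <- match.arg(mode)
  d <- resolve_dataset(pairs, panel)
  trim <- trim_pairs(d$pairs, d$panel)
  if (mode == "trimmed") {
    assigned <- trim$pairs
  } else {
    # keep the raw sequences; trimming only provides the assignment
    raw <- d$pairs[match(trim$pairs$id, d$pairs$id), , drop = FALSE]
    assigned <- data.frame(id = trim$pairs$id,
                           amplicon_id = trim$pairs$amplicon_id,
                           seq1 = raw$seq1, qual1 = raw$qual1,
                           seq2 = raw$seq2, qual2 = raw$qual2,
                           stringsAsFactors = FALSE)
  }
  aln <- align_reads(assigned, d$panel, align_params, mode = mode)
  pile <- build_pileup(aln$alignments, d$panel)
  vs <- call_variants(pile, call_params, step = 1L, panel = d$panel)
  attr(vs, "stats") <- list(trim = trim$stats, unaligned = aln$unaligned,
                            mode = mode)
  attr(vs, "pileup") <- pile
  vs
}

#' @export
print.ado_result <- function(x, ...) {
  cat("Two-round ADO trimming pipeline result\n")
  cat(sprintf("  pairs: %d total, %d assigned, %d discarded at trimming\n",
              x$stats$trim$total_pairs, x$stats$trim$assigned_pairs,
              x$stats$trim$discarded_pairs))
  cat(sprintf("  round 1: %d variant(s); affected amplicon(s): %s\n",
              nrow(x$step1),
              if (length(x$affected_amplicons)) {
                paste(x$affected_amplicons, collapse = ", ")
              } else "none"))
  if (length(x$affected_amplicons)) {
    cat(sprintf("  round 2: removed %d pair(s); %d variant(s)\n",
                x$removed_pairs, nrow(x$step2)))
  } else {
    cat("  round 2: skipped (no primer-footprint variant)\n")
  }
  cat(sprintf("  merged: %d variant(s)\n", nrow(x$merged)))
  invisible(x)
}

#' @export
summary.ado_result <- function(object, ...) {
  cat(sprintf(
    "step1=%d step2=%d merged=%d removed_pairs=%d mean_depth1=%.1f\n",
    nrow(object$step1), nrow(object$step2), nrow(object$merged),
    object$removed_pairs, object$stats$mean_depth_step1))
  invisible(object$merged)
}
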
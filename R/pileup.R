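# Pileup construction over the panel target regions (the union of insert
# intervals). Soft-clipped bases contribute nothing; deleted reference
# bases count towards depth at the columns they span; inserted bases are
# tallied at their anchor (the base preceding the insertion point) and do
# not add depth there.

# full per-base accounting for one chrom target block
pileup_block <- function(chrom, block_start, block_end, aln, ref) {
  npos <- block_end - block_start
  counts <- matrix(0L, npos, 5L, dimnames = list(NULL, DNA_ALPHABET))
  del_cover <- integer(npos)
  ins_rows <- list()
  del_rows <- list()
  if (nrow(aln) > 0L) {
    key <- paste(aln$ref_start, aln$cigar, aln$seq, sep = "\r")
    tab <- table(key)
    first <- aln[!duplicated(key), , drop = FALSE]
    w <- as.integer(tab[paste(first$ref_start, first$cigar, first$seq,
                              sep = "\r")])
    for (r in seq_len(nrow(first))) {
      ops <- cigar_to_ops(first$cigar[r])
      g <- first$ref_start[r]
      rp <- 0L
      chars <- seq_chars(first$seq[r])
      for (k in seq_along(ops$ops)) {
        op <- ops$ops[k]; len <- ops$lens[k]
        if (op == 3L) {                       # S
          rp <- rp + len
        } else if (op == 0L) {                # M
          pos <- g:(g + len - 1L)
          base <- chars[(rp + 1L):(rp + len)]
          inb <- pos >= block_start & pos < block_end
          if (any(inb)) {
            idx <- cbind(pos[inb] - block_start + 1L,
                         match(base[inb], DNA_ALPHABET))
            counts[idx] <- counts[idx] + w[r]
          }
          g <- g + len; rp <- rp + len
        } else if (op == 1L) {                # I, anchored at g - 1
          anchor <- g - 1L
          if (anchor >= block_start && anchor < block_end) {
            ins_rows[[length(ins_rows) + 1L]] <- data.frame(
              pos = anchor,
              seq = paste(chars[(rp + 1L):(rp + len)], collapse = ""),
              count = w[r], stringsAsFactors = FALSE)
          }
          rp <- rp + len
        } else {                              # D
          pos <- g:(g + len - 1L)
          inb <- pos >= block_start & pos < block_end
          del_cover[pos[inb] - block_start + 1L] <-
            del_cover[pos[inb] - block_start + 1L] + w[r]
          if (g >= block_start && g < block_end) {
            del_rows[[length(del_rows) + 1L]] <- data.frame(
              pos = g, len = len, count = w[r], stringsAsFactors = FALSE)
          }
          g <- g + len
        }
      }
    }
  }
  agg <- function(rows, keys) {
    if (length(rows) == 0L) {
      out <- data.frame(chrom = character(0), pos = integer(0),
                        count = integer(0), stringsAsFactors = FALSE)
      for (k in keys) out[[k]] <- if (k == "len") integer(0) else character(0)
      return(out[, c("chrom", "pos", keys, "count")])
    }
    d <- do.call(rbind, rows)
    d <- stats::aggregate(count ~ ., data = d, FUN = sum)
    d$chrom <- chrom
    d[order(d$pos), c("chrom", "pos", keys, "count")]
  }
  ref_chars <- seq_chars(ref_slice(ref, block_start, block_end))
  cols <- data.frame(chrom = chrom, pos = block_start:(block_end - 1L),
                     ref = ref_chars, stringsAsFactors = FALSE)
  cols <- cbind(cols, as.data.frame(counts))
  cols$del <- del_cover
  cols$depth <- as.integer(rowSums(counts) + del_cover)
  list(columns = cols, ins = agg(ins_rows, "seq"), del = agg(del_rows, "len"))
}

pileup_full <- function(alignments, panel) {
  targets <- panel_targets(panel)
  blocks <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    aln <- alignments[alignments$chrom == t$chrom, , drop = FALSE]
    pileup_block(t$chrom, t$start, t$end, aln, panel$reference[[t$chrom]])
  })
  out <- list(
    columns = do.call(rbind, lapply(blocks, `[[`, "columns")),
    ins = do.call(rbind, lapply(blocks, `[[`, "ins")),
    del = do.call(rbind, lapply(blocks, `[[`, "del")),
    targets = targets)
  rownames(out$columns) <- NULL
  structure(out, class = "ado_pileup")
}

#' Build a pileup over the panel target regions
#'
#' Tallies aligned bases per target position from an alignment table.
#' Returns one column per target base with at least one covering read;
#' per-column depth is the sum of base counts plus reads whose deletion
#' spans the column.
#'
#' @param alignments alignment data frame from [align_reads()].
#' @param panel an [amplicon_panel()].
#' @return Object of class `ado_pileup`: list with `columns` (data frame
#'   `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`, `N`, `del`, `depth`),
#'   `ins` (insertion tallies anchored after `pos`), `del` (deletion
#'   tallies anchored at their first deleted base) and `targets`.
#' @export
build_pileup <- function(alignments, panel) {
  p <- pileup_full(alignments, panel)
  p$columns <- p$columns[p$columns$depth > 0L, , drop = FALSE]
  rownames(p$columns) <- NULL
  p
}

#' @export
print.ado_pileup <- function(x, ...) {
  cat(sprintf("Pileup over %d target interval(s): %d covered column(s), %d insertion and %d deletion record(s)\n",
              nrow(x$targets), sum(x$columns$depth > 0L), nrow(x$ins),
              nrow(x$del)))
  invisible(x)
}
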
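#' Variant calling parameters
#'
#' Deterministic allele-fraction thresholds standing in for a
#' likelihood-based genotyper. A site is called when its depth reaches
#' `min_depth`, some non-reference allele (base, insertion or deletion)
#' has at least `min_alt_count` supporting reads, and its fraction of the
#' column depth reaches `min_alt_fraction`; the genotype is homozygous
#' when the fraction reaches `hom_fraction`, heterozygous otherwise.
#' The 0.25 default reflects the allele fraction below which callers
#' typically dismiss an allele (the mechanism behind ADO false
#' homozygosity); 30x is the conventional minimum amplicon coverage.
#'
#' @param min_alt_fraction minimum alternate allele fraction (default 0.25).
#' @param hom_fraction fraction at or above which a call is homozygous
#'   (default 0.75).
#' @param min_depth minimum column depth (default 30).
#' @param min_alt_count minimum alternate read count (default 5).
#' @return List of class `call_params`.
#' @export
call_params <- function(min_alt_fraction = 0.25, hom_fraction = 0.75,
                        min_depth = 30L, min_alt_count = 5L) {
  stopifnot(min_alt_fraction > 0, min_alt_fraction <= hom_fraction,
            hom_fraction <= 1, min_depth >= 0, min_alt_count >= 0)
  structure(list(min_alt_fraction = min_alt_fraction,
                 hom_fraction = hom_fraction,
                 min_depth = as.integer(min_depth),
                 min_alt_count = as.integer(min_alt_count)),
            class = "call_params")
}

#' Construct a variant set
#'
#' A variant set is a data frame keyed (uniquely) by
#' `(chrom, pos, ref, alt)`, with `pos` the 0-based VCF-style anchor
#' position (for indels, the base preceding the event is included in
#' `ref`/`alt`). Rows are kept sorted by `(chrom, pos)`.
#'
#' @param chrom,pos,ref,alt variant key fields (`pos` 0-based).
#' @param kind `"SNV"`, `"INS"` or `"DEL"` (derived from `ref`/`alt` when
#'   missing).
#' @param genotype `"het"` or `"hom"`.
#' @param alt_fraction,depth call support.
#' @param step provenance round (1 or 2).
#' @return Data frame of class `variant_set`.
#' @export
variant_set <- function(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        kind = NULL, genotype = "het", alt_fraction = NA_real_,
                        depth = NA_integer_, step = 1L) {
  if (is.null(kind)) {
    kind <- ifelse(nchar(ref) < nchar(alt), "INS",
                   ifelse(nchar(ref) > nchar(alt), "DEL", "SNV"))
  }
  vs <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   kind = as.character(kind),
                   genotype = rep_len(as.character(genotype), length(chrom)),
                   alt_fraction = rep_len(as.numeric(alt_fraction),
                                          length(chrom)),
                   depth = rep_len(as.integer(depth), length(chrom)),
                   step = rep_len(as.integer(step), length(chrom)),
                   in_both = rep_len(FALSE, length(chrom)),
                   stringsAsFactors = FALSE)
  as_variant_set(vs)
}

variant_key <- function(vs) paste(vs$chrom, vs$pos, vs$ref, vs$alt, sep = "\r")

as_variant_set <- function(vs) {
  if (anyDuplicated(variant_key(vs))) {
    ado_error("variant set has duplicate (chrom,pos,ref,alt) keys",
              "ado_variant_key_error")
  }
  vs <- vs[order(vs$chrom, vs$pos, vs$ref, vs$alt), , drop = FALSE]
  rownames(vs) <- NULL
  class(vs) <- c("variant_set", "data.frame")
  vs
}

# left-align a 1+ base insertion or deletion (VCF normalization)
shift_ins_left <- function(ref, anchor, ins_seq) {
  # inserting S after `anchor`; shifting left is possible while the base
  # at `anchor` equals the last base of S (rotate S right)
  while (anchor > 0L) {
    last <- substr(ins_seq, nchar(ins_seq), nchar(ins_seq))
    if (ref_slice(ref, anchor, anchor + 1L) != last) break
    ins_seq <- paste0(last, substr(ins_seq, 1L, nchar(ins_seq) - 1L))
    anchor <- anchor - 1L
  }
  list(anchor = anchor, seq = ins_seq)
}

shift_del_left <- function(ref, start, len) {
  while (start > 0L &&
         ref_slice(ref, start - 1L, start) ==
           ref_slice(ref, start + len - 1L, start + len)) {
    start <- start - 1L
  }
  start
}

#' Call variants from a pileup
#'
#' Scans each pileup column for the gating rules of [call_params()] and
#' reports at most the single highest-fraction alternate allele per site.
#' Indels are left-aligned and emitted VCF-style (anchor base included).
#'
#' @param pileup an `ado_pileup` from [build_pileup()].
#' @param params a [call_params()] object.
#' @param step provenance label for the calling round (1 or 2).
#' @param panel the panel the pileup was built on (used for indel
#'   normalisation against the reference).
#' @return A [variant_set()].
#' @export
call_variants <- function(pileup, params = call_params(), step = 1L,
                          panel = NULL) {
  cols <- pileup$columns
  cand <- list()
  add <- function(chrom, pos, ref, alt, kind, count, depth) {
    cand[[length(cand) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, kind = kind,
      count = count, depth = depth, stringsAsFactors = FALSE)
  }
  if (nrow(cols) > 0L) {
    depth_at <- function(chrom, pos) {
      i <- which(cols$chrom == chrom & cols$pos == pos)
      if (length(i) == 0L) 0L else cols$depth[i]
    }
    # SNVs: vectorised over the base count matrix
    bases <- as.matrix(cols[, DNA_ALPHABET[1:4]])
    for (b in DNA_ALPHABET[1:4]) {
      hit <- which(cols$ref != b & cols[[b]] > 0L)
      for (i in hit) {
        add(cols$chrom[i], cols$pos[i], cols$ref[i], b, "SNV",
            cols[[b]][i], cols$depth[i])
      }
    }
    ref_of <- function(chrom) {
      if (!is.null(panel)) panel$reference[[chrom]] else NULL
    }
    if (nrow(pileup$ins) > 0L) {
      for (i in seq_len(nrow(pileup$ins))) {
        r <- pileup$ins[i, ]
        anchor <- r$pos
        ins_seq <- r$seq
        rs <- ref_of(r$chrom)
        if (!is.null(rs)) {
          sh <- shift_ins_left(rs, anchor, ins_seq)
          anchor <- sh$anchor; ins_seq <- sh$seq
          anchor_base <- ref_slice(rs, anchor, anchor + 1L)
        } else {
          i2 <- which(cols$chrom == r$chrom & cols$pos == anchor)
          anchor_base <- if (length(i2)) cols$ref[i2] else "N"
        }
        add(r$chrom, anchor, anchor_base, paste0(anchor_base, ins_seq),
            "INS", r$count, depth_at(r$chrom, r$pos))
      }
    }
    if (nrow(pileup$del) > 0L) {
      for (i in seq_len(nrow(pileup$del))) {
        r <- pileup$del[i, ]
        start <- r$pos
        rs <- ref_of(r$chrom)
        if (!is.null(rs)) {
          start <- shift_del_left(rs, start, r$len)
          anchor_base <- ref_slice(rs, start - 1L, start)
          del_seq <- ref_slice(rs, start, start + r$len)
        } else {
          anchor_base <- "N"
          del_seq <- strrep("N", r$len)
        }
        add(r$chrom, start - 1L, paste0(anchor_base, del_seq), anchor_base,
            "DEL", r$count, depth_at(r$chrom, r$pos))
      }
    }
  }
  if (length(cand) == 0L) return(variant_set())
  cand <- do.call(rbind, cand)
  cand$alt_fraction <- cand$count / cand$depth
  pass <- cand$depth >= params$min_depth &
    cand$count >= params$min_alt_count &
    cand$alt_fraction >= params$min_alt_fraction
  cand <- cand[pass, , drop = FALSE]
  if (nrow(cand) == 0L) return(variant_set())
  # one alt per site: keep the highest-fraction candidate at each column
  site <- paste(cand$chrom, cand$pos, sep = "\r")
  cand <- cand[order(site, -cand$alt_fraction), , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$chrom, cand$pos, sep = "\r")), ,
               drop = FALSE]
  variant_set(chrom = cand$chrom, pos = cand$pos, ref = cand$ref,
              alt = cand$alt, kind = cand$kind,
              genotype = ifelse(cand$alt_fraction >= params$hom_fraction,
                                "hom", "het"),
              alt_fraction = cand$alt_fraction, depth = cand$depth,
              step = step)
}

#' Merge two rounds of variant calls
#'
#' Key union of the two sets; on a key collision the round-one record is
#' kept and flagged `in_both`. Every record retains its provenance step.
#'
#' @param step1,step2 [variant_set()] objects.
#' @return A merged [variant_set()], sorted by `(chrom, pos)`.
#' @export
merge_variant_sets <- function(step1, step2) {
  k1 <- variant_key(step1)
  k2 <- variant_key(step2)
  step1$in_both <- step1$in_both | k1 %in% k2
  out <- rbind(as.data.frame(step1),
               as.data.frame(step2)[!(k2 %in% k1), , drop = FALSE])
  as_variant_set(out)
}

#' Compare two variant sets
#'
#' Splits the calls of a query ("trimming") set against a baseline set by
#' key and computes the new discovery rate per variant kind: the
#' percentage of query variants of that kind absent from the baseline.
#'
#' @param trimming query [variant_set()].
#' @param baseline baseline [variant_set()].
#' @return List with `shared`, `trimming_only`, `baseline_only` (variant
#'   sets) and `new_discovery_rate` (data frame `kind`, `n_trimming`,
#'   `n_only`, `ndr_pct`).
#' @export
compare_variant_sets <- function(trimming, baseline) {
  kt <- variant_key(trimming)
  kb <- variant_key(baseline)
  shared <- trimming[kt %in% kb, , drop = FALSE]
  t_only <- trimming[!(kt %in% kb), , drop = FALSE]
  b_only <- baseline[!(kb %in% kt), , drop = FALSE]
  kinds <- sort(unique(c(trimming$kind, baseline$kind)))
  ndr <- data.frame(
    kind = kinds,
    n_trimming = vapply(kinds, function(k) sum(trimming$kind == k),
                        integer(1L)),
    n_only = vapply(kinds, function(k) sum(t_only$kind == k), integer(1L)),
    stringsAsFactors = FALSE)
  ndr$ndr_pct <- ifelse(ndr$n_trimming > 0L,
                        100 * ndr$n_only / ndr$n_trimming, NA_real_)
  rownames(ndr) <- NULL
  list(shared = as_variant_set(as.data.frame(shared)),
       trimming_only = as_variant_set(as.data.frame(t_only)),
       baseline_only = as_variant_set(as.data.frame(b_only)),
       new_discovery_rate = ndr)
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("Variant set: %d call(s)\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x)
  invisible(x)
}
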
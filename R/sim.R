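#' Simulator configuration
#'
#' Parameters of the synthetic ADO dataset generator. The defaults encode
#' the study conditions of the two-amplicon benchmark: 3186 amplicon-A
#' and 5484 amplicon-B read pairs (an A:B ratio of about 37:63), a
#' heterozygous carrier (amplicon-A haplotypes mutated with probability
#' 0.5), a 100-fold amplification-yield reduction of the mutated allele
#' on amplicon B (haplotype odds wild:mutated = 1:0.01), a linked second
#' SNV carried by mutated haplotypes with probability 0.9, and 2x150 bp
#' reads. `mode = "SD1"` plants a substitution in B's upstream-primer
#' footprint; `"SD2"` replaces it with a single-base insertion.
#'
#' @param n_A,n_B read-pair pool sizes for amplicons A and B.
#' @param het_fraction probability that an amplicon-A pair comes from the
#'   mutated haplotype.
#' @param second_mut_prob probability that a mutated-haplotype pair also
#'   carries the downstream second SNV.
#' @param ado_yield_ratio mutated:wild amplification yield for amplicon B
#'   (0.01 = 100-fold reduction).
#' @param read_len read length in bases.
#' @param base_error_rate per-base uniform substitution error rate
#'   (default 0: the planted variants are the only non-reference bases).
#' @param mode `"SD1"` (primer-footprint SNV) or `"SD2"` (primer-footprint
#'   insertion).
#' @param seed integer seed; identical configurations generate
#'   byte-identical datasets.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_A = 3186L, n_B = 5484L, het_fraction = 0.5,
                       second_mut_prob = 0.9, ado_yield_ratio = 0.01,
                       read_len = 150L, base_error_rate = 0,
                       mode = c("SD1", "SD2"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_A >= 0L, n_B >= 0L,
            het_fraction >= 0, het_fraction <= 1,
            second_mut_prob >= 0, second_mut_prob <= 1,
            ado_yield_ratio >= 0,
            base_error_rate >= 0, base_error_rate <= 1,
            read_len > 0L)
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 het_fraction = het_fraction,
                 second_mut_prob = second_mut_prob,
                 ado_yield_ratio = ado_yield_ratio,
                 read_len = as.integer(read_len),
                 base_error_rate = base_error_rate,
                 mode = mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the two-amplicon benchmark panel
#'
#' Generates a random ~600 bp reference carrying two overlapping 250 bp
#' amplicons (20-base primers, 210-base inserts): A at insert
#' `[100, 310)` and B at insert `[300, 510)`. The planted-variant
#' geometry is fixed so that every constraint of the ADO benchmark holds:
#' the primer-footprint variant m1 sits at position 297 (0-based), inside
#' B's upstream-primer footprint `[280, 300)` and inside A's insert; the
#' linked second SNV m2 sits 5 bases downstream at 302, covered by both
#' inserts and outside every primer footprint. For the insertion variant
#' (SD2) the inserted base is chosen to differ from both flanking
#' reference bases (unique placement) and so that the shifted primer
#' prefix differs from the ULSO at two or more positions.
#'
#' @param seed integer seed for the reference draw.
#' @return List of class `ado_fixture` with elements `panel` (an
#'   [amplicon_panel()]) and `truth` (planted-variant skeleton: `m1_snv`,
#'   `m1_ins`, `m2`, and the fixture geometry).
#' @export
build_fixture_panel <- function(seed = 1L) {
  set.seed(seed)
  chrom <- "ampliconRef"
  repeat {
    ref_chars <- sample(DNA_ALPHABET[1:4], 600L, replace = TRUE)
    ref_chars[298L] <- "C"   # m1 site, 0-based 297
    ref_chars[303L] <- "G"   # m2 site, 0-based 302
    ref <- paste(ref_chars, collapse = "")
    amp <- data.frame(
      amplicon_id = c("A", "B"),
      chrom = chrom,
      insert_start = c(100L, 300L),
      insert_end = c(310L, 510L),
      stringsAsFactors = FALSE)
    amp$ulso <- c(ref_slice(ref, 80L, 100L), ref_slice(ref, 280L, 300L))
    amp$dlso <- c(revcomp(ref_slice(ref, 310L, 330L)),
                  revcomp(ref_slice(ref, 510L, 530L)))
    # primers must be mutually unambiguous under the 1-mismatch rule
    cross <- c(prefix_mismatches(amp$ulso[1L], amp$ulso[2L]),
               prefix_mismatches(amp$dlso[1L], amp$dlso[2L]))
    # SD2 inserted base: differs from both neighbours of the insertion
    # point, and the shifted prefix must fail the 1-mismatch primer rule
    ins_ok <- FALSE
    for (base in setdiff(DNA_ALPHABET[1:4],
                         c(ref_chars[298L], ref_chars[299L]))) {
      local_anchor <- 297L - 280L  # offset of m1 within amplicon B
      prefix <- paste0(substr(amp$ulso[2L], 1L, local_anchor + 1L), base,
                       substr(amp$ulso[2L], local_anchor + 2L, 20L))
      prefix <- substr(prefix, 1L, 20L)
      if (isTRUE(prefix_mismatches(prefix, amp$ulso[2L]) >= 2L)) {
        ins_base <- base
        ins_ok <- TRUE
        break
      }
    }
    if (all(cross >= 2L) && ins_ok) break
  }
  panel <- amplicon_panel("ado-fixture", amp, stats::setNames(ref, chrom))
  truth <- list(
    chrom = chrom,
    m1_pos = 297L,
    m1_snv = list(chrom = chrom, pos = 297L, ref = "C", alt = "T",
                  kind = "SNV"),
    m1_ins = list(chrom = chrom, pos = 297L, ref = "C",
                  alt = paste0("C", ins_base), kind = "INS",
                  ins_base = ins_base),
    m2 = list(chrom = chrom, pos = 302L, ref = "G", alt = "A",
              kind = "SNV"))
  structure(list(panel = panel, truth = truth), class = "ado_fixture")
}

# full amplicon sequence (primer footprint to primer footprint) on the
# plus strand, with the requested variants applied
haplotype_seq <- function(fixture, amplicon_id, m1 = FALSE, m2 = FALSE,
                          mode = "SD1") {
  panel <- fixture$panel
  amp <- panel$amplicons
  a <- amp[amp$amplicon_id == amplicon_id, ]
  ref <- panel$reference[[a$chrom]]
  start <- a$insert_start - nchar(a$ulso)
  end <- a$insert_end + nchar(a$dlso)
  s <- ref_slice(ref, start, end)
  apply_at <- function(s, pos0, value) {
    local <- pos0 - start
    paste0(substr(s, 1L, local), value, substr(s, local + 2L, nchar(s)))
  }
  if (m2) s <- apply_at(s, fixture$truth$m2$pos, fixture$truth$m2$alt)
  if (m1) {
    t1 <- fixture$truth$m1_pos
    if (mode == "SD1") {
      s <- apply_at(s, t1, fixture$truth$m1_snv$alt)
    } else {
      local <- t1 - start
      s <- paste0(substr(s, 1L, local + 1L), fixture$truth$m1_ins$ins_base,
                  substr(s, local + 2L, nchar(s)))
    }
  }
  s
}

apply_base_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    k <- stats::rbinom(1L, n, rate)
    if (k > 0L) {
      pos <- sample.int(n, k)
      ch <- seq_chars(seqs[i])
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(DNA_ALPHABET[1:4], b), 1L)
      }, character(1L))
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  seqs
}

#' Generate a synthetic ADO dataset
#'
#' Draws the amplicon-A and amplicon-B read-pair pools of the benchmark:
#' A pairs take the mutated haplotype with probability `het_fraction`, B
#' pairs with probability `ado_yield_ratio / (1 + ado_yield_ratio)`
#' (haplotype odds wild:mutated = 1:`ado_yield_ratio`, the ADO yield
#' model). Mutated-haplotype pairs carry the primer-footprint variant m1
#' wherever their coordinates cover it — for amplicon B that is inside
#' the read-1 primer prefix — and additionally carry the downstream SNV
#' m2 with probability `second_mut_prob`. Read 1 is the first `read_len`
#' bases of the amplicon (primer included); read 2 the reverse complement
#' of the last `read_len` bases. Base qualities are constant `"I"`.
#'
#' @param cfg a [sim_config()].
#' @param fixture an [build_fixture_panel()] fixture (defaults to the
#'   fixture built from `cfg$seed`).
#' @return List of class `ado_dataset`: `pairs` (read-pair data frame),
#'   `truth` (per-pair provenance: `id`, `amplicon`, `haplotype`, `m1`,
#'   `m2`), `config`, `fixture`.
#' @export
simulate_dataset <- function(cfg, fixture = build_fixture_panel(cfg$seed)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(fixture, "ado_fixture"))
  set.seed(cfg$seed + 1L)
  p_B <- cfg$ado_yield_ratio / (1 + cfg$ado_yield_ratio)
  draw_pool <- function(amplicon_id, n, p_mut, prefix) {
    mut <- stats::runif(n) < p_mut
    m2 <- mut & stats::runif(n) < cfg$second_mut_prob
    variant <- paste0(ifelse(mut, "m", "w"), ifelse(m2, "2", "0"))
    hap <- c(w0 = haplotype_seq(fixture, amplicon_id, FALSE, FALSE, cfg$mode),
             m0 = haplotype_seq(fixture, amplicon_id, TRUE, FALSE, cfg$mode),
             m2 = haplotype_seq(fixture, amplicon_id, TRUE, TRUE, cfg$mode))
    s <- unname(hap[variant])
    L <- nchar(s)
    seq1 <- substr(s, 1L, cfg$read_len)
    seq2 <- revcomp(substring(s, L - cfg$read_len + 1L, L))
    seq1 <- apply_base_errors(seq1, cfg$base_error_rate)
    seq2 <- apply_base_errors(seq2, cfg$base_error_rate)
    qual <- strrep("I", nchar(seq1))
    list(
      pairs = data.frame(
        id = sprintf("%s_%05d", prefix, seq_len(n)),
        seq1 = seq1, qual1 = qual, seq2 = seq2,
        qual2 = strrep("I", nchar(seq2)), stringsAsFactors = FALSE),
      truth = data.frame(
        id = sprintf("%s_%05d", prefix, seq_len(n)),
        amplicon = amplicon_id,
        haplotype = ifelse(mut, "mut", "wild"),
        m1 = mut, m2 = m2, stringsAsFactors = FALSE))
  }
  a <- draw_pool("A", cfg$n_A, cfg$het_fraction, "A")
  b <- draw_pool("B", cfg$n_B, p_B, "B")
  structure(list(pairs = rbind(a$pairs, b$pairs),
                 truth = rbind(a$truth, b$truth),
                 config = cfg, fixture = fixture),
            class = "ado_dataset")
}

#' Mix amplicon-A and amplicon-B read pairs in a target proportion
#'
#' Draws `round(fraction_A * total)` pairs from the amplicon-A pool and
#' the complement from the B pool, uniformly without replacement when the
#' pool is large enough, with replacement otherwise (flagged in the truth
#' table's `resampled` column). The default total preserves the dataset's
#' read count so depth — and hence caller behaviour — stays comparable
#' across mixes.
#'
#' @param dataset an `ado_dataset` from [simulate_dataset()].
#' @param fraction_A target fraction of amplicon-A pairs, in `[0, 1]`.
#' @param total total number of pairs to emit (default: pool total).
#' @param seed integer seed for the draw.
#' @return An `ado_dataset` with the mixed pairs (re-keyed ids) and the
#'   matching truth rows.
#' @export
mix_reads <- function(dataset, fraction_A, total = NULL, seed = 1L) {
  stopifnot(fraction_A >= 0, fraction_A <= 1)
  set.seed(seed)
  if (is.null(total)) total <- nrow(dataset$pairs)
  n_a <- round(fraction_A * total)
  n_b <- total - n_a
  take <- function(amp, n) {
    pool <- which(dataset$truth$amplicon == amp)
    replace <- n > length(pool)
    if (length(pool) == 0L && n > 0L) {
      ado_error(sprintf("amplicon %s pool is empty", amp),
                "ado_mix_error")
    }
    idx <- if (n == 0L) integer(0) else sample(pool, n, replace = replace)
    list(idx = idx, resampled = replace)
  }
  ta <- take("A", n_a)
  tb <- take("B", n_b)
  idx <- c(ta$idx, tb$idx)
  pairs <- dataset$pairs[idx, , drop = FALSE]
  truth <- dataset$truth[idx, , drop = FALSE]
  truth$resampled <- rep(c(ta$resampled, tb$resampled), c(n_a, n_b))
  new_id <- sprintf("%s_x%05d", truth$id, seq_along(idx))
  pairs$id <- new_id
  truth$id <- new_id
  rownames(pairs) <- rownames(truth) <- NULL
  out <- dataset
  out$pairs <- pairs
  out$truth <- truth
  out$fraction_A <- fraction_A
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the FASTQ pair, the per-pair truth TSV, the fixture manifest TSV
#' and the reference FASTA.
#'
#' @param dataset an `ado_dataset`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @param gzip compress the FASTQ pair.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, prefix = "sim", gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- c(
    fastq1 = file.path(dir, paste0(prefix, "_R1", ext)),
    fastq2 = file.path(dir, paste0(prefix, "_R2", ext)),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")),
    manifest = file.path(dir, paste0(prefix, "_manifest.tsv")),
    reference = file.path(dir, paste0(prefix, "_reference.fa")))
  write_fastq_pair(dataset$pairs, paths[["fastq1"]], paths[["fastq2"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(dataset$fixture$panel, paths[["manifest"]],
                 paths[["reference"]])
  invisible(paths)
}

#' @export
print.ado_dataset <- function(x, ...) {
  tab <- table(x$truth$amplicon)
  cat(sprintf("Synthetic ADO dataset (%s): %d read pair(s) [%s]\n",
              x$config$mode, nrow(x$pairs),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  mutated haplotype: %d pair(s), second SNV: %d pair(s)\n",
              sum(x$truth$m1), sum(x$truth$m2)))
  invisible(x)
}
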
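# Shared fixtures, memoised so the simulated pools are drawn once per
# session. All seeds here are fixed arbitrary constants.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

test_fixture <- function() cached("fx", build_fixture_panel(seed = 7))

sd1_dataset <- function() {
  cached("sd1", simulate_dataset(sim_config(seed = 7), test_fixture()))
}

sd2_dataset <- function() {
  cached("sd2",
         simulate_dataset(sim_config(mode = "SD2", seed = 7), test_fixture()))
}

# pileup constructed directly, for caller unit tests that need exact
# depths without simulating reads
manual_pileup <- function(chrom = "c", pos, ref, counts, ins = NULL,
                          del = NULL) {
  stopifnot(is.matrix(counts), ncol(counts) == 5L)
  colnames(counts) <- c("A", "C", "G", "T", "N")
  cols <- data.frame(chrom = chrom, pos = pos, ref = ref,
                     stringsAsFactors = FALSE)
  cols <- cbind(cols, as.data.frame(counts))
  cols$del <- 0L
  cols$depth <- as.integer(rowSums(counts))
  empty_ins <- data.frame(chrom = character(0), pos = integer(0),
                          seq = character(0), count = integer(0),
                          stringsAsFactors = FALSE)
  empty_del <- data.frame(chrom = character(0), pos = integer(0),
                          len = integer(0), count = integer(0),
                          stringsAsFactors = FALSE)
  structure(list(columns = cols,
                 ins = if (is.null(ins)) empty_ins else ins,
                 del = if (is.null(del)) empty_del else del,
                 targets = data.frame(chrom = chrom,
                                      start = min(pos),
                                      end = max(pos) + 1L,
                                      stringsAsFactors = FALSE)),
            class = "ado_pileup")
}

# single-site pileup column with a given depth and alt count
site_pileup <- function(depth, alt_count, ref = "C", alt = "T",
                        pos = 50L) {
  counts <- matrix(0L, 1L, 5L)
  colnames(counts) <- c("A", "C", "G", "T", "N")
  counts[1L, ref] <- depth - alt_count
  counts[1L, alt] <- alt_count
  manual_pileup(pos = pos, ref = ref, counts = counts)
}

# independent prefix Hamming count (oracle-side reimplementation)
prefix_mm <- function(read, primer) {
  if (nchar(read) < nchar(primer)) return(NA_integer_)
  r <- strsplit(substr(read, 1L, nchar(primer)), "")[[1L]]
  p <- strsplit(primer, "")[[1L]]
  sum(r != p & r != "N" & p != "N")
}

# independent brute-force pair assignment used as an oracle against
# trim_pairs: plain loops, no shared code with the implementation
brute_force_assign <- function(pairs, panel) {
  amp <- panel$amplicons
  ham <- function(read, primer) {
    if (nchar(read) < nchar(primer)) return(NA_integer_)
    r <- strsplit(substr(read, 1L, nchar(primer)), "")[[1L]]
    p <- strsplit(primer, "")[[1L]]
    sum(r != p & r != "N" & p != "N")
  }
  out <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    best_amp <- NA_character_
    best_mm <- Inf
    for (j in seq_len(nrow(amp))) {
      m1 <- ham(pairs$seq1[i], amp$ulso[j])
      m2 <- ham(pairs$seq2[i], amp$dlso[j])
      if (!is.na(m1) && !is.na(m2) && m1 <= 1L && m2 <= 1L &&
          m1 + m2 < best_mm) {
        best_mm <- m1 + m2
        best_amp <- amp$amplicon_id[j]
      }
    }
    out[i] <- best_amp
  }
  out
}

# substitution matrix matching the default aligner scoring, for
# Biostrings::pairwiseAlignment used as the full-DP oracle
oracle_submat <- function(match = 2, mismatch = -2) {
  m <- matrix(mismatch, 4L, 4L,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- match
  m
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
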
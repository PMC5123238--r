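test_that("error-free trimmed reads align as a single match run at the insert start", {
  fx <- test_fixture()
  insert <- fx$panel$amplicons$insert_seq[1]  # amplicon A, [100, 310)
  read <- substr(insert, 1, 130)
  aln <- align_to_amplicon(read, "A", fx$panel, mode = "trimmed")
  expect_equal(aln$cigar, "130M")
  expect_equal(aln$ref_start, 100L)
  expect_equal(aln$chrom, "ampliconRef")
  expect_error(align_to_amplicon(read, "Z", fx$panel),
               class = "ado_unknown_amplicon_error")
})

test_that("a mid-read single-base insertion yields exactly one I op placed as the full DP oracle places it", {
  fx <- test_fixture()
  insert <- fx$panel$amplicons$insert_seq[1]
  ins_base <- setdiff(c("A", "C", "G", "T"),
                      c(substr(insert, 60, 60), substr(insert, 61, 61)))[1]
  read <- paste0(substr(insert, 1, 60), ins_base, substr(insert, 61, 129))
  aln <- align_to_amplicon(read, "A", fx$panel, mode = "trimmed")
  ops <- regmatches(aln$cigar, gregexpr("[0-9]+[MIDS]", aln$cigar))[[1]]
  expect_identical(ops, c("60M", "1I", "69M"))
  expect_equal(aln$ref_start, 100L)

  pa <- Biostrings::pairwiseAlignment(
    read, insert, type = "local", substitutionMatrix = oracle_submat(),
    gapOpening = 4, gapExtension = 1)
  expect_equal(aln$score, Biostrings::score(pa))
})

test_that("alignments needing more gap than a third of the read length are rejected", {
  fx <- test_fixture()
  insert <- fx$panel$amplicons$insert_seq[1]
  # read spanning a 60-base deletion: cumulative gap 60 > floor(150/3)
  read <- paste0(substr(insert, 1, 75), substr(insert, 136, 210))
  expect_null(align_to_amplicon(read, "A", fx$panel, mode = "trimmed"))
  # the same read passes with a permissive gap budget
  loose <- align_params(max_gap_fraction = 0.5)
  aln <- align_to_amplicon(read, "A", fx$panel, params = loose,
                           mode = "trimmed")
  expect_match(aln$cigar, "60D")
})

test_that("banded aligner score and placement equal the full DP oracle on random simulated reads", {
  fx <- test_fixture()
  insert <- fx$panel$amplicons$insert_seq[1]
  set.seed(3)
  n_checked <- 0
  for (i in 1:120) {
    start <- sample(1:80, 1)
    len <- sample(60:130, 1)
    read <- substr(insert, start, start + len - 1)
    nmm <- sample(0:2, 1)
    if (nmm > 0) {
      ch <- strsplit(read, "")[[1]]
      pos <- sample(seq(5, len - 5), nmm)
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      read <- paste(ch, collapse = "")
    }
    aln <- align_to_amplicon(read, "A", fx$panel, mode = "trimmed")
    pa <- Biostrings::pairwiseAlignment(
      read, insert, type = "local", substitutionMatrix = oracle_submat(),
      gapOpening = 4, gapExtension = 1)
    expect_equal(aln$score, Biostrings::score(pa))
    if (nmm == 0) {
      # unique placement for gap-free reads: genomic start must agree
      expect_equal(aln$ref_start,
                   100L + Biostrings::start(Biostrings::subject(pa)) - 1L)
      expect_equal(aln$cigar, paste0(len, "M"))
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 120)
})

test_that("op bookkeeping holds for every emitted alignment", {
  ds <- sd1_dataset()
  panel <- ds$fixture$panel
  trim <- trim_pairs(ds$pairs[1:400, ], panel)
  for (mode in c("trimmed", "softclip", "untrimmed")) {
    pairs <- if (mode == "trimmed") {
      trim$pairs
    } else {
      raw <- ds$pairs[match(trim$pairs$id, ds$pairs$id), ]
      data.frame(id = trim$pairs$id, amplicon_id = trim$pairs$amplicon_id,
                 seq1 = raw$seq1, qual1 = raw$qual1, seq2 = raw$seq2,
                 qual2 = raw$qual2, stringsAsFactors = FALSE)
    }
    aln <- align_reads(pairs, panel, mode = mode)$alignments
    for (i in seq_len(nrow(aln))) {
      ops <- regmatches(aln$cigar[i],
                        gregexpr("([0-9]+)([MIDS])", aln$cigar[i]))[[1]]
      kinds <- sub("[0-9]+", "", ops)
      lens <- as.integer(sub("[MIDS]", "", ops))
      # consumed read bases equal read length
      expect_equal(sum(lens[kinds %in% c("M", "I", "S")]),
                   nchar(aln$seq[i]))
      # soft clips only at the ends
      expect_true(all(which(kinds == "S") %in% c(1L, length(kinds))))
      # no adjacent ops of the same kind
      expect_false(any(kinds[-1] == kinds[-length(kinds)]))
    }
  }
})

test_that("softclip and trimmed modes contribute identically to the insert pileup for error-free reads", {
  ds <- sd1_dataset()
  panel <- ds$fixture$panel
  sub <- ds$pairs[c(1:150, 4001:4150), ]
  trim <- trim_pairs(sub, panel)
  aln_t <- align_reads(trim$pairs, panel, mode = "trimmed")
  raw <- sub[match(trim$pairs$id, sub$id), ]
  assigned <- data.frame(id = trim$pairs$id,
                         amplicon_id = trim$pairs$amplicon_id,
                         seq1 = raw$seq1, qual1 = raw$qual1,
                         seq2 = raw$seq2, qual2 = raw$qual2,
                         stringsAsFactors = FALSE)
  aln_s <- align_reads(assigned, panel, mode = "softclip")
  p_t <- build_pileup(aln_t$alignments, panel)
  p_s <- build_pileup(aln_s$alignments, panel)
  expect_equal(p_t$columns, p_s$columns)
  expect_equal(p_t$ins, p_s$ins)
})

test_that("SAM output is well-formed, with soft-clipped primers in softclip mode", {
  fx <- test_fixture()
  insert <- fx$panel$amplicons$insert_seq[1]
  dir <- withr::local_tempdir()

  read <- substr(insert, 1, 130)
  aln <- align_reads(
    data.frame(id = "r1", amplicon_id = "A", seq1 = read,
               qual1 = strrep("I", 130),
               seq2 = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(insert, 81, 210)))),
               qual2 = strrep("I", 130), stringsAsFactors = FALSE),
    fx$panel, mode = "trimmed")
  path <- file.path(dir, "out.sam")
  write_sam(aln$alignments, fx$panel, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "@HD"))
  expect_true(any(startsWith(lines, "@SQ\tSN:ampliconRef\tLN:600")))
  recs <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_equal(length(recs), 2L)
  expect_equal(recs[[1]][6], "130M")
  expect_equal(as.integer(recs[[1]][4]), 101L)  # SAM is 1-based

  # softclip mode: the 20-base primer prefix becomes a leading soft clip
  amp_seq <- paste0(fx$panel$amplicons$ulso[1], insert,
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(fx$panel$amplicons$dlso[1]))))
  raw1 <- substr(amp_seq, 1, 150)
  aln_s <- align_reads(
    data.frame(id = "r2", amplicon_id = "A", seq1 = raw1,
               qual1 = strrep("I", 150),
               seq2 = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(amp_seq, 101, 250)))),
               qual2 = strrep("I", 150), stringsAsFactors = FALSE),
    fx$panel, mode = "softclip")
  expect_equal(aln_s$alignments$cigar[1], "20S130M")
  expect_equal(aln_s$alignments$ref_start[1], 100L)

  # empty stream: header-only SAM
  empty <- aln$alignments[0, ]
  write_sam(empty, fx$panel, file.path(dir, "empty.sam"))
  expect_true(all(startsWith(readLines(file.path(dir, "empty.sam")), "@")))
})
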
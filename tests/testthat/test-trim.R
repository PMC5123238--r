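test_that("primer prefix matching accepts one mismatch and no gaps", {
  expect_identical(match_primer_prefix("ACGTTTTT", "ACGT"),
                   list(matched = TRUE, mismatches = 0L))
  expect_identical(match_primer_prefix("ACCTTTTT", "ACGT"),
                   list(matched = TRUE, mismatches = 1L))
  expect_false(match_primer_prefix("ATCATTTT", "ACGT")$matched)
  expect_false(match_primer_prefix("ACG", "ACGT")$matched)
  # N is a wildcard on either side and never counts as a mismatch
  expect_identical(match_primer_prefix("ANGTTT", "ACGT")$mismatches, 0L)
  expect_identical(match_primer_prefix("ACGTTT", "ANGT")$mismatches, 0L)
})

test_that("pairs are assigned, trimmed in lockstep, or discarded as a pair", {
  fx <- test_fixture()
  panel <- fx$panel
  amp <- panel$amplicons
  ref <- panel$reference[["ampliconRef"]]

  # error-free pair from amplicon A
  amp_seq <- substr(ref, 81, 330)
  pair <- data.frame(id = "p1",
                     seq1 = substr(amp_seq, 1, 150),
                     qual1 = strrep("I", 150),
                     seq2 = as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(substr(amp_seq, 101, 250)))),
                     qual2 = strrep("F", 150), stringsAsFactors = FALSE)
  tp <- assign_and_trim(pair, panel)
  expect_equal(tp$amplicon_id, "A")
  expect_equal(c(tp$mismatches1, tp$mismatches2), c(0L, 0L))
  expect_equal(nchar(tp$seq1), 130L)
  expect_equal(nchar(tp$qual1), 130L)
  expect_identical(tp$qual2, strrep("F", 130))

  # read 1 matches B's ULSO but read 2 fails B's DLSO by two mismatches:
  # the whole pair is discarded
  b <- amp[amp$amplicon_id == "B", ]
  s2 <- paste0("AA", random_dna(148))
  d <- b$dlso
  while (prefix_mm(s2, d) <= 1) s2 <- paste0(random_dna(20), random_dna(130))
  pair2 <- data.frame(id = "p2",
                      seq1 = paste0(b$ulso, random_dna(130)),
                      qual1 = strrep("I", 150),
                      seq2 = s2, qual2 = strrep("I", 150),
                      stringsAsFactors = FALSE)
  expect_null(assign_and_trim(pair2, panel))
})

test_that("a single-base insertion inside the primer prefix defeats the matcher", {
  ds <- sd2_dataset()
  panel <- ds$fixture$panel
  b_mut <- ds$truth$amplicon == "B" & ds$truth$m1
  expect_gt(sum(b_mut), 0L)
  # brute force over all mutated-B read-1 prefixes: the insertion shifts
  # two or more positions relative to the ULSO
  ulso <- panel$amplicons$ulso[panel$amplicons$amplicon_id == "B"]
  prefixes <- unique(substr(ds$pairs$seq1[b_mut], 1, nchar(ulso)))
  mm <- vapply(prefixes, function(p) prefix_mm(p, ulso), integer(1))
  expect_true(all(mm >= 2L))
  # hence every mutated-B pair is discarded at trimming
  res <- trim_pairs(ds$pairs, panel)
  expect_false(any(res$pairs$id %in% ds$truth$id[b_mut]))
  expect_true(all(ds$truth$id[b_mut] %in% res$rejects$id))
})

test_that("trimming conserves pairs and agrees with a brute-force matcher", {
  ds <- sd1_dataset()
  panel <- ds$fixture$panel
  res <- trim_pairs(ds$pairs, panel)

  expect_equal(res$stats$assigned_pairs + res$stats$discarded_pairs,
               res$stats$total_pairs)
  expect_equal(sum(res$stats$per_amplicon), res$stats$assigned_pairs)
  expect_equal(nrow(res$pairs) + nrow(res$rejects), nrow(ds$pairs))
  # every error-free pair matches its primers, so nearly all are kept
  expect_gte(res$stats$assigned_pairs / res$stats$total_pairs, 0.99)

  # brute-force equivalence on a random subset
  set.seed(11)
  idx <- sample(nrow(ds$pairs), 400)
  sub <- ds$pairs[idx, , drop = FALSE]
  bf <- brute_force_assign(sub, panel)
  res_sub <- trim_pairs(sub, panel)
  got <- res_sub$pairs$amplicon_id[match(sub$id, res_sub$pairs$id)]
  expect_identical(got, bf)

  # assignments agree with the simulator's ground truth
  truth_amp <- ds$truth$amplicon[match(res$pairs$id, ds$truth$id)]
  expect_identical(res$pairs$amplicon_id, truth_amp)
})

test_that("trimming is idempotent: primer prefixes are gone after removal", {
  ds <- sd1_dataset()
  panel <- ds$fixture$panel
  res <- trim_pairs(ds$pairs, panel)
  again <- trim_pairs(res$pairs[, c("id", "seq1", "qual1", "seq2", "qual2")],
                      panel)
  expect_equal(again$stats$assigned_pairs, 0L)
  expect_equal(again$stats$discarded_pairs, nrow(res$pairs))
})

test_that("FASTQ pair I/O round-trips and reports malformed records by index", {
  ds <- sd1_dataset()
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.fastq")
  f2 <- file.path(dir, "r2.fastq")
  sub <- ds$pairs[1:25, ]
  rownames(sub) <- NULL
  write_fastq_pair(sub, f1, f2)
  back <- read_fastq_pair(f1, f2)
  expect_equal(back, sub)

  # gzip round trip is byte-identical content
  g1 <- file.path(dir, "r1.fastq.gz")
  g2 <- file.path(dir, "r2.fastq.gz")
  write_fastq_pair(sub, g1, g2)
  expect_identical(read_fastq_pair(g1, g2), back)

  # corrupt record 3's separator line
  lines <- readLines(f1)
  lines[11] <- "not-a-plus"
  writeLines(lines, file.path(dir, "bad.fastq"))
  err <- tryCatch(read_fastq_pair(file.path(dir, "bad.fastq"), f2),
                  error = identity)
  expect_s3_class(err, "ado_fastq_parse_error")
  expect_match(conditionMessage(err), "record 3")

  # truncated file
  writeLines(lines[1:6], file.path(dir, "trunc.fastq"))
  expect_error(read_fastq_pair(file.path(dir, "trunc.fastq"), f2),
               class = "ado_fastq_parse_error")

  # empty input is a valid empty pair set
  writeLines(character(0), file.path(dir, "e1.fastq"))
  writeLines(character(0), file.path(dir, "e2.fastq"))
  empty <- read_fastq_pair(file.path(dir, "e1.fastq"),
                           file.path(dir, "e2.fastq"))
  expect_equal(nrow(empty), 0L)
  expect_equal(trim_pairs(empty, ds$fixture$panel)$stats$total_pairs, 0L)
})

test_that("all-N reads follow the N wildcard rule", {
  fx <- test_fixture()
  pair <- data.frame(id = "n", seq1 = strrep("N", 150),
                     qual1 = strrep("I", 150), seq2 = strrep("N", 150),
                     qual2 = strrep("I", 150), stringsAsFactors = FALSE)
  # N matches every primer base without counting as a mismatch, so the
  # pair is assignable; manifest order breaks the tie
  tp <- assign_and_trim(pair, fx$panel)
  expect_equal(tp$amplicon_id, "A")
  expect_equal(tp$mismatches1, 0L)
})
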
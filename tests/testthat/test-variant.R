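test_that("pileup counts conserve covering reads, including deletions", {
  fx <- test_fixture()
  insert <- fx$panel$amplicons$insert_seq[1]
  read <- substr(insert, 1, 130)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  pairs <- data.frame(id = sprintf("r%02d", 1:10), amplicon_id = "A",
                      seq1 = read, qual1 = strrep("I", 130),
                      seq2 = rc(substr(insert, 81, 210)),
                      qual2 = strrep("I", 130), stringsAsFactors = FALSE)
  aln <- align_reads(pairs, fx$panel, mode = "trimmed")
  pile <- build_pileup(aln$alignments, fx$panel)
  cols <- pile$columns
  # bases covered by one mate only have depth 10, the mate overlap 20
  expect_true(all(cols$depth[cols$pos >= 100 & cols$pos < 180] == 10L))
  expect_true(all(cols$depth[cols$pos >= 180 & cols$pos < 230] == 20L))
  ref_count <- unname(mapply(function(r, i) cols[[r]][i], cols$ref,
                             seq_len(nrow(cols))))
  expect_equal(as.integer(ref_count), cols$depth)

  # naive per-read recount oracle at three positions
  recount <- function(pos) {
    n <- 0L
    for (i in seq_len(nrow(aln$alignments))) {
      a <- aln$alignments[i, ]
      ops <- regmatches(a$cigar, gregexpr("[0-9]+[MIDS]", a$cigar))[[1]]
      g <- a$ref_start
      for (o in ops) {
        len <- as.integer(sub("[MIDS]", "", o))
        k <- sub("[0-9]+", "", o)
        if (k %in% c("M", "D")) {
          if (pos >= g && pos < g + len) n <- n + 1L
          g <- g + len
        }
      }
    }
    n
  }
  for (p in c(100L, 200L, 309L)) {
    expect_equal(cols$depth[cols$pos == p],
                 recount(p), info = paste("pos", p))
  }

  # a read with a 1-base deletion contributes to del counts and depth
  del_read <- paste0(substr(insert, 1, 50), substr(insert, 52, 130))
  pairs2 <- rbind(pairs,
                  data.frame(id = "rdel", amplicon_id = "A",
                             seq1 = del_read, qual1 = strrep("I", 129),
                             seq2 = rc(substr(insert, 81, 210)),
                             qual2 = strrep("I", 130),
                             stringsAsFactors = FALSE))
  aln2 <- align_reads(pairs2, fx$panel, mode = "trimmed")
  pile2 <- build_pileup(aln2$alignments, fx$panel)
  expect_equal(nrow(pile2$del), 1L)
  expect_equal(pile2$del$len, 1L)
  expect_equal(pile2$del$count, 1L)
  del_pos <- pile2$del$pos
  col <- pile2$columns[pile2$columns$pos == del_pos, ]
  expect_equal(col$depth, 11L)  # 10 M reads + 1 deletion-spanning read
  expect_equal(col$del, 1L)
})

test_that("allele-fraction gates reproduce the ADO calling outcomes", {
  cp <- call_params()
  # balanced heterozygote
  vs <- call_variants(site_pileup(100L, 50L), cp)
  expect_equal(nrow(vs), 1L)
  expect_equal(vs$genotype, "het")
  expect_equal(vs$alt_fraction, 0.5)
  # ADO-suppressed allele at ~1%: far below the fraction gate
  expect_equal(nrow(call_variants(site_pileup(5484L, 54L), cp)), 0L)
  # untrimmed primer-footprint fraction ~18% < 25%
  expect_equal(nrow(call_variants(site_pileup(8670L, 1560L), cp)), 0L)
  # near-fixed alternate: homozygous call
  vs_hom <- call_variants(site_pileup(100L, 99L), cp)
  expect_equal(vs_hom$genotype, "hom")
  # depth gate
  expect_equal(nrow(call_variants(site_pileup(20L, 10L), cp)), 0L)
  # alt count gate
  expect_equal(nrow(call_variants(site_pileup(40L, 4L),
                                  call_params(min_alt_fraction = 0.05))), 0L)
})

test_that("raising the alternate-fraction threshold never adds calls", {
  set.seed(5)
  for (rep in 1:20) {
    depth <- sample(30:500, 1)
    alt <- sample(0:depth, 1)
    p <- site_pileup(depth, alt)
    fracs <- c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9)
    n_calls <- vapply(fracs, function(f) {
      nrow(call_variants(p, call_params(min_alt_fraction = f,
                                        hom_fraction = 1)))
    }, integer(1))
    expect_true(all(diff(n_calls) <= 0))
  }
})

test_that("variant-set merge keeps round-one precedence and behaves like a keyed union", {
  m1 <- variant_set("c", 297L, "C", "T", alt_fraction = 0.5, depth = 100L,
                    step = 1L)
  m1b <- variant_set("c", 297L, "C", "T", alt_fraction = 0.45, depth = 80L,
                     step = 2L)
  m2 <- variant_set("c", 302L, "G", "A", alt_fraction = 0.45, depth = 80L,
                    step = 2L)
  both <- merge_variant_sets(m1b, m2)

  merged <- merge_variant_sets(m1, both)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$step, c(1L, 2L))       # m1 kept from round one
  expect_equal(merged$alt_fraction[1], 0.5)  # the round-one record
  expect_true(merged$in_both[1])
  expect_false(merged$in_both[2])

  empty <- variant_set()
  expect_equal(nrow(merge_variant_sets(empty, empty)), 0L)
  # disjoint sets concatenate sorted by position
  disj <- merge_variant_sets(m2, m1)
  expect_equal(disj$pos, c(297L, 302L))
  # idempotence and size bound
  expect_equal(merge_variant_sets(merged, merged)$pos, merged$pos)
  expect_lte(nrow(merged), nrow(m1) + nrow(both))
  # associativity on disjoint keys
  m3 <- variant_set("c", 310L, "A", "G", step = 1L)
  left <- merge_variant_sets(merge_variant_sets(m1, m2), m3)
  right <- merge_variant_sets(m1, merge_variant_sets(m2, m3))
  expect_equal(left$pos, right$pos)
})

test_that("variant-set comparison reports sharing and new discovery rates", {
  a <- variant_set("c", 1L, "A", "T")
  b <- variant_set("c", 2L, "C", "G")
  cc <- variant_set("c", 3L, "G", "GA")
  trimming <- merge_variant_sets(merge_variant_sets(a, b), cc)
  baseline <- merge_variant_sets(a, b)

  same <- compare_variant_sets(trimming, trimming)
  expect_true(all(same$new_discovery_rate$ndr_pct == 0))

  cmp <- compare_variant_sets(trimming, baseline)
  expect_equal(nrow(cmp$shared), 2L)
  expect_equal(nrow(cmp$trimming_only), 1L)
  ndr <- cmp$new_discovery_rate
  expect_equal(ndr$ndr_pct[ndr$kind == "INS"], 100)
  expect_equal(ndr$ndr_pct[ndr$kind == "SNV"], 0)
  # overall rate on the 3-vs-2 configuration: 1/3
  expect_equal(sum(ndr$n_only) / sum(ndr$n_trimming) * 100, 100 / 3)

  rev <- compare_variant_sets(baseline, trimming)
  expect_equal(nrow(rev$baseline_only), 1L)
})

test_that("VCF output is 1-based and read/write round-trips variant sets", {
  dir <- withr::local_tempdir()
  vs <- variant_set(chrom = c("c1", "c1", "c1"),
                    pos = c(297L, 300L, 310L),
                    ref = c("C", "A", "TGA"),
                    alt = c("T", "AG", "T"),
                    genotype = c("het", "het", "hom"),
                    alt_fraction = c(0.494, 0.3, 0.8),
                    depth = c(3186L, 120L, 90L),
                    step = c(1L, 2L, 1L))
  path <- file.path(dir, "x.vcf")
  write_vcf(vs, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(sapply(strsplit(body, "\t"), `[`, 2), c("298", "301", "311"))
  back <- read_vcf(path)
  expect_equal(as.data.frame(back), as.data.frame(vs))

  # empty set: header-only VCF that reads back empty
  e <- file.path(dir, "empty.vcf")
  write_vcf(variant_set(), e)
  expect_true(all(startsWith(readLines(e), "#")))
  expect_equal(nrow(read_vcf(e)), 0L)

  # malformed input
  writeLines(c("##fileformat=VCFv4.2", "garbage with no header"),
             file.path(dir, "bad.vcf"))
  expect_error(read_vcf(file.path(dir, "bad.vcf")),
               class = "ado_vcf_parse_error")
})
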
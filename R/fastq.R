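# Minimal 4-line FASTQ I/O for read pairs. Implemented directly over text
# connections because the trimmer's error contract requires parse errors
# that name the offending record index; gzip input is handled transparently
# by R's file() connection.

parse_fastq <- function(lines, path) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    ado_error(sprintf("%s: truncated FASTQ (%d lines, record %d incomplete)",
                      path, n, n %/% 4L + 1L),
              "ado_fastq_parse_error")
  }
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  idx <- seq(1L, n, by = 4L)
  heads <- lines[idx]
  plus <- lines[idx + 2L]
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0L) {
    ado_error(sprintf("%s: malformed FASTQ record %d", path, bad[1L]),
              "ado_fastq_parse_error")
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L) {
    ado_error(sprintf(
      "%s: FASTQ record %d: sequence and quality lengths differ",
      path, bad[1L]), "ado_fastq_parse_error")
  }
  bad <- which(!is_dna(seqs))
  if (length(bad) > 0L) {
    ado_error(sprintf("%s: FASTQ record %d: non-ACGTN base", path, bad[1L]),
              "ado_fastq_parse_error")
  }
  id <- sub("\\s.*$", "", substring(heads, 2L))
  data.frame(id = id, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Read a paired-end FASTQ file pair
#'
#' Mates are matched positionally; ids must agree after stripping a
#' trailing `/1` or `/2`. Malformed records raise an
#' `ado_fastq_parse_error` naming the record index.
#'
#' @param fastq1,fastq2 paths to the read-1 and read-2 FASTQ files
#'   (optionally gzip-compressed).
#' @return Data frame of read pairs with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(fastq1, fastq2) {
  r1 <- parse_fastq(read_lines_any(fastq1), fastq1)
  r2 <- parse_fastq(read_lines_any(fastq2), fastq2)
  if (nrow(r1) != nrow(r2)) {
    ado_error(sprintf("mate files differ in record count (%d vs %d)",
                      nrow(r1), nrow(r2)), "ado_fastq_parse_error")
  }
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  if (!identical(id1, id2)) {
    bad <- which(id1 != id2)[1L]
    ado_error(sprintf("mate ids disagree at record %d ('%s' vs '%s')",
                      bad, r1$id[bad], r2$id[bad]), "ado_fastq_parse_error")
  }
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Write a paired-end FASTQ file pair
#'
#' @param pairs data frame as returned by [read_fastq_pair()].
#' @param fastq1,fastq2 output paths; a `.gz` suffix selects gzip output.
#' @return `c(fastq1, fastq2)`, invisibly.
#' @export
write_fastq_pair <- function(pairs, fastq1, fastq2) {
  write_one <- function(path, ids, seqs, quals, mate) {
    con <- open_out(path)
    on.exit(close(con))
    if (length(ids) > 0L) {
      writeLines(paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", quals),
                 con, sep = "\n")
    }
    invisible(NULL)
  }
  write_one(fastq1, pairs$id, pairs$seq1, pairs$qual1, 1L)
  write_one(fastq2, pairs$id, pairs$seq2, pairs$qual2, 2L)
  invisible(c(fastq1, fastq2))
}

# mean Phred+33 quality over all bases of a set of strings
mean_phred <- function(quals) {
  if (length(quals) == 0L) return(NA_real_)
  total <- 0; nb <- 0
  for (q in quals) {
    total <- total + sum(utf8ToInt(q) - 33L)
    nb <- nb + nchar(q)
  }
  total / nb
}
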
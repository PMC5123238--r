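# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open; conversion to 1-based happens only at the
# VCF boundary.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

ado_error <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ado_error", "error", "condition")))
}

#' @keywords internal
ref_slice <- function(ref, start0, end0) {
  substr(ref, start0 + 1L, end0)
}

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

is_dna <- function(x) {
  !grepl(sprintf("[^%s]", paste(DNA_ALPHABET, collapse = "")), x)
}

#' Hamming mismatches between read prefixes and a primer
#'
#' Vectorised over reads. `N` on either side matches anything and does not
#' count as a mismatch. Reads shorter than the primer get `NA` (no match
#' possible).
#' @noRd
prefix_mismatches <- function(seqs, primer) {
  k <- nchar(primer)
  p <- seq_chars(primer)
  out <- rep(NA_integer_, length(seqs))
  long <- !is.na(seqs) & nchar(seqs) >= k
  if (!any(long)) return(out)
  pre <- substr(seqs[long], 1L, k)
  u <- unique(pre)
  mm <- vapply(strsplit(u, "", fixed = TRUE), function(ch) {
    sum(ch != p & ch != "N" & p != "N")
  }, integer(1L))
  out[long] <- mm[match(pre, u)]
  out
}

# union of half-open intervals given as a data.frame(chrom, start, end)
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  out <- do.call(rbind, lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start[1L]; e <- d$end[1L]
    res <- list()
    for (i in seq_len(nrow(d))[-1L]) {
      if (d$start[i] <= e) {
        e <- max(e, d$end[i])
      } else {
        res[[length(res) + 1L]] <- c(s, e)
        s <- d$start[i]; e <- d$end[i]
      }
    }
    res[[length(res) + 1L]] <- c(s, e)
    m <- do.call(rbind, res)
    data.frame(chrom = d$chrom[1L], start = m[, 1L], end = m[, 2L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

read_lines_any <- function(path) {
  con <- file(path, "rt")  # file() auto-detects gzip
  on.exit(close(con))
  readLines(con)
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}
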
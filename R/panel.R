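#' Amplicon panel objects
#'
#' An amplicon panel bundles the amplicon definitions of a targeted
#' resequencing design with the reference sequences they live on. Each
#' amplicon records its primer pair in sequencing-read orientation: `ulso`
#' (upstream locus-specific oligo) is the sequence read 1 begins with, and
#' `dlso` the sequence read 2 begins with (i.e. the reverse complement of
#' the plus strand at the downstream primer footprint). The insert is the
#' amplicon with both primers excluded; `insert_start`/`insert_end` are
#' 0-based half-open genomic coordinates of the insert.
#'
#' @param name panel name.
#' @param amplicons data frame with columns `amplicon_id`, `chrom`,
#'   `insert_start`, `insert_end`, `ulso`, `dlso` (and optionally
#'   `insert_seq`, which is rederived from the reference).
#' @param reference named character vector of chromosome sequences.
#' @return An object of class `ado_panel`: a list with elements `name`,
#'   `amplicons` (data frame including the derived `insert_seq`) and
#'   `reference`.
#' @examples
#' fx <- build_fixture_panel(seed = 1)
#' fx$panel
#' @export
amplicon_panel <- function(name, amplicons, reference) {
  required <- c("amplicon_id", "chrom", "insert_start", "insert_end",
                "ulso", "dlso")
  missing_cols <- setdiff(required, names(amplicons))
  if (length(missing_cols) > 0L) {
    ado_error(sprintf("manifest is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "ado_manifest_column_error")
  }
  amplicons <- amplicons[, required, drop = FALSE]
  amplicons$insert_start <- as.integer(amplicons$insert_start)
  amplicons$insert_end <- as.integer(amplicons$insert_end)
  rownames(amplicons) <- NULL
  panel <- structure(list(name = name, amplicons = amplicons,
                          reference = reference),
                     class = "ado_panel")
  validate_panel(panel)
}

validate_panel <- function(panel) {
  amp <- panel$amplicons
  ref <- panel$reference
  if (anyDuplicated(amp$amplicon_id)) {
    dup <- unique(amp$amplicon_id[duplicated(amp$amplicon_id)])
    ado_error(sprintf("duplicate amplicon id(s): %s",
                      paste(dup, collapse = ", ")),
              "ado_duplicate_id_error")
  }
  unknown <- setdiff(unique(amp$chrom), names(ref))
  if (length(unknown) > 0L) {
    ado_error(sprintf("chromosome(s) not in reference: %s",
                      paste(unknown, collapse = ", ")),
              "ado_unknown_chrom_error")
  }
  insert_seq <- character(nrow(amp))
  for (i in seq_len(nrow(amp))) {
    a <- amp[i, ]
    if (!nzchar(a$ulso) || !nzchar(a$dlso) ||
        !is_dna(a$ulso) || !is_dna(a$dlso)) {
      ado_error(sprintf("amplicon '%s': primers must be non-empty ACGTN",
                        a$amplicon_id), "ado_manifest_column_error")
    }
    clen <- nchar(ref[[a$chrom]])
    u_start <- a$insert_start - nchar(a$ulso)
    d_end <- a$insert_end + nchar(a$dlso)
    if (a$insert_start > a$insert_end || u_start < 0L || d_end > clen) {
      ado_error(sprintf("amplicon '%s': coordinates out of range",
                        a$amplicon_id), "ado_coordinate_error")
    }
    insert_seq[i] <- ref_slice(ref[[a$chrom]], a$insert_start, a$insert_end)
    # primer orientation check against the reference (N is a wildcard)
    ulso_ref <- ref_slice(ref[[a$chrom]], u_start, a$insert_start)
    dlso_ref <- revcomp(ref_slice(ref[[a$chrom]], a$insert_end, d_end))
    if (!isTRUE(prefix_mismatches(ulso_ref, a$ulso) == 0L) ||
        !isTRUE(prefix_mismatches(dlso_ref, a$dlso) == 0L)) {
      ado_error(sprintf(
        "amplicon '%s': primer sequence disagrees with the reference",
        a$amplicon_id), "ado_reference_mismatch_error")
    }
    if ("insert_seq" %in% names(amp) && !is.null(amp$insert_seq) &&
        !is.na(amp$insert_seq[i]) && amp$insert_seq[i] != insert_seq[i]) {
      ado_error(sprintf(
        "amplicon '%s': insert_seq disagrees with the reference",
        a$amplicon_id), "ado_reference_mismatch_error")
    }
  }
  panel$amplicons$insert_seq <- insert_seq
  panel
}

MANIFEST_HEADER <- c("amplicon_id", "chrom", "insert_start", "insert_end",
                     "ulso", "dlso")

#' Read a panel manifest and its reference
#'
#' The manifest is a UTF-8, tab-separated table with header
#' `amplicon_id  chrom  insert_start  insert_end  ulso  dlso`
#' (coordinates 0-based half-open); the expected insert sequence is derived
#' from the FASTA reference and checked. Load failures raise classed errors
#' (`ado_manifest_column_error`, `ado_unknown_chrom_error`,
#' `ado_reference_mismatch_error`, `ado_duplicate_id_error`).
#'
#' @param manifest_path path to the manifest TSV.
#' @param reference_path path to the reference FASTA.
#' @param name panel name (defaults to the manifest file name).
#' @return An [amplicon_panel()] object.
#' @export
read_manifest <- function(manifest_path, reference_path,
                          name = basename(manifest_path)) {
  lines <- read_lines_any(manifest_path)
  if (length(lines) == 0L) {
    ado_error("manifest is empty (no header line)", "ado_manifest_column_error")
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, MANIFEST_HEADER)) {
    ado_error(sprintf("manifest header must be exactly: %s",
                      paste(MANIFEST_HEADER, collapse = "\t")),
              "ado_manifest_column_error")
  }
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) == 0L) {
    amp <- data.frame(amplicon_id = character(0), chrom = character(0),
                      insert_start = integer(0), insert_end = integer(0),
                      ulso = character(0), dlso = character(0),
                      stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != length(MANIFEST_HEADER))) {
      ado_error("manifest row with wrong number of fields",
                "ado_manifest_column_error")
    }
    m <- do.call(rbind, fields)
    amp <- data.frame(amplicon_id = m[, 1L], chrom = m[, 2L],
                      insert_start = as.integer(m[, 3L]),
                      insert_end = as.integer(m[, 4L]),
                      ulso = toupper(m[, 5L]), dlso = toupper(m[, 6L]),
                      stringsAsFactors = FALSE)
  }
  reference <- read_reference(reference_path)
  amplicon_panel(name, amp, reference)
}

read_reference <- function(reference_path) {
  ref <- Biostrings::readDNAStringSet(reference_path)
  out <- as.character(ref)
  names(out) <- sub("\\s.*$", "", names(ref))
  out
}

#' Write a panel back to manifest TSV and reference FASTA
#'
#' Inverse of [read_manifest()]; `read_manifest(write_manifest(...))` is the
#' identity on the manifest dialect.
#'
#' @param panel an [amplicon_panel()].
#' @param manifest_path output manifest path.
#' @param reference_path optional output FASTA path.
#' @return `manifest_path`, invisibly.
#' @export
write_manifest <- function(panel, manifest_path, reference_path = NULL) {
  amp <- panel$amplicons
  con <- open_out(manifest_path)
  writeLines(paste(MANIFEST_HEADER, collapse = "\t"), con)
  if (nrow(amp) > 0L) {
    writeLines(paste(amp$amplicon_id, amp$chrom, amp$insert_start,
                     amp$insert_end, amp$ulso, amp$dlso, sep = "\t"), con)
  }
  close(con)
  if (!is.null(reference_path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(panel$reference), reference_path)
  }
  invisible(manifest_path)
}

#' Genomic footprints of the panel primers
#'
#' The upstream primer footprint is `[insert_start - len(ulso),
#' insert_start)` and the downstream one `[insert_end, insert_end +
#' len(dlso))`, both 0-based half-open on the plus strand. Variants falling
#' in these intervals disrupt primer hybridisation and can cause allele
#' drop-out.
#'
#' @param panel an [amplicon_panel()].
#' @return Data frame with one row per amplicon and primer: `amplicon_id`,
#'   `primer` (`"ULSO"`/`"DLSO"`), `chrom`, `start`, `end`.
#' @export
primer_footprints <- function(panel) {
  amp <- panel$amplicons
  if (nrow(amp) == 0L) {
    return(data.frame(amplicon_id = character(0), primer = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- rbind(
    data.frame(amplicon_id = amp$amplicon_id, primer = "ULSO",
               chrom = amp$chrom,
               start = amp$insert_start - nchar(amp$ulso),
               end = amp$insert_start, stringsAsFactors = FALSE),
    data.frame(amplicon_id = amp$amplicon_id, primer = "DLSO",
               chrom = amp$chrom, start = amp$insert_end,
               end = amp$insert_end + nchar(amp$dlso),
               stringsAsFactors = FALSE))
  out <- out[order(match(out$amplicon_id, amp$amplicon_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Primer list table
#'
#' One row per amplicon, manifest order preserved: the primer pair used for
#' read assignment. Duplicate primer sequences across amplicons are allowed
#' and preserved (ambiguity is resolved by the trimmer's tie-breaking rule).
#'
#' @param panel an [amplicon_panel()].
#' @return Data frame with columns `amplicon_id`, `ulso`, `dlso`.
#' @export
generate_primer_list <- function(panel) {
  panel$amplicons[, c("amplicon_id", "ulso", "dlso"), drop = FALSE]
}

# union of insert intervals: the calling target regions
panel_targets <- function(panel) {
  amp <- panel$amplicons
  merge_intervals(data.frame(chrom = amp$chrom, start = amp$insert_start,
                             end = amp$insert_end, stringsAsFactors = FALSE))
}

#' @export
print.ado_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel '%s': %d amplicon(s), %d reference sequence(s)\n",
              x$name, nrow(x$amplicons), length(x$reference)))
  if (nrow(x$amplicons) > 0L) {
    amp <- x$amplicons
    cat(sprintf("  %s %s:[%d,%d) ulso=%dnt dlso=%dnt insert=%dnt\n",
                amp$amplicon_id, amp$chrom, amp$insert_start, amp$insert_end,
                nchar(amp$ulso), nchar(amp$dlso), nchar(amp$insert_seq)),
        sep = "")
  }
  invisible(x)
}
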
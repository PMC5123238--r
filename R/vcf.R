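# VCF 4.2 output and input for variant sets. The writer emits a minimal
# single-sample VCF (INFO STEP/AF/DP, FORMAT GT); internal 0-based
# positions are converted to 1-based POS here and nowhere else. Reading
# goes through vcfR.

vcf_header <- function(panel = NULL) {
  h <- c("##fileformat=VCFv4.2",
         "##source=adotrim",
         "##INFO=<ID=STEP,Number=1,Type=Integer,Description=\"Variant calling round (1 or 2)\">",
         "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
         "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Column depth at the call\">",
         "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(panel)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(panel$reference),
                      nchar(panel$reference)))
  }
  c(h, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT", "SAMPLE", sep = "\t"))
}

#' Write a variant set as VCF 4.2
#'
#' @param vs a [variant_set()].
#' @param path output path.
#' @param panel optional panel; adds `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, panel = NULL) {
  con <- open_out(path)
  on.exit(close(con))
  writeLines(vcf_header(panel), con)
  if (nrow(vs) > 0L) {
    info <- sprintf("STEP=%d;AF=%g;DP=%d", vs$step, vs$alt_fraction,
                    vs$depth)
    gt <- ifelse(vs$genotype == "hom", "1/1", "0/1")
    writeLines(paste(vs$chrom, vs$pos + 1L, ".", vs$ref, vs$alt, ".",
                     "PASS", info, "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF file back into a variant set
#'
#' Accepts the VCFs produced by [write_vcf()] (and any single-allele VCF
#' with STEP/AF/DP INFO fields). `read_vcf(write_vcf(vs))` is the
#' identity on variant sets. Malformed files raise an
#' `ado_vcf_parse_error`.
#'
#' @param path VCF path.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  # structural pre-checks: vcfR's parser is not robust to files without a
  # #CHROM header line
  lines <- read_lines_any(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L || !any(startsWith(lines, "##fileformat=VCF"))) {
    ado_error(sprintf("'%s' is not a VCF file (missing header)", path),
              "ado_vcf_parse_error")
  }
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) > 0L &&
      any(lengths(strsplit(body, "\t", fixed = TRUE)) < 8L)) {
    ado_error(sprintf("VCF '%s' has a record with fewer than 8 fields",
                      path), "ado_vcf_parse_error")
  }
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) {
      ado_error(sprintf("failed to parse VCF '%s': %s", path,
                        conditionMessage(e)), "ado_vcf_parse_error")
    })
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(variant_set())
  needed <- c("CHROM", "POS", "REF", "ALT", "INFO")
  if (!all(needed %in% names(fix))) {
    ado_error(sprintf("VCF '%s' lacks mandatory columns", path),
              "ado_vcf_parse_error")
  }
  info_field <- function(info, key) {
    pat <- paste0("(^|;)", key, "=([^;]*)")
    out <- rep(NA_character_, length(info))
    m <- regexec(pat, info)
    hit <- vapply(m, function(x) x[1L] != -1L, logical(1L))
    out[hit] <- vapply(regmatches(info[hit], m[hit]), `[`, character(1L), 3L)
    out
  }
  step <- suppressWarnings(as.integer(info_field(fix$INFO, "STEP")))
  af <- suppressWarnings(as.numeric(info_field(fix$INFO, "AF")))
  dp <- suppressWarnings(as.integer(info_field(fix$INFO, "DP")))
  gt <- if (ncol(vcf@gt) >= 2L) {
    sub(":.*$", "", vcf@gt[, 2L])
  } else {
    rep("0/1", nrow(fix))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    ado_error(sprintf("VCF '%s' has a non-numeric POS", path),
              "ado_vcf_parse_error")
  }
  variant_set(chrom = fix$CHROM, pos = pos - 1L, ref = fix$REF,
              alt = fix$ALT,
              genotype = ifelse(gt == "1/1", "hom", "het"),
              alt_fraction = af, depth = dp,
              step = ifelse(is.na(step), 1L, step))
}
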
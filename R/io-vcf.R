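#' Write pooled variant records as VCF v4.2
#'
#' Emits one biallelic record per site with a FORMAT field `AD`
#' (ref,alt read depths) for the two pool samples.
#'
#' @param records data.frame of variant site records (see
#'   [simulate_pool_depths()]).
#' @param path output path.
#' @param sample_S,sample_T sample column names for the sensitive and
#'   tolerant pools.
#' @param contig_lengths optional named integer vector for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(records, path, sample_S = "S", sample_T = "T",
                           contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsascreen",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">'
  ), con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), contig_lengths), con)
  }
  writeLines(sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s\t%s",
                     sample_S, sample_T), con)
  if (nrow(records) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                       records$contig, records$pos, records$ref, records$alt,
                       records$ref_depth_S, records$alt_depth_S,
                       records$ref_depth_T, records$alt_depth_T), con)
  }
  invisible(path)
}

#' Read pooled allele depths from a VCF
#'
#' Extracts per-pool (ref, alt) read depths from the `AD` FORMAT field of
#' two named samples. Multiallelic sites are decomposed by keeping the first
#' ALT allele (with a warning); the variant kind is inferred from allele
#' lengths (SNP iff both alleles are single bases). Record order is
#' preserved. Indices downstream are computed strictly from AD, never DP.
#'
#' @param path VCF file path.
#' @param sample_S,sample_T names of the sensitive- and tolerant-pool sample
#'   columns.
#' @return A data.frame of variant site records (columns as in
#'   [simulate_pool_depths()]).
#' @export
read_vcf_pools <- function(path, sample_S = "S", sample_T = "T") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1L]
  for (s in c(sample_S, sample_T)) {
    if (!s %in% have) {
      stop_fmt("sample '%s' not found in VCF; available samples: %s",
               s, paste(have, collapse = ", "))
    }
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (nrow(vcf@fix) > 0L &&
      !all(vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1)))) {
    stop_fmt("VCF '%s': AD missing from FORMAT on one or more records", path)
  }
  n <- nrow(vcf@fix)
  if (n == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      kind = character(),
                      ref_depth_S = integer(), alt_depth_S = integer(),
                      ref_depth_T = integer(), alt_depth_T = integer(),
                      stringsAsFactors = FALSE))
  }
  ref <- vcf@fix[, "REF"]
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf(
      "%d multiallelic site(s): keeping the first ALT allele, dropping the rest",
      sum(multi)), call. = FALSE)
    alt <- sub(",.*$", "", alt)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x, sample) {
    parts <- strsplit(x, ",", fixed = TRUE)
    bad <- which(is.na(x) | lengths(parts) < 2L)
    if (length(bad)) {
      stop_fmt("VCF '%s': malformed or missing AD for sample %s at record %d",
               path, sample, bad[1L])
    }
    rd <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    ad1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    bad <- which(is.na(rd) | is.na(ad1) | rd < 0L | ad1 < 0L)
    if (length(bad)) {
      stop_fmt("VCF '%s': non-numeric or negative AD for sample %s at record %d",
               path, sample, bad[1L])
    }
    cbind(rd, ad1)
  }
  ad_S <- parse_ad(ad[, sample_S], sample_S)
  ad_T <- parse_ad(ad[, sample_T], sample_T)
  pos <- suppressWarnings(as.integer(vcf@fix[, "POS"]))
  if (any(is.na(pos) | pos < 1L)) {
    stop_fmt("VCF '%s': invalid POS at record %d", path,
             which(is.na(pos) | pos < 1L)[1L])
  }
  if (any(grepl("[^ACGTN]", c(ref, alt)))) {
    stop_fmt("VCF '%s': REF/ALT alleles must be A/C/G/T/N sequences", path)
  }
  data.frame(
    contig = vcf@fix[, "CHROM"], pos = pos, ref = ref, alt = alt,
    kind = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel"),
    ref_depth_S = ad_S[, 1L], alt_depth_S = ad_S[, 2L],
    ref_depth_T = ad_T[, 1L], alt_depth_T = ad_T[, 2L],
    stringsAsFactors = FALSE, row.names = NULL
  )
}
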
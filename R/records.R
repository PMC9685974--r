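#' Build variant join keys
#'
#' A variant is identified everywhere in the package by the string
#' `chrom:pos:ref:alt`. Coordinates are 1-based as in VCF; the transcript
#' HGVS notation, when available, is carried alongside for display only and
#' never used for joining.
#'
#' @param chrom chromosome label (any non-empty string).
#' @param pos 1-based position, `>= 1`.
#' @param ref,alt reference and alternate allele strings; must differ.
#' @return character vector of keys.
#' @examples
#' variant_key("7", 2710, "C", "T")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) .stop2("variant positions must be integers >= 1")
  if (any(!nzchar(chrom))) .stop2("chromosome labels must be non-empty")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (any(ref == alt)) .stop2("ref and alt alleles must differ")
  if (any(!grepl("^[ACGTN]+$", c(ref, alt)))) .stop2("alleles must be nucleotide strings (ACGTN)")
  paste(chrom, pos, ref, alt, sep = ":")
}

.CONSEQUENCES <- c("nonsynonymous_snv", "frameshift_insertion",
                   "frameshift_deletion", "stopgain", "other")
.ACMG <- c("pathogenic", "likely_pathogenic", "uncertain",
           "likely_benign", "benign", "unknown")
.REGION_FLAGS <- c("repetitive", "polymorphic_locus",
                   "segmental_duplication", "homopolymer")

#' Annotated variant table
#'
#' Validates and classes a data frame of annotated candidate variants, one
#' row per (decomposed) alternate allele. Required columns: `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `consequence`. Optional columns receive permissive
#' defaults: `cadd` (`NA`), `maf_reference` (`NA`, meaning *unreported*,
#' which is distinct from 0), `qc_pass` (`TRUE`), `acmg` (`"unknown"`),
#' `region_flags` (empty; semicolon-separated subset of
#' `r paste(.REGION_FLAGS, collapse = ", ")`), `review_pass` (`NA`, meaning
#' not reviewed), `hgvs` (`NA`).
#'
#' @param df data frame as described above.
#' @return the validated data frame with a `key` column, classed
#'   `variant_records`.
#' @export
variant_records <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(req, names(df))
  if (length(miss)) .stop2("variant table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$key)) .stop2("duplicated variant keys: ",
    paste(unique(df$key[duplicated(df$key)]), collapse = ", "))
  bad <- !df$consequence %in% .CONSEQUENCES
  if (any(bad)) .stop2("unknown consequence class: ", paste(unique(df$consequence[bad]), collapse = ", "))
  if (is.null(df$cadd)) df$cadd <- NA_real_
  if (any(!is.na(df$cadd) & df$cadd < 0)) .stop2("scaled CADD scores must be >= 0")
  if (is.null(df$maf_reference)) df$maf_reference <- NA_real_
  mr <- df$maf_reference
  if (any(!is.na(mr) & (mr < 0 | mr > 1))) .stop2("maf_reference must lie in [0, 1]")
  if (is.null(df$qc_pass)) df$qc_pass <- TRUE
  if (is.null(df$acmg)) df$acmg <- "unknown"
  if (any(!df$acmg %in% .ACMG)) .stop2("unknown ACMG class")
  if (is.null(df$region_flags)) df$region_flags <- ""
  df$region_flags[is.na(df$region_flags)] <- ""
  fl <- setdiff(unlist(strsplit(df$region_flags, ";", fixed = TRUE)), "")
  if (any(!fl %in% .REGION_FLAGS)) .stop2("unknown region flag: ",
    paste(setdiff(fl, .REGION_FLAGS), collapse = ", "))
  if (is.null(df$review_pass)) df$review_pass <- NA
  df$review_pass <- as.logical(df$review_pass)
  if (is.null(df$hgvs)) df$hgvs <- NA_character_
  class(df) <- c("variant_records", "data.frame")
  df
}

# TRUE for rows carrying any of the given region flags
has_region_flag <- function(records, flags) {
  vapply(strsplit(records$region_flags, ";", fixed = TRUE),
         function(f) any(f %in% flags), logical(1))
}
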
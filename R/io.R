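# Readers and writers for the external representations: per-sample
# genotypes (VCF or flat summary), aggregate frequency panels, gene lists
# and the association result table.

# dosage of alt allele j in a GT string like "0/1", "1|2", "./."
.gt_dosage <- function(gt, j) {
  alleles <- strsplit(sub(":.*$", "", gt), "[/|]")
  vapply(alleles, function(al) {
    if (!length(al) || anyNA(al) || any(al == ".")) return(NA_integer_)
    sum(al == as.character(j))
  }, integer(1))
}

#' Read case genotypes from a VCF or a flat summary table
#'
#' VCF input (`.vcf`) is parsed with \pkg{vcfR}; multi-allelic sites are
#' decomposed into one record per alternate allele, dosages are taken from
#' the GT field, and each missing genotype reduces that variant's allele
#' number by 2. A flat tab-delimited file must carry columns
#' `chrom, pos, ref, alt, carriers` and may add `alt_alleles` and
#' `allele_number`.
#'
#' @param path input file.
#' @param cohort_size number of diploid individuals; mandatory for flat
#'   input, checked against the sample columns for VCF input.
#' @param name cohort label.
#' @return a [case_cohort()]; for VCF input the per-sample dosage matrix is
#'   retained in `$genotypes`.
#' @export
read_case_genotypes <- function(path, cohort_size = NULL, name = "cases") {
  if (!file.exists(path)) .stop2("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) .stop2("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix  # always a matrix, unlike the getFIX accessor on 1-row files
    gt <- vcfR::extract.gt(v, element = "GT")
    n_samples <- ncol(gt)
    if (!is.null(cohort_size) && n_samples != cohort_size)
      .stop2("VCF has ", n_samples, " samples but cohort_size = ", cohort_size)
    rows <- list(); geno <- list()
    for (r in seq_len(nrow(fix))) {
      alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]]
      for (j in seq_along(alts)) {
        dose <- .gt_dosage(gt[r, ], j)
        if (any(!is.na(dose) & !dose %in% 0:2))
          .stop2("dosage outside {0,1,2} at ", fix[r, "CHROM"], ":", fix[r, "POS"])
        key <- variant_key(fix[r, "CHROM"], as.integer(fix[r, "POS"]),
                           fix[r, "REF"], alts[j])
        rows[[length(rows) + 1L]] <- data.frame(
          key = key,
          carriers = sum(dose >= 1L, na.rm = TRUE),
          alt_alleles = sum(dose, na.rm = TRUE),
          allele_number = 2L * (n_samples - sum(is.na(dose))),
          stringsAsFactors = FALSE)
        geno[[key]] <- dose
      }
    }
    calls <- if (length(rows)) do.call(rbind, rows) else
      data.frame(key = character(), carriers = integer(),
                 alt_alleles = integer(), allele_number = integer())
    gm <- if (length(geno)) do.call(rbind, geno) else NULL
    case_cohort(calls, n_individuals = n_samples, name = name, genotypes = gm)
  } else {
    if (is.null(cohort_size)) .stop2("cohort_size is required for flat input")
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character", ref = "character",
                                     alt = "character"))
    req <- c("chrom", "pos", "ref", "alt", "carriers")
    if (!all(req %in% names(tab)))
      .stop2("flat case table needs columns: ", paste(req, collapse = ", "))
    calls <- data.frame(key = variant_key(tab$chrom, tab$pos, tab$ref, tab$alt),
                        carriers = tab$carriers, stringsAsFactors = FALSE)
    if (!is.null(tab$alt_alleles)) calls$alt_alleles <- tab$alt_alleles
    if (!is.null(tab$allele_number)) calls$allele_number <- tab$allele_number
    case_cohort(calls, n_individuals = cohort_size, name = name)
  }
}

#' Write a case cohort as a flat summary table
#'
#' Inverse of the flat branch of [read_case_genotypes()]: counts and allele
#' numbers round-trip exactly.
#'
#' @param cohort a [case_cohort()].
#' @param path output file.
#' @export
write_case_genotypes <- function(cohort, path) {
  parts <- strsplit(cohort$calls$key, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = vapply(parts, `[`, "", 2L),
                    ref = vapply(parts, `[`, "", 3L),
                    alt = vapply(parts, `[`, "", 4L),
                    carriers = cohort$calls$carriers,
                    alt_alleles = cohort$calls$alt_alleles,
                    allele_number = cohort$calls$allele_number,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aggregate allele-frequency panel
#'
#' Tab-delimited input with columns `chrom, pos, ref, alt, af` and
#' optionally `an`. Frequencies may be given as fractions (default) or
#' percentages (`dialect = "percent"`, divided by 100 on input). Rows with
#' a missing frequency are marked absent from the panel.
#'
#' @param path input file.
#' @param n_individuals diploid panel size; supplies the default allele
#'   number `2 * n_individuals` where `an` is missing.
#' @param name cohort label.
#' @param dialect `"fraction"` or `"percent"`.
#' @return a [frequency_table()].
#' @export
read_control_frequencies <- function(path, n_individuals, name = "controls",
                                     dialect = c("fraction", "percent")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stop2("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", ref = "character",
                                   alt = "character"))
  req <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(req %in% names(tab))) .stop2("frequency table needs columns: ", paste(req, collapse = ", "))
  af <- suppressWarnings(as.numeric(tab$af))
  if (dialect == "percent") af <- af / 100
  if (any(!is.na(af) & (af < 0 | af > 1)))
    .stop2("allele frequencies outside [0, 1] after dialect handling")
  out <- data.frame(key = variant_key(tab$chrom, tab$pos, tab$ref, tab$alt),
                    af = af, stringsAsFactors = FALSE)
  if (!is.null(tab$an)) out$an <- tab$an
  frequency_table(out, n_individuals = n_individuals, name = name)
}

#' Write an aggregate allele-frequency panel
#'
#' @param ft a [frequency_table()].
#' @param path output file.
#' @export
write_control_frequencies <- function(ft, path) {
  parts <- strsplit(ft$table$key, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = vapply(parts, `[`, "", 2L),
                    ref = vapply(parts, `[`, "", 3L),
                    alt = vapply(parts, `[`, "", 4L),
                    af = ft$table$af, an = ft$table$an,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cancer-gene lists into a gene-evidence table
#'
#' The primary list (e.g. an NCG-style known/candidate cancer-gene list)
#' defines first-pass eligibility; each additional list corroborates.
#' Symbols are matched case-insensitively, one per line; blank lines and
#' `#` comments are ignored. A gene is *eligible* for the cascade's gene
#' stage when it is on the primary list and on at least one other list.
#'
#' @param primary path to the primary list; must be non-empty.
#' @param others named character vector/list of corroborating list paths.
#' @return data frame with columns `gene` (upper case),
#'   `in_primary_list` and `corroborating_lists` (semicolon-separated list
#'   names, empty when none), covering every gene seen in any list.
#' @export
read_gene_lists <- function(primary, others = character()) {
  read_one <- function(p) {
    if (!file.exists(p)) .stop2("no such file: ", p)
    x <- trimws(readLines(p, warn = FALSE))
    toupper(x[nzchar(x) & !startsWith(x, "#")])
  }
  prim <- unique(read_one(primary))
  if (!length(prim)) .stop2("primary gene list is empty: ", primary)
  other_sets <- lapply(others, read_one)
  genes <- sort(unique(c(prim, unlist(other_sets))))
  corr <- vapply(genes, function(g) {
    hit <- names(other_sets)[vapply(other_sets, function(s) g %in% s, logical(1))]
    paste(hit, collapse = ";")
  }, character(1))
  data.frame(gene = genes, in_primary_list = genes %in% prim,
             corroborating_lists = unname(corr), stringsAsFactors = FALSE)
}

# significance stars matching the usual table convention
.stars <- function(q) {
  ifelse(is.na(q), "",
         ifelse(q < 0.001, "***", ifelse(q < 0.01, "**", ifelse(q < 0.05, "*", ""))))
}

#' Write an association result table
#'
#' Tab-delimited, one row per variant per comparison, with significance
#' stars on the adjusted p-value (`***` < 0.001, `**` < 0.01, `*` < 0.05)
#' and infinite odds ratios serialized as `Inf`.
#'
#' @param results one `association_results` data frame or a list of them.
#' @param path output file.
#' @param variants optional [variant_records()] used to fill the gene
#'   column.
#' @export
write_association_table <- function(results, path, variants = NULL) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results) || !sum(vapply(results, nrow, 0L))) .stop2("no results to write")
  res <- do.call(rbind, results)
  gene <- if (!is.null(variants)) variants$gene[match(res$key, variants$key)] else NA_character_
  out <- data.frame(key = res$key, gene = gene, comparison = res$comparison,
                    case_af = res$case_af, control_af = res$control_af,
                    or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
                    p_raw = res$p_raw, p_adjusted = res$p_adjusted,
                    stars = .stars(res$p_adjusted),
                    status = res$status, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the carrier matrix for selected variants
#'
#' Variants x cases dosage table (the data layer of an oncoplot), available
#' when the case cohort was read from a per-sample source.
#'
#' @param cohort a [case_cohort()] with retained genotypes.
#' @param keys variant keys to include (default: all).
#' @param path output file.
#' @export
write_carrier_matrix <- function(cohort, path, keys = NULL) {
  if (is.null(cohort$genotypes)) .stop2("cohort has no per-sample genotypes")
  gm <- cohort$genotypes
  if (!is.null(keys)) gm <- gm[rownames(gm) %in% keys, , drop = FALSE]
  write.table(data.frame(key = rownames(gm), gm, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
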
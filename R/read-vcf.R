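#' Read a multi-sample VCF into a genotype table
#'
#' Keeps biallelic SNP records only; multiallelic and indel records are
#' skipped and counted. VCF positions (1-based) are converted to the
#' package-internal 0-based convention. Site depth (`INFO/DP`) and RMS
#' mapping quality (`INFO/MQ`) are carried along; absent values become `NA`,
#' never 0.
#'
#' @param path Path to a VCF 4.x file (plain or bgzip).
#' @param samples Optional character vector restricting to a sample subset.
#' @return A [genotype_table()] with attributes `n_skipped` (records dropped
#'   as non-biallelic-SNP) and `skip_reason` (a named count breakdown).
#' @seealso [write_vcf()] for the inverse.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | alt == ".")
  keep <- !multi & !indel
  skip_reason <- c(multiallelic = sum(multi), indel_or_other = sum(indel))

  gt_chr <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_chr))) gt_chr <- matrix(gt_chr, nrow = nrow(fix),
                                             dimnames = list(NULL, colnames(v@gt)[-1]))
  all_samples <- colnames(gt_chr)
  if (!is.null(samples)) {
    missing <- setdiff(samples, all_samples)
    if (length(missing)) {
      stop("samples absent from VCF header: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    gt_chr <- gt_chr[, samples, drop = FALSE]
    all_samples <- samples
  }

  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))

  gt_chr <- gt_chr[keep, , drop = FALSE]
  dosage <- dosage_from_gt_strings(gt_chr)
  colnames(dosage) <- all_samples

  sites <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]) - 1L,
    ref = ref[keep],
    alt = alt[keep],
    dp = dp[keep],
    mq = mq[keep]
  )
  out <- genotype_table(sites, dosage)
  attr(out, "n_skipped") <- sum(!keep)
  attr(out, "skip_reason") <- skip_reason
  out
}

# "0/1", "0|1", "./.", "1", "." -> alt dosage; any missing allele -> NA call
dosage_from_gt_strings <- function(m) {
  flat <- gsub("|", "/", as.character(m), fixed = TRUE)
  u <- unique(flat)
  dos <- vapply(strsplit(u, "/", fixed = TRUE), function(a) {
    if (any(is.na(a)) || any(a == ".") || length(a) == 0L) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
  out <- dos[match(flat, u)]
  matrix(out, nrow = nrow(m), ncol = ncol(m))
}

#' Write a genotype table as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with `INFO/DP`, `INFO/MQ` and per-sample `GT`
#' fields, converting internal 0-based positions back to the 1-based VCF
#' convention. `read_vcf(write_vcf(x))` reproduces genotypes and site fields
#' exactly.
#'
#' @param gt A genotype table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  samples <- gt_samples(gt)
  m <- gt_dosage(gt)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[m + 1L], nrow = nrow(m))
  gt_str[is.na(m)] <- "./."
  info <- paste0(
    ifelse(is.na(gt$dp), "", paste0("DP=", gt$dp)),
    ifelse(is.na(gt$dp) | is.na(gt$mq), "", ";"),
    ifelse(is.na(gt$mq), "", paste0("MQ=", format_num(gt$mq)))
  )
  info[info == ""] <- "."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(gt$chrom, gt$pos + 1L, ".", gt$ref, gt$alt, ".", "PASS",
                info, "GT",
                apply(gt_str, 1L, paste, collapse = "\t"),
                sep = "\t")
  if (nrow(gt) == 0L) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

# locale-independent, full-precision numeric formatting for text outputs
format_num <- function(x) {
  out <- vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), character(1))
  out[is.na(x)] <- "NA"
  out
}
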
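# shared fixture builders; everything is generated in code at test time

# genotype table from an explicit dosage matrix (sites x samples)
gt_from_dosage <- function(dosage, chrom = "chr1", pos = NULL,
                           dp = 30L, mq = 60) {
  n <- nrow(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("s", seq_len(ncol(dosage)))
  }
  genotype_table(
    tibble::tibble(chrom = chrom,
                   pos = pos %||% (seq_len(n) * 10L),
                   ref = "A", alt = "T",
                   dp = rep_len(dp, n), mq = rep_len(mq, n)),
    dosage
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random two-group diploid fixture (<= 20 samples, <= 50 sites)
random_fixture <- function(seed, max_samples = 20, max_sites = 50,
                           missing_rate = 0) {
  set.seed(seed)
  n1 <- sample(2:(max_samples %/% 2), 1)
  n2 <- sample(2:(max_samples %/% 2), 1)
  n_sites <- sample(5:max_sites, 1)
  freq <- stats::runif(n_sites, 0.05, 0.95)
  dosage <- sapply(seq_len(n1 + n2), function(i)
    stats::rbinom(n_sites, 2, freq))
  if (missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < missing_rate] <- NA
  }
  colnames(dosage) <- paste0("s", seq_len(n1 + n2))
  list(gt = gt_from_dosage(dosage, pos = sort(sample(0:9999, n_sites))),
       group1 = paste0("s", seq_len(n1)),
       group2 = paste0("s", n1 + seq_len(n2)))
}

# one window covering an entire fixture
whole_window <- function(gt, length_bp = NULL) {
  tibble::tibble(chrom = gt$chrom[1], start = 0L,
                 end = as.integer(length_bp %||% (max(gt$pos) + 1L)))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal VCF text for hand-built cases
toy_vcf_lines <- function(records, samples = c("s1", "s2", "s3", "s4")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"rms mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records)
}

# the six-site filter fixture: five sites each violating exactly one
# criterion (DP=4; DP=150; MQ=10; maf=0.05; missing=0.2) plus one clean site
six_site_fixture <- function() {
  dosage <- rbind(
    rep(1L, 10),                                  # DP too low
    rep(1L, 10),                                  # DP too high
    rep(1L, 10),                                  # MQ too low
    c(1L, rep(0L, 9)),                            # maf 1/20 = 0.05
    c(NA, NA, rep(1L, 8)),                        # missing 2/10 = 0.2
    rep(1L, 10)                                   # passes everything
  )
  colnames(dosage) <- paste0("s", 1:10)
  gt_from_dosage(dosage,
                 dp = c(4L, 150L, 30L, 30L, 30L, 30L),
                 mq = c(60, 60, 10, 60, 60, 60))
}

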
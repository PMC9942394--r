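#' Read gene annotations from BED or GFF3
#'
#' Both formats are normalised to the package-internal 0-based half-open
#' interval convention (BED's native convention; GFF3's 1-based inclusive
#' coordinates are shifted at the boundary). For GFF3, only `gene`-type
#' records are retained. `gene_name` falls back to `gene_id` when absent.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gff3"`; guessed from the file extension when
#'   omitted.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `gene_id`, `gene_name`.
#' @export
read_gene_annotations <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    gene_id <- if ("ID" %in% names(df)) as.character(df$ID) else
      if ("gene_id" %in% names(df)) as.character(df$gene_id) else
        paste0("gene", seq_len(nrow(df)))
    gene_name <- if ("Name" %in% names(df)) as.character(df$Name) else
      NA_character_
  } else {
    gene_id <- if ("name" %in% names(df)) as.character(df$name) else
      paste0("gene", seq_len(nrow(df)))
    gene_name <- NA_character_
  }
  gene_name <- dplyr::coalesce(gene_name, gene_id)
  out <- tibble::tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start) - 1L,  # GRanges is 1-based inclusive
    end = as.integer(df$end),
    strand = as.character(df$strand),
    gene_id = gene_id,
    gene_name = gene_name
  )
  bad <- out$start >= out$end
  if (any(bad)) {
    warning(sum(bad), " annotation record(s) with start >= end dropped",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}
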
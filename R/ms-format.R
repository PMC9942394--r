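#' Write haplotype blocks in ms format
#'
#' Emits the standard text dialect of Hudson's coalescent simulator: each
#' replicate is introduced by `//`, followed by `segsites: k`, a
#' `positions:` line of relative positions in \[0, 1\], and one 0/1 row per
#' haplotype. [read_ms()] is the exact inverse.
#'
#' @param blocks A single haplotype block or list of blocks. A block is a
#'   list with `haps` (0/1 integer matrix, haplotypes x sites) and
#'   `positions` (sorted numeric vector in \[0, 1\], length `ncol(haps)`),
#'   as produced by [simulate_neutral_iwm()].
#' @param path Output path, or `NULL` to return the lines invisibly.
#' @param header Optional first two header lines (command line and seeds);
#'   defaults to a minimal stub.
#' @return The character vector of lines, invisibly.
#' @export
write_ms <- function(blocks, path = NULL, header = NULL) {
  if (!is.null(blocks$haps)) blocks <- list(blocks)
  lines <- header %||% c("ms (sweepscan)", "0 0 0")
  for (b in blocks) {
    haps <- b$haps
    pos <- b$positions
    if (!is.matrix(haps)) haps <- matrix(haps, nrow = length(haps))
    if (ncol(haps) != length(pos)) {
      stop("haplotype width (", ncol(haps), ") != number of positions (",
           length(pos), ")", call. = FALSE)
    }
    lines <- c(lines, "", "//", paste0("segsites: ", ncol(haps)))
    if (ncol(haps) > 0L) {
      lines <- c(lines,
                 paste("positions:", paste(sprintf("%.6f", pos), collapse = " ")),
                 apply(haps, 1L, paste, collapse = ""))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read ms-format haplotype blocks
#'
#' @param path Path to an ms-format file, or a character vector of lines.
#' @return A list of haplotype blocks (`haps`, `positions`); see [write_ms()].
#' @export
read_ms <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  starts <- which(trimws(lines) == "//")
  if (!length(starts)) stop("no '//' replicate separator found", call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[nzchar(trimws(chunk))]
    seg_line <- grep("^segsites:", chunk, value = TRUE)
    if (!length(seg_line)) stop("replicate ", i, " missing 'segsites:'",
                                call. = FALSE)
    k <- as.integer(sub("^segsites:\\s*", "", seg_line[1]))
    if (k == 0L) {
      return(list(haps = matrix(integer(0), nrow = 0, ncol = 0),
                  positions = numeric(0)))
    }
    pos_line <- grep("^positions:", chunk, value = TRUE)[1]
    positions <- as.numeric(strsplit(trimws(sub("^positions:", "", pos_line)),
                                     "\\s+")[[1]])
    rows <- chunk[grepl("^[01]+$", chunk)]
    haps <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    if (ncol(haps) != k) stop("replicate ", i, ": row width != segsites",
                              call. = FALSE)
    list(haps = haps, positions = positions)
  })
}
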
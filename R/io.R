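#' Read and write the plain-text formats used by the pipeline
#'
#' Thin wrappers around [utils::read.table()]/[utils::write.table()] with the
#' conventions used throughout the package: tab separation, a header line,
#' no quoting, no row names. BED files follow the BED6 convention (0-based
#' half-open coordinates, no header).
#'
#' @param path file path.
#' @param x data frame to write.
#' @name io
NULL

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED6 file of genomic intervals
#'
#' Coordinates are 0-based half-open as in the BED standard. Intervals with
#' `start >= end` are rejected with the offending line numbers.
#'
#' @param path path to a BED6 (or BED3+) file without header.
#' @return data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing trailing columns filled with defaults).
#' @export
read_bed6 <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(ncol(x))]
  if (is.null(x$name)) x$name <- paste0("iv", seq_len(nrow(x)))
  if (is.null(x$score)) x$score <- 0L
  if (is.null(x$strand)) x$strand <- "."
  validate_intervals(x, what = basename(path))
  x[, cols]
}

#' @rdname read_bed6
#' @param x data frame with at least `chrom`, `start`, `end`.
#' @export
write_bed6 <- function(x, path) {
  if (is.null(x$name)) x$name <- paste0("iv", seq_len(nrow(x)))
  if (is.null(x$score)) x$score <- 0L
  if (is.null(x$strand)) x$strand <- "."
  utils::write.table(x[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Reject malformed half-open intervals, naming the offending rows.
validate_intervals <- function(x, what = "intervals") {
  bad <- which(!(x$start < x$end))
  if (length(bad)) {
    stop(sprintf("malformed intervals (start >= end) in %s at line(s) %s",
                 what, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if (any(x$start < 0)) {
    stop(sprintf("negative coordinates in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read or write gene sets in GMT format
#'
#' One line per gene set: id, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# 0-based half-open BED intervals -> GRanges (1-based closed).
bed_to_granges <- function(x) {
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1L,
                                                   end = x$end))
}
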
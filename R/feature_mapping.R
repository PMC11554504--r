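#' TSS-centered analysis window
#'
#' Computes the half-open genomic interval `[tss - width/2, tss + width/2)`
#' around a canonical transcription start site, in BED (0-based half-open)
#' coordinates. The window is centered regardless of strand and clipped at
#' the chromosome origin; clipping shortens the window rather than shifting
#' it.
#'
#' @param tss_pos integer vector of 0-based TSS positions.
#' @param width window width in bp; must be even and positive (default
#'   10000, i.e. a 10-kb frame).
#' @return data frame with columns `start`, `end`.
#' @examples
#' tss_window(100000)            # [95000, 105000)
#' tss_window(3000)              # [0, 8000)
#' @export
tss_window <- function(tss_pos, width = 10000L) {
  stopifnot(width > 0, width %% 2 == 0)
  half <- width %/% 2L
  data.frame(start = pmax(0L, as.integer(tss_pos) - half),
             end = as.integer(tss_pos) + half)
}

#' Flag feature hits that overlap the retroelement annotation
#'
#' A hit is RE-linked iff it overlaps at least `min_overlap` bp of any RE
#' interval on the same chromosome, under the half-open BED convention
#' (intervals that merely touch do not overlap).
#'
#' @param hits data frame of feature hits with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param re data frame of RE intervals with the same columns.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return logical vector, one element per row of `hits`.
#' @export
annotate_re_linked <- function(hits, re, min_overlap = 1L) {
  validate_intervals(hits, what = "hits")
  validate_intervals(re, what = "RE annotation")
  if (nrow(hits) == 0) return(logical(0))
  if (nrow(re) == 0) return(rep(FALSE, nrow(hits)))
  # disjoint chromosome sets are legitimate (no overlap), not a warning
  suppressWarnings(
    IRanges::overlapsAny(bed_to_granges(hits), bed_to_granges(re),
                         minoverlap = as.integer(min_overlap)))
}

#' Count feature hits per gene window: FES and TFS
#'
#' For every gene-by-profile cell, `TFS` is the number of hits of that
#' profile overlapping the gene's TSS window by at least `min_overlap` bp
#' and `FES` is the RE-linked subset of those hits. A hit overlapping the
#' windows of two genes counts for both. Cells of genes not assayed by a
#' profile (absent from `coverage`) are flagged `no_data` with undefined
#' counts -- distinct from an observed `TFS = 0` in a covered cell.
#'
#' @param hits data frame with columns `chrom`, `start`, `end`,
#'   `profile_id` (plus anything else, ignored).
#' @param re_linked logical vector parallel to `hits`, from
#'   [annotate_re_linked()].
#' @param tss data frame with columns `gene_id`, `chrom`, `tss_pos`.
#' @param width window width passed to [tss_window()].
#' @param coverage optional data frame (`profile_id`, `gene_id`) listing the
#'   assayed cells; `NULL` means every cell is covered.
#' @param min_overlap minimum window overlap in bp (default 1).
#' @return data frame with one row per gene-by-profile cell: `gene_id`,
#'   `profile_id`, `FES`, `TFS` (NA when `no_data`), `no_data`.
#' @export
count_features <- function(hits, re_linked, tss, width = 10000L,
                           coverage = NULL, min_overlap = 1L) {
  stopifnot(nrow(hits) == length(re_linked))
  validate_intervals(hits, what = "hits")
  profiles <- sort(unique(c(hits$profile_id, coverage$profile_id)))
  n <- nrow(tss)
  np <- length(profiles)
  miss_chr <- setdiff(unique(tss$chrom), unique(hits$chrom))
  if (length(miss_chr) && nrow(hits) > 0) {
    warning(sprintf("no hits on chromosome(s) %s; counts there are 0",
                    paste(miss_chr, collapse = ", ")), call. = FALSE)
  }

  win <- tss_window(tss$tss_pos, width)
  win_gr <- GenomicRanges::GRanges(tss$chrom,
                                   IRanges::IRanges(win$start + 1L, win$end))
  tfs <- matrix(0L, n, np, dimnames = list(tss$gene_id, profiles))
  fes <- tfs
  if (nrow(hits) > 0) {
    hit_gr <- bed_to_granges(hits)
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(win_gr, hit_gr,
                                  minoverlap = as.integer(min_overlap)))
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    p <- match(hits$profile_id[s], profiles)
    cell <- (p - 1L) * n + q
    tab <- tabulate(cell, nbins = n * np)
    tfs[] <- tab
    re_cell <- cell[re_linked[s]]
    fes[] <- tabulate(re_cell, nbins = n * np)
  }

  out <- data.frame(gene_id = rep(tss$gene_id, times = np),
                    profile_id = rep(profiles, each = n),
                    FES = as.integer(fes),
                    TFS = as.integer(tfs),
                    no_data = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(coverage)) {
    covered_key <- paste(coverage$profile_id, coverage$gene_id)
    out$no_data <- !(paste(out$profile_id, out$gene_id) %in% covered_key)
    out$FES[out$no_data] <- NA_integer_
    out$TFS[out$no_data] <- NA_integer_
  }
  out <- out[order(out$gene_id, out$profile_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
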
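## Assembly of the Identical Repeated Backbone: merge overlapping Identical
## Cores into non-overlapping Identical Sequence Tracks (ISTs), and summarize
## the resulting track set (per-window densities, per-chromosome statistics).

#' Merge overlapping Identical Cores into Identical Sequence Tracks
#'
#' ISTs are the connected components of the core-overlap graph, where two
#' cores overlap if they share at least one bp. Cores that merely touch
#' (end of one adjacent to start of the next) stay separate. Each IST's span
#' is the union of its member cores; an IST with one member core is "simple"
#' (complexity 1), with two or more "complex". The whole set of ISTs forms
#' the IRB.
#'
#' @param cores A core [GenomicRanges::GRanges] from [pairs_to_cores()].
#' @return A [GenomicRanges::GRanges] of pairwise non-overlapping tracks with
#'   mcols `ist_id`, `complexity` (number of member cores) and `core_ids`
#'   (a [IRanges::CharacterList]). Identifiers follow (chromosome, start)
#'   order.
#' @export
build_ists <- function(cores) {
  stopifnot(methods::is(cores, "GRanges"))
  ists <- GenomicRanges::reduce(GenomicRanges::sort(
    GenomicRanges::granges(cores)), min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(cores, ists, minoverlap = 1L)
  ids <- split(cores$ic_id[S4Vectors::queryHits(hits)],
               factor(S4Vectors::subjectHits(hits), levels = seq_along(ists)))
  ids <- lapply(ids, function(x) sort(unique(x)))
  ists$ist_id <- sprintf("IST%06d", seq_along(ists))
  ists$complexity <- unname(lengths(ids))
  ists$core_ids <- IRanges::CharacterList(unname(ids))
  ists
}

#' Per-window IST density
#'
#' Counts the number of bp belonging to ISTs in consecutive chromosomal
#' windows (1 Mb by default). The trailing window of each chromosome keeps
#' its natural (shorter) size. Per chromosome, the window densities sum to
#' the chromosome's total IST bp.
#'
#' @param ists An IST [GenomicRanges::GRanges] from [build_ists()].
#' @param chrom_lengths Named integer vector of chromosome lengths in bp
#'   (e.g. from [chrom_lengths()]).
#' @param window_bp Window size in bp (default 1e6).
#' @return A data frame with `chrom`, `window_index` (1-based), `window_start`,
#'   `window_end` (1-based inclusive) and `ist_bp`.
#' @export
ist_density <- function(ists, chrom_lengths, window_bp = 1e6) {
  stopifnot(methods::is(ists, "GRanges"), length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)), window_bp >= 1)
  window_bp <- as.integer(window_bp)
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1L, len)
    data.frame(chrom = ch, window_index = seq_along(starts),
               window_start = starts, window_end = ends,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, rows)
  wgr <- GenomicRanges::GRanges(win$chrom,
                                IRanges::IRanges(win$window_start,
                                                 win$window_end))
  cov <- GenomicRanges::reduce(GenomicRanges::granges(ists),
                               min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(wgr, cov)
  bp <- integer(nrow(win))
  if (length(ov)) {
    iw <- GenomicRanges::pintersect(
      wgr[S4Vectors::queryHits(ov)], cov[S4Vectors::subjectHits(ov)])
    agg <- tapply(GenomicRanges::width(iw), S4Vectors::queryHits(ov), sum)
    bp[as.integer(names(agg))] <- as.integer(agg)
  }
  win$ist_bp <- bp
  win
}

#' IRB summary statistics
#'
#' Per-genome and per-chromosome summaries of an IST set: track count, total
#' bp, minimum/maximum/mean track length, percent of the chromosome covered
#' by the IRB, and the minimum/maximum/mean gap between consecutive ISTs on
#' the same chromosome (a gap of 1 means one bp separates them;
#' interchromosomal neighbours are never compared). Gap statistics are `NA`
#' for chromosomes with fewer than two ISTs.
#'
#' @param ists An IST [GenomicRanges::GRanges] from [build_ists()].
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @return A list with elements `genome` (one-row data frame) and
#'   `per_chrom` (one row per chromosome).
#' @export
irb_summary <- function(ists, chrom_lengths) {
  stopifnot(methods::is(ists, "GRanges"), !is.null(names(chrom_lengths)))
  ists <- GenomicRanges::sort(ists)
  sn <- as.character(GenomicRanges::seqnames(ists))
  w <- GenomicRanges::width(ists)
  st <- GenomicRanges::start(ists)
  en <- GenomicRanges::end(ists)
  per <- lapply(names(chrom_lengths), function(ch) {
    i <- which(sn == ch)
    n <- length(i)
    gaps <- if (n >= 2L) st[i][-1L] - en[i][-n] - 1L else NA_integer_
    data.frame(
      chrom = ch, n_ist = n, ist_bp = sum(w[i]),
      min_len = if (n) min(w[i]) else NA_integer_,
      max_len = if (n) max(w[i]) else NA_integer_,
      mean_len = if (n) mean(w[i]) else NA_real_,
      pct_chrom = 100 * sum(w[i]) / chrom_lengths[[ch]],
      min_gap = if (n >= 2L) min(gaps) else NA_integer_,
      max_gap = if (n >= 2L) max(gaps) else NA_integer_,
      mean_gap = if (n >= 2L) mean(gaps) else NA_real_,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  all_gaps <- unlist(lapply(names(chrom_lengths), function(ch) {
    i <- which(sn == ch)
    if (length(i) >= 2L) st[i][-1L] - en[i][-length(i)] - 1L else integer()
  }))
  genome <- data.frame(
    n_ist = length(ists), ist_bp = sum(w),
    min_len = if (length(w)) min(w) else NA_integer_,
    max_len = if (length(w)) max(w) else NA_integer_,
    mean_len = if (length(w)) mean(w) else NA_real_,
    pct_genome = 100 * sum(w) / sum(chrom_lengths),
    min_gap = if (length(all_gaps)) min(all_gaps) else NA_integer_,
    max_gap = if (length(all_gaps)) max(all_gaps) else NA_integer_,
    mean_gap = if (length(all_gaps)) mean(all_gaps) else NA_real_)
  list(genome = genome, per_chrom = per)
}

#' Write ISTs to BED and TSV
#'
#' @param ists An IST [GenomicRanges::GRanges].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_ists <- function(ists, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    out <- GenomicRanges::granges(ists)
    out$name <- ists$ist_id
    rtracklayer::export(out, bed_path, format = "BED")
  }
  if (!is.null(tsv_path)) {
    tab <- data.frame(
      ist_id = ists$ist_id,
      chrom = as.character(GenomicRanges::seqnames(ists)),
      start = GenomicRanges::start(ists), end = GenomicRanges::end(ists),
      complexity = ists$complexity,
      core_ids = vapply(ists$core_ids, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
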
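## bp-level comparison of the IRB against annotation interval sets
## (segmental duplications, CNV catalogues, masked common repeats).

## put two GRanges on a shared seqlevel universe so set operations work
.harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

.strandless <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  gr
}

#' Merge an interval set into a non-redundant list
#'
#' Returns the sorted union of the input intervals: pairwise non-overlapping,
#' with coverage identical to the input. Overlapping intervals are
#' concatenated; abutting intervals stay separate (consistent with IST
#' assembly). Merging is idempotent.
#'
#' @param intervals A [GenomicRanges::GRanges] (strand ignored).
#' @return A sorted, non-overlapping [GenomicRanges::GRanges].
#' @export
merge_intervals <- function(intervals) {
  stopifnot(methods::is(intervals, "GRanges"))
  GenomicRanges::reduce(GenomicRanges::sort(.strandless(intervals)),
                        min.gapwidth = 0L)
}

#' bp overlap between two interval sets
#'
#' Computes the symmetric bp overlap between the coverage of sets A and B,
#' the fraction of each set's total bp involved, and how many intervals of
#' one set are fully embedded in the other (span containment of the whole
#' interval within a single merged interval of the other set).
#'
#' @param A,B [GenomicRanges::GRanges] interval sets (merged internally;
#'   strand ignored).
#' @return An object of class `overlap_report`: a list with `bp_overlap`,
#'   `bp_A`, `bp_B`, `fraction_of_A`, `fraction_of_B`,
#'   `n_A_fully_embedded_in_B`, `n_B_fully_embedded_in_A`.
#' @export
overlap_bp <- function(A, B) {
  stopifnot(methods::is(A, "GRanges"), methods::is(B, "GRanges"))
  h <- .harmonize(.strandless(A), .strandless(B))
  mA <- merge_intervals(h$a)
  mB <- merge_intervals(h$b)
  ov <- GenomicRanges::intersect(mA, mB)
  bp <- sum(GenomicRanges::width(ov))
  bpA <- sum(GenomicRanges::width(mA))
  bpB <- sum(GenomicRanges::width(mB))
  emb_A <- sum(GenomicRanges::countOverlaps(h$a, mB, type = "within") > 0L)
  emb_B <- sum(GenomicRanges::countOverlaps(h$b, mA, type = "within") > 0L)
  structure(list(
    bp_overlap = bp, bp_A = bpA, bp_B = bpB,
    fraction_of_A = if (bpA > 0) bp / bpA else NA_real_,
    fraction_of_B = if (bpB > 0) bp / bpB else NA_real_,
    n_A_fully_embedded_in_B = emb_A,
    n_B_fully_embedded_in_A = emb_B), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap: %d bp (%.1f%% of A [%d bp], %.1f%% of B [%d bp])\n",
              x$bp_overlap, 100 * x$fraction_of_A, x$bp_A,
              100 * x$fraction_of_B, x$bp_B))
  cat(sprintf("A intervals fully embedded in B: %d; B in A: %d\n",
              x$n_A_fully_embedded_in_B, x$n_B_fully_embedded_in_A))
  invisible(x)
}

#' Identity-stratified overlap against segmental duplications
#'
#' Splits the bp overlap between an IST set and an annotation set carrying a
#' per-interval percent-identity attribute into identity bins. A bp
#' overlapped by annotation intervals in several bins is credited to the
#' highest-identity bin only, so the per-bin overlaps always sum to the
#' unstratified overlap.
#'
#' @param ists An IST [GenomicRanges::GRanges] (strand ignored).
#' @param sds A [GenomicRanges::GRanges] with a numeric `identity` mcol
#'   (percent identity). Missing attribute is an error.
#' @param breaks Numeric bin breakpoints passed to [cut()] (bins are
#'   left-open, right-closed; values at the lowest break are included).
#'   Default `c(0, 99, 100)` reproduces the "up to 99%" vs "more than 99%"
#'   stratification.
#' @return A data frame with `bin` (highest-identity bin first) and
#'   `bp_overlap`.
#' @export
stratified_overlap <- function(ists, sds, breaks = c(0, 99, 100)) {
  stopifnot(methods::is(ists, "GRanges"), methods::is(sds, "GRanges"))
  if (!("identity" %in% names(S4Vectors::mcols(sds))))
    stop("`sds` must carry a numeric `identity` mcol")
  idy <- sds$identity
  if (!is.numeric(idy) || any(is.na(idy)))
    stop("`identity` attribute must be numeric and non-missing")
  bins <- cut(idy, breaks = breaks, include.lowest = TRUE)
  if (any(is.na(bins)))
    stop("identity value(s) outside `breaks` range")
  h <- .harmonize(.strandless(ists), .strandless(sds))
  remaining <- merge_intervals(h$a)
  lv <- rev(levels(bins)) # highest-identity bin first
  out <- data.frame(bin = lv, bp_overlap = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(lv)) {
    sub <- h$b[which(bins == lv[i])]
    if (length(sub) == 0L) next
    ov <- GenomicRanges::intersect(remaining, merge_intervals(sub))
    out$bp_overlap[i] <- sum(GenomicRanges::width(ov))
    remaining <- GenomicRanges::setdiff(remaining, ov)
  }
  out
}

#' Read an annotation BED with a numeric attribute column
#'
#' Convenience reader for segmental-duplication style BED files where the
#' 4th (name) or 5th (score) column carries percent identity. The value is
#' stored in an `identity` mcol for [stratified_overlap()].
#'
#' @param path Path to a BED file.
#' @param attr_from Which BED column holds the identity value: `"name"`
#'   (4th) or `"score"` (5th).
#' @return A [GenomicRanges::GRanges] with an `identity` mcol.
#' @export
read_sd_bed <- function(path, attr_from = c("name", "score")) {
  attr_from <- match.arg(attr_from)
  gr <- read_intervals(path, "bed")
  val <- S4Vectors::mcols(gr)[[attr_from]]
  if (is.null(val))
    stop("BED file has no '", attr_from, "' column to read identity from")
  idy <- suppressWarnings(as.numeric(as.character(val)))
  if (any(is.na(idy)))
    stop("non-numeric identity value(s) in BED '", attr_from, "' column")
  out <- GenomicRanges::granges(gr)
  out$identity <- idy
  out
}

#' Write an overlap report to TSV
#'
#' @param report An `overlap_report` from [overlap_bp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  stopifnot(inherits(report, "overlap_report"))
  tab <- data.frame(metric = names(report),
                    value = unlist(report, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
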
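## Maximal identical repeat pair detection and decomposition into Identical
## Core sequences (ICs). The pair finder itself lives in src/find_pairs.cpp;
## here we mask ineligible positions, convert coordinates, and impose the
## canonical ordering that makes the output reproducible.

#' Find all maximal identical repeat pairs
#'
#' Detects every pair of distinct, equal-length genomic intervals whose
#' sequences are 100% identical (direct orientation) or identical to each
#' other's reverse complement (inverted orientation), of length at least
#' `min_len`, and maximal: extending both members one base outward in the
#' orientation-appropriate geometry either breaks identity or leaves the
#' eligible region. Matches may be intra- or interchromosomal; two
#' distinct-but-overlapping intervals (tandem structure) are allowed; a
#' palindromic interval matching itself at identical coordinates is a
#' self-pair and is excluded. Positions that are excluded (see
#' [apply_exclusions()]) or non-A/C/G/T (gaps, ambiguity codes) can never be
#' part of a pair.
#'
#' @param genome A [GenomeSeq].
#' @param min_len Minimum pair length in bp (>= 2). Default 300, the minimal
#'   length associated with efficient non-allelic homologous recombination.
#' @return A data frame of class `irb_pairs` with one row per unordered pair:
#'   `pair_id`, `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`
#'   (1-based inclusive), `length`, `orientation` (`"direct"`/`"inverted"`).
#'   Rows are in canonical order (chromosome record order, then start, end).
#' @examples
#' g <- GenomeSeq(c(chr1 = "AAAANAAAA"))
#' find_maximal_identical_pairs(g, min_len = 4)
#' @export
find_maximal_identical_pairs <- function(genome, min_len = 300L) {
  stopifnot(inherits(genome, "GenomeSeq"))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 2L)
    stop("`min_len` must be an integer >= 2")
  chroms <- names(genome$seq)
  if (length(chroms) == 0L)
    return(.empty_pairs(chroms))
  raw <- .find_pairs_cpp(.masked_strings(genome), min_len)
  df <- data.frame(
    chrom1 = chroms[raw$chrom1], start1 = raw$start1 + 1L, end1 = raw$end1,
    chrom2 = chroms[raw$chrom2], start2 = raw$start2 + 1L, end2 = raw$end2,
    length = raw$length,
    orientation = c("direct", "inverted")[raw$inverted + 1L],
    stringsAsFactors = FALSE)
  o <- order(raw$chrom1, df$start1, df$end1, raw$chrom2, df$start2, df$end2,
             df$orientation)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(pair_id = sprintf("P%06d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  attr(df, "chrom_levels") <- chroms
  attr(df, "chrom_lengths") <- chrom_lengths(genome)
  class(df) <- c("irb_pairs", "data.frame")
  df
}

.empty_pairs <- function(chroms = character()) {
  df <- data.frame(pair_id = character(), chrom1 = character(),
                   start1 = integer(), end1 = integer(), chrom2 = character(),
                   start2 = integer(), end2 = integer(), length = integer(),
                   orientation = character(), stringsAsFactors = FALSE)
  attr(df, "chrom_levels") <- chroms
  class(df) <- c("irb_pairs", "data.frame")
  df
}

#' Decompose repeat pairs into non-redundant Identical Cores
#'
#' Every pair member becomes an Identical Core (IC); members of several pairs
#' with the exact same span collapse to a single core, so no two cores share
#' a span. Core identifiers are assigned in (chromosome record order, start,
#' end) order.
#'
#' @param pairs An `irb_pairs` data frame from
#'   [find_maximal_identical_pairs()].
#' @return A [GenomicRanges::GRanges] with mcols `ic_id` and `pair_ids`
#'   (a [IRanges::CharacterList] of the pairs each core participates in).
#' @export
pairs_to_cores <- function(pairs) {
  stopifnot(inherits(pairs, "irb_pairs"))
  chroms <- attr(pairs, "chrom_levels")
  if (is.null(chroms))
    chroms <- unique(c(pairs$chrom1, pairs$chrom2))
  members <- data.frame(
    chrom = c(pairs$chrom1, pairs$chrom2),
    start = c(pairs$start1, pairs$start2),
    end = c(pairs$end1, pairs$end2),
    pair_id = c(pairs$pair_id, pairs$pair_id),
    stringsAsFactors = FALSE)
  key <- paste(members$chrom, members$start, members$end, sep = ":")
  uniq <- !duplicated(key)
  spans <- members[uniq, c("chrom", "start", "end")]
  o <- order(match(spans$chrom, chroms), spans$start, spans$end)
  spans <- spans[o, , drop = FALSE]
  ukey <- paste(spans$chrom, spans$start, spans$end, sep = ":")
  pair_ids <- split(members$pair_id, factor(key, levels = ukey))
  pair_ids <- lapply(pair_ids, function(x) sort(unique(x)))
  gr <- GenomicRanges::GRanges(
    factor(spans$chrom, levels = chroms),
    IRanges::IRanges(spans$start, spans$end))
  ln <- attr(pairs, "chrom_lengths")
  if (!is.null(ln))
    GenomeInfoDb::seqlengths(gr) <- unname(ln[chroms])
  gr$ic_id <- sprintf("IC%06d", seq_along(gr))
  gr$pair_ids <- IRanges::CharacterList(pair_ids)
  gr
}

#' Group Identical Cores into sequence families
#'
#' Two cores belong to the same family if and only if their canonical
#' sequences are equal, where the canonical sequence is the lexicographic
#' minimum of a core's sequence and its reverse complement. Members of one
#' pair always share a family, so every original pair is recoverable as an
#' intra-family relation.
#'
#' @param cores A core [GenomicRanges::GRanges] from [pairs_to_cores()].
#' @param genome The [GenomeSeq] the cores were found in.
#' @return `cores` with an added `family_id` mcol.
#' @export
assign_families <- function(cores, genome) {
  stopifnot(methods::is(cores, "GRanges"), inherits(genome, "GenomeSeq"))
  if (length(cores) == 0L) {
    cores$family_id <- character()
    return(cores)
  }
  seqs <- .span_seq(genome, cores)
  canon <- .canonical_seq(seqs)
  fam <- match(canon, unique(canon))
  cores$family_id <- sprintf("F%05d", fam)
  cores
}

## plus-strand sequence of each span in a GRanges
.span_seq <- function(genome, gr) {
  s <- as.character(genome$seq)
  sn <- as.character(GenomicRanges::seqnames(gr))
  substring(s[sn], GenomicRanges::start(gr), GenomicRanges::end(gr))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.canonical_seq <- function(x) {
  rc <- .revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Project a span through a repeat pair onto the partner member
#'
#' Given a span fully contained in one member of a pair, returns the
#' homologous span on the other member: same offset for direct pairs,
#' reflected offset with flipped strand for inverted pairs. Projection is an
#' involution: projecting the result back returns the original span.
#'
#' @param pair A single row of an `irb_pairs` data frame (or a one-row data
#'   frame/list with the same fields).
#' @param span A [GenomicRanges::GRanges] (may contain several ranges), each
#'   fully inside `pair`'s left or right member. Anything else is an error.
#' @return A [GenomicRanges::GRanges] of projected spans, strand flipped for
#'   inverted pairs.
#' @export
project_span <- function(pair, span) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L)
    pair <- as.list(pair)
  }
  stopifnot(methods::is(span, "GRanges"))
  if (length(span) == 0L) return(span)
  sn <- as.character(GenomicRanges::seqnames(span))
  st <- GenomicRanges::start(span)
  en <- GenomicRanges::end(span)
  sd <- as.character(GenomicRanges::strand(span))
  in_left <- sn == pair$chrom1 & st >= pair$start1 & en <= pair$end1
  in_right <- sn == pair$chrom2 & st >= pair$start2 & en <= pair$end2
  ## a span inside both members (overlapping pair): treat as left member
  use_left <- in_left
  use_right <- !in_left & in_right
  if (any(!use_left & !use_right))
    stop("span not contained in either member of the pair")
  base_s <- ifelse(use_left, pair$start1, pair$start2)
  base_e <- ifelse(use_left, pair$end1, pair$end2)
  targ_s <- ifelse(use_left, pair$start2, pair$start1)
  targ_e <- ifelse(use_left, pair$end2, pair$end1)
  targ_c <- ifelse(use_left, pair$chrom2, pair$chrom1)
  if (pair$orientation == "direct") {
    new_s <- targ_s + (st - base_s)
    new_e <- targ_s + (en - base_s)
    new_sd <- sd
  } else {
    new_s <- targ_e - (en - base_s)
    new_e <- targ_e - (st - base_s)
    new_sd <- c("+" = "-", "-" = "+", "*" = "*")[sd]
  }
  GenomicRanges::GRanges(targ_c, IRanges::IRanges(new_s, new_e),
                         strand = unname(new_sd))
}

#' Write repeat pairs to TSV
#'
#' One row per pair with both members' coordinates (1-based inclusive),
#' length and orientation.
#'
#' @param pairs An `irb_pairs` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  write.table(as.data.frame(pairs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write Identical Cores to BED and TSV
#'
#' The BED file carries the core spans with `ic_id` as the name column; the
#' TSV additionally lists `family_id` (if assigned) and the pairs each core
#' participates in.
#'
#' @param cores A core [GenomicRanges::GRanges].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the written paths.
#' @export
write_cores <- function(cores, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    out <- GenomicRanges::granges(cores)
    out$name <- cores$ic_id
    rtracklayer::export(out, bed_path, format = "BED")
  }
  if (!is.null(tsv_path)) {
    tab <- data.frame(
      ic_id = cores$ic_id,
      chrom = as.character(GenomicRanges::seqnames(cores)),
      start = GenomicRanges::start(cores), end = GenomicRanges::end(cores),
      family_id = if (!is.null(cores$family_id)) cores$family_id else NA,
      pair_ids = vapply(cores$pair_ids, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}
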
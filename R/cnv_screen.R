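## In-silico hybridization screen for copy-number change: exact full-length
## probe hits in a read set, a resampled single-copy-fragment null, a
## per-copy hit-ratio statistic, and a 2-standard-deviation flagging rule.

#' Count exact occurrences of a sequence in a genome
#'
#' Counts start positions of exact occurrences of `sequence` on both strands
#' of the genome; overlapping occurrences are counted. Note that a
#' reverse-complement-palindromic sequence is counted once per strand at the
#' same position (a non-issue for natural probes).
#'
#' @param sequence A character string or [Biostrings::DNAString], A/C/G/T
#'   only.
#' @param genome A [GenomeSeq].
#' @return Integer occurrence count.
#' @examples
#' count_genome_occurrences("AAAA", GenomeSeq(c(chr1 = "AAAAAA"))) # 3
#' @export
count_genome_occurrences <- function(sequence, genome) {
  stopifnot(inherits(genome, "GenomeSeq"))
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence))
    stop("probe sequence must be non-empty and A/C/G/T only")
  fwd <- sum(Biostrings::vcountPattern(sequence, genome$seq))
  rc <- .revcomp(sequence)
  rev <- sum(Biostrings::vcountPattern(rc, genome$seq))
  as.integer(fwd + rev)
}

#' Count reads hit by a probe
#'
#' A hit is a read containing the full probe, or its reverse complement, as
#' an exact substring (100% identity over the whole probe length). Each read
#' counts at most once, however many times the probe occurs in it.
#'
#' @param probe A character string or [Biostrings::DNAString].
#' @param reads A [Biostrings::DNAStringSet] of reads.
#' @return Integer hit count. If the probe is longer than every read, a
#'   warning is emitted and the count is 0.
#' @export
count_read_hits <- function(probe, reads) {
  stopifnot(methods::is(reads, "DNAStringSet"))
  probe <- toupper(as.character(probe))
  if (length(reads) == 0L) return(0L)
  if (nchar(probe) > max(Biostrings::width(reads))) {
    warning("probe (", nchar(probe), " bp) is longer than every read")
    return(0L)
  }
  hit <- Biostrings::vcountPattern(probe, reads) > 0L
  rc <- .revcomp(probe)
  if (rc != probe)
    hit <- hit | (Biostrings::vcountPattern(rc, reads) > 0L)
  sum(hit)
}

#' Build the random single-copy-fragment null model
#'
#' Samples `n_fragments` fragments of length `fragment_len` uniformly from
#' the genome, rejecting any fragment containing non-A/C/G/T characters or
#' occurring more than once in the reference (both strands), and records the
#' read-hit count of each retained fragment. Since every fragment is
#' single-copy, its hit count equals its hit ratio, and the mean and sample
#' standard deviation over fragments define the null against which probe
#' ratios are compared.
#'
#' @param genome A [GenomeSeq] (the reference).
#' @param reads A [Biostrings::DNAStringSet] of sample reads.
#' @param n_fragments Number of fragments (default 220).
#' @param fragment_len Fragment length in bp; conventionally the rounded
#'   mean probe length of the screen.
#' @param seed Integer seed; the same seed reproduces the same fragments and
#'   model.
#' @param max_tries Attempt cap per fragment slot before giving up.
#' @return An object of class `irb_null`: a list with `n_fragments`,
#'   `fragment_len`, `mean`, `sd`, `seed`, `fragments` (a
#'   [GenomicRanges::GRanges]) and `hit_counts`.
#' @export
build_null_model <- function(genome, reads, n_fragments = 220L,
                             fragment_len, seed = 1L, max_tries = 50L) {
  stopifnot(inherits(genome, "GenomeSeq"), methods::is(reads, "DNAStringSet"),
            n_fragments >= 2L, fragment_len >= 1L)
  ln <- chrom_lengths(genome)
  if (all(ln < fragment_len))
    stop("fragment_len exceeds every chromosome length")
  ok_chr <- names(ln)[ln >= fragment_len]
  wts <- ln[ok_chr] - fragment_len + 1
  set.seed(as.integer(seed))
  chroms <- character(n_fragments)
  starts <- integer(n_fragments)
  seqs <- character(n_fragments)
  got <- 0L
  tries <- 0L
  seen <- character()
  while (got < n_fragments) {
    if (tries >= max_tries * n_fragments)
      stop("could not find ", n_fragments,
           " single-copy fragments after ", tries, " attempts")
    tries <- tries + 1L
    ch <- sample(ok_chr, 1L, prob = wts)
    st <- sample.int(ln[[ch]] - fragment_len + 1L, 1L)
    sq <- .span_seq(genome, GenomicRanges::GRanges(
      ch, IRanges::IRanges(st, st + fragment_len - 1L)))
    key <- paste(ch, st, sep = ":")
    if (key %in% seen) next
    if (!grepl("^[ACGT]+$", sq)) next
    if (count_genome_occurrences(sq, genome) != 1L) next
    got <- got + 1L
    seen <- c(seen, key)
    chroms[got] <- ch
    starts[got] <- st
    seqs[got] <- sq
  }
  hits <- vapply(seqs, function(s)
    suppressWarnings(count_read_hits(s, reads)), integer(1),
    USE.NAMES = FALSE)
  structure(list(
    n_fragments = n_fragments, fragment_len = as.integer(fragment_len),
    mean = mean(hits), sd = sd(hits), seed = as.integer(seed),
    fragments = GenomicRanges::GRanges(
      chroms, IRanges::IRanges(starts, starts + fragment_len - 1L)),
    hit_counts = hits), class = "irb_null")
}

#' @export
print.irb_null <- function(x, ...) {
  cat(sprintf(
    "single-copy fragment null: n = %d, length = %d bp, mean = %.2f, sd = %.2f (seed %d)\n",
    x$n_fragments, x$fragment_len, x$mean, x$sd, x$seed))
  invisible(x)
}

#' Construct a null model from stated statistics
#'
#' For worked examples where the null mean and standard deviation are given
#' rather than resampled (e.g. re-scoring a published hit table).
#'
#' @param mean,sd Null mean and standard deviation of single-copy hit counts.
#' @param n_fragments,fragment_len,seed Optional metadata.
#' @return An `irb_null` object.
#' @export
null_model <- function(mean, sd, n_fragments = NA_integer_,
                       fragment_len = NA_integer_, seed = NA_integer_) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  structure(list(n_fragments = n_fragments, fragment_len = fragment_len,
                 mean = mean, sd = sd, seed = seed,
                 fragments = GenomicRanges::GRanges(),
                 hit_counts = numeric()), class = "irb_null")
}

## round half away from zero, one decimal by default (55/9 -> 6.1)
.round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Score one probe against the null model
#'
#' The ratio is `hit_count / ref_count`: per-copy read support, comparable
#' with the single-copy fragments of the null. Flags: `absent` when the
#' probe has no hits at all; `amplified` when the ratio exceeds
#' `mean + k sd`; `reduced` when hits exist but the ratio falls below
#' `mean - k sd`; otherwise `normal` (k = `sd_mult`, default 2). Zero hits
#' are deliberately kept apart from `reduced`: absence of exact hits may
#' reflect sequencing error or polymorphism rather than deletion, so it is
#' reported as its own flag.
#'
#' @param probe_id Probe label.
#' @param ref_count Occurrences of the probe in the reference genome (> 0).
#' @param hit_count Reads hit in the sample read set.
#' @param null An `irb_null` model.
#' @param sd_mult Flagging threshold in standard deviations (default 2).
#' @return One-row data frame: `probe_id`, `ref_count`, `hit_count`,
#'   `ratio` (exact), `ratio_rounded` (half-up, one decimal, as reported),
#'   `flag`.
#' @export
score_probe <- function(probe_id, ref_count, hit_count, null, sd_mult = 2) {
  stopifnot(inherits(null, "irb_null"))
  if (is.na(ref_count) || ref_count == 0L)
    stop("ref_count must be positive (probe '", probe_id,
         "' not found in reference?)")
  ratio <- hit_count / ref_count
  lo <- null$mean - sd_mult * null$sd
  hi <- null$mean + sd_mult * null$sd
  flag <- if (hit_count == 0L) "absent"
    else if (ratio > hi) "amplified"
    else if (ratio < lo) "reduced"
    else "normal"
  data.frame(probe_id = probe_id, ref_count = as.integer(ref_count),
             hit_count = as.integer(hit_count), ratio = ratio,
             ratio_rounded = .round_half_up(ratio, 1L), flag = flag,
             stringsAsFactors = FALSE)
}

#' Score a table of precomputed hit counts
#'
#' Applies [score_probe()] row-wise to a table of reference and sample hit
#' counts — the worked-example path when counts come from an external search
#' rather than from [count_read_hits()].
#'
#' @param counts Data frame with columns `probe_id`, `ref_count`,
#'   `hit_count`.
#' @param null An `irb_null` model.
#' @param sd_mult Threshold in standard deviations (default 2).
#' @return Data frame of scored probes (one row each).
#' @export
score_hit_table <- function(counts, null, sd_mult = 2) {
  stopifnot(all(c("probe_id", "ref_count", "hit_count") %in% names(counts)))
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    score_probe(counts$probe_id[i], counts$ref_count[i],
                counts$hit_count[i], null, sd_mult)))
  rownames(out) <- NULL
  out
}

#' Run the full copy-number screen
#'
#' For each probe: count reference occurrences (both strands), count read
#' hits (full-length exact containment, once per read), compute the
#' per-copy hit ratio, and flag against the single-copy-fragment null. The
#' null is built here unless one is supplied.
#'
#' @param probes Data frame with `probe_id` and `sequence` columns, or a
#'   named character vector of sequences.
#' @param genome The reference [GenomeSeq].
#' @param reads A [Biostrings::DNAStringSet] of sample reads.
#' @param null An `irb_null`, or `NULL` to build one.
#' @param n_fragments,fragment_len,seed,sd_mult Null/threshold parameters
#'   (used when `null` is `NULL`); `fragment_len` defaults to the rounded
#'   mean probe length.
#' @return An object of class `irb_screen`: a data frame of scored probes,
#'   with the null model in attribute `null`.
#' @export
run_screen <- function(probes, genome, reads, null = NULL,
                       n_fragments = 220L, fragment_len = NULL, seed = 1L,
                       sd_mult = 2) {
  if (is.character(probes))
    probes <- data.frame(probe_id = names(probes), sequence = unname(probes),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "sequence") %in% names(probes)))
  if (is.null(null)) {
    if (is.null(fragment_len))
      fragment_len <- max(1L, as.integer(round(mean(nchar(probes$sequence)))))
    null <- build_null_model(genome, reads, n_fragments = n_fragments,
                             fragment_len = fragment_len, seed = seed)
  }
  if (nrow(probes) == 0L) {
    out <- data.frame(probe_id = character(), ref_count = integer(),
                      hit_count = integer(), ratio = numeric(),
                      ratio_rounded = numeric(), flag = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(probes)), function(i) {
      sq <- probes$sequence[i]
      rc <- count_genome_occurrences(sq, genome)
      hc <- count_read_hits(sq, reads)
      score_probe(probes$probe_id[i], rc, hc, null, sd_mult)
    }))
    rownames(out) <- NULL
  }
  attr(out, "null") <- null
  class(out) <- c("irb_screen", "data.frame")
  out
}

#' Read the packaged in-silico hybridization worked-example table
#'
#' A fixture encoding a published 52-probe non-coding RNA screen: printed
#' reference/sample hit counts for two read sets and the printed per-copy
#' ratios, used for regression tests of the scoring arithmetic.
#'
#' @return Data frame with columns `num`, `gene_name`, `type`, `ensembl_id`,
#'   `size_bp`, `ref`, `vent`, `wat`, `ratio_vent`, `ratio_wat`.
#' @export
read_example_hit_table <- function() {
  path <- system.file("extdata", "table2_hits.tsv", package = "irbkit",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a null model to JSON
#'
#' @param null An `irb_null`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null_model <- function(null, path) {
  stopifnot(inherits(null, "irb_null"))
  x <- list(n_fragments = null$n_fragments, fragment_len = null$fragment_len,
            mean = null$mean, sd = null$sd, seed = null$seed,
            fragments = if (length(null$fragments)) data.frame(
              chrom = as.character(GenomicRanges::seqnames(null$fragments)),
              start = GenomicRanges::start(null$fragments),
              end = GenomicRanges::end(null$fragments)) else NULL,
            hit_counts = null$hit_counts)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
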
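## Seeded simulators: genomes with planted exact duplications, identical
## gene copies with deliberately corrupted annotations, and read sets with
## planted copy-number changes. The planted truth is returned alongside each
## artefact so recovery can be asserted exactly.

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted exact duplications
#'
#' Background sequence is i.i.d. uniform over A/C/G/T and verified to be
#' repeat-free at `min_len` (regenerated on failure), so the planted
#' duplications are the only repeat structure present. Each planting copies
#' a source segment to a destination segment exactly (direct) or as its
#' reverse complement (inverted); source and destination may sit on the same
#' or different chromosomes. Planting positions may be given explicitly or
#' left `NA` for seeded automatic placement (non-overlapping, with a small
#' margin).
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{chrom_lengths}{named numeric vector of chromosome lengths (bp).}
#'     \item{plantings}{optional data frame with columns `length`,
#'       `orientation` (`"direct"`/`"inverted"`), and optionally `src_chrom`,
#'       `src_start`, `dest_chrom`, `dest_start` (NA for automatic
#'       placement).}
#'     \item{min_len}{repeat length threshold the background must stay
#'       below (default 300).}
#'   }
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param max_regen Regeneration cap for the repeat-free background check.
#' @return A list with `genome` (a [GenomeSeq]) and `truth` (a list with
#'   `planted_pairs` data frame, `min_len`, `seed`).
#' @export
simulate_genome <- function(config, seed = 1L, max_regen = 25L) {
  stopifnot(is.list(config), !is.null(config$chrom_lengths))
  ln <- config$chrom_lengths
  if (is.null(names(ln)) || any(!nzchar(names(ln))))
    stop("chrom_lengths must be named")
  ln <- setNames(as.integer(ln), names(ln))
  min_len <- if (is.null(config$min_len)) 300L else as.integer(config$min_len)
  pl <- config$plantings
  if (is.null(pl))
    pl <- data.frame(length = integer(), orientation = character(),
                     stringsAsFactors = FALSE)
  pl <- as.data.frame(pl, stringsAsFactors = FALSE)
  if (nrow(pl)) {
    if (is.null(pl$orientation)) pl$orientation <- "direct"
    stopifnot(all(pl$orientation %in% c("direct", "inverted")),
              all(pl$length >= 1L))
    for (col in c("src_chrom", "dest_chrom"))
      if (is.null(pl[[col]])) pl[[col]] <- NA_character_
    for (col in c("src_start", "dest_start"))
      if (is.null(pl[[col]])) pl[[col]] <- NA_integer_
    if (2 * sum(pl$length) > sum(ln))
      stop("infeasible config: planted features exceed background length")
  }
  set.seed(as.integer(seed))

  ## repeat-free background
  regen <- 0L
  repeat {
    bg <- vapply(ln, .random_dna, "")
    gbg <- GenomeSeq(setNames(bg, names(ln)))
    if (nrow(find_maximal_identical_pairs(gbg, min_len)) == 0L) break
    regen <- regen + 1L
    if (regen > max_regen)
      stop("could not generate a repeat-free background at min_len = ",
           min_len)
  }

  ## place plantings
  occupied <- GenomicRanges::GRanges(
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(ln),
                                    seqlengths = unname(ln)))
  margin <- 2L
  place <- function(chrom, start, len) {
    if (is.na(chrom)) chrom <- sample(names(ln)[ln >= len + 2L], 1L)
    if (is.na(start)) {
      for (i in 1:200) {
        cand <- sample.int(ln[[chrom]] - len + 1L, 1L)
        gr <- GenomicRanges::GRanges(
          chrom,
          IRanges::IRanges(max(1L, cand - margin),
                           min(ln[[chrom]], cand + len - 1L + margin)),
          seqinfo = GenomeInfoDb::seqinfo(occupied))
        if (!length(GenomicRanges::findOverlaps(gr, occupied))) {
          start <- cand
          break
        }
      }
      if (is.na(start)) stop("infeasible config: could not place planting")
    }
    if (start < 1L || start + len - 1L > ln[[chrom]])
      stop("infeasible config: planting outside chromosome bounds")
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start, start + len - 1L),
      seqinfo = GenomeInfoDb::seqinfo(occupied))
    if (length(GenomicRanges::findOverlaps(gr, occupied)))
      stop("infeasible config: plantings overlap")
    occupied <<- c(occupied, gr)
    list(chrom = chrom, start = as.integer(start))
  }
  seqs <- bg
  truth <- NULL
  if (nrow(pl)) {
    rows <- lapply(seq_len(nrow(pl)), function(i) {
      len <- as.integer(pl$length[i])
      src <- place(pl$src_chrom[i], pl$src_start[i], len)
      dst <- place(pl$dest_chrom[i], pl$dest_start[i], len)
      block <- substring(seqs[[src$chrom]], src$start, src$start + len - 1L)
      if (pl$orientation[i] == "inverted") block <- .revcomp(block)
      s <- seqs[[dst$chrom]]
      substr(s, dst$start, dst$start + len - 1L) <- block
      seqs[[dst$chrom]] <<- s
      data.frame(
        name = sprintf("dup%02d", i),
        src_chrom = src$chrom, src_start = src$start,
        src_end = src$start + len - 1L,
        dest_chrom = dst$chrom, dest_start = dst$start,
        dest_end = dst$start + len - 1L,
        length = len, orientation = pl$orientation[i],
        stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
  } else {
    truth <- data.frame(
      name = character(), src_chrom = character(), src_start = integer(),
      src_end = integer(), dest_chrom = character(), dest_start = integer(),
      dest_end = integer(), length = integer(), orientation = character(),
      stringsAsFactors = FALSE)
  }
  list(genome = GenomeSeq(setNames(seqs, names(ln))),
       truth = list(planted_pairs = truth, min_len = min_len,
                    seed = as.integer(seed)))
}

#' Plant identical gene copies with a corrupted annotation
#'
#' Builds a genome carrying `n_copies` identical copies of one gene, each
#' embedded at the same offset inside an identical duplication block (so
#' containment in an Identical Core holds by construction), and emits the
#' gene annotation with the requested corruption applied to exactly one
#' non-source copy:
#' \describe{
#'   \item{none}{all copies annotated consistently.}
#'   \item{drop}{one copy's annotation entry deleted.}
#'   \item{shrink}{one copy's annotated span shrunk at both ends.}
#'   \item{pseudogenize}{one copy's biotype flipped to `pseudogene`.}
#' }
#'
#' @param chrom_lengths Named lengths of the background chromosomes.
#' @param n_copies Number of identical copies (>= 2).
#' @param corruption One of `"none"`, `"drop"`, `"shrink"`, `"pseudogenize"`.
#' @param seed Integer seed.
#' @param dup_len Length of each duplication block (default 600).
#' @param gene_len Gene length (default 200; must fit in `dup_len`).
#' @param orientation Orientation of the planted duplications.
#' @param min_len Repeat threshold for the repeat-free background check.
#' @param biotype,description Annotation fields of the planted gene.
#' @return A list with `genome` ([GenomeSeq]), `genes` (annotation
#'   [GenomicRanges::GRanges], corruption applied), `truth` (a list:
#'   `copies` data frame of the true gene loci, `corruption`,
#'   `corrupted_copy`, `expected_category`, `planted_pairs`).
#' @export
plant_gene_copies <- function(chrom_lengths = c(chrA = 4000, chrB = 4000),
                              n_copies = 2L,
                              corruption = c("none", "drop", "shrink",
                                             "pseudogenize"),
                              seed = 1L, dup_len = 600L, gene_len = 200L,
                              orientation = "direct", min_len = 300L,
                              biotype = "protein_coding",
                              description = "synthetic test gene") {
  corruption <- match.arg(corruption)
  stopifnot(n_copies >= 2L, gene_len >= 3L, dup_len >= gene_len,
            dup_len >= min_len)
  cfg <- list(
    chrom_lengths = chrom_lengths,
    plantings = data.frame(length = rep(dup_len, n_copies - 1L),
                           orientation = orientation,
                           stringsAsFactors = FALSE),
    min_len = min_len)
  sim <- simulate_genome(cfg, seed = seed)
  pp <- sim$truth$planted_pairs
  ## re-plant every destination from the FIRST source block, so that all
  ## n_copies blocks (and the genes inside them) are identical
  gofs <- as.integer((dup_len - gene_len) %/% 2)
  src_chrom <- pp$src_chrom[1]
  src_start <- pp$src_start[1]
  seqs <- as.character(sim$genome$seq)
  block <- substring(seqs[[src_chrom]], src_start, src_start + dup_len - 1L)
  copies <- data.frame(
    chrom = src_chrom, start = src_start + gofs,
    end = src_start + gofs + gene_len - 1L, strand = "+",
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pp))) {
    b <- if (pp$orientation[i] == "inverted") .revcomp(block) else block
    s <- seqs[[pp$dest_chrom[i]]]
    substr(s, pp$dest_start[i], pp$dest_end[i]) <- b
    seqs[[pp$dest_chrom[i]]] <- s
    if (pp$orientation[i] == "direct") {
      copies <- rbind(copies, data.frame(
        chrom = pp$dest_chrom[i], start = pp$dest_start[i] + gofs,
        end = pp$dest_start[i] + gofs + gene_len - 1L, strand = "+",
        stringsAsFactors = FALSE))
    } else {
      copies <- rbind(copies, data.frame(
        chrom = pp$dest_chrom[i],
        start = pp$dest_end[i] - (gofs + gene_len - 1L),
        end = pp$dest_end[i] - gofs, strand = "-",
        stringsAsFactors = FALSE))
    }
    pp$src_chrom[i] <- src_chrom
    pp$src_start[i] <- src_start
    pp$src_end[i] <- src_start + dup_len - 1L
  }
  genome <- GenomeSeq(setNames(seqs, names(chrom_lengths)))
  ann <- copies
  ann$gene_id <- sprintf("gene1_copy%d", seq_len(nrow(ann)))
  ann$name <- "GENE1"
  ann$biotype <- biotype
  ann$description <- description
  corrupted <- if (corruption == "none") NA_integer_ else 2L
  if (corruption == "drop") {
    ann <- ann[-corrupted, , drop = FALSE]
  } else if (corruption == "shrink") {
    shrink <- max(1L, gene_len %/% 10L)
    ann$start[corrupted] <- ann$start[corrupted] + shrink
    ann$end[corrupted] <- ann$end[corrupted] - shrink
  } else if (corruption == "pseudogenize") {
    ann$biotype[corrupted] <- "pseudogene"
  }
  genes <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start, ann$end), strand = ann$strand,
    gene_id = ann$gene_id, name = ann$name, biotype = ann$biotype,
    description = ann$description)
  expected <- switch(corruption, none = "consistent",
                     drop = "unannotated_member",
                     shrink = "size_inconsistent",
                     pseudogenize = "description_inconsistent")
  list(genome = genome, genes = genes,
       truth = list(copies = copies, corruption = corruption,
                    corrupted_copy = corrupted,
                    expected_category = expected,
                    planted_pairs = pp, min_len = min_len,
                    seed = as.integer(seed)))
}

#' Simulate a read set with planted copy-number changes
#'
#' Builds the sample genome by applying `cnv_spec` to the reference (a locus
#' at copy number 0 is deleted; copy number k >= 2 gains k - 1 extra
#' copies), then draws reads of fixed length with uniform start positions
#' over the adjusted sequence, equiprobable strands, and i.i.d. per-base
#' substitution errors. Read count is
#' `ceiling(total_bp_after_cnv * coverage / read_len)`.
#'
#' In the default `"dispersed"` mode each extra copy becomes its own
#' contig, carrying no junction with any flanking sequence — so a fragment
#' that is single-copy in the reference stays single-copy in the sample
#' unless it lies inside a duplicated locus, and the planted copy numbers
#' are the only copy-number truth in the read set. `"tandem"` mode instead
#' repeats the locus in place; note that a tandem junction (locus end
#' abutting locus start) can by base coincidence recreate sequence
#' adjacent to the locus and thereby amplify near-edge fragments that were
#' unique in the reference.
#'
#' @param genome The reference [GenomeSeq].
#' @param cnv_spec `NULL`, or a data frame with `chrom`, `start`, `end`,
#'   `copy_number` (non-overlapping loci, within bounds).
#' @param duplication_mode `"dispersed"` (default) or `"tandem"`; see
#'   Details.
#' @param read_len Read length in bp (default 250, typical of the Sanger
#'   shotgun reads the screen is designed around).
#' @param coverage Mean coverage of the sample genome.
#' @param error_rate Per-base substitution probability (default 0.001; no
#'   indels — the screen's exact matching makes substitutions the binding
#'   error mode).
#' @param seed Integer seed; identical seeds give byte-identical read sets.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
simulate_reads <- function(genome, cnv_spec = NULL, read_len = 250L,
                           coverage, error_rate = 0.001, seed = 1L,
                           duplication_mode = c("dispersed", "tandem")) {
  stopifnot(inherits(genome, "GenomeSeq"), coverage > 0, read_len >= 1L,
            error_rate >= 0, error_rate < 1)
  duplication_mode <- match.arg(duplication_mode)
  read_len <- as.integer(read_len)
  set.seed(as.integer(seed))
  seqs <- .apply_cnv(genome, cnv_spec, duplication_mode)
  lens <- nchar(seqs)
  if (any(lens < read_len))
    stop("read_len exceeds a (CNV-adjusted) chromosome length")
  total <- sum(lens)
  n_reads <- as.integer(ceiling(total * coverage / read_len))
  nvalid <- lens - read_len + 1L
  chrom_idx <- sample.int(length(seqs), n_reads, replace = TRUE,
                          prob = nvalid)
  starts <- as.integer(floor(runif(n_reads) * nvalid[chrom_idx])) + 1L
  reads <- substring(seqs[chrom_idx], starts, starts + read_len - 1L)
  flip <- runif(n_reads) < 0.5
  if (any(flip)) reads[flip] <- .revcomp(reads[flip])
  nerr <- rbinom(n_reads, read_len, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0L)) {
    pos <- sample.int(read_len, nerr[i])
    r <- strsplit(reads[i], "")[[1]]
    for (p in pos) r[p] <- sample(setdiff(bases, r[p]), 1L)
    reads[i] <- paste(r, collapse = "")
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read%07d", seq_len(n_reads))
  out
}

## apply a CNV spec to the reference; returns named character vector
.apply_cnv <- function(genome, cnv_spec, duplication_mode = "dispersed") {
  seqs <- as.character(genome$seq)
  if (is.null(cnv_spec) || nrow(cnv_spec) == 0L) return(seqs)
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in%
                  names(cnv_spec)),
            all(cnv_spec$copy_number >= 0))
  ln <- chrom_lengths(genome)
  if (any(!(cnv_spec$chrom %in% names(ln))) ||
      any(cnv_spec$start < 1L) || any(cnv_spec$end > ln[cnv_spec$chrom]) ||
      any(cnv_spec$start > cnv_spec$end))
    stop("cnv_spec locus out of bounds")
  gr <- GenomicRanges::GRanges(cnv_spec$chrom,
                               IRanges::IRanges(cnv_spec$start, cnv_spec$end))
  if (length(GenomicRanges::reduce(gr, min.gapwidth = 0L)) != length(gr))
    stop("cnv_spec loci overlap")
  extra <- character()
  for (ch in unique(cnv_spec$chrom)) {
    sub <- cnv_spec[cnv_spec$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    pieces <- character()
    cursor <- 1L
    for (i in seq_len(nrow(sub))) {
      if (sub$start[i] > cursor)
        pieces <- c(pieces, substring(seqs[[ch]], cursor, sub$start[i] - 1L))
      locus <- substring(seqs[[ch]], sub$start[i], sub$end[i])
      k <- sub$copy_number[i]
      if (duplication_mode == "tandem") {
        pieces <- c(pieces, strrep(locus, k))
      } else {
        if (k >= 1L) pieces <- c(pieces, locus)
        if (k >= 2L) {
          add <- setNames(rep(locus, k - 1L),
                          sprintf("%s_cnv_%d_copy%d", ch, sub$start[i],
                                  seq_len(k - 1L) + 1L))
          extra <- c(extra, add)
        }
      }
      cursor <- sub$end[i] + 1L
    }
    if (cursor <= nchar(seqs[[ch]]))
      pieces <- c(pieces, substring(seqs[[ch]], cursor))
    seqs[[ch]] <- paste(pieces, collapse = "")
  }
  c(seqs, extra)
}

#' Write simulation truth to JSON
#'
#' @param truth A truth list as returned by [simulate_genome()] or
#'   [plant_gene_copies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
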
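## Genome, interval and gene-model I/O, plus the masking conventions shared by
## every other module. Coordinates are 1-based closed (GRanges convention)
## throughout the package; BED files are converted at the boundary by
## rtracklayer, tabular reports carry the same 1-based inclusive columns.

#' The closed biotype vocabulary for gene models
#'
#' Gene biotypes recognized by the package. `gene_probe_biotypes()` is the
#' subset used when searching for genes inside Identical Cores: pseudogenes
#' (and uncategorized "other" entries) are never used as probes, so that
#' pseudogene matches surface as annotation inconsistencies rather than as
#' gene copies.
#'
#' @return Character vector of biotype labels.
#' @export
gene_biotypes <- function() {
  c("protein_coding", "miRNA", "misc_RNA", "retrotransposed", "rRNA",
    "scRNA", "snoRNA", "snRNA", "pseudogene", "other")
}

#' @rdname gene_biotypes
#' @export
gene_probe_biotypes <- function() {
  setdiff(gene_biotypes(), c("pseudogene", "other"))
}

#' Construct a GenomeSeq object
#'
#' A `GenomeSeq` bundles the chromosome sequences of an assembly with the set
#' of intervals excluded from repeat analysis (e.g. pseudoautosomal regions,
#' whose identity reflects shared ancestry rather than duplication). Sequences
#' are uppercased; only A/C/G/T positions outside excluded intervals are
#' eligible to belong to a repeat. Exclusion never alters sequence content.
#'
#' @param seq A named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome sequences. Names must be unique and non-empty; sequences
#'   must be non-empty.
#' @param excluded A [GenomicRanges::GRanges] of intervals ineligible for
#'   repeat membership. Must lie within chromosome bounds.
#' @return An object of class `GenomeSeq` with elements `seq` (DNAStringSet)
#'   and `excluded` (GRanges, reduced).
#' @examples
#' g <- GenomeSeq(c(chr1 = "ACGTACGT"))
#' chrom_lengths(g)
#' @export
GenomeSeq <- function(seq, excluded = GenomicRanges::GRanges()) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  if (!methods::is(seq, "DNAStringSet"))
    stop("`seq` must be a DNAStringSet or named character vector")
  nm <- names(seq)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
    stop("every chromosome must have a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(Biostrings::width(seq) == 0L))
    stop("empty sequence record(s): ",
         paste(nm[Biostrings::width(seq) == 0L], collapse = ", "))
  seq <- Biostrings::DNAStringSet(toupper(seq))
  g <- structure(list(seq = seq, excluded = GenomicRanges::GRanges()),
                 class = "GenomeSeq")
  if (length(excluded)) g <- apply_exclusions(g, excluded)
  g
}

#' @export
print.GenomeSeq <- function(x, ...) {
  cat("GenomeSeq with", length(x$seq), "chromosome(s),",
      sum(Biostrings::width(x$seq)), "bp total\n")
  ln <- chrom_lengths(x)
  for (i in seq_along(ln))
    cat(sprintf("  %s: %d bp\n", names(ln)[i], ln[i]))
  if (length(x$excluded))
    cat("  excluded:", length(x$excluded), "interval(s),",
        sum(GenomicRanges::width(x$excluded)), "bp\n")
  invisible(x)
}

#' Chromosome lengths of a GenomeSeq
#'
#' @param genome A [GenomeSeq].
#' @return Named integer vector of chromosome lengths in bp, in record order.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "GenomeSeq"))
  setNames(Biostrings::width(genome$seq), names(genome$seq))
}

.seqinfo <- function(genome) {
  ln <- chrom_lengths(genome)
  GenomeInfoDb::Seqinfo(seqnames = names(ln), seqlengths = unname(ln))
}

#' Read a genome assembly from FASTA
#'
#' Record names are taken as the first whitespace-delimited word of each
#' header. Sequences are uppercased (soft-masked lowercase stays
#' match-eligible); record order is preserved. Duplicate record names and
#' empty records are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A [GenomeSeq].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  GenomeSeq(seq)
}

#' Write a genome assembly to FASTA
#'
#' @param genome A [GenomeSeq].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeSeq"))
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Mark intervals as ineligible for repeat membership
#'
#' Adds `regions` to the genome's excluded set. Sequence content is not
#' modified; excluded positions simply cannot start, extend or be contained
#' in any repeat pair.
#'
#' @param genome A [GenomeSeq].
#' @param regions A [GenomicRanges::GRanges] (strand ignored). Out-of-bounds
#'   regions are a hard error.
#' @return The updated [GenomeSeq].
#' @export
apply_exclusions <- function(genome, regions) {
  stopifnot(inherits(genome, "GenomeSeq"))
  if (length(regions) == 0L) return(genome)
  stopifnot(methods::is(regions, "GRanges"))
  ln <- chrom_lengths(genome)
  sn <- as.character(GenomicRanges::seqnames(regions))
  bad <- !(sn %in% names(ln))
  if (any(bad))
    stop("excluded region on unknown chromosome: ",
         paste(unique(sn[bad]), collapse = ", "))
  oob <- GenomicRanges::start(regions) < 1L |
    GenomicRanges::end(regions) > ln[sn]
  if (any(oob))
    stop("excluded region out of chromosome bounds (",
         sum(oob), " region(s))")
  regions <- GenomicRanges::GRanges(sn, IRanges::IRanges(
    GenomicRanges::start(regions), GenomicRanges::end(regions)))
  all <- c(genome$excluded, regions)
  GenomeInfoDb::seqlevels(all) <- names(ln)
  genome$excluded <- GenomicRanges::reduce(GenomicRanges::sort(all))
  genome
}

## Chromosome strings with ineligible positions masked by a sentinel that can
## never match anything ('#'). Used by the pair finder and the simulators.
.masked_strings <- function(genome) {
  s <- as.character(genome$seq)
  ex <- genome$excluded
  if (length(ex)) {
    sn <- as.character(GenomicRanges::seqnames(ex))
    st <- GenomicRanges::start(ex)
    en <- GenomicRanges::end(ex)
    for (i in seq_along(ex)) {
      substr(s[sn[i]], st[i], en[i]) <-
        strrep("#", en[i] - st[i] + 1L)
    }
  }
  s
}

#' Read an interval set from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are both
#' converted to 1-based closed [GenomicRanges::GRanges]. Format is detected
#' from the file extension when `format = "auto"`.
#'
#' @param path Path to the interval file.
#' @param format One of `"auto"`, `"bed"`, `"gff3"`.
#' @return A [GenomicRanges::GRanges]; extra columns (name, score, GFF3
#'   attributes) are carried in `mcols`.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer interval format from extension '.",
                          ext, "'; pass `format`"))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("malformed ", toupper(format), " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (length(gr) && any(GenomicRanges::width(gr) < 1L))
    stop("malformed ", toupper(format), " file '", path,
         "': interval with start >= end")
  gr
}

#' Write an interval set to BED or GFF3
#'
#' The inverse of [read_intervals()]; coordinate conventions are converted at
#' the boundary so that a write/read round trip is the identity.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @param format One of `"auto"`, `"bed"`, `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     stop("cannot infer interval format from extension"))
  }
  rtracklayer::export(gr, path, format = if (format == "bed") "BED" else "GFF3")
  invisible(path)
}

#' Read gene models from GFF3 or a tabular gene list
#'
#' GFF3 input keeps features of type `gene` and expects `gene_id`, `Name`,
#' `biotype` and `description` attributes. Tabular input (TSV) must have
#' columns `gene_id`, `name`, `biotype`, `description`, `chrom`, `start`,
#' `end`, `strand`, with 1-based inclusive coordinates. Biotypes outside the
#' closed vocabulary of [gene_biotypes()] are a hard error.
#'
#' @param path Path to the gene file.
#' @param format One of `"auto"`, `"gff3"`, `"tsv"`.
#' @return A [GenomicRanges::GRanges] with mcols `gene_id`, `name`,
#'   `biotype`, `description`.
#' @export
read_genes <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", tsv = "tsv",
                     txt = "tsv",
                     stop("cannot infer gene file format from extension"))
  }
  if (format == "gff3") {
    gr <- read_intervals(path, "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    m <- S4Vectors::mcols(gr)
    get <- function(col) if (col %in% names(m)) as.character(m[[col]])
      else rep(NA_character_, length(gr))
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      gene_id = get("gene_id"), name = get("Name"),
      biotype = get("biotype"), description = get("description"))
    gr <- out
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "name", "biotype", "description",
              "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("gene table is missing column(s): ", paste(miss, collapse = ", "))
    gr <- GenomicRanges::GRanges(
      tab$chrom, IRanges::IRanges(tab$start, tab$end), strand = tab$strand,
      gene_id = tab$gene_id, name = tab$name, biotype = tab$biotype,
      description = tab$description)
  }
  bad <- !(gr$biotype %in% gene_biotypes())
  if (any(bad))
    stop("biotype(s) outside the closed vocabulary: ",
         paste(unique(gr$biotype[bad]), collapse = ", "))
  if (anyDuplicated(gr$gene_id))
    stop("duplicate gene_id(s) in gene file")
  gr
}

#' Write gene models
#'
#' @param genes A gene [GenomicRanges::GRanges] as returned by [read_genes()].
#' @param path Output path (`.gff3` or `.tsv`).
#' @param format One of `"auto"`, `"gff3"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = "gff3", gff3 = "gff3", tsv = "tsv",
                     stop("cannot infer gene file format from extension"))
  }
  if (format == "gff3") {
    out <- genes
    out$type <- "gene"
    out$source <- "irbkit"
    out$Name <- genes$name
    out$name <- NULL
    rtracklayer::export(out, path, format = "GFF3")
  } else {
    tab <- data.frame(
      gene_id = genes$gene_id, name = genes$name, biotype = genes$biotype,
      description = genes$description,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path Path to a FASTA or FASTQ file (optionally gzipped).
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, fq = "fastq", fastq = "fastq", "fasta")
  }
  Biostrings::readDNAStringSet(path, format = format)
}

#' Write sequencing reads
#'
#' FASTQ output carries a constant dummy quality (the simulators' substitution
#' error model does not produce per-base qualities).
#'
#' @param reads A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, fq = "fastq", fastq = "fastq", "fasta")
  }
  if (format == "fastq") {
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(reads, path)
  }
  invisible(path)
}
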
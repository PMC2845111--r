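# Shared fixture builders: tiny genomes built in code, random sequence
# generators, and planted-duplication genomes for property tests.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

make_genome <- function(...) GenomeSeq(unlist(list(...)))

gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

# random multi-chromosome genome with planted direct/inverted duplications;
# returns list(genome, n_planted)
random_planted_genome <- function(seed, n_chrom = NULL, min_len = 25L) {
  set.seed(seed)
  if (is.null(n_chrom)) n_chrom <- sample(1:2, 1)
  lens <- sample(200:700, n_chrom, replace = TRUE)
  seqs <- vapply(lens, rand_seq, "")
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  n_plant <- sample(0:3, 1)
  for (i in seq_len(n_plant)) {
    L <- sample(30:80, 1)
    csrc <- sample(n_chrom, 1)
    cdst <- sample(n_chrom, 1)
    if (lens[csrc] < L + 2 || lens[cdst] < L + 2) next
    s <- sample(lens[csrc] - L + 1, 1)
    d <- sample(lens[cdst] - L + 1, 1)
    block <- substring(seqs[csrc], s, s + L - 1)
    if (runif(1) < 0.5)
      block <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(block)))
    substr(seqs[cdst], d, d + L - 1) <- block
  }
  # sprinkle a few N gaps
  if (runif(1) < 0.5) {
    ci <- sample(n_chrom, 1)
    p <- sample(lens[ci] - 5, 1)
    substr(seqs[ci], p, p + sample(1:4, 1)) <- "NNNNN"
  }
  list(genome = GenomeSeq(seqs), n_planted = n_plant)
}

# write a GenomeSeq to a temp FASTA and return the path
tmp_fasta <- function(genome) {
  path <- tempfile(fileext = ".fasta")
  write_genome(genome, path)
  path
}
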
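# Screen-simulation scenario shared by the acceptance suite: a reference
# genome carrying a multi-copy short gene (8 identical copies, echoing the
# multi-copy rRNA case the screen is designed to flag), 30 single-copy
# control loci, and one unique locus destined for deletion. Each replicate
# draws two samples: one doubling every gene copy (8 -> 16, a tandem
# duplication at each locus) for the sensitivity/specificity measurements,
# and one deleting the unique locus for the absence measurement — a
# deletion inside the sample used to build the null would contaminate the
# single-copy fragments with zero-hit draws and widen the null band.

screen_scenario <- function(seed) {
  pg <- plant_gene_copies(
    chrom_lengths = c(chr1 = 24000), n_copies = 8, corruption = "none",
    seed = seed, dup_len = 600, gene_len = 100, min_len = 300,
    biotype = "rRNA", description = "multi-copy short RNA")
  genome <- pg$genome
  chrom <- as.character(genome$seq[["chr1"]])
  blocks <- gr("chr1",
               c(pg$truth$planted_pairs$src_start[1],
                 pg$truth$planted_pairs$dest_start),
               c(pg$truth$planted_pairs$src_end[1],
                 pg$truth$planted_pairs$dest_end))
  blocks <- merge_intervals(blocks)

  # the multi-copy probe: the planted gene itself
  gene <- pg$truth$copies[1, ]
  gene_probe <- substring(chrom, gene$start, gene$end)

  # a unique 600 bp locus for deletion, plus 30 single-copy control probes,
  # all clear of the planted blocks and of each other
  taken <- blocks
  pick_free <- function(len) {
    for (i in 1:500) {
      st <- sample.int(24000 - len + 1L, 1L)
      cand <- gr("chr1", st, st + len - 1L)
      if (!length(GenomicRanges::findOverlaps(cand, taken))) {
        taken <<- c(taken, cand)
        return(st)
      }
    }
    stop("could not place a free locus")
  }
  set.seed(seed + 1000L)
  del_start <- pick_free(600L)
  del_probe <- substring(chrom, del_start + 250L, del_start + 349L)
  ctl_starts <- vapply(1:30, function(i) pick_free(100L), integer(1))
  ctl_probes <- substring(chrom, ctl_starts, ctl_starts + 99L)

  cnv_amp <- data.frame(chrom = "chr1", start = GenomicRanges::start(blocks),
                        end = GenomicRanges::end(blocks), copy_number = 2)
  cnv_del <- data.frame(chrom = "chr1", start = del_start,
                        end = del_start + 599L, copy_number = 0)

  probes <- data.frame(
    probe_id = c("gene8x", sprintf("ctl%02d", 1:30)),
    sequence = c(gene_probe, ctl_probes),
    stringsAsFactors = FALSE)
  list(genome = genome, probes = probes, del_probe = del_probe,
       cnv_amp = cnv_amp, cnv_del = cnv_del)
}

# one full replicate: screen the amplified sample (gene doubled, controls
# unchanged), then score the deleted probe against its own sample's reads
screen_replicate <- function(sc, seed, coverage = 20, read_len = 250,
                             error_rate = 0.001) {
  reads_amp <- simulate_reads(sc$genome, cnv_spec = sc$cnv_amp,
                              read_len = read_len, coverage = coverage,
                              error_rate = error_rate, seed = seed)
  res <- run_screen(sc$probes, sc$genome, reads_amp, n_fragments = 220,
                    fragment_len = 100, seed = seed + 1L)
  reads_del <- simulate_reads(sc$genome, cnv_spec = sc$cnv_del,
                              read_len = read_len, coverage = coverage,
                              error_rate = error_rate, seed = seed + 2L)
  del_hits <- count_read_hits(sc$del_probe, reads_del)
  del <- score_probe("deleted", count_genome_occurrences(sc$del_probe,
                                                         sc$genome),
                     del_hits, attr(res, "null"))
  list(screen = res, deleted = del)
}
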
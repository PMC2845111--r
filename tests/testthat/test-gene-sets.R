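# Gene containment, set inference via projection, annotation-consistency
# classification, identity verification, genome-scan extension.

# full gene pipeline on a planted genome; returns everything downstream
run_gene_pipeline <- function(pg, min_len = 300) {
  pairs <- find_maximal_identical_pairs(pg$genome, min_len)
  cores <- pairs_to_cores(pairs)
  cont <- find_contained_genes(pg$genes, cores)
  sets <- infer_gene_sets(cont, pairs, cores, pg$genes)
  list(pairs = pairs, cores = cores, cont = cont, sets = sets)
}

test_that("containment requires the whole gene span inside the core", {
  cores <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 500))
  cores$ic_id <- "IC000001"
  genes <- gr("chr1", c(150, 450, 100), c(300, 600, 500), "+")
  genes$gene_id <- c("in", "straddle", "equal")
  genes$name <- genes$gene_id
  genes$biotype <- "protein_coding"
  genes$description <- "d"
  cont <- find_contained_genes(genes, cores)
  expect_setequal(cont$gene_id, c("in", "equal")) # straddler excluded
  # pseudogenes are never probes
  genes$biotype <- "pseudogene"
  expect_equal(nrow(find_contained_genes(genes, cores)), 0L)
})

test_that("a contained gene seeds a set with its projected partner", {
  pg <- plant_gene_copies(n_copies = 2, corruption = "none", seed = 21)
  pipe <- run_gene_pipeline(pg)
  expect_equal(length(unique(pipe$sets$set_id)), 1L)
  expect_equal(nrow(pipe$sets), 2L)
  expect_true(all(pipe$sets$provenance == "annotated"))
  # member loci are exactly the planted copies
  got <- sort(paste(pipe$sets$chrom, pipe$sets$start, pipe$sets$end))
  want <- sort(paste(pg$truth$copies$chrom, pg$truth$copies$start,
                     pg$truth$copies$end))
  expect_equal(got, want)
})

test_that("a core in several pairs yields a transitive multi-member set", {
  pg <- plant_gene_copies(n_copies = 3, corruption = "none", seed = 8,
                          chrom_lengths = c(chrA = 4000, chrB = 4000,
                                            chrC = 4000))
  pipe <- run_gene_pipeline(pg)
  expect_equal(length(unique(pipe$sets$set_id)), 1L)
  expect_equal(nrow(pipe$sets), 3L)
})

test_that("an unannotated partner locus becomes a projected member", {
  pg <- plant_gene_copies(n_copies = 2, corruption = "drop", seed = 13)
  pipe <- run_gene_pipeline(pg)
  expect_equal(nrow(pipe$sets), 2L)
  expect_setequal(pipe$sets$provenance, c("annotated", "projected"))
})

test_that("each planted corruption maps to its intended category", {
  cases <- expand.grid(corr = c("none", "drop", "shrink", "pseudogenize"),
                       seed = c(2, 14), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    pg <- plant_gene_copies(n_copies = 2, corruption = cases$corr[i],
                            seed = cases$seed[i])
    pipe <- run_gene_pipeline(pg)
    cats <- classify_gene_sets(pipe$sets)
    expect_equal(nrow(cats), 1L, info = paste(cases$corr[i], cases$seed[i]))
    expect_equal(cats$category, pg$truth$expected_category,
                 info = paste(cases$corr[i], cases$seed[i]))
    expect_equal(classify_set(pipe$sets, cats$set_id[1]), cats$category)
    # every set from an exact-duplication planting verifies at 100%
    expect_true(all(verify_gene_sets(pipe$sets, pg$genome)$verified))
  }
})

test_that("category precedence puts absence above other inconsistencies", {
  # hand-built set: one unannotated member plus one pseudogenized member
  sets <- data.frame(
    set_id = "S0001", chrom = "chr1", start = c(1L, 500L), end = c(100L, 599L),
    strand = "+", provenance = c("projected", "annotated"),
    gene_id = c(NA, "g2"), gene_name = c(NA, "G"),
    biotype = c(NA, "pseudogene"), description = c(NA, "x"),
    ann_start = c(NA, 500L), ann_end = c(NA, 599L),
    stringsAsFactors = FALSE)
  class(sets) <- c("irb_gene_sets", "data.frame")
  expect_equal(classify_set(sets, "S0001"), "unannotated_member")
})

test_that("identity verification is exact and strand-aware", {
  s <- rand_seq(600)
  block <- substring(s, 101, 300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(block)))
  g <- GenomeSeq(c(chr1 = s, chr2 = paste0(rand_seq(50), block, rand_seq(50)),
                   chr3 = paste0(rand_seq(50), rc, rand_seq(50))))
  mk <- function(rows) {
    class(rows) <- c("irb_gene_sets", "data.frame")
    rows
  }
  same <- mk(data.frame(
    set_id = "S1", chrom = c("chr1", "chr2", "chr3"),
    start = c(101L, 51L, 51L), end = c(300L, 250L, 250L),
    strand = c("+", "+", "-"), provenance = "annotated",
    gene_id = NA, gene_name = NA, biotype = NA, description = NA,
    ann_start = NA, ann_end = NA, stringsAsFactors = FALSE))
  expect_true(verify_identity(same, "S1", g))
  # one mismatching base breaks verification
  off <- same
  off$start[2] <- 52L
  off$end[2] <- 251L
  expect_false(verify_identity(off, "S1", g))
  # reading the chr3 copy on + would also fail: strand matters
  wrong_strand <- same
  wrong_strand$strand[3] <- "+"
  expect_false(verify_identity(wrong_strand, "S1", g))
})

test_that("genome scan recovers extra copies and regrouping is idempotent", {
  pg <- plant_gene_copies(n_copies = 2, corruption = "none", seed = 4)
  gene <- pg$truth$copies[1, ]
  gseq <- substring(as.character(pg$genome$seq[[gene$chrom]]),
                    gene$start, gene$end)
  # plant a bare third copy (no flanking context, so it joins no core)
  s <- as.character(pg$genome$seq)
  substr(s["chrB"], 3500, 3699) <- gseq
  g2 <- GenomeSeq(s)
  pipe <- run_gene_pipeline(list(genome = g2, genes = pg$genes))
  expect_equal(nrow(pipe$sets), 2L)
  ext <- extend_and_regroup(pipe$sets, g2, annotation = pg$genes)
  expect_equal(nrow(ext), 3L)
  expect_equal(sum(ext$provenance == "genome_scan"), 1L)
  scan <- ext[ext$provenance == "genome_scan", ]
  expect_equal(scan$start, 3500L)
  expect_equal(scan$end, 3699L)
  # idempotent on member content
  ext2 <- extend_and_regroup(ext, g2, annotation = pg$genes)
  df1 <- as.data.frame(ext)
  df2 <- as.data.frame(ext2)
  attributes(df1)[c("group_map")] <- NULL
  attributes(df2)[c("group_map")] <- NULL
  expect_equal(df1, df2)
})

test_that("sets over the same sequence merge into one group", {
  # two independent plantings of the SAME block at four loci: the pipeline
  # sees two 2-member sets whose sequences are identical; regrouping unites
  # them (different minimal repeat contexts, same gene)
  set.seed(71)
  block <- rand_seq(400)
  mk_chrom <- function() paste0(rand_seq(300), block, rand_seq(300))
  g <- GenomeSeq(c(c1 = mk_chrom(), c2 = mk_chrom(), c3 = mk_chrom(),
                   c4 = mk_chrom()))
  genes <- gr(c("c1", "c2", "c3", "c4"), 401, 700, "+")
  genes$gene_id <- paste0("g", 1:4)
  genes$name <- "GENE"
  genes$biotype <- "rRNA"
  genes$description <- "same gene everywhere"
  pairs <- find_maximal_identical_pairs(g, 300)
  cores <- pairs_to_cores(pairs)
  cont <- find_contained_genes(genes, cores)
  sets <- infer_gene_sets(cont, pairs, cores, genes)
  ext <- extend_and_regroup(sets, g, annotation = genes)
  expect_equal(length(unique(ext$set_id)), 1L)
  expect_equal(nrow(ext), 4L)
})

test_that("planted k-copy genes give a group of size k via genome scan", {
  for (k in 2:4) {
    pg <- plant_gene_copies(n_copies = k, corruption = "none", seed = 30 + k,
                            chrom_lengths = c(chrA = 6000, chrB = 6000))
    pipe <- run_gene_pipeline(pg)
    ext <- extend_and_regroup(pipe$sets, pg$genome, annotation = pg$genes)
    expect_equal(length(unique(ext$set_id)), 1L)
    expect_equal(nrow(ext), k)
  }
})
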
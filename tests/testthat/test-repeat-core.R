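# Maximal identical pair detection, IC decomposition, families, projection.

test_that("no pair is reported when the only identity is a self-match", {
  # the palindromic ACGT matches itself at identical coordinates: a
  # self-pair, excluded by convention
  g <- GenomeSeq(c(chr1 = "ACGTGCTA"))
  expect_equal(nrow(find_maximal_identical_pairs(g, 4)), 0L)
})

test_that("N breaks eligibility and bounds maximal extension", {
  g <- GenomeSeq(c(chr1 = "AAAANAAAA"))
  p <- find_maximal_identical_pairs(g, 4)
  expect_equal(nrow(p), 1L)
  expect_equal(p$start1, 1L)
  expect_equal(p$end1, 4L)
  expect_equal(p$start2, 6L)
  expect_equal(p$end2, 9L)
  expect_equal(p$orientation, "direct")
})

test_that("a homopolymer yields one maximal pair per offset", {
  g <- GenomeSeq(c(chr1 = "AAAAAAAAAA"))
  p <- find_maximal_identical_pairs(g, 5)
  expect_equal(nrow(p), 5L)
  # pairs are [1, 10-d] x [d+1, 10] for d = 1..5
  expect_setequal(p$start2 - p$start1, 1:5)
  expect_true(all(p$start1 == 1L & p$end2 == 10L))
  expect_true(all(p$end1 - p$start1 + 1L == p$length))
})

test_that("a planted copy in random background matches the exhaustive oracle", {
  set.seed(42)
  s <- rand_seq(300)
  block <- substring(s, 40, 64)
  substr(s, 200, 224) <- block
  g <- GenomeSeq(c(chr1 = s))
  imp <- pairs_for_compare(find_maximal_identical_pairs(g, 20))
  ora <- oracle_pairs(g, 20)
  expect_equal(imp, ora)
  expect_gte(nrow(imp), 1L)
  expect_true(any(imp$length >= 25L))
})

test_that("implementation equals the oracle across random seeded genomes", {
  for (seed in 1:25) {
    rp <- random_planted_genome(seed)
    ml <- c(20L, 25L, 30L)[seed %% 3 + 1]
    imp <- pairs_for_compare(find_maximal_identical_pairs(rp$genome, ml))
    ora <- oracle_pairs(rp$genome, ml)
    expect_equal(imp, ora, info = paste("seed", seed))
  }
})

test_that("every emitted pair is maximal under one-base extension", {
  check_maximal <- function(genome, pairs) {
    s <- lapply(as.character(genome$seq), function(x) strsplit(x, "")[[1]])
    acgt <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ok <- function(ch, pos) pos >= 1 && pos <= length(s[[ch]]) &&
      s[[ch]][pos] %in% acgt
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      if (p$orientation == "direct") {
        left_ext <- ok(p$chrom1, p$start1 - 1) && ok(p$chrom2, p$start2 - 1) &&
          s[[p$chrom1]][p$start1 - 1] == s[[p$chrom2]][p$start2 - 1]
        right_ext <- ok(p$chrom1, p$end1 + 1) && ok(p$chrom2, p$end2 + 1) &&
          s[[p$chrom1]][p$end1 + 1] == s[[p$chrom2]][p$end2 + 1]
      } else {
        left_ext <- ok(p$chrom1, p$start1 - 1) && ok(p$chrom2, p$end2 + 1) &&
          s[[p$chrom1]][p$start1 - 1] == comp[s[[p$chrom2]][p$end2 + 1]]
        right_ext <- ok(p$chrom1, p$end1 + 1) && ok(p$chrom2, p$start2 - 1) &&
          s[[p$chrom1]][p$end1 + 1] == comp[s[[p$chrom2]][p$start2 - 1]]
      }
      expect_false(isTRUE(left_ext), info = paste("left ext, pair", i))
      expect_false(isTRUE(right_ext), info = paste("right ext, pair", i))
    }
  }
  for (seed in c(7, 19, 23)) {
    rp <- random_planted_genome(seed)
    pairs <- find_maximal_identical_pairs(rp$genome, 20)
    check_maximal(rp$genome, pairs)
  }
})

test_that("identical input yields identical, canonically ordered output", {
  rp <- random_planted_genome(11)
  p1 <- find_maximal_identical_pairs(rp$genome, 20)
  p2 <- find_maximal_identical_pairs(rp$genome, 20)
  expect_identical(p1, p2)
  ci1 <- match(p1$chrom1, names(rp$genome$seq))
  expect_true(!is.unsorted(order(ci1, p1$start1, p1$end1)))
  # left member never after right member in canonical coordinates
  ci2 <- match(p1$chrom2, names(rp$genome$seq))
  expect_true(all(ci1 < ci2 | (ci1 == ci2 & (p1$start1 < p1$start2 |
    (p1$start1 == p1$start2 & p1$end1 <= p1$end2)))))
})

test_that("pairs decompose into one core per distinct member span", {
  # disjoint members: 2 cores; a member shared by two pairs dedups
  s <- rand_seq(500)
  block <- substring(s, 1, 40)
  substr(s, 200, 239) <- block
  substr(s, 400, 439) <- block
  g <- GenomeSeq(c(chr1 = s))
  pairs <- find_maximal_identical_pairs(g, 30)
  cores <- pairs_to_cores(pairs)
  key <- paste(c(pairs$chrom1, pairs$chrom2), c(pairs$start1, pairs$start2),
               c(pairs$end1, pairs$end2))
  expect_equal(length(cores), length(unique(key)))
  expect_lte(length(cores), 2L * nrow(pairs))
  # no two cores share the same span
  ckey <- paste(GenomicRanges::seqnames(cores), GenomicRanges::start(cores),
                GenomicRanges::end(cores))
  expect_equal(anyDuplicated(ckey), 0L)
  # the shared member lists every pair it participates in
  n_pairs_per_core <- lengths(cores$pair_ids)
  expect_equal(sum(n_pairs_per_core), 2L * nrow(pairs))
  expect_true(any(n_pairs_per_core >= 2L))
})

test_that("core count equals distinct member spans on random inputs", {
  for (seed in c(3, 13, 31)) {
    rp <- random_planted_genome(seed)
    pairs <- find_maximal_identical_pairs(rp$genome, 20)
    if (nrow(pairs) == 0) next
    cores <- pairs_to_cores(pairs)
    key <- unique(paste(c(pairs$chrom1, pairs$chrom2),
                        c(pairs$start1, pairs$start2),
                        c(pairs$end1, pairs$end2)))
    expect_equal(length(cores), length(key))
  }
})

test_that("families group cores by strand-canonicalized sequence", {
  seqA <- "ACGTTACGGTACCGTTAGCA"
  g <- GenomeSeq(c(
    chr1 = paste0("TTTTTTTTTT", seqA, "CCCCCCCCCC"),
    chr2 = paste0("GGGGGGGGGG", seqA, "AAAAAAAAAA"),
    chr3 = paste0("TGTGTGTGTG", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seqA))), "CACACACACA")))
  pairs <- find_maximal_identical_pairs(g, 15)
  cores <- assign_families(pairs_to_cores(pairs), g)
  # the direct copy and the reverse-complement copy all share one family
  fams <- unique(cores$family_id[GenomicRanges::start(cores) == 11 &
                                   GenomicRanges::width(cores) == 20])
  expect_equal(length(fams), 1L)
  # both members of every pair share a family (pairs recoverable in-family)
  fam_of <- setNames(cores$family_id,
                     paste(GenomicRanges::seqnames(cores),
                           GenomicRanges::start(cores),
                           GenomicRanges::end(cores)))
  expect_equal(unname(fam_of[paste(pairs$chrom1, pairs$start1, pairs$end1)]),
               unname(fam_of[paste(pairs$chrom2, pairs$start2, pairs$end2)]))
  # a distinct sequence gets a distinct family
  set.seed(99)
  g2 <- GenomeSeq(c(chr1 = paste0(strrep(substring(rand_seq(40), 1, 20), 2),
                                  rand_seq(10))))
  p2 <- find_maximal_identical_pairs(g2, 10)
  c2 <- assign_families(pairs_to_cores(p2), g2)
  expect_gte(length(unique(c2$family_id)), 1L)
})

test_that("span projection follows offset/reflection arithmetic", {
  direct <- data.frame(pair_id = "P1", chrom1 = "chr1", start1 = 1L,
                       end1 = 1000L, chrom2 = "chr2", start2 = 5001L,
                       end2 = 6000L, length = 1000L, orientation = "direct",
                       stringsAsFactors = FALSE)
  sp <- gr("chr1", 101, 300, "+")
  pr <- project_span(direct, sp)
  expect_equal(as.character(GenomicRanges::seqnames(pr)), "chr2")
  expect_equal(GenomicRanges::start(pr), 5101L)
  expect_equal(GenomicRanges::end(pr), 5300L)
  expect_equal(as.character(GenomicRanges::strand(pr)), "+")

  inverted <- data.frame(pair_id = "P2", chrom1 = "chr1", start1 = 1L,
                         end1 = 1000L, chrom2 = "chr1", start2 = 9001L,
                         end2 = 10000L, length = 1000L,
                         orientation = "inverted", stringsAsFactors = FALSE)
  pi <- project_span(inverted, sp)
  expect_equal(GenomicRanges::start(pi), 9701L)
  expect_equal(GenomicRanges::end(pi), 9900L)
  expect_equal(as.character(GenomicRanges::strand(pi)), "-")

  # projection is an involution for both orientations
  for (pair in list(direct, inverted)) {
    back <- project_span(pair, project_span(pair, sp))
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(sp))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(sp))
    expect_equal(as.character(GenomicRanges::strand(back)), "+")
  }
  # spans outside both members are an error
  expect_error(project_span(direct, gr("chr1", 900, 1100)), "not contained")
})

test_that("planted duplications project sequences onto identical partners", {
  sim <- simulate_genome(list(
    chrom_lengths = c(chrA = 3000, chrB = 3000),
    plantings = data.frame(length = 400, orientation = "inverted",
                           src_chrom = "chrA", src_start = 500,
                           dest_chrom = "chrB", dest_start = 1200),
    min_len = 300), seed = 5)
  pairs <- find_maximal_identical_pairs(sim$genome, 300)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$orientation, "inverted")
  span <- gr("chrA", 550, 649, "+")
  proj <- project_span(pairs[1, ], span)
  s1 <- substring(as.character(sim$genome$seq[["chrA"]]), 550, 649)
  s2 <- substring(as.character(sim$genome$seq[["chrB"]]),
                  GenomicRanges::start(proj), GenomicRanges::end(proj))
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s2))), s1)
})
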
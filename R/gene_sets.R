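## Identical gene-copy sets: genes fully contained in Identical Cores are
## projected through the repeat pairs of their cores to infer every copy,
## the copies are grouped into sets, each set is classified by the
## consistency of its annotation, verified for 100% identity, and finally
## extended/regrouped by whole-genome exact search.

#' Find genes fully contained in Identical Cores
#'
#' Only genes with a probe biotype (see [gene_probe_biotypes()]; pseudogenes
#' and uncategorized entries are excluded) are considered. A gene qualifies
#' when its whole span lies inside a core's span (boundary-equal spans
#' included).
#'
#' @param genes A gene [GenomicRanges::GRanges] (see [read_genes()]).
#' @param cores A core [GenomicRanges::GRanges] from [pairs_to_cores()].
#' @return A data frame of containments with columns `gene_id` and `ic_id`
#'   (one row per gene/core containment).
#' @export
find_contained_genes <- function(genes, cores) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(cores, "GRanges"))
  probes <- genes[genes$biotype %in% gene_probe_biotypes()]
  if (length(probes) == 0L || length(cores) == 0L)
    return(data.frame(gene_id = character(), ic_id = character(),
                      stringsAsFactors = FALSE))
  h <- .harmonize(.strandless(probes), .strandless(cores))
  hits <- GenomicRanges::findOverlaps(h$a, h$b, type = "within")
  data.frame(gene_id = probes$gene_id[S4Vectors::queryHits(hits)],
             ic_id = cores$ic_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

.locus_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

#' Infer sets of identical gene copies by pair projection
#'
#' Each contained gene's span is projected through every repeat pair its
#' core participates in, and transitively through pairs containing the
#' projected loci, until closure. Loci that are projections of one another
#' form one set (connected components of the projection graph). Every locus
#' is then resolved against the annotation: a locus overlapped by an
#' annotated gene becomes an annotated member (the maximum-overlap gene is
#' recorded, including pseudogenes), all other loci become projected
#' members. Because cores come in pairs, every set has at least two members.
#'
#' @param containments Data frame from [find_contained_genes()].
#' @param pairs The `irb_pairs` data frame the cores were derived from.
#' @param cores The core [GenomicRanges::GRanges] (must carry `pair_ids`).
#' @param annotation Full gene [GenomicRanges::GRanges] used to resolve
#'   members — the unfiltered list, so that pseudogene annotations are seen.
#' @param max_loci Safety cap on the closure size (default 10000).
#' @return A data frame of class `irb_gene_sets`: one row per member with
#'   `set_id`, `chrom`, `start`, `end`, `strand`, `provenance`
#'   (`"annotated"`/`"projected"`), `gene_id`, `gene_name`, `biotype`,
#'   `description`, `ann_start`, `ann_end`.
#' @export
infer_gene_sets <- function(containments, pairs, cores, annotation,
                            max_loci = 10000L) {
  stopifnot(is.data.frame(containments), inherits(pairs, "irb_pairs"),
            methods::is(cores, "GRanges"), methods::is(annotation, "GRanges"))
  if (nrow(containments) == 0L) return(.empty_gene_sets())
  seed_ids <- unique(containments$gene_id)
  if (any(is.na(match(seed_ids, annotation$gene_id))))
    stop("containment gene_id(s) missing from annotation")
  seeds <- annotation[match(seed_ids, annotation$gene_id)]
  ## pair member lookup tables
  prow <- seq_len(nrow(pairs))
  memb <- GenomicRanges::GRanges(
    c(pairs$chrom1, pairs$chrom2),
    IRanges::IRanges(c(pairs$start1, pairs$start2),
                     c(pairs$end1, pairs$end2)))
  memb_pair <- c(prow, prow)

  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(seeds)),
    start = GenomicRanges::start(seeds), end = GenomicRanges::end(seeds),
    strand = as.character(GenomicRanges::strand(seeds)),
    stringsAsFactors = FALSE)
  loci$key <- .locus_key(loci$chrom, loci$start, loci$end)
  loci <- loci[!duplicated(loci$key), , drop = FALSE]
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  todo <- seq_len(nrow(loci))
  while (length(todo)) {
    cur <- loci[todo, , drop = FALSE]
    cur_gr <- GenomicRanges::GRanges(
      cur$chrom, IRanges::IRanges(cur$start, cur$end), strand = cur$strand)
    h <- .harmonize(cur_gr, memb)
    hits <- GenomicRanges::findOverlaps(h$a, h$b, type = "within",
                                        ignore.strand = TRUE)
    fresh <- list()
    new_edges <- list()
    for (i in seq_along(hits)) {
      q <- S4Vectors::queryHits(hits)[i]
      p <- memb_pair[S4Vectors::subjectHits(hits)[i]]
      proj <- project_span(pairs[p, , drop = FALSE], cur_gr[q])
      pk <- .locus_key(as.character(GenomicRanges::seqnames(proj)),
                       GenomicRanges::start(proj), GenomicRanges::end(proj))
      if (pk == cur$key[q]) next # self-image (e.g. palindromic geometry)
      new_edges[[length(new_edges) + 1L]] <- c(cur$key[q], pk)
      if (!(pk %in% loci$key) &&
          !any(vapply(fresh, function(x) x$key == pk, logical(1)))) {
        fresh[[length(fresh) + 1L]] <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(proj)),
          start = GenomicRanges::start(proj),
          end = GenomicRanges::end(proj),
          strand = as.character(GenomicRanges::strand(proj)),
          key = pk, stringsAsFactors = FALSE)
      }
    }
    if (length(new_edges))
      edges <- rbind(edges, data.frame(
        from = vapply(new_edges, `[`, "", 1L),
        to = vapply(new_edges, `[`, "", 2L), stringsAsFactors = FALSE))
    if (length(fresh)) {
      add <- do.call(rbind, fresh)
      first_new <- nrow(loci) + 1L
      loci <- rbind(loci, add)
      todo <- seq.int(first_new, nrow(loci))
    } else {
      todo <- integer()
    }
    if (nrow(loci) > max_loci)
      stop("projection closure exceeded max_loci = ", max_loci)
  }

  ## overlap edges: loci sharing bp on the same chromosome describe the same
  ## gene copy (e.g. an annotation shorter than the projected span), so they
  ## must land in the same set
  all_gr <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(loci$start, loci$end))
  self_ov <- GenomicRanges::findOverlaps(all_gr, all_gr)
  qo <- S4Vectors::queryHits(self_ov)
  so <- S4Vectors::subjectHits(self_ov)
  keep_ov <- qo < so
  if (any(keep_ov))
    edges <- rbind(edges, data.frame(from = loci$key[qo[keep_ov]],
                                     to = loci$key[so[keep_ov]],
                                     stringsAsFactors = FALSE))

  ## connected components of the projection graph
  g <- igraph::graph_from_data_frame(
    unique(edges), directed = FALSE,
    vertices = data.frame(name = loci$key, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[loci$key]

  ## within a component, overlapping loci are one gene copy: keep the widest
  ## locus per copy location (the shortest element adjusted to the largest)
  keep <- rep(TRUE, nrow(loci))
  for (cp in unique(comp)) {
    idx <- which(comp == cp)
    cl_gr <- all_gr[idx]
    clusters <- GenomicRanges::reduce(cl_gr, min.gapwidth = 0L)
    assign <- GenomicRanges::findOverlaps(cl_gr, clusters,
                                          select = "arbitrary")
    for (cl in unique(assign)) {
      members <- idx[assign == cl]
      if (length(members) > 1L) {
        w <- loci$end[members] - loci$start[members]
        keep[members[-which.max(w)]] <- FALSE
      }
    }
  }
  loci <- loci[keep, , drop = FALSE]
  comp <- comp[keep]
  ## order sets by their first locus (chromosome order, start)
  chroms <- attr(pairs, "chrom_levels")
  if (is.null(chroms)) chroms <- unique(loci$chrom)
  loci_ord <- order(match(loci$chrom, chroms), loci$start, loci$end)
  set_of <- match(comp, unique(comp[loci_ord]))
  loci$set_id <- sprintf("S%04d", set_of)

  ## resolve members against annotation (maximum-overlap gene, if any)
  loci_gr <- GenomicRanges::GRanges(loci$chrom,
                                    IRanges::IRanges(loci$start, loci$end))
  h <- .harmonize(loci_gr, .strandless(annotation))
  hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = TRUE)
  ann_idx <- rep(NA_integer_, nrow(loci))
  if (length(hits)) {
    ovw <- GenomicRanges::width(GenomicRanges::pintersect(
      h$a[S4Vectors::queryHits(hits)], h$b[S4Vectors::subjectHits(hits)]))
    hdf <- data.frame(q = S4Vectors::queryHits(hits),
                      s = S4Vectors::subjectHits(hits), w = ovw)
    hdf <- hdf[order(hdf$q, -hdf$w, hdf$s), , drop = FALSE]
    hdf <- hdf[!duplicated(hdf$q), , drop = FALSE]
    ann_idx[hdf$q] <- hdf$s
  }
  out <- data.frame(
    set_id = loci$set_id,
    chrom = loci$chrom, start = loci$start, end = loci$end,
    strand = loci$strand,
    provenance = ifelse(is.na(ann_idx), "projected", "annotated"),
    gene_id = ifelse(is.na(ann_idx), NA_character_,
                     annotation$gene_id[ann_idx]),
    gene_name = ifelse(is.na(ann_idx), NA_character_,
                       annotation$name[ann_idx]),
    biotype = ifelse(is.na(ann_idx), NA_character_,
                     annotation$biotype[ann_idx]),
    description = ifelse(is.na(ann_idx), NA_character_,
                         annotation$description[ann_idx]),
    ann_start = ifelse(is.na(ann_idx), NA_integer_,
                       GenomicRanges::start(annotation)[ann_idx]),
    ann_end = ifelse(is.na(ann_idx), NA_integer_,
                     GenomicRanges::end(annotation)[ann_idx]),
    stringsAsFactors = FALSE)
  out <- out[order(out$set_id, match(out$chrom, chroms), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("irb_gene_sets", "data.frame")
  out
}

.empty_gene_sets <- function() {
  out <- data.frame(set_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    provenance = character(), gene_id = character(),
                    gene_name = character(), biotype = character(),
                    description = character(), ann_start = integer(),
                    ann_end = integer(), stringsAsFactors = FALSE)
  class(out) <- c("irb_gene_sets", "data.frame")
  out
}

.norm_desc <- function(name, biotype, description) {
  squish <- function(x) tolower(gsub("\\s+", " ", trimws(
    ifelse(is.na(x), "", x))))
  paste(squish(name), squish(biotype), squish(description), sep = "\r")
}

## category of one set's member data frame
.classify_members <- function(m) {
  if (any(m$provenance != "annotated")) return("unannotated_member")
  ann <- m[m$biotype != "pseudogene", , drop = FALSE]
  if (nrow(ann) == 0L) return("description_inconsistent")
  tuples <- .norm_desc(ann$gene_name, ann$biotype, ann$description)
  ref <- names(sort(table(tuples), decreasing = TRUE))[1L]
  all_t <- .norm_desc(m$gene_name, m$biotype, m$description)
  if (any(m$biotype == "pseudogene") || any(all_t != ref))
    return("description_inconsistent")
  if (any(m$ann_start != m$start | m$ann_end != m$end))
    return("size_inconsistent")
  "consistent"
}

#' Classify gene sets by annotation consistency
#'
#' Each set receives one of four categories, by decreasing precedence:
#' `unannotated_member` (at least one member has no annotation at its locus),
#' `description_inconsistent` (at least one member is annotated as a
#' pseudogene, or with a different name/biotype/description — compared
#' case-insensitively after whitespace normalization),
#' `size_inconsistent` (same description but the annotated span of at least
#' one member differs from its projected span), and `consistent`. Absence
#' from the annotation is treated as the strongest defect, which is why the
#' precedence runs in that order and each set gets exactly one label.
#'
#' @param sets An `irb_gene_sets` data frame from [infer_gene_sets()].
#' @return A data frame with `set_id`, `n_members`, `category`.
#' @export
classify_gene_sets <- function(sets) {
  stopifnot(inherits(sets, "irb_gene_sets"))
  ids <- unique(sets$set_id)
  cat <- vapply(ids, function(s)
    .classify_members(sets[sets$set_id == s, , drop = FALSE]), "")
  data.frame(set_id = ids,
             n_members = as.integer(table(sets$set_id)[ids]),
             category = unname(cat), stringsAsFactors = FALSE)
}

#' @rdname classify_gene_sets
#' @param set_id A single set identifier.
#' @return `classify_set`: the category string for one set.
#' @export
classify_set <- function(sets, set_id) {
  stopifnot(inherits(sets, "irb_gene_sets"), set_id %in% sets$set_id)
  .classify_members(sets[sets$set_id == set_id, , drop = FALSE])
}

.oriented_seq <- function(genome, chrom, start, end, strand) {
  s <- .span_seq(genome, GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end)))
  ifelse(strand == "-", .revcomp(s), s)
}

#' Verify 100% identity within gene sets
#'
#' A set verifies when all member sequences are equal once read on their
#' projected strand. Members are compared on their projection-harmonized
#' spans (all the same length by construction: annotated spans that deviate
#' in size are already replaced by the projection of the set's gene span, so
#' shorter annotations are effectively extended to the largest element
#' before comparison).
#'
#' @param sets An `irb_gene_sets` data frame.
#' @param genome The [GenomeSeq].
#' @return `verify_gene_sets`: a data frame with `set_id` and logical
#'   `verified`.
#' @export
verify_gene_sets <- function(sets, genome) {
  stopifnot(inherits(sets, "irb_gene_sets"), inherits(genome, "GenomeSeq"))
  ids <- unique(sets$set_id)
  ver <- vapply(ids, function(s) {
    m <- sets[sets$set_id == s, , drop = FALSE]
    sq <- .oriented_seq(genome, m$chrom, m$start, m$end, m$strand)
    length(unique(sq)) == 1L
  }, logical(1))
  data.frame(set_id = ids, verified = unname(ver), stringsAsFactors = FALSE)
}

#' @rdname verify_gene_sets
#' @param set_id A single set identifier.
#' @return `verify_identity`: `TRUE` iff the one set's members are identical.
#' @export
verify_identity <- function(sets, set_id, genome) {
  stopifnot(set_id %in% sets$set_id)
  m <- sets[sets$set_id == set_id, , drop = FALSE]
  sq <- .oriented_seq(genome, m$chrom, m$start, m$end, m$strand)
  length(unique(sq)) == 1L
}

#' Extend gene sets by whole-genome exact search and regroup
#'
#' For each set, every exact occurrence of the set's sequence in the genome
#' (both strands, overlapping occurrences included) that is not already a
#' member is added as a `genome_scan` member — copies whose surrounding
#' context falls short of the repeat length threshold are recovered this
#' way. Sets whose canonical sequences are equal describe the same gene and
#' are merged into a single group. The operation is idempotent.
#'
#' @param sets An `irb_gene_sets` data frame (normally verified first).
#' @param genome The [GenomeSeq].
#' @param annotation Optional gene [GenomicRanges::GRanges]; when supplied,
#'   newly found loci are resolved against it (gene fields filled in),
#'   though their provenance stays `genome_scan`.
#' @return An `irb_gene_sets` data frame with group identifiers `G....` as
#'   `set_id`; attribute `group_map` records which input sets merged into
#'   which group.
#' @export
extend_and_regroup <- function(sets, genome, annotation = NULL) {
  stopifnot(inherits(sets, "irb_gene_sets"), inherits(genome, "GenomeSeq"))
  if (nrow(sets) == 0L) return(sets)
  ids <- unique(sets$set_id)
  chrom_names <- names(genome$seq)
  gseq <- genome$seq
  per_set <- lapply(ids, function(s) {
    m <- sets[sets$set_id == s, , drop = FALSE]
    refseq <- .oriented_seq(genome, m$chrom[1], m$start[1], m$end[1],
                            m$strand[1])
    rc <- .revcomp(refseq)
    occ <- list()
    pat_fwd <- Biostrings::DNAString(refseq)
    hits_f <- Biostrings::vmatchPattern(pat_fwd, gseq)
    for (ci in seq_along(gseq)) {
      ir <- hits_f[[ci]]
      if (length(ir))
        occ[[length(occ) + 1L]] <- data.frame(
          chrom = chrom_names[ci], start = IRanges::start(ir),
          end = IRanges::end(ir), strand = "+", stringsAsFactors = FALSE)
    }
    if (rc != refseq) {
      hits_r <- Biostrings::vmatchPattern(Biostrings::DNAString(rc), gseq)
      for (ci in seq_along(gseq)) {
        ir <- hits_r[[ci]]
        if (length(ir))
          occ[[length(occ) + 1L]] <- data.frame(
            chrom = chrom_names[ci], start = IRanges::start(ir),
            end = IRanges::end(ir), strand = "-", stringsAsFactors = FALSE)
      }
    }
    occ <- do.call(rbind, occ)
    occ$key <- .locus_key(occ$chrom, occ$start, occ$end)
    have <- .locus_key(m$chrom, m$start, m$end)
    new <- occ[!(occ$key %in% have) & !duplicated(occ$key), , drop = FALSE]
    members <- m
    if (nrow(new)) {
      add <- data.frame(
        set_id = s, chrom = new$chrom, start = new$start, end = new$end,
        strand = new$strand, provenance = "genome_scan",
        gene_id = NA_character_, gene_name = NA_character_,
        biotype = NA_character_, description = NA_character_,
        ann_start = NA_integer_, ann_end = NA_integer_,
        stringsAsFactors = FALSE)
      if (!is.null(annotation)) {
        agr <- GenomicRanges::GRanges(add$chrom,
                                      IRanges::IRanges(add$start, add$end))
        h <- .harmonize(agr, .strandless(annotation))
        hits <- GenomicRanges::findOverlaps(h$a, h$b, ignore.strand = TRUE)
        if (length(hits)) {
          first <- !duplicated(S4Vectors::queryHits(hits))
          q <- S4Vectors::queryHits(hits)[first]
          sj <- S4Vectors::subjectHits(hits)[first]
          add$gene_id[q] <- annotation$gene_id[sj]
          add$gene_name[q] <- annotation$name[sj]
          add$biotype[q] <- annotation$biotype[sj]
          add$description[q] <- annotation$description[sj]
          add$ann_start[q] <- GenomicRanges::start(annotation)[sj]
          add$ann_end[q] <- GenomicRanges::end(annotation)[sj]
        }
      }
      members <- rbind(m, add)
    }
    list(canonical = .canonical_seq(refseq), members = members)
  })
  canon <- vapply(per_set, `[[`, "", "canonical")
  ## merge sets sharing a canonical sequence; order groups by first member
  first_pos <- t(vapply(per_set, function(x)
    c(match(x$members$chrom[1], chrom_names), x$members$start[1]),
    numeric(2)))
  set_order <- order(first_pos[, 1], first_pos[, 2])
  group_of <- match(canon, unique(canon[set_order]))
  gids <- sprintf("G%04d", group_of)
  out <- do.call(rbind, lapply(seq_along(per_set), function(i) {
    m <- per_set[[i]]$members
    m$set_id <- gids[i]
    m
  }))
  out$.key <- .locus_key(out$chrom, out$start, out$end)
  out <- out[!duplicated(paste(out$set_id, out$.key)), , drop = FALSE]
  out$.key <- NULL
  out <- out[order(out$set_id, match(out$chrom, chrom_names), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("irb_gene_sets", "data.frame")
  attr(out, "group_map") <- data.frame(set_id = ids, group_id = gids,
                                       stringsAsFactors = FALSE)
  out
}

#' Write gene sets to TSV
#'
#' One row per member, mirroring the package's gene-set report format:
#' set id, category and verification status (if supplied), member
#' coordinates, provenance, and annotation fields.
#'
#' @param sets An `irb_gene_sets` data frame.
#' @param path Output path.
#' @param categories Optional data frame from [classify_gene_sets()].
#' @param verified Optional data frame from [verify_gene_sets()].
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, categories = NULL, verified = NULL) {
  tab <- as.data.frame(sets)
  if (!is.null(categories))
    tab$category <- categories$category[match(tab$set_id, categories$set_id)]
  if (!is.null(verified))
    tab$verified <- verified$verified[match(tab$set_id, verified$set_id)]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
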
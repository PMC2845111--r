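# Independent oracle for maximal identical pair detection: exhaustive
# per-diagonal (direct) and per-anti-diagonal (inverted) run scanning over
# every chromosome pair. Quadratic and vectorized; intended for sequences up
# to a few kb. Shares no code with the package's seeded hash implementation.

oracle_pairs <- function(genome, min_len) {
  chroms <- names(genome$seq)
  raw <- lapply(as.character(genome$seq), function(s) strsplit(s, "")[[1]])
  names(raw) <- chroms
  # apply exclusions
  ex <- genome$excluded
  if (length(ex)) {
    sn <- as.character(GenomicRanges::seqnames(ex))
    st <- GenomicRanges::start(ex)
    en <- GenomicRanges::end(ex)
    for (i in seq_along(ex)) raw[[sn[i]]][st[i]:en[i]] <- "#"
  }
  acgt <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # two differently-masked copies so a masked char never equals itself
  A_side <- lapply(raw, function(v) ifelse(v %in% acgt, v, "!"))
  B_side <- lapply(raw, function(v) ifelse(v %in% acgt, v, "?"))
  B_rc <- lapply(raw, function(v) {
    cv <- unname(comp[rev(v)])
    ifelse(is.na(cv), "?", cv)
  })

  runs <- function(eq) {
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    list(start = starts[keep], len = r$lengths[keep])
  }

  out <- list()
  emit <- function(ci, s1, e1, cj, s2, e2, orient) {
    if (ci > cj || (ci == cj && (s1 > s2 || (s1 == s2 && e1 > e2)))) {
      tmp <- c(ci, s1, e1); ci <- cj; s1 <- s2; e1 <- e2
      cj <- tmp[1]; s2 <- tmp[2]; e2 <- tmp[3]
    }
    out[[length(out) + 1L]] <<- data.frame(
      chrom1 = chroms[ci], start1 = s1, end1 = e1,
      chrom2 = chroms[cj], start2 = s2, end2 = e2,
      length = e1 - s1 + 1L, orientation = orient,
      stringsAsFactors = FALSE)
  }

  for (ci in seq_along(chroms)) {
    for (cj in ci:length(chroms)) {
      A <- A_side[[ci]]
      na <- length(A)
      # ---- direct: A[p] vs B[p + d] ----
      B <- B_side[[cj]]
      nb <- length(B)
      dmin <- if (ci == cj) 1L else -(na - 1L)
      for (d in dmin:(nb - 1L)) {
        p1 <- max(1L, 1L - d)
        p2 <- min(na, nb - d)
        if (p2 - p1 + 1L < min_len) next
        eq <- A[p1:p2] == B[(p1 + d):(p2 + d)]
        r <- runs(eq)
        for (i in seq_along(r$start)) {
          s <- p1 + r$start[i] - 1L
          e <- s + r$len[i] - 1L
          emit(ci, s, e, cj, s + d, e + d, "direct")
        }
      }
      # ---- inverted: A vs revcomp(B); run [s,e] at shift d maps back to
      # B positions [nb + 1 - (e + d), nb + 1 - (s + d)] ----
      Brc <- B_rc[[cj]]
      nbr <- length(Brc)
      for (d in (-(na - 1L)):(nbr - 1L)) {
        p1 <- max(1L, 1L - d)
        p2 <- min(na, nbr - d)
        if (p2 - p1 + 1L < min_len) next
        eq <- A[p1:p2] == Brc[(p1 + d):(p2 + d)]
        r <- runs(eq)
        for (i in seq_along(r$start)) {
          s <- p1 + r$start[i] - 1L
          e <- s + r$len[i] - 1L
          bs <- nbr + 1L - (e + d)
          be <- nbr + 1L - (s + d)
          if (ci == cj && s == bs && e == be) next # palindromic self-pair
          emit(ci, s, e, cj, bs, be, "inverted")
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- unique(df)
  ci1 <- match(df$chrom1, chroms)
  ci2 <- match(df$chrom2, chroms)
  df <- df[order(ci1, df$start1, df$end1, ci2, df$start2, df$end2,
                 df$orientation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# strip pair ids / attributes for comparison with oracle output
pairs_for_compare <- function(pairs) {
  df <- as.data.frame(pairs)[, c("chrom1", "start1", "end1", "chrom2",
                                 "start2", "end2", "length", "orientation")]
  rownames(df) <- NULL
  df
}
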
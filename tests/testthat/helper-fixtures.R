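# fixtures built in code: tiny genomes, exon annotation and alignments

random_genome <- function(len, seed, name = "chr1") {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- name
  g
}

# exon GRanges from a list of per-transcript exon matrices (1-based closed)
make_exons <- function(..., chrom = "chr1", strand = "+", gene_id = "G1") {
  txs <- list(...)
  rows <- do.call(rbind, lapply(seq_along(txs), function(t) {
    m <- txs[[t]]
    data.frame(start = m[, 1], end = m[, 2],
               transcript_id = paste0(gene_id, ".T", t))
  }))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(rows$start, rows$end),
                         strand = strand, type = "exon", gene_id = gene_id,
                         transcript_id = rows$transcript_id)
}

# single-end alignments from a data.frame with chrom/pos/cigar
make_fragments <- function(df, seqlengths = c(chr1 = 100000L)) {
  GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(df$chrom, levels = names(seqlengths))),
    pos = as.integer(df$pos), cigar = df$cigar,
    strand = S4Vectors::Rle(factor(rep("+", nrow(df)),
                                   levels = c("+", "-", "*"))),
    names = if (is.null(df$name)) sprintf("f%d", seq_len(nrow(df))) else df$name,
    seqlengths = seqlengths)
}

# exhaustive per-read mapping oracle, independent of the Biostrings path:
# byte-level mismatch scan over every position on both strands
oracle_unique <- function(read_seq, genome_seq, max_mismatch = 1L) {
  g <- utf8ToInt(genome_seq)
  comp <- function(v) {
    out <- v
    out[v == utf8ToInt("A")] <- utf8ToInt("T")
    out[v == utf8ToInt("T")] <- utf8ToInt("A")
    out[v == utf8ToInt("C")] <- utf8ToInt("G")
    out[v == utf8ToInt("G")] <- utf8ToInt("C")
    out
  }
  hits_on <- function(r) {
    k <- length(r)
    np <- length(g) - k + 1L
    if (np < 1L) return(0L)
    mm <- integer(np)
    for (j in seq_len(k)) {
      mm <- mm + (g[j:(j + np - 1L)] != r[j])
    }
    sum(mm <= max_mismatch)
  }
  r <- utf8ToInt(read_seq)
  hits_on(r) + hits_on(rev(comp(r))) == 1L
}

oracle_mask <- function(genome, read_len = 70L, step = 10L, min_unique = 5L) {
  reads <- generate_synthetic_reads(genome, read_len = read_len, step = step)
  gseq <- as.character(genome[[1]])
  ok <- vapply(reads$seq, oracle_unique, logical(1), genome_seq = gseq)
  L <- length(genome[[1]])
  tally <- integer(L)
  for (i in which(ok)) {
    tally[reads$start[i]:reads$end[i]] <- tally[reads$start[i]:reads$end[i]] + 1L
  }
  bad <- tally < min_unique
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
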
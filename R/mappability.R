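#' Generate the synthetic-read mappability screen
#'
#' Error-bearing synthetic reads are taken from the reference itself: 70 bp
#' long, stepped at 10 bp across each chromosome, every second read
#' reverse-complemented, with a single deterministic base substitution at the
#' centre of each read (applied before the orientation flip). Re-aligning
#' these reads measures whether each genomic position can be recovered
#' uniquely by a short-read aligner despite one sequencing error.
#'
#' The substitution is a fixed rotation A->C, C->G, G->T, T->A (N->A), so the
#' screen is a pure function of the genome and its parameters; no seed is
#' involved. Orientation alternates forward/reverse starting forward,
#' restarting at each chromosome.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param read_len Read length in bp (default 70).
#' @param step Start-to-start distance in bp (default 10).
#' @param error_pos 0-based position of the substituted base within the read;
#'   default `read_len %/% 2 - 1` (position 34 for 70 bp reads).
#' @return data.frame with `read_id` (`chrom:start0:orientation`), `chrom`,
#'   `start` (1-based), `end`, `orientation` (`F`/`R`) and `seq` (the read as
#'   sequenced, i.e. after substitution and any reverse complement).
#' @export
generate_synthetic_reads <- function(genome, read_len = 70L, step = 10L,
                                     error_pos = read_len %/% 2L - 1L) {
  stopifnot(read_len > 0L, step > 0L, error_pos >= 0L, error_pos < read_len)
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- length(genome[[ci]])
    if (L < read_len) {
      warning("chromosome ", chrom, " shorter than read length; no reads")
      out[[ci]] <- NULL
      next
    }
    starts0 <- seq.int(0L, L - read_len, by = step)
    views <- Biostrings::Views(genome[[ci]], start = starts0 + 1L,
                               width = read_len)
    seqs <- as.character(views)
    centre <- substr(seqs, error_pos + 1L, error_pos + 1L)
    substr(seqs, error_pos + 1L, error_pos + 1L) <-
      chartr("ACGTN", "CGTAA", centre)
    rc <- seq_along(seqs) %% 2L == 0L  # ordinals 1,3,5.. forward; 2,4,.. reverse
    if (any(rc)) {
      seqs[rc] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
    }
    ori <- ifelse(rc, "R", "F")
    out[[ci]] <- data.frame(
      read_id = sprintf("%s:%d:%s", chrom, starts0, ori),
      chrom = chrom, start = starts0 + 1L, end = starts0 + read_len,
      orientation = ori, seq = seqs, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write synthetic reads as FASTA for an external aligner
#'
#' @param reads data.frame from [generate_synthetic_reads()].
#' @param path Output FASTA path.
#' @export
write_reads_fasta <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$read_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Tally uniquely and correctly mapped synthetic reads per base
#'
#' Each synthetic read is re-aligned and counts toward every base of its
#' origin interval iff it maps uniquely to its true origin. "Unique" means
#' exactly one location genome-wide matches the read at no more than one
#' mismatch (the planted error guarantees the origin itself matches with
#' exactly one); a second location at equal or better score destroys
#' uniqueness. With 70 bp reads stepped at 10 bp an interior base can be
#' overlapped by at most 7 reads.
#'
#' Two aligners are available: the built-in exhaustive search over both
#' strands (exact, intended for toy genomes up to a few hundred kb), or a SAM
#' file produced by an external aligner run on [write_reads_fasta()] output
#' (see `sam`); in the latter case a read is credited when it has exactly one
#' alignment record and that record reproduces the origin encoded in its id.
#'
#' @param reads data.frame from [generate_synthetic_reads()].
#' @param genome Named [Biostrings::DNAStringSet] (used by the built-in
#'   aligner; ignored when `sam` is given).
#' @param sam Optional path to external alignments of the synthetic reads.
#' @param max_mismatch Mismatch allowance of the built-in aligner (default 1,
#'   the planted error).
#' @return Named [IRanges::RleList]: per-chromosome per-base tallies.
#' @export
unique_mapping_tally <- function(reads, genome, sam = NULL, max_mismatch = 1L) {
  unique_ok <- if (is.null(sam)) {
    map_reads_builtin(reads, genome, max_mismatch)
  } else {
    map_reads_sam(reads, sam)
  }
  origins <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start, reads$end),
    seqinfo = GenomeInfoDb::Seqinfo(names(genome), Biostrings::width(genome)))
  GenomicRanges::coverage(origins[unique_ok])
}

# exhaustive both-strand substring search; TRUE iff exactly one hit <= max_mismatch
map_reads_builtin <- function(reads, genome, max_mismatch) {
  vapply(seq_len(nrow(reads)), function(i) {
    pat <- Biostrings::DNAString(reads$seq[i])
    rcp <- Biostrings::reverseComplement(pat)
    hits <- 0L
    for (ci in seq_along(genome)) {
      hits <- hits +
        Biostrings::countPattern(pat, genome[[ci]], max.mismatch = max_mismatch) +
        Biostrings::countPattern(rcp, genome[[ci]], max.mismatch = max_mismatch)
      if (hits > 1L) return(FALSE)
    }
    hits == 1L
  }, logical(1))
}

# credit reads with exactly one SAM record at the origin encoded in the read id
map_reads_sam <- function(reads, sam) {
  gal <- read_fragments(sam)
  ids <- names(gal)
  parsed <- regmatches(reads$read_id,
                       regexec("^(.+):([0-9]+):([FR])$", reads$read_id))
  if (any(lengths(parsed) != 4L)) {
    stop("read_id not parseable into chrom:start:orientation")
  }
  n_aln <- table(ids)
  vapply(seq_len(nrow(reads)), function(i) {
    id <- reads$read_id[i]
    if (is.na(n_aln[id]) || n_aln[id] != 1L) return(FALSE)
    j <- match(id, ids)
    as.character(GenomeInfoDb::seqnames(gal)[j]) == reads$chrom[i] &&
      BiocGenerics::start(gal)[j] == reads$start[i]
  }, logical(1))
}

#' Build the poor-mappability mask from per-base tallies
#'
#' Any base overlapped by fewer than `min_unique` uniquely-and-correctly
#' mapped synthetic reads (out of a possible 7 under the default 70 bp / 10 bp
#' scheme) is poorly mappable; maximal runs of failing bases are merged into
#' intervals. The threshold is absolute, so chromosome ends -- where fewer
#' than 7 reads are geometrically possible -- are masked by construction.
#'
#' @param tallies Per-chromosome [IRanges::RleList] from
#'   [unique_mapping_tally()].
#' @param min_unique Minimum unique-read tally for a mappable base (default 5).
#' @return GRanges of poorly mappable intervals, sorted and disjoint.
#' @export
build_mask <- function(tallies, min_unique = 5L) {
  per_chrom <- lapply(names(tallies), function(chrom) {
    bad <- IRanges::reduce(methods::as(tallies[[chrom]] < min_unique,
                                       "IRanges"))
    GenomicRanges::GRanges(chrom, bad)
  })
  sort(do.call(c, per_chrom), ignore.strand = TRUE)
}

#' One-shot mappability mask for a genome
#'
#' Runs [generate_synthetic_reads()], [unique_mapping_tally()] and
#' [build_mask()] with the standard parameters.
#'
#' @inheritParams generate_synthetic_reads
#' @inheritParams build_mask
#' @param sam Optional external alignments (see [unique_mapping_tally()]).
#' @return GRanges mask of poorly mappable intervals.
#' @export
mappability_mask <- function(genome, read_len = 70L, step = 10L,
                             min_unique = 5L, sam = NULL) {
  reads <- generate_synthetic_reads(genome, read_len = read_len, step = step)
  if (is.null(reads) || nrow(reads) == 0L) {
    return(GenomicRanges::GRanges())
  }
  build_mask(unique_mapping_tally(reads, genome, sam = sam),
             min_unique = min_unique)
}

#' Write a mappability mask as 3-column BED
#' @param mask GRanges from [build_mask()].
#' @param path Output path.
#' @export
write_mask_bed <- function(mask, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(mask)),
                   start = BiocGenerics::start(mask) - 1L,
                   end = BiocGenerics::end(mask))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED mask
#' @param path BED path (0-based half-open).
#' @return GRanges.
#' @export
read_mask_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}
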
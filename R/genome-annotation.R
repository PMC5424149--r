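#' Read a genome FASTA into a named DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that normalises FASTA
#' record names to their first whitespace-delimited token so they match
#' chromosome names used in GTF/SAM files.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract a genome subsequence in 0-based half-open coordinates
#'
#' External interval exchange (BED, junction offsets) is 0-based half-open;
#' this accessor enforces that convention on top of the 1-based genome
#' container. Requesting bases beyond the chromosome end is an error rather
#' than a silent clip.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval `[start, end)`.
#' @return A character scalar of length `end - start`.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom)
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || end < start) {
    stop(sprintf("interval [%d,%d) outside chromosome %s (length %d)",
                 start, end, chrom, len))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Read exon annotation from a GTF file
#'
#' Imports an Ensembl-dialect GTF via [rtracklayer::import()] and returns the
#' exon features as a GRanges with `gene_id` and `transcript_id` metadata
#' columns. Non-exon features (genes, transcripts, CDS, ncRNA features) are
#' available through `feature = NULL`.
#'
#' @param path Path to a GTF file.
#' @param feature Feature type to keep (default `"exon"`); `NULL` keeps all.
#' @return A [GenomicRanges::GRanges].
#' @export
read_annotation <- function(path, feature = "exon") {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(feature)) {
    gr <- gr[gr$type %in% feature]
  }
  gr
}

#' Derive the intron catalogue from exon annotation
#'
#' One intron per distinct genomic gap between consecutive exons of any
#' transcript of a gene. Gaps are deduplicated per gene by (chrom, span,
#' strand): the same intron annotated in several transcripts yields one
#' record, while identical gaps in two different (e.g. overlapping) genes stay
#' separate because retention is reported per gene. Single-exon transcripts
#' contribute nothing.
#'
#' The returned GRanges carries, per intron:
#' \describe{
#'   \item{intron_id}{`<gene_id>.I<rank>` with rank in strand-aware
#'     (transcription) order.}
#'   \item{gene_id, intron_rank, n_introns}{gene of origin, 1-based ordinal of
#'     the intron within the gene in transcription order, and the gene's
#'     intron count.}
#'   \item{junction5, junction3}{0-based genomic boundary coordinates of the
#'     donor (5') and acceptor (3') splice junctions. On the minus strand
#'     `junction5` is the right-hand genomic boundary.}
#'   \item{excluded, measurable}{GRangesList columns: spans removed from
#'     quantification (overlapping foreign features, poor mappability) and
#'     their complement within the intron. Initially `excluded` is empty and
#'     `measurable` is the whole span.}
#' }
#'
#' @param exons GRanges of exons with `gene_id` and `transcript_id` metadata
#'   columns (as returned by [read_annotation()]).
#' @return GRanges of introns.
#' @export
derive_introns <- function(exons) {
  stopifnot(is(exons, "GRanges"),
            all(c("gene_id", "transcript_id") %in% names(S4Vectors::mcols(exons))))
  if (length(exons) == 0L) {
    return(empty_intron_catalog())
  }

  by_tx <- split(exons, exons$transcript_id)
  gaps <- lapply(by_tx, function(tx) {
    tx <- sort(tx, ignore.strand = TRUE)
    if (length(tx) < 2L) return(NULL)
    if (length(unique(as.character(GenomeInfoDb::seqnames(tx)))) != 1L ||
        length(unique(as.character(BiocGenerics::strand(tx)))) != 1L) {
      stop("malformed annotation: transcript ", tx$transcript_id[1],
           " spans multiple chromosomes or strands")
    }
    if (any(BiocGenerics::start(tx)[-1] <= BiocGenerics::end(tx)[-length(tx)])) {
      stop("malformed annotation: overlapping exons in transcript ",
           tx$transcript_id[1])
    }
    GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(tx)[-1],
      ranges = IRanges::IRanges(start = BiocGenerics::end(tx)[-length(tx)] + 1L,
                                end = BiocGenerics::start(tx)[-1] - 1L),
      strand = BiocGenerics::strand(tx)[-1],
      gene_id = tx$gene_id[-1]
    )
  })
  gaps <- gaps[!vapply(gaps, is.null, logical(1))]
  if (length(gaps) == 0L) {
    return(empty_intron_catalog())
  }
  introns <- unlist(GenomicRanges::GRangesList(gaps), use.names = FALSE)

  key <- paste(introns$gene_id, GenomeInfoDb::seqnames(introns),
               BiocGenerics::start(introns), BiocGenerics::end(introns),
               BiocGenerics::strand(introns))
  introns <- introns[!duplicated(key)]

  # transcription-order rank within each gene (minus strand: right to left)
  ord <- order(introns$gene_id, BiocGenerics::start(introns))
  introns <- introns[ord]
  rank <- unlist(lapply(split(seq_along(introns), introns$gene_id), function(i) {
    if (as.character(BiocGenerics::strand(introns)[i[1]]) == "-") {
      rev(seq_along(i))
    } else {
      seq_along(i)
    }
  }), use.names = FALSE)
  introns$intron_rank <- rank
  n_by_gene <- table(introns$gene_id)
  introns$n_introns <- as.integer(n_by_gene[introns$gene_id])
  introns$intron_id <- sprintf("%s.I%d", introns$gene_id, introns$intron_rank)

  minus <- as.character(BiocGenerics::strand(introns)) == "-"
  introns$junction5 <- ifelse(minus, BiocGenerics::end(introns),
                              BiocGenerics::start(introns) - 1L)
  introns$junction3 <- ifelse(minus, BiocGenerics::start(introns) - 1L,
                              BiocGenerics::end(introns))

  introns$excluded <- GenomicRanges::GRangesList(
    replicate(length(introns), GenomicRanges::GRanges(), simplify = FALSE))
  introns$measurable <- methods::as(GenomicRanges::granges(introns, use.mcols = FALSE),
                                    "GRangesList")
  names(introns) <- introns$intron_id
  introns
}

empty_intron_catalog <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = character(), intron_rank = integer(), n_introns = integer(),
    intron_id = character(), junction5 = integer(), junction3 = integer(),
    excluded = GenomicRanges::GRangesList(),
    measurable = GenomicRanges::GRangesList())
  gr
}

#' Exclude foreign features from the measurable intron area
#'
#' Any annotated feature of another gene (the classic confounders being
#' miRNAs and snoRNAs hosted inside introns) that overlaps an intron is
#' removed from its measurable spans, regardless of the feature's strand:
#' expression of the embedded feature would otherwise inflate the apparent
#' intronic abundance.
#'
#' @param introns Intron catalogue from [derive_introns()].
#' @param features GRanges of foreign features. If it has a `gene_id` column,
#'   features belonging to the intron's own gene are ignored (an intron always
#'   overlaps its own gene's record).
#' @return The catalogue with updated `excluded`/`measurable` columns.
#' @export
apply_feature_exclusions <- function(introns, features) {
  if (length(features) == 0L || length(introns) == 0L) return(introns)
  features <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(features), IRanges::ranges(features),
    strand = "*",
    gene_id = if ("gene_id" %in% names(S4Vectors::mcols(features)))
      features$gene_id else NA_character_)
  hits <- GenomicRanges::findOverlaps(introns, features, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    foreign <- is.na(features$gene_id[S4Vectors::subjectHits(hits)]) |
      features$gene_id[S4Vectors::subjectHits(hits)] !=
        introns$gene_id[S4Vectors::queryHits(hits)]
    hits <- hits[foreign]
  }
  if (length(hits) == 0L) return(introns)
  clipped <- GenomicRanges::pintersect(
    GenomicRanges::granges(introns)[S4Vectors::queryHits(hits)],
    GenomicRanges::granges(features)[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE)
  add_exclusions(introns, split(clipped, S4Vectors::queryHits(hits)))
}

#' Exclude poorly mappable regions from the measurable intron area
#'
#' @param introns Intron catalogue.
#' @param mask GRanges of poorly mappable intervals (see [build_mask()]);
#'   applied regardless of strand or direction.
#' @return The catalogue with updated `excluded`/`measurable` columns.
#' @export
apply_mappability_mask <- function(introns, mask) {
  if (length(mask) == 0L || length(introns) == 0L) return(introns)
  hits <- GenomicRanges::findOverlaps(introns, mask, ignore.strand = TRUE)
  if (length(hits) == 0L) return(introns)
  clipped <- GenomicRanges::pintersect(
    GenomicRanges::granges(introns)[S4Vectors::queryHits(hits)],
    GenomicRanges::granges(mask)[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE)
  add_exclusions(introns, split(clipped, S4Vectors::queryHits(hits)))
}

# merge new per-intron exclusion spans and recompute measurable = span \ excluded
add_exclusions <- function(introns, new_by_intron) {
  idx <- as.integer(names(new_by_intron))
  excluded <- introns$excluded
  measurable <- introns$measurable
  span <- GenomicRanges::granges(introns)
  for (k in seq_along(idx)) {
    i <- idx[k]
    ex <- GenomicRanges::reduce(
      c(GenomicRanges::granges(excluded[[i]]),
        GenomicRanges::granges(new_by_intron[[k]])), ignore.strand = TRUE)
    excluded[[i]] <- ex
    measurable[[i]] <- GenomicRanges::setdiff(
      GenomicRanges::granges(span[i]), ex, ignore.strand = TRUE)
  }
  introns$excluded <- excluded
  introns$measurable <- measurable
  introns
}

#' Per-intron sequence features: length, GC fraction, CpG density
#'
#' Computed over the full intron span (not the masked area): these features
#' describe the genomic element itself. CpG density is the count of CG
#' dinucleotides on the forward genomic strand divided by intron length;
#' CG is its own reverse complement so the forward count is strand-neutral.
#'
#' @param introns Intron catalogue.
#' @param genome Named [Biostrings::DNAStringSet].
#' @return data.frame with `intron_id`, `length`, `gc_fraction`, `cpg_density`.
#' @export
sequence_features <- function(introns, genome) {
  if (any(BiocGenerics::width(introns) == 0L)) {
    stop("zero-length intron span")
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(introns), function(i) {
    genome[[as.character(GenomeInfoDb::seqnames(introns)[i])]][
      BiocGenerics::start(introns)[i]:BiocGenerics::end(introns)[i]]
  }))
  len <- Biostrings::width(seqs)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  gc <- (freq[, "G"] + freq[, "C"]) / len
  cpg <- Biostrings::vcountPattern("CG", seqs) / len
  data.frame(intron_id = introns$intron_id, length = len,
             gc_fraction = gc, cpg_density = cpg,
             stringsAsFactors = FALSE)
}

#' Write the intron catalogue as 6-column BED
#'
#' BED is 0-based half-open; name column is the intron id.
#'
#' @param introns Intron catalogue.
#' @param path Output path.
#' @export
write_intron_bed <- function(introns, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(introns)),
    start = BiocGenerics::start(introns) - 1L,
    end = BiocGenerics::end(introns),
    name = introns$intron_id,
    score = 0L,
    strand = as.character(BiocGenerics::strand(introns)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
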
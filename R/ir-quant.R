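#' Read aligned RNA-seq fragments from SAM or BAM
#'
#' Alignments are loaded with [GenomicAlignments::readGAlignments()]; a SAM
#' file is first converted to a temporary BAM via [Rsamtools::asBam()].
#' Spliced alignments are carried as N operations in the cigar; multi-mapping
#' reads are assumed to have been excluded by the aligner upstream.
#'
#' @param path SAM or BAM file.
#' @return A [GenomicAlignments::GAlignments], named by fragment (read) id.
#' @export
read_fragments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai")), force = TRUE))
    path <- bam
  }
  GenomicAlignments::readGAlignments(path, use.names = TRUE)
}

#' Count splice-junction fragments for one or more introns
#'
#' Abundance of normal splicing for an intron is counted from fragments whose
#' alignment gap spans the intron. Beyond the exact donor-to-acceptor
#' junction, fragments spliced from the 5' exon into any downstream exon
#' (donor anchored at the intron's 5' junction) and fragments spliced from any
#' upstream exon into the 3' exon (acceptor anchored at the 3' junction) are
#' also counted, and the larger of the two one-sided tallies is used. Exact
#' fragments count in both one-sided tallies, so
#' `splice_abundance = max(splice_left, splice_right) >= splice_exact`.
#'
#' @param fragments [GenomicAlignments::GAlignments] (or the junction
#'   GRangesList from [GenomicAlignments::junctions()]).
#' @param introns Intron catalogue from [derive_introns()].
#' @return data.frame with `intron_id`, `splice_exact`, `splice_left`,
#'   `splice_right`, `splice_abundance`.
#' @export
count_splice <- function(fragments, introns) {
  juncs <- if (methods::is(fragments, "GRangesList")) fragments
           else GenomicAlignments::junctions(fragments)
  flat <- unlist(juncs, use.names = FALSE)
  frag_of <- rep(seq_along(juncs), lengths(juncs))

  count_frags <- function(hits) {
    # fragments, not junction instances: dedupe (intron, fragment) pairs
    if (length(hits) == 0L) return(integer(length(introns)))
    keys <- unique(paste0(S4Vectors::queryHits(hits), "_",
                          frag_of[S4Vectors::subjectHits(hits)]))
    tab <- table(as.integer(sub("_.*", "", keys)))
    out <- integer(length(introns))
    out[as.integer(names(tab))] <- as.integer(tab)
    out
  }

  span <- GenomicRanges::granges(introns)
  exact <- count_frags(GenomicRanges::findOverlaps(
    span, flat, type = "equal", ignore.strand = TRUE))

  # one-sided anchors: the gap shares the intron's donor (5') or acceptor (3')
  # genomic boundary; on the minus strand the donor is the right-hand boundary.
  # all anchors are built as plain 1 bp coordinates, ignoring strand
  minus <- as.character(BiocGenerics::strand(introns)) == "-"
  point <- function(pos) {
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(span),
                           IRanges::IRanges(pos, pos))
  }
  left_anchor <- point(BiocGenerics::start(span))
  right_anchor <- point(BiocGenerics::end(span))
  gap_left <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(flat),
    IRanges::IRanges(BiocGenerics::start(flat), BiocGenerics::start(flat)))
  gap_right <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(flat),
    IRanges::IRanges(BiocGenerics::end(flat), BiocGenerics::end(flat)))

  anchored <- function(anchor, gaps) {
    count_frags(GenomicRanges::findOverlaps(anchor, gaps, type = "equal",
                                            ignore.strand = TRUE))
  }
  left_at_left <- anchored(left_anchor, gap_left)    # gap starts at intron start
  right_at_right <- anchored(right_anchor, gap_right) # gap ends at intron end
  # plus strand: donor = left boundary; minus strand: donor = right boundary
  donor <- ifelse(minus, right_at_right, left_at_left)
  acceptor <- ifelse(minus, left_at_left, right_at_right)

  data.frame(intron_id = introns$intron_id,
             splice_exact = exact,
             splice_left = donor,
             splice_right = acceptor,
             splice_abundance = pmax(donor, acceptor),
             stringsAsFactors = FALSE)
}

#' Trimmed mean of per-base coverage depth
#'
#' Values are sorted and `floor(trim_fraction * n)` are dropped from each end
#' before averaging; with the default 30% trim the highest and lowest 30% of
#' values are excluded, compensating for noise in intronic coverage. Depths
#' must already be restricted to the measurable spans (poor mappability and
#' foreign features removed, not zero-filled).
#'
#' @param depths Numeric vector of per-base depths over measurable positions.
#' @param trim_fraction Fraction trimmed from each end (default 0.30).
#' @return The trimmed mean, or `NA_real_` when no measurable base exists
#'   (not assessable; distinct from an IR ratio of 0).
#' @export
trimmed_mean_depth <- function(depths, trim_fraction = 0.30) {
  n <- length(depths)
  if (n == 0L) return(NA_real_)
  k <- floor(trim_fraction * n)
  mean(sort(depths)[(k + 1L):(n - k)])
}

#' The IR ratio
#'
#' `intronic / (intronic + splice)`: the intron's trimmed-mean fragment depth
#' as a share of that depth plus the splice-junction fragment count. Bounded
#' in \[0, 1\]; 0/0 (no evidence either way) is not assessable.
#'
#' @param intronic_abundance Trimmed-mean intronic depth (>= 0).
#' @param splice_abundance Splice-junction fragment count (>= 0).
#' @return IR ratio in \[0,1\], `NA_real_` if not assessable. Vectorised.
#' @export
ir_ratio <- function(intronic_abundance, splice_abundance) {
  if (any(intronic_abundance < 0, na.rm = TRUE) ||
      any(splice_abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  total <- intronic_abundance + splice_abundance
  ifelse(is.na(total) | total == 0, NA_real_, intronic_abundance / total)
}

#' Classify an intron as retained
#'
#' The retention floor is an IR level of 10%, inclusive.
#'
#' @param ratio IR ratio (vectorised); `NA` (not assessable) propagates.
#' @param threshold Retention threshold (default 0.10).
#' @return Logical vector.
#' @export
classify_retained <- function(ratio, threshold = 0.10) {
  ratio >= threshold
}

#' Quantify intron retention for one sample
#'
#' For every intron: the splice-junction counts from [count_splice()], the
#' per-base fragment depth over the measurable spans, its 30%-trimmed mean,
#' the IR ratio and the retained flag. Depth counts every fragment base
#' (alignment block base) overlapping a measurable position, including reads
#' running across the exon-intron boundary; alignment gaps contribute no
#' depth. Introns whose measurable area is empty are marked not assessable
#' (`NA` abundance and ratio).
#'
#' @param fragments [GenomicAlignments::GAlignments] from [read_fragments()]
#'   or a path to a SAM/BAM file.
#' @param introns Intron catalogue, ideally after [apply_mappability_mask()]
#'   and [apply_feature_exclusions()].
#' @param sample_id Sample label stored in the output.
#' @param trim_fraction Trim for the intronic depth mean (default 0.30).
#' @param threshold Retention threshold on the IR ratio (default 0.10).
#' @return data.frame (one row per intron): `intron_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `sample_id`, `splice_exact`, `splice_left`,
#'   `splice_right`, `splice_abundance`, `measurable_bases`,
#'   `intronic_abundance`, `ir_ratio`, `retained`.
#' @export
quantify_ir <- function(fragments, introns, sample_id = "sample",
                        trim_fraction = 0.30, threshold = 0.10) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  sp <- count_splice(fragments, introns)

  blocks <- GenomicRanges::granges(unlist(
    GenomicAlignments::grglist(fragments), use.names = FALSE))
  cov <- GenomicRanges::coverage(blocks)

  measurable <- introns$measurable
  intronic <- rep(NA_real_, length(introns))
  nbases <- integer(length(introns))
  for (i in seq_along(introns)) {
    ms <- measurable[[i]]
    if (length(ms) == 0L) next
    chrom <- as.character(GenomeInfoDb::seqnames(ms))[1]
    depths <- if (chrom %in% names(cov)) {
      unlist(lapply(seq_along(ms), function(j) {
        as.numeric(S4Vectors::window(cov[[chrom]],
                                     BiocGenerics::start(ms)[j],
                                     BiocGenerics::end(ms)[j]))
      }), use.names = FALSE)
    } else {
      numeric(sum(BiocGenerics::width(ms)))
    }
    nbases[i] <- length(depths)
    intronic[i] <- trimmed_mean_depth(depths, trim_fraction)
  }

  # NA intronic abundance (empty measurable area) and 0/0 both yield NA:
  # the intron is not assessable, which is distinct from an IR ratio of 0
  ratio <- ir_ratio(intronic, sp$splice_abundance)

  data.frame(intron_id = introns$intron_id,
             gene_id = introns$gene_id,
             chrom = as.character(GenomeInfoDb::seqnames(introns)),
             start = BiocGenerics::start(introns) - 1L,
             end = BiocGenerics::end(introns),
             strand = as.character(BiocGenerics::strand(introns)),
             sample_id = sample_id,
             splice_exact = sp$splice_exact,
             splice_left = sp$splice_left,
             splice_right = sp$splice_right,
             splice_abundance = sp$splice_abundance,
             measurable_bases = nbases,
             intronic_abundance = ifelse(nbases == 0L, NA_real_, intronic),
             ir_ratio = ratio,
             retained = classify_retained(ratio, threshold),
             stringsAsFactors = FALSE)
}

#' Collect per-base depths over the measurable spans of one intron
#'
#' Exposed mainly for depth-accounting checks: the sum over fragments of
#' their overlap with the measurable spans equals the sum of this vector.
#'
#' @param fragments [GenomicAlignments::GAlignments].
#' @param intron A single-intron subset of the catalogue.
#' @return Numeric vector of depths, one per measurable base.
#' @export
intron_depth_vector <- function(fragments, intron) {
  stopifnot(length(intron) == 1L)
  ms <- intron$measurable[[1]]
  if (length(ms) == 0L) return(numeric(0))
  blocks <- GenomicRanges::granges(unlist(
    GenomicAlignments::grglist(fragments), use.names = FALSE))
  cov <- GenomicRanges::coverage(blocks)
  chrom <- as.character(GenomeInfoDb::seqnames(ms))[1]
  if (!chrom %in% names(cov)) return(numeric(sum(BiocGenerics::width(ms))))
  unlist(lapply(seq_along(ms), function(j) {
    as.numeric(S4Vectors::window(cov[[chrom]], BiocGenerics::start(ms)[j],
                                 BiocGenerics::end(ms)[j]))
  }), use.names = FALSE)
}

#' Write / read a per-sample IR quantification table
#'
#' Tab-separated with a header; `NA` marks not-assessable introns.
#' @param quant data.frame from [quantify_ir()].
#' @param path File path.
#' @export
write_ir_quant <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ir_quant
#' @export
read_ir_quant <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
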
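#' Simulation configuration
#'
#' Bundles every knob of the synthetic toy-genome pipeline. Identical config
#' plus seed yields byte-identical outputs.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_genes Number of genes (placed on alternating strands along one
#'   chromosome).
#' @param exons_per_gene Exons per gene (introns per gene is one fewer).
#' @param exon_len,intron_len Length ranges (min, max) in bp.
#' @param true_ir Per-intron true retention fraction in \[0,1\]: a scalar, a
#'   vector recycled over introns, or `NULL` to draw each uniformly from
#'   \[0, 0.8\].
#' @param fragments_per_gene RNA-seq fragments simulated per gene.
#' @param frag_len Fragment length in bp (fixed).
#' @param intergenic Gap between genes and padding at chromosome ends, bp.
#' @param duplication Either `NULL` or a list `list(length =, copies =)`:
#'   plants exact copies of one random block at the chromosome end to stress
#'   the mappability screen.
#' @param foreign_features Number of introns that receive a planted foreign
#'   ncRNA feature (annotated under its own gene id).
#' @param baseline_beta Background CpG methylation level.
#' @param dip_depth Drop in beta near retained-intron junctions (0 disables).
#' @param dip_width Half-width in bp of the junction-proximal dip.
#' @param cpg_spacing `NULL` to use the CpGs arising naturally in the random
#'   sequence, or an integer to additionally plant a CG every that many bp.
#' @param coverage_mean Mean (Poisson) read coverage per CpG site.
#' @param chip_base,chip_scale ChIP fold enrichment is
#'   `chip_base + chip_scale * beta` at the peak centre.
#' @param chip_peak_width Width of the tiled ChIP signal intervals, bp.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_genes = 20L, exons_per_gene = 3L,
                       exon_len = c(150L, 250L), intron_len = c(200L, 400L),
                       true_ir = NULL, fragments_per_gene = 2000L,
                       frag_len = 70L, intergenic = 500L,
                       duplication = NULL, foreign_features = 0L,
                       baseline_beta = 0.8, dip_depth = 0.3,
                       dip_width = 100L, cpg_spacing = NULL,
                       coverage_mean = 30, chip_base = 1, chip_scale = 4,
                       chip_peak_width = 50L) {
  stopifnot(exon_len[1] > 0, intron_len[1] > 0, exons_per_gene >= 1,
            frag_len > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a toy genome with annotated multi-exon genes
#'
#' Random A/C/G/T chromosomes carrying `n_genes` planted genes on alternating
#' strands, separated by intergenic spacers. Optional extras: exact
#' duplicated blocks (poor-mappability stress), foreign ncRNA features
#' planted inside chosen introns, and regularly spaced CpGs.
#'
#' @param config A [sim_config()].
#' @return list with `genome` (DNAStringSet), `exons` (GRanges with
#'   gene_id/transcript_id/type), `foreign` (GRanges of planted foreign
#'   features), `introns` (catalogue from [derive_introns()], foreign
#'   features already excluded), `truth` (data.frame: intron_id, true_r,
#'   retained_truth and coordinates) and `config`.
#' @export
simulate_genome_annotation <- function(config) {
  set.seed(config$seed)
  n_introns_per_gene <- config$exons_per_gene - 1L

  gene_layouts <- lapply(seq_len(config$n_genes), function(g) {
    el <- sample(config$exon_len[1]:config$exon_len[2],
                 config$exons_per_gene, replace = TRUE)
    il <- if (n_introns_per_gene > 0L) {
      sample(config$intron_len[1]:config$intron_len[2],
             n_introns_per_gene, replace = TRUE)
    } else integer(0)
    list(exon_len = el, intron_len = il,
         strand = if (g %% 2L == 1L) "+" else "-")
  })

  gene_widths <- vapply(gene_layouts, function(l) {
    sum(l$exon_len) + sum(l$intron_len)
  }, numeric(1))
  chrom_len <- as.integer(config$intergenic * (config$n_genes + 1L) +
                          sum(gene_widths))
  if (!is.null(config$duplication)) {
    chrom_len <- chrom_len +
      config$intergenic * config$duplication$copies +
      config$duplication$length * config$duplication$copies
  }

  seq_chr <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                   collapse = "")
  if (!is.null(config$cpg_spacing)) {
    at <- seq.int(1L, chrom_len - 1L, by = config$cpg_spacing)
    for (p in at) substr(seq_chr, p, p + 1L) <- "CG"
  }
  if (!is.null(config$duplication)) {
    # copies of one random block, planted back to back at the chromosome end
    blk_len <- config$duplication$length
    blk_start <- config$intergenic * (config$n_genes + 1L) + sum(gene_widths) +
      config$intergenic
    block <- substr(seq_chr, blk_start, blk_start + blk_len - 1L)
    dup_starts <- blk_start + (seq_len(config$duplication$copies) - 1L) *
      (blk_len + config$intergenic)
    for (s in dup_starts) substr(seq_chr, s, s + blk_len - 1L) <- block
    dup_ranges <- IRanges::IRanges(dup_starts, width = blk_len)
  } else {
    dup_ranges <- IRanges::IRanges()
  }

  # place genes left to right
  exon_rows <- list()
  cursor <- config$intergenic + 1L
  for (g in seq_len(config$n_genes)) {
    l <- gene_layouts[[g]]
    starts <- integer(config$exons_per_gene)
    ends <- integer(config$exons_per_gene)
    p <- cursor
    for (e in seq_len(config$exons_per_gene)) {
      starts[e] <- p
      ends[e] <- p + l$exon_len[e] - 1L
      p <- ends[e] + 1L
      if (e <= length(l$intron_len)) p <- p + l$intron_len[e]
    }
    exon_rows[[g]] <- data.frame(
      start = starts, end = ends, strand = l$strand,
      gene_id = sprintf("G%03d", g),
      transcript_id = sprintf("G%03d.T1", g))
    cursor <- cursor + gene_widths[g] + config$intergenic
  }
  exon_df <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(exon_df$start, exon_df$end),
    strand = exon_df$strand, type = "exon",
    gene_id = exon_df$gene_id, transcript_id = exon_df$transcript_id,
    seqinfo = GenomeInfoDb::Seqinfo("chr1", chrom_len))

  introns <- derive_introns(exons)

  foreign <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo("chr1", chrom_len))
  if (config$foreign_features > 0L && length(introns) > 0L) {
    host <- sample(length(introns), min(config$foreign_features,
                                        length(introns)))
    fr <- lapply(seq_along(host), function(k) {
      i <- host[k]
      w <- max(20L, BiocGenerics::width(introns)[i] %/% 5L)
      s <- BiocGenerics::start(introns)[i] +
        (BiocGenerics::width(introns)[i] - w) %/% 2L
      GenomicRanges::GRanges("chr1", IRanges::IRanges(s, width = w),
                             strand = sample(c("+", "-"), 1L),
                             type = "exon",
                             gene_id = sprintf("NC%03d", k),
                             transcript_id = sprintf("NC%03d.T1", k))
    })
    foreign <- unlist(GenomicRanges::GRangesList(fr))
    introns <- apply_feature_exclusions(introns, foreign)
  }

  n_int <- length(introns)
  true_r <- if (is.null(config$true_ir)) {
    stats::runif(n_int, 0, 0.8)
  } else {
    rep_len(config$true_ir, n_int)
  }
  truth <- data.frame(
    intron_id = introns$intron_id, gene_id = introns$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(introns)),
    start = BiocGenerics::start(introns) - 1L,
    end = BiocGenerics::end(introns),
    strand = as.character(BiocGenerics::strand(introns)),
    junction5 = introns$junction5, junction3 = introns$junction3,
    true_r = true_r, retained_truth = true_r >= 0.1,
    stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(seq_chr)
  names(genome) <- "chr1"
  duplication <- if (length(dup_ranges) > 0L) {
    GenomicRanges::GRanges("chr1", dup_ranges)
  } else {
    GenomicRanges::GRanges()
  }
  list(genome = genome, exons = exons, foreign = foreign, introns = introns,
       truth = truth, duplication = duplication, config = config)
}

#' Simulate aligned RNA-seq fragments at the configured true IR ratios
#'
#' Transcript molecules of each gene retain each of its introns independently
#' with the intron's true retention fraction `r`; fragment start positions
#' are uniform over all molecule positions, with molecules weighted by their
#' number of valid starts (as fragmentation of an RNA pool would). A spliced
#' intron becomes an N gap in the cigar; a retained intron is covered
#' contiguously. Fragments are emitted pre-aligned, since read alignment is
#' outside this pipeline.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @param sample_id Prefix for fragment names.
#' @param true_r Optional named vector (by `intron_id`) overriding the
#'   truth's retention fractions, e.g. to create a shifted second sample.
#' @param fragments_per_gene Optional override of the configured count.
#' @param seed Optional seed; defaults to `config$seed + 1` so that genome
#'   and fragments are independent streams.
#' @return A named [GenomicAlignments::GAlignments].
#' @export
simulate_fragments <- function(sim, sample_id = "s1", true_r = NULL,
                               fragments_per_gene = NULL, seed = NULL) {
  config <- sim$config
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)
  n_frag <- if (is.null(fragments_per_gene)) config$fragments_per_gene
            else fragments_per_gene
  fl <- config$frag_len

  r_by_intron <- stats::setNames(sim$truth$true_r, sim$truth$intron_id)
  if (!is.null(true_r)) r_by_intron[names(true_r)] <- true_r

  all_chrom <- character(0); all_pos <- integer(0); all_cigar <- character(0)
  all_name <- character(0)

  genes <- unique(sim$exons$gene_id)
  for (gid in genes) {
    ex <- sort(sim$exons[sim$exons$gene_id == gid], ignore.strand = TRUE)
    ids <- sim$truth$intron_id[sim$truth$gene_id == gid]
    # introns in genomic order between consecutive exons
    ids <- ids[order(sim$truth$start[match(ids, sim$truth$intron_id)])]
    k <- length(ids)
    r <- unname(r_by_intron[ids])
    if (fl > sum(BiocGenerics::width(ex))) {
      stop("fragment length exceeds spliced transcript length for ", gid)
    }

    # enumerate retention patterns; sample pattern counts with probability
    # prior(pattern) * valid-start weight, then place starts uniformly
    if (k > 0L) {
      patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
      prior <- apply(patterns, 1L, function(z) prod(ifelse(z, r, 1 - r)))
    } else {
      patterns <- matrix(logical(0), nrow = 1L, ncol = 0L)
      prior <- 1
    }
    layouts <- lapply(seq_len(nrow(patterns)), function(pi) {
      molecule_layout(ex, patterns[pi, ])
    })
    wts <- vapply(layouts, function(l) max(l$total - fl + 1L, 0L), numeric(1))
    pr <- prior * wts
    if (sum(pr) == 0) stop("no valid fragment placement for ", gid)
    counts <- as.vector(stats::rmultinom(1L, n_frag, pr))

    for (pi in which(counts > 0L)) {
      lay <- layouts[[pi]]
      m <- counts[pi]
      starts <- sample.int(lay$total - fl + 1L, m, replace = TRUE)
      frag <- place_fragments(lay, starts, fl)
      all_chrom <- c(all_chrom, rep("chr1", m))
      all_pos <- c(all_pos, frag$pos)
      all_cigar <- c(all_cigar, frag$cigar)
      all_name <- c(all_name, sprintf("%s_%s_p%d_%d", sample_id, gid, pi,
                                      seq_len(m)))
    }
  }

  gal <- GenomicAlignments::GAlignments(
    seqnames = S4Vectors::Rle(factor(all_chrom)),
    pos = all_pos, cigar = all_cigar,
    strand = S4Vectors::Rle(factor(rep("+", length(all_pos)),
                                   levels = c("+", "-", "*"))),
    names = all_name,
    seqlengths = stats::setNames(Biostrings::width(sim$genome),
                                 names(sim$genome)))
  gal
}

# maximal genomic blocks of a molecule given the retention pattern:
# exons plus retained introns merged when contiguous; spliced introns are gaps
molecule_layout <- function(ex, pattern) {
  segs_start <- BiocGenerics::start(ex)
  segs_end <- BiocGenerics::end(ex)
  blocks_start <- segs_start[1]
  blocks_end <- segs_end[1]
  for (i in seq_along(pattern)) {
    if (pattern[i]) {
      # retained: extend the current block across the intron into the next exon
      blocks_end[length(blocks_end)] <- segs_end[i + 1L]
    } else {
      blocks_start <- c(blocks_start, segs_start[i + 1L])
      blocks_end <- c(blocks_end, segs_end[i + 1L])
    }
  }
  widths <- blocks_end - blocks_start + 1L
  list(start = blocks_start, end = blocks_end, width = widths,
       cum = cumsum(widths), total = sum(widths))
}

# molecule-coordinate starts -> genomic pos + cigar (vectorised by block span)
place_fragments <- function(lay, starts, fl) {
  ends <- starts + fl - 1L
  cum0 <- c(0L, lay$cum)
  b1 <- findInterval(starts - 1L, cum0, rightmost.closed = FALSE)
  b2 <- findInterval(ends - 1L, cum0)
  pos <- lay$start[b1] + (starts - cum0[b1] - 1L)
  cigar <- character(length(starts))

  same <- b1 == b2
  cigar[same] <- sprintf("%dM", fl)
  multi <- which(!same)
  for (i in multi) {
    lens <- integer(0)
    ops <- character(0)
    remaining <- fl
    for (b in b1[i]:b2[i]) {
      take <- if (b == b1[i]) lay$cum[b] - (starts[i] - 1L) else
        min(remaining, lay$width[b])
      lens <- c(lens, take)
      ops <- c(ops, "M")
      remaining <- remaining - take
      if (b < b2[i]) {
        gap <- lay$start[b + 1L] - lay$end[b] - 1L
        lens <- c(lens, gap)
        ops <- c(ops, "N")
      }
    }
    cigar[i] <- paste0(lens, ops, collapse = "")
  }
  list(pos = pos, cigar = cigar)
}

#' Simulate per-CpG methylation counts and ChIP signal
#'
#' CpG sites are located on the simulated genome (forward-strand CG
#' dinucleotides). Each site's true beta is the configured baseline, dropped
#' by `dip_depth` within `dip_width` bp of either junction of a truly
#' retained intron; coverage is Poisson and the methylated count binomial.
#' ChIP fold enrichment mirrors the beta shape on a positive scale, tiled as
#' `chip_peak_width`-bp intervals across the gene regions.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @param seed Optional seed; defaults to `config$seed + 2`.
#' @return list with `cpg` (data.frame: chrom, pos, strand, n_methylated,
#'   n_unmethylated) and `chip` (GRanges with `value`).
#' @export
simulate_methylation <- function(sim, seed = NULL) {
  config <- sim$config
  if (is.null(seed)) seed <- config$seed + 2L
  set.seed(seed)

  cpg_pos <- BiocGenerics::start(
    Biostrings::matchPattern("CG", sim$genome[[1]]))
  beta_true <- rep(config$baseline_beta, length(cpg_pos))
  if (config$dip_depth > 0 && any(sim$truth$retained_truth)) {
    ret <- sim$truth[sim$truth$retained_truth, , drop = FALSE]
    for (j in c(ret$junction5, ret$junction3)) {
      hit <- abs(cpg_pos - 1L - j) <= config$dip_width
      beta_true[hit] <- config$baseline_beta - config$dip_depth
    }
  }
  beta_true <- pmin(pmax(beta_true, 0), 1)
  coverage <- stats::rpois(length(cpg_pos), config$coverage_mean)
  meth <- stats::rbinom(length(cpg_pos), coverage, beta_true)
  cpg <- data.frame(chrom = names(sim$genome)[1], pos = cpg_pos,
                    strand = "+", n_methylated = meth,
                    n_unmethylated = coverage - meth,
                    stringsAsFactors = FALSE)

  chrom_len <- length(sim$genome[[1]])
  w <- config$chip_peak_width
  peak_start <- seq.int(1L, chrom_len - w + 1L, by = w)
  centre <- peak_start + w %/% 2L
  beta_at <- rep(config$baseline_beta, length(centre))
  if (config$dip_depth > 0 && any(sim$truth$retained_truth)) {
    ret <- sim$truth[sim$truth$retained_truth, , drop = FALSE]
    for (j in c(ret$junction5, ret$junction3)) {
      hit <- abs(centre - 1L - j) <= config$dip_width
      beta_at[hit] <- config$baseline_beta - config$dip_depth
    }
  }
  chip <- GenomicRanges::GRanges(
    names(sim$genome)[1], IRanges::IRanges(peak_start, width = w),
    value = config$chip_base + config$chip_scale * beta_at)

  list(cpg = cpg, chip = chip)
}

#' Write simulated data to disk
#'
#' Emits FASTA, GTF (gene exons plus planted foreign features), SAM, CpG
#' count TSV, ChIP bedGraph and the ground-truth TSV. Every file re-parses
#' through the pipeline's own readers.
#'
#' @param sim Output of [simulate_genome_annotation()].
#' @param dir Output directory (created if missing).
#' @param fragments Optional [GenomicAlignments::GAlignments] (defaults to
#'   `simulate_fragments(sim)`).
#' @param methylation Optional output of [simulate_methylation()] (defaults
#'   to computing it).
#' @return Named character vector of written paths.
#' @export
write_simulation <- function(sim, dir, fragments = NULL, methylation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fragments)) fragments <- simulate_fragments(sim)
  if (is.null(methylation)) methylation <- simulate_methylation(sim)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    fragments = file.path(dir, "fragments.sam"),
    cpg = file.path(dir, "cpg_counts.tsv"),
    chip = file.path(dir, "chip_signal.bedgraph"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  ann <- c(sim$exons, sim$foreign)
  rtracklayer::export(ann, paths["annotation"], format = "gtf")
  write_sam(fragments, sim$genome, paths["fragments"])
  utils::write.table(methylation$cpg, paths["cpg"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(methylation$chip)),
               start = BiocGenerics::start(methylation$chip) - 1L,
               end = BiocGenerics::end(methylation$chip),
               value = methylation$chip$value),
    paths["chip"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Write alignments as a SAM text file
#'
#' Minimal valid single-end SAM: @HD/@SQ headers from the genome, one record
#' per fragment with mapq 255 and omitted sequence/quality. Read back with
#' [read_fragments()].
#'
#' @param fragments Named [GenomicAlignments::GAlignments].
#' @param genome Named [Biostrings::DNAStringSet] (for @SQ lines).
#' @param path Output path (should end in `.sam`).
#' @export
write_sam <- function(fragments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     Biostrings::width(genome)), con)
  if (length(fragments) > 0L) {
    flag <- ifelse(as.character(BiocGenerics::strand(fragments)) == "-",
                   16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                       names(fragments), flag,
                       as.character(GenomeInfoDb::seqnames(fragments)),
                       BiocGenerics::start(fragments),
                       GenomicAlignments::cigar(fragments)), con)
  }
  invisible(path)
}
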
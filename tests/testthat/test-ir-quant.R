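# one intron [101,200] between exons [1,100] and [201,300]
quant_introns <- function(strand = "+") {
  derive_introns(make_exons(rbind(c(1, 100), c(201, 300)), strand = strand))
}

# spliced fragments: n_exact across the intron, n_donor from the 5' exon into
# a farther exon (longer gap), n_acceptor from an upstream position into the
# 3' exon (gap starting inside a fictional upstream intron)
spliced_set <- function(n_exact, n_donor, n_acceptor) {
  rows <- list()
  if (n_exact > 0) {
    rows <- c(rows, list(data.frame(chrom = "chr1", pos = 81,
                                    cigar = "20M100N50M")[rep(1, n_exact), ]))
  }
  if (n_donor > 0) {
    # gap starts at 101 (the donor) but ends past the intron
    rows <- c(rows, list(data.frame(chrom = "chr1", pos = 81,
                                    cigar = "20M150N50M")[rep(1, n_donor), ]))
  }
  if (n_acceptor > 0) {
    # gap ends at 200 (the acceptor) but starts before the intron
    rows <- c(rows, list(data.frame(chrom = "chr1", pos = 31,
                                    cigar = "20M150N50M")[rep(1, n_acceptor), ]))
  }
  df <- do.call(rbind, rows)
  df$name <- sprintf("f%d", seq_len(nrow(df)))
  make_fragments(df)
}

test_that("splice counting takes the larger one-sided tally, exact counted in both", {
  introns <- quant_introns()
  sp <- count_splice(spliced_set(10, 2, 5), introns)
  expect_equal(sp$splice_exact, 10L)
  expect_equal(sp$splice_left, 12L)
  expect_equal(sp$splice_right, 15L)
  expect_equal(sp$splice_abundance, 15L)

  # exact only: both sides equal the exact count
  sp2 <- count_splice(spliced_set(10, 0, 0), introns)
  expect_equal(sp2$splice_left, 10L)
  expect_equal(sp2$splice_right, 10L)
  expect_equal(sp2$splice_abundance, 10L)

  # no spliced fragments at all
  none <- make_fragments(data.frame(chrom = "chr1", pos = 1, cigar = "50M"))
  expect_equal(count_splice(none, introns)$splice_abundance, 0L)
})

test_that("donor/acceptor anchoring is strand-aware", {
  minus <- quant_introns(strand = "-")
  # on the minus strand the right-hand boundary is the donor: a gap ending at
  # the intron end anchors the 5' (donor) side, i.e. splice_left
  sp <- count_splice(spliced_set(0, 0, 3), minus)
  expect_equal(sp$splice_left, 3L)
  expect_equal(sp$splice_right, 0L)
})

test_that("trimmed mean drops the configured share from each tail", {
  expect_equal(trimmed_mean_depth(1:10), 5.5)       # drop {1,2,3},{8,9,10}
  expect_equal(trimmed_mean_depth(rep(4.2, 17)), 4.2)
  expect_equal(trimmed_mean_depth(c(5, 5, 5)), 5)   # floor(0.9)=0 per side
  expect_equal(trimmed_mean_depth(numeric(0)), NA_real_)
  # asymmetric check against base R trimmed mean on a clean multiple of 10
  v <- c(0, 0, 0, 10, 10, 10, 10, 100, 100, 100)
  expect_equal(trimmed_mean_depth(v), 10)
})

test_that("the IR ratio is the intronic share and handles the degenerate corners", {
  expect_equal(ir_ratio(10, 90), 0.10)
  expect_equal(ir_ratio(0, 50), 0)
  expect_equal(ir_ratio(7, 0), 1)
  expect_true(is.na(ir_ratio(0, 0)))
  expect_error(ir_ratio(-1, 5), "non-negative")
  # monotone: up in intronic, down in splice
  expect_true(ir_ratio(11, 90) > ir_ratio(10, 90))
  expect_true(ir_ratio(10, 95) < ir_ratio(10, 90))
})

test_that("the retention call is inclusive at the 10% floor", {
  expect_true(classify_retained(0.10))
  expect_false(classify_retained(0.0999))
  expect_true(classify_retained(1.0))
  expect_true(is.na(classify_retained(NA_real_)))
})

test_that("depth accounting: per-base depths sum to total fragment overlap", {
  set.seed(7)
  introns <- quant_introns()
  n <- 40
  frags <- make_fragments(data.frame(
    chrom = "chr1", pos = sample(1:250, n, replace = TRUE), cigar = "50M"))
  depths <- intron_depth_vector(frags, introns[1])
  blocks <- GenomicRanges::granges(unlist(
    GenomicAlignments::grglist(frags), use.names = FALSE))
  overlap <- sum(BiocGenerics::width(GenomicRanges::pintersect(
    IRanges::subsetByOverlaps(blocks, introns[1], ignore.strand = TRUE),
    rep(GenomicRanges::granges(introns[1]),
        sum(IRanges::overlapsAny(blocks, introns[1], ignore.strand = TRUE))),
    ignore.strand = TRUE)))
  expect_equal(sum(depths), overlap)
  expect_length(depths, 100L)
})

test_that("masked positions are removed from the depth vector, not zero-filled", {
  introns <- quant_introns()
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(121, 180))
  masked <- apply_mappability_mask(introns, mask)
  # uniform coverage 1 over the intron
  frags <- make_fragments(data.frame(chrom = "chr1", pos = 101, cigar = "100M"))
  d_full <- intron_depth_vector(frags, introns[1])
  d_mask <- intron_depth_vector(frags, masked[1])
  expect_length(d_full, 100L)
  expect_length(d_mask, 40L)
  expect_true(all(d_mask == 1))
})

test_that("an intron with an empty measurable area is not assessable", {
  introns <- quant_introns()
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  gone <- apply_mappability_mask(introns, mask)
  q <- quantify_ir(spliced_set(20, 0, 0), gone, "s")
  expect_true(is.na(q$ir_ratio))
  expect_true(is.na(q$intronic_abundance))
  expect_equal(q$measurable_bases, 0L)
  # whereas splice counting still works
  expect_equal(q$splice_abundance, 20L)
})

test_that("quantify_ir reads SAM input and matches in-memory quantification", {
  cfg <- sim_config(seed = 21, n_genes = 2, true_ir = 0.3,
                    fragments_per_gene = 500)
  sim <- simulate_genome_annotation(cfg)
  frags <- simulate_fragments(sim)
  q_mem <- quantify_ir(frags, sim$introns, "s")
  sam <- tempfile(fileext = ".sam")
  write_sam(frags, sim$genome, sam)
  q_sam <- quantify_ir(sam, sim$introns, "s")
  expect_equal(q_sam$ir_ratio, q_mem$ir_ratio)
  expect_equal(q_sam$splice_abundance, q_mem$splice_abundance)
})
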
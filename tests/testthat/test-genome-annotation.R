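test_that("introns are the gaps between consecutive exons, with strand-aware junctions", {
  # two exons [0,100) and [200,300) in 0-based half-open terms
  ex <- make_exons(rbind(c(1, 100), c(201, 300)))
  introns <- derive_introns(ex)
  expect_length(introns, 1L)
  expect_equal(BiocGenerics::start(introns), 101L)
  expect_equal(BiocGenerics::end(introns), 200L)
  expect_equal(introns$junction5, 100)
  expect_equal(introns$junction3, 200)

  three <- make_exons(rbind(c(1, 100), c(201, 300), c(401, 500)))
  expect_length(derive_introns(three), 2L)

  # same gap in two transcripts -> one record
  dup <- make_exons(rbind(c(1, 100), c(201, 300)),
                    rbind(c(1, 100), c(201, 300), c(401, 500)))
  got <- derive_introns(dup)
  expect_equal(sum(BiocGenerics::start(got) == 101L), 1L)
})

test_that("strand flip swaps junction anchors but not spans", {
  plus <- derive_introns(make_exons(rbind(c(1, 100), c(201, 300))))
  minus <- derive_introns(make_exons(rbind(c(1, 100), c(201, 300)),
                                     strand = "-"))
  expect_equal(BiocGenerics::start(minus), BiocGenerics::start(plus))
  expect_equal(BiocGenerics::end(minus), BiocGenerics::end(plus))
  expect_equal(minus$junction5, plus$junction3)
  expect_equal(minus$junction3, plus$junction5)
})

test_that("intron ranks follow transcription order on the minus strand", {
  ex <- make_exons(rbind(c(1, 100), c(201, 300), c(401, 500)), strand = "-")
  introns <- derive_introns(ex)
  # leftmost genomic intron is transcribed last on the minus strand
  left <- which.min(BiocGenerics::start(introns))
  expect_equal(introns$intron_rank[left], 2L)
})

test_that("overlapping exons within a transcript are a malformed-annotation error", {
  bad <- make_exons(rbind(c(1, 100), c(90, 200)))
  expect_error(derive_introns(bad), "overlapping exons")
})

test_that("foreign features are clipped out of the measurable area", {
  introns <- derive_introns(make_exons(rbind(c(1, 100), c(201, 300))))

  # feature [150,160) inside the intron -> measurable splits in two
  sno <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160),
                                gene_id = "NC1")
  got <- apply_feature_exclusions(introns, sno)
  ms <- got$measurable[[1]]
  expect_equal(BiocGenerics::start(ms), c(101L, 161L))
  expect_equal(BiocGenerics::end(ms), c(150L, 200L))

  # partially overlapping feature is clipped to the intron
  part <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 110),
                                 gene_id = "NC1")
  got2 <- apply_feature_exclusions(introns, part)
  expect_equal(BiocGenerics::start(got2$excluded[[1]]), 101L)
  expect_equal(BiocGenerics::end(got2$excluded[[1]]), 110L)

  # non-overlapping feature is a no-op; own-gene features are ignored
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1100),
                                gene_id = "NC1")
  expect_equal(apply_feature_exclusions(introns, far)$measurable[[1]],
               introns$measurable[[1]])
  own <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160),
                                gene_id = "G1")
  expect_equal(apply_feature_exclusions(introns, own)$measurable[[1]],
               introns$measurable[[1]])
})

test_that("measurable and excluded spans tile the intron for random exclusion sets", {
  set.seed(41)
  introns <- derive_introns(make_exons(rbind(c(1, 200), c(1201, 1400))))
  width_intron <- BiocGenerics::width(introns)
  for (rep in 1:20) {
    n_feat <- sample(1:5, 1)
    starts <- sample(100:1300, n_feat)
    feats <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, width = sample(10:200, n_feat,
                                                      replace = TRUE)),
      gene_id = "X")
    got <- apply_feature_exclusions(introns, feats)
    w_meas <- sum(BiocGenerics::width(got$measurable[[1]]))
    w_excl <- sum(BiocGenerics::width(got$excluded[[1]]))
    expect_equal(w_meas + w_excl, width_intron)
    expect_false(any(IRanges::overlapsAny(got$measurable[[1]],
                                          got$excluded[[1]])))
  }
})

test_that("sequence features report length, GC and CpG density", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 100),          # exon 1
    "ACGT", strrep("A", 96),   # intron: ACGT then A*96
    strrep("T", 100))))        # exon 2
  introns <- derive_introns(make_exons(rbind(c(1, 100), c(201, 300))))
  f <- sequence_features(introns, g)
  expect_equal(f$length, 100L)
  expect_equal(f$gc_fraction, 2 / 100)
  expect_equal(f$cpg_density, 1 / 100)

  # dense cases: "CGCG"-style sequence has gc 1 and a CG at every other base
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 100), strrep("CG", 50), strrep("T", 100))))
  f2 <- sequence_features(introns, g2)
  expect_equal(f2$gc_fraction, 1.0)
  expect_equal(f2$cpg_density, 0.5)
})

test_that("the 0-based half-open genome accessor enforces bounds", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_equal(genome_sequence(g, "chr1", 0, 4), "ACGT")
  expect_equal(nchar(genome_sequence(g, "chr1", 2, 7)), 5L)
  expect_error(genome_sequence(g, "chr1", 0, 9), "outside")
  expect_error(genome_sequence(g, "chr2", 0, 1), "unknown chromosome")
})

test_that("intron BED output is 0-based half-open with ids and strands", {
  introns <- derive_introns(make_exons(rbind(c(1, 100), c(201, 300)),
                                       strand = "-"))
  path <- tempfile(fileext = ".bed")
  write_intron_bed(introns, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 100L)
  expect_equal(bed$V3, 200L)
  expect_equal(bed$V6, "-")
})
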
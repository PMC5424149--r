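cpg_df <- function(pos, beta, chrom = "chr1", coverage = 20L) {
  n_meth <- as.integer(round(beta * coverage))
  compute_beta_table(data.frame(
    chrom = chrom, pos = pos, strand = "+",
    n_methylated = n_meth, n_unmethylated = coverage - n_meth,
    stringsAsFactors = FALSE))
}

test_that("the coverage filter keeps sites with strictly more than five reads", {
  counts <- data.frame(chrom = "chr1", pos = c(10, 20, 30), strand = "+",
                       n_methylated = c(3, 5, 10),
                       n_unmethylated = c(3, 0, 0))
  beta <- compute_beta_table(counts)
  expect_equal(beta$pos, c(10, 30))       # coverage 6 and 10 kept, 5 dropped
  expect_equal(beta$beta, c(0.5, 1.0))
  # zero coverage is dropped, not an error
  zero <- data.frame(chrom = "chr1", pos = 1, strand = "+",
                     n_methylated = 0, n_unmethylated = 0)
  expect_equal(nrow(compute_beta_table(zero)), 0L)
  expect_error(compute_beta_table(transform(zero, n_methylated = -1)),
               "negative")
})

test_that("the +/-100 bp scan yields exactly 20 sub-windows of 10 bp", {
  introns <- derive_introns(make_exons(rbind(c(1, 300), c(801, 1100))))
  prof <- window_profile(cpg_df(400, 0.5), introns, "junction5")
  expect_equal(nrow(prof), 20L)
  expect_equal(prof$offset_start, seq(-100, 90, by = 10))
  expect_error(window_profile(cpg_df(400, 0.5), introns, flank = 95),
               "divisible")
})

test_that("window means pool beta values; empty windows are missing with n=0", {
  # junction5 boundary at 0-based 300; offsets -95 and -92 are exonic sites
  introns <- derive_introns(make_exons(rbind(c(1, 300), c(801, 1100))))
  expect_equal(introns$junction5, 300)
  sites <- cpg_df(c(300 - 95 + 1, 300 - 92 + 1), c(0.8, 0.6))
  prof <- window_profile(sites, introns, "junction5")
  expect_equal(prof$mean[prof$offset_start == -100], 0.7)
  expect_equal(prof$n[prof$offset_start == -100], 2L)
  expect_true(all(is.na(prof$mean[prof$offset_start != -100])))
  expect_true(all(prof$n[prof$offset_start != -100] == 0L))
})

test_that("a uniform beta field gives flat profiles and conserves site counts", {
  cfg <- sim_config(seed = 31, n_genes = 8, true_ir = c(0.4, 0.05),
                    dip_depth = 0)
  sim <- simulate_genome_annotation(cfg)
  pos <- BiocGenerics::start(Biostrings::matchPattern("CG", sim$genome[[1]]))
  sites <- cpg_df(pos, 0.65)
  for (anchor in c("junction5", "junction3", "midpoint")) {
    prof <- window_profile(sites, sim$introns, anchor)
    expect_true(all(abs(prof$mean[prof$n > 0] - 0.65) < 1e-12))
    # site conservation at the junctions (no clipping there): total n equals
    # the number of sites within +/-100 of the anchors
    if (anchor != "midpoint") {
      ai <- retainr:::anchor_info(sim$introns, anchor)
      expected <- sum(vapply(seq_along(sim$introns), function(i) {
        off <- retainr:::relative_offset(pos - 1L, ai$boundary[i], ai$flip[i])
        sum(off >= -100 & off < 100)
      }, numeric(1)))
      expect_equal(sum(prof$n), expected)
    }
  }
})

test_that("minus-strand flipping is an involution and orients the exonic side", {
  plus <- derive_introns(make_exons(rbind(c(1, 300), c(801, 1100))))
  minus <- derive_introns(make_exons(rbind(c(1, 300), c(801, 1100)),
                                     strand = "-"))
  # an exonic site 5 bp left of the plus-strand donor
  s_plus <- cpg_df(296, 0.9)
  p_plus <- window_profile(s_plus, plus, "junction5")
  expect_equal(p_plus$n[p_plus$offset_start == -10], 1L)
  # the mirror site for the minus-strand donor (right-hand boundary at 800)
  s_minus <- cpg_df(805, 0.9)
  p_minus <- window_profile(s_minus, minus, "junction5")
  expect_equal(p_minus$n[p_minus$offset_start == -10], 1L)
  # flipping the intron strand twice restores the genomic assignment
  again <- derive_introns(make_exons(rbind(c(1, 300), c(801, 1100))))
  expect_equal(window_profile(s_plus, again, "junction5")$n,
               p_plus$n)
})

test_that("midpoint windows are clipped to the intron span", {
  # a 100 bp intron: windows extend +/-100 around its midpoint but only
  # intronic sites may contribute
  introns <- derive_introns(make_exons(rbind(c(1, 300), c(401, 700))))
  expect_equal(BiocGenerics::width(introns), 100L)
  inside <- cpg_df(350, 0.4)   # intronic
  outside <- cpg_df(290, 0.4)  # exonic, within 100 bp of the midpoint
  expect_equal(sum(window_profile(inside, introns, "midpoint")$n), 1L)
  expect_equal(sum(window_profile(outside, introns, "midpoint")$n), 0L)
})

test_that("interval signal contributes once per overlapped window", {
  introns <- derive_introns(make_exons(rbind(c(1, 300), c(801, 1100))))
  # one 25 bp record overlapping windows [0,10) and [10,20) and [20,30)
  sig <- GenomicRanges::GRanges("chr1", IRanges::IRanges(305, 329), value = 3)
  prof <- window_profile(sig, introns, "junction5")
  expect_equal(prof$n[prof$offset_start %in% c(0, 10, 20)], rep(1L, 3))
  expect_equal(prof$mean[prof$offset_start == 0], 3)
  expect_equal(sum(prof$n), 3L)
})

test_that("paired window test matches the closed-form paired t", {
  set.seed(32)
  mk_prof <- function(means) {
    data.frame(anchor = "junction5", stratum = "x", window = 1:20,
               offset_start = seq(-100, 90, 10), mean = means, n = 5L)
  }
  a <- runif(20, 0.4, 0.8)
  d <- rnorm(20, 0.1, 0.05)
  res <- paired_window_test(mk_prof(a), mk_prof(a - d))
  t_exp <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(res$t, t_exp, tolerance = 1e-10)
  expect_equal(res$df, 19)
  expect_equal(res$p_value, 2 * pt(abs(t_exp), 19, lower.tail = FALSE),
               tolerance = 1e-10)

  # identical profiles: no difference
  res0 <- paired_window_test(mk_prof(a), mk_prof(a))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)

  # constant non-zero shift: degenerate, no p
  resd <- paired_window_test(mk_prof(a), mk_prof(a - 0.1))
  expect_true(resd$degenerate)
  expect_true(is.na(resd$p_value))

  # fewer than 3 complete pairs is an error
  short <- mk_prof(a); short$mean[3:20] <- NA
  expect_error(paired_window_test(short, mk_prof(a)), "fewer than 3")
})
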
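# retainr

Intron retention (IR) discovery from spliced RNA-seq alignments, differential
IR calling between samples, and epigenomic metaprofiles around splice
junctions — for researchers studying how splicing outcomes couple to DNA
methylation and methyl-CpG readers such as MeCP2.

## What it computes

For each annotated intron and sample, two abundances and their ratio:

* **splice abundance** — fragments whose alignment gap (`N` cigar operation)
  spans the intron: exact donor-to-acceptor gaps, plus gaps anchored at only
  the donor or only the acceptor, the larger one-sided tally being used;
* **intronic abundance** — a 30%-trimmed mean of per-base fragment depth over
  the intron's *measurable* area, i.e. after excluding overlapping features
  of other genes (miRNAs, snoRNAs) and regions of poor mappability;
* the **IR ratio**

  ```
  IR = intronic / (intronic + splice)          retained  ⇔  IR ≥ 0.10
  ```

Poor mappability is determined empirically: synthetic 70 bp reads with a
single planted central error are taken every 10 bp from the reference, every
second one reverse-complemented, and re-aligned; a base with fewer than 5 of
a possible 7 uniquely-and-correctly mapping overlapping reads is masked.

Differential IR between two samples is tested per intron with the exact
Audic–Claverie statistic for digital counts (log-space implementation), and
called significant when p < 0.05, splice abundance is above 10 in both
samples, and the IR ratio is above 0.1 in at least one. The imbalance of
increased versus decreased calls is assessed with an exact binomial test.

Methylation beta values (per-CpG, coverage > 5 reads) or ChIP fold
enrichment are aggregated in twenty 10-bp windows across ±100 bp of the 5′
junction, 3′ junction or intron midpoint, stratified by retained versus
non-retained introns, and the strata are compared with a paired t-test
across the sub-windows.

A seeded simulator (toy genome, GTF, spliced/retaining SAM fragments at
programmed true IR ratios, CpG count tables with junction-proximal dips)
makes the whole pipeline testable without any external data.

## Worked example

```r
library(retainr)

# a 4-gene toy genome; introns 1 of each gene truly retained at r = 0.3,
# introns 2 spliced (r = 0.05)
cfg <- sim_config(seed = 42, n_genes = 4, true_ir = c(0.3, 0.05),
                  fragments_per_gene = 3000)
sim  <- simulate_genome_annotation(cfg)
mask <- mappability_mask(sim$genome)            # synthetic-read screen
introns <- apply_mappability_mask(sim$introns, mask)

q1 <- quantify_ir(simulate_fragments(sim, "s1", seed = 421), introns, "s1")
q1[, c("intron_id", "splice_abundance", "intronic_abundance", "ir_ratio", "retained")]
#>   intron_id splice_abundance intronic_abundance ir_ratio retained
#> 1   G001.I1              194               88.5   0.3134     TRUE
#> 2   G001.I2              296               11.2   0.0365    FALSE
#> 3   G002.I2              212               89.0   0.2957     TRUE
#> 4   G002.I1              299               19.3   0.0608    FALSE
#> ...
```

The quantification recovers the programmed retention levels: introns
simulated at r = 0.3 come back with IR ratios of 0.30–0.31 (retained),
introns at r = 0.05 with 0.04–0.06 (not retained). A second sample in which
the spliced introns are shifted to r = 0.45 is then screened:

```r
shift <- setNames(rep(0.45, 4), sim$truth$intron_id[sim$truth$true_r < 0.1])
q2  <- quantify_ir(simulate_fragments(sim, "s2", true_r = shift, seed = 422),
                   introns, "s2")
res <- differential_ir(q1, q2)
res[, c("intron_id", "ir_ratio_1", "ir_ratio_2", "p_value", "passes_filter")]
#>   intron_id ir_ratio_1 ir_ratio_2  p_value passes_filter
#> 1   G001.I1     0.3134      0.282 4.89e-01         FALSE
#> 2   G001.I2     0.0365      0.451 1.46e-27          TRUE
#> 3   G002.I1     0.0608      0.453 4.00e-24          TRUE
#> ...
attr(res, "summary")
#> $n_increased [1] 4    $n_decreased [1] 0    $binomial_p [1] 0.125
```

Exactly the four shifted introns pass the three-part filter, all in the
increased direction; the unshifted introns do not.

## Command line

Each subcommand writes its outputs plus a JSON run manifest (parameters,
input checksums, seed, version):

```sh
retainr simulate    --seed 42 --out-dir sim
retainr mappability --genome sim/genome.fa --out-dir mask
retainr quantify    --alignments sim/fragments.sam --annotation sim/annotation.gtf \
                    --mask mask/mappability_mask.bed --sample-id s1 --out-dir quant
retainr diff        --quant1 quant/s1_ir.tsv --quant2 quant/s2_ir.tsv --out-dir diff
retainr metaprofile --cpg sim/cpg_counts.tsv --annotation sim/annotation.gtf \
                    --quant quant/s1_ir.tsv --out-dir meta
```

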
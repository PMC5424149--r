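#' Compare a numeric feature between retained and non-retained introns
#'
#' Two-sample t-test (Welch by default; pooled-variance Student via
#' `var_equal = TRUE`) on e.g. intron length, GC fraction or CpG density.
#'
#' @param retained,non_retained Numeric vectors, n >= 2 each.
#' @param feature Feature label for the report.
#' @param var_equal Use the pooled-variance Student test (default FALSE).
#' @return One-row data.frame: `feature`, `mean_retained`,
#'   `mean_non_retained`, `t`, `df`, `p_value`.
#' @export
compare_feature <- function(retained, non_retained, feature = "feature",
                            var_equal = FALSE) {
  if (length(retained) < 2L || length(non_retained) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(retained) == 0 && stats::sd(non_retained) == 0 &&
      mean(retained) == mean(non_retained)) {
    return(data.frame(feature = feature, mean_retained = mean(retained),
                      mean_non_retained = mean(non_retained),
                      t = 0, df = NA_real_, p_value = 1,
                      stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(retained, non_retained, var.equal = var_equal)
  data.frame(feature = feature,
             mean_retained = mean(retained),
             mean_non_retained = mean(non_retained),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, stringsAsFactors = FALSE)
}

#' Are genes with retained introns closer together than random gene pairs?
#'
#' Observed set: edge-to-edge genomic gaps between all same-chromosome pairs
#' of IR genes (0 when the spans overlap). Null set: gaps of
#' `n_random_pairs` same-chromosome pairs sampled uniformly without
#' replacement from all genes. The two sets are compared with a t-test.
#' Cross-chromosome pairs carry no distance and are excluded.
#'
#' @param ir_genes,all_genes GRanges of gene spans (names or `gene_id` used
#'   for reporting only).
#' @param n_random_pairs Number of null pairs to sample (default 1000).
#' @param seed Seed for the null sampling.
#' @return One-row data.frame as in [compare_feature()], with
#'   `feature = "gene_distance"`, plus `n_observed_pairs`, `n_null_pairs`.
#' @export
gene_distance_stat <- function(ir_genes, all_genes, n_random_pairs = 1000L,
                               seed = 1L) {
  if (length(ir_genes) < 2L) stop("need at least 2 IR genes")
  obs <- same_chrom_pair_gaps(ir_genes)
  if (length(obs) == 0L) stop("no same-chromosome IR gene pair")

  set.seed(seed)
  n_all <- length(all_genes)
  all_pairs <- utils::combn(n_all, 2L)
  same <- as.character(GenomeInfoDb::seqnames(all_genes))[all_pairs[1, ]] ==
    as.character(GenomeInfoDb::seqnames(all_genes))[all_pairs[2, ]]
  all_pairs <- all_pairs[, same, drop = FALSE]
  if (ncol(all_pairs) == 0L) stop("no same-chromosome pair among all genes")
  take <- sample(ncol(all_pairs), min(n_random_pairs, ncol(all_pairs)))
  null <- pair_gaps(all_genes, all_pairs[, take, drop = FALSE])

  out <- compare_feature(obs, null, feature = "gene_distance")
  names(out)[names(out) == "mean_retained"] <- "mean_observed"
  names(out)[names(out) == "mean_non_retained"] <- "mean_null"
  out$n_observed_pairs <- length(obs)
  out$n_null_pairs <- length(null)
  out
}

same_chrom_pair_gaps <- function(genes) {
  pairs <- utils::combn(length(genes), 2L)
  same <- as.character(GenomeInfoDb::seqnames(genes))[pairs[1, ]] ==
    as.character(GenomeInfoDb::seqnames(genes))[pairs[2, ]]
  pair_gaps(genes, pairs[, same, drop = FALSE])
}

pair_gaps <- function(genes, pairs) {
  if (ncol(pairs) == 0L) return(numeric(0))
  s1 <- BiocGenerics::start(genes)[pairs[1, ]]
  e1 <- BiocGenerics::end(genes)[pairs[1, ]]
  s2 <- BiocGenerics::start(genes)[pairs[2, ]]
  e2 <- BiocGenerics::end(genes)[pairs[2, ]]
  pmax(pmax(s1, s2) - pmin(e1, e2) - 1L, 0L)
}

#' Are retained introns adjacent within genes more often than by chance?
#'
#' Observed statistic: among all within-gene pairs of retained introns, the
#' fraction whose transcription-order ordinals differ by exactly 1. Null:
#' the same statistic when each gene's retained introns are re-placed
#' uniformly among its intron slots, preserving the per-gene retained count
#' (which controls for gene length and intron number); the resampling p is
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param intron_table data.frame with columns `gene_id`, `intron_rank`,
#'   `n_introns`, `retained` (as produced by joining the catalogue with
#'   [quantify_ir()] output).
#' @param n_perm Number of resampling draws (default 1000).
#' @param seed Seed for the resampling.
#' @return list with `observed`, `null_mean`, `p_value`, `n_pairs`, `n_perm`.
#' @export
adjacency_stat <- function(intron_table, n_perm = 1000L, seed = 1L) {
  tab <- intron_table[!is.na(intron_table$retained), , drop = FALSE]
  by_gene <- split(tab, tab$gene_id)
  eligible <- Filter(function(g) sum(g$retained) >= 2L, by_gene)
  if (length(eligible) == 0L) {
    stop("no gene with at least 2 retained introns")
  }
  adj_frac <- function(rank_sets) {
    pairs <- 0L; adj <- 0L
    for (r in rank_sets) {
      cmb <- utils::combn(sort(r), 2L)
      pairs <- pairs + ncol(cmb)
      adj <- adj + sum(cmb[2, ] - cmb[1, ] == 1L)
    }
    adj / pairs
  }
  obs_sets <- lapply(eligible, function(g) g$intron_rank[g$retained])
  observed <- adj_frac(obs_sets)
  n_pairs <- sum(vapply(obs_sets, function(r) choose(length(r), 2),
                        numeric(1)))

  set.seed(seed)
  k_by_gene <- vapply(eligible, function(g) sum(g$retained), integer(1))
  slots_by_gene <- lapply(eligible, function(g) g$intron_rank)
  null <- vapply(seq_len(n_perm), function(b) {
    adj_frac(lapply(seq_along(eligible), function(gi) {
      sample(slots_by_gene[[gi]], k_by_gene[gi])
    }))
  }, numeric(1))

  list(observed = observed, null_mean = mean(null),
       p_value = (1 + sum(null >= observed)) / (n_perm + 1),
       n_pairs = n_pairs, n_perm = n_perm)
}

#' Regression of gene expression on IR level with an F-test
#'
#' Ordinary least squares of log expression on IR level; the F-test of the
#' regression assesses significance. A negative slope reflects the
#' association of higher IR with lower mRNA expression.
#'
#' @param ir_levels Numeric IR levels per gene.
#' @param expression Matched positive expression values (e.g. FPKM);
#'   log-transformed internally.
#' @return list with `slope`, `intercept`, `F`, `df1`, `df2`, `p_value`, `n`.
#' @export
ir_expression_regression <- function(ir_levels, expression) {
  ok <- !is.na(ir_levels) & !is.na(expression)
  ir_levels <- ir_levels[ok]; expression <- expression[ok]
  if (length(ir_levels) < 3L) stop("need at least 3 matched points")
  if (any(expression <= 0)) stop("expression must be positive")
  if (stats::sd(expression) == 0) stop("constant expression: regression degenerate")
  fit <- stats::lm(log(expression) ~ ir_levels)
  a <- stats::anova(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p_value = a$`Pr(>F)`[1], n = length(ir_levels))
}
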
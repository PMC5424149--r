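#' Audic-Claverie test for a difference between two digital counts
#'
#' Given counts `x` and `y` observed in two libraries with normalisation
#' totals `N1` and `N2`, the posterior probability of observing `y` in library
#' 2 given `x` in library 1 is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' which is a negative-binomial mass in `y` with size `x + 1` and success
#' probability `N1/(N1+N2)`. The two-sided p-value doubles the smaller tail
#' (`P(Y <= y | x)` or `P(Y >= y | x)`), capped at 1.
#'
#' All tail sums are accumulated in log space (log-sum-exp over the log pmf),
#' so counts up to at least 1e6 are handled without overflow. The upper
#' (infinite) tail is obtained as the complement of the finite lower sum.
#'
#' @param x,y Non-negative integer counts (vectorised).
#' @param n1,n2 Positive normalisation totals for the two libraries.
#' @return Two-sided p-value(s) in (0, 1].
#' @export
audic_claverie_p <- function(x, y, n1 = 1, n2 = 1) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("normalisation totals must be positive")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) ac_two_sided(x[i], y[i], n1[i], n2[i]),
         numeric(1))
}

# log p(y'|x) for a vector of y', fixed x
ac_log_pmf <- function(yv, x, n1, n2) {
  log_r <- log(n2) - log(n1)
  yv * log_r + lgamma(x + yv + 1) - lgamma(x + 1) - lgamma(yv + 1) -
    (x + yv + 1) * log1p(exp(log_r))
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

ac_two_sided <- function(x, y, n1, n2) {
  # the smaller tail decides the p-value, so it is always accumulated by
  # direct log-space summation; the larger tail (>= ~0.5) may safely be
  # taken as the complement, where cancellation is harmless
  pmf_y <- exp(ac_log_pmf(y, x, n1, n2))
  mean_y <- (x + 1) * n2 / n1  # mean of the posterior over y
  if (y <= mean_y) {
    lower <- exp(log_sum_exp(ac_log_pmf(0:y, x, n1, n2)))
    upper <- 1 - lower + pmf_y
  } else {
    # sum P(Y >= y) upward until the terms stop contributing
    chunk <- 1024L
    from <- y
    acc <- -Inf
    repeat {
      block <- ac_log_pmf(from:(from + chunk - 1L), x, n1, n2)
      acc <- log_sum_exp(c(acc, block))
      if (block[chunk] < acc + log(1e-18)) break
      from <- from + chunk
    }
    upper <- exp(acc)
    lower <- 1 - upper + pmf_y
  }
  min(1, 2 * min(max(lower, 0), max(upper, 0)))
}

#' Two-sample differential IR with the three-part significance filter
#'
#' For each intron quantified in both samples, the shift in its digital counts
#' is evaluated with the Audic-Claverie statistic, and the change in IR ratio
#' is called significant under the standard cutoff: (1) p-value < 0.05,
#' (2) exonic splice abundance above 10 in both samples, and (3) IR ratio
#' above 0.1 in at least one sample.
#'
#' Which counts feed the test is a pluggable contrast. The default `"local"`
#' strategy compares the rounded intronic abundances with per-intron totals
#' `N = intronic + splice` per sample, i.e. it detects a shift in the intron's
#' share of its local fragment pool; `"library"` normalises by total library
#' splice abundance instead. Intronic abundances are rounded half-up since
#' the test requires integers.
#'
#' @param quant1,quant2 Per-sample quantification tables from [quantify_ir()]
#'   (or paths read with [read_ir_quant()]).
#' @param alpha P-value cutoff (default 0.05, exclusive).
#' @param splice_min Splice-abundance floor, strict (default 10: "above 10").
#' @param ir_min IR-ratio floor for at least one sample, strict (default 0.1).
#' @param epsilon Pseudocount for the IR-ratio fold change (default 0.01).
#' @param strategy `"local"` or `"library"` normalisation (see above).
#' @param adjust Apply Benjamini-Hochberg to the p-values before filtering
#'   (default `FALSE`; the raw-p filter is the standard cutoff).
#' @return data.frame (one row per assessable intron): IR ratios, `p_value`,
#'   `fold_change`, `direction` (`increased`/`decreased`), the three
#'   per-criterion flags and `passes_filter`; with a `summary` attribute
#'   holding the increased/decreased tallies among passing introns and the
#'   two-sided binomial p for the direction bias.
#' @export
differential_ir <- function(quant1, quant2, alpha = 0.05, splice_min = 10,
                            ir_min = 0.1, epsilon = 0.01,
                            strategy = c("local", "library"),
                            adjust = FALSE) {
  strategy <- match.arg(strategy)
  if (is.character(quant1)) quant1 <- read_ir_quant(quant1)
  if (is.character(quant2)) quant2 <- read_ir_quant(quant2)
  m <- merge(quant1, quant2, by = "intron_id", suffixes = c("_1", "_2"))
  assessable <- !is.na(m$ir_ratio_1) & !is.na(m$ir_ratio_2)
  if (any(!assessable)) {
    message(sum(!assessable), " intron(s) not assessable in one or both ",
            "samples; skipped")
  }
  m <- m[assessable, , drop = FALSE]

  x <- round_half_up(m$intronic_abundance_1)
  y <- round_half_up(m$intronic_abundance_2)
  if (strategy == "local") {
    n1 <- pmax(m$intronic_abundance_1 + m$splice_abundance_1, 1)
    n2 <- pmax(m$intronic_abundance_2 + m$splice_abundance_2, 1)
  } else {
    n1 <- max(sum(m$splice_abundance_1), 1)
    n2 <- max(sum(m$splice_abundance_2), 1)
  }
  p <- audic_claverie_p(x, y, n1, n2)
  p_used <- if (adjust) stats::p.adjust(p, method = "BH") else p

  crit_p <- p_used < alpha
  crit_splice <- m$splice_abundance_1 > splice_min &
    m$splice_abundance_2 > splice_min
  crit_ir <- m$ir_ratio_1 > ir_min | m$ir_ratio_2 > ir_min
  passes <- crit_p & crit_splice & crit_ir

  res <- data.frame(
    intron_id = m$intron_id,
    ir_ratio_1 = m$ir_ratio_1,
    ir_ratio_2 = m$ir_ratio_2,
    p_value = p,
    fold_change = (m$ir_ratio_2 + epsilon) / (m$ir_ratio_1 + epsilon),
    direction = ifelse(m$ir_ratio_2 >= m$ir_ratio_1, "increased", "decreased"),
    crit_p = crit_p, crit_splice = crit_splice, crit_ir = crit_ir,
    passes_filter = passes,
    stringsAsFactors = FALSE)

  n_inc <- sum(passes & res$direction == "increased")
  n_dec <- sum(passes & res$direction == "decreased")
  attr(res, "summary") <- list(
    n_increased = n_inc, n_decreased = n_dec,
    binomial_p = if (n_inc + n_dec >= 1) direction_bias_test(n_inc, n_dec)
                 else NA_real_)
  res
}

# round half away from zero to the nearest integer (test needs integer counts)
round_half_up <- function(v) floor(v + 0.5)

#' Exact binomial test for increased vs decreased IR events
#'
#' Under the null that an IR change is equally likely to go either way, the
#' number of increased events among all changed events is Binomial(n, 1/2).
#' The two-sided p doubles the smaller exact tail, capped at 1.
#'
#' @param n_increased,n_decreased Event counts (sum >= 1).
#' @return Two-sided exact binomial p-value.
#' @export
direction_bias_test <- function(n_increased, n_decreased) {
  stopifnot(n_increased >= 0, n_decreased >= 0,
            n_increased + n_decreased >= 1)
  n <- n_increased + n_decreased
  k <- min(n_increased, n_decreased)
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Write a differential IR table with its direction-bias summary
#'
#' The per-intron table is tab-separated; the increased/decreased tallies and
#' binomial p are appended as `#`-prefixed comment lines.
#' @param res data.frame from [differential_ir()].
#' @param path File path.
#' @export
write_differential_ir <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- attr(res, "summary")
  if (!is.null(s)) {
    cat(sprintf("# increased\t%d\n# decreased\t%d\n# binomial_p\t%.6g\n",
                s$n_increased, s$n_decreased, s$binomial_p),
        file = path, append = TRUE)
  }
  invisible(path)
}
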
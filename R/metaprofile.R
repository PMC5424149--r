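#' Compute per-CpG beta values with the coverage filter
#'
#' The beta value of a CpG site is the methylated read count over total
#' coverage. Only sites covered by more than five reads (coverage >=
#' `min_coverage`, default 6) are valid; the rest are dropped, not errors.
#'
#' @param counts data.frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `n_methylated`, `n_unmethylated`.
#' @param min_coverage Minimum total coverage for a valid site (default 6,
#'   i.e. strictly more than five reads).
#' @return The valid rows with added `coverage` and `beta` columns.
#' @export
compute_beta_table <- function(counts, min_coverage = 6L) {
  stopifnot(all(c("chrom", "pos", "n_methylated", "n_unmethylated")
                %in% names(counts)))
  if (any(counts$n_methylated < 0 | counts$n_unmethylated < 0)) {
    stop("negative counts")
  }
  counts$coverage <- counts$n_methylated + counts$n_unmethylated
  keep <- counts$coverage >= min_coverage
  out <- counts[keep, , drop = FALSE]
  out$beta <- out$n_methylated / out$coverage
  rownames(out) <- NULL
  out
}

#' Read a per-CpG methylation count table
#'
#' Tab-separated cytosine-report shape: chrom, 1-based position, strand,
#' methylated count, unmethylated count. A header line is auto-detected.
#'
#' @param path File path.
#' @return data.frame with the canonical column names.
#' @export
read_cpg_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "pos", "strand", "n_methylated", "n_unmethylated")
  df
}

#' Read interval signal (e.g. ChIP fold enrichment) from BED+value/bedGraph
#'
#' Four tab-separated columns: chrom, start (0-based), end, value.
#'
#' @param path File path.
#' @return GRanges with a `value` metadata column.
#' @export
read_signal_bed <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                         value = df$value)
}

# 0-based positions of the anchor boundary for each intron, plus a flip flag;
# offsets are oriented so negative is always the exonic side of a 5' junction
# (for the 3' junction, negative is the intronic side; the intron is always
# on the side where a 5'-junction offset is non-negative)
anchor_info <- function(introns, anchor) {
  minus <- as.character(BiocGenerics::strand(introns)) == "-"
  start0 <- BiocGenerics::start(introns) - 1L
  end0 <- BiocGenerics::end(introns)
  boundary <- switch(anchor,
    junction5 = introns$junction5,
    junction3 = introns$junction3,
    midpoint = start0 + (end0 - start0) %/% 2L,
    stop("unknown anchor: ", anchor))
  list(boundary = boundary, flip = minus)
}

# signed offset of 0-based base position p relative to boundary b:
# plus strand: p - b (first base right of the boundary gets 0);
# minus strand: (b - 1) - p (first base left of the boundary gets 0)
relative_offset <- function(pos0, boundary, flip) {
  if (flip) boundary - 1L - pos0 else pos0 - boundary
}

#' Windowed metaprofile of point or interval signal around intron anchors
#'
#' Scans the +/- `flank` bp region around the 5' junction, 3' junction or
#' midpoint of each intron of a stratum with non-overlapping `window`-bp
#' bins (the default 200 bp region divided into 20 sub-windows of 10 bp).
#' Within each window, the mean is the sum of values over all contributing
#' sites (pooled across introns) divided by their number: for CpG beta
#' tables each valid site within the window contributes its beta once; for
#' interval signal (ChIP peaks) each record contributes its fold enrichment
#' once to every window its interval overlaps.
#'
#' Profiles are strand-aware: minus-strand introns are flipped so that
#' negative offsets are always the exonic side of a 5' junction (and the
#' intronic side of a 3' junction). Midpoint windows are clipped to the
#' intron span, so short introns contribute no signal beyond their ends.
#'
#' @param signal Either a beta table from [compute_beta_table()] (point
#'   sites, columns `chrom`, `pos`, `beta`) or a GRanges with a `value`
#'   column (interval signal).
#' @param introns Intron catalogue (a stratum subset, e.g.
#'   `introns[quant$retained]`).
#' @param anchor `"junction5"`, `"junction3"` or `"midpoint"`.
#' @param stratum Label stored in the output (e.g. `"retained"`).
#' @param window Window width in bp (default 10).
#' @param flank Half-width of the scanned region in bp (default 100);
#'   must be divisible by `window`.
#' @return data.frame with one row per window: `anchor`, `stratum`,
#'   `window` (1-based index), `offset_start` (signed start offset of the
#'   window, -flank for the first), `mean` (NA when empty) and `n`
#'   (contributing sites).
#' @export
window_profile <- function(signal, introns, anchor = "junction5",
                           stratum = "all", window = 10L, flank = 100L) {
  if (flank %% window != 0L) stop("flank must be divisible by window")
  n_win <- 2L * flank %/% window
  ai <- anchor_info(introns, anchor)
  acc_sum <- numeric(n_win)
  acc_n <- integer(n_win)

  if (methods::is(signal, "GRanges")) {
    # interval signal: one contribution per (record, window) overlap
    for (i in seq_along(introns)) {
      wins <- window_ranges(introns[i], ai$boundary[i], ai$flip[i],
                            window, flank, anchor)
      hits <- GenomicRanges::findOverlaps(wins, signal, ignore.strand = TRUE)
      if (length(hits) == 0L) next
      w <- wins$window[S4Vectors::queryHits(hits)]
      v <- signal$value[S4Vectors::subjectHits(hits)]
      acc_sum <- acc_sum + as.numeric(tapply(v, factor(w, levels = seq_len(n_win)),
                                             sum, default = 0))
      acc_n <- acc_n + as.integer(table(factor(w, levels = seq_len(n_win))))
    }
  } else {
    stopifnot(all(c("chrom", "pos", "beta") %in% names(signal)))
    pos0 <- signal$pos - 1L
    for (i in seq_along(introns)) {
      chrom <- as.character(GenomeInfoDb::seqnames(introns)[i])
      on_chrom <- signal$chrom == chrom
      if (!any(on_chrom)) next
      off <- relative_offset(pos0[on_chrom], ai$boundary[i], ai$flip[i])
      keep <- off >= -flank & off < flank
      if (anchor == "midpoint") {
        # clip to the intron span to avoid re-counting junction-adjacent signal
        inside <- pos0[on_chrom] >= BiocGenerics::start(introns)[i] - 1L &
          pos0[on_chrom] < BiocGenerics::end(introns)[i]
        keep <- keep & inside
      }
      if (!any(keep)) next
      w <- (off[keep] + flank) %/% window + 1L
      b <- signal$beta[on_chrom][keep]
      acc_sum <- acc_sum + as.numeric(tapply(b, factor(w, levels = seq_len(n_win)),
                                             sum, default = 0))
      acc_n <- acc_n + as.integer(table(factor(w, levels = seq_len(n_win))))
    }
  }

  data.frame(anchor = anchor, stratum = stratum,
             window = seq_len(n_win),
             offset_start = seq.int(-flank, flank - window, by = window),
             mean = ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L), NA_real_),
             n = acc_n,
             stringsAsFactors = FALSE)
}

# genomic GRanges of the n_win windows around one intron's anchor, with a
# `window` index in profile orientation (window 1 starts at offset -flank)
window_ranges <- function(intron, boundary, flip, window, flank, anchor) {
  n_win <- 2L * flank %/% window
  if (!flip) {
    starts0 <- boundary - flank + (seq_len(n_win) - 1L) * window
    idx <- seq_len(n_win)
  } else {
    # window k covers offsets [-flank + (k-1)*w, ...); offset o maps to
    # genomic pos0 = boundary - 1 - o, so windows run right to left
    ends0 <- boundary - 1L - (-flank + (seq_len(n_win) - 1L) * window) + 1L
    starts0 <- ends0 - window
    idx <- seq_len(n_win)
  }
  gr <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(intron)),
    IRanges::IRanges(start = starts0 + 1L, width = window),
    window = idx)
  if (anchor == "midpoint") {
    span <- GenomicRanges::granges(intron)
    hit <- IRanges::overlapsAny(gr, span, ignore.strand = TRUE)
    gr <- GenomicRanges::pintersect(gr[hit],
                                    rep(span, sum(hit)), ignore.strand = TRUE)
  }
  gr
}

#' Paired t-test across metaprofile sub-windows
#'
#' The region is divided into sub-windows; the window means of the two strata
#' (e.g. retained vs non-retained introns) are paired by window and a
#' classical paired t-test assesses the overall difference. Windows missing
#' (empty) in either profile are excluded pairwise.
#'
#' @param profile1,profile2 data.frames from [window_profile()] sharing
#'   anchor and window grid.
#' @return list with `t`, `df`, `p_value`, `n_pairs`, `mean_difference`
#'   (profile1 minus profile2) and `degenerate` (TRUE when the differences
#'   have zero variance, in which case no p is reported).
#' @export
paired_window_test <- function(profile1, profile2) {
  stopifnot(identical(profile1$anchor, profile2$anchor),
            identical(profile1$offset_start, profile2$offset_start))
  ok <- !is.na(profile1$mean) & !is.na(profile2$mean)
  if (sum(ok) < 3L) stop("fewer than 3 complete window pairs")
  a <- profile1$mean[ok]; b <- profile2$mean[ok]
  d <- a - b
  if (all(d == 0)) {
    return(list(t = 0, df = length(d) - 1L, p_value = 1, n_pairs = length(d),
                mean_difference = 0, degenerate = FALSE))
  }
  if (stats::sd(d) == 0) {
    # constant non-zero shift: t is infinite, no finite p is reported
    return(list(t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                n_pairs = length(d), mean_difference = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_pairs = length(d),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Write a metaprofile table
#' @param profile data.frame from [window_profile()] (rows from several
#'   anchors/strata may be concatenated).
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
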
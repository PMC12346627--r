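#' @name metrics
#' @title Read-level methylation pattern metrics
#'
#' @description
#' Six per-region statistics computed from the clipped read haplotypes of a
#' region (a [extract_region_reads()] result or any table of 0/1 patterns
#' with multiplicities):
#'
#' * **methylation ratio** — methylated CpG observations over all CpG
#'   observations; the bulk average level every downstream selection is
#'   conditioned on.
#' * **MCR** (methylation concurrence ratio) — unmethylated CpG observations
#'   residing on *partially* methylated reads (reads carrying both states),
#'   over all CpG observations.  Sensitive to the co-occurrence of
#'   unmethylated CpGs on individual DNA molecules; bounded by
#'   `1 - ratio`.
#' * **MHL** (methylated haplotype load) — length-weighted fraction of fully
#'   methylated substrings: `sum(l * P(l)) / sum(l)` for `l = 1..L`, where
#'   `P(l)` is the count-weighted fraction of length-`l` CpG substrings that
#'   are all methylated and `L` is the longest clipped read (optionally
#'   capped).
#' * **MBS** (methylation block score) — count-weighted mean over reads of
#'   `sum(run_length^2) / read_length^2` taken over the read's maximal runs
#'   of consecutive methylated CpGs; rewards contiguous methylation.
#' * **PDR** (proportion of discordant reads) — among reads covering at
#'   least `min_cpgs_per_read` CpGs, the count-weighted fraction carrying
#'   both states.
#' * **entropy** — normalized Shannon entropy (bits per CpG) of the pooled
#'   `word_size`-CpG pattern frequencies over all contiguous windows of all
#'   reads; 1 when all `2^word_size` patterns are equiprobable.
#'
#' All computations weight reads by their multiplicity and use observed CpGs
#' only.  Metrics that cannot be computed return `NA`, never 0, so that "no
#' data" is not conflated with "no signal".
#'
#' @param rrs A `RegionReadSet`, an `mhap_reads` data frame, or any data
#'   frame with `pattern` and `count` columns.
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
NULL

# Normalize input to an aggregated (pattern, count) table with derived
# per-pattern quantities shared by all metrics.
pattern_table <- function(rrs) {
  reads <- if (inherits(rrs, "RegionReadSet")) rrs$reads else rrs
  if (is.null(reads$pattern)) stop("expected a RegionReadSet or reads table")
  if (nrow(reads) == 0L) {
    return(list(pattern = character(0), count = integer(0),
                len = integer(0), n1 = integer(0)))
  }
  cnt <- rowsum(as.numeric(reads$count), reads$pattern)
  pattern <- rownames(cnt)
  len <- nchar(pattern)
  list(pattern = pattern,
       count = as.numeric(cnt[, 1]),
       len = len,
       n1 = len - nchar(gsub("1", "", pattern, fixed = TRUE)))
}

# Lengths of maximal runs of '1' per pattern.
runs_of_1 <- function(pattern) {
  lapply(strsplit(pattern, "0", fixed = TRUE),
         function(s) nchar(s[nzchar(s)]))
}

#' @rdname metrics
#' @export
methylation_ratio <- function(rrs) {
  pt <- pattern_table(rrs)
  tot <- sum(pt$count * pt$len)
  if (tot == 0) return(NA_real_)
  sum(pt$count * pt$n1) / tot
}

#' @rdname metrics
#' @export
mcr <- function(rrs) {
  pt <- pattern_table(rrs)
  tot <- sum(pt$count * pt$len)
  if (tot == 0) return(NA_real_)
  partial <- pt$n1 > 0L & pt$n1 < pt$len
  sum(pt$count[partial] * (pt$len[partial] - pt$n1[partial])) / tot
}

#' @rdname metrics
#' @param max_len Longest substring length entering MHL; `NULL` (default)
#'   uses the longest clipped read.
#' @export
mhl <- function(rrs, max_len = NULL) {
  pt <- pattern_table(rrs)
  if (!length(pt$pattern)) return(NA_real_)
  L <- max(pt$len)
  if (!is.null(max_len)) {
    stopifnot(max_len >= 1L)
    L <- min(L, as.integer(max_len))
  }
  runs <- runs_of_1(pt$pattern)
  num <- den <- numeric(L)
  for (l in seq_len(L)) {
    meth_sub <- vapply(runs, function(r) sum(pmax(r - l + 1L, 0L)), numeric(1))
    num[l] <- sum(pt$count * meth_sub)
    den[l] <- sum(pt$count * pmax(pt$len - l + 1L, 0L))
  }
  P <- num / den # den > 0 for all l <= longest read
  sum(seq_len(L) * P) / sum(seq_len(L))
}

#' @rdname metrics
#' @export
mbs <- function(rrs) {
  pt <- pattern_table(rrs)
  if (!length(pt$pattern)) return(NA_real_)
  runs <- runs_of_1(pt$pattern)
  score <- vapply(runs, function(r) sum(r^2), numeric(1)) / pt$len^2
  sum(pt$count * score) / sum(pt$count)
}

#' @rdname metrics
#' @param min_cpgs_per_read Minimum clipped CpGs for a read to enter PDR
#'   (default 4, the convention for discordance calling).
#' @export
pdr <- function(rrs, min_cpgs_per_read = 4L) {
  pt <- pattern_table(rrs)
  q <- pt$len >= min_cpgs_per_read
  if (!any(q)) return(NA_real_)
  disc <- pt$n1 > 0L & pt$n1 < pt$len
  sum(pt$count[q & disc]) / sum(pt$count[q])
}

#' @rdname metrics
#' @param word_size CpG word length for entropy (default 4).
#' @export
meth_entropy <- function(rrs, word_size = 4L) {
  stopifnot(word_size >= 2L)
  pt <- pattern_table(rrs)
  q <- which(pt$len >= word_size)
  if (!length(q)) return(NA_real_)
  words <- character(0); wcount <- numeric(0)
  for (i in q) {
    starts <- seq_len(pt$len[i] - word_size + 1L)
    words <- c(words, substring(pt$pattern[i], starts,
                                starts + word_size - 1L))
    wcount <- c(wcount, rep(pt$count[i], length(starts)))
  }
  freq <- rowsum(wcount, words)[, 1]
  p <- freq / sum(freq)
  -sum(p * log2(p)) / word_size
}

#' Compute all six metrics for one region read set
#'
#' Applies the region-level coverage filter and per-metric minima, returning
#' one row per region.  Regions with total read multiplicity below
#' `min_reads` are flagged low-coverage and all metric fields are `NA`.
#'
#' @inheritParams metrics
#' @param min_reads Minimum total read multiplicity for a region to be
#'   scored (default 10).
#' @param pdr_min_cpgs Passed to [pdr()].
#' @param entropy_word Passed to [meth_entropy()].
#' @param mhl_max_len Passed to [mhl()].
#' @return One-row data frame: `n_reads`, `n_cpg_obs`, `ratio`, `mcr`,
#'   `mhl`, `mbs`, `pdr`, `entropy`, `low_coverage`.
#' @export
compute_metrics <- function(rrs, min_reads = 10L, pdr_min_cpgs = 4L,
                            entropy_word = 4L, mhl_max_len = NULL) {
  pt <- pattern_table(rrs)
  n_reads <- sum(pt$count)
  n_obs <- sum(pt$count * pt$len)
  if (n_reads < min_reads) {
    return(data.frame(n_reads = n_reads, n_cpg_obs = n_obs,
                      ratio = NA_real_, mcr = NA_real_, mhl = NA_real_,
                      mbs = NA_real_, pdr = NA_real_, entropy = NA_real_,
                      low_coverage = TRUE))
  }
  df <- data.frame(pattern = pt$pattern, count = pt$count)
  data.frame(n_reads = n_reads, n_cpg_obs = n_obs,
             ratio = methylation_ratio(df),
             mcr = mcr(df),
             mhl = mhl(df, max_len = mhl_max_len),
             mbs = mbs(df),
             pdr = pdr(df, min_cpgs_per_read = pdr_min_cpgs),
             entropy = meth_entropy(df, word_size = entropy_word),
             low_coverage = FALSE)
}

#' Per-region metric table for one sample
#'
#' Clips the sample's reads to each region and computes all six metrics,
#' producing the per-sample table consumed by [build_metric_matrix()].
#'
#' @param reads An `mhap_reads` data frame (one sample).
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `id`.
#' @param cpg_index A `CpGIndex`.
#' @param min_reads,pdr_min_cpgs,entropy_word,mhl_max_len See
#'   [compute_metrics()].
#' @param min_overlap_cpgs Minimum clipped read length (see
#'   [extract_region_reads()]).
#' @return Data frame with one row per region: region columns followed by
#'   the [compute_metrics()] columns.
#' @export
region_metrics <- function(reads, regions, cpg_index, min_reads = 10L,
                           pdr_min_cpgs = 4L, entropy_word = 4L,
                           mhl_max_len = NULL, min_overlap_cpgs = 1L) {
  if (is.null(regions$id)) {
    regions$id <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rrs <- extract_region_reads(reads, regions[i, ], cpg_index,
                                min_overlap_cpgs = min_overlap_cpgs)
    rows[[i]] <- compute_metrics(rrs, min_reads = min_reads,
                                 pdr_min_cpgs = pdr_min_cpgs,
                                 entropy_word = entropy_word,
                                 mhl_max_len = mhl_max_len)
  }
  cbind(regions[, c("id", "chrom", "start", "end"), drop = FALSE],
        do.call(rbind, rows), row.names = NULL)
}

#' Write a per-region metric table as TSV
#'
#' Missing values are written as `NA`.
#'
#' @param metrics_table Output of [region_metrics()].
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed provenance
#'   lines to prepend.
#' @return Invisibly, the path.
#' @export
write_metrics_tsv <- function(metrics_table, path, header_lines = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(metrics_table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
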
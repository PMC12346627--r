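# Brute-force reference implementations of every metric, kept deliberately
# naive and independent of the package internals: multiplicities are
# expanded into duplicate reads, substrings and windows are enumerated
# explicitly, and everything is computed by looping over individual reads.

expand_reads <- function(patterns, counts = rep(1L, length(patterns))) {
  rep(patterns, counts)
}

oracle_ratio <- function(patterns, counts = rep(1L, length(patterns))) {
  reads <- expand_reads(patterns, counts)
  if (!length(reads)) return(NA_real_)
  ones <- 0; total <- 0
  for (r in reads) {
    bits <- as.integer(strsplit(r, "")[[1]])
    ones <- ones + sum(bits)
    total <- total + length(bits)
  }
  ones / total
}

oracle_mcr <- function(patterns, counts = rep(1L, length(patterns))) {
  reads <- expand_reads(patterns, counts)
  if (!length(reads)) return(NA_real_)
  num <- 0; total <- 0
  for (r in reads) {
    bits <- as.integer(strsplit(r, "")[[1]])
    total <- total + length(bits)
    if (any(bits == 1L) && any(bits == 0L)) num <- num + sum(bits == 0L)
  }
  num / total
}

oracle_mhl <- function(patterns, counts = rep(1L, length(patterns)),
                       max_len = NULL) {
  reads <- expand_reads(patterns, counts)
  if (!length(reads)) return(NA_real_)
  L <- max(nchar(reads))
  if (!is.null(max_len)) L <- min(L, max_len)
  num_sum <- 0; den_sum <- 0
  for (l in seq_len(L)) {
    meth <- 0; tot <- 0
    for (r in reads) {
      n <- nchar(r)
      if (n < l) next
      for (i in seq_len(n - l + 1L)) {
        sub <- substr(r, i, i + l - 1L)
        tot <- tot + 1L
        if (sub == strrep("1", l)) meth <- meth + 1L
      }
    }
    num_sum <- num_sum + l * meth / tot
    den_sum <- den_sum + l
  }
  num_sum / den_sum
}

oracle_mbs <- function(patterns, counts = rep(1L, length(patterns))) {
  reads <- expand_reads(patterns, counts)
  if (!length(reads)) return(NA_real_)
  scores <- numeric(length(reads))
  for (k in seq_along(reads)) {
    bits <- as.integer(strsplit(reads[k], "")[[1]])
    r <- rle(bits)
    runs1 <- r$lengths[r$values == 1L]
    scores[k] <- sum(runs1^2) / length(bits)^2
  }
  mean(scores)
}

oracle_pdr <- function(patterns, counts = rep(1L, length(patterns)),
                       min_cpgs = 4L) {
  reads <- expand_reads(patterns, counts)
  reads <- reads[nchar(reads) >= min_cpgs]
  if (!length(reads)) return(NA_real_)
  disc <- vapply(reads, function(r) {
    bits <- strsplit(r, "")[[1]]
    any(bits == "1") && any(bits == "0")
  }, logical(1))
  mean(disc)
}

oracle_entropy <- function(patterns, counts = rep(1L, length(patterns)),
                           word = 4L) {
  reads <- expand_reads(patterns, counts)
  words <- character(0)
  for (r in reads) {
    n <- nchar(r)
    if (n < word) next
    for (i in seq_len(n - word + 1L)) {
      words <- c(words, substr(r, i, i + word - 1L))
    }
  }
  if (!length(words)) return(NA_real_)
  p <- table(words) / length(words)
  -sum(p * log2(p)) / word
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# group-A assignments (mid-ranks for ties).
oracle_wilcox_p <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); na <- length(x)
  ranks <- rank(vals)
  w_obs <- sum(ranks[seq_len(na)])
  combs <- utils::combn(n, na)
  w_all <- apply(combs, 2L, function(i) sum(ranks[i]))
  mu <- na * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric p for a 2x2 overlap table by explicit summation.
oracle_hyper_p <- function(a, b, c, d) {
  K <- a + c; n_draw <- a + b; N <- a + b + c + d
  ks <- a:min(K, n_draw)
  sum(choose(K, ks) * choose(N - K, n_draw - ks)) / choose(N, n_draw)
}

# Random small read sets for oracle-equivalence sweeps.
random_patterns <- function(max_cpgs = 6L, max_reads = 8L) {
  n <- sample.int(max_reads, 1L)
  patterns <- vapply(seq_len(n), function(i) {
    len <- sample.int(max_cpgs, 1L)
    paste(sample(c("0", "1"), len, replace = TRUE), collapse = "")
  }, character(1))
  counts <- sample.int(3L, n, replace = TRUE)
  list(patterns = patterns, counts = counts)
}

as_reads <- function(patterns, counts = rep(1L, length(patterns)),
                     start_index = 0L) {
  read_haplotypes(rep("chr1", length(patterns)), start_index, patterns,
                  counts)
}

# A CpG index with `n` CpGs on chr1 at positions 2, 12, 22, ...
toy_index <- function(n = 10L, chrom = "chr1") {
  pos <- list(2L + 10L * (seq_len(n) - 1L))
  names(pos) <- chrom
  cpg_index_from_positions(pos)
}
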
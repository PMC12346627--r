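#' Construct a read-haplotype table
#'
#' A read haplotype is one sequencing read's binary methylation pattern over
#' consecutive CpG sites.  Collections of read haplotypes are plain data
#' frames so that they compose with base R and can be streamed to/from the
#' MHAP text format.
#'
#' @param chrom Chromosome names.
#' @param start_index 0-based per-chromosome ordinal of the first covered CpG.
#' @param pattern Strings over `{0,1}` (`0` unmethylated, `1` methylated).
#' @param count Positive integer multiplicities.
#' @param strand `"+"`, `"-"` or `"."` per read.
#' @return Data frame of class `mhap_reads` with those five columns.
#' @export
read_haplotypes <- function(chrom, start_index, pattern,
                            count = 1L, strand = ".") {
  n <- length(pattern)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start_index = rep_len(as.integer(start_index), n),
                   pattern = as.character(pattern),
                   count = rep_len(as.integer(count), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_reads(df)
  class(df) <- c("mhap_reads", "data.frame")
  df
}

validate_reads <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!grepl("^[01]+$", df$pattern))) {
    stop("read patterns must be non-empty strings over {0,1}")
  }
  if (any(is.na(df$count)) || any(df$count < 1L)) {
    stop("read counts must be positive integers")
  }
  if (any(df$start_index < 0L)) {
    stop("start_index must be >= 0")
  }
  if (any(!df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read an MHAP methylation-haplotype file
#'
#' MHAP is a tab-delimited read-level format: chrom, start, end (1-based
#' genomic positions of the first and last covered CpG cytosine), pattern
#' (string over `{0,1}`), count, strand.  Coordinates are resolved into
#' per-chromosome CpG ordinals through `cpg_index`; the pattern length must
#' equal the number of indexed CpGs spanned, which validates both the record
#' and the coordinate dialect.
#'
#' @param path Path to a (possibly gzip-compressed) MHAP file.
#' @param cpg_index A `CpGIndex` covering the file's chromosomes.
#' @return An `mhap_reads` data frame (see [read_haplotypes()]).  Records on
#'   chromosomes absent from the index are skipped with a warning; malformed
#'   records raise an error naming the line number.
#' @export
read_mhap <- function(path, cpg_index) {
  stopifnot(inherits(cpg_index, "CpGIndex"))
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(read_haplotypes(character(0), integer(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("MHAP line ", which(nf < 6L)[1], ": expected 6 tab-delimited fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  chrom <- m[, 1]; start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  pattern <- m[, 4]; count <- suppressWarnings(as.integer(m[, 5]))
  strand <- m[, 6]
  bad_pat <- !grepl("^[01]+$", pattern)
  if (any(bad_pat)) {
    stop("MHAP line ", which(bad_pat)[1], ": pattern must be a 0/1 string")
  }
  bad_count <- is.na(count) | count < 1L
  if (any(bad_count)) {
    stop("MHAP line ", which(bad_count)[1], ": count must be a positive integer")
  }
  known <- chrom %in% names(cpg_index$positions)
  if (any(!known)) {
    warning("skipping ", sum(!known), " MHAP record(s) on chromosome(s) ",
            paste(unique(chrom[!known]), collapse = ", "),
            " absent from the CpG index")
  }
  keep <- which(known)
  si <- ei <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom[keep])) {
    i <- keep[chrom[keep] == ch]
    si[i] <- cpg_ordinal(cpg_index, ch, start[i])
    ei[i] <- cpg_ordinal(cpg_index, ch, end[i])
  }
  bad_pos <- keep[is.na(si[keep]) | is.na(ei[keep])]
  if (length(bad_pos)) {
    stop("MHAP line ", bad_pos[1],
         ": start/end is not an indexed CpG position")
  }
  span <- ei[keep] - si[keep] + 1L
  bad_span <- which(span != nchar(pattern[keep]))
  if (length(bad_span)) {
    j <- bad_span[1]
    stop("MHAP line ", keep[j], ": pattern/CpG mismatch (pattern length ",
         nchar(pattern[keep[j]]), ", indexed CpGs spanned ", span[j], ")")
  }
  read_haplotypes(chrom[keep], si[keep], pattern[keep],
                  count[keep], strand[keep])
}

#' Write read haplotypes to an MHAP file
#'
#' Inverse of [read_mhap()]: per-chromosome CpG ordinals are mapped back to
#' the 1-based genomic positions of the first and last covered CpG cytosine.
#' Records are written sorted by chromosome and start ordinal so that output
#' is deterministic.
#'
#' @param reads An `mhap_reads` data frame.
#' @param path Output path (gzip-compressed when ending in `.gz`).
#' @param cpg_index A `CpGIndex` covering the reads' chromosomes.
#' @return Invisibly, the path.
#' @export
write_mhap <- function(reads, path, cpg_index) {
  stopifnot(inherits(cpg_index, "CpGIndex"))
  validate_reads(reads)
  reads <- reads[order(reads$chrom, reads$start_index, reads$pattern), ,
                 drop = FALSE]
  lines <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    p <- cpg_positions(cpg_index, ch)
    i <- which(reads$chrom == ch)
    s <- reads$start_index[i]
    e <- s + nchar(reads$pattern[i]) - 1L
    if (any(e >= length(p))) {
      stop("read extends beyond indexed CpGs on ", ch)
    }
    lines[i] <- paste(ch, p[s + 1L], p[e + 1L], reads$pattern[i],
                      reads$count[i], reads$strand[i], sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a PAT methylation-haplotype file
#'
#' PAT is a tab-delimited read-level dialect: chrom, CpG start index, pattern
#' over `{C,T,.}` (`C` methylated, `T` unmethylated, `.` not observed),
#' count.  CpG indices are interpreted as 1-based per-chromosome ordinals
#' over `cpg_index`.  A `.` splits the read into separate maximal contiguous
#' segments, each inheriting the parent multiplicity — observed CpGs only,
#' nothing is imputed.  Strand is recorded as `"."`.
#'
#' @param path Path to a (possibly gzip-compressed) PAT file.
#' @param cpg_index A `CpGIndex` used to validate index bounds.
#' @return An `mhap_reads` data frame.
#' @export
read_pat <- function(path, cpg_index) {
  stopifnot(inherits(cpg_index, "CpGIndex"))
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(read_haplotypes(character(0), integer(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("PAT line ", which(nf < 4L)[1], ": expected 4 tab-delimited fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  chrom <- m[, 1]; idx1 <- suppressWarnings(as.integer(m[, 2]))
  pat <- m[, 3]; count <- suppressWarnings(as.integer(m[, 4]))
  bad_pat <- !grepl("^[CT.]+$", pat)
  if (any(bad_pat)) {
    stop("PAT line ", which(bad_pat)[1],
         ": pattern must use only C, T and '.'")
  }
  bad_count <- is.na(count) | count < 1L
  if (any(bad_count)) {
    stop("PAT line ", which(bad_count)[1], ": count must be a positive integer")
  }
  if (any(is.na(idx1) | idx1 < 1L)) {
    stop("PAT line ", which(is.na(idx1) | idx1 < 1L)[1],
         ": CpG start index must be a positive integer")
  }
  ncpg <- n_cpgs(cpg_index)
  known <- chrom %in% names(ncpg)
  if (any(!known)) {
    warning("skipping ", sum(!known), " PAT record(s) on chromosome(s) ",
            paste(unique(chrom[!known]), collapse = ", "),
            " absent from the CpG index")
  }
  out_chrom <- character(0); out_start <- integer(0)
  out_pat <- character(0); out_count <- integer(0)
  for (i in which(known)) {
    # split on runs of '.', keeping each segment's offset within the read
    segs <- regmatches(pat[i], gregexpr("[CT]+", pat[i]))[[1]]
    if (!length(segs)) next
    offs <- gregexpr("[CT]+", pat[i])[[1]]
    starts0 <- idx1[i] - 1L + (as.integer(offs) - 1L) # 0-based ordinals
    ends0 <- starts0 + nchar(segs) - 1L
    if (any(ends0 >= ncpg[[chrom[i]]])) {
      stop("PAT line ", i, ": CpG index beyond chromosome ", chrom[i],
           " (", ncpg[[chrom[i]]], " indexed CpGs)")
    }
    out_chrom <- c(out_chrom, rep(chrom[i], length(segs)))
    out_start <- c(out_start, starts0)
    out_pat <- c(out_pat, chartr("CT", "10", segs))
    out_count <- c(out_count, rep(count[i], length(segs)))
  }
  read_haplotypes(out_chrom, out_start, out_pat, out_count, ".")
}

#' Merge duplicate haplotype records
#'
#' Identical records (same chromosome, start ordinal, pattern and strand) are
#' collapsed with their multiplicities summed.  Every metric in this package
#' is invariant to this aggregation.
#'
#' @param reads An `mhap_reads` data frame.
#' @return Aggregated `mhap_reads` data frame.
#' @export
aggregate_reads <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  key <- paste(reads$chrom, reads$start_index, reads$pattern, reads$strand,
               sep = "\r")
  cnt <- rowsum(reads$count, key)
  first <- reads[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(cnt[match(paste(first$chrom, first$start_index,
                                            first$pattern, first$strand,
                                            sep = "\r"),
                                      rownames(cnt)), 1])
  rownames(first) <- NULL
  class(first) <- c("mhap_reads", "data.frame")
  first
}

#' Extract and clip the reads overlapping a region
#'
#' Every read overlapping the region's CpG ordinals is truncated to the
#' in-region CpG columns, preserving multiplicities; clipped reads shorter
#' than `min_overlap_cpgs` are dropped.  The result is the unit on which all
#' per-region metrics are computed.
#'
#' @param reads An `mhap_reads` data frame.
#' @param region A list or one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive genomic coordinates) and optionally `id`.
#' @param cpg_index A `CpGIndex`.
#' @param min_overlap_cpgs Minimum clipped length to retain a read (>= 1).
#' @return A `RegionReadSet`: list with `region` (including the 0-based CpG
#'   ordinal bounds `lo`, `hi` and `n_cpg`) and `reads` (clipped
#'   `mhap_reads`).  A region containing no indexed CpG yields an empty read
#'   set flagged `no_cpgs`.
#' @export
extract_region_reads <- function(reads, region, cpg_index,
                                 min_overlap_cpgs = 1L) {
  stopifnot(min_overlap_cpgs >= 1L)
  region <- as.list(region)[c("chrom", "start", "end",
                              intersect("id", names(region)))]
  rng <- cpg_ordinal_range(cpg_index, region$chrom, region$start, region$end)
  if (is.null(rng)) {
    rrs <- structure(list(
      region = c(region, list(lo = NA_integer_, hi = NA_integer_, n_cpg = 0L)),
      reads = read_haplotypes(character(0), integer(0), character(0))),
      class = "RegionReadSet", no_cpgs = TRUE)
    return(rrs)
  }
  lo <- rng[1]; hi <- rng[2]
  r <- reads[reads$chrom == region$chrom, , drop = FALSE]
  len <- nchar(r$pattern)
  a <- pmax(r$start_index, lo)
  b <- pmin(r$start_index + len - 1L, hi)
  keep <- which(b - a + 1L >= min_overlap_cpgs & b >= a)
  clipped <- read_haplotypes(
    r$chrom[keep],
    a[keep],
    substr(r$pattern[keep], a[keep] - r$start_index[keep] + 1L,
           b[keep] - r$start_index[keep] + 1L),
    r$count[keep], r$strand[keep])
  structure(list(
    region = c(region, list(lo = lo, hi = hi, n_cpg = hi - lo + 1L)),
    reads = clipped), class = "RegionReadSet")
}

#' @export
print.RegionReadSet <- function(x, ...) {
  cat("RegionReadSet:", x$region$chrom, paste0(x$region$start, "-", x$region$end),
      "|", x$region$n_cpg, "CpGs,", sum(x$reads$count), "reads\n")
  invisible(x)
}

#' Read regions from a BED file
#'
#' BED intervals (0-based half-open) are converted to the package's internal
#' 1-based inclusive coordinates.
#'
#' @param path Path to a BED file.
#' @return Data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `id` (from the BED name column, or `chrom:start-end` when absent).
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  id <- if (!is.null(gr$name) && !all(is.na(gr$name))) {
    as.character(gr$name)
  } else {
    paste0(GenomicRanges::seqnames(gr), ":", GenomicRanges::start(gr), "-",
           GenomicRanges::end(gr))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             id = id, stringsAsFactors = FALSE)
}

#' Write regions to a BED file
#'
#' @param regions Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), optional `id` and `score`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- regions_to_granges(regions)
  if (!is.null(regions$id)) gr$name <- regions$id
  if (!is.null(regions$score)) gr$score <- regions$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end))
}
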
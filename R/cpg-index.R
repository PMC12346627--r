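#' Build a CpG-site index from genome sequence
#'
#' Scans each chromosome of a nucleotide sequence source for the dinucleotide
#' `CG` on the forward strand and records the 1-based genomic position of the
#' cytosine.  The resulting index is the shared coordinate system of all
#' methylation haplotype formats handled by this package: MHAP records locate
#' reads by the genomic positions of their first and last covered CpG, and PAT
#' records locate them by per-chromosome CpG ordinal.
#'
#' Reads on the reverse strand are assumed to have been destranded onto the
#' forward-strand CpG unit upstream of this package (standard WGBS practice),
#' so a single forward-strand index suffices.
#'
#' @param x A named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file (read with
#'   [Biostrings::readDNAStringSet()]).
#' @return A `CpGIndex` object: a list with element `positions`, a named list
#'   of strictly increasing integer vectors (one per chromosome) giving the
#'   1-based position of each CpG cytosine.
#' @examples
#' idx <- build_cpg_index(c(chr1 = "ACGTCGA"))
#' cpg_positions(idx, "chr1")  # 2 5
#' @export
build_cpg_index <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
    # FASTA headers may carry descriptions after the first token
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else if (is.character(x)) {
    if (length(x) && is.null(names(x))) {
      stop("sequence source must be named by chromosome")
    }
    seqs <- x
  } else {
    stop("unsupported sequence source of class ", paste(class(x), collapse = "/"))
  }
  if (length(seqs) == 0L) {
    warning("empty sequence source: CpG index has no chromosomes")
  }
  positions <- lapply(seqs, function(s) {
    s <- toupper(s)
    bad <- gsub("[ACGTUNRYSWKMBDHV]", "", s)
    if (nzchar(bad)) {
      stop("non-nucleotide characters in sequence: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    }
    hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  })
  new_cpg_index(positions)
}

#' Construct a CpG index directly from known positions
#'
#' Used when CpG coordinates are already available (e.g. from a CpG BED file
#' or a synthetic genome layout) rather than from sequence.
#'
#' @param positions Named list of integer vectors of 1-based CpG cytosine
#'   positions, one element per chromosome, each strictly increasing.
#' @return A `CpGIndex` object.
#' @export
cpg_index_from_positions <- function(positions) {
  positions <- lapply(positions, function(p) as.integer(p))
  new_cpg_index(positions)
}

new_cpg_index <- function(positions) {
  stopifnot(is.list(positions))
  if (length(positions) && is.null(names(positions))) {
    stop("CpG position list must be named by chromosome")
  }
  for (chrom in names(positions)) {
    p <- positions[[chrom]]
    if (length(p) && any(diff(p) <= 0L)) {
      stop("CpG positions not strictly increasing on ", chrom)
    }
  }
  structure(list(positions = positions), class = "CpGIndex")
}

#' @export
print.CpGIndex <- function(x, ...) {
  n <- vapply(x$positions, length, integer(1))
  cat("CpGIndex:", length(n), "chromosome(s),", sum(n), "CpG site(s)\n")
  invisible(x)
}

#' CpG positions of one chromosome
#' @param index A `CpGIndex`.
#' @param chrom Chromosome name.
#' @return Integer vector of 1-based CpG positions (empty if the chromosome
#'   has no CpGs or is absent).
#' @export
cpg_positions <- function(index, chrom) {
  stopifnot(inherits(index, "CpGIndex"))
  p <- index$positions[[chrom]]
  if (is.null(p)) integer(0) else p
}

#' Number of CpG sites per chromosome
#' @param index A `CpGIndex`.
#' @return Named integer vector.
#' @export
n_cpgs <- function(index) {
  vapply(index$positions, length, integer(1))
}

# 0-based ordinal of an exactly-matching CpG position; NA when the position
# is not an indexed CpG cytosine.
cpg_ordinal <- function(index, chrom, pos) {
  p <- cpg_positions(index, chrom)
  if (!length(p)) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, p)
  ok <- i >= 1L & p[pmax(i, 1L)] == pos
  out <- rep(NA_integer_, length(pos))
  out[ok] <- i[ok] - 1L
  out
}

# Ordinal range (0-based, inclusive) of CpGs inside [start, end]; NULL when
# the interval contains no indexed CpG.
cpg_ordinal_range <- function(index, chrom, start, end) {
  p <- cpg_positions(index, chrom)
  if (!length(p)) return(NULL)
  lo <- findInterval(start - 1L, p) # CpGs strictly before start
  hi <- findInterval(end, p)        # CpGs at or before end
  if (hi <= lo) return(NULL)
  c(lo, hi - 1L)
}

#' Load a CpG index from a BED file
#'
#' Inverse of [cpg_index_to_bed()]: reads a BED file of CpG cytosines
#' (0-based half-open) and reconstructs the index from the 1-based cytosine
#' positions.
#'
#' @param path Path to a CpG BED file.
#' @return A `CpGIndex`.
#' @export
cpg_index_from_bed <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  pos1 <- as.integer(d[[2]]) + 1L
  cpg_index_from_positions(split(pos1, d[[1]]))
}

#' Export a CpG index as a BED data frame
#'
#' @param index A `CpGIndex`.
#' @param path Optional output path; when given, a 4-column BED file
#'   (0-based half-open, name = per-chromosome 1-based ordinal) is written.
#' @return Invisibly, a data frame with columns `chrom`, `start` (0-based),
#'   `end`, `ordinal`.
#' @export
cpg_index_to_bed <- function(index, path = NULL) {
  stopifnot(inherits(index, "CpGIndex"))
  rows <- lapply(names(index$positions), function(chrom) {
    p <- index$positions[[chrom]]
    if (!length(p)) return(NULL)
    data.frame(chrom = chrom, start = p - 1L, end = p + 1L,
               ordinal = seq_along(p))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), ordinal = integer(0))
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(out)
}
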
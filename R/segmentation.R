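#' Segment per-CpG methylation profiles into homogeneous blocks
#'
#' Greedy left-to-right segmentation: a CpG joins the current block when its
#' ratio lies within `max_within_delta` of the running block mean and it is
#' no more than `max_gap_bp` downstream of the previous CpG; otherwise a new
#' block starts.  Blocks covering fewer than `min_cpg` CpGs are discarded.
#' The output therefore covers a subset of CpGs with non-overlapping,
#' sorted, homogeneously methylated blocks — the unit at which the
#' read-level metrics are computed.
#'
#' This is a deliberately simple single-profile homogeneity rule; externally
#' produced block definitions (BED) are accepted everywhere a block set is
#' needed, so this module is interchangeable.
#'
#' @param cpg_ratios Data frame with columns `chrom`, `pos` (1-based CpG
#'   position), `ratio` in `[0, 1]` and optionally `coverage`; positions
#'   must be sorted within chromosome.
#' @param min_cpg Minimum CpGs per emitted block (default 4).
#' @param max_within_delta Maximum absolute deviation of a joining CpG from
#'   the running block mean (default 0.25).
#' @param max_gap_bp Maximum distance between consecutive CpGs within a
#'   block (default 500).
#' @return Data frame of blocks: `chrom`, `start`, `end` (1-based inclusive,
#'   first to last CpG position), `id`, `n_cpg`, `mean_ratio`.
#' @export
segment_blocks <- function(cpg_ratios, min_cpg = 4L, max_within_delta = 0.25,
                           max_gap_bp = 500L) {
  stopifnot(min_cpg >= 1L, max_within_delta >= 0, max_gap_bp >= 1L)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), id = character(0),
                      n_cpg = integer(0), mean_ratio = numeric(0))
  if (is.null(cpg_ratios) || nrow(cpg_ratios) == 0L) return(empty)
  if (any(cpg_ratios$ratio < 0 | cpg_ratios$ratio > 1, na.rm = TRUE)) {
    stop("ratios must lie in [0, 1]")
  }
  out <- list()
  for (ch in unique(cpg_ratios$chrom)) {
    d <- cpg_ratios[cpg_ratios$chrom == ch, , drop = FALSE]
    if (is.unsorted(d$pos, strictly = TRUE)) {
      stop("CpG positions must be strictly increasing within ", ch)
    }
    pos <- d$pos; ratio <- d$ratio
    start_i <- 1L; run_sum <- ratio[1]; run_n <- 1L
    run_min <- ratio[1]; run_max <- ratio[1]
    flush <- function(i_end) {
      if (run_n >= min_cpg) {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = ch, start = pos[start_i], end = pos[i_end],
          n_cpg = run_n, mean_ratio = run_sum / run_n)
      }
    }
    for (i in seq_along(pos)[-1]) {
      # within delta of the running mean, and the mean must not have drifted
      # so far that the block's total ratio range exceeds 2 * delta
      joins <- (pos[i] - pos[i - 1L] <= max_gap_bp) &&
        (abs(ratio[i] - run_sum / run_n) <= max_within_delta) &&
        (max(run_max, ratio[i]) - min(run_min, ratio[i]) <=
           2 * max_within_delta)
      if (joins) {
        run_sum <- run_sum + ratio[i]; run_n <- run_n + 1L
        run_min <- min(run_min, ratio[i]); run_max <- max(run_max, ratio[i])
      } else {
        flush(i - 1L)
        start_i <- i; run_sum <- ratio[i]; run_n <- 1L
        run_min <- ratio[i]; run_max <- ratio[i]
      }
    }
    flush(length(pos))
  }
  if (!length(out)) return(empty)
  blocks <- do.call(rbind, out)
  blocks$id <- paste0(blocks$chrom, ":", blocks$start, "-", blocks$end)
  blocks[, c("chrom", "start", "end", "id", "n_cpg", "mean_ratio")]
}
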
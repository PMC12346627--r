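#' Pool single-cell reads into a pseudobulk sample
#'
#' Concatenates the read haplotypes of a set of cells and sums
#' multiplicities of identical records.  Because every metric in this
#' package is count-weighted, metrics computed on the pseudobulk equal
#' metrics computed on a bulk sample containing the same reads exactly.
#'
#' @param cells Named list of `mhap_reads` data frames, one per cell.
#' @param which Optional character vector of cell ids to pool (default all).
#' @return An `mhap_reads` data frame.
#' @export
pseudobulk <- function(cells, which = NULL) {
  if (!is.null(which)) cells <- cells[which]
  if (length(cells) == 0L) stop("empty cell set: nothing to pool")
  pooled <- do.call(rbind, cells)
  rownames(pooled) <- NULL
  class(pooled) <- c("mhap_reads", "data.frame")
  aggregate_reads(pooled)
}

# Per-region concurrence value on clipped reads: unmethylated CpG
# observations on partially methylated reads over all CpG observations.
region_concurrence <- function(reads, region, cpg_index, min_cpgs = 2L) {
  rrs <- extract_region_reads(reads, region, cpg_index,
                              min_overlap_cpgs = min_cpgs)
  pt <- pattern_table(rrs)
  tot <- sum(pt$count * pt$len)
  if (tot == 0) return(NA_real_)
  partial <- pt$n1 > 0L & pt$n1 < pt$len
  sum(pt$count[partial] * (pt$len[partial] - pt$n1[partial])) / tot
}

#' Single-cell methylation concurrence (scMCR)
#'
#' For one cell, computes the concurrence value in every region of a fixed
#' region set (typically the MCDRs called from bulk data): the number of
#' unmethylated CpGs on partially methylated clipped reads divided by the
#' total CpG observations of the region's clipped reads.  Only reads
#' covering at least `min_cpgs` in-region CpGs qualify (a single-CpG read
#' can never be partial).  The scMCR is the unweighted mean over regions
#' with at least one qualifying read; uncovered regions are excluded from
#' the mean, not imputed as zero.
#'
#' @param cell_reads `mhap_reads` data frame of one cell.
#' @param regions Region data frame (`chrom`, `start`, `end`, optional
#'   `id`).
#' @param cpg_index A `CpGIndex`.
#' @param min_cpgs Minimum clipped CpGs for a read to qualify (default 2).
#' @return List with `sc_mcr` (`NA` when no region is covered),
#'   `n_regions_used`, and `per_region` (named numeric vector).
#' @export
sc_mcr <- function(cell_reads, regions, cpg_index, min_cpgs = 2L) {
  if (nrow(regions) == 0L) stop("MCDR region set is empty")
  if (is.null(regions$id)) {
    regions$id <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  vals <- vapply(seq_len(nrow(regions)), function(i)
    region_concurrence(cell_reads, regions[i, ], cpg_index,
                       min_cpgs = min_cpgs), numeric(1))
  names(vals) <- regions$id
  used <- !is.na(vals)
  list(sc_mcr = if (any(used)) mean(vals[used]) else NA_real_,
       n_regions_used = sum(used),
       per_region = vals)
}

#' scMCR for a manifest of cells
#'
#' @param cells Named list of `mhap_reads` data frames (names = cell ids).
#' @param manifest Data frame with `cell`, `group` and optionally `patient`.
#' @inheritParams sc_mcr
#' @return Data frame: `cell`, `group`, `patient`, `sc_mcr`,
#'   `n_regions_used`.  Cells with no reads over the region set carry `NA`.
#' @export
sc_mcr_table <- function(cells, manifest, regions, cpg_index,
                         min_cpgs = 2L) {
  missing_cells <- setdiff(manifest$cell, names(cells))
  if (length(missing_cells)) {
    stop("manifest cell(s) without reads: ",
         paste(missing_cells, collapse = ", "))
  }
  res <- lapply(manifest$cell, function(cid)
    sc_mcr(cells[[cid]], regions, cpg_index, min_cpgs = min_cpgs))
  data.frame(cell = manifest$cell,
             group = manifest$group,
             patient = if (!is.null(manifest$patient)) manifest$patient
                       else NA_character_,
             sc_mcr = vapply(res, `[[`, numeric(1), "sc_mcr"),
             n_regions_used = vapply(res, `[[`, numeric(1),
                                     "n_regions_used"))
}

#' Read-category composition over a region set
#'
#' Classifies every clipped read with at least `min_cpgs` in-region CpGs as
#' fully unmethylated (all 0), partially methylated (mixed), or fully
#' methylated (all 1), and returns the count-weighted fractions across the
#' whole region set.  A decline of the partial fraction at fixed ratio is
#' the read-level signature of concurrence depletion.
#'
#' @param reads `mhap_reads` data frame (a cell, a patient's pooled cells,
#'   or a bulk sample).
#' @param regions Region data frame.
#' @param cpg_index A `CpGIndex`.
#' @param min_cpgs Minimum clipped CpGs to classify a read (default 2).
#' @return Named numeric vector `c(unmeth, partial, meth)` summing to 1, or
#'   all-`NA` when no read qualifies.
#' @export
read_category_profile <- function(reads, regions, cpg_index, min_cpgs = 2L) {
  counts <- c(unmeth = 0, partial = 0, meth = 0)
  for (i in seq_len(nrow(regions))) {
    rrs <- extract_region_reads(reads, regions[i, ], cpg_index,
                                min_overlap_cpgs = min_cpgs)
    pt <- pattern_table(rrs)
    if (!length(pt$pattern)) next
    counts["unmeth"] <- counts["unmeth"] + sum(pt$count[pt$n1 == 0L])
    counts["meth"] <- counts["meth"] + sum(pt$count[pt$n1 == pt$len])
    counts["partial"] <- counts["partial"] +
      sum(pt$count[pt$n1 > 0L & pt$n1 < pt$len])
  }
  tot <- sum(counts)
  if (tot == 0) return(c(unmeth = NA_real_, partial = NA_real_,
                         meth = NA_real_))
  counts / tot
}
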
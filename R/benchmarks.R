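#' Metric response to the methylation level
#'
#' Simulates regions of i.i.d. Bernoulli reads over a grid of methylation
#' levels (no polarization) and records each metric's mean across regions.
#' The expected picture: MHL and MBS increase monotonically with the level,
#' while MCR, PDR and entropy vanish at both extremes and peak at
#' intermediate methylation — the read-level metrics carry information that
#' is not a rebranding of the average level.
#'
#' @param m_grid Methylation levels to simulate (default 0.05 to 0.95 in
#'   steps of 0.05).
#' @param depth Reads per region (default 500).
#' @param n_regions_per_m Regions per grid point (default 10).
#' @param cpgs_per_region,read_span Region geometry (defaults 8 and 4).
#' @param seed Seed for the whole sweep.
#' @return Data frame with one row per grid point: `m` plus the mean of
#'   each metric over the regions simulated at that level.
#' @export
metric_ratio_response <- function(m_grid = seq(0.05, 0.95, by = 0.05),
                                  depth = 500L, n_regions_per_m = 10L,
                                  cpgs_per_region = 8L, read_span = 4L,
                                  seed = 1L) {
  rows <- lapply(seq_along(m_grid), function(k) {
    cfg <- synth_config(n_regions = n_regions_per_m,
                        cpgs_per_region = cpgs_per_region,
                        read_span = read_span, depth = depth,
                        n_samples = c(g = 1L), planted_fraction = 0,
                        pi_background = 0,
                        m = rep(m_grid[k], n_regions_per_m),
                        seed = seed + k)
    sim <- generate_bulk(cfg)
    tab <- region_metrics(sim$reads[[1]], sim$regions, sim$cpg_index)
    data.frame(m = m_grid[k],
               ratio = mean(tab$ratio), mcr = mean(tab$mcr),
               mhl = mean(tab$mhl), mbs = mean(tab$mbs),
               pdr = mean(tab$pdr), entropy = mean(tab$entropy))
  })
  do.call(rbind, rows)
}

#' Cross-tissue coefficient-of-variation panel
#'
#' Simulates a panel of groups ("tissues") that share every region's
#' methylation level and differ only in read polarization, then ranks the
#' five read-level metrics by the median coefficient of variation of their
#' per-region group means ([cv_benchmark()]).  The panel emulates the
#' predominantly methylated fraction of the somatic methylome
#' (`m ~ Beta(8, 2)`) at modest sequencing depth; see the package vignette
#' for why the methylation regime matters to the MCR-vs-PDR ordering.
#'
#' @param pi_grid Polarization per group (default 6 groups, 0 to 0.95).
#' @param n_regions Regions in the panel (default 300).
#' @param depth Reads per region per sample (default 20).
#' @param n_samples_per_group Samples per group (default 3).
#' @param seed Seed.
#' @return The [cv_benchmark()] result (per-region CVs and per-metric
#'   summary, ordered by decreasing median CV).
#' @export
cv_panel <- function(pi_grid = c(0, 0.2, 0.4, 0.6, 0.8, 0.95),
                     n_regions = 300L, depth = 20L,
                     n_samples_per_group = 3L, seed = 1L) {
  groups <- paste0("tissue", seq_along(pi_grid))
  m <- with_seed(seed + 104729L, stats::rbeta(n_regions, 8, 2))
  cfg <- synth_config(
    n_regions = n_regions, depth = depth,
    n_samples = stats::setNames(rep(n_samples_per_group, length(pi_grid)),
                                groups),
    pi_by_group = stats::setNames(pi_grid, groups),
    m = m, seed = seed)
  sim <- generate_bulk(cfg)
  tables <- lapply(sim$reads, region_metrics, regions = sim$regions,
                   cpg_index = sim$cpg_index)
  mm <- build_metric_matrix(tables, sim$manifest)
  cv_benchmark(mm)
}

#' Planted-MCDR recovery experiment
#'
#' Runs the full two-group pipeline on generated data — bulk samples,
#' per-sample metrics, metric matrix, differential MCR calls — and scores
#' the calls against the generator's truth table.  Sensitivity is the
#' fraction of planted concurrence-depleted regions called as MCDRs
#' (decreased in the focal group); the false-positive rate is the fraction
#' of null regions called in either direction.
#'
#' @param config A `SyntheticConfig`; the default plants 25% of 200
#'   regions at depth 50 with 5 samples in each of two groups.
#' @param p_thresh,ratio_delta_max,metric_delta_min See
#'   [call_differential()].
#' @return List with `sensitivity`, `fpr`, `n_planted`, `n_null`, `calls`
#'   (the differential table joined with the planted truth), and `sim`.
#' @export
mcdr_recovery <- function(config = synth_config(),
                          p_thresh = 0.05, ratio_delta_max = 0.2,
                          metric_delta_min = 0.2) {
  sim <- generate_bulk(config)
  tables <- lapply(sim$reads, region_metrics, regions = sim$regions,
                   cpg_index = sim$cpg_index)
  mm <- build_metric_matrix(tables, sim$manifest)
  groups <- unique(sim$manifest$group)
  focal <- config$focal_group
  other <- setdiff(groups, focal)[1]
  calls <- call_differential(mm, "mcr", focal, other,
                             p_thresh = p_thresh,
                             ratio_delta_max = ratio_delta_max,
                             metric_delta_min = metric_delta_min)
  calls$planted <- sim$truth$planted[match(calls$id, sim$truth$id)]
  calls$planted_elevated <-
    sim$truth$planted_elevated[match(calls$id, sim$truth$id)]
  depleted <- calls$planted & !calls$planted_elevated
  mcdr <- calls$call & calls$direction == "decreased"
  list(sensitivity = sum(mcdr & depleted) / sum(depleted),
       fpr = sum(calls$call & !calls$planted) / sum(!calls$planted),
       n_planted = sum(depleted), n_null = sum(!calls$planted),
       calls = calls, sim = sim)
}

#' MCDR / accessibility-peak enrichment experiment
#'
#' Emulates the intersection of concurrence calls with differential
#' chromatin-accessibility peaks: regions are planted with depleted *and*
#' elevated concurrence in the focal (tumor-like) group, synthetic "gained
#' peaks" are laid over most of the truly depleted regions (plus background
#' regions), "lost peaks" over background only, and the four query-by-peak
#' combinations are scored with [fisher_enrichment()] against the
#' ratio-stable universe (all testable regions with `p_ratio >=
#' p_thresh`).  Concurrence depletion coinciding with gained accessibility
#' should attain the largest odds ratio.
#'
#' @param seed Seed.
#' @param n_regions Total regions (default 200).
#' @param depth Reads per region per sample (default 50).
#' @param peak_cover_fraction Fraction of truly depleted (resp. elevated)
#'   regions covered by gained (resp. lost-background) peaks (default 0.8).
#' @param n_background_peaks Background regions additionally covered by
#'   each peak set (default 10).
#' @return List with `grid` (data frame of the four combinations: query,
#'   target, odds ratio, p), `results` (the `EnrichmentResult` objects),
#'   `calls`, and `sim`.
#' @export
peak_enrichment_experiment <- function(seed = 1L, n_regions = 200L,
                                       depth = 50L,
                                       peak_cover_fraction = 0.8,
                                       n_background_peaks = 10L) {
  cfg <- synth_config(n_regions = n_regions, cpgs_per_region = 8L,
                      read_span = 6L, depth = depth,
                      n_samples = c(normal = 5L, tumor = 5L),
                      planted_fraction = 0.3,
                      planted_elevated_fraction = 0.5,
                      pi_background = 0.5, pi_focal = 0.95,
                      pi_focal_elevated = 0.05,
                      planted_m_range = c(0.25, 0.45),
                      seed = seed)
  rec <- mcdr_recovery(cfg)
  calls <- rec$calls
  mcdrs <- calls[calls$call & calls$direction == "decreased", ]
  elev <- calls[calls$call & calls$direction == "elevated", ]
  if (nrow(mcdrs) == 0L || nrow(elev) == 0L) {
    stop("experiment produced an empty call set; increase depth or size")
  }
  universe <- calls[calls$p_ratio >= 0.05,
                    c("chrom", "start", "end", "id")]
  truth <- rec$sim$truth
  truth_dep <- truth$id[truth$planted & !truth$planted_elevated]
  truth_ele <- truth$id[truth$planted_elevated]
  null_ids <- truth$id[!truth$planted]
  regions <- rec$sim$regions
  pick <- function(ids, frac, extra_pool, n_extra, sub_seed) {
    with_seed(seed + 7919L * sub_seed, {
      covered <- sample(ids, round(frac * length(ids)))
      extra <- sample(extra_pool, n_extra)
      regions[regions$id %in% c(covered, extra),
              c("chrom", "start", "end")]
    })
  }
  gained <- pick(truth_dep, peak_cover_fraction, null_ids,
                 n_background_peaks, 1L)
  lost <- pick(truth_ele, 0, null_ids,
               n_background_peaks + length(truth_ele), 2L)
  combos <- list(
    mcdr_gained = list(q = mcdrs, t = gained),
    mcdr_lost = list(q = mcdrs, t = lost),
    elevated_gained = list(q = elev, t = gained),
    elevated_lost = list(q = elev, t = lost))
  results <- lapply(names(combos), function(nm) {
    fisher_enrichment(combos[[nm]]$q, combos[[nm]]$t, universe,
                      query_name = sub("_.*", "", nm),
                      target_name = sub(".*_", "", nm))
  })
  names(results) <- names(combos)
  grid <- do.call(rbind, lapply(names(results), function(nm)
    data.frame(combo = nm, query = results[[nm]]$query,
               target = results[[nm]]$target,
               odds_ratio = results[[nm]]$odds_ratio,
               p_value = results[[nm]]$p_value)))
  list(grid = grid, results = results, calls = calls, sim = rec$sim)
}

#' Single-cell consistency experiment
#'
#' Generates two-population single cells (normal-like and tumor-like with
#' polarized planted regions), verifies pseudobulk behaviour, and tests
#' per-cell scMCR separation.
#'
#' @param seed Seed.
#' @param n_cells_per_group Cells per group (default 50).
#' @param n_regions Regions (default 60).
#' @return List with `mcdr_regions` (the planted depleted regions used as
#'   the MCDR set), `sc_table` (per-cell scMCR), `p_separation` (one-sided
#'   Wilcoxon p, tumor < normal), `pseudobulk_identity` (logical),
#'   `subsample_correlation` (per-region MCR correlation between a 50%
#'   cell subsample pseudobulk and the full pool), and `sc`.
#' @export
sc_consistency_experiment <- function(seed = 1L, n_cells_per_group = 50L,
                                      n_regions = 60L) {
  cfg <- synth_config(n_regions = n_regions, depth = 50L,
                      n_samples = c(normal = 1L, tumor = 1L),
                      n_cells = c(normal = n_cells_per_group,
                                  tumor = n_cells_per_group),
                      planted_fraction = 0.5, cell_depth = 3,
                      dropout = 0.3, seed = seed)
  sc <- generate_cells(cfg)
  truth <- sc$truth
  mcdr_regions <- sc$regions[truth$planted, , drop = FALSE]

  # pseudobulk of all cells vs the same reads treated as one bulk sample
  pool <- pseudobulk(sc$cells)
  bulk_equiv <- do.call(rbind, sc$cells)
  class(bulk_equiv) <- c("mhap_reads", "data.frame")
  tab_pool <- region_metrics(pool, sc$regions, sc$cpg_index, min_reads = 1L)
  tab_bulk <- region_metrics(bulk_equiv, sc$regions, sc$cpg_index,
                             min_reads = 1L)
  identity_ok <- isTRUE(all.equal(tab_pool$mcr, tab_bulk$mcr,
                                  tolerance = 1e-12))

  # 50% cell subsample: per-region MCR still tracks the full pool
  half <- with_seed(seed + 5L,
                    sample(names(sc$cells), length(sc$cells) %/% 2L))
  tab_half <- region_metrics(pseudobulk(sc$cells, half), sc$regions,
                             sc$cpg_index, min_reads = 1L)
  ok <- !is.na(tab_half$mcr) & !is.na(tab_pool$mcr)
  subsample_cor <- stats::cor(tab_half$mcr[ok], tab_pool$mcr[ok])

  sc_table <- sc_mcr_table(sc$cells, sc$manifest, mcdr_regions,
                           sc$cpg_index)
  x <- sc_table$sc_mcr[sc_table$group == "tumor"]
  y <- sc_table$sc_mcr[sc_table$group == "normal"]
  p_sep <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less")$p.value)
  list(mcdr_regions = mcdr_regions, sc_table = sc_table,
       p_separation = p_sep, pseudobulk_identity = identity_ok,
       subsample_correlation = subsample_cor, sc = sc)
}
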
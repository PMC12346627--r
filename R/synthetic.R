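#' Configure the synthetic read-haplotype generator
#'
#' The generator emulates grouped WGBS samples (and single cells) as
#' collections of read haplotypes per region, with the methylation level
#' and the read-level concurrence controlled independently.  Each read of a
#' region with methylation level `m` and polarization `pi` is drawn from a
#' two-component mixture:
#'
#' * with probability `pi` the read is *polarized*: all-methylated with
#'   probability `m`, all-unmethylated otherwise;
#' * with probability `1 - pi` each CpG is i.i.d. Bernoulli(`m`).
#'
#' Under this mixture the expected methylation ratio is `m` regardless of
#' `pi`, while the expected concurrence (MCR) of a read spanning `s` CpGs
#' is `(1 - pi) * ((1 - m) - (1 - m)^s)` — strictly decreasing in `pi`.
#' Polarization therefore models concurrence depletion at constant level,
#' the contrast the differential caller is designed to detect.
#'
#' Planted regions share `m` across groups but receive `pi_focal` in the
#' focal group and `pi_background` elsewhere; null regions receive
#' `pi_background` everywhere.  By default the methylation level of null
#' regions is drawn from a bimodal mixture (70% Beta(6,2), 30% Beta(2,6)),
#' mimicking the largely bimodal somatic methylome, while planted regions
#' draw `m ~ U(0.3, 0.7)`: intermediate-methylation regions are where
#' read-level concurrence is informative (MCR is capped by `1 - ratio`).
#'
#' @param n_regions Number of regions (default 200).
#' @param cpgs_per_region CpGs per region (default 8).
#' @param read_span CpGs covered by each read (default 4; must not exceed
#'   `cpgs_per_region`).
#' @param depth Reads per region per bulk sample (default 50).
#' @param n_samples Named integer vector: samples per group (default
#'   `c(normal = 5, tumor = 5)`).
#' @param focal_group Group receiving `pi_focal` in planted regions
#'   (default the last group).
#' @param planted_fraction Fraction of regions planted with a concurrence
#'   shift (default 0.25).
#' @param pi_background,pi_focal Polarization of unplanted/planted-focal
#'   reads (defaults 0.1 and 0.9).
#' @param planted_elevated_fraction Fraction of *planted* regions whose
#'   focal-group polarization is `pi_focal_elevated` instead of `pi_focal`,
#'   planting concurrence-elevated (rather than depleted) regions
#'   (default 0).
#' @param pi_focal_elevated Polarization of elevated planted regions in the
#'   focal group (default 0).
#' @param planted_m_range Range of the uniform methylation-level draw for
#'   planted regions (default `c(0.3, 0.7)`).
#' @param m Optional numeric vector of per-region methylation levels
#'   (length `n_regions`); drawn as described above when `NULL`.
#' @param pi_by_group Optional named numeric vector giving every group a
#'   fixed polarization applied to *all* regions (overrides planting; used
#'   e.g. for the cross-group CV benchmark).
#' @param n_cells Named integer vector: cells per group for
#'   [generate_cells()] (default `c(normal = 50, tumor = 50)`).
#' @param cell_depth Mean extra reads per covered region per cell; per-cell
#'   per-region read counts are `1 + Poisson(cell_depth - 1)` (default 2).
#' @param dropout Per-cell per-region probability of no coverage
#'   (default 0.3).
#' @param n_patients Patients per group for the cell manifest (default 3).
#' @param error_rate Symmetric per-CpG state-flip probability emulating
#'   bisulfite conversion error (default 0).
#' @param cpg_spacing,region_gap_bp Genomic layout of the synthetic
#'   chromosome (defaults 20 bp between CpGs, 200 bp between regions).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated `SyntheticConfig` list.
#' @export
synth_config <- function(n_regions = 200L, cpgs_per_region = 8L,
                         read_span = 4L, depth = 50L,
                         n_samples = c(normal = 5L, tumor = 5L),
                         focal_group = NULL, planted_fraction = 0.25,
                         pi_background = 0.1, pi_focal = 0.9,
                         planted_elevated_fraction = 0,
                         pi_focal_elevated = 0,
                         planted_m_range = c(0.3, 0.7),
                         m = NULL, pi_by_group = NULL,
                         n_cells = c(normal = 50L, tumor = 50L),
                         cell_depth = 2, dropout = 0.3, n_patients = 3L,
                         error_rate = 0, cpg_spacing = 20L,
                         region_gap_bp = 200L, seed = 1L) {
  if (read_span > cpgs_per_region) {
    stop("read_span (", read_span, ") exceeds cpgs_per_region (",
         cpgs_per_region, ")")
  }
  stopifnot(n_regions >= 1L, depth >= 1L, read_span >= 1L)
  probs <- c(planted_fraction, pi_background, pi_focal, dropout, error_rate,
             planted_elevated_fraction, pi_focal_elevated)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (is.null(names(n_samples))) {
    names(n_samples) <- paste0("group", seq_along(n_samples))
  }
  if (is.null(focal_group)) focal_group <- names(n_samples)[length(n_samples)]
  if (!focal_group %in% names(n_samples)) {
    stop("focal_group not among group names")
  }
  if (!is.null(m) && length(m) != n_regions) {
    stop("m must have length n_regions")
  }
  if (!is.null(pi_by_group)) {
    if (is.null(names(pi_by_group)) ||
        !setequal(names(pi_by_group), names(n_samples))) {
      stop("pi_by_group must be named by the groups in n_samples")
    }
    if (any(pi_by_group < 0 | pi_by_group > 1)) {
      stop("probabilities must lie in [0, 1]")
    }
  }
  structure(list(n_regions = as.integer(n_regions),
                 cpgs_per_region = as.integer(cpgs_per_region),
                 read_span = as.integer(read_span),
                 depth = as.integer(depth),
                 n_samples = n_samples, focal_group = focal_group,
                 planted_fraction = planted_fraction,
                 pi_background = pi_background, pi_focal = pi_focal,
                 planted_elevated_fraction = planted_elevated_fraction,
                 pi_focal_elevated = pi_focal_elevated,
                 planted_m_range = planted_m_range,
                 m = m, pi_by_group = pi_by_group,
                 n_cells = n_cells, cell_depth = cell_depth,
                 dropout = dropout, n_patients = as.integer(n_patients),
                 error_rate = error_rate,
                 cpg_spacing = as.integer(cpg_spacing),
                 region_gap_bp = as.integer(region_gap_bp),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Evaluate code with a private RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Genomic layout, planted flags, per-region m and per-group pi; drawn once
# per config under the config seed so that bulk and cell runs of the same
# config describe the same regions.
synth_truth <- function(config) {
  g <- names(config$n_samples)
  with_seed(config$seed, {
    nr <- config$n_regions
    planted <- rep(FALSE, nr)
    elevated <- rep(FALSE, nr)
    if (is.null(config$pi_by_group) && config$planted_fraction > 0) {
      planted[sample.int(nr, round(config$planted_fraction * nr))] <- TRUE
      if (config$planted_elevated_fraction > 0) {
        pl <- which(planted)
        elev <- sample(pl, round(config$planted_elevated_fraction *
                                   length(pl)))
        elevated[elev] <- TRUE
      }
    }
    m <- config$m
    if (is.null(m)) {
      hi <- stats::runif(nr) < 0.7
      m <- ifelse(hi, stats::rbeta(nr, 6, 2), stats::rbeta(nr, 2, 6))
      m[planted] <- stats::runif(sum(planted), config$planted_m_range[1],
                                 config$planted_m_range[2])
    }
    pi_mat <- matrix(config$pi_background, nrow = nr, ncol = length(g),
                     dimnames = list(NULL, g))
    if (!is.null(config$pi_by_group)) {
      for (gg in g) pi_mat[, gg] <- config$pi_by_group[[gg]]
    } else {
      pi_mat[planted & !elevated, config$focal_group] <- config$pi_focal
      pi_mat[elevated, config$focal_group] <- config$pi_focal_elevated
    }
    s <- config$read_span
    expected_mcr <- sapply(g, function(gg)
      (1 - pi_mat[, gg]) * ((1 - m) - (1 - m)^s))
    truth <- data.frame(id = sprintf("region_%04d", seq_len(nr)),
                        planted = planted, planted_elevated = elevated,
                        m = m)
    for (gg in g) truth[[paste0("pi_", gg)]] <- pi_mat[, gg]
    truth$expected_ratio <- m
    for (gg in g) truth[[paste0("expected_mcr_", gg)]] <- expected_mcr[, gg]
    truth
  })
}

synth_layout <- function(config) {
  nr <- config$n_regions; C <- config$cpgs_per_region
  sp <- config$cpg_spacing; gap <- config$region_gap_bp
  region_starts <- 1L + (seq_len(nr) - 1L) * ((C - 1L) * sp + gap)
  pos <- as.integer(outer(seq_len(C) - 1L, region_starts,
                          function(i, s) s + i * sp))
  index <- cpg_index_from_positions(list(chrS1 = sort(pos)))
  regions <- data.frame(chrom = "chrS1",
                        start = region_starts,
                        end = region_starts + (C - 1L) * sp,
                        id = sprintf("region_%04d", seq_len(nr)))
  list(index = index, regions = regions)
}

# Draw `n` read patterns of span `s` from the polarization mixture.
draw_patterns <- function(n, s, m, pi, error_rate = 0) {
  polar <- stats::runif(n) < pi
  states <- matrix(0L, nrow = n, ncol = s)
  if (any(polar)) {
    # one Bernoulli(m) draw per read, constant across its CpGs
    v <- stats::rbinom(sum(polar), 1L, m)
    states[polar, ] <- matrix(rep(v, s), ncol = s)
  }
  if (any(!polar)) {
    states[!polar, ] <- matrix(stats::rbinom(sum(!polar) * s, 1L, m),
                               ncol = s)
  }
  if (error_rate > 0) {
    flip <- matrix(stats::runif(n * s) < error_rate, ncol = s)
    states <- abs(states - flip)
  }
  apply(states, 1L, paste, collapse = "")
}

# Reads of one sample drawn over all regions of a config.
draw_sample_reads <- function(config, truth, group) {
  nr <- config$n_regions; C <- config$cpgs_per_region
  s <- config$read_span; depth <- config$depth
  pi_col <- truth[[paste0("pi_", group)]]
  offsets <- pattern <- vector("list", nr)
  for (r in seq_len(nr)) {
    off0 <- sample.int(C - s + 1L, depth, replace = TRUE) - 1L
    offsets[[r]] <- (r - 1L) * C + off0
    pattern[[r]] <- draw_patterns(depth, s, truth$m[r], pi_col[r],
                                  config$error_rate)
  }
  aggregate_reads(read_haplotypes("chrS1", unlist(offsets),
                                  unlist(pattern), 1L, "+"))
}

#' Generate grouped bulk WGBS samples
#'
#' Draws every sample of every group from the configured polarization
#' mixture (see [synth_config()]) and returns the reads together with the
#' region set, the CpG index, a sample manifest and the ground-truth table.
#' Deterministic for a fixed config (seed included).
#'
#' @param config A `SyntheticConfig`.
#' @param dir Optional directory; when given, MHAP files (one per sample),
#'   `regions.bed`, `manifest.tsv` and `truth.tsv` are written there.
#' @return List with `reads` (named list of `mhap_reads`, one per sample),
#'   `manifest` (`sample`, `group`), `regions`, `truth`, `cpg_index` and
#'   `config`.
#' @export
generate_bulk <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  truth <- synth_truth(config)
  layout <- synth_layout(config)
  manifest <- do.call(rbind, lapply(names(config$n_samples), function(g)
    data.frame(sample = sprintf("%s_s%02d", g, seq_len(config$n_samples[[g]])),
               group = g)))
  reads <- with_seed(config$seed + 1L, {
    out <- lapply(seq_len(nrow(manifest)), function(i)
      draw_sample_reads(config, truth, manifest$group[i]))
    names(out) <- manifest$sample
    out
  })
  res <- list(reads = reads, manifest = manifest, regions = layout$regions,
              truth = truth, cpg_index = layout$index, config = config)
  if (!is.null(dir)) write_synth(res, dir)
  res
}

#' Generate synthetic single cells
#'
#' Cells are drawn from their group's mixture with sparse coverage: each
#' region is missed with probability `dropout`, and covered regions carry
#' `1 + Poisson(cell_depth - 1)` reads.  The union of a group's cells is
#' therefore distributionally identical to one bulk sample of the summed
#' depth.
#'
#' @inheritParams generate_bulk
#' @return List with `cells` (named list of `mhap_reads`), `manifest`
#'   (`cell`, `group`, `patient`), `regions`, `truth`, `cpg_index`,
#'   `config`.
#' @export
generate_cells <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  truth <- synth_truth(config)
  layout <- synth_layout(config)
  nr <- config$n_regions; C <- config$cpgs_per_region
  s <- config$read_span
  manifest <- do.call(rbind, lapply(names(config$n_cells), function(g) {
    n <- config$n_cells[[g]]
    if (n < 1L) return(NULL)
    data.frame(cell = sprintf("%s_c%03d", g, seq_len(n)), group = g,
               patient = sprintf("%s_p%d", g,
                                 1L + (seq_len(n) - 1L) %% config$n_patients))
  }))
  if (is.null(manifest)) stop("no cells configured")
  cells <- with_seed(config$seed + 2L, {
    out <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      g <- manifest$group[i]
      pi_col <- truth[[paste0("pi_", g)]]
      covered <- which(stats::runif(nr) >= config$dropout)
      offsets <- pattern <- list()
      for (r in covered) {
        nread <- 1L + stats::rpois(1L, max(config$cell_depth - 1, 0))
        off0 <- sample.int(C - s + 1L, nread, replace = TRUE) - 1L
        offsets[[length(offsets) + 1L]] <- (r - 1L) * C + off0
        pattern[[length(pattern) + 1L]] <-
          draw_patterns(nread, s, truth$m[r], pi_col[r], config$error_rate)
      }
      out[[i]] <- if (length(offsets)) {
        aggregate_reads(read_haplotypes("chrS1", unlist(offsets),
                                        unlist(pattern), 1L, "+"))
      } else {
        read_haplotypes(character(0), integer(0), character(0))
      }
    }
    names(out) <- manifest$cell
    out
  })
  res <- list(cells = cells, manifest = manifest, regions = layout$regions,
              truth = truth, cpg_index = layout$index, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cid in names(cells)) {
      write_mhap(cells[[cid]], file.path(dir, paste0(cid, ".mhap")),
                 layout$index)
    }
    write_regions_bed(layout$regions, file.path(dir, "regions.bed"))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

write_synth <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(res$reads)) {
    write_mhap(res$reads[[s]], file.path(dir, paste0(s, ".mhap")),
               res$cpg_index)
  }
  write_regions_bed(res$regions, file.path(dir, "regions.bed"))
  utils::write.table(res$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
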
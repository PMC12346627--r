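#' Parse a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored.  Numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
parse_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- lapply(kv, function(p) {
    v <- trimws(p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, trimws(vapply(kv, `[`, character(1), 1L)))
}

pipeline_defaults <- function() {
  list(min_cpg = 4, min_reads = 10, p_thresh = 0.05, ratio_delta_max = 0.2,
       metric_delta_min = 0.2, pdr_min_cpgs = 4, entropy_word = 4,
       metric = "mcr", n_regions = 200, cpgs_per_region = 8, read_span = 4,
       depth = 50, n_samples_per_group = 5, planted_fraction = 0.25,
       seed = 1)
}

validate_pipeline_config <- function(config) {
  cfg <- utils::modifyList(pipeline_defaults(), as.list(config))
  validate_thresholds(cfg$p_thresh, cfg$ratio_delta_max,
                      cfg$metric_delta_min)
  if (cfg$min_reads < 1 || cfg$min_cpg < 1 || cfg$depth < 1) {
    stop("min_reads, min_cpg and depth must be >= 1")
  }
  if (cfg$pdr_min_cpgs < 1 || cfg$entropy_word < 2) {
    stop("pdr_min_cpgs must be >= 1 and entropy_word >= 2")
  }
  cfg
}

provenance_header <- function(config, inputs = character(0)) {
  cfg_norm <- config[order(names(config))]
  cfg_str <- paste(names(cfg_norm), vapply(cfg_norm, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- c(paste0("# methconcur ",
                as.character(utils::packageVersion("methconcur"))),
         paste0("# config_hash=", substr(digest_string(cfg_str), 1, 12)))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    h <- c(h, paste0("# input=", basename(inputs), " md5=", sums))
  }
  h
}

# md5 of a string via tools::md5sum on a temp file (base R has no direct
# string digest).
digest_string <- function(s) {
  f <- tempfile()
  writeLines(s, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Run the simulate -> metrics -> differential pipeline
#'
#' Generates a grouped bulk dataset from the configuration, computes the
#' per-sample metric tables, assembles the metric matrix, and calls
#' differential regions (default metric MCR, so calls with direction
#' `"decreased"` in the focal group are MCDRs).  All outputs are written
#' under `out_dir` with provenance headers (tool version, config hash,
#' input checksums); outputs are byte-identical across runs with the same
#' configuration.
#'
#' @param config Named list or path to a key=value config file.  Recognized
#'   keys (defaults in parentheses): `min_cpg` (4), `min_reads` (10),
#'   `p_thresh` (0.05), `ratio_delta_max` (0.2), `metric_delta_min` (0.2),
#'   `pdr_min_cpgs` (4), `entropy_word` (4), `metric` ("mcr"),
#'   `n_regions` (200), `cpgs_per_region` (8), `read_span` (4),
#'   `depth` (50), `n_samples_per_group` (5), `planted_fraction` (0.25),
#'   `seed` (1).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `calls` (the differential table), `mcdrs`
#'   (called regions, focal-decreased), `metric_matrix`, `sim` and the
#'   paths written.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- parse_pipeline_config(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))

  scfg <- synth_config(n_regions = cfg$n_regions,
                       cpgs_per_region = cfg$cpgs_per_region,
                       read_span = cfg$read_span, depth = cfg$depth,
                       n_samples = c(normal = cfg$n_samples_per_group,
                                     tumor = cfg$n_samples_per_group),
                       planted_fraction = cfg$planted_fraction,
                       seed = cfg$seed)
  sim_dir <- file.path(out_dir, "sim")
  sim <- generate_bulk(scfg, dir = sim_dir)

  mhap_paths <- file.path(sim_dir, paste0(sim$manifest$sample, ".mhap"))
  header <- provenance_header(cfg, mhap_paths)
  tables <- lapply(sim$reads, function(r)
    region_metrics(r, sim$regions, sim$cpg_index,
                   min_reads = cfg$min_reads,
                   pdr_min_cpgs = cfg$pdr_min_cpgs,
                   entropy_word = cfg$entropy_word))
  met_dir <- file.path(out_dir, "metrics")
  dir.create(met_dir, showWarnings = FALSE)
  for (s in names(tables)) {
    write_metrics_tsv(tables[[s]], file.path(met_dir, paste0(s, ".tsv")),
                      header_lines = header)
  }
  mm <- build_metric_matrix(tables, sim$manifest)
  calls <- call_differential(mm, cfg$metric, "tumor", "normal",
                             p_thresh = cfg$p_thresh,
                             ratio_delta_max = cfg$ratio_delta_max,
                             metric_delta_min = cfg$metric_delta_min)
  calls_path <- file.path(out_dir, "calls.tsv")
  con <- file(calls_path, "wt")
  writeLines(header, con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  mcdrs <- calls[calls$call & calls$direction == "decreased", , drop = FALSE]
  mcdr_path <- file.path(out_dir, "mcdrs.bed")
  write_regions_bed(mcdrs[, c("chrom", "start", "end", "id")], mcdr_path)
  ok <- TRUE
  invisible(list(calls = calls, mcdrs = mcdrs, metric_matrix = mm,
                 sim = sim,
                 paths = c(calls = calls_path, mcdrs = mcdr_path)))
}
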
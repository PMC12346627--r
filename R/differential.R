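#' Assemble per-sample metric tables into aligned metric matrices
#'
#' Aligns the [region_metrics()] tables of several samples on a common
#' region set and stacks each metric into a regions-by-samples matrix.
#' Regions absent (or low-coverage) in a sample carry `NA` in that column —
#' they are kept, not dropped.
#'
#' @param tables Named list of [region_metrics()] data frames; names are
#'   sample ids (when unnamed, the manifest's `sample` order is used).
#' @param manifest Data frame with columns `sample` and `group` covering
#'   exactly the supplied samples.
#' @return A `MetricMatrix`: list with `regions` (data frame), `samples`,
#'   `groups` (named character vector sample -> group) and `metrics`, a list
#'   of numeric matrices (`ratio`, `mcr`, `mhl`, `mbs`, `pdr`, `entropy`).
#' @export
build_metric_matrix <- function(tables, manifest) {
  if (length(tables) == 0L) stop("no samples: empty table list")
  if (is.null(names(tables))) names(tables) <- manifest$sample[seq_along(tables)]
  samples <- names(tables)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(manifest$sample)) stop("duplicate sample ids in manifest")
  unknown <- setdiff(manifest$sample, samples)
  if (length(unknown)) {
    stop("manifest sample(s) without a metric table: ",
         paste(unknown, collapse = ", "))
  }
  missing_grp <- setdiff(samples, manifest$sample)
  if (length(missing_grp)) {
    stop("sample(s) missing from manifest: ",
         paste(missing_grp, collapse = ", "))
  }
  # union of regions keyed by id; coordinates must agree across samples
  all_regions <- unique(do.call(rbind, lapply(tables, function(t)
    t[, c("id", "chrom", "start", "end")])))
  if (anyDuplicated(all_regions$id)) {
    stop("region coordinate clash: id(s) ",
         paste(unique(all_regions$id[duplicated(all_regions$id)]),
               collapse = ", "), " map to different coordinates")
  }
  all_regions <- all_regions[order(all_regions$chrom, all_regions$start), ,
                             drop = FALSE]
  rownames(all_regions) <- NULL
  metric_names <- c("ratio", "mcr", "mhl", "mbs", "pdr", "entropy")
  metrics <- lapply(metric_names, function(mn) {
    m <- matrix(NA_real_, nrow = nrow(all_regions), ncol = length(samples),
                dimnames = list(all_regions$id, samples))
    for (s in samples) {
      t <- tables[[s]]
      m[match(t$id, all_regions$id), s] <- t[[mn]]
    }
    m
  })
  names(metrics) <- metric_names
  groups <- stats::setNames(as.character(manifest$group),
                            as.character(manifest$sample))[samples]
  structure(list(regions = all_regions, samples = samples,
                 groups = groups, metrics = metrics),
            class = "MetricMatrix")
}

#' @export
print.MetricMatrix <- function(x, ...) {
  cat("MetricMatrix:", nrow(x$regions), "regions x", length(x$samples),
      "samples;", length(unique(x$groups)), "group(s)\n")
  invisible(x)
}

# Two-sided Wilcoxon rank-sum p-value: exact for small untied groups,
# normal approximation with continuity and tie correction otherwise.
# Fully tied data carries no evidence of a shift -> p = 1.
wilcox_p <- function(x, y) {
  exact <- length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) 1 else p
}

# Smallest attainable two-sided exact Wilcoxon p for group sizes na, nb.
wilcox_min_p <- function(na, nb) 2 / choose(na + nb, na)

#' Call regions where a pattern metric differs while the ratio does not
#'
#' Per region, two-sided Wilcoxon rank-sum tests compare the two groups on
#' the methylation ratio and on the chosen pattern metric.  A region is
#' called when the ratio shows no significant difference
#' (`p_ratio >= p_thresh` and `|delta_ratio| < ratio_delta_max`) while the
#' metric does (`p_metric < p_thresh` and `|delta_metric| >
#' metric_delta_min`).  Calls on the MCR metric with direction `"decreased"`
#' in the focal group are methylation-concurrence-depleted regions (MCDRs).
#'
#' Deltas are absolute differences of group means (computed over non-missing
#' samples).  Regions lacking `min_per_group` non-missing values for either
#' quantity in either group are skipped as untestable.  When the group sizes
#' make the smallest attainable exact Wilcoxon p exceed `p_thresh` (e.g.
#' 3 vs 3, where min p = 0.1), no call is possible and a warning says so.
#'
#' @param mm A `MetricMatrix`.
#' @param metric One of `"mcr"`, `"mhl"`, `"mbs"`, `"pdr"`, `"entropy"`.
#' @param group_a,group_b Group labels; direction is reported for `group_a`
#'   relative to `group_b`.
#' @param p_thresh Significance threshold for both tests (default 0.05).
#' @param ratio_delta_max Maximum allowed absolute ratio difference
#'   (default 0.2).
#' @param metric_delta_min Minimum required absolute metric difference
#'   (default 0.2).
#' @param min_per_group Minimum non-missing samples per group per region
#'   (default 3).
#' @return Data frame with one row per testable region: region columns,
#'   `n_a`, `n_b`, `mean_ratio_a`, `mean_ratio_b`, `mean_metric_a`,
#'   `mean_metric_b`, `p_ratio`, `p_metric`, `delta_ratio`, `delta_metric`,
#'   `direction` (`"elevated"`/`"decreased"` in `group_a` relative to
#'   `group_b`) and `call`.  The metric name is carried in the `metric`
#'   column.
#' @export
call_differential <- function(mm, metric, group_a, group_b,
                              p_thresh = 0.05, ratio_delta_max = 0.2,
                              metric_delta_min = 0.2, min_per_group = 3L) {
  stopifnot(inherits(mm, "MetricMatrix"))
  metric <- match.arg(metric, c("mcr", "mhl", "mbs", "pdr", "entropy"))
  validate_thresholds(p_thresh, ratio_delta_max, metric_delta_min)
  sa <- names(mm$groups)[mm$groups == group_a]
  sb <- names(mm$groups)[mm$groups == group_b]
  if (!length(sa)) stop("group not found: ", group_a)
  if (!length(sb)) stop("group not found: ", group_b)
  if (length(sa) < min_per_group || length(sb) < min_per_group) {
    stop("insufficient replication: groups have ", length(sa), " and ",
         length(sb), " samples, need >= ", min_per_group, " each")
  }
  if (wilcox_min_p(length(sa), length(sb)) > p_thresh) {
    warning("group sizes ", length(sa), " vs ", length(sb),
            ": smallest attainable exact Wilcoxon p = ",
            signif(wilcox_min_p(length(sa), length(sb)), 3), " exceeds ",
            p_thresh, "; no region can be called at this threshold")
  }
  ratio_m <- mm$metrics$ratio
  met_m <- mm$metrics[[metric]]
  rows <- vector("list", nrow(mm$regions))
  for (i in seq_len(nrow(mm$regions))) {
    ra <- ratio_m[i, sa]; rb <- ratio_m[i, sb]
    ma <- met_m[i, sa]; mb <- met_m[i, sb]
    ra <- ra[!is.na(ra)]; rb <- rb[!is.na(rb)]
    ma <- ma[!is.na(ma)]; mb <- mb[!is.na(mb)]
    if (min(length(ra), length(rb), length(ma), length(mb)) < min_per_group) {
      next
    }
    p_ratio <- wilcox_p(ra, rb)
    p_metric <- wilcox_p(ma, mb)
    d_ratio <- abs(mean(ra) - mean(rb))
    d_metric <- abs(mean(ma) - mean(mb))
    rows[[i]] <- cbind(
      mm$regions[i, , drop = FALSE],
      data.frame(metric = metric,
                 n_a = length(ma), n_b = length(mb),
                 mean_ratio_a = mean(ra), mean_ratio_b = mean(rb),
                 mean_metric_a = mean(ma), mean_metric_b = mean(mb),
                 p_ratio = p_ratio, p_metric = p_metric,
                 delta_ratio = d_ratio, delta_metric = d_metric,
                 direction = if (mean(ma) >= mean(mb)) "elevated"
                             else "decreased",
                 call = p_ratio >= p_thresh & p_metric < p_thresh &
                   d_ratio < ratio_delta_max & d_metric > metric_delta_min))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("insufficient replication: no region has >= ", min_per_group,
         " non-missing values in both groups")
  }
  rownames(out) <- NULL
  out
}

validate_thresholds <- function(p_thresh, ratio_delta_max, metric_delta_min) {
  if (!is.numeric(p_thresh) || p_thresh <= 0 || p_thresh > 1) {
    stop("p_thresh must lie in (0, 1]")
  }
  if (ratio_delta_max < 0 || ratio_delta_max > 1) {
    stop("ratio_delta_max must lie in [0, 1]")
  }
  if (metric_delta_min < 0 || metric_delta_min > 1) {
    stop("metric_delta_min must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Tissue-specific (one-vs-rest) differential calls
#'
#' Compares the target group against all other groups pooled, with
#' [call_differential()] semantics; requires at least two non-target groups
#' so that "rest" represents more than one tissue.
#'
#' @inheritParams call_differential
#' @param target_group The focal group label.
#' @return As [call_differential()], with an added `target` column;
#'   direction is relative to the pooled rest.
#' @export
call_tissue_specific <- function(mm, metric, target_group,
                                 p_thresh = 0.05, ratio_delta_max = 0.2,
                                 metric_delta_min = 0.2, min_per_group = 3L) {
  stopifnot(inherits(mm, "MetricMatrix"))
  if (!target_group %in% mm$groups) stop("group not found: ", target_group)
  others <- unique(mm$groups[mm$groups != target_group])
  if (length(others) < 2L) {
    stop("one-vs-rest comparison needs >= 2 non-target groups")
  }
  pooled <- mm
  pooled$groups <- ifelse(mm$groups == target_group, target_group, ".rest")
  names(pooled$groups) <- names(mm$groups)
  out <- call_differential(pooled, metric, target_group, ".rest",
                           p_thresh = p_thresh,
                           ratio_delta_max = ratio_delta_max,
                           metric_delta_min = metric_delta_min,
                           min_per_group = min_per_group)
  out$target <- target_group
  out
}

#' Cross-group coefficient-of-variation benchmark
#'
#' For each metric and region, computes per-group means over non-missing
#' samples and summarizes their dispersion as CV = sd/mean (sd with
#' denominator n-1).  Regions where any group mean is missing, or where the
#' mean of group means is 0, are excluded for that metric.  The per-metric
#' median CV ranks how strongly each read-level metric separates the groups.
#'
#' @param mm A `MetricMatrix` with at least 3 groups.
#' @param metrics Metric names to compare (default: the five pattern
#'   metrics).
#' @return List with `per_region` (long data frame: `id`, `metric`, `cv`)
#'   and `summary` (per metric: `median_cv`, `q1`, `q3`, `n_regions`).
#' @export
cv_benchmark <- function(mm, metrics = c("mcr", "mhl", "mbs", "pdr",
                                         "entropy")) {
  stopifnot(inherits(mm, "MetricMatrix"))
  grps <- unique(mm$groups)
  if (length(grps) < 3L) stop("CV benchmark needs >= 3 groups")
  per_region <- list()
  for (mn in metrics) {
    m <- mm$metrics[[mn]]
    gm <- vapply(grps, function(g) {
      cols <- names(mm$groups)[mm$groups == g]
      rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(m)))
    if (!is.matrix(gm)) gm <- matrix(gm, nrow = 1L)
    gm[is.nan(gm)] <- NA_real_
    ok <- rowSums(is.na(gm)) == 0L & rowMeans(gm) != 0
    if (!any(ok)) next
    cv <- apply(gm[ok, , drop = FALSE], 1L,
                function(v) stats::sd(v) / mean(v))
    per_region[[mn]] <- data.frame(id = mm$regions$id[ok], metric = mn,
                                   cv = as.numeric(cv))
  }
  per_region <- do.call(rbind, per_region)
  rownames(per_region) <- NULL
  summary <- do.call(rbind, lapply(split(per_region, per_region$metric),
    function(d) data.frame(metric = d$metric[1],
                           median_cv = stats::median(d$cv),
                           q1 = unname(stats::quantile(d$cv, 0.25)),
                           q3 = unname(stats::quantile(d$cv, 0.75)),
                           n_regions = nrow(d))))
  summary <- summary[order(-summary$median_cv), ]
  rownames(summary) <- NULL
  list(per_region = per_region, summary = summary)
}
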
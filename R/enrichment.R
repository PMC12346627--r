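#' Promoter windows around transcription start sites
#'
#' @param tss Data frame with `chrom`, `pos` (1-based TSS position) and
#'   `strand` (`"+"`/`"-"`; `"."` treated as `"+"`).
#' @param upstream,downstream Window extent in bp (defaults 2000 and 500).
#' @return Region data frame (`chrom`, `start`, `end`, 1-based inclusive).
#' @export
promoters_from_tss <- function(tss, upstream = 2000L, downstream = 500L) {
  minus <- tss$strand == "-"
  start <- ifelse(minus, tss$pos - downstream, tss$pos - upstream)
  end <- ifelse(minus, tss$pos + upstream, tss$pos + downstream)
  data.frame(chrom = tss$chrom, start = pmax(1L, as.integer(start)),
             end = as.integer(end))
}

#' Assign called regions to genomic feature categories
#'
#' Each region is assigned exactly one category by the position of its
#' midpoint, resolving multiple hits by the priority order of the
#' annotation list (typically promoter > exon > intron).  Midpoints hitting
#' no feature are `"intergenic"`; regions on chromosomes absent from every
#' annotation track are `"unannotated"`.
#'
#' @param regions Region data frame (`chrom`, `start`, `end`, optional
#'   `id`).
#' @param annotation Named list of region data frames (or `GRanges`), in
#'   priority order.
#' @return List with `assignments` (data frame `id`, `category`) and
#'   `distribution` (data frame `category`, `n`, `fraction`, covering all
#'   annotation categories plus `"intergenic"` and `"unannotated"`).
#' @export
annotate_regions <- function(regions, annotation) {
  if (is.null(regions$id)) {
    regions$id <- paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  ann_gr <- lapply(annotation, function(a) {
    if (methods::is(a, "GRanges")) a else regions_to_granges(a)
  })
  mid <- floor((regions$start + regions$end) / 2)
  mid_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(mid, mid))
  ann_chroms <- unique(unlist(lapply(ann_gr, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  category <- ifelse(regions$chrom %in% ann_chroms, "intergenic",
                     "unannotated")
  # assign lowest-priority first; later (higher-priority) tracks overwrite
  for (nm in rev(names(ann_gr))) {
    hit <- IRanges::overlapsAny(mid_gr, ann_gr[[nm]])
    category[hit & category != "unannotated"] <- nm
  }
  levels <- c(names(annotation), "intergenic", "unannotated")
  tab <- table(factor(category, levels = levels))
  list(assignments = data.frame(id = regions$id, category = category),
       distribution = data.frame(category = levels,
                                 n = as.integer(tab),
                                 fraction = as.numeric(tab) / nrow(regions)))
}

#' One-sided Fisher overlap enrichment of a region set
#'
#' Locus-overlap enrichment in the style of LOLA: counts how many query
#' regions and how many background regions (universe minus query) overlap
#' the target set by at least `min_overlap_bp`, and tests enrichment with a
#' one-sided Fisher's exact test (upper hypergeometric tail).  The universe
#' should be the set of all testable regions — for concurrence analysis,
#' all regions without a significant methylation-ratio difference, so that
#' enrichment is assessed against a ratio-stable background.
#'
#' @param query,universe Region data frames; query regions must be members
#'   of the universe (matched on coordinates; non-members are dropped with
#'   a warning).
#' @param target Region data frame (or `GRanges`) of the feature set, e.g.
#'   gained or lost accessibility peaks.
#' @param min_overlap_bp Minimum intersection width to count an overlap
#'   (default 1).
#' @param query_name,target_name Labels carried into the result.
#' @return An `EnrichmentResult` list: `a`, `b`, `c`, `d` (query-hit,
#'   query-miss, background-hit, background-miss), `odds_ratio` (with
#'   Haldane 0.5 correction when any cell is 0), `p_value`, `query`,
#'   `target`.
#' @export
fisher_enrichment <- function(query, target, universe, min_overlap_bp = 1L,
                              query_name = "query", target_name = "target") {
  if (is.null(universe) || nrow(universe) == 0L) stop("empty universe")
  if (is.null(query) || nrow(query) == 0L) stop("empty query")
  ukey <- paste(universe$chrom, universe$start, universe$end)
  universe <- universe[!duplicated(ukey), , drop = FALSE]
  ukey <- unique(ukey)
  qkey <- unique(paste(query$chrom, query$start, query$end))
  outside <- !(qkey %in% ukey)
  if (any(outside)) {
    warning("dropping ", sum(outside),
            " query region(s) not present in the universe")
    qkey <- qkey[!outside]
  }
  if (!length(qkey)) stop("empty query after restriction to the universe")
  tgt_gr <- if (methods::is(target, "GRanges")) target
            else regions_to_granges(target)
  uni_gr <- regions_to_granges(universe)
  hit <- GenomicRanges::countOverlaps(uni_gr, tgt_gr,
                                      minoverlap = min_overlap_bp) > 0L
  is_q <- ukey %in% qkey
  a <- sum(is_q & hit); b <- sum(is_q & !hit)
  c <- sum(!is_q & hit); d <- sum(!is_q & !hit)
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  or <- if (any(c(a, b, c, d) == 0L)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  structure(list(query = query_name, target = target_name,
                 a = a, b = b, c = c, d = d,
                 odds_ratio = or, p_value = p),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult:", x$query, "x", x$target, "\n",
      " table a,b,c,d =", x$a, x$b, x$c, x$d, "\n",
      " odds ratio =", signif(x$odds_ratio, 4),
      " one-sided p =", signif(x$p_value, 4), "\n")
  invisible(x)
}
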
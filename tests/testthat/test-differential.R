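# Small helper: fabricate per-sample metric tables directly (regions x
# metrics), bypassing read-level computation, to exercise matrix assembly
# and calling logic in isolation.
fake_table <- function(ids, ratio, mcr_v = ratio) {
  data.frame(id = ids, chrom = "chr1",
             start = seq_along(ids) * 100L,
             end = seq_along(ids) * 100L + 50L,
             n_reads = 50, n_cpg_obs = 200,
             ratio = ratio, mcr = mcr_v, mhl = ratio, mbs = ratio,
             pdr = mcr_v, entropy = mcr_v, low_coverage = FALSE)
}

test_that("metric matrices align regions and carry missing cells", {
  t1 <- fake_table(c("a", "b", "c"), c(0.1, 0.5, 0.9))
  t2 <- fake_table(c("a", "b"), c(0.2, 0.6))
  mm <- build_metric_matrix(list(s1 = t1, s2 = t2),
                            data.frame(sample = c("s1", "s2"),
                                       group = c("g1", "g2")))
  expect_equal(dim(mm$metrics$ratio), c(3L, 2L))
  expect_true(is.na(mm$metrics$ratio["c", "s2"]))
  expect_equal(mm$metrics$ratio["b", "s1"], 0.5)
})

test_that("matrix assembly rejects inconsistent input", {
  t1 <- fake_table("a", 0.5)
  expect_error(build_metric_matrix(list(), data.frame()), "no samples")
  expect_error(
    build_metric_matrix(list(s1 = t1, s1 = t1),
                        data.frame(sample = "s1", group = "g")),
    "duplicate")
  expect_error(
    build_metric_matrix(list(s1 = t1),
                        data.frame(sample = c("s1", "ghost"),
                                   group = c("g", "g"))),
    "ghost")
  t2 <- fake_table("a", 0.5); t2$start <- 999L
  expect_error(
    build_metric_matrix(list(s1 = t1, s2 = t2),
                        data.frame(sample = c("s1", "s2"),
                                   group = c("g1", "g2"))),
    "clash")
})

make_mm <- function(ratio_a, ratio_b, mcr_a, mcr_b, ids = "r1") {
  na <- length(ratio_a[[1]]); nb <- length(ratio_b[[1]])
  tabs <- c(
    lapply(seq_len(na), function(i)
      fake_table(ids, vapply(ratio_a, `[`, numeric(1), i),
                 vapply(mcr_a, `[`, numeric(1), i))),
    lapply(seq_len(nb), function(i)
      fake_table(ids, vapply(ratio_b, `[`, numeric(1), i),
                 vapply(mcr_b, `[`, numeric(1), i))))
  names(tabs) <- c(paste0("a", seq_len(na)), paste0("b", seq_len(nb)))
  build_metric_matrix(tabs, data.frame(sample = names(tabs),
                                       group = rep(c("A", "B"),
                                                   c(na, nb))))
}

test_that("an MCR drop at stable ratio is called, with exact Wilcoxon", {
  # group A: ratio ~0.50, MCR ~0.30; group B: ratio ~0.52, MCR ~0.05
  # (values chosen tie-free so the exact enumeration oracle applies)
  ra <- c(0.48, 0.50, 0.51, 0.49, 0.52)
  rb <- c(0.505, 0.53, 0.525, 0.54, 0.515)
  ma <- c(0.28, 0.31, 0.30, 0.29, 0.32)
  mb <- c(0.04, 0.06, 0.05, 0.03, 0.07)
  mm <- make_mm(list(ra), list(rb), list(ma), list(mb))
  calls <- call_differential(mm, "mcr", "A", "B")
  expect_equal(nrow(calls), 1L)
  expect_true(calls$call)
  expect_equal(calls$direction, "elevated") # A relative to B
  # p-values match full-enumeration exact Wilcoxon
  expect_equal(calls$p_ratio, oracle_wilcox_p(ra, rb), tolerance = 1e-12)
  expect_equal(calls$p_metric, oracle_wilcox_p(ma, mb), tolerance = 1e-12)
  expect_equal(calls$delta_metric, abs(mean(ma) - mean(mb)))
  # seen from B, the same region is an MCDR (decreased)
  calls_b <- call_differential(mm, "mcr", "B", "A")
  expect_true(calls_b$call)
  expect_equal(calls_b$direction, "decreased")
})

test_that("effect-size and ratio-exclusion gates veto calls", {
  ra <- c(0.48, 0.50, 0.51, 0.49, 0.52)
  rb <- c(0.505, 0.53, 0.525, 0.54, 0.515)
  # significant but small metric shift: delta 0.15 < 0.2
  ma <- c(0.28, 0.31, 0.30, 0.29, 0.32)
  mb <- ma - 0.15
  mm <- make_mm(list(ra), list(rb), list(ma), list(mb))
  calls <- call_differential(mm, "mcr", "A", "B")
  expect_lt(calls$p_metric, 0.05)
  expect_false(calls$call)
  # significant ratio difference excludes the region regardless of metric
  rb2 <- rb + 0.05 # separated -> exact p < 0.05
  mm2 <- make_mm(list(ra), list(rb2), list(ma), list(mb - 0.3))
  calls2 <- call_differential(mm2, "mcr", "A", "B")
  expect_lt(calls2$p_ratio, 0.05)
  expect_false(calls2$call)
})

test_that("swapping groups flips direction but preserves calls and p", {
  set.seed(5)
  ids <- paste0("r", 1:12)
  ratio_a <- lapply(1:12, function(i) runif(4, 0.4, 0.6))
  ratio_b <- lapply(1:12, function(i) runif(4, 0.4, 0.6))
  mcr_a <- lapply(1:12, function(i) runif(4, 0, 0.5))
  mcr_b <- lapply(1:12, function(i) runif(4, 0, 0.5))
  to_tabs <- function(rl, ml, prefix, group) {
    n <- length(rl[[1]])
    tabs <- lapply(seq_len(n), function(i)
      fake_table(ids, vapply(rl, `[`, numeric(1), i),
                 vapply(ml, `[`, numeric(1), i)))
    names(tabs) <- paste0(prefix, seq_len(n))
    tabs
  }
  tabs <- c(to_tabs(ratio_a, mcr_a, "a"), to_tabs(ratio_b, mcr_b, "b"))
  mm <- build_metric_matrix(tabs, data.frame(
    sample = names(tabs), group = rep(c("A", "B"), each = 4)))
  ab <- call_differential(mm, "mcr", "A", "B", min_per_group = 3L)
  ba <- call_differential(mm, "mcr", "B", "A", min_per_group = 3L)
  expect_equal(ab$p_metric, ba$p_metric)
  expect_equal(ab$p_ratio, ba$p_ratio)
  expect_equal(ab$call, ba$call)
  flip <- c(elevated = "decreased", decreased = "elevated")
  expect_equal(unname(flip[ab$direction]), ba$direction)
})

test_that("3 vs 3 hits the exact-Wilcoxon floor and warns", {
  ra <- list(c(0.1, 0.2, 0.3)); rb <- list(c(0.11, 0.21, 0.31))
  ma <- list(c(0.5, 0.6, 0.7)); mb <- list(c(0.0, 0.05, 0.1))
  mm <- make_mm(ra, rb, ma, mb)
  expect_warning(calls <- call_differential(mm, "mcr", "A", "B"),
                 "0.1")
  expect_false(any(calls$call))
  # the floor itself: most extreme 3v3 split has exact two-sided p = 0.1
  expect_equal(oracle_wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
})

test_that("insufficient replication errors", {
  ra <- list(c(0.1, 0.2)); rb <- list(c(0.15, 0.25))
  mm <- make_mm(ra, rb, ra, rb)
  expect_error(call_differential(mm, "mcr", "A", "B"),
               "insufficient replication")
  expect_error(call_differential(mm, "mcr", "A", "nope"), "not found")
})

test_that("tissue-specific one-vs-rest recovers a planted group shift", {
  set.seed(6)
  groups <- paste0("t", 1:4)
  ids <- paste0("r", 1:8)
  # region r1 has low MCR in t2 only; ratios identical everywhere
  tabs <- list(); man <- NULL
  for (g in groups) {
    for (i in 1:3) {
      mcr_v <- runif(8, 0.38, 0.42)
      if (g == "t2") mcr_v[1] <- runif(1, 0.02, 0.05)
      s <- paste0(g, "_", i)
      tabs[[s]] <- fake_table(ids, ratio = runif(8, 0.49, 0.51), mcr_v)
      man <- rbind(man, data.frame(sample = s, group = g))
    }
  }
  mm <- build_metric_matrix(tabs, man)
  calls <- call_tissue_specific(mm, "mcr", "t2")
  hit <- calls[calls$call, ]
  expect_equal(hit$id, "r1")
  expect_equal(hit$direction, "decreased")
  expect_equal(unique(calls$target), "t2")
  # an identical metric profile yields no calls
  flat <- lapply(tabs, function(t) { t$mcr <- 0.4; t$ratio <- 0.5; t })
  mm_flat <- build_metric_matrix(flat, man)
  expect_equal(sum(call_tissue_specific(mm_flat, "mcr", "t2")$call), 0L)
  expect_error(call_tissue_specific(mm, "mcr", "t9"), "not found")
})

test_that("CV summarizes dispersion of group means", {
  # three groups, one sample each; CV on region r1 = sd/mean of (.1,.2,.3)
  tabs <- list(s1 = fake_table("r1", 0.5, 0.1),
               s2 = fake_table("r1", 0.5, 0.2),
               s3 = fake_table("r1", 0.5, 0.3))
  man <- data.frame(sample = c("s1", "s2", "s3"),
                    group = c("g1", "g2", "g3"))
  cvb <- cv_benchmark(build_metric_matrix(tabs, man), metrics = "mcr")
  expect_equal(cvb$per_region$cv, sd(c(0.1, 0.2, 0.3)) / 0.2)
  # constant group means give CV 0; zero-mean regions are excluded
  tabs0 <- list(s1 = fake_table(c("r1", "r2"), 0.5, c(0.2, 0)),
                s2 = fake_table(c("r1", "r2"), 0.5, c(0.2, 0)),
                s3 = fake_table(c("r1", "r2"), 0.5, c(0.2, 0)))
  cvb0 <- cv_benchmark(build_metric_matrix(tabs0, man), metrics = "mcr")
  expect_equal(cvb0$per_region$id, "r1")
  expect_equal(cvb0$per_region$cv, 0)
  expect_error(cv_benchmark(build_metric_matrix(
    tabs[1:2], man[1:2, ])), ">= 3 groups")
})
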
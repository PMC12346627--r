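toy <- as_reads(c("111", "000", "101"))

test_that("worked toy read set matches hand-enumerated values", {
  # oracle first: the frozen expectations below were produced by the
  # brute-force enumeration implementations in helper-oracles.R
  expect_equal(oracle_ratio(c("111", "000", "101")), 5 / 9)
  expect_equal(oracle_mcr(c("111", "000", "101")), 1 / 9)
  expect_equal(oracle_mhl(c("111", "000", "101")), 0.37037037, tolerance = 1e-8)
  expect_equal(oracle_mbs(c("111", "000", "101")), 0.40740741, tolerance = 1e-8)
  expect_equal(oracle_pdr(c("111", "000", "101"), min_cpgs = 3), 1 / 3)

  expect_equal(methylation_ratio(toy), 5 / 9)
  expect_equal(mcr(toy), 1 / 9)
  expect_equal(mhl(toy), 0.37037037, tolerance = 1e-8)
  expect_equal(mbs(toy), 0.40740741, tolerance = 1e-8)
  expect_equal(pdr(toy, min_cpgs_per_read = 3), 1 / 3)
  expect_true(is.na(pdr(toy, min_cpgs_per_read = 4)))
})

test_that("entropy pools count-weighted word frequencies", {
  e <- as_reads(c("1111", "0000", "1010"), c(2L, 1L, 1L))
  expect_equal(oracle_entropy(c("1111", "0000", "1010"), c(2L, 1L, 1L)),
               0.375)
  expect_equal(meth_entropy(e), 0.375)
  expect_equal(meth_entropy(as_reads(rep("1011", 5))), 0)
  expect_true(is.na(meth_entropy(as_reads(c("111", "000")))))
  # sliding windows: "11110" contributes words 1111 and 1110
  expect_equal(meth_entropy(as_reads("11110")),
               oracle_entropy("11110"))
})

test_that("fully methylated / unmethylated limits", {
  all1 <- as_reads(rep("1111", 3))
  all0 <- as_reads(rep("0000", 3))
  expect_equal(methylation_ratio(all1), 1)
  expect_equal(mcr(all1), 0)
  expect_equal(mhl(all1), 1)
  expect_equal(mbs(all1), 1)
  expect_equal(pdr(all1), 0)
  expect_equal(meth_entropy(all1), 0)
  expect_equal(methylation_ratio(all0), 0)
  expect_equal(mcr(all0), 0)
  expect_equal(mhl(all0), 0)
  expect_equal(mbs(all0), 0)
  expect_equal(pdr(all0), 0)
  expect_equal(meth_entropy(all0), 0)
  # single-run MBS: "1100" -> 2^2 / 4^2
  expect_equal(mbs(as_reads("1100")), 0.25)
  # MCR multiplicity scale invariance: {10} x k -> 1/2
  for (k in c(1L, 4L, 9L)) {
    expect_equal(mcr(as_reads("10", k)), 0.5)
  }
})

test_that("all metrics equal brute-force enumeration on random read sets", {
  set.seed(101)
  for (i in 1:300) {
    rp <- random_patterns()
    r <- as_reads(rp$patterns, rp$counts)
    expect_equal(methylation_ratio(r),
                 oracle_ratio(rp$patterns, rp$counts), tolerance = 1e-12)
    expect_equal(mcr(r), oracle_mcr(rp$patterns, rp$counts),
                 tolerance = 1e-12)
    expect_equal(mhl(r), oracle_mhl(rp$patterns, rp$counts),
                 tolerance = 1e-12)
    expect_equal(mbs(r), oracle_mbs(rp$patterns, rp$counts),
                 tolerance = 1e-12)
    expect_equal(pdr(r), oracle_pdr(rp$patterns, rp$counts),
                 tolerance = 1e-12)
    expect_equal(meth_entropy(r),
                 oracle_entropy(rp$patterns, rp$counts), tolerance = 1e-12)
  }
})

test_that("a read with count k equals k duplicate count-1 reads", {
  set.seed(202)
  for (i in 1:25) {
    rp <- random_patterns()
    weighted <- as_reads(rp$patterns, rp$counts)
    expanded <- as_reads(rep(rp$patterns, rp$counts))
    for (f in list(methylation_ratio, mcr, mhl, mbs, pdr, meth_entropy)) {
      expect_equal(f(weighted), f(expanded), tolerance = 1e-12)
    }
  }
})

test_that("MCR never exceeds the unmethylated fraction", {
  set.seed(303)
  for (i in 1:200) {
    rp <- random_patterns()
    r <- as_reads(rp$patterns, rp$counts)
    expect_lte(mcr(r), 1 - methylation_ratio(r) + 1e-12)
  }
})

test_that("MHL with L = 1 reduces to the methylation ratio and caps apply", {
  set.seed(404)
  for (i in 1:20) {
    rp <- random_patterns()
    r <- as_reads(rp$patterns, rp$counts)
    expect_equal(mhl(r, max_len = 1L),
                 methylation_ratio(r), tolerance = 1e-12)
    expect_equal(mhl(r, max_len = 2L),
                 oracle_mhl(rp$patterns, rp$counts, max_len = 2L),
                 tolerance = 1e-12)
  }
})

test_that("region coverage filter and per-metric minima", {
  nine <- as_reads(rep("11", 9))
  res <- compute_metrics(nine, min_reads = 10L)
  expect_true(res$low_coverage)
  expect_true(all(is.na(res[, c("ratio", "mcr", "mhl", "mbs", "pdr",
                                "entropy")])))
  ten <- as_reads(rep("11", 10))
  res <- compute_metrics(ten, min_reads = 10L)
  expect_false(res$low_coverage)
  expect_equal(res$ratio, 1)
  expect_equal(res$mcr, 0)
  expect_equal(res$mhl, 1)
  expect_equal(res$mbs, 1)
  expect_true(is.na(res$pdr))     # no read spans 4 CpGs
  expect_true(is.na(res$entropy)) # no 4-CpG word
  expect_equal(res$n_reads, 10)
  expect_equal(res$n_cpg_obs, 20)
})

test_that("compute_metrics agrees with the individual operations", {
  r <- as_reads(c("111", "000", "101"), c(4L, 4L, 4L))
  res <- compute_metrics(r, min_reads = 10L, pdr_min_cpgs = 3L)
  expect_equal(res$ratio, 5 / 9)
  expect_equal(res$mcr, 1 / 9)
  expect_equal(res$mhl, mhl(r))
  expect_equal(res$mbs, mbs(r))
  expect_equal(res$pdr, 1 / 3)
})

test_that("empty read sets give missing values, never zero", {
  empty <- as_reads(character(0))
  expect_true(is.na(methylation_ratio(empty)))
  expect_true(is.na(mcr(empty)))
  expect_true(is.na(mhl(empty)))
  expect_true(is.na(mbs(empty)))
  expect_true(is.na(pdr(empty)))
  expect_true(is.na(meth_entropy(empty)))
})

test_that("region_metrics clips reads per region and keys by id", {
  idx <- toy_index(8L)
  pos <- cpg_positions(idx, "chr1")
  regions <- data.frame(chrom = "chr1", start = pos[c(1, 5)],
                        end = pos[c(4, 8)], id = c("r1", "r2"))
  reads <- as_reads(rep(c("1111", "0000"), each = 6),
                    start_index = rep(c(0L, 4L), each = 6))
  tab <- region_metrics(reads, regions, idx, min_reads = 5L)
  expect_equal(tab$id, c("r1", "r2"))
  expect_equal(tab$ratio, c(1, 0))
  expect_equal(tab$n_reads, c(6, 6))
})
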
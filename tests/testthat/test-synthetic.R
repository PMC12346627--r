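test_that("config validation rejects impossible settings", {
  expect_error(synth_config(read_span = 10L, cpgs_per_region = 8L),
               "exceeds")
  expect_error(synth_config(pi_background = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(pi_by_group = c(a = 0.5)), "named by the groups")
  expect_error(synth_config(m = c(0.5, 0.5), n_regions = 3L), "length")
})

test_that("fully polarized regions produce zero concurrence exactly", {
  cfg <- synth_config(n_regions = 10L, depth = 40L,
                      n_samples = c(g = 1L), planted_fraction = 0,
                      pi_background = 1, seed = 3L)
  sim <- generate_bulk(cfg)
  tab <- region_metrics(sim$reads[[1]], sim$regions, sim$cpg_index)
  expect_true(all(tab$mcr == 0))
  expect_true(all(tab$pdr == 0))
})

test_that("span-2 Bernoulli mixture matches the closed-form concurrence", {
  # pi = 0, m = 0.5, span 2: E[MCR] = P(10 or 01) * 1/2 = 0.25
  cfg <- synth_config(n_regions = 4L, cpgs_per_region = 2L, read_span = 2L,
                      depth = 10000L, n_samples = c(g = 1L),
                      planted_fraction = 0, pi_background = 0,
                      m = rep(0.5, 4L), seed = 8L)
  sim <- generate_bulk(cfg)
  tab <- region_metrics(sim$reads[[1]], sim$regions, sim$cpg_index)
  se <- sqrt(0.25 * 0.75 / 10000) # generous per-observation bound
  expect_true(all(abs(tab$mcr - 0.25) < 3 * sqrt(0.5) / sqrt(10000) * 3))
  expect_true(all(abs(tab$ratio - 0.5) < 0.02))
})

test_that("ratio is invariant to polarization; concurrence decreases in it", {
  pis <- c(0, 0.25, 0.5, 0.75, 1)
  mcr_by_pi <- numeric(length(pis))
  for (k in seq_along(pis)) {
    cfg <- synth_config(n_regions = 2L, cpgs_per_region = 8L,
                        read_span = 4L, depth = 10000L,
                        n_samples = c(g = 1L), planted_fraction = 0,
                        pi_background = pis[k], m = rep(0.5, 2L),
                        seed = 40L + k)
    sim <- generate_bulk(cfg)
    tab <- region_metrics(sim$reads[[1]], sim$regions, sim$cpg_index)
    expect_true(all(abs(tab$ratio - 0.5) < 0.02))
    mcr_by_pi[k] <- mean(tab$mcr)
  }
  expect_true(all(diff(mcr_by_pi) < 0))
  expect_equal(mcr_by_pi[5], 0)
})

test_that("planted regions shift concurrence but not the expected ratio", {
  cfg <- synth_config(n_regions = 40L, depth = 200L,
                      n_samples = c(normal = 1L, tumor = 1L),
                      planted_fraction = 0.5, seed = 5L)
  sim <- generate_bulk(cfg)
  truth <- sim$truth
  expect_true(any(truth$planted) && any(!truth$planted))
  expect_equal(truth$pi_normal[truth$planted],
               rep(cfg$pi_background, sum(truth$planted)))
  expect_equal(truth$pi_tumor[truth$planted],
               rep(cfg$pi_focal, sum(truth$planted)))
  expect_equal(truth$expected_ratio, truth$m)
  # analytic expected MCR: (1 - pi) * ((1 - m) - (1 - m)^span)
  s <- cfg$read_span
  expect_equal(truth$expected_mcr_tumor,
               (1 - truth$pi_tumor) * ((1 - truth$m) - (1 - truth$m)^s))
  tabs <- lapply(sim$reads, region_metrics, regions = sim$regions,
                 cpg_index = sim$cpg_index)
  planted <- truth$planted
  d_mcr <- tabs$normal_s01$mcr - tabs$tumor_s01$mcr
  d_ratio <- abs(tabs$normal_s01$ratio - tabs$tumor_s01$ratio)
  expect_gt(mean(d_mcr[planted]), 0.15)
  expect_lt(mean(d_ratio[planted]), 0.1)
})

test_that("identical config and seed give byte-identical MHAP output", {
  cfg <- synth_config(n_regions = 8L, depth = 20L,
                      n_samples = c(a = 2L, b = 2L), seed = 77L)
  d1 <- tempfile(); d2 <- tempfile()
  generate_bulk(cfg, dir = d1)
  generate_bulk(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_bulk(synth_config(
    n_regions = 2L, depth = 5L, n_samples = c(a = 1L), seed = 9L)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("single cells are sparse and unite into their group's bulk", {
  cfg <- synth_config(n_regions = 30L, depth = 50L,
                      n_samples = c(normal = 1L, tumor = 1L),
                      n_cells = c(normal = 20L, tumor = 20L),
                      dropout = 0.4, cell_depth = 2, seed = 12L)
  sc <- generate_cells(cfg)
  expect_equal(nrow(sc$manifest), 40L)
  expect_setequal(unique(sc$manifest$group), c("normal", "tumor"))
  # dropout: most cells miss some regions
  covered <- vapply(sc$cells, function(r)
    length(unique(r$start_index %/% cfg$cpgs_per_region)), numeric(1))
  expect_true(mean(covered) < cfg$n_regions)
  # pooled cells behave like bulk of the same group: concurrence of
  # planted regions collapses in tumor but not normal
  pool_n <- pseudobulk(sc$cells, sc$manifest$cell[sc$manifest$group == "normal"])
  pool_t <- pseudobulk(sc$cells, sc$manifest$cell[sc$manifest$group == "tumor"])
  tab_n <- region_metrics(pool_n, sc$regions, sc$cpg_index, min_reads = 5L)
  tab_t <- region_metrics(pool_t, sc$regions, sc$cpg_index, min_reads = 5L)
  planted <- sc$truth$planted
  expect_gt(mean(tab_n$mcr[planted], na.rm = TRUE),
            mean(tab_t$mcr[planted], na.rm = TRUE))
})

test_that("dropout of 1 removes all coverage", {
  cfg <- synth_config(n_regions = 5L, n_samples = c(a = 1L),
                      n_cells = c(a = 3L), dropout = 1, seed = 2L)
  sc <- generate_cells(cfg)
  expect_true(all(vapply(sc$cells, nrow, numeric(1)) == 0L))
})

test_that("bisulfite error flips states symmetrically", {
  cfg <- synth_config(n_regions = 4L, depth = 3000L,
                      n_samples = c(a = 1L), planted_fraction = 0,
                      pi_background = 1, m = rep(1, 4L),
                      error_rate = 0.1, seed = 31L)
  sim <- generate_bulk(cfg)
  tab <- region_metrics(sim$reads[[1]], sim$regions, sim$cpg_index)
  expect_true(all(abs(tab$ratio - 0.9) < 0.02))
})
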
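gm_small <- make_genome(1, 1e6, seed = 11)

test_that("read starts are assigned to half-open 50 kb bins", {
  reads <- data.frame(chrom = "chr1", pos = c(0, 49999, 50000))
  p <- bin_counts(reads, gm_small)
  expect_equal(p$count[1:3], c(2L, 1L, 0L))

  empty <- bin_counts(data.frame(chrom = character(0), pos = numeric(0)),
                      gm_small)
  expect_true(all(empty$count == 0))

  expect_error(bin_counts(data.frame(chrom = "chrX", pos = 1), gm_small),
               class = "unknown_chromosome_error")
  expect_error(bin_counts(data.frame(chrom = "chr1", pos = 1e6), gm_small),
               class = "position_out_of_bounds_error")
})

test_that("total-count normalization and its guards", {
  gm <- make_genome(1, 1e6, seed = 1, par_fraction = 0)
  bins <- gm$bins
  bins$count <- 100L
  p <- normalize_total(new_cn_profile(bins))
  expect_true(all(abs(p$ratio - 1 / 20) < 1e-12))

  bins$count <- c(2000L, rep(0L, 19))
  p2 <- normalize_total(new_cn_profile(bins))
  expect_equal(p2$ratio, c(1, rep(0, 19)))

  bins$count <- 0L
  expect_error(normalize_total(new_cn_profile(bins)),
               class = "zero_reads_error")
})

test_that("log2 ratios are invariant to library-size scaling", {
  gm <- make_genome(2, 1e7, seed = 3)
  cfg <- sim_config(tumor_fraction = 0.3, total_reads = 2e6, seed = 5)
  raw <- simulate_counts(gm, sim_event("chr1", 2e6, 5e6, 4), cfg)
  panel <- simulate_control_panel(gm, 3, sim_config(seed = 6))
  res1 <- profile_sample(raw, panel)

  scaled_bins <- as.data.frame(raw)
  scaled_bins$count <- scaled_bins$count * 7L
  scaled <- new_cn_profile(scaled_bins[, c("chrom", "start", "end", "gc",
                                           "mappable", "count")])
  res2 <- profile_sample(scaled, panel)
  expect_equal(res1$profile$log2, res2$profile$log2, tolerance = 1e-9)
})

test_that("GC correction decorrelates injected bias and guards its fit", {
  gm <- make_genome(2, 2e7, seed = 8)
  cfg <- sim_config(total_reads = 6e6,
                    gc_bias = c(peak = 0.45, strength = 0), seed = 2)
  raw <- simulate_counts(gm, NULL, cfg)

  # without injected bias the correction is close to the identity
  p0 <- normalize_total(raw)
  p1 <- gc_correct(p0)
  rel <- abs(p1$ratio[p1$mappable] - p0$ratio[p0$mappable]) /
    p0$ratio[p0$mappable]
  expect_lt(quantile(rel, 0.95), 0.02)

  # inject a linear bias ratio ~ (1 + 0.5 gc) and check decorrelation
  biased <- as.data.frame(raw)
  biased$count <- round(biased$count * (1 + 0.5 * biased$gc))
  pb <- gc_correct(normalize_total(new_cn_profile(
    biased[, c("chrom", "start", "end", "gc", "mappable", "count")])))
  keep <- pb$mappable
  rho <- suppressWarnings(cor.test(pb$ratio[keep], pb$gc[keep],
                                   method = "spearman",
                                   exact = FALSE))$estimate
  expect_lt(abs(rho), 0.05)

  # degenerate GC landscape: identity transform
  flat <- as.data.frame(raw)
  flat$gc <- 0.4
  pf0 <- normalize_total(new_cn_profile(
    flat[, c("chrom", "start", "end", "gc", "mappable", "count")]))
  pf1 <- gc_correct(pf0)
  expect_equal(pf1$ratio, pf0$ratio)

  expect_error(gc_correct(normalize_total(
    simulate_counts(make_genome(1, 1e6, seed = 1), NULL,
                    sim_config(total_reads = 1e5, seed = 1)))),
    class = "too_few_bins_error")
})

test_that("control normalization: self-panel, dropout bins, guards", {
  gm <- make_genome(2, 1e7, seed = 4)
  cfg <- sim_config(total_reads = 2e6, seed = 3)
  raw <- simulate_counts(gm, NULL, cfg)
  p <- gc_correct(normalize_total(raw))

  self <- control_normalize(p, list(p))
  expect_true(all(abs(self$log2[self$usable]) < 1e-12))

  # a bin with zero baseline across the panel is flagged unusable
  pz <- p
  pz$ratio[5] <- 0
  out <- control_normalize(p, list(pz))
  expect_false(out$usable[5])
  expect_true(is.na(out$log2[5]))

  expect_error(control_normalize(p, list()), class = "empty_panel_error")
  expect_error(control_normalize(self, list(p)),
               class = "already_normalized_error")
  expect_error(control_normalize(raw, list(p)),
               class = "missing_stage_error")
})

test_that("rebinning conserves counts and aggregates GC by length", {
  gm <- make_genome(1, 1e6, seed = 9, par_fraction = 0)
  bins <- gm$bins
  bins$count <- 100L
  p <- new_cn_profile(bins)
  coarse <- rebin(p, 1e6)
  expect_equal(nrow(coarse), 1L)
  expect_equal(coarse$count, 2000)
  expect_equal(coarse$gc, weighted.mean(bins$gc, bins$end - bins$start))

  gm2 <- make_genome(2, 2.05e6, seed = 10)
  cfg <- sim_config(total_reads = 1e5, seed = 4)
  raw <- simulate_counts(gm2, NULL, cfg)
  c2 <- rebin(raw, 1e6)
  expect_equal(sum(c2$count), sum(raw$count))
  expect_error(rebin(raw, 4e4), class = "invalid_width_error")
  expect_error(rebin(raw, 1.2e5), class = "invalid_width_error")
})

test_that("count TSV round-trips through the BED-like writer", {
  gm <- make_genome(1, 1e6, seed = 2)
  raw <- simulate_counts(gm, NULL, sim_config(total_reads = 1e5, seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(raw, path)
  back <- read_counts_tsv(path, gm)
  expect_equal(back$count, raw$count)
})
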
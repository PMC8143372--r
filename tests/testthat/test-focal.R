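seg_row <- function(chrom, start, end, mean_log2) {
  data.frame(chrom = chrom, start = start, end = end,
             n_bins = as.integer((end - start) / 5e4),
             mean_log2 = mean_log2, length_bp = end - start,
             stringsAsFactors = FALSE)
}

# hand-built annotation with one driver, one plain gene, one deletion
# target, and clean repeat tracks on chr9
toy_annotation <- function() {
  genes <- data.frame(
    chrom = c("chr1", "chr1", "chr9"),
    start = c(10.5e6, 30.2e6, 21.2e6),
    end = c(10.7e6, 30.4e6, 21.4e6),
    name = c("EGFR", "g1_001", "CDKN2A"),
    is_driver = c(TRUE, FALSE, FALSE),
    is_deletion_target = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  segdups <- data.frame(chrom = "chr2", start = 1e6, end = 2e6)
  dgv <- data.frame(chrom = "chr2", start = 5e6, end = 6e6)
  annotation_bundle(genes, segdups, dgv)
}

test_that("neighbor context is a length-weighted mean of the 20 Mb flanks", {
  segs <- rbind(seg_row("chr1", 0, 3e7, 0.1),
                seg_row("chr1", 3e7, 3.2e7, 0.8),
                seg_row("chr1", 3.2e7, 6.2e7, 0.3))
  ctx <- neighbor_weighted_mean(segs, 2)
  expect_equal(ctx$left_mean, 0.1)
  expect_equal(ctx$right_mean, 0.3)
  expect_equal(ctx$left_span, 2e7)
  expect_equal(ctx$right_span, 2e7)
  expect_equal(ctx$combined_weighted_mean, 0.2) # equal-weight average
  expect_false(ctx$empty)

  flat <- rbind(seg_row("chr1", 0, 3e7, 0), seg_row("chr1", 3e7, 3.2e7, 0.9),
                seg_row("chr1", 3.2e7, 6e7, 0))
  expect_equal(neighbor_weighted_mean(flat, 2)$combined_weighted_mean, 0)

  # terminal segment: only the right flank contributes
  edge <- rbind(seg_row("chr1", 0, 1e6, 0.9), seg_row("chr1", 1e6, 3e7, 0.2))
  ctx_e <- neighbor_weighted_mean(edge, 1)
  expect_true(is.na(ctx_e$left_mean))
  expect_equal(ctx_e$combined_weighted_mean, 0.2)

  # no neighbors at all: flagged empty, falls back to diploid baseline
  lone <- seg_row("chr1", 0, 1e6, 0.9)
  ctx_l <- neighbor_weighted_mean(lone, 1)
  expect_true(ctx_l$empty)
  expect_equal(ctx_l$combined_weighted_mean, 0)
})

test_that("overlap_fraction computes interval-union coverage", {
  seg <- seg_row("chr1", 1e6, 2e6, 0.5)
  none <- data.frame(chrom = "chr1", start = 5e6, end = 6e6)
  expect_equal(overlap_fraction(seg, none), 0)
  full <- data.frame(chrom = "chr1", start = 0, end = 3e6)
  expect_equal(overlap_fraction(seg, full), 1)
  two <- data.frame(chrom = "chr1", start = c(1e6, 1.5e6),
                    end = c(1.3e6, 1.75e6))
  expect_equal(overlap_fraction(seg, two), 0.55)
  # overlapping track entries are unioned, not double counted
  dup <- data.frame(chrom = "chr1", start = c(1e6, 1.1e6),
                    end = c(1.4e6, 1.5e6))
  expect_equal(overlap_fraction(seg, dup), 0.5)
})

test_that("amplification criteria: driver threshold, size and gene gates", {
  ann <- toy_annotation()
  base <- rbind(seg_row("chr1", 0, 1e7, 0), seg_row("chr1", 1e7, 1.2e7, 0.30),
                seg_row("chr1", 1.2e7, 6e7, 0))
  called <- call_focal_amplifications(base, ann)
  expect_equal(nrow(called), 1L)
  expect_equal(called$genes, "EGFR")
  expect_true(called$contains_driver)
  expect_equal(called$neighbor_delta, 0.30, tolerance = 1e-9)

  # same amplitude without a driver gene fails the 0.58 delta rule
  no_driver <- rbind(seg_row("chr1", 0, 3e7, 0),
                     seg_row("chr1", 3e7, 3.1e7, 0.30),
                     seg_row("chr1", 3.1e7, 6e7, 0))
  expect_equal(nrow(call_focal_amplifications(no_driver, ann)), 0L)
  # ... but passes once the amplitude clears 0.58
  no_driver$mean_log2[2] <- 0.60
  high <- call_focal_amplifications(no_driver, ann)
  expect_equal(nrow(high), 1L)
  expect_false(high$contains_driver)

  # >= 20 Mb segments are never focal, regardless of amplitude
  big <- rbind(seg_row("chr1", 0, 2.5e7, 0.9), seg_row("chr1", 2.5e7, 6e7, 0))
  expect_equal(nrow(call_focal_amplifications(big, ann)), 0L)

  # flat profile: nothing called
  flat <- rbind(seg_row("chr1", 0, 6e7, 0))
  expect_equal(nrow(call_focal_amplifications(flat, ann)), 0L)

  expect_error(call_focal_amplifications(base, list(genes = ann$genes)),
               class = "missing_annotation_error")
})

test_that("deletion criteria require a deletion-target gene", {
  ann <- toy_annotation()
  del <- rbind(seg_row("chr9", 0, 2.1e7, 0),
               seg_row("chr9", 2.1e7, 2.2e7, -0.35),
               seg_row("chr9", 2.2e7, 6e7, 0))
  called <- call_focal_deletions(del, ann)
  expect_equal(nrow(called), 1L)
  expect_equal(called$genes, "CDKN2A")
  expect_equal(called$direction, "deletion")

  # same segment over a non-target gene is rejected
  non_target <- rbind(seg_row("chr1", 0, 3e7, 0),
                      seg_row("chr1", 3e7, 3.05e7, -0.35),
                      seg_row("chr1", 3.05e7, 6e7, 0))
  expect_equal(nrow(call_focal_deletions(non_target, ann)), 0L)

  # shallow dips above -0.2 are rejected
  del$mean_log2[2] <- -0.1
  expect_equal(nrow(call_focal_deletions(del, ann)), 0L)
})

test_that("repeat-track vetoes: segdup majority and DGV reciprocal overlap", {
  genes <- data.frame(chrom = "chr2", start = 10.4e6, end = 10.6e6,
                      name = "EGFR", is_driver = TRUE,
                      is_deletion_target = FALSE)
  segs <- rbind(seg_row("chr2", 0, 1e7, 0), seg_row("chr2", 1e7, 1.1e7, 0.5),
                seg_row("chr2", 1.1e7, 6e7, 0))

  # segdups covering 60% of the segment veto it; 40% does not
  ann_60 <- annotation_bundle(genes,
                              data.frame(chrom = "chr2", start = 1e7,
                                         end = 1.06e7),
                              data.frame(chrom = "chr2", start = 5e7,
                                         end = 5.1e7))
  expect_equal(nrow(call_focal_amplifications(segs, ann_60)), 0L)
  ann_40 <- annotation_bundle(genes,
                              data.frame(chrom = "chr2", start = 1e7,
                                         end = 1.04e7),
                              data.frame(chrom = "chr2", start = 5e7,
                                         end = 5.1e7))
  expect_equal(nrow(call_focal_amplifications(segs, ann_40)), 1L)

  # DGV: reciprocal 50% match vetoes; a tiny nested entry does not
  ann_dgv <- annotation_bundle(genes,
                               data.frame(chrom = "chr2", start = 5e7,
                                          end = 5.1e7),
                               data.frame(chrom = "chr2", start = 1e7,
                                          end = 1.1e7))
  expect_equal(nrow(call_focal_amplifications(segs, ann_dgv)), 0L)
  ann_small <- annotation_bundle(genes,
                                 data.frame(chrom = "chr2", start = 5e7,
                                            end = 5.1e7),
                                 data.frame(chrom = "chr2", start = 1.02e7,
                                            end = 1.03e7))
  expect_equal(nrow(call_focal_amplifications(segs, ann_small)), 1L)
  # under "any" matching even the nested entry vetoes
  expect_equal(nrow(call_focal_amplifications(segs, ann_small,
                                              dgv_mode = "any")), 0L)
})

test_that("raising a called amplification never un-calls it", {
  for (seed in 1:10) {
    case <- random_focal_case(seed, max_segments = 30)
    called <- call_focal_amplifications(case$segments, case$annotation)
    if (nrow(called) == 0) next
    for (i in seq_len(nrow(called))) {
      segs2 <- case$segments
      row <- which(segs2$chrom == called$chrom[i] &
                     segs2$start == called$start[i])
      segs2$mean_log2[row] <- segs2$mean_log2[row] + runif(1, 0.1, 1)
      again <- call_focal_amplifications(segs2, case$annotation)
      expect_true(any(again$chrom == called$chrom[i] &
                        again$start == called$start[i]))
    }
  }
})

test_that("caller agrees with the literal brute-force checker", {
  for (seed in 101:140) {
    case <- random_focal_case(seed)
    amps <- call_focal_amplifications(case$segments, case$annotation)
    dels <- call_focal_deletions(case$segments, case$annotation)
    for (i in seq_len(nrow(case$segments))) {
      key_called_amp <- any(amps$chrom == case$segments$chrom[i] &
                              amps$start == case$segments$start[i])
      key_called_del <- any(dels$chrom == case$segments$chrom[i] &
                              dels$start == case$segments$start[i])
      expect_identical(
        key_called_amp,
        literal_focal_call(case$segments, case$annotation, i,
                           "amplification"),
        info = sprintf("amplification, seed %d, segment %d", seed, i)
      )
      expect_identical(
        key_called_del,
        literal_focal_call(case$segments, case$annotation, i, "deletion"),
        info = sprintf("deletion, seed %d, segment %d", seed, i)
      )
    }
  }
})

test_that("identical inputs give identical event lists", {
  case <- random_focal_case(7)
  a <- call_focal_amplifications(case$segments, case$annotation)
  b <- call_focal_amplifications(case$segments, case$annotation)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
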
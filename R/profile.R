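#' Construct a copy-number profile
#'
#' A `cn_profile` is a data frame of ordered genomic bins (0-based half-open)
#' carrying raw counts and, as the pipeline stages run, total-count
#' normalized ratios, GC-corrected ratios and control-normalized log2
#' ratios. Sample-level metadata travel as attributes.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end`, `gc`,
#'   `mappable`, `count`.
#' @param sample_id Sample identifier.
#' @param timepoint Optional `"pre"`/`"post"` label.
#' @return An object of class `cn_profile` (a data frame).
#' @export
new_cn_profile <- function(bins, sample_id = "sample",
                           timepoint = NA_character_) {
  required <- c("chrom", "start", "end", "gc", "mappable", "count")
  missing <- setdiff(required, names(bins))
  if (length(missing) > 0) {
    abort(paste("bins lack column(s):", paste(missing, collapse = ", ")),
          "invalid_profile_error")
  }
  ord <- order(bins$chrom, bins$start)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  bins$usable <- bins$mappable
  structure(bins,
            class = c("cn_profile", "data.frame"),
            sample_id = sample_id,
            total_reads = sum(bins$count),
            timepoint = timepoint)
}

#' @export
print.cn_profile <- function(x, ...) {
  stages <- intersect(c("ratio", "log2"), names(x))
  cat(sprintf(
    "<cn_profile> %s: %d bins on %d chromosome(s), %.3g reads%s\n",
    attr(x, "sample_id"), nrow(x), length(unique(x$chrom)),
    attr(x, "total_reads"),
    if (length(stages)) paste0(" [", paste(stages, collapse = ", "), "]")
    else " [raw]"
  ))
  invisible(x)
}

# rebuild a cn_profile after column surgery, preserving metadata
update_profile <- function(profile, bins) {
  structure(bins,
            class = c("cn_profile", "data.frame"),
            sample_id = attr(profile, "sample_id"),
            total_reads = attr(profile, "total_reads"),
            timepoint = attr(profile, "timepoint"))
}

#' Count read starts in non-overlapping genomic bins
#'
#' Each read is assigned to exactly one bin by its start coordinate. Reads
#' falling in masked (unmappable) bins are counted but the bins stay flagged
#' unusable for downstream normalization and segmentation.
#'
#' @param read_starts Data frame with columns `chrom` and `pos` (0-based).
#' @param genome A `genome_model` providing the binning.
#' @param sample_id Sample identifier.
#' @param timepoint Optional timepoint label.
#' @return A raw-count `cn_profile`.
#' @export
#' @examples
#' gm <- make_genome(1, 1e6, seed = 1)
#' p <- bin_counts(data.frame(chrom = "chr1", pos = c(0, 49999, 50000)), gm)
#' p$count[1:2] # 2, 1
bin_counts <- function(read_starts, genome, sample_id = "sample",
                       timepoint = NA_character_) {
  stopifnot(inherits(genome, "genome_model"))
  bins <- genome$bins
  bins$count <- 0L
  if (nrow(read_starts) > 0) {
    len <- chrom_length_of(genome, read_starts$chrom)
    if (any(read_starts$pos < 0 | read_starts$pos >= len)) {
      abort("read position outside chromosome bounds",
            "position_out_of_bounds_error")
    }
    for (chrom in unique(read_starts$chrom)) {
      sel <- bins$chrom == chrom
      pos <- read_starts$pos[read_starts$chrom == chrom]
      idx <- findInterval(pos, bins$start[sel])
      tab <- tabulate(idx, nbins = sum(sel))
      bins$count[sel] <- tab
    }
  }
  new_cn_profile(bins, sample_id = sample_id, timepoint = timepoint)
}

#' Normalize bin counts by total library size
#'
#' @param profile A raw-count `cn_profile`.
#' @return The profile with a `ratio` column (`count / total_reads`).
#' @export
normalize_total <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  total <- attr(profile, "total_reads")
  if (is.na(total) || total <= 0) {
    abort("profile has zero total reads", "zero_reads_error")
  }
  bins <- as.data.frame(profile)
  bins$ratio <- bins$count / total
  update_profile(profile, bins)
}

#' Correct normalized ratios for GC content
#'
#' Fits a robust local-regression (lowess) curve of the normalized ratio on
#' bin GC fraction across usable bins and divides it out, rescaling by the
#' median usable ratio so an unbiased profile passes through essentially
#' unchanged. If all bins share one GC value, the transform is the identity.
#'
#' @param profile A `cn_profile` with a `ratio` column.
#' @param span Lowess smoother span (fraction of points).
#' @return The profile with GC-corrected `ratio`.
#' @export
gc_correct <- function(profile, span = 0.3) {
  stopifnot(inherits(profile, "cn_profile"))
  bins <- as.data.frame(profile)
  if (is.null(bins$ratio)) {
    abort("run `normalize_total()` before `gc_correct()`",
          "missing_stage_error")
  }
  use <- bins$mappable
  if (sum(use) < 100) {
    abort("GC correction needs >= 100 mappable bins", "too_few_bins_error")
  }
  if (length(unique(bins$gc[use])) == 1L) {
    attr(profile, "gc_corrected") <- TRUE
    return(profile)
  }
  med <- median(bins$ratio[use])
  lo <- lowess(bins$gc[use], bins$ratio[use], f = span)
  fitted <- approx(lo$x, lo$y, xout = bins$gc, rule = 2, ties = mean)$y
  fitted <- pmax(fitted, 1e-6 * med) # keep the divisor strictly positive
  bins$ratio <- bins$ratio / fitted * med
  out <- update_profile(profile, bins)
  attr(out, "gc_corrected") <- TRUE
  out
}

#' Normalize a profile against a healthy-control panel
#'
#' Converts GC-corrected ratios into log2 ratios against the per-bin median
#' ratio of a panel of control profiles processed through the same binning
#' and GC correction, removing recurrent position effects. Bins whose panel
#' baseline falls below 5% of the median baseline are flagged unusable and
#' excluded from segmentation; ratios are clipped at 1e-6 before the log to
#' guard dropout bins.
#'
#' Re-applying control normalization to a profile that already carries log2
#' ratios is an error, never a silent double application.
#'
#' @param profile A `cn_profile` with (GC-corrected) `ratio`.
#' @param panel Non-empty list of control `cn_profile`s with `ratio`.
#' @return The profile with `log2` and updated `usable` columns.
#' @export
control_normalize <- function(profile, panel) {
  stopifnot(inherits(profile, "cn_profile"))
  if (!is.null(profile$log2)) {
    abort("profile already control-normalized (log2 present)",
          "already_normalized_error")
  }
  if (!is.list(panel) || length(panel) == 0) {
    abort("`panel` must be a non-empty list of control profiles",
          "empty_panel_error")
  }
  bins <- as.data.frame(profile)
  if (is.null(bins$ratio)) {
    abort("run `normalize_total()` (and `gc_correct()`) first",
          "missing_stage_error")
  }
  ratios <- vapply(panel, function(ctrl) {
    if (!inherits(ctrl, "cn_profile") || is.null(ctrl$ratio)) {
      abort("every panel member needs a `ratio` column (same pipeline stages)",
            "invalid_panel_error")
    }
    if (nrow(ctrl) != nrow(bins)) {
      abort("panel binning does not match the profile", "invalid_panel_error")
    }
    ctrl$ratio
  }, numeric(nrow(bins)))
  baseline <- apply(as.matrix(ratios), 1L, median)
  floor_b <- 0.05 * median(baseline[baseline > 0 & bins$mappable])
  ok <- bins$mappable & baseline > floor_b
  bins$log2 <- NA_real_
  bins$log2[ok] <- log2(pmax(bins$ratio[ok], 1e-6) / baseline[ok])
  bins$usable <- ok
  update_profile(profile, bins)
}

#' Re-bin a raw-count profile to a coarser resolution
#'
#' Sums raw counts of member fine bins into windows of `width` bp (a
#' multiple of the fine bin width); the coarse GC fraction is the
#' length-weighted mean and a coarse bin is mappable when at least half of
#' its covered length is.
#'
#' @param profile A raw-count `cn_profile`.
#' @param width Coarse bin width in bp (default 1 Mb).
#' @return A coarse `cn_profile` with summed counts.
#' @export
rebin <- function(profile, width = 1e6) {
  stopifnot(inherits(profile, "cn_profile"))
  fine <- as.data.frame(profile)
  fine_width <- max(fine$end - fine$start)
  if (width < fine_width || width %% fine_width != 0) {
    abort("`width` must be a multiple of the fine bin width",
          "invalid_width_error")
  }
  key <- paste(fine$chrom, floor(fine$start / width), sep = ":")
  key <- factor(key, levels = unique(key))
  len <- fine$end - fine$start
  agg <- data.frame(
    chrom = tapply(fine$chrom, key, `[`, 1L),
    start = as.numeric(tapply(fine$start, key, min)),
    end = as.numeric(tapply(fine$end, key, max)),
    gc = as.numeric(tapply(fine$gc * len, key, sum) / tapply(len, key, sum)),
    count = as.numeric(tapply(fine$count, key, sum)),
    stringsAsFactors = FALSE
  )
  map_len <- tapply(len * fine$mappable, key, sum)
  agg$mappable <- as.numeric(map_len) / as.numeric(tapply(len, key, sum)) >= 0.5
  rownames(agg) <- NULL
  new_cn_profile(agg[, c("chrom", "start", "end", "gc", "mappable", "count")],
                 sample_id = attr(profile, "sample_id"),
                 timepoint = attr(profile, "timepoint"))
}

#' Read / write binned counts as BED-like TSV
#'
#' `read_counts_tsv()` expects 4 columns (`chrom`, `start`, `end`, `count`)
#' and joins them onto a genome model's bins; `write_counts_tsv()` writes
#' the same format.
#'
#' @param path File path.
#' @param genome A `genome_model` supplying GC and mappability.
#' @param profile A `cn_profile`.
#' @param sample_id Sample identifier for the returned profile.
#' @return `read_counts_tsv()` returns a `cn_profile`.
#' @export
read_counts_tsv <- function(path, genome, sample_id = basename(path)) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  bins <- genome$bins
  key_g <- paste(bins$chrom, bins$start)
  key_t <- paste(tab$chrom, tab$start)
  idx <- match(key_g, key_t)
  if (anyNA(idx)) {
    abort("count file does not cover every genome bin", "invalid_input_error")
  }
  bins$count <- tab$count[idx]
  new_cn_profile(bins, sample_id = sample_id)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(profile, path) {
  out <- as.data.frame(profile)[, c("chrom", "start", "end", "count")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write segments in SEG format
#'
#' @param segments Segment data frame from [segment_profile()].
#' @param path File path.
#' @param sample_id Sample column value.
#' @export
write_seg <- function(segments, path, sample_id = "sample") {
  out <- data.frame(sample = sample_id,
                    segments[, c("chrom", "start", "end", "n_bins",
                                 "mean_log2")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
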
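#' Segment a log2 copy-number profile
#'
#' Finds, per chromosome, the segmentation of the usable-bin log2 ratios
#' that minimizes the penalized weighted least-squares cost
#' `sum_s SSE_w(s) + penalty * (#segments - 1)`, by exact optimal-partition
#' dynamic programming. Bins are weighted by their length, so a short
#' terminal bin is retained but contributes proportionally less to segment
#' means and breakpoint placement.
#'
#' The default penalty is `4 * sigma^2 * log(n)` (a conservative BIC-style
#' choice guarding against over-segmentation of flat profiles) with
#' `sigma` estimated robustly from the median absolute first difference of
#' the log2 ratios across the genome, so it adapts to sequencing depth.
#'
#' @param profile A `cn_profile` with `log2` ratios.
#' @param penalty Per-breakpoint penalty; `NULL` for the adaptive default.
#' @param min_bins Minimum bins per segment (>= 2; chromosomes with fewer
#'   usable bins yield a single segment).
#' @return Data frame of class `cn_segments` with columns `chrom`, `start`,
#'   `end`, `n_bins`, `mean_log2`, `length_bp`, ordered and non-overlapping
#'   within each chromosome.
#' @export
segment_profile <- function(profile, penalty = NULL, min_bins = 3) {
  stopifnot(inherits(profile, "cn_profile"))
  if (is.null(profile$log2)) {
    abort("profile has no log2 ratios; run `control_normalize()` first",
          "missing_stage_error")
  }
  if (min_bins < 2) abort("`min_bins` must be >= 2", "invalid_config_error")
  bins <- as.data.frame(profile)
  use <- bins$usable & !is.na(bins$log2)
  if (!any(use)) {
    abort("no usable bins to segment", "too_few_bins_error")
  }
  x_all <- bins$log2[use]
  if (is.null(penalty)) {
    sigma <- mad(diff(x_all)) / sqrt(2)
    sigma <- max(sigma, 1e-4)
    penalty <- 4 * sigma^2 * log(length(x_all))
  }

  out <- lapply(unique(bins$chrom), function(chrom) {
    sel <- use & bins$chrom == chrom
    if (!any(sel)) return(NULL)
    x <- bins$log2[sel]
    w <- (bins$end[sel] - bins$start[sel]) / max(bins$end[sel] - bins$start[sel])
    starts <- bins$start[sel]
    ends <- bins$end[sel]
    bk <- optimal_partition(x, w, penalty, min_bins)
    seg_start <- c(1L, bk + 1L)
    seg_end <- c(bk, length(x))
    data.frame(
      chrom = chrom,
      start = starts[seg_start],
      end = ends[seg_end],
      n_bins = seg_end - seg_start + 1L,
      mean_log2 = vapply(seq_along(seg_start), function(i) {
        idx <- seg_start[i]:seg_end[i]
        sum(w[idx] * x[idx]) / sum(w[idx])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  segs <- do.call(rbind, out)
  segs$length_bp <- segs$end - segs$start
  rownames(segs) <- NULL
  class(segs) <- c("cn_segments", "data.frame")
  segs
}

# Exact penalized optimal partition of one chromosome.
# Returns the breakpoint indices (last bin of each non-final segment).
optimal_partition <- function(x, w, penalty, min_bins) {
  n <- length(x)
  if (n < 2 * min_bins) return(integer(0)) # single segment
  cw <- cumsum(w)
  cwx <- cumsum(w * x)
  cwx2 <- cumsum(w * x^2)
  # weighted SSE of bins (j+1)..i, vectorized over j (j = 0 means the
  # segment starts at bin 1; guard the cumulative-sum lookup accordingly)
  sse <- function(j, i) {
    nz <- j > 0
    sw <- cw[i] - cw[pmax(j, 1L)] * nz
    swx <- cwx[i] - cwx[pmax(j, 1L)] * nz
    swx2 <- cwx2[i] - cwx2[pmax(j, 1L)] * nz
    swx2 - swx^2 / sw
  }
  f <- rep(Inf, n + 1L)
  f[1] <- -penalty # so the first segment carries no penalty
  prev <- integer(n)
  for (i in seq_len(n)) {
    if (i < min_bins) next
    j <- 0:(i - min_bins)
    j <- j[j == 0L | j >= min_bins] # every segment respects min_bins
    cand <- f[j + 1L] + sse(j, i) + penalty
    best <- which.min(cand)
    f[i + 1L] <- cand[best]
    prev[i] <- j[best]
  }
  if (!is.finite(f[n + 1L])) return(integer(0))
  bk <- integer(0)
  i <- n
  while (i > 0) {
    j <- prev[i]
    if (j > 0) bk <- c(j, bk)
    i <- j
  }
  bk
}

# Total penalized cost of a segmentation (used for oracle comparisons).
segmentation_cost <- function(x, w, breaks, penalty) {
  bounds <- c(0L, breaks, length(x))
  cost <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    mu <- sum(w[idx] * x[idx]) / sum(w[idx])
    cost <- cost + sum(w[idx] * (x[idx] - mu)^2)
  }
  cost + penalty * (length(bounds) - 2L)
}
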
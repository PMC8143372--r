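# Independent oracles used across the suite. These re-derive expected
# results by brute force or from first principles, sharing no code path
# with the implementation they check.

# ---- literal focal-criteria checker --------------------------------------
# Applies every amplification/deletion criterion exactly as written, with
# plain loops and base arithmetic (no interval packages, no shared helpers).

literal_union_overlap <- function(seg, track) {
  ivals <- list()
  for (k in seq_len(nrow(track))) {
    if (track$chrom[k] != seg$chrom) next
    lo <- max(track$start[k], seg$start)
    hi <- min(track$end[k], seg$end)
    if (hi > lo) ivals[[length(ivals) + 1L]] <- c(lo, hi)
  }
  if (length(ivals) == 0) return(0)
  m <- do.call(rbind, ivals)
  m <- m[order(m[, 1]), , drop = FALSE]
  covered <- 0
  cur_lo <- m[1, 1]; cur_hi <- m[1, 2]
  if (nrow(m) > 1) {
    for (k in 2:nrow(m)) {
      if (m[k, 1] <= cur_hi) {
        cur_hi <- max(cur_hi, m[k, 2])
      } else {
        covered <- covered + (cur_hi - cur_lo)
        cur_lo <- m[k, 1]; cur_hi <- m[k, 2]
      }
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  covered / (seg$end - seg$start)
}

literal_neighbor_mean <- function(segments, i, flank = 2e7) {
  seg <- segments[i, ]
  num <- 0; den <- 0
  for (k in seq_len(nrow(segments))) {
    if (k == i || segments$chrom[k] != seg$chrom) next
    for (win in list(c(seg$start - flank, seg$start),
                     c(seg$end, seg$end + flank))) {
      lo <- max(segments$start[k], win[1])
      hi <- min(segments$end[k], win[2])
      if (hi > lo) {
        num <- num + (hi - lo) * segments$mean_log2[k]
        den <- den + (hi - lo)
      }
    }
  }
  if (den > 0) return(num / den)
  # fallback: chromosome-wide length-weighted mean excluding the segment
  num <- 0; den <- 0
  for (k in seq_len(nrow(segments))) {
    if (k == i || segments$chrom[k] != seg$chrom) next
    w <- segments$end[k] - segments$start[k]
    num <- num + w * segments$mean_log2[k]
    den <- den + w
  }
  if (den > 0) num / den else 0
}

literal_focal_call <- function(segments, ann, i, direction,
                               dgv_frac = 0.5) {
  seg <- segments[i, ]
  if (!((seg$end - seg$start) < 2e7)) return(FALSE)
  if (direction == "amplification") {
    if (!(seg$mean_log2 > 0.2)) return(FALSE)
  } else {
    if (!(seg$mean_log2 < -0.2)) return(FALSE)
  }
  n_genes <- 0L; has_driver <- FALSE; has_del_target <- FALSE
  for (k in seq_len(nrow(ann$genes))) {
    g <- ann$genes[k, ]
    if (g$chrom == seg$chrom && g$start < seg$end && g$end > seg$start) {
      n_genes <- n_genes + 1L
      if (g$is_driver) has_driver <- TRUE
      if (g$is_deletion_target) has_del_target <- TRUE
    }
  }
  if (n_genes < 1L || n_genes > 100L) return(FALSE)
  if (direction == "deletion" && !has_del_target) return(FALSE)
  nb <- literal_neighbor_mean(segments, i)
  delta <- seg$mean_log2 - nb
  if (direction == "amplification") {
    thr <- if (has_driver) 0.2 else 0.58
    if (!(delta >= thr)) return(FALSE)
  } else {
    if (!(delta <= -0.2)) return(FALSE)
  }
  if (literal_union_overlap(seg, ann$segdups) > 0.5) return(FALSE)
  for (k in seq_len(nrow(ann$dgv))) {
    d <- ann$dgv[k, ]
    if (d$chrom != seg$chrom) next
    ov <- min(d$end, seg$end) - max(d$start, seg$start)
    if (ov <= 0) next
    if (ov / (seg$end - seg$start) >= dgv_frac &&
        ov / (d$end - d$start) >= dgv_frac) return(FALSE)
  }
  TRUE
}

# random segmented profile + annotation for caller-vs-oracle comparisons
random_focal_case <- function(seed, max_segments = 50) {
  withr::with_seed(seed, {
    n_chrom <- sample(1:3, 1)
    chrom_len <- 6e7
    segs <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
      n_seg <- sample(1:ceiling(max_segments / n_chrom), 1)
      bk <- sort(sample(seq(5e5, chrom_len - 5e5, by = 5e4),
                        n_seg - 1L))
      start <- c(0, bk)
      end <- c(bk, chrom_len)
      # means cluster near the decision boundaries on purpose
      mean_log2 <- sample(c(0, 0.1, 0.19, 0.2, 0.21, 0.25, 0.3, 0.55,
                            0.58, 0.6, 0.9, -0.19, -0.2, -0.21, -0.35,
                            -0.6), n_seg, replace = TRUE) +
        rnorm(n_seg, 0, 0.02)
      data.frame(chrom = paste0("chr", ci), start = start, end = end,
                 n_bins = as.integer((end - start) / 5e4),
                 mean_log2 = mean_log2, length_bp = end - start,
                 stringsAsFactors = FALSE)
    }))
    rand_track <- function(n) {
      chrom <- paste0("chr", sample(seq_len(n_chrom), n, replace = TRUE))
      start <- runif(n, 0, chrom_len - 5e6)
      width <- runif(n, 1e4, 5e6)
      out <- data.frame(chrom = chrom, start = start, end = start + width,
                        stringsAsFactors = FALSE)
      out[order(out$chrom, out$start), ]
    }
    genes <- rand_track(40)
    genes$name <- sprintf("gene%02d", seq_len(nrow(genes)))
    genes$is_driver <- runif(40) < 0.3
    genes$is_deletion_target <- runif(40) < 0.15
    ann <- annotation_bundle(genes, rand_track(8), rand_track(12))
    list(segments = segs, annotation = ann)
  })
}

# ---- exhaustive segmentation oracle --------------------------------------
# Enumerates every admissible segmentation of x (all breakpoint subsets
# honoring min_bins) and returns the minimum penalized cost.

enumerate_best_cost <- function(x, w, penalty, min_bins) {
  n <- length(x)
  seg_cost <- function(idx) {
    mu <- sum(w[idx] * x[idx]) / sum(w[idx])
    sum(w[idx] * (x[idx] - mu)^2)
  }
  if (n < 2 * min_bins) return(seg_cost(seq_len(n)))
  best <- Inf
  positions <- seq_len(n - 1L)
  for (k in 0:(n %/% min_bins - 1L)) {
    combos <- if (k == 0) list(integer(0)) else
      asplit(utils::combn(positions, k), 2L)
    for (bk in combos) {
      bounds <- c(0L, bk, n)
      if (any(diff(bounds) < min_bins)) next
      cost <- penalty * k
      for (s in seq_len(length(bounds) - 1L)) {
        cost <- cost + seg_cost((bounds[s] + 1L):bounds[s + 1L])
      }
      if (cost < best) best <- cost
    }
  }
  best
}

# ---- Efron partial-likelihood score --------------------------------------
# Analytic gradient of the Cox log partial likelihood with Efron tie
# handling, evaluated at beta; used to certify reported optima.

efron_score <- function(beta, time, status, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  score <- numeric(ncol(X))
  for (t in unique(time[status == 1])) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_w_R <- sum(w[R])
    sum_wx_R <- colSums(X[R, , drop = FALSE] * w[R])
    sum_w_D <- sum(w[D])
    sum_wx_D <- colSums(X[D, , drop = FALSE] * w[D])
    score <- score + colSums(X[D, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      denom <- sum_w_R - (l / d) * sum_w_D
      numer <- sum_wx_R - (l / d) * sum_wx_D
      score <- score - numer / denom
    }
  }
  score
}

# ---- shared fixtures ------------------------------------------------------

load_fixture_cohort <- function() {
  mut <- read_cohort(cohort_fixture_path("mutations"), "mutations")
  dd <- read_cohort(cohort_fixture_path("ddpcr"), "ddpcr")
  build_patient_records(mut, dd)
}
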
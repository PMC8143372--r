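#' Build a synthetic genome model for plasma copy-number simulation
#'
#' Constructs the reference scaffolding the simulator and the profiling
#' pipeline operate on: chromosomes tiled by non-overlapping 50 kb bins with
#' a smooth GC landscape, a gene annotation with named driver and
#' deletion-target genes, segmental-duplication and common-CNV (DGV-style)
#' tracks used to veto artifact focal calls, and a pseudoautosomal-style
#' mask whose bins are flagged unmappable.
#'
#' Chromosome sizes are deliberately a scaled-down model of a human genome;
#' every interval is 0-based half-open. The terminal bin of a chromosome may
#' be shorter than `bin_width` when the length is not an exact multiple.
#' Driver and deletion-target genes are placed away from the repeat tracks so
#' that simulated driver amplifications exercise the calling logic rather
#' than the artifact filters; on real data these tracks are external inputs.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length in bp of each chromosome (scalar or vector of
#'   length `n_chrom`); must be at least one bin width.
#' @param gene_density Background gene density in genes per Mb.
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param bin_width Bin width in bp (default 50 kb).
#' @param driver_genes Character vector of named driver genes to place
#'   (flagged `is_driver`).
#' @param deletion_genes Character vector of named deletion-target genes
#'   (flagged `is_deletion_target`).
#' @param par_fraction Fraction of the last chromosome masked as a
#'   pseudoautosomal-like region (bins flagged unmappable).
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes`, `bins`, `genes`, `segdups`, `dgv`, `par_mask`,
#'   `bin_width`.
#' @export
#' @examples
#' gm <- make_genome(n_chrom = 1, chrom_length = 1e6, seed = 1)
#' nrow(gm$bins) # 20 bins of 50 kb
make_genome <- function(n_chrom = 6,
                        chrom_length = 8e7,
                        gene_density = 0.25,
                        seed = 1,
                        bin_width = 50000,
                        driver_genes = c("EGFR", "ERBB2", "MET", "CDK4",
                                         "CDK6", "MDM2", "AKT2", "PIK3CA"),
                        deletion_genes = c("CDKN2A", "RB1"),
                        par_fraction = 0.02) {
  if (!is.numeric(n_chrom) || length(n_chrom) != 1L || n_chrom < 1) {
    abort("`n_chrom` must be a single integer >= 1", "invalid_genome_error")
  }
  n_chrom <- as.integer(n_chrom)
  chrom_length <- rep_len(as.double(chrom_length), n_chrom)
  if (any(chrom_length < bin_width)) {
    abort("`chrom_length` must be at least one bin width",
          "invalid_genome_error")
  }

  chroms <- data.frame(
    name = paste0("chr", seq_len(n_chrom)),
    length = chrom_length,
    stringsAsFactors = FALSE
  )

  with_stream(seed, "genome", {
    bins <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
      len <- chrom_length[ci]
      start <- seq(0, len - 1, by = bin_width)
      end <- pmin(start + bin_width, len)
      # smooth GC landscape: long-wavelength oscillation plus local jitter
      phase <- runif(1, 0, 2 * pi)
      gc <- 0.42 + 0.08 * sin(2 * pi * start / 7e6 + phase) +
        rnorm(length(start), 0, 0.015)
      data.frame(
        chrom = chroms$name[ci], start = start, end = end,
        gc = pmin(pmax(gc, 0.25), 0.65), mappable = TRUE,
        stringsAsFactors = FALSE
      )
    }))

    named <- data.frame(
      name = c(driver_genes, deletion_genes),
      is_driver = c(rep(TRUE, length(driver_genes)),
                    rep(FALSE, length(deletion_genes))),
      is_deletion_target = c(rep(FALSE, length(driver_genes)),
                             rep(TRUE, length(deletion_genes))),
      stringsAsFactors = FALSE
    )
    # spread named genes across chromosomes, clear of the masked tail
    named_rows <- lapply(seq_len(nrow(named)), function(i) {
      ci <- ((i - 1L) %% n_chrom) + 1L
      len <- chrom_length[ci]
      lo <- 0.05 * len
      hi <- 0.90 * len
      start <- floor(runif(1, lo, hi) / 1e4) * 1e4
      data.frame(chrom = chroms$name[ci], start = start,
                 end = min(start + 1e5, len), name = named$name[i],
                 is_driver = named$is_driver[i],
                 is_deletion_target = named$is_deletion_target[i],
                 stringsAsFactors = FALSE)
    })
    named_df <- do.call(rbind, named_rows)

    background <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
      len <- chrom_length[ci]
      n_genes <- max(1L, round(gene_density * len / 1e6))
      start <- floor(runif(n_genes, 0, len - 2e5) / 1e3) * 1e3
      width <- round(runif(n_genes, 2e4, 2e5))
      data.frame(
        chrom = chroms$name[ci], start = start,
        end = pmin(start + width, len),
        name = sprintf("g%d_%03d", ci, seq_len(n_genes)),
        is_driver = FALSE, is_deletion_target = FALSE,
        stringsAsFactors = FALSE
      )
    }))
    genes <- rbind(named_df, background)
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
    rownames(genes) <- NULL

    # repeat/common-CNV tracks, rejection-sampled away from named genes
    sample_track <- function(per_chrom, w_lo, w_hi) {
      out <- do.call(rbind, lapply(seq_len(n_chrom), function(ci) {
        len <- chrom_length[ci]
        hi <- max(min(w_hi, 0.2 * len), w_lo + 1)
        margin <- min(2e6, 0.05 * len)
        kept <- 0L
        rows <- vector("list", per_chrom)
        tries <- 0L
        while (kept < per_chrom && tries < 200L) {
          tries <- tries + 1L
          start <- floor(runif(1, 0, len - hi))
          end <- start + round(runif(1, w_lo, hi))
          clash <- any(named_df$chrom == chroms$name[ci] &
                         named_df$start < end + margin &
                         named_df$end > start - margin)
          # after enough rejections accept a clash: the track must be
          # non-empty even on toy genomes too small to avoid every gene
          if (!clash || tries > 150L) {
            kept <- kept + 1L
            rows[[kept]] <- data.frame(chrom = chroms$name[ci],
                                       start = start, end = end,
                                       stringsAsFactors = FALSE)
          }
        }
        do.call(rbind, rows[seq_len(kept)])
      }))
      out <- out[order(out$chrom, out$start), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    segdups <- sample_track(3L, 5e4, 5e5)
    dgv <- sample_track(5L, 2e4, 3e5)

    par_len <- floor(par_fraction * chrom_length[n_chrom] / bin_width) *
      bin_width
    par_mask <- data.frame(chrom = chroms$name[n_chrom], start = 0,
                           end = par_len, stringsAsFactors = FALSE)
    masked <- bins$chrom == par_mask$chrom &
      bins$start < par_mask$end & bins$end > par_mask$start
    bins$mappable[masked] <- FALSE

    structure(
      list(chromosomes = chroms, bins = bins, genes = genes,
           segdups = segdups, dgv = dgv, par_mask = par_mask,
           bin_width = bin_width),
      class = "genome_model"
    )
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosome(s), %.1f Mb, %d bins of %d kb, %d genes (%d driver, %d deletion-target)\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6, nrow(x$bins),
    x$bin_width %/% 1000L, nrow(x$genes), sum(x$genes$is_driver),
    sum(x$genes$is_deletion_target)
  ))
  invisible(x)
}

# Length of a named chromosome; errors on unknown names.
chrom_length_of <- function(genome, chrom) {
  idx <- match(chrom, genome$chromosomes$name)
  if (anyNA(idx)) {
    abort(sprintf("unknown chromosome(s): %s",
                  paste(unique(chrom[is.na(idx)]), collapse = ", ")),
          "unknown_chromosome_error")
  }
  genome$chromosomes$length[idx]
}
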
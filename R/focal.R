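#' Bundle annotation tracks for focal SCNA calling
#'
#' @param genes Data frame with `chrom`, `start`, `end`, `name`,
#'   `is_driver`, `is_deletion_target`.
#' @param segdups Segmental-duplication intervals (`chrom`, `start`, `end`).
#' @param dgv Common copy-number variant intervals (DGV-style).
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(genes, segdups, dgv) {
  if (is.null(genes) || is.null(segdups) || is.null(dgv)) {
    abort("genes, segdups and dgv tracks are all required",
          "missing_annotation_error")
  }
  need <- c("chrom", "start", "end", "name", "is_driver",
            "is_deletion_target")
  if (!all(need %in% names(genes))) {
    abort("gene track lacks required columns", "missing_annotation_error")
  }
  check_track <- function(track, what) {
    if (!all(c("chrom", "start", "end") %in% names(track))) {
      abort(sprintf("%s track lacks chrom/start/end", what),
            "missing_annotation_error")
    }
    if (any(track$end <= track$start)) {
      abort(sprintf("%s track has degenerate intervals", what),
            "invalid_annotation_error")
    }
    track[order(track$chrom, track$start), , drop = FALSE]
  }
  structure(
    list(genes = check_track(genes, "gene"),
         segdups = check_track(segdups, "segdup"),
         dgv = check_track(dgv, "dgv")),
    class = "annotation_bundle"
  )
}

#' Annotation bundle of a synthetic genome
#'
#' @param genome A `genome_model`.
#' @return An `annotation_bundle` built from the genome's own tracks.
#' @export
annotation_from_genome <- function(genome) {
  annotation_bundle(genome$genes, genome$segdups, genome$dgv)
}

df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Length-weighted mean log2 of a segment's 20 Mb neighborhood
#'
#' Summarizes the copy-number context a candidate focal event must stand
#' out from: the log2 ratios of segments overlapping the 20 Mb flanks on
#' both sides, weighted by the length each neighbor actually covers within
#' the flank windows (truncated at chromosome ends). The segment itself is
#' excluded. When neither flank is covered by another segment, the context
#' is flagged empty and the combined mean falls back to the length-weighted
#' chromosome mean excluding the segment (0 if the segment is alone).
#'
#' @param segments Segment data frame (one profile), ordered.
#' @param index Row index of the segment under test.
#' @param flank Flank width in bp (default 20 Mb).
#' @return List with `left_mean`, `right_mean`, `combined_weighted_mean`,
#'   `left_span`, `right_span`, `empty`.
#' @export
neighbor_weighted_mean <- function(segments, index, flank = 2e7) {
  if (index < 1 || index > nrow(segments)) {
    abort("`index` out of range", "invalid_index_error")
  }
  seg <- segments[index, ]
  others <- segments[-index, , drop = FALSE]
  others <- others[others$chrom == seg$chrom, , drop = FALSE]

  side <- function(win_lo, win_hi) {
    if (win_hi <= win_lo || nrow(others) == 0) {
      return(list(mean = NA_real_, span = 0))
    }
    ov <- pmin(others$end, win_hi) - pmax(others$start, win_lo)
    hit <- ov > 0
    if (!any(hit)) return(list(mean = NA_real_, span = 0))
    list(mean = sum(ov[hit] * others$mean_log2[hit]) / sum(ov[hit]),
         span = sum(ov[hit]))
  }
  left <- side(seg$start - flank, seg$start)
  right <- side(seg$end, seg$end + flank)

  total_span <- left$span + right$span
  if (total_span > 0) {
    combined <- (ifelse(left$span > 0, left$mean * left$span, 0) +
                   ifelse(right$span > 0, right$mean * right$span, 0)) /
      total_span
    empty <- FALSE
  } else if (nrow(others) > 0) {
    w <- others$end - others$start
    combined <- sum(w * others$mean_log2) / sum(w)
    empty <- TRUE
  } else {
    combined <- 0 # lone segment: diploid reference is the only context
    empty <- TRUE
  }
  list(left_mean = left$mean, right_mean = right$mean,
       combined_weighted_mean = combined,
       left_span = left$span, right_span = right$span, empty = empty)
}

#' Fraction of a segment covered by a track
#'
#' Union of the track's overlaps with the segment divided by the segment
#' length; always in `[0, 1]`.
#'
#' @param segment One-row data frame (or list) with `chrom`, `start`, `end`.
#' @param track Interval data frame.
#' @return Covered fraction.
#' @export
overlap_fraction <- function(segment, track) {
  track <- track[track$chrom == segment$chrom, , drop = FALSE]
  if (nrow(track) == 0) return(0)
  seg_ir <- IRanges::IRanges(start = segment$start + 1L, end = segment$end)
  track_ir <- IRanges::reduce(
    IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  hits <- IRanges::intersect(seg_ir, track_ir)
  sum(IRanges::width(hits)) / (segment$end - segment$start)
}

# genes overlapping a segment by >= 1 bp
genes_in_segment <- function(segment, genes) {
  hit <- genes$chrom == segment$chrom & genes$start < segment$end &
    genes$end > segment$start
  genes[hit, , drop = FALSE]
}

# TRUE if any single track entry matches the segment under the given rule
dgv_conflict <- function(segment, dgv, mode, frac) {
  hit <- dgv$chrom == segment$chrom & dgv$start < segment$end &
    dgv$end > segment$start
  if (!any(hit)) return(FALSE)
  if (mode == "any") return(TRUE)
  ov <- pmin(dgv$end[hit], segment$end) - pmax(dgv$start[hit], segment$start)
  seg_len <- segment$end - segment$start
  dgv_len <- dgv$end[hit] - dgv$start[hit]
  any(ov / seg_len >= frac & ov / dgv_len >= frac)
}

focal_thresholds <- function(direction) {
  if (direction == "amplification") {
    list(max_length = 2e7, log2_cut = 0.2, delta_driver = 0.2,
         delta_no_driver = 0.58, max_genes = 100L)
  } else {
    list(max_length = 2e7, log2_cut = -0.2, delta = -0.2, max_genes = 100L)
  }
}

# Shared criteria engine. Returns the per-segment filter record and the
# called events. Criteria are evaluated in a fixed short-circuiting order
# (size, log2, gene content, [deletion target], neighbor delta, segdup,
# DGV); later criteria of a failed segment are NA in the record.
apply_focal_criteria <- function(segments, annotation, direction,
                                 flank = 2e7, dgv_mode = "reciprocal",
                                 dgv_frac = 0.5, segdup_frac = 0.5) {
  if (!inherits(annotation, "annotation_bundle")) {
    abort("`annotation` must be an annotation_bundle",
          "missing_annotation_error")
  }
  th <- focal_thresholds(direction)
  is_amp <- direction == "amplification"
  crit_names <- c("size", "log2", "gene_content",
                  if (!is_amp) "deletion_target",
                  "neighbor_delta", "segdup", "dgv")

  records <- vector("list", nrow(segments))
  events <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    rec <- setNames(rep(NA, length(crit_names)), crit_names)
    genes <- character(0)
    has_driver <- FALSE
    delta <- NA_real_

    passed <- local({
      rec["size"] <<- seg$length_bp < th$max_length
      if (!rec["size"]) return(FALSE)
      rec["log2"] <<- if (is_amp) seg$mean_log2 > th$log2_cut
        else seg$mean_log2 < th$log2_cut
      if (!rec["log2"]) return(FALSE)
      gin <- genes_in_segment(seg, annotation$genes)
      genes <<- sort(gin$name)
      has_driver <<- any(gin$is_driver)
      rec["gene_content"] <<- nrow(gin) >= 1L && nrow(gin) <= th$max_genes
      if (!rec["gene_content"]) return(FALSE)
      if (!is_amp) {
        rec["deletion_target"] <<- any(gin$is_deletion_target)
        if (!rec["deletion_target"]) return(FALSE)
      }
      ctx <- neighbor_weighted_mean(segments, i, flank = flank)
      delta <<- seg$mean_log2 - ctx$combined_weighted_mean
      rec["neighbor_delta"] <<- if (is_amp) {
        delta >= (if (has_driver) th$delta_driver else th$delta_no_driver)
      } else {
        delta <= th$delta
      }
      if (!rec["neighbor_delta"]) return(FALSE)
      rec["segdup"] <<-
        overlap_fraction(seg, annotation$segdups) <= segdup_frac
      if (!rec["segdup"]) return(FALSE)
      rec["dgv"] <<- !dgv_conflict(seg, annotation$dgv, dgv_mode, dgv_frac)
      rec["dgv"]
    })

    records[[i]] <- rec
    if (isTRUE(passed)) {
      events[[i]] <- data.frame(
        chrom = seg$chrom, start = seg$start, end = seg$end,
        n_bins = seg$n_bins, length_bp = seg$length_bp,
        mean_log2 = seg$mean_log2, direction = direction,
        genes = paste(genes, collapse = ","),
        contains_driver = has_driver, neighbor_delta = delta,
        stringsAsFactors = FALSE
      )
    }
  }
  called <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(called)) {
    called <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), n_bins = integer(0),
                         length_bp = numeric(0), mean_log2 = numeric(0),
                         direction = character(0), genes = character(0),
                         contains_driver = logical(0),
                         neighbor_delta = numeric(0),
                         stringsAsFactors = FALSE)
  } else {
    called <- called[order(called$chrom, called$start), , drop = FALSE]
    rownames(called) <- NULL
  }
  structure(called, class = c("focal_events", "data.frame"),
            filter_log = records)
}

#' Call focal amplifications from a segmented profile
#'
#' A segment is emitted as a focal amplification iff all of the following
#' hold: it is shorter than 20 Mb; its mean log2 ratio exceeds 0.2; it
#' contains at least one but no more than 100 genes; its log2 ratio exceeds
#' the length-weighted mean of the neighboring 20 Mb on both sides by at
#' least 0.2 when it contains a known tumor driver gene, or by at least
#' 0.58 (about three copies in a pure tumor sample) when it does not;
#' segmental duplications cover at most 50% of its length; and it does not
#' match a known common copy-number variant (by default a reciprocal-50%
#' overlap with any single DGV-style entry).
#'
#' @param segments A `cn_segments` data frame from one profile.
#' @param annotation An [annotation_bundle()].
#' @param flank Neighborhood width in bp.
#' @param dgv_mode `"reciprocal"` (default) or `"any"` overlap matching for
#'   the common-CNV veto.
#' @param dgv_frac Reciprocal overlap fraction for `dgv_mode = "reciprocal"`.
#' @return A `focal_events` data frame of called events (sorted by
#'   position), with the per-segment criterion record in
#'   `attr(, "filter_log")`.
#' @export
call_focal_amplifications <- function(segments, annotation, flank = 2e7,
                                      dgv_mode = c("reciprocal", "any"),
                                      dgv_frac = 0.5) {
  dgv_mode <- match.arg(dgv_mode)
  apply_focal_criteria(segments, annotation, "amplification", flank,
                       dgv_mode, dgv_frac)
}

#' Call focal deletions from a segmented profile
#'
#' Mirrors [call_focal_amplifications()] with the deletion rule set: mean
#' log2 below -0.2, a single neighbor-delta threshold of 0.2 below the
#' 20 Mb context, and the requirement that the segment contain a gene known
#' to be affected by deletions (the `is_deletion_target` flag of the gene
#' track) in addition to the 1-100 gene-content rule, the sub-20 Mb size
#' rule, and the segmental-duplication and common-CNV vetoes.
#'
#' @inheritParams call_focal_amplifications
#' @return A `focal_events` data frame.
#' @export
call_focal_deletions <- function(segments, annotation, flank = 2e7,
                                 dgv_mode = c("reciprocal", "any"),
                                 dgv_frac = 0.5) {
  dgv_mode <- match.arg(dgv_mode)
  apply_focal_criteria(segments, annotation, "deletion", flank,
                       dgv_mode, dgv_frac)
}

#' Write focal events as TSV
#'
#' @param events A `focal_events` data frame.
#' @param path File path.
#' @export
write_focal_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
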
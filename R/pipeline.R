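#' Run the profiling pipeline on a raw-count profile
#'
#' Convenience composition of the per-sample stages: total-count
#' normalization, GC correction, control normalization against a panel
#' processed through the same stages, and segmentation.
#'
#' @param raw A raw-count `cn_profile`.
#' @param raw_panel List of raw-count control `cn_profile`s.
#' @param span GC-correction lowess span.
#' @param penalty Segmentation penalty (`NULL` = adaptive).
#' @param min_bins Minimum bins per segment.
#' @return List with the normalized `profile` and its `segments`.
#' @export
profile_sample <- function(raw, raw_panel, span = 0.3, penalty = NULL,
                           min_bins = 3) {
  panel <- lapply(raw_panel, function(p) gc_correct(normalize_total(p), span))
  prof <- control_normalize(gc_correct(normalize_total(raw), span), panel)
  list(profile = prof, segments = segment_profile(prof, penalty, min_bins))
}

#' Estimate tumor fraction of a raw-count profile at 1 Mb resolution
#'
#' Re-bins the sample and its control panel to `width` (default 1 Mb),
#' runs the same normalization stages at the coarse resolution, and hands
#' the resulting log2 ratios to [estimate_tf()].
#'
#' @inheritParams profile_sample
#' @param width Coarse bin width in bp.
#' @param ... Passed to [estimate_tf()].
#' @return A `tf_estimate`.
#' @export
estimate_tf_from_counts <- function(raw, raw_panel, width = 1e6,
                                    span = 0.3, ...) {
  coarse <- rebin(raw, width)
  coarse_panel <- lapply(raw_panel, function(p) {
    gc_correct(normalize_total(rebin(p, width)), span)
  })
  prof <- control_normalize(gc_correct(normalize_total(coarse), span),
                            coarse_panel)
  estimate_tf(prof, ...)
}

#' End-to-end analysis of one plasma sample
#'
#' Profiles and segments the sample, estimates its tumor fraction, calls
#' focal amplifications and deletions, and classifies resistance-related
#' SCNAs. Focal events are reported only when the estimated tumor fraction
#' passes the 3% detection gate.
#'
#' @inheritParams profile_sample
#' @param annotation An [annotation_bundle()].
#' @param gene_list An [rrscna_gene_list()].
#' @return List with `profile`, `segments`, `tf` (a `tf_estimate`),
#'   `focal_events`, `rrscna_genes`, `any_scna`.
#' @export
analyze_sample <- function(raw, raw_panel, annotation,
                           gene_list = rrscna_gene_list(), span = 0.3,
                           penalty = NULL, min_bins = 3) {
  prof <- profile_sample(raw, raw_panel, span, penalty, min_bins)
  tf <- estimate_tf_from_counts(raw, raw_panel, span = span)
  events <- rbind(
    call_focal_amplifications(prof$segments, annotation),
    call_focal_deletions(prof$segments, annotation)
  )
  if (!tf$detectable) events <- events[0, , drop = FALSE]
  list(profile = prof$profile, segments = prof$segments, tf = tf,
       focal_events = events, rrscna_genes = classify_rrscna(events, gene_list),
       any_scna = nrow(events) > 0)
}
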
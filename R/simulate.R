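#' Expected log2 ratio of a copy-number state at a given tumor fraction
#'
#' In a plasma sample where a fraction `tf` of the cell-free DNA derives from
#' tumor cells carrying `copies` copies of a locus (against a diploid
#' background), the expected read-depth ratio relative to a diploid reference
#' is `(tf * copies + (1 - tf) * 2) / 2`. Its log2 is the amplitude at which
#' the event appears in a normalized copy-number profile; at `tf = 1` a
#' three-copy gain gives log2(3/2) = 0.58.
#'
#' @param tf Tumor fraction in `[0, 1]`.
#' @param copies Non-negative copy number of the tumor clone (2 = neutral).
#' @param floor Lower clip applied to the log2 ratio, guarding the
#'   `copies = 0`, `tf = 1` case from -Inf.
#' @return Numeric vector of log2 ratios (vectorized over `tf`/`copies`).
#' @export
#' @examples
#' round(expected_log2(1, 3), 2)   # 0.58
#' expected_log2(0.5, 2)           # 0: diploid is baseline
#' expected_log2(0.2, 4)           # log2(1.2)
expected_log2 <- function(tf, copies, floor = -8) {
  if (!is.numeric(tf) || anyNA(tf) || any(tf < 0 | tf > 1)) {
    abort("`tf` must lie in [0, 1]", "invalid_tf_error")
  }
  if (!is.numeric(copies) || anyNA(copies) || any(copies < 0)) {
    abort("`copies` must be >= 0", "invalid_copies_error")
  }
  pmax(log2((tf * copies + (1 - tf) * 2) / 2), floor)
}

#' Simulation configuration for binned plasma read counts
#'
#' Bundles the sampling conditions of one simulated plasma library: the
#' tumor fraction, the sequencing depth, the GC bias curve, the count noise
#' family, and the seed every draw flows from.
#'
#' The GC bias is a quadratic efficiency curve `1 - strength * (gc - peak)^2`
#' (floored at 0.05), peaking at `peak` so coverage drops off at extreme GC.
#' `overdispersion = 0` gives Poisson counts; values > 0 give negative
#' binomial counts with variance `mu + overdispersion * mu^2`.
#'
#' @param tumor_fraction Tumor fraction in `[0, 1]`.
#' @param total_reads Expected total read count of the library.
#' @param gc_bias Numeric `c(peak, strength)` of the bias curve.
#' @param overdispersion Negative-binomial overdispersion (>= 0; 0 = Poisson).
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tumor_fraction = 0,
                       total_reads = 6569227,
                       gc_bias = c(peak = 0.45, strength = 3),
                       overdispersion = 0,
                       seed = 1) {
  if (!is.numeric(tumor_fraction) || length(tumor_fraction) != 1L ||
      tumor_fraction < 0 || tumor_fraction > 1) {
    abort("`tumor_fraction` must lie in [0, 1]", "invalid_tf_error")
  }
  if (!is.numeric(total_reads) || total_reads <= 0) {
    abort("`total_reads` must be > 0", "invalid_config_error")
  }
  if (overdispersion < 0) {
    abort("`overdispersion` must be >= 0", "invalid_config_error")
  }
  structure(
    list(tumor_fraction = tumor_fraction,
         total_reads = as.double(total_reads),
         gc_bias = gc_bias, overdispersion = overdispersion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Define a simulated copy-number event
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds in bp (`end > start`).
#' @param copies Integer tumor copy number (not 2, which is background).
#' @param clonal_fraction Fraction of tumor cells carrying the event, in
#'   `(0, 1]`.
#' @return One-row data frame describing the event.
#' @export
sim_event <- function(chrom, start, end, copies, clonal_fraction = 1) {
  if (end <= start) abort("`end` must exceed `start`", "invalid_event_error")
  if (copies == 2) {
    abort("`copies` must differ from the diploid background (2)",
          "invalid_event_error")
  }
  if (copies < 0) abort("`copies` must be >= 0", "invalid_event_error")
  if (clonal_fraction <= 0 || clonal_fraction > 1) {
    abort("`clonal_fraction` must lie in (0, 1]", "invalid_event_error")
  }
  data.frame(chrom = chrom, start = start, end = end, copies = copies,
             clonal_fraction = clonal_fraction, stringsAsFactors = FALSE)
}

gc_bias_curve <- function(gc, coef) {
  peak <- unname(coef[1])
  strength <- unname(coef[2])
  pmax(1 - strength * (gc - peak)^2, 0.05)
}

validate_events <- function(genome, events) {
  if (is.null(events) || nrow(events) == 0) {
    return(invisible(NULL))
  }
  len <- chrom_length_of(genome, events$chrom)
  if (any(events$start < 0 | events$end > len)) {
    abort("event outside chromosome bounds", "invalid_event_error")
  }
  if (nrow(events) > 1) {
    ord <- order(events$chrom, events$start)
    ev <- events[ord, ]
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start[-1] < ev$end[-nrow(ev)])) {
      abort("overlapping events on one locus", "overlapping_events_error")
    }
  }
  invisible(NULL)
}

#' Expected per-bin read counts of the simulator's forward model
#'
#' The noise-free mean inverted by the profiling stage: bin `i` receives an
#' expected count proportional to
#' `bin_length * gc_bias(gc_i) * (tf * c_i + (1 - tf) * 2) / 2`,
#' where `c_i` is the (clonality-weighted) tumor copy number overlapping the
#' bin, rescaled so the expected counts of mappable bins sum exactly to
#' `total_reads`. Unmappable bins have expectation 0.
#'
#' @param genome A `genome_model`.
#' @param events Data frame of events (see [sim_event()]); may be `NULL`.
#' @param config A [sim_config()].
#' @return Numeric vector of expected counts, one per genome bin.
#' @export
expected_bin_counts <- function(genome, events, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "sim_config"))
  validate_events(genome, events)
  bins <- genome$bins
  copies <- rep(2, nrow(bins))
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      hit <- bins$chrom == ev$chrom & bins$start < ev$end & bins$end > ev$start
      if (!any(hit)) next
      ov <- pmin(bins$end[hit], ev$end) - pmax(bins$start[hit], ev$start)
      frac <- ov / (bins$end[hit] - bins$start[hit])
      eff <- ev$clonal_fraction * (ev$copies - 2)
      copies[hit] <- copies[hit] + frac * eff
    }
  }
  tf <- config$tumor_fraction
  mult <- (bins$end - bins$start) / genome$bin_width *
    gc_bias_curve(bins$gc, config$gc_bias) *
    (tf * copies + (1 - tf) * 2) / 2
  mult[!bins$mappable] <- 0
  mult / sum(mult) * config$total_reads
}

#' Simulate a binned plasma read-count profile
#'
#' Draws per-bin counts around [expected_bin_counts()] (Poisson, or negative
#' binomial when the configuration is overdispersed) and wraps them as a
#' [cn_profile] ready for the profiling pipeline. Deterministic given
#' `config$seed`.
#'
#' @inheritParams expected_bin_counts
#' @param sample_id Sample identifier carried in the profile.
#' @param timepoint Optional `"pre"`/`"post"` label.
#' @return A `cn_profile` with raw counts.
#' @export
simulate_counts <- function(genome, events, config, sample_id = "sim",
                            timepoint = NA_character_) {
  mu <- expected_bin_counts(genome, events, config)
  counts <- with_stream(config$seed, paste0("counts/", sample_id), {
    if (config$overdispersion > 0) {
      rnbinom(length(mu), size = 1 / config$overdispersion, mu = mu)
    } else {
      rpois(length(mu), mu)
    }
  })
  bins <- genome$bins
  bins$count <- counts
  new_cn_profile(bins, sample_id = sample_id, timepoint = timepoint)
}

#' Simulate a healthy-control panel
#'
#' Controls are tumor-free (`tf = 0`) libraries used to normalize position
#' effects. Default read depths are drawn uniformly from the observed range
#' of a 10-donor healthy panel sequenced at ~6.9M reads.
#'
#' @param genome A `genome_model`.
#' @param n Number of control samples (>= 1).
#' @param config A [sim_config()]; its `tumor_fraction` is ignored (forced
#'   to 0) and its seed splits into one stream per control.
#' @param reads_range Length-2 numeric range the per-control total reads are
#'   drawn from.
#' @return List of `n` raw-count `cn_profile` objects.
#' @export
simulate_control_panel <- function(genome, n = 10, config = sim_config(),
                                   reads_range = c(6833913, 6981005)) {
  if (n < 1) abort("`n` must be >= 1", "invalid_config_error")
  lapply(seq_len(n), function(i) {
    reads <- with_stream(config$seed, paste0("panel-depth/", i),
                         runif(1, reads_range[1], reads_range[2]))
    cfg <- sim_config(tumor_fraction = 0, total_reads = reads,
                      gc_bias = config$gc_bias,
                      overdispersion = config$overdispersion,
                      seed = derive_seed(config$seed, paste0("panel/", i)))
    simulate_counts(genome, NULL, cfg, sample_id = sprintf("control_%02d", i))
  })
}
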
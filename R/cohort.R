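#' Droplet digital PCR positivity call
#'
#' An assay is positive iff it measured strictly more than 1 mutant-allele
#' copy per mL of plasma.
#'
#' @param copies_per_ml Non-negative copies/mL (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' call_ddpcr(c(1.1, 1.0, 0)) # TRUE FALSE FALSE
call_ddpcr <- function(copies_per_ml) {
  if (!is.numeric(copies_per_ml) || anyNA(copies_per_ml) ||
      any(copies_per_ml < 0)) {
    abort("`copies_per_ml` must be non-negative", "invalid_ddpcr_error")
  }
  copies_per_ml > 1
}

#' Resistance-related gene list
#'
#' Direction-aware gene sets defining which focal SCNAs count as
#' resistance-related (rrSCNAs): genes whose focal amplification, or whose
#' focal deletion, has been associated with resistance to osimertinib. The
#' defaults are the genes observed as rrSCNAs in the reference cohort; both
#' sets are user-overridable since any literature-derived list evolves.
#'
#' @param amplification Genes counted when focally amplified.
#' @param deletion Genes counted when focally deleted.
#' @return Object of class `rrscna_gene_list`.
#' @export
rrscna_gene_list <- function(amplification = c("EGFR", "ERBB2", "MET",
                                               "CDK4", "CDK6", "MDM2",
                                               "AKT2", "PIK3CA"),
                             deletion = c("CDKN2A", "RB1")) {
  if (length(amplification) + length(deletion) == 0) {
    abort("gene list must not be empty", "invalid_gene_list_error")
  }
  structure(list(amplification = amplification, deletion = deletion),
            class = "rrscna_gene_list")
}

#' Classify focal events as resistance-related SCNAs
#'
#' Intersects the gene content of focal amplifications with the
#' amplification gene set and of focal deletions with the deletion gene
#' set; the union is returned deduplicated and sorted. The classification
#' is idempotent and independent of event order.
#'
#' @param events A `focal_events` data frame (genes comma-joined per event).
#' @param gene_list An [rrscna_gene_list()].
#' @return Sorted character vector of rrSCNA gene names.
#' @export
classify_rrscna <- function(events, gene_list = rrscna_gene_list()) {
  if (is.null(events) || nrow(events) == 0) return(character(0))
  split_genes <- function(g) unlist(strsplit(g, ",", fixed = TRUE))
  amp <- split_genes(events$genes[events$direction == "amplification"])
  del <- split_genes(events$genes[events$direction == "deletion"])
  sort(unique(c(intersect(amp, gene_list$amplification),
                intersect(del, gene_list$deletion))))
}

#' Patient evaluability gate
#'
#' A patient is excluded from outcome analyses when the presence of
#' rrSCNAs cannot be ruled out: the pre-treatment tumor fraction is below
#' 5% (a censored "<3.0%" value counts as below) AND no SCNAs of any kind
#' were detected in the pre-treatment sample. Patients with SCNAs are
#' evaluable regardless of TF.
#'
#' @param tf Pre-treatment tumor fraction (fraction, `NA` allowed only when
#'   censored).
#' @param any_scna Logical: any focal SCNA detected pre-treatment.
#' @param tf_censored Logical: TF reported as "<3.0%".
#' @param threshold Evaluability TF threshold (default 0.05).
#' @return Logical vector: `TRUE` = evaluable.
#' @export
assess_evaluability <- function(tf, any_scna, tf_censored = FALSE,
                                threshold = 0.05) {
  n <- max(length(tf), length(any_scna))
  tf <- rep_len(tf, n)
  any_scna <- rep_len(any_scna, n)
  tf_censored <- rep_len(tf_censored, n)
  if (any(is.na(tf) & !tf_censored)) {
    abort("`tf` missing for an uncensored sample", "missing_tf_error")
  }
  low_tf <- tf_censored | (!is.na(tf) & tf < threshold)
  !(low_tf & !any_scna)
}

# ---- cohort table dialects ----------------------------------------------

parse_tf_percent <- function(s) {
  censored <- grepl("^<", s)
  value <- suppressWarnings(as.numeric(sub("%", "", sub("^<", "", s)))) / 100
  value[censored] <- NA_real_
  list(value = value, censored = censored)
}

render_tf_percent <- function(value, censored) {
  ifelse(censored, "<3.0%", sprintf("%.1f%%", 100 * value))
}

parse_mutation_string <- function(s) {
  lapply(s, function(one) {
    if (is.na(one) || one == "-" || one == "") return(character(0))
    trimws(unlist(strsplit(one, ",", fixed = TRUE)))
  })
}

render_mutation_string <- function(muts) {
  vapply(muts, function(m) if (length(m) == 0) "-"
         else paste(m, collapse = ", "), character(1))
}

parse_rrscna_string <- function(s) {
  lapply(s, function(one) {
    if (is.na(one) || one == "No rrSCNAs" || one == "") return(character(0))
    trimws(unlist(strsplit(one, ",", fixed = TRUE)))
  })
}

render_rrscna_string <- function(genes) {
  vapply(genes, function(g) if (length(g) == 0) "No rrSCNAs"
         else paste(g, collapse = ", "), character(1))
}

ACTIVATING_ASSAYS <- c("del19", "L858R", "L861Q")

#' Read a cohort table
#'
#' Two strict TSV dialects are supported. `"mutations"`: one row per
#' patient with pre- and post-treatment EGFR mutation strings (comma
#' separated assay names, `-` for none detected), rrSCNA gene lists
#' (`No rrSCNAs` for none) and tumor fractions rendered as percentages with
#' `<3.0%` censoring. `"ddpcr"`: one row per patient with pre-treatment
#' activating and T790M copies/mL, tumor fraction, a `Yes`/`No` SCNA flag
#' and a `yes`/`no` exclusion flag.
#'
#' @param path TSV file path.
#' @param dialect `"mutations"` or `"ddpcr"`.
#' @return A data frame with parsed columns; mutation and gene lists are
#'   list-columns, tumor fractions are split into a numeric fraction plus a
#'   censoring flag.
#' @export
read_cohort <- function(path, dialect = c("mutations", "ddpcr")) {
  dialect <- match.arg(dialect)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (dialect == "mutations") {
    need <- c("patient", "pre_egfr_mutation", "pre_rrscna",
              "pre_tumor_fraction", "post_egfr_mutation", "post_rrscna",
              "post_tumor_fraction")
    if (!all(need %in% names(tab))) {
      abort("mutations dialect requires columns: patient, pre/post mutation, rrSCNA and tumor-fraction",
            "invalid_cohort_error")
    }
    pre_tf <- parse_tf_percent(tab$pre_tumor_fraction)
    post_tf <- parse_tf_percent(tab$post_tumor_fraction)
    out <- data.frame(patient = tab$patient, stringsAsFactors = FALSE)
    out$pre_mutations <- parse_mutation_string(tab$pre_egfr_mutation)
    out$pre_rrscna <- parse_rrscna_string(tab$pre_rrscna)
    out$pre_tf <- pre_tf$value
    out$pre_tf_censored <- pre_tf$censored
    out$post_mutations <- parse_mutation_string(tab$post_egfr_mutation)
    out$post_rrscna <- parse_rrscna_string(tab$post_rrscna)
    out$post_tf <- post_tf$value
    out$post_tf_censored <- post_tf$censored
    out
  } else {
    need <- c("patient", "activating_copies_per_ml", "t790m_copies_per_ml",
              "tumor_fraction", "scna", "flagged")
    if (!all(need %in% names(tab))) {
      abort("ddpcr dialect requires columns: patient, copies/mL, tumor_fraction, scna, flagged",
            "invalid_cohort_error")
    }
    if (!all(tab$scna %in% c("Yes", "No"))) {
      abort("`scna` must be Yes/No", "invalid_cohort_error")
    }
    tf <- parse_tf_percent(tab$tumor_fraction)
    data.frame(patient = tab$patient,
               activating_copies = tab$activating_copies_per_ml,
               t790m_copies = tab$t790m_copies_per_ml,
               tf = tf$value, tf_censored = tf$censored,
               any_scna = tab$scna == "Yes",
               flagged_excluded = tab$flagged == "yes",
               stringsAsFactors = FALSE)
  }
}

#' Write a cohort table in the mutations dialect
#'
#' Inverse of [read_cohort()] for the `"mutations"` dialect; censored
#' tumor fractions round-trip as `<3.0%`.
#'
#' @param cohort Parsed cohort data frame (mutations dialect).
#' @param path Output TSV path.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    patient = cohort$patient,
    pre_egfr_mutation = render_mutation_string(cohort$pre_mutations),
    pre_rrscna = render_rrscna_string(cohort$pre_rrscna),
    pre_tumor_fraction = render_tf_percent(cohort$pre_tf,
                                           cohort$pre_tf_censored),
    post_egfr_mutation = render_mutation_string(cohort$post_mutations),
    post_rrscna = render_rrscna_string(cohort$post_rrscna),
    post_tumor_fraction = render_tf_percent(cohort$post_tf,
                                            cohort$post_tf_censored),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble per-patient records from the two cohort dialects
#'
#' Joins the mutation/rrSCNA table with the ddPCR/TF table by patient and
#' applies the evaluability gate.
#'
#' @param mutations Parsed `"mutations"`-dialect data frame.
#' @param ddpcr Parsed `"ddpcr"`-dialect data frame.
#' @return A `patient_records` data frame (one row per patient) with
#'   list-columns for mutations and rrSCNA genes and an `evaluable` flag.
#' @export
build_patient_records <- function(mutations, ddpcr) {
  idx <- match(mutations$patient, ddpcr$patient)
  if (anyNA(idx)) {
    abort("patients missing from the ddPCR table", "invalid_cohort_error")
  }
  ddpcr <- ddpcr[idx, , drop = FALSE]
  rec <- mutations
  rec$activating_copies <- ddpcr$activating_copies
  rec$t790m_copies <- ddpcr$t790m_copies
  rec$any_scna_pre <- ddpcr$any_scna
  rec$evaluable <- assess_evaluability(rec$pre_tf, rec$any_scna_pre,
                                       rec$pre_tf_censored)
  class(rec) <- c("patient_records", "data.frame")
  rec
}

censored_values <- function(value, censored, policy_value = 0.029) {
  ifelse(censored, policy_value, value)
}

has_any <- function(mut_list, assays) {
  vapply(mut_list, function(m) any(m %in% assays), logical(1))
}

#' Cohort-level summary counts and medians
#'
#' Reproduces the headline counts of the cohort: evaluable and excluded
#' patients, pre-treatment rrSCNA carriers, per-assay mutation detection at
#' both timepoints, patients simultaneously positive for an activating
#' mutation, T790M and C797S after progression, C797S carriers who also
#' harbor rrSCNAs, and tumor-fraction medians by rrSCNA status (censored
#' values entering at the 2.9% policy value, which lies below both group
#' medians).
#'
#' @param records A `patient_records` data frame.
#' @return Object of class `cohort_summary` (a list of counts/medians).
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0) abort("no records", "invalid_cohort_error")
  rr_pre <- lengths(records$pre_rrscna) > 0
  rr_post <- lengths(records$post_rrscna) > 0
  act_pre <- has_any(records$pre_mutations, ACTIVATING_ASSAYS)
  act_post <- has_any(records$post_mutations, ACTIVATING_ASSAYS)
  t790m_pre <- has_any(records$pre_mutations, "T790M")
  t790m_post <- has_any(records$post_mutations, "T790M")
  c797s_pre <- has_any(records$pre_mutations, "C797S")
  c797s_post <- has_any(records$post_mutations, "C797S")
  tf_pre <- censored_values(records$pre_tf, records$pre_tf_censored)

  structure(list(
    n_patients = nrow(records),
    n_evaluable = sum(records$evaluable),
    n_excluded = sum(!records$evaluable),
    n_pre_rrscna = sum(rr_pre & records$evaluable),
    pre = c(activating = sum(act_pre), t790m = sum(t790m_pre),
            c797s = sum(c797s_pre)),
    post = c(activating = sum(act_post), t790m = sum(t790m_post),
             c797s = sum(c797s_post)),
    n_triple_positive_post = sum(act_post & t790m_post & c797s_post),
    n_c797s_with_rrscna_post = sum(c797s_post & rr_post),
    median_tf_rrscna = median(tf_pre[rr_pre]),
    median_tf_no_rrscna_evaluable =
      median(tf_pre[!rr_pre & records$evaluable])
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients (%d evaluable, %d excluded)\n",
              x$n_patients, x$n_evaluable, x$n_excluded))
  cat(sprintf("  pre-treatment rrSCNAs: %d of %d evaluable\n",
              x$n_pre_rrscna, x$n_evaluable))
  cat(sprintf("  detection pre:  activating %d, T790M %d, C797S %d\n",
              x$pre["activating"], x$pre["t790m"], x$pre["c797s"]))
  cat(sprintf("  detection post: activating %d, T790M %d, C797S %d\n",
              x$post["activating"], x$post["t790m"], x$post["c797s"]))
  cat(sprintf("  triple-positive post: %d; C797S with rrSCNAs: %d\n",
              x$n_triple_positive_post, x$n_c797s_with_rrscna_post))
  cat(sprintf("  median TF: rrSCNA %.1f%%, no rrSCNA %.1f%%\n",
              100 * x$median_tf_rrscna,
              100 * x$median_tf_no_rrscna_evaluable))
  invisible(x)
}

#' Paths to the bundled reference-cohort fixtures
#'
#' Per-patient values of a published 43-patient osimertinib cohort
#' (pre/post EGFR mutation calls, rrSCNA gene lists, tumor fractions, and
#' pre-treatment ddPCR copy numbers with the SCNA and exclusion flags),
#' shipped as plain TSV in the two cohort dialects.
#'
#' @param which `"mutations"` or `"ddpcr"`.
#' @return File path.
#' @export
cohort_fixture_path <- function(which = c("mutations", "ddpcr")) {
  which <- match.arg(which)
  file <- switch(which,
                 mutations = "cohort_mutations_rrscna.tsv",
                 ddpcr = "cohort_ddpcr_tf.tsv")
  system.file("extdata", file, package = "plasmaSCNA", mustWork = TRUE)
}
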
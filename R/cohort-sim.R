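#' Simulate a paired-sample clinical cohort
#'
#' Generates per-patient records with the statistical structure the
#' cohort-level analysis assumes: a latent rrSCNA status with configurable
#' prevalence; pre- and post-treatment tumor fractions drawn log-normally
#' around the group medians observed in plasma cohorts (about 17% for
#' rrSCNA carriers, about 5% otherwise); ddPCR copy numbers of the
#' activating EGFR mutation and T790M coupled to the pre-treatment TF
#' through a shared latent Gaussian factor calibrated to a target Spearman
#' correlation; a response indicator with a lower response probability for
#' rrSCNA carriers; and exponential progression-free and overall survival
#' times whose hazard is multiplied by `hr_rrscna` (PFS) and `hr_os` (OS)
#' for rrSCNA-positive patients, administratively censored at the follow-up
#' horizon. Null clinical covariates (age, sex, metastases, tissue
#' genotype, prior TKI therapy) are drawn with realistic marginals.
#'
#' @param n_patients Number of patients (>= 2).
#' @param rr_prevalence rrSCNA prevalence in `(0, 1)`.
#' @param hr_rrscna PFS hazard ratio of rrSCNA-positive patients (> 0).
#' @param hr_os OS hazard ratio of rrSCNA-positive patients.
#' @param seed Integer master seed; the cohort is deterministic given it.
#' @param target_rho Target Spearman correlation between activating-copies
#'   and TF.
#' @param response_prob Response probabilities `c(no_rr, rr)`.
#' @param median_pfs,median_os Baseline (rrSCNA-negative) median survival
#'   in months.
#' @param followup Administrative censoring horizon in months.
#' @return A `simulated_cohort` data frame, one row per patient.
#' @export
simulate_cohort <- function(n_patients,
                            rr_prevalence = 10 / 31,
                            hr_rrscna = 3.33,
                            hr_os = 2.54,
                            seed = 1,
                            target_rho = 0.46,
                            response_prob = c(no_rr = 0.81, rr = 0.50),
                            median_pfs = 10.4,
                            median_os = 18.7,
                            followup = 38.4) {
  if (n_patients < 2) abort("`n_patients` must be >= 2",
                            "invalid_cohort_error")
  if (rr_prevalence <= 0 || rr_prevalence >= 1) {
    abort("`rr_prevalence` must lie in (0, 1)", "invalid_cohort_error")
  }
  if (hr_rrscna <= 0 || hr_os <= 0) {
    abort("hazard ratios must be > 0", "invalid_cohort_error")
  }

  with_stream(seed, "cohort", {
    n <- n_patients
    rr <- runif(n) < rr_prevalence

    # group-wise log-normal TF, clipped to the plausible plasma range
    tf_pre <- exp(rnorm(n, mean = ifelse(rr, log(0.17), log(0.051)),
                        sd = 0.45))
    tf_pre <- pmin(pmax(tf_pre, 0.005), 0.6)
    tf_post <- pmin(pmax(tf_pre * exp(rnorm(n, 0, 0.5)), 0.005), 0.6)

    # bivariate-normal latent coupling: Spearman rho_s of a Gaussian copula
    # with correlation r is (6/pi) asin(r/2), inverted here
    r <- 2 * sin(pi * target_rho / 6)
    z_tf <- scale(log(tf_pre))[, 1L]
    act_copies <- round(exp(3.5 + 2.2 * (r * z_tf +
                                           sqrt(1 - r^2) * rnorm(n))), 1)
    r2 <- 2 * sin(pi * 0.30 / 6)
    t790m_copies <- round(exp(2.5 + 1.8 * (r2 * z_tf +
                                             sqrt(1 - r2^2) * rnorm(n))), 1)

    response <- runif(n) < ifelse(rr, response_prob[["rr"]],
                                  response_prob[["no_rr"]])

    pfs_raw <- rexp(n, rate = log(2) / median_pfs *
                      ifelse(rr, hr_rrscna, 1))
    os_raw <- rexp(n, rate = log(2) / median_os * ifelse(rr, hr_os, 1))
    pfs_event <- pfs_raw <= followup
    os_event <- os_raw <= followup

    rr_genes <- rrscna_gene_list()$amplification
    cohort <- data.frame(
      patient = sprintf("P%04d", seq_len(n)),
      rrscna = rr,
      rrscna_genes = vapply(seq_len(n), function(i) {
        if (!rr[i]) return("")
        paste(sample(rr_genes, sample(1:2, 1)), collapse = ",")
      }, character(1)),
      tf_pre = tf_pre,
      tf_post = tf_post,
      activating_copies = act_copies,
      t790m_copies = t790m_copies,
      response = response,
      pfs_months = pmin(pfs_raw, followup),
      pfs_event = pfs_event,
      os_months = pmin(os_raw, followup),
      os_event = os_event,
      age = pmin(pmax(round(rnorm(n, 66, 9)), 40), 90),
      sex = sample(c("female", "male"), n, replace = TRUE,
                   prob = c(0.65, 0.35)),
      metastases = sample(c("M1a", "M1b"), n, replace = TRUE,
                          prob = c(0.19, 0.81)),
      genotype = sample(c("del19", "L858R", "L861Q"), n, replace = TRUE,
                        prob = c(0.68, 0.26, 0.06)),
      prior_tki = sample(c("afatinib", "erlotinib", "gefitinib",
                           "multiple"), n, replace = TRUE,
                         prob = c(0.42, 0.10, 0.32, 0.16)),
      stringsAsFactors = FALSE
    )
    structure(cohort, class = c("simulated_cohort", "data.frame"),
              seed = seed, hr_rrscna = hr_rrscna, hr_os = hr_os)
  })
}
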
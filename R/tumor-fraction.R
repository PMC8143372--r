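#' Estimate tumor fraction from a 1 Mb log2 profile
#'
#' A desk-scale hidden-state estimator of the tumor fraction (TF) of a
#' plasma sample from its control-normalized log2 ratios at 1 Mb
#' resolution. For each candidate TF on a grid, bins are modeled by a
#' 7-state chain (integer copy numbers 0-6) with Gaussian emissions
#' centered at [expected_log2()] of each state, a shared emission SD
#' estimated robustly from the data (median absolute deviation), sticky
#' transitions (self-transition probability `self_prob`) reflecting that
#' 1 Mb events span many bins, and a per-bin state prior `exp(-lambda *
#' |c - 2|)` expressing that aberrations are parsimonious relative to the
#' diploid state. The reported TF maximizes the joint (Viterbi) log score
#' of the best state path; ties break toward the smaller TF, so a flat
#' profile is called at the grid floor.
#'
#' This is deliberately not a reimplementation of full ichorCNA (no
#' subclonal states, ploidy search or panel-of-normals correction); it
#' shares its contract - a TF estimate with a per-bin copy-state path and a
#' 3% detection gate - and is validated by parameter-recovery properties.
#'
#' @param profile A 1 Mb `cn_profile` with `log2` ratios (or a plain
#'   numeric vector of log2 ratios).
#' @param grid_step TF grid step (default 0.005).
#' @param tf_max Upper end of the TF grid (default 0.6).
#' @param max_copies Largest modeled copy state (default 6).
#' @param self_prob Self-transition probability (default 0.99).
#' @param state_penalty Prior penalty `lambda` per unit of `|c - 2|`.
#' @param min_bins Minimum usable bins required (default 50).
#' @param sd_floor Lower bound of the emission SD.
#' @param log2_floor Clip for the state-0 emission mean.
#' @param center `"mode"` (default) recenters the log2 ratios at their
#'   density mode before estimation, so the copy-neutral level sits at 0
#'   even when large aberrations have shifted the total-count
#'   normalization; assumes most of the genome is copy-neutral. `"none"`
#'   disables recentering.
#' @param mask_outliers Exclude isolated extreme bins (residual from a
#'   5-bin running median beyond `max(6 MAD, 0.3)`) before fitting
#'   (default `TRUE`). High-copy focal amplifications spanning one or two
#'   1 Mb bins carry a regionally elevated tumor fraction and would
#'   otherwise hijack the genome-wide estimate; resolving such events is
#'   the job of the 50 kb focal caller, not the TF estimator.
#' @return Object of class `tf_estimate`: list with `tf`, `detectable`
#'   (`tf >= 0.03`), `state_path` (one copy state per fitted bin),
#'   `log_likelihood` (joint Viterbi score of path and data, including the
#'   state prior), `censored_label`, `sigma`, `n_bins`, `grid_step`, and
#'   `used` (which usable input bins entered the fit after outlier
#'   masking; `state_path` aligns with them).
#' @export
estimate_tf <- function(profile, grid_step = 0.005, tf_max = 0.6,
                        max_copies = 6L, self_prob = 0.99,
                        state_penalty = 0.5, min_bins = 50,
                        sd_floor = 1e-3, log2_floor = -8,
                        center = c("mode", "none"), mask_outliers = TRUE) {
  center <- match.arg(center)
  x <- if (inherits(profile, "cn_profile")) {
    if (is.null(profile$log2)) {
      abort("profile has no log2 ratios", "missing_stage_error")
    }
    profile$log2[profile$usable & !is.na(profile$log2)]
  } else {
    as.numeric(profile[!is.na(profile)])
  }
  n <- length(x)
  if (n < min_bins) {
    abort(sprintf("tumor-fraction estimation needs >= %d usable bins, got %d",
                  min_bins, n), "too_few_bins_error")
  }
  used <- rep(TRUE, n)
  if (mask_outliers && n >= 5) {
    resid <- x - stats::runmed(x, 5)
    cut <- max(6 * mad(resid), 0.3)
    used <- abs(resid) <= cut
    x <- x[used]
    n <- length(x)
  }
  offset <- 0
  if (center == "mode") {
    d <- stats::density(x, n = 1024)
    offset <- d$x[which.max(d$y)]
    x <- x - offset
  }
  sigma <- max(mad(x), sd_floor)
  states <- 0:max_copies
  l_self <- log(self_prob)
  l_off <- log((1 - self_prob) / max_copies)
  l_init <- -log(length(states))
  prior <- -state_penalty * abs(states - 2)

  grid <- seq(0, tf_max, by = grid_step)
  best <- list(score = -Inf, tf = NA_real_)
  for (tf in grid) {
    means <- expected_log2(tf, states, floor = log2_floor)
    # emission + per-bin prior, states x bins
    em <- vapply(x, function(xi) dnorm(xi, means, sigma, log = TRUE) + prior,
                 numeric(length(states)))
    delta <- l_init + em[, 1L]
    if (n > 1) {
      for (i in 2:n) {
        m1 <- max(delta)
        i1 <- which.max(delta)
        m2 <- max(delta[-i1])
        other <- ifelse(seq_along(delta) == i1, m2, m1)
        delta <- em[, i] + pmax(delta + l_self, other + l_off)
      }
    }
    score <- max(delta)
    if (score > best$score + 1e-9) { # strict improvement: ties keep smaller tf
      best <- list(score = score, tf = tf)
    }
  }

  # recover the Viterbi path for the selected TF
  means <- expected_log2(best$tf, states, floor = log2_floor)
  em <- vapply(x, function(xi) dnorm(xi, means, sigma, log = TRUE) + prior,
               numeric(length(states)))
  delta <- l_init + em[, 1L]
  back <- matrix(0L, nrow = length(states), ncol = n)
  if (n > 1) {
    for (i in 2:n) {
      cand <- outer(delta, rep(l_off, length(states)), `+`)
      diag(cand) <- delta + l_self
      best_prev <- apply(cand, 2L, which.max)
      delta <- em[, i] + cand[cbind(best_prev, seq_along(states))]
      back[, i] <- best_prev
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) {
    for (i in n:2) path[i - 1L] <- back[path[i], i]
  }

  tf <- best$tf
  structure(
    list(tf = tf, detectable = tf >= 0.03, state_path = states[path],
         log_likelihood = max(delta), censored_label = format_tf(tf),
         sigma = sigma, n_bins = n, grid_step = grid_step,
         self_prob = self_prob, state_penalty = state_penalty,
         log2_floor = log2_floor, center_offset = offset, used = used),
    class = "tf_estimate"
  )
}

#' @export
print.tf_estimate <- function(x, ...) {
  cat(sprintf("<tf_estimate> TF = %s (raw %.3f), %sdetectable, %d bins, logLik %.1f\n",
              x$censored_label, x$tf, if (x$detectable) "" else "not ",
              x$n_bins, x$log_likelihood))
  invisible(x)
}

#' Detection gate for focal SCNA calling
#'
#' Focal SCNAs are only reliably detectable when the plasma tumor fraction
#' reaches 3%; samples below the gate are reported with a censored TF.
#'
#' @param tf Tumor fraction in `[0, 1]`.
#' @return Logical: `TRUE` iff `tf >= 0.03`.
#' @export
#' @examples
#' detectable_for_focal(c(0.030, 0.029, 0)) # TRUE FALSE FALSE
detectable_for_focal <- function(tf) {
  if (!is.numeric(tf) || anyNA(tf) || any(tf < 0 | tf > 1)) {
    abort("`tf` must lie in [0, 1]", "invalid_tf_error")
  }
  tf >= 0.03
}

#' Render a tumor fraction in the censored cohort-table dialect
#'
#' Values below the 3% detection gate print as `"<3.0%"`; others as a
#' one-decimal percentage.
#'
#' @param tf Tumor fraction(s) in `[0, 1]`.
#' @return Character vector.
#' @export
#' @examples
#' format_tf(c(0.424, 0.02)) # "42.4%" "<3.0%"
format_tf <- function(tf) {
  ifelse(detectable_for_focal(tf), sprintf("%.1f%%", 100 * tf), "<3.0%")
}
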
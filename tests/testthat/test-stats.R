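test_that("chi-square on 2x2 tables matches the closed form", {
  res <- chi_square_2x2(matrix(c(17, 4, 5, 5), 2, byrow = TRUE))
  expect_equal(round(res$p_value, 2), 0.08)

  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag$statistic, 20)

  # closed-form identity N(ad-bc)^2 / (r1 r2 c1 c2) on random tables
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rpois(4, 8) + 1, 2)
    res <- chi_square_2x2(m)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    expect_equal(res$statistic,
                 n * (a * d - b * c)^2 /
                   (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2])))
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "zero_margin_error")
})

test_that("Fisher p equals brute-force hypergeometric enumeration", {
  brute_fisher <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    a_range <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(a_range, r1, n - r1, c1)
    p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(2)
  tables <- c(list(matrix(c(1, 9, 9, 1), 2, byrow = TRUE),
                   matrix(c(5, 5, 5, 5), 2),
                   matrix(c(17, 4, 5, 5), 2, byrow = TRUE)),
              lapply(1:15, function(i) matrix(rpois(4, 6), 2)))
  for (m in tables) {
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m)$p_value, brute_fisher(m),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # symmetry: row order does not change the two-sided p
  m <- matrix(c(3, 8, 9, 2), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(m)$p_value,
               fisher_exact_2x2(m[2:1, ])$p_value)
})

test_that("Mann-Whitney handles exact small samples and degenerate input", {
  # full separation of n=m=3: U = 0, one-sided p 1/20, two-sided 1/10
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$U), 0)
  # enumeration: P(U <= 0) = 1/C(6,3) = 1/20 one-sided, doubled
  expect_equal(res$p_value, 2 / choose(6, 3))

  same <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "empty_sample_error")
})

test_that("pre and post tumor fractions do not differ in the fixture", {
  mut <- read_cohort(cohort_fixture_path("mutations"), "mutations")
  pre <- ifelse(mut$pre_tf_censored, 0.029, mut$pre_tf)
  post <- ifelse(mut$post_tf_censored, 0.029, mut$post_tf)
  expect_gt(mann_whitney_u(pre, post)$p_value, 0.05)
})

test_that("Spearman correlation applies the censoring policy", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  expect_error(spearman_rho(1:5, 1:4), class = "length_mismatch_error")
  expect_error(spearman_rho(1:3, 1:3), class = "too_few_values_error")

  dd <- read.delim(cohort_fixture_path("ddpcr"), check.names = FALSE)
  res <- spearman_rho(dd$activating_copies_per_ml, dd$tumor_fraction)
  expect_equal(round(res$rho, 2), 0.46)
  expect_lt(res$p_value, 0.01)
})

test_that("Kaplan-Meier medians follow the product-limit definition", {
  expect_equal(km_median(rep(5, 4), rep(1, 4))$median, 5)
  # S(t) = 0.75, 0.50, 0.25, 0 -> first time S <= 0.5 is t = 2
  expect_equal(km_median(1:4, rep(1, 4))$median, 2)
  allc <- km_median(1:4, rep(0, 4))
  expect_false(allc$defined)
  expect_true(is.na(allc$median))
  # without censoring the KM curve is the empirical survival function
  set.seed(3)
  tt <- rexp(40)
  fit <- km_median(tt, rep(1, 40))$fit
  expect_equal(fit$surv, 1 - seq_along(sort(tt)) / 40)
})

test_that("log-rank matches a hand-computed risk-set tally", {
  # groups fully separated in time: a = {1,2,3}, b = {10,11,12}, all events
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1, 6)
  group <- rep(c("a", "b"), each = 3)
  # observed events in a: 3; expected under H0 summed over risk sets:
  # 3/6 + 2/5 + 1/4 = 1.15; variance terms hand-derived below
  o_minus_e <- 3 - (3 / 6 + 2 / 5 + 1 / 4)
  v <- (3 * 3 / 36) * 1 + (2 * 3 / 25) * 1 + (1 * 3 / 16) * 1
  res <- logrank_test(time, event, group)
  expect_equal(res$statistic, o_minus_e^2 / v, tolerance = 1e-9)

  ident <- logrank_test(c(time, time), c(event, event),
                        rep(c("a", "b"), each = 6))
  expect_equal(ident$statistic, 0, tolerance = 1e-9)
  expect_equal(logrank_test(1:4, rep(0, 4), c("a", "a", "b", "b"))$p_value, 1)
})

test_that("Cox fits report Wald inference and reject degenerate input", {
  co <- simulate_cohort(300, seed = 41)
  fit <- cox_fit(co, "pfs_months", "pfs_event", c("rrscna", "age"))
  expect_s3_class(fit, "cox_result")
  expect_true(all(fit$coefficients$ci_low <= fit$coefficients$hr &
                    fit$coefficients$hr <= fit$coefficients$ci_high))
  expect_true(all(fit$coefficients$hr > 0))
  expect_false(fit$flagged)

  co$const <- 1
  expect_error(cox_fit(co, "pfs_months", "pfs_event", "const"),
               class = "constant_covariate_error")
})

test_that("partial-likelihood score vanishes at the reported optimum", {
  co <- simulate_cohort(250, seed = 17)
  fit <- cox_fit(co, "pfs_months", "pfs_event", c("rrscna", "age", "tf_pre"))
  X <- cbind(rrscna = as.numeric(co$rrscna), age = co$age,
             tf_pre = co$tf_pre)
  g <- efron_score(fit$coefficients$coef, co$pfs_months,
                   as.integer(co$pfs_event), X)
  expect_lt(max(abs(g)), 1e-6)
})

test_that("Cox confidence intervals attain nominal coverage for a null covariate", {
  hits <- 0L
  reps <- 100L
  for (i in seq_len(reps)) {
    co <- simulate_cohort(500, hr_rrscna = 1.8, seed = 9000 + i)
    fit <- cox_fit(co, "os_months", "os_event", "age") # age is null
    row <- fit$coefficients[1, ]
    if (row$ci_low <= 1 && 1 <= row$ci_high) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("stepwise backward elimination behaves at its boundaries", {
  co <- simulate_cohort(400, seed = 23)
  covs <- c("rrscna", "age", "sex", "tf_pre")

  # p_remove = 1: nothing is removable, the full model is returned
  full <- stepwise_backward(co, "pfs_months", "pfs_event", covs,
                            p_remove = 1)
  expect_setequal(full$retained, covs)

  # the strong covariate survives the default threshold
  sel <- stepwise_backward(co, "pfs_months", "pfs_event", covs)
  expect_true("rrscna" %in% sel$retained)

  # all-null model: elimination may empty the retained set without error
  null_co <- simulate_cohort(150, hr_rrscna = 1, hr_os = 1, seed = 31)
  res <- stepwise_backward(null_co, "os_months", "os_event",
                           c("age", "sex"), p_remove = 0.001)
  expect_true(length(res$retained) %in% 0:2)
  if (length(res$retained) == 0) expect_equal(nrow(res$coefficients), 0L)
})
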
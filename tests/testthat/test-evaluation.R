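make_cases <- function(plans, ids = sprintf("P%02d", seq_along(plans))) {
  Map(function(p, id) list(patient_id = id, plan = p), plans, ids)
}

test_that("prediction errors are predicted minus planned per endpoint", {
  oc <- oar_config("stem", loss_k = 8, eud_a = 8)
  plans <- list(dvh(rep(50, 100)), linear_dvh(60))
  cases <- make_cases(plans)
  err0 <- prediction_errors(plans, cases, oc)
  expect_equal(err0$eud, c(0, 0))
  expect_equal(err0$dmax, c(0, 0))
  shifted <- lapply(plans, function(p) dvh(as.numeric(p) + 2))
  err2 <- prediction_errors(shifted, cases, oc)
  expect_equal(err2$dmax, c(2, 2), tolerance = 1e-9)
  expect_equal(err2$eud[1], 2, tolerance = 1e-9)
})

test_that("parallel organs report EUD only", {
  oc <- oar_config("parotid", loss_k = 1, eud_a = 1)
  plans <- list(dvh(rep(30, 100)))
  err <- prediction_errors(list(dvh(rep(32, 100))), make_cases(plans), oc)
  expect_equal(err$eud, 2)
  expect_null(err$dmax)
  expect_setequal(unique(err$values$endpoint), "EUD")
})

test_that("missing predictions are rejected naming the patient", {
  oc <- oar_config("stem", loss_k = 8, eud_a = 8)
  cases <- make_cases(list(dvh(rep(50, 100)), dvh(rep(40, 100))))
  preds <- list(P01 = dvh(rep(50, 100)))
  expect_error(prediction_errors(preds, cases, oc), "P02")
})

test_that("mu and sigma use the population denominator", {
  expect_equal(mu_sigma(c(1, -1)), c(mu = 0, sigma = 1))
  expect_equal(mu_sigma(5), c(mu = 5, sigma = 0))
  set.seed(41)
  x <- rnorm(17)
  ms <- mu_sigma(x)
  expect_equal(ms[["sigma"]], sqrt(mean((x - mean(x))^2)))
  # population sigma, strictly smaller than the n-1 sample form
  expect_lt(ms[["sigma"]], sd(x))
  shifted <- mu_sigma(x + 3.2)
  expect_equal(shifted[["mu"]], ms[["mu"]] + 3.2)
  expect_equal(shifted[["sigma"]], ms[["sigma"]])
  expect_error(mu_sigma(numeric(0)), "non-empty")
})

test_that("Wilcoxon handles degenerate and small exact cases", {
  expect_warning(w <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)),
                 "degenerate")
  expect_equal(w$p_value, 1)
  # n = 3 one-sided extreme: all differences positive -> p = 2/8
  w3 <- wilcoxon_signed_rank(c(5, 6, 7), c(1, 2, 3))
  expect_equal(w3$p_value, 0.25)
  expect_equal(w3$method, "exact")
})

test_that("exact Wilcoxon matches brute-force enumeration for n <= 10", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    a <- round(rnorm(n), 2)
    b <- round(rnorm(n), 2)
    got <- suppressWarnings(wilcoxon_signed_rank(a, b))
    expect_equal(got$p_value, brute_wilcoxon_p(a, b), tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is symmetric in the two methods", {
  set.seed(43)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                 wilcoxon_signed_rank(b, a)$p_value, tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with the reference test when tie-free", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- wilcoxon_signed_rank(a, b)$p_value
    ref <- wilcox.test(a - b, exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("normal-approximation branch engages above the exact cutoff", {
  set.seed(45)
  a <- rnorm(40); b <- rnorm(40)
  got <- wilcoxon_signed_rank(a, b)
  expect_equal(got$method, "normal")
  ref <- wilcox.test(a - b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-9)
})

test_that("pooled regression recovers exact and mirrored agreement", {
  p <- pooled_regression(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(p$slope, 1)
  expect_equal(p$intercept, 0)
  expect_equal(p$r, 1)
  expect_equal(pooled_regression(-(1:4), 1:4)$r, -1)
  # closed-form Pearson on {(1,2), (2,3), (3,5)}
  expect_equal(pooled_regression(c(2, 3, 5), c(1, 2, 3))$r,
               3 / sqrt(2 * 14 / 3), tolerance = 1e-9)
  expect_error(pooled_regression(c(1, 2), c(3, 3)), "constant")
})

test_that("correlation is invariant to affine dose rescaling", {
  set.seed(46)
  pred <- runif(30, 20, 60)
  plan <- pred + rnorm(30)
  r0 <- pooled_regression(pred, plan)$r
  r1 <- pooled_regression(2.2 * pred - 5, 0.9 * plan + 3)$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("boxplot statistics follow the interpolated-quantile rule", {
  b <- boxplot_stats(1:7)
  expect_equal(b$median, 4)
  expect_equal(b$q1, 2.5)
  expect_equal(b$q3, 5.5)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 7)
  cst <- boxplot_stats(rep(2, 5))
  expect_equal(cst$q1, cst$q3)
  expect_length(cst$outliers, 0)
  iqr <- b$q3 - b$q1
  b2 <- boxplot_stats(c(1:7, b$q3 + 10 * iqr))
  expect_length(b2$outliers, 1)
  expect_equal(b2$outliers, b$q3 + 10 * iqr)
})

test_that("evaluation reports combine endpoints, tests and pooling", {
  oc <- list(stem = oar_config("stem", 8, 8),
             parotid = oar_config("parotid", 1, 1))
  plans <- list(stem = list(linear_dvh(55), linear_dvh(60), linear_dvh(50)),
                parotid = list(linear_dvh(30), linear_dvh(35),
                               linear_dvh(28)))
  cases <- lapply(plans, make_cases)
  preds <- lapply(plans, function(ps) {
    lapply(ps, function(p) dvh(as.numeric(p) * 1.02))
  })
  rep_ <- evaluate_predictions(preds, cases, oc)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(nrow(rep_$table), 3)  # stem EUD + Dmax, parotid EUD
  expect_true(all(rep_$table$sigma >= 0))
  expect_equal(sort(unique(rep_$scatter$endpoint)), c("Dmax", "EUD"))
  expect_lte(abs(rep_$pooled$r), 1)
  # mu equals difference of endpoint means (linearity)
  stem_vals <- subset(rep_$scatter, oar == "stem" & endpoint == "EUD")
  expect_equal(rep_$table$mu[rep_$table$oar == "stem" &
                               rep_$table$endpoint == "EUD"],
               mean(stem_vals$predicted) - mean(stem_vals$planned),
               tolerance = 1e-12)
  # comparison arm adds paired p-values
  rep2 <- suppressWarnings(
    evaluate_predictions(preds, cases, oc, comparison_by_oar = preds))
  expect_true(all(rep2$table$p_value == 1))
})
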
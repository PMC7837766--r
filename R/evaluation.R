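#' Per-patient endpoint prediction errors
#'
#' For every test patient, `delta_i = predicted endpoint - planned
#' endpoint`, with the gEUD endpoint computed at the organ's exponent `a`
#' and, for serial organs only, the maximum-dose endpoint as well.
#'
#' @param predictions List of predicted [dvh] objects, or a named list
#'   (by `patient_id`) covering every case.
#' @param cases Per-patient `(beams, plan)` case list (see [oar_cases()]).
#' @param oar An [oar_config()].
#' @return List with `eud` (numeric delta vector, Gy, in patient order),
#'   `dmax` (serial organs only), and the endpoint value matrices
#'   `values` (columns: patient, endpoint, planned, predicted).
#' @export
prediction_errors <- function(predictions, cases, oar) {
  stopifnot(inherits(oar, "oar_config"))
  ids <- vapply(cases, function(cs) cs$patient_id %||% "", character(1))
  if (!is.null(names(predictions))) {
    missing <- setdiff(ids, names(predictions))
    if (length(missing) > 0L) {
      stop("no prediction for patient ", missing[1L], call. = FALSE)
    }
    predictions <- predictions[ids]
  }
  if (length(predictions) != length(cases)) {
    stop("got ", length(predictions), " predictions for ", length(cases),
         " cases", call. = FALSE)
  }
  ep <- function(dvh, fun) vapply(dvh, fun, numeric(1))
  plan_eud <- vapply(cases, function(cs) compute_eud(cs$plan, oar$eud_a),
                     numeric(1))
  pred_eud <- ep(predictions, function(d) compute_eud(d, oar$eud_a))
  values <- data.frame(patient = ids, endpoint = "EUD",
                       planned = plan_eud, predicted = pred_eud,
                       row.names = NULL)
  out <- list(eud = pred_eud - plan_eud)
  if (oar$serial) {
    plan_dm <- vapply(cases, function(cs) max_dose(cs$plan), numeric(1))
    pred_dm <- ep(predictions, max_dose)
    out$dmax <- pred_dm - plan_dm
    values <- rbind(values,
                    data.frame(patient = ids, endpoint = "Dmax",
                               planned = plan_dm, predicted = pred_dm,
                               row.names = NULL))
  }
  out$values <- values
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean and population standard deviation of prediction errors
#'
#' `mu = mean(delta)`; `sigma = sqrt(sum((delta - mu)^2) / n)` with the
#' *population* denominator `n` (not `n - 1`), matching the evaluation
#' convention of the method; note this differs from [stats::sd()].
#'
#' @param delta Numeric error vector, `n >= 1`.
#' @return Named numeric vector `c(mu = , sigma = )`, in Gy.
#' @export
mu_sigma <- function(delta) {
  if (length(delta) < 1L || anyNA(delta)) {
    stop("`delta` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  mu <- mean(delta)
  c(mu = mu, sigma = sqrt(sum((delta - mu)^2) / length(delta)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on the paired per-patient errors of two methods. The
#' paired differences are `delta_a - delta_b` (signed errors by default;
#' `absolute = TRUE` pairs `|delta|` instead). Zero differences are
#' discarded; ties in `|d|` receive midranks. For `n <= 15` nonzero pairs
#' the p-value is exact, by enumeration of all `2^n` sign assignments of
#' the observed ranks; above that a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param delta_a,delta_b Equal-length paired error vectors (Gy).
#' @param absolute Compare absolute errors instead of signed errors.
#' @param exact_max Largest `n` for which the exact enumeration is used.
#' @return List with `p_value`, `statistic` (sum of positive ranks `V`),
#'   `n_effective` (nonzero pairs) and `method` (`"exact"` or
#'   `"normal"`).
#' @export
wilcoxon_signed_rank <- function(delta_a, delta_b, absolute = FALSE,
                                 exact_max = 15L) {
  if (length(delta_a) != length(delta_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- if (absolute) abs(delta_a) - abs(delta_b) else delta_a - delta_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; test is degenerate (p = 1)")
    return(list(p_value = 1, statistic = NA_real_, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))   # midranks for ties
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: every sign assignment of the observed ranks equally likely
    stats <- signed_rank_distribution(r)
    tail_ge <- mean(stats >= V)
    tail_le <- mean(stats <= V)
    p <- min(1, 2 * min(tail_ge, tail_le))
    list(p_value = p, statistic = V, n_effective = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(p_value = p, statistic = V, n_effective = n, method = "normal")
  }
}

# all 2^n values of the positive-rank sum over sign assignments
signed_rank_distribution <- function(ranks) {
  n <- length(ranks)
  stats <- 0
  for (r in ranks) stats <- c(stats, stats + r)  # subset-sum expansion
  stats
}

#' Pooled least-squares regression of predicted on planned endpoints
#'
#' Ordinary least squares of the predicted endpoint values on the planned
#' ones, pooled across organs and endpoints, with the Pearson correlation
#' coefficient `r`.
#'
#' @param predicted,planned Numeric vectors of endpoint values (Gy),
#'   `n >= 2`, `planned` non-constant.
#' @return List with `slope`, `intercept`, `r`.
#' @examples
#' pooled_regression(c(2, 3, 5), c(1, 2, 3))
#' @export
pooled_regression <- function(predicted, planned) {
  if (length(predicted) != length(planned) || length(planned) < 2L) {
    stop("need >= 2 paired values", call. = FALSE)
  }
  if (stats::var(planned) == 0) {
    stop("planned values are constant; correlation undefined", call. = FALSE)
  }
  slope <- stats::cov(predicted, planned) / stats::var(planned)
  intercept <- mean(predicted) - slope * mean(planned)
  list(slope = slope, intercept = intercept,
       r = stats::cor(predicted, planned))
}

#' Boxplot summary statistics
#'
#' Quartiles by linear-interpolation quantiles (type 7); whiskers extend to
#' the most extreme observations within `1.5 * IQR` of the box; points
#' beyond the whiskers are outliers.
#'
#' @param delta Numeric vector, `n >= 1`.
#' @return List with `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
boxplot_stats <- function(delta) {
  if (length(delta) < 1L || anyNA(delta)) {
    stop("`delta` must be non-empty without NA", call. = FALSE)
  }
  q <- unname(quantile(delta, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- delta[delta >= lo_fence & delta <= hi_fence]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(delta[delta < lo_fence | delta > hi_fence]))
}

#' Evaluate per-organ predictions over a test set
#'
#' Assembles the full evaluation report: per organ and endpoint the error
#' vector, `mu`, `sigma` (population), optional paired Wilcoxon p-value
#' against a comparison method, and the pooled regression across all
#' organs and endpoints.
#'
#' @param predictions_by_oar Named list (by organ) of prediction lists.
#' @param cases_by_oar Named list (by organ) of test-case lists.
#' @param oar_configs Named list of [oar_config()] objects.
#' @param comparison_by_oar Optional second prediction set (same shape) for
#'   the paired Wilcoxon comparison.
#' @return An `evaluation_report`: `table` (data.frame: oar, endpoint, mu,
#'   sigma, p_value), `scatter` (data.frame: oar, endpoint, patient,
#'   planned, predicted), `deltas` (nested list), and `pooled` (slope,
#'   intercept, r).
#' @export
evaluate_predictions <- function(predictions_by_oar, cases_by_oar,
                                 oar_configs, comparison_by_oar = NULL) {
  oars <- names(predictions_by_oar)
  stopifnot(!is.null(oars), all(oars %in% names(oar_configs)),
            all(oars %in% names(cases_by_oar)))
  rows <- list()
  scatter <- list()
  deltas <- list()
  for (o in oars) {
    oc <- oar_configs[[o]]
    err <- prediction_errors(predictions_by_oar[[o]], cases_by_oar[[o]], oc)
    cmp <- if (!is.null(comparison_by_oar)) {
      prediction_errors(comparison_by_oar[[o]], cases_by_oar[[o]], oc)
    }
    endpoints <- c("eud", if (oc$serial) "dmax")
    for (ep in endpoints) {
      ms <- mu_sigma(err[[ep]])
      p <- if (!is.null(cmp)) {
        wilcoxon_signed_rank(err[[ep]], cmp[[ep]])$p_value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        oar = o, endpoint = toupper(ep), mu = ms[["mu"]],
        sigma = ms[["sigma"]], p_value = p, row.names = NULL)
    }
    deltas[[o]] <- err[c("eud", if (oc$serial) "dmax")]
    sc <- err$values
    sc <- cbind(oar = o, sc)
    scatter[[length(scatter) + 1L]] <- sc
  }
  scatter <- do.call(rbind, scatter)
  pooled <- pooled_regression(scatter$predicted, scatter$planned)
  structure(list(table = do.call(rbind, rows), scatter = scatter,
                 deltas = deltas, pooled = pooled),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  tab <- x$table
  tab$mu <- sprintf("%.3f", tab$mu)
  tab$sigma <- sprintf("%.3f", tab$sigma)
  print(tab, row.names = FALSE)
  cat(sprintf("pooled: r = %.4f (slope %.3f, intercept %.3f Gy)\n",
              x$pooled$r, x$pooled$slope, x$pooled$intercept))
  invisible(x)
}
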
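test_that("the weighted loss matches hand-computed values", {
  expect_equal(eud_weighted_loss(c(1, 2), c(1, 2), 2), 0)
  # target {1, 2}, predicted {2, 2}, k = 2: s = {1/3, 2/3}, f = 1/3
  expect_equal(eud_weighted_loss(c(2, 2), c(1, 2), 2), 1 / 3)
  expect_error(eud_weighted_loss(c(1, 2, 3), c(1, 2), 2), "shapes differ")
  expect_error(eud_weighted_loss(c(1, 2), c(1, 2), 0), "positive integer")
})

test_that("k = 1 loss is the uniformly weighted MSE to machine precision", {
  set.seed(21)
  for (i in 1:100) {
    n_pat <- sample(1:5, 1)
    n_bin <- sample(2:100, 1)
    target <- matrix(runif(n_pat * n_bin, 0, 70), n_pat)
    pred <- target + matrix(rnorm(n_pat * n_bin), n_pat)
    mse <- mean(rowMeans((pred - target)^2))
    expect_equal(eud_weighted_loss(pred, target, 1), mse,
                 tolerance = 1e-14)
  }
})

test_that("increasing k moves loss mass into the top-dose decile", {
  set.seed(22)
  for (i in 1:20) {
    target <- sort(runif(100, 0, 70), decreasing = TRUE)
    pred <- target + rnorm(100)
    top <- 1:10  # top-dose decile of the sorted target
    frac <- vapply(c(1, 2, 4, 8, 15), function(k) {
      s <- sensitivity_weights(target, k)
      contrib <- s * (pred - target)^2
      sum(contrib[top]) / sum(contrib)
    }, numeric(1))
    expect_true(all(diff(frac) >= -1e-12))
  }
})

test_that("analytic loss gradients match finite differences", {
  set.seed(23)
  # gradient with respect to the predictions (the closed form behind the
  # sensitivity-weighted quadratic)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    target <- runif(n, 1, 70)
    pred <- target + rnorm(n)
    k <- sample(c(1, 2, 8), 1)
    s <- sensitivity_weights(target, k)
    analytic <- 2 * s * (pred - target)
    eps <- 1e-6
    numeric_g <- vapply(seq_len(n), function(j) {
      up <- pred; up[j] <- up[j] + eps
      dn <- pred; dn[j] <- dn[j] - eps
      (eud_weighted_loss(up, target, k) -
         eud_weighted_loss(dn, target, k)) / (2 * eps)
    }, numeric(1))
    expect_equal(numeric_g, analytic, tolerance = 1e-5)
  }
  # backpropagated parameter gradients of the full model
  sp <- model_spec(hidden_size = 4, dropout_p = 0, seed = 31)
  m <- build_model(sp)
  B <- 2; T <- 6
  X <- array(runif(9 * B * T), dim = c(9, B, T))
  Y <- matrix(runif(T * B, 10, 60), T, B)
  S <- apply(matrix(runif(T * B), T, B), 2, function(s) s / sum(s))
  lg <- dvhgru:::cpp_gru_loss_grad(m$theta, X, Y, S, 4, 1, 70)
  eps <- 1e-6
  idx <- seq(1, length(m$theta), by = 7)  # spot-check a parameter subset
  for (i in idx) {
    up <- m$theta; up[i] <- up[i] + eps
    dn <- m$theta; dn[i] <- dn[i] - eps
    fd <- (dvhgru:::cpp_gru_loss_grad(up, X, Y, S, 4, 1, 70)$loss -
             dvhgru:::cpp_gru_loss_grad(dn, X, Y, S, 4, 1, 70)$loss) /
      (2 * eps)
    expect_equal(lg$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("training is deterministic and decreases the loss", {
  co <- tiny_cohort(n = 8)
  tr <- oar_cases(co, "test_oar", co$train)
  m1 <- train_oar_model(tr, tiny_oar(), fast_spec(), fast_cfg(epochs = 30))
  m2 <- train_oar_model(tr, tiny_oar(), fast_spec(), fast_cfg(epochs = 30))
  expect_identical(m1$theta, m2$theta)
  expect_lt(m1$final_loss, m1$loss_history[1])
  expect_length(m1$loss_history, 30)
  expect_equal(m1$k, 2L)  # from the organ config
})

test_that("a diverging run aborts with an epoch diagnostic", {
  co <- tiny_cohort(n = 6)
  tr <- oar_cases(co, "test_oar", co$train)
  expect_error(
    train_oar_model(tr, tiny_oar(), fast_spec(),
                    train_config(learning_rate = 1e300, epochs = 10,
                                 seed = 1)),
    "non-finite at epoch")
})

test_that("early stopping tracks the best validation loss", {
  co <- tiny_cohort(n = 10)
  tr <- oar_cases(co, "test_oar", co$train)
  val <- oar_cases(co, "test_oar", co$test)
  m <- train_oar_model(tr, tiny_oar(), fast_spec(),
                       train_config(epochs = 60, seed = 3, patience = 10),
                       val_cases = val)
  expect_equal(m$best_val, min(m$val_history))
  expect_equal(m$val_history[m$best_epoch], m$best_val)
})

test_that("grid search with a singleton candidate returns it with scores", {
  co <- tiny_cohort(n = 8)
  tr <- oar_cases(co, "test_oar", co$train)
  val <- oar_cases(co, "test_oar", co$test)
  gs <- grid_search_k(tr, tiny_oar(), 1, fast_spec(), fast_cfg(epochs = 15),
                      val_cases = val)
  expect_equal(gs$selected_k, 1L)
  expect_equal(nrow(gs$table), 1)
  expect_error(grid_search_k(tr, tiny_oar(), integer(0), fast_spec(),
                             fast_cfg(), val_cases = val), "non-empty")
})

test_that("the grid-search objective is reproducible from its models", {
  co <- tiny_cohort(n = 10)
  tr <- oar_cases(co, "test_oar", co$train)
  val <- oar_cases(co, "test_oar", co$test)
  oc <- tiny_oar()
  gs <- grid_search_k(tr, oc, c(1, 4), fast_spec(), fast_cfg(epochs = 15),
                      val_cases = val)
  for (row in seq_len(nrow(gs$table))) {
    k <- gs$table$k[row]
    m <- gs$models[[as.character(k)]]
    preds <- predict_dvh(m, lapply(val, `[[`, "beams"))
    err <- prediction_errors(preds, val, oc)
    e <- mu_sigma(err$eud); d <- mu_sigma(err$dmax)
    obj <- abs(e[["mu"]]) + e[["sigma"]] + abs(d[["mu"]]) + d[["sigma"]]
    expect_equal(gs$table$objective[row], obj, tolerance = 1e-12)
  }
})

test_that("the joint baseline trains on pooled organs and predicts DVHs", {
  prof <- c(tiny_profiles(), list(other_oar = list(
    M = 25, w = rep(0.8, 9), gamma = seq(1, 3, length.out = 9),
    c = rep(1 / 9, 9), eta = 0)))
  co <- generate_cohort(cohort_spec(n_patients = 8, seed = 6,
                                    oar_profiles = prof,
                                    train_fraction = 0.6))
  cases_by_oar <- list(
    test_oar = oar_cases(co, "test_oar", co$train),
    other_oar = oar_cases(co, "other_oar", co$train))
  m <- train_previous_baseline(
    cases_by_oar, model_spec(hidden_size = 8, num_layers = 3, seed = 2),
    fast_cfg(epochs = 20))
  expect_equal(m$spec$input_size, 11L)
  expect_equal(m$k, 1L)
  expect_true(all(is.finite(m$loss_history)))
  for (o in names(cases_by_oar)) {
    te <- oar_cases(co, o, co$test)
    preds <- predict_baseline(m, lapply(te, `[[`, "beams"), o)
    for (p in preds) {
      expect_s3_class(p, "dvh")
      expect_true(all(diff(as.numeric(p)) <= 1e-12))
    }
  }
  expect_error(predict_baseline(m, co$cases[[1]]$oars$test_oar$beams,
                                "missing_oar"), "not trained")
})

test_that("the joint k = 1 baseline is no better on serial max dose", {
  oc <- serial_scenario_oar(loss_k = 15)
  sigma_prop <- sigma_base <- numeric(2)
  for (i in 1:2) {
    co <- generate_cohort(serial_scenario(n_patients = 40, seed = 20 + i))
    tr <- oar_cases(co, "serial_oar", co$train)
    te <- oar_cases(co, "serial_oar", co$test)
    prop <- train_oar_model(tr, oc, model_spec(seed = i),
                            train_config(seed = 50 + i))
    base <- train_previous_baseline(
      list(serial_oar = tr), model_spec(num_layers = 3, seed = i),
      train_config(seed = 50 + i))
    sig <- function(preds) {
      mu_sigma(prediction_errors(preds, te, oc)$dmax)[["sigma"]]
    }
    sigma_prop[i] <- sig(predict_dvh(prop, lapply(te, `[[`, "beams")))
    sigma_base[i] <- sig(predict_baseline(base, lapply(te, `[[`, "beams"),
                                          "serial_oar"))
  }
  expect_gte(mean(sigma_base), mean(sigma_prop))
})
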
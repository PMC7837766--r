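#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Number of full-batch epochs (default 500).
#' @param k Loss exponent override; `NULL` (default) takes `loss_k` from
#'   the organ configuration.
#' @param seed Seed for the dropout masks (the parameter initialisation is
#'   seeded by the model spec).
#' @param patience Early-stopping patience in epochs on the validation
#'   loss; `NULL` disables early stopping.
#' @param loss_floor Stop once the (dropout-free) training loss reaches
#'   this value (default 0 = run all epochs).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 500L, k = NULL,
                         seed = 1L, patience = NULL, loss_floor = 0) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (!is.null(k) && (k < 1 || k != round(k))) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 k = if (is.null(k)) NULL else as.integer(k),
                 seed = as.integer(seed),
                 patience = if (is.null(patience)) NULL else
                   as.integer(patience),
                 loss_floor = loss_floor),
            class = "train_config")
}

#' gEUD-weighted mean-squared training loss
#'
#' \deqn{f = \frac{1}{n}\sum_p \sum_i s(D_{pi}, k)\,(D'_{pi} - D_{pi})^2,}
#' where the sensitivity weights `s` ([sensitivity_weights()]) are computed
#' from the *target* doses and `n` is the number of patients. With `k = 1`
#' this is the per-patient-averaged uniformly weighted MSE; larger `k`
#' shifts the loss mass toward the high-dose bins.
#'
#' @param predicted,target Numeric vectors (one patient) or matrices
#'   (patients in rows) of doses in Gy; shapes must match.
#' @param k Positive integer loss exponent.
#' @return Non-negative scalar; zero iff predictions equal targets on every
#'   bin with nonzero weight.
#' @examples
#' eud_weighted_loss(c(2, 2), c(1, 2), k = 2)  # 1/3
#' @export
eud_weighted_loss <- function(predicted, target, k) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1L)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1L)
  if (!identical(dim(predicted), dim(target))) {
    stop("`predicted` and `target` shapes differ: ",
         paste(dim(predicted), collapse = "x"), " vs ",
         paste(dim(target), collapse = "x"), call. = FALSE)
  }
  if (k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  n <- nrow(target)
  total <- 0
  for (p in seq_len(n)) {
    s <- sensitivity_weights(target[p, ], k)
    total <- total + sum(s * (predicted[p, ] - target[p, ])^2)
  }
  total / n
}

# extract the per-patient (beams, plan) pairs of one organ from a cohort
#' Extract one organ's cases from a cohort
#'
#' @param cohort A `cohort` from [generate_cohort()] (or a plain list of
#'   `patient_case` objects).
#' @param oar_name Organ label present in the cases.
#' @param indices Patient indices to keep (default all).
#' @return List of per-patient lists with `patient_id`, `beams`, `plan`.
#' @export
oar_cases <- function(cohort, oar_name, indices = NULL) {
  cases <- if (inherits(cohort, "cohort")) cohort$cases else cohort
  if (is.null(indices)) indices <- seq_along(cases)
  lapply(cases[indices], function(cs) {
    if (!oar_name %in% names(cs$oars)) {
      stop("patient ", cs$patient_id, " has no organ '", oar_name, "'",
           call. = FALSE)
    }
    list(patient_id = cs$patient_id,
         beams = cs$oars[[oar_name]]$beams,
         plan = cs$oars[[oar_name]]$plan)
  })
}

# build (X, Y, S) tensors for the compiled training loop
training_tensors <- function(cases, spec, k, extra = NULL) {
  B <- length(cases)
  X <- feature_array(lapply(cases, `[[`, "beams"), spec, extra)
  Y <- matrix(0, DVH_NBINS, B)
  S <- matrix(0, DVH_NBINS, B)
  for (b in seq_len(B)) {
    y <- as_dose_vector(cases[[b]]$plan)
    s <- sensitivity_weights(y, k)
    if (spec$reverse) { y <- rev(y); s <- rev(s) }
    Y[, b] <- y
    S[, b] <- s
  }
  list(X = X, Y = Y, S = S)
}

#' Train a per-organ DVH prediction model
#'
#' Minimises the gEUD-weighted loss ([eud_weighted_loss()]) with full-batch
#' Adam. Fully deterministic under `(model_spec$seed, cfg$seed)` and a
#' fixed case order. The recorded loss history is the training loss under
#' each epoch's dropout mask; `final_loss` is the dropout-free training
#' loss of the returned parameters.
#'
#' @param cases Per-patient `(beams, plan)` list for one organ, e.g. from
#'   [oar_cases()]; at least 2 cases.
#' @param oar An [oar_config()]; supplies the loss exponent `k` unless
#'   `cfg$k` overrides it.
#' @param spec A [model_spec()].
#' @param cfg A [train_config()].
#' @param val_cases Optional validation cases; enables loss tracking and,
#'   with `cfg$patience`, early stopping on the validation loss (the best
#'   parameters are returned).
#' @return A `trained_model` with `loss_history` (and `val_history` if
#'   validation cases were given).
#' @export
train_oar_model <- function(cases, oar, spec = model_spec(),
                            cfg = train_config(), val_cases = NULL) {
  stopifnot(inherits(oar, "oar_config"), inherits(spec, "model_spec"),
            inherits(cfg, "train_config"))
  if (length(cases) < 2L) {
    stop("need at least 2 training cases", call. = FALSE)
  }
  k <- if (is.null(cfg$k)) oar$loss_k else cfg$k
  tens <- training_tensors(cases, spec, k)
  model <- build_model(spec, oar_name = oar$name)
  vt <- if (!is.null(val_cases)) training_tensors(val_cases, spec, k)
  fit <- cpp_gru_train(
    model$theta, tens$X, tens$Y, tens$S,
    spec$hidden_size, spec$num_layers, spec$dose_norm,
    cfg$learning_rate, cfg$epochs, spec$dropout_p, cfg$seed, cfg$loss_floor,
    if (is.null(vt)) NULL else vt$X,
    if (is.null(vt)) NULL else vt$Y,
    if (is.null(vt)) NULL else vt$S,
    if (is.null(cfg$patience)) -1L else cfg$patience)
  model$theta <- fit$theta
  model$k <- k
  model$epochs_run <- length(fit$train_loss)
  model$final_loss <- fit$final_loss
  model$loss_history <- fit$train_loss
  if (!is.null(vt)) {
    model$val_history <- fit$val_loss
    model$best_epoch <- fit$best_epoch
    model$best_val <- fit$best_val
  }
  model
}

# evaluation-endpoint statistics of a model on held-out cases
endpoint_stats <- function(model, cases, oar, extra = NULL) {
  preds <- predict_dvh(model, lapply(cases, `[[`, "beams"), extra)
  err <- prediction_errors(preds, cases, oar)
  e <- mu_sigma(err$eud)
  out <- list(mu_eud = e[["mu"]], sigma_eud = e[["sigma"]])
  if (oar$serial) {
    d <- mu_sigma(err$dmax)
    out$mu_dmax <- d[["mu"]]
    out$sigma_dmax <- d[["sigma"]]
  }
  out
}

#' Grid search over the loss exponent k
#'
#' Trains one model per candidate `k` and selects the one minimising the
#' composite validation objective
#' `|mu_EUD| + sigma_EUD (+ |mu_Dmax| + sigma_Dmax for serial organs)`,
#' i.e. accurate prediction of both gEUD and (for serial organs) maximum
#' dose. Ties break toward the smaller `k`.
#'
#' @param cases Training cases (one organ), as in [train_oar_model()].
#' @param oar An [oar_config()].
#' @param candidate_ks Non-empty set of positive integers.
#' @param spec,cfg Model and training configuration shared by all arms.
#' @param val_cases Held-out validation cases, disjoint from `cases`.
#' @return List with `selected_k`, `table` (one row per k: endpoint error
#'   stats and the objective) and `models` (named by k).
#' @export
grid_search_k <- function(cases, oar, candidate_ks, spec = model_spec(),
                          cfg = train_config(), val_cases) {
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  if (length(candidate_ks) == 0L) {
    stop("`candidate_ks` must be non-empty", call. = FALSE)
  }
  if (any(candidate_ks < 1)) {
    stop("all candidate k must be >= 1", call. = FALSE)
  }
  if (missing(val_cases) || length(val_cases) < 1L) {
    stop("`val_cases` (disjoint from `cases`) is required", call. = FALSE)
  }
  models <- list()
  rows <- lapply(candidate_ks, function(k) {
    cfg_k <- cfg
    cfg_k$k <- k
    m <- train_oar_model(cases, oar, spec, cfg_k, val_cases = val_cases)
    models[[as.character(k)]] <<- m
    st <- endpoint_stats(m, val_cases, oar)
    obj <- abs(st$mu_eud) + st$sigma_eud
    if (oar$serial) obj <- obj + abs(st$mu_dmax) + st$sigma_dmax
    data.frame(k = k, mu_eud = st$mu_eud, sigma_eud = st$sigma_eud,
               mu_dmax = if (oar$serial) st$mu_dmax else NA_real_,
               sigma_dmax = if (oar$serial) st$sigma_dmax else NA_real_,
               objective = obj)
  })
  table <- do.call(rbind, rows)
  best <- which.min(table$objective)  # which.min breaks ties low
  list(selected_k = table$k[best], table = table, models = models)
}

#' Jointly-trained multi-layer baseline
#'
#' The comparison arm: a single 3-layer GRU trained on all organs pooled,
#' with the uniform (`k = 1`) loss and a one-hot organ-identity feature
#' appended to the nine beam doses at every step. This approximates the
#' earlier multi-organ approach that the per-organ gEUD-weighted models are
#' compared against; it is a stand-in, not a reimplementation of that work.
#'
#' @param cases_by_oar Named list (by organ) of per-patient `(beams, plan)`
#'   case lists.
#' @param spec A [model_spec()]; `num_layers` defaults to 3 here and
#'   `input_size` is set to `9 + length(cases_by_oar)` automatically.
#' @param cfg A [train_config()]; the loss exponent is forced to `k = 1`.
#' @return A `trained_model` carrying the organ order in `$oar_names`; use
#'   [predict_baseline()] for inference.
#' @export
train_previous_baseline <- function(cases_by_oar,
                                    spec = model_spec(num_layers = 3L),
                                    cfg = train_config()) {
  oar_names <- names(cases_by_oar)
  if (is.null(oar_names) || length(oar_names) == 0L) {
    stop("`cases_by_oar` must be a non-empty named list", call. = FALSE)
  }
  n_oars <- length(oar_names)
  spec$input_size <- 9L + n_oars
  pooled <- unlist(lapply(seq_along(cases_by_oar), function(i) {
    lapply(cases_by_oar[[i]], function(cs) c(cs, list(oar_idx = i)))
  }), recursive = FALSE)
  extra <- sapply(pooled, function(cs) {
    v <- numeric(n_oars)
    v[cs$oar_idx] <- 1
    v
  })
  if (is.null(dim(extra))) extra <- matrix(extra, nrow = 1L)
  tens <- training_tensors(pooled, spec, k = 1L, extra = extra)
  model <- build_model(spec, oar_name = "joint_baseline")
  fit <- cpp_gru_train(
    model$theta, tens$X, tens$Y, tens$S,
    spec$hidden_size, spec$num_layers, spec$dose_norm,
    cfg$learning_rate, cfg$epochs, spec$dropout_p, cfg$seed, cfg$loss_floor,
    NULL, NULL, NULL, -1L)
  model$theta <- fit$theta
  model$k <- 1L
  model$epochs_run <- length(fit$train_loss)
  model$final_loss <- fit$final_loss
  model$loss_history <- fit$train_loss
  model$oar_names <- oar_names
  model
}

#' Predict with the jointly-trained baseline
#'
#' @param model A baseline model from [train_previous_baseline()].
#' @param beams A [beam_dvh_set()] or list of them.
#' @param oar_name Organ of the case(s); must be one the baseline was
#'   trained on.
#' @return A [dvh] or list of them, as [predict_dvh()].
#' @export
predict_baseline <- function(model, beams, oar_name) {
  if (is.null(model$oar_names)) {
    stop("`model` is not a joint baseline model", call. = FALSE)
  }
  idx <- match(oar_name, model$oar_names)
  if (is.na(idx)) {
    stop("baseline was not trained on organ '", oar_name, "'", call. = FALSE)
  }
  single <- inherits(beams, "beam_dvh_set")
  n <- if (single) 1L else length(beams)
  extra <- matrix(0, length(model$oar_names), n)
  extra[idx, ] <- 1
  predict_dvh(model, beams, extra = extra)
}
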
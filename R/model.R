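#' GRU model specification
#'
#' Architecture of the sequence regressor: at each percent-volume step the
#' model consumes the nine nonmodulated-beam doses (normalised by
#' `dose_norm`), updates a GRU hidden state, and emits the predicted
#' clinical-plan dose through a dropout layer and a one-unit affine head.
#'
#' @param hidden_size Hidden-state dimension (default 64).
#' @param num_layers Number of stacked GRU layers (default 1; the
#'   jointly-trained baseline uses 3).
#' @param dropout_p Dropout probability between the recurrent output and
#'   the affine head, active during training only (default 0.5).
#' @param dose_norm Dose divisor in Gy for input/output normalisation
#'   (default 70, the prescription dose).
#' @param input_size Features per step; 9 beam doses, plus any appended
#'   organ-identity features for the joint baseline.
#' @param reverse Consume the sequence in descending volume order instead
#'   of the default ascending (1% to 100%) order.
#' @param seed Seed for the deterministic parameter initialisation.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(hidden_size = 64L, num_layers = 1L, dropout_p = 0.5,
                       dose_norm = 70, input_size = 9L, reverse = FALSE,
                       seed = 1L) {
  if (hidden_size < 1) stop("`hidden_size` must be >= 1", call. = FALSE)
  if (num_layers < 1) stop("`num_layers` must be >= 1", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("`dropout_p` must be in [0, 1)", call. = FALSE)
  }
  if (dose_norm <= 0) stop("`dose_norm` must be positive", call. = FALSE)
  if (input_size < 1) stop("`input_size` must be >= 1", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 dropout_p = dropout_p, dose_norm = dose_norm,
                 reverse = isTRUE(reverse), seed = as.integer(seed)),
            class = "model_spec")
}

#' Number of trainable parameters of a GRU spec
#'
#' `3(h*in + h^2 + 2h)` per layer (input size `h` above the first layer)
#' plus `h + 1` for the affine output head.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(spec) {
  cpp_gru_n_par(spec$input_size, spec$hidden_size, spec$num_layers)
}

#' Build an (untrained) GRU model
#'
#' Parameters are initialised uniformly on `[-1/sqrt(h), 1/sqrt(h)]`,
#' deterministically under `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @param oar_name Organ label attached to the model.
#' @return An object of class `trained_model` with zeroed training
#'   metadata.
#' @export
build_model <- function(spec, oar_name = "unnamed") {
  stopifnot(inherits(spec, "model_spec"))
  np <- n_parameters(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  bound <- 1 / sqrt(spec$hidden_size)
  theta <- runif(np, -bound, bound)
  structure(list(spec = spec, theta = theta, oar_name = oar_name,
                 k = NA_integer_, epochs_run = 0L, final_loss = NA_real_,
                 loss_history = numeric(0)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %s: %d-layer GRU, hidden %d, %d parameters%s\n",
    x$oar_name, x$spec$num_layers, x$spec$hidden_size, length(x$theta),
    if (x$epochs_run > 0)
      sprintf(", trained %d epochs (k = %s, final loss %.4g)",
              x$epochs_run, x$k, x$final_loss)
    else " (untrained)"))
  invisible(x)
}

# features: input_size x B x 100 array from a list of beam_dvh_set
# (plus optional per-case constant extra features, e.g. organ identity)
feature_array <- function(beam_sets, spec, extra = NULL) {
  B <- length(beam_sets)
  n_extra <- if (is.null(extra)) 0L else nrow(extra)
  stopifnot(spec$input_size == 9L + n_extra)
  X <- array(0, dim = c(spec$input_size, B, DVH_NBINS))
  for (b in seq_len(B)) {
    bm <- beam_matrix(beam_sets[[b]]) / spec$dose_norm  # 9 x 100
    if (spec$reverse) bm <- bm[, DVH_NBINS:1]
    X[1:9, b, ] <- bm
    if (n_extra > 0) X[9L + seq_len(n_extra), b, ] <- extra[, b]
  }
  X
}

#' Predict a plan DVH from nine beam DVHs
#'
#' Runs the model over the 100-step percent-volume sequence with dropout
#' disabled, rescales outputs to Gy, clips at zero and restores
#' monotonicity by a running maximum from the 100%-volume tail. Inference
#' is a pure function of the parameters and the input.
#'
#' @param model A `trained_model` (from [build_model()] or
#'   [train_oar_model()]).
#' @param beams A [beam_dvh_set()], or a list of them for batched
#'   prediction.
#' @param extra Optional extra per-case constant feature matrix
#'   (`n_extra x n_cases`), required when the model was built with
#'   `input_size > 9`.
#' @return A [dvh] (or a list of them for a list input).
#' @export
predict_dvh <- function(model, beams, extra = NULL) {
  stopifnot(inherits(model, "trained_model"))
  single <- inherits(beams, "beam_dvh_set")
  beam_sets <- if (single) list(beams) else beams
  if (!all(vapply(beam_sets, inherits, logical(1), "beam_dvh_set"))) {
    stop("`beams` must be a beam_dvh_set or a list of them", call. = FALSE)
  }
  X <- feature_array(beam_sets, model$spec, extra)
  Y <- cpp_gru_forward(model$theta, X, model$spec$hidden_size,
                       model$spec$num_layers, model$spec$dose_norm)
  out <- lapply(seq_len(ncol(Y)), function(b) {
    y <- Y[, b]
    if (model$spec$reverse) y <- rev(y)
    dvh(monotone_repair(pmax(y, 0)))
  })
  if (single) out[[1L]] else out
}

#' Save / load a trained model
#'
#' The checkpoint is a single file with a stable structure (spec, weights,
#' organ, k, seed, loss history); reloading reproduces predictions
#' bit-identically. A human-readable JSON metadata sidecar
#' (`<path>.json`) is written alongside.
#'
#' @param model A `trained_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  meta <- list(oar = model$oar_name, k = model$k,
               epochs_run = model$epochs_run, final_loss = model$final_loss,
               spec = unclass(model$spec), n_parameters = length(model$theta))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_model")) {
    stop("file does not contain a trained_model: ", path, call. = FALSE)
  }
  model
}
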
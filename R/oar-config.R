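# Fixed gantry angles (degrees) of the nine nonmodulated conformal beams.
GANTRY_ANGLES <- c(160, 200, 240, 280, 320, 0, 40, 80, 120)

#' Bundle the nine nonmodulated-beam DVHs of one organ
#'
#' The nine conformal beams (gantry angles 160, 200, 240, 280, 320, 0, 40,
#' 80, 120 degrees) encode the patient geometry as dosimetric features: the
#' dose each beam alone deposits in the organ at every percent-volume bin.
#'
#' @param beams A list of exactly 9 [dvh] objects, ordered B1..B9 to match
#'   the gantry angles.
#' @return An object of class `beam_dvh_set`.
#' @export
beam_dvh_set <- function(beams) {
  if (!is.list(beams) || length(beams) != 9L) {
    stop("`beams` must be a list of exactly 9 DVHs (B1..B9)", call. = FALSE)
  }
  beams <- lapply(beams, function(b) if (is_dvh(b)) b else dvh(b))
  structure(list(beams = beams, gantry_angles = GANTRY_ANGLES),
            class = "beam_dvh_set")
}

#' @export
print.beam_dvh_set <- function(x, ...) {
  cat("<beam_dvh_set> 9 beams at gantry angles",
      paste(x$gantry_angles, collapse = ", "), "deg\n")
  invisible(x)
}

# 9 x 100 matrix of beam doses (rows = beams, cols = volume bins)
beam_matrix <- function(bs) {
  stopifnot(inherits(bs, "beam_dvh_set"))
  do.call(rbind, lapply(bs$beams, as_dose_vector))
}

#' Per-organ configuration
#'
#' Holds the organ-specific parameters of the method: the loss exponent `k`
#' used in the gEUD-weighted training loss, the gEUD exponent `a` used at
#' evaluation time, whether the organ is serial (in which case the maximum
#' dose is also reported), and the prescription dose used to normalise model
#' inputs and outputs.
#'
#' @param name Organ label.
#' @param loss_k Positive integer `k >= 1` for the loss weights.
#' @param eud_a Exponent `a >= 1` for gEUD evaluation (8 for serial organs,
#'   1 for parallel organs).
#' @param serial Logical; defaults to `eud_a == 8`.
#' @param dose_cap Normalisation dose in Gy (default 70, the prescription).
#' @return An object of class `oar_config`.
#' @seealso [default_oar_configs()] for the organ table used throughout.
#' @export
oar_config <- function(name, loss_k, eud_a, serial = (eud_a == 8),
                       dose_cap = 70) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(loss_k) || length(loss_k) != 1L || loss_k < 1 ||
      loss_k != round(loss_k)) {
    stop("`loss_k` must be a positive integer >= 1", call. = FALSE)
  }
  if (!is.numeric(eud_a) || length(eud_a) != 1L || eud_a < 1) {
    stop("`eud_a` must be a number >= 1", call. = FALSE)
  }
  if (!is.numeric(dose_cap) || length(dose_cap) != 1L || dose_cap <= 0) {
    stop("`dose_cap` must be a positive dose in Gy", call. = FALSE)
  }
  structure(list(name = name, loss_k = as.integer(loss_k), eud_a = eud_a,
                 serial = isTRUE(serial), dose_cap = dose_cap),
            class = "oar_config")
}

#' @export
print.oar_config <- function(x, ...) {
  cat(sprintf("<oar_config> %s: k = %d, a = %g, %s, dose cap %g Gy\n",
              x$name, x$loss_k, x$eud_a,
              if (x$serial) "serial" else "parallel", x$dose_cap))
  invisible(x)
}

#' Default organ-at-risk table
#'
#' The eleven head-and-neck organs with their loss exponents `k` (found by
#' trial and error in the source study), gEUD exponents `a` (8 for serial
#' organs, 1 for parallel organs) and serial flags:
#' brainstem k=8, spinal cord k=15, optic nerve L k=3, optic nerve R k=2,
#' chiasm k=1 (all serial, a=8); larynx, parotid L/R and temporal lobe L/R
#' k=1 (parallel, a=1).
#'
#' @param dose_cap Normalisation dose in Gy applied to every organ.
#' @return Named list of [oar_config] objects.
#' @export
default_oar_configs <- function(dose_cap = 70) {
  defs <- list(
    c("brainstem",       8, 8),
    c("spinal_cord",    15, 8),
    c("optic_nerve_l",   3, 8),
    c("optic_nerve_r",   2, 8),
    c("chiasm",          1, 8),
    c("larynx",          1, 1),
    c("parotid_l",       1, 1),
    c("parotid_r",       1, 1),
    c("temporal_lobe_l", 1, 1),
    c("temporal_lobe_r", 1, 1)
  )
  cfgs <- lapply(defs, function(d) {
    oar_config(d[1L], loss_k = as.numeric(d[2L]), eud_a = as.numeric(d[3L]),
               dose_cap = dose_cap)
  })
  setNames(cfgs, vapply(cfgs, `[[`, character(1), "name"))
}
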
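#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
NULL

DVH_TABLE_HEADER <- c("patient_id", "oar", "source", "v_percent", "dose_gy")
DVH_SOURCES <- c(paste0("beam", 1:9), "plan", "prediction")

# doses serialised with 17 significant digits so read(write(x)) is
# bit-exact for doubles
format_dose <- function(x) sprintf("%.17g", x)

#' Write / read a long-format DVH table
#'
#' The on-disk format is a CSV with header exactly
#' `patient_id,oar,source,v_percent,dose_gy`, one row per volume bin, with
#' `source` one of `beam1..beam9`, `plan` or `prediction`, sorted by
#' (patient, oar, source, v). Doses are written with 17 significant digits
#' so a round trip is bit-exact.
#'
#' @param cohort A `cohort`, or a list of `patient_case` objects.
#' @param path CSV file path.
#' @return `write_dvh_table` returns `path` invisibly; `read_dvh_table`
#'   returns a list of `patient_case` objects (no latent factor), after
#'   validating every DVH invariant.
#' @export
write_dvh_table <- function(cohort, path) {
  cases <- if (inherits(cohort, "cohort")) cohort$cases else cohort
  rows <- lapply(cases, function(cs) {
    per_oar <- lapply(names(cs$oars), function(o) {
      entry <- cs$oars[[o]]
      bm <- beam_matrix(entry$beams)
      src <- list()
      for (b in 1:9) {
        src[[b]] <- data.table(patient_id = cs$patient_id, oar = o,
                               source = paste0("beam", b),
                               v_percent = DVH_GRID,
                               dose_gy = format_dose(bm[b, ]))
      }
      src[[10]] <- data.table(patient_id = cs$patient_id, oar = o,
                              source = "plan", v_percent = DVH_GRID,
                              dose_gy = format_dose(as_dose_vector(entry$plan)))
      data.table::rbindlist(src)
    })
    data.table::rbindlist(per_oar)
  })
  dt <- data.table::rbindlist(rows)
  setorder(dt, patient_id, oar, source, v_percent)
  fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_dvh_table
#' @export
read_dvh_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path)
  if (!identical(names(dt), DVH_TABLE_HEADER)) {
    stop("bad header: expected ", paste(DVH_TABLE_HEADER, collapse = ","),
         ", got ", paste(names(dt), collapse = ","), call. = FALSE)
  }
  dt[, c("patient_id", "oar", "source", "v_percent", "dose_gy") :=
       .(as.character(patient_id), as.character(oar), as.character(source),
         as.integer(v_percent), as.numeric(dose_gy))]
  if (anyNA(dt$dose_gy) || anyNA(dt$v_percent)) {
    stop("non-numeric dose or volume values in ", path, call. = FALSE)
  }
  bad_src <- setdiff(unique(dt$source), DVH_SOURCES)
  if (length(bad_src) > 0L) {
    stop("unknown source value(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  dt[, row_number := .I]
  setorder(dt, patient_id, oar, source, v_percent)
  grp_sizes <- dt[, .N, by = c("patient_id", "oar", "source")]
  n_grp <- nrow(grp_sizes)
  # every (patient, oar, source) group must hold exactly the bins 1..100
  expected_v <- rep.int(DVH_GRID, n_grp)
  if (nrow(dt) != n_grp * DVH_NBINS ||
      !identical(as.integer(dt$v_percent), expected_v)) {
    bad <- grp_sizes[grp_sizes$N != DVH_NBINS][1L]
    if (nrow(bad) == 0L) bad <- grp_sizes[1L]  # right count, wrong bins
    g <- dt[dt$patient_id == bad$patient_id & dt$oar == bad$oar &
              dt$source == bad$source]
    key <- sprintf("patient %s / %s / %s", bad$patient_id, bad$oar,
                   bad$source)
    if (anyDuplicated(g$v_percent)) {
      v <- g$v_percent[duplicated(g$v_percent)][1L]
      stop("duplicate bin v = ", v, " for ", key, " (row ",
           g$row_number[g$v_percent == v][2L], ")", call. = FALSE)
    }
    miss <- setdiff(DVH_GRID, g$v_percent)
    stop("missing bin v = ", miss[1L], " for ", key, call. = FALSE)
  }
  doses <- matrix(dt$dose_gy, nrow = DVH_NBINS)  # one column per group
  first_rows <- dt[seq(1L, nrow(dt), by = DVH_NBINS)]
  make_dvh <- function(col) {
    tryCatch(dvh(doses[, col]), error = function(e) {
      stop("invalid DVH for patient ", first_rows$patient_id[col], " / ",
           first_rows$oar[col], " / ", first_rows$source[col], ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  cases <- list()
  for (pid in unique(first_rows$patient_id)) {
    oars <- list()
    for (o in unique(first_rows$oar[first_rows$patient_id == pid])) {
      cols <- which(first_rows$patient_id == pid & first_rows$oar == o)
      srcs <- first_rows$source[cols]
      beams_present <- paste0("beam", 1:9) %in% srcs
      entry <- list()
      if (all(beams_present)) {
        entry$beams <- beam_dvh_set(lapply(paste0("beam", 1:9), function(b) {
          make_dvh(cols[srcs == b])
        }))
      } else if (any(beams_present)) {
        stop("patient ", pid, " / ", o, ": incomplete beam set (",
             sum(beams_present), " of 9 beams)", call. = FALSE)
      }
      if ("plan" %in% srcs) entry$plan <- make_dvh(cols[srcs == "plan"])
      if ("prediction" %in% srcs) {
        entry$prediction <- make_dvh(cols[srcs == "prediction"])
      }
      oars[[o]] <- entry
    }
    cases[[length(cases) + 1L]] <- structure(
      list(patient_id = pid, latent = NA_real_, oars = oars),
      class = "patient_case")
  }
  cases
}

#' Write predictions as a DVH table
#'
#' @param predictions Nested named list `predictions[[oar]][[patient_id]]`
#'   of predicted [dvh] objects.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(predictions, path) {
  rows <- list()
  for (o in names(predictions)) {
    for (pid in names(predictions[[o]])) {
      rows[[length(rows) + 1L]] <- data.table(
        patient_id = pid, oar = o, source = "prediction",
        v_percent = DVH_GRID,
        dose_gy = format_dose(as_dose_vector(predictions[[o]][[pid]])))
    }
  }
  dt <- data.table::rbindlist(rows)
  setorder(dt, patient_id, oar, source, v_percent)
  fwrite(dt, path, quote = FALSE)
  invisible(path)
}

# read a prediction table back into predictions[[oar]][[patient_id]]
read_prediction_table <- function(path) {
  cases <- read_dvh_table(path)
  out <- list()
  for (cs in cases) {
    for (o in names(cs$oars)) {
      if (!is.null(cs$oars[[o]]$prediction)) {
        out[[o]][[cs$patient_id]] <- cs$oars[[o]]$prediction
      }
    }
  }
  out
}

# 32-bit multiplicative hash of a serialised R object; stamps outputs with
# the exact configuration that produced them
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-(1:14)])  # skip header
  h <- 2166136261
  for (b in bytes) {
    h <- ((h + b + 1) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
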
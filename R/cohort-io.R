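#' Resample a raw stance trace onto the canonical time-normalised grid
#'
#' Stance-phase traces recorded at arbitrary sampling rates are linearly
#' interpolated on a uniform parameterisation from the first to the last
#' sample, the standard time-normalisation used in clinical gait analysis.
#' Endpoints are preserved exactly; resampling a trace already at the target
#' length is the identity.
#'
#' @param raw_values numeric vector of at least 2 finite samples.
#' @param n_points target grid length (default 60, the canonical stance grid).
#' @return numeric vector of length `n_points`.
#' @examples
#' resample_stance(c(0, 1, 4, 9), n_points = 7)
#' @export
resample_stance <- function(raw_values, n_points = STANCE_N) {
  if (!is.numeric(raw_values) || length(raw_values) < 2L) {
    stop("resample_stance needs at least 2 numeric samples", call. = FALSE)
  }
  if (!all(is.finite(raw_values))) {
    stop("resample_stance: non-finite input sample(s) at index ",
         paste(which(!is.finite(raw_values)), collapse = ", "), call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    stop("n_points must be an integer >= 2", call. = FALSE)
  }
  if (length(raw_values) == n_points) {
    return(as.numeric(raw_values))
  }
  src <- seq(0, 1, length.out = length(raw_values))
  out <- seq(0, 1, length.out = n_points)
  y <- stats::approx(src, raw_values, xout = out, method = "linear")$y
  # guard endpoint round-off from the parameterisation
  y[1L] <- raw_values[1L]
  y[n_points] <- raw_values[length(raw_values)]
  y
}

## Interchange schema --------------------------------------------------------
## Long format, one row per sample:
##   subject_id, side, variable, sample_index (0..59), value
## Kinematic variables keep their names (PelvicTilt, HipFlx, ...); moment
## curves are encoded as <Joint>Mom_meas / <Joint>Mom_pred so that the five
## fixed columns suffice to round-trip a full record.

moment_var_name <- function(joint, kind) {
  paste0(MOMENT_VARS[[joint]], "_", kind)
}

#' Write a cohort to the long-format interchange file
#'
#' The CSV schema has columns `subject_id`, `side`, `variable`,
#' `sample_index` (0-59) and `value`. Measured and predicted moments are
#' stored under `HipMom_meas`/`HipMom_pred` (similarly knee, ankle). Values
#' are written with 17 significant digits so that a write/read round trip is
#' lossless and repeated writes are byte-identical. A JSON mirror of the same
#' content is available with `format = "json"`.
#'
#' @param records list of [subject_record()] objects (may be empty: a
#'   header-only file is written).
#' @param path output file path.
#' @param format `"csv"` (default) or `"json"`.
#' @param meta_path optional path for a per-record metadata CSV
#'   (`subject_id`, `side`, `severity`); written only when any record carries
#'   a non-`NA` severity or `meta_path` is given explicitly.
#' @return `invisible(path)`.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(records, path, format = c("csv", "json"),
                         meta_path = NULL) {
  format <- match.arg(format)
  if (length(records)) {
    check_cohort(records)
    # canonical record order (subject then side) mirrors read_cohort, so
    # writing is deterministic regardless of how the cohort was assembled
    records <- records[order(vapply(records, `[[`, character(1), "subject_id"),
                             vapply(records, `[[`, character(1), "side"))]
  }
  long <- cohort_to_long(records)
  if (format == "csv") {
    con <- try(file(path, open = "wt"), silent = TRUE)
    if (inherits(con, "try-error")) {
      stop("cannot open '", path, "' for writing", call. = FALSE)
    }
    on.exit(close(con), add = TRUE)
    writeLines("subject_id,side,variable,sample_index,value", con)
    if (nrow(long)) {
      writeLines(sprintf("%s,%s,%s,%d,%.17g", long$subject_id, long$side,
                         long$variable, long$sample_index, long$value), con)
    }
  } else {
    payload <- lapply(records, function(r) {
      list(subject_id = r$subject_id, side = r$side,
           severity = r$severity, kinematics = r$kinematics,
           measured_moments = r$measured_moments,
           predicted_moments = r$predicted_moments)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  severities <- vapply(records, function(r) r$severity, numeric(1))
  if (!is.null(meta_path) || any(!is.na(severities))) {
    if (is.null(meta_path)) {
      meta_path <- paste0(sub("\\.[^.]+$", "", path), "_meta.csv")
    }
    meta <- data.frame(subject_id = vapply(records, `[[`, character(1), "subject_id"),
                       side = vapply(records, `[[`, character(1), "side"),
                       severity = severities)
    utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

cohort_to_long <- function(records) {
  if (!length(records)) {
    return(data.frame(subject_id = character(), side = character(),
                      variable = character(), sample_index = integer(),
                      value = numeric()))
  }
  blocks <- lapply(records, function(r) {
    # canonical variable order (kinematics alphabetical, then moments by
    # joint) so that repeated writes are byte-identical regardless of how
    # the record was assembled
    kin <- r$kinematics[sort(names(r$kinematics))]
    jnt <- intersect(JOINTS, names(r$measured_moments))
    curves <- c(kin,
                stats::setNames(r$measured_moments[jnt],
                                vapply(jnt, moment_var_name, character(1),
                                       kind = "meas")),
                stats::setNames(r$predicted_moments[jnt],
                                vapply(jnt, moment_var_name, character(1),
                                       kind = "pred")))
    data.frame(subject_id = r$subject_id, side = r$side,
               variable = rep(names(curves), each = STANCE_N),
               sample_index = rep(seq_len(STANCE_N) - 1L, length(curves)),
               value = unlist(curves, use.names = FALSE))
  })
  do.call(rbind, blocks)
}

#' Read a cohort from the long-format interchange file
#'
#' Reads the schema documented in [write_cohort()] and assembles one
#' [subject_record()] per `(subject_id, side)` pair, ordered by subject id
#' then side so that the record order is deterministic. Validation errors name
#' the offending subject/variable (missing required kinematics) or row index
#' (non-finite values).
#'
#' @param path input file path.
#' @param format `"csv"` (default) or `"json"`.
#' @param meta_path optional metadata CSV carrying `subject_id`, `side` and
#'   `severity`; when `NULL`, `<path stem>_meta.csv` is used if it exists.
#' @return list of `subject_record` objects.
#' @export
read_cohort <- function(path, format = c("csv", "json"), meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
    records <- lapply(payload, function(p) {
      subject_record(p$subject_id, p$side, p$kinematics,
                     p$measured_moments, p$predicted_moments,
                     severity = if (is.null(p$severity)) NA_real_ else p$severity)
    })
    ord <- order(vapply(records, `[[`, character(1), "subject_id"),
                 vapply(records, `[[`, character(1), "side"))
    return(records[ord])
  }
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character",
                                         side = "character",
                                         variable = "character",
                                         sample_index = "integer",
                                         value = "numeric"))
  required <- c("subject_id", "side", "variable", "sample_index", "value")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(long$value))
  if (length(bad)) {
    stop("non-finite value(s) in cohort file at data row ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(long$sample_index < 0L | long$sample_index >= STANCE_N)) {
    stop("sample_index out of range 0..", STANCE_N - 1L, call. = FALSE)
  }

  meta <- NULL
  if (is.null(meta_path)) {
    candidate <- paste0(sub("\\.[^.]+$", "", path), "_meta.csv")
    if (file.exists(candidate)) meta_path <- candidate
  }
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character"))
  }

  keys <- unique(long[, c("subject_id", "side")])
  keys <- keys[order(keys$subject_id, keys$side), , drop = FALSE]
  records <- vector("list", nrow(keys))
  meas_pat <- "_meas$"
  pred_pat <- "_pred$"
  joint_of <- stats::setNames(names(MOMENT_VARS), MOMENT_VARS)
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; sd <- keys$side[i]
    sub <- long[long$subject_id == sid & long$side == sd, , drop = FALSE]
    curves <- split(sub[order(sub$sample_index), c("sample_index", "value")],
                    sub$variable[order(sub$sample_index)])
    curves <- lapply(curves, function(d) {
      if (nrow(d) != STANCE_N || !identical(d$sample_index, seq_len(STANCE_N) - 1L)) {
        stop("subject ", sid, " (", sd, "): incomplete sample grid for a variable",
             call. = FALSE)
      }
      d$value
    })
    is_meas <- grepl(meas_pat, names(curves))
    is_pred <- grepl(pred_pat, names(curves))
    kin <- curves[!is_meas & !is_pred]
    missing_vars <- setdiff(SAGITTAL_VARS, names(kin))
    if (length(missing_vars)) {
      stop("subject ", sid, " (", sd, "): missing required kinematic ",
           "variable(s): ", paste(missing_vars, collapse = ", "), call. = FALSE)
    }
    meas <- curves[is_meas]
    names(meas) <- joint_of[sub(meas_pat, "", names(meas))]
    meas <- meas[intersect(JOINTS, names(meas))]
    pred <- curves[is_pred]
    names(pred) <- joint_of[sub(pred_pat, "", names(pred))]
    pred <- pred[intersect(JOINTS, names(pred))]
    sev <- NA_real_
    if (!is.null(meta)) {
      hit <- meta$subject_id == sid & meta$side == sd
      if (any(hit)) sev <- meta$severity[which(hit)[1L]]
    }
    records[[i]] <- subject_record(sid, sd, kin, meas, pred, severity = sev)
  }
  records
}

#' Write a reference profile as CSV (`variable, sample_index, mean_value`)
#' @param reference a [reference_profile()].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "reference_profile"))
  vars <- names(reference$mean_curves)
  con <- file(path, open = "wt"); on.exit(close(con), add = TRUE)
  writeLines("variable,sample_index,mean_value", con)
  for (v in vars) {
    writeLines(sprintf("%s,%d,%.17g", v, seq_len(STANCE_N) - 1L,
                       reference$mean_curves[[v]]), con)
  }
  invisible(path)
}

#' Read a reference profile written by [write_reference()]
#' @param path input CSV path.
#' @param description description attached to the returned profile.
#' @return a [reference_profile()].
#' @export
read_reference <- function(path, description = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  curves <- lapply(split(d[order(d$sample_index), ],
                         d$variable[order(d$sample_index)]),
                   `[[`, "mean_value")
  reference_profile(curves, description = description)
}
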
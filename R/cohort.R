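#' Construct a per-side stance-phase subject record
#'
#' A subject record holds one side of one subject: the four sagittal kinematic
#' curves (degrees), and the measured and predicted moment curves (Nm/kg) for
#' one or more joints, all time-normalised to 60 stance samples.
#'
#' @param subject_id character scalar identifying the subject.
#' @param side `"left"` or `"right"`.
#' @param kinematics named list of numeric(60) curves in degrees; must contain
#'   at least `PelvicTilt`, `HipFlx`, `KneeFlx` and `AnkleDorsi`. Extra
#'   variables (e.g. for a wider GPS variable set) are allowed.
#' @param measured_moments named list of numeric(60) curves in Nm/kg, keyed by
#'   joint (`hip`, `knee`, `ankle`).
#' @param predicted_moments named list with exactly the same keys as
#'   `measured_moments`.
#' @param severity optional scalar in `[0, 1]`: synthetic ground-truth crouch
#'   severity. `NA` for clinical records.
#' @return An object of class `subject_record`.
#' @examples
#' flat <- rep(0, 60)
#' wave <- sin(seq(0, pi, length.out = 60))
#' rec <- subject_record("S01", "left",
#'   kinematics = list(PelvicTilt = flat + 15, HipFlx = wave * 40,
#'                     KneeFlx = wave * 30, AnkleDorsi = wave * 10),
#'   measured_moments = list(ankle = wave * 1.4),
#'   predicted_moments = list(ankle = wave * 1.4 + 0.05))
#' rec
#' @export
subject_record <- function(subject_id, side, kinematics,
                           measured_moments, predicted_moments,
                           severity = NA_real_) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  side <- match.arg(side, c("left", "right"))
  if (!is.list(kinematics) || is.null(names(kinematics))) {
    stop("kinematics must be a named list of curves", call. = FALSE)
  }
  missing_vars <- setdiff(SAGITTAL_VARS, names(kinematics))
  if (length(missing_vars)) {
    stop("subject ", subject_id, " (", side, "): missing required kinematic ",
         "variable(s): ", paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (!identical(sort(names(measured_moments)), sort(names(predicted_moments)))) {
    stop("subject ", subject_id, ": measured and predicted moment maps must ",
         "share identical joint keys", call. = FALSE)
  }
  bad_joints <- setdiff(names(measured_moments), JOINTS)
  if (length(bad_joints)) {
    stop("unknown joint(s): ", paste(bad_joints, collapse = ", "),
         " (expected ", paste(JOINTS, collapse = "/"), ")", call. = FALSE)
  }
  kinematics <- lapply(stats::setNames(names(kinematics), names(kinematics)),
                       function(v) check_curve(kinematics[[v]], v))
  measured_moments <- lapply(
    stats::setNames(names(measured_moments), names(measured_moments)),
    function(j) check_curve(measured_moments[[j]], paste0(j, " measured moment")))
  predicted_moments <- lapply(
    stats::setNames(names(predicted_moments), names(predicted_moments)),
    function(j) check_curve(predicted_moments[[j]], paste0(j, " predicted moment")))
  if (!is.na(severity) && (severity < 0 || severity > 1)) {
    stop("severity must be in [0, 1] or NA", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, side = side, kinematics = kinematics,
         measured_moments = measured_moments,
         predicted_moments = predicted_moments,
         severity = as.numeric(severity)),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id, " [", x$side, "]\n", sep = "")
  cat("  kinematics: ", paste(names(x$kinematics), collapse = ", "), "\n", sep = "")
  cat("  moments:    ", paste(names(x$measured_moments), collapse = ", "),
      " (measured + predicted)\n", sep = "")
  if (!is.na(x$severity)) cat("  severity:  ", format(x$severity), "\n")
  invisible(x)
}

#' Construct a typically-developed reference profile for GPS computation
#'
#' @param mean_curves named list of numeric(60) mean curves in degrees, one per
#'   gait variable in the GPS variable set.
#' @param description free-text provenance of the reference.
#' @return An object of class `reference_profile`.
#' @seealso [gait_profile_score()]
#' @export
reference_profile <- function(mean_curves,
                              description = "unspecified reference") {
  if (!is.list(mean_curves) || is.null(names(mean_curves))) {
    stop("mean_curves must be a named list of curves", call. = FALSE)
  }
  mean_curves <- lapply(stats::setNames(names(mean_curves), names(mean_curves)),
                        function(v) check_curve(mean_curves[[v]], v))
  structure(list(mean_curves = mean_curves, description = description),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile> ", x$description, "\n  variables: ",
      paste(names(x$mean_curves), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a cohort (list of subject records)
#' @keywords internal
check_cohort <- function(records) {
  if (!is.list(records) || !length(records)) {
    stop("cohort must be a non-empty list of subject_record objects",
         call. = FALSE)
  }
  ok <- vapply(records, inherits, logical(1), what = "subject_record")
  if (!all(ok)) {
    stop("cohort element(s) ", paste(which(!ok), collapse = ", "),
         " are not subject_record objects", call. = FALSE)
  }
  invisible(records)
}

#' Record identifiers of a cohort as "subject_id:side" strings
#' @keywords internal
record_ids <- function(records) {
  vapply(records, function(r) paste(r$subject_id, r$side, sep = ":"),
         character(1))
}
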
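#' MAX / ROM / MEAN of a stance-phase angle curve
#'
#' The three scalar features summarising a kinematic curve over stance:
#' maximal value, range of motion (max minus min) and arithmetic mean. The
#' minimum is computed internally for ROM but not reported.
#'
#' @param curve numeric(60) angle curve in degrees.
#' @return named numeric vector `c(MAX, ROM, MEAN)`.
#' @export
curve_features <- function(curve) {
  curve <- check_curve(curve, "curve", n_points = length(curve))
  c(MAX = max(curve), ROM = max(curve) - min(curve), MEAN = mean(curve))
}

#' Gait Variable Scores against a reference profile
#'
#' The gait variable score (GVS) of one variable is the root-mean-square
#' difference over the 60 stance samples between the subject's curve and the
#' reference mean curve.
#'
#' @param record a [subject_record()].
#' @param reference a [reference_profile()].
#' @param variable_set character vector of variables to score; defaults to the
#'   four sagittal variables. The conventional clinical set (nine variables
#'   minus foot progression) can be supplied when the corresponding curves are
#'   present.
#' @return named numeric vector of per-variable GVS in degrees.
#' @export
gait_variable_scores <- function(record, reference,
                                 variable_set = SAGITTAL_VARS) {
  stopifnot(inherits(record, "subject_record"),
            inherits(reference, "reference_profile"))
  missing_rec <- setdiff(variable_set, names(record$kinematics))
  if (length(missing_rec)) {
    stop("record ", record$subject_id, " lacks variable(s): ",
         paste(missing_rec, collapse = ", "), call. = FALSE)
  }
  missing_ref <- setdiff(variable_set, names(reference$mean_curves))
  if (length(missing_ref)) {
    stop("reference lacks variable(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  vapply(stats::setNames(variable_set, variable_set), function(v) {
    sqrt(mean((record$kinematics[[v]] - reference$mean_curves[[v]])^2))
  }, numeric(1))
}

#' Gait Profile Score of one record
#'
#' Root-mean-square of the per-variable gait variable scores over
#' `variable_set`: a single-number summary (degrees) of how far a subject's
#' kinematics deviate from a typically-developed reference. Higher is more
#' pathological. If exactly one of k variables is offset from the reference by
#' a constant d, the GPS equals `d / sqrt(k)`.
#'
#' @inheritParams gait_variable_scores
#' @return GPS in degrees (scalar).
#' @export
gait_profile_score <- function(record, reference,
                               variable_set = SAGITTAL_VARS) {
  gvs <- gait_variable_scores(record, reference, variable_set)
  sqrt(mean(gvs^2))
}

#' Summarise kinematic features and GPS per moment label
#'
#' Groups records by the label their `joint` moment received and reports, per
#' label, the mean and standard deviation of MAX/ROM/MEAN for each kinematic
#' variable and of the GPS, together with group sizes — the per-label feature
#' table used to relate gait severity to prediction quality. An empty label
#' group yields rows with `n = 0` and `NA` statistics.
#'
#' @param records list of [subject_record()]s.
#' @param label_results a [label_cohort()] result for `joint`, or its
#'   `results` data frame.
#' @param joint joint whose labels are used.
#' @param reference a [reference_profile()] for GPS.
#' @param variable_set variables to profile (default: sagittal four).
#' @return data frame with columns label, n, variable, feature, mean, sd.
#'   GPS appears as `variable = "GPS", feature = "GPS"`.
#' @export
features_by_label <- function(records, label_results, joint,
                              reference, variable_set = SAGITTAL_VARS) {
  check_cohort(records)
  joint <- match.arg(joint, JOINTS)
  res <- if (inherits(label_results, "moment_labeling")) label_results$results
         else label_results
  ids <- record_ids(records)
  res_ids <- paste(res$subject_id, res$side, sep = ":")
  labelled <- ids %in% res_ids
  label_of <- stats::setNames(as.character(res$label), res_ids)

  feat_rows <- list()
  per_record <- lapply(records[labelled], function(r) {
    feats <- lapply(r$kinematics[variable_set], curve_features)
    list(label = label_of[[paste(r$subject_id, r$side, sep = ":")]],
         feats = feats,
         gps = gait_profile_score(r, reference, variable_set))
  })
  if (any(!labelled) && length(per_record) == 0L) {
    stop("no labelled records to summarise", call. = FALSE)
  }
  labels_vec <- vapply(per_record, `[[`, character(1), "label")
  out <- list()
  for (lb in MOMENT_LABELS) {
    in_group <- which(labels_vec == lb)
    n <- length(in_group)
    for (v in variable_set) {
      for (f in c("MAX", "ROM", "MEAN")) {
        vals <- vapply(per_record[in_group],
                       function(p) p$feats[[v]][[f]], numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          label = lb, n = n, variable = v, feature = f,
          mean = if (n) mean(vals) else NA_real_,
          sd = if (n > 1L) stats::sd(vals) else NA_real_)
      }
    }
    gps_vals <- vapply(per_record[in_group], `[[`, numeric(1), "gps")
    out[[length(out) + 1L]] <- data.frame(
      label = lb, n = n, variable = "GPS", feature = "GPS",
      mean = if (n) mean(gps_vals) else NA_real_,
      sd = if (n > 1L) stats::sd(gps_vals) else NA_real_)
  }
  res_df <- do.call(rbind, out)
  res_df$label <- factor(res_df$label, levels = MOMENT_LABELS)
  res_df
}

#' Per-record subphase nRMSE decomposition
#'
#' Splits the stance into `n_subphases` equal contiguous bins (default 5,
#' matching initial contact, loading response, mid stance, terminal stance and
#' pre-swing on the normalised grid) and computes, per bin, the RMSE
#' restricted to the bin normalised by the *full-stance* measured peak-to-peak
#' amplitude. Normalising by the full range rather than per-bin ranges keeps
#' bins comparable (mid-stance per-bin ranges can be near zero). The
#' width-weighted mean of the squared bin values equals the squared full-curve
#' nRMSE.
#'
#' @param measured,predicted numeric(60) moment curves.
#' @param n_subphases number of equal bins; must divide 60.
#' @return numeric vector of length `n_subphases`.
#' @export
subphase_nrmse <- function(measured, predicted, n_subphases = 5L) {
  n <- length(measured)
  measured <- check_curve(measured, "measured", n_points = n)
  predicted <- check_curve(predicted, "predicted", n_points = n)
  n_subphases <- as.integer(n_subphases)
  if (n %% n_subphases != 0L) {
    stop("n_subphases must divide the grid length (", n, ")", call. = FALSE)
  }
  p2p <- max(measured) - min(measured)
  if (p2p <= 0) stop("degenerate trace: flat measured curve", call. = FALSE)
  width <- n %/% n_subphases
  vapply(seq_len(n_subphases), function(b) {
    idx <- ((b - 1L) * width + 1L):(b * width)
    sqrt(mean((measured[idx] - predicted[idx])^2)) / p2p
  }, numeric(1))
}

#' Subphase error profile per label
#'
#' For each label and stance subphase, the median and first/third quartiles of
#' the per-record subphase nRMSE (the boxplot-ready decomposition of where in
#' stance the prediction error concentrates).
#'
#' @inheritParams features_by_label
#' @param n_subphases number of equal bins; must divide 60.
#' @return data frame: joint, label, bin, n, q1, median, q3.
#' @export
subphase_error_profile <- function(records, label_results, joint,
                                   n_subphases = 5L) {
  check_cohort(records)
  joint <- match.arg(joint, JOINTS)
  if (STANCE_N %% as.integer(n_subphases) != 0L) {
    stop("n_subphases must divide ", STANCE_N, call. = FALSE)
  }
  res <- if (inherits(label_results, "moment_labeling")) label_results$results
         else label_results
  res_ids <- paste(res$subject_id, res$side, sep = ":")
  label_of <- stats::setNames(as.character(res$label), res_ids)
  ids <- record_ids(records)
  keep <- which(ids %in% res_ids)

  sub_mat <- t(vapply(records[keep], function(r) {
    subphase_nrmse(r$measured_moments[[joint]], r$predicted_moments[[joint]],
                   n_subphases)
  }, numeric(n_subphases)))
  labels_vec <- label_of[ids[keep]]

  out <- list()
  for (lb in MOMENT_LABELS) {
    rows <- which(labels_vec == lb)
    for (b in seq_len(n_subphases)) {
      v <- sub_mat[rows, b]
      qs <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
            else rep(NA_real_, 3L)
      out[[length(out) + 1L]] <- data.frame(
        joint = joint, label = lb, bin = b, n = length(rows),
        q1 = qs[1L], median = qs[2L], q3 = qs[3L])
    }
  }
  prof <- do.call(rbind, out)
  prof$label <- factor(prof$label, levels = MOMENT_LABELS)
  prof
}
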
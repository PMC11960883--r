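#' Standardised peak of a joint-moment trace
#'
#' The standardised peak moment is the within-trace z-score of the peak:
#' `(max - mean) / sd` over the 60 stance samples, with the sample (n-1)
#' standard deviation. It is dimensionless, strictly positive for any
#' non-constant trace, and invariant under adding a constant or multiplying by
#' a positive factor — which is what makes it usable as a normalisation basis
#' for acceptance thresholds across joints with very different moment
#' magnitudes.
#'
#' @param moment numeric(60) moment trace (Nm/kg).
#' @return dimensionless scalar.
#' @examples
#' standardized_peak(sin(seq(0, pi, length.out = 60)))
#' @export
standardized_peak <- function(moment) {
  moment <- check_curve(moment, "moment", n_points = length(moment))
  s <- stats::sd(moment)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate trace: constant moment curve has no standardised peak",
         call. = FALSE)
  }
  (max(moment) - mean(moment)) / s
}

#' Lower and upper kinetic limits for a moment trace
#'
#' The acceptance band for prediction error is anchored on the trace's own
#' standardised peak moment `MaxMom*`: the lower kinetic limit is
#' `LKL = lkl_fraction * MaxMom*` (default 10%) and the upper kinetic limit is
#' `UKL = ukl_fraction * MaxMom*` (default 20%). Both are dimensionless and
#' compare directly against the nRMSE of the prediction.
#'
#' @param moment numeric(60) measured moment trace. Thresholds are always
#'   computed from the measured trace so that prediction error cannot move its
#'   own acceptance band.
#' @param lkl_fraction,ukl_fraction threshold fractions,
#'   `0 < lkl_fraction < ukl_fraction`.
#' @return object of class `threshold_pair` with elements `max_mom_star`,
#'   `lkl`, `ukl`, `lkl_fraction`, `ukl_fraction`.
#' @seealso [assign_label()], [nrmse()]
#' @export
kinetic_limits <- function(moment, lkl_fraction = 0.10, ukl_fraction = 0.20) {
  if (!is.finite(lkl_fraction) || !is.finite(ukl_fraction) ||
      lkl_fraction <= 0 || lkl_fraction >= ukl_fraction) {
    stop("threshold fractions must satisfy 0 < lkl_fraction < ukl_fraction",
         call. = FALSE)
  }
  mm <- standardized_peak(moment)
  structure(list(max_mom_star = mm,
                 lkl = lkl_fraction * mm,
                 ukl = ukl_fraction * mm,
                 lkl_fraction = lkl_fraction,
                 ukl_fraction = ukl_fraction),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> MaxMom* = %.4f | LKL = %.4f (%.0f%%) | UKL = %.4f (%.0f%%)\n",
              x$max_mom_star, x$lkl, 100 * x$lkl_fraction,
              x$ukl, 100 * x$ukl_fraction))
  invisible(x)
}

#' Normalised root-mean-square error between measured and predicted curves
#'
#' RMSE over the stance samples divided by the peak-to-peak amplitude of the
#' *measured* curve. Dimensionless, zero iff the curves are identical, and
#' invariant under a common positive rescaling of both curves.
#'
#' @param measured,predicted numeric vectors of equal length (the canonical
#'   60-sample stance grid in normal use).
#' @return dimensionless scalar `>= 0`.
#' @export
nrmse <- function(measured, predicted) {
  n <- length(measured)
  measured <- check_curve(measured, "measured", n_points = n)
  predicted <- check_curve(predicted, "predicted", n_points = n)
  p2p <- max(measured) - min(measured)
  if (p2p <= 0) {
    stop("degenerate trace: flat measured curve has zero peak-to-peak range",
         call. = FALSE)
  }
  sqrt(mean((measured - predicted)^2)) / p2p
}

#' Traffic-light label for a prediction error
#'
#' Green when the nRMSE is strictly below the lower kinetic limit
#' (acceptable), Red when strictly above the upper kinetic limit
#' (unacceptable), Yellow otherwise (acceptable with caution). Boundary ties
#' are Yellow: Green requires being strictly smaller than LKL and Red strictly
#' bigger than UKL.
#'
#' @param nrmse_value numeric vector of nRMSE values (`>= 0`).
#' @param thresholds a [kinetic_limits()] `threshold_pair`.
#' @return factor with ordered levels Green, Yellow, Red.
#' @export
assign_label <- function(nrmse_value, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (any(!is.finite(nrmse_value) | nrmse_value < 0)) {
    stop("nrmse_value must be finite and >= 0", call. = FALSE)
  }
  lab <- ifelse(nrmse_value < thresholds$lkl, "Green",
                ifelse(nrmse_value > thresholds$ukl, "Red", "Yellow"))
  factor(lab, levels = MOMENT_LABELS)
}

#' Label a whole cohort for one joint
#'
#' Computes per record the nRMSE between the measured and predicted moment of
#' `joint`, the per-trace kinetic limits, and the Green/Yellow/Red label, and
#' summarises label populations and per-label nRMSE in the shape of the
#' label-population table used in clinical reporting. Records whose
#' measured trace is degenerate (constant) are excluded from the summary and
#' reported separately — a constant physiological moment signals corrupt
#' input, not a borderline case.
#'
#' @param records list of [subject_record()]s, each carrying measured and
#'   predicted curves for `joint`.
#' @param joint `"hip"`, `"knee"` or `"ankle"`.
#' @param lkl_fraction,ukl_fraction threshold fractions passed to
#'   [kinetic_limits()].
#' @return object of class `moment_labeling`: a list with
#'   \describe{
#'     \item{results}{data frame: subject_id, side, joint, nrmse,
#'       max_mom_star, lkl, ukl, label.}
#'     \item{summary}{data frame per label: n, percent, nrmse_mean, nrmse_sd
#'       (percentages over labelled records).}
#'     \item{excluded}{data frame of degenerate records with the error
#'       message.}
#'   }
#' @export
label_cohort <- function(records, joint, lkl_fraction = 0.10,
                         ukl_fraction = 0.20) {
  check_cohort(records)
  joint <- match.arg(joint, JOINTS)
  rows <- vector("list", length(records))
  excluded <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$measured_moments[[joint]]) ||
        is.null(r$predicted_moments[[joint]])) {
      stop("subject ", r$subject_id, " (", r$side, "): no measured/predicted ",
           joint, " moment", call. = FALSE)
    }
    res <- tryCatch({
      lim <- kinetic_limits(r$measured_moments[[joint]], lkl_fraction,
                            ukl_fraction)
      e <- nrmse(r$measured_moments[[joint]], r$predicted_moments[[joint]])
      data.frame(subject_id = r$subject_id, side = r$side, joint = joint,
                 nrmse = e, max_mom_star = lim$max_mom_star,
                 lkl = lim$lkl, ukl = lim$ukl,
                 label = as.character(assign_label(e, lim)))
    }, error = function(cond) cond)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = r$subject_id, side = r$side, joint = joint,
                   reason = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results)) {
    results <- data.frame(subject_id = character(), side = character(),
                          joint = character(), nrmse = numeric(),
                          max_mom_star = numeric(), lkl = numeric(),
                          ukl = numeric(), label = character())
  }
  results$label <- factor(results$label, levels = MOMENT_LABELS)
  n_lab <- nrow(results)
  summary <- do.call(rbind, lapply(MOMENT_LABELS, function(lb) {
    v <- results$nrmse[results$label == lb]
    data.frame(label = lb, n = length(v),
               percent = if (n_lab) 100 * length(v) / n_lab else NA_real_,
               nrmse_mean = if (length(v)) mean(v) else NA_real_,
               nrmse_sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(subject_id = character(), side = character(),
               joint = character(), reason = character())
  structure(list(results = results, summary = summary, excluded = excluded,
                 joint = joint, lkl_fraction = lkl_fraction,
                 ukl_fraction = ukl_fraction),
            class = "moment_labeling")
}

#' @export
print.moment_labeling <- function(x, ...) {
  cat("<moment_labeling> joint:", x$joint, "| labelled:", nrow(x$results),
      "| excluded:", nrow(x$excluded), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s n = %4d (%5.1f%%)  nRMSE = %s +/- %s\n",
                s$label[i], s$n[i], s$percent[i],
                ifelse(is.na(s$nrmse_mean[i]), "-", sprintf("%.3f", s$nrmse_mean[i])),
                ifelse(is.na(s$nrmse_sd[i]), "-", sprintf("%.3f", s$nrmse_sd[i]))))
  }
  invisible(x)
}
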
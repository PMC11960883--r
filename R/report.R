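#' Run the full three-step pipeline and write the report bundle
#'
#' For every requested joint this labels the cohort (step 1), profiles the
#' kinematic features and subphase errors by label (step 2), compares nRMSE
#' across labels (ANOVA + Bonferroni) and fits/evaluates the label classifier
#' on a train/test split (step 3), then writes six CSV outputs plus a JSON
#' manifest to `out_dir`:
#'
#' * `labels.csv` — per record/joint nRMSE, thresholds and label (also the
#'   per-label histogram source data);
#' * `label_summary.csv` — per-joint label populations, percentages and
#'   nRMSE mean/sd;
#' * `features_by_label.csv` — per-label kinematic feature and GPS summary;
#' * `subphase_profiles.csv` — per-label subphase error quartiles;
#' * `comparisons.csv` — ANOVA and Bonferroni pairwise results;
#' * `classifier_metrics.csv` — per-joint confusion marginals, F-scores and
#'   accuracy, including the Green+Yellow merged row;
#' * `manifest.json` — configuration, seed and group sizes of the run.
#'
#' Outputs are deterministic given the same cohort and seed.
#'
#' @param records list of [subject_record()]s.
#' @param reference a [reference_profile()] for GPS and features.
#' @param out_dir output directory (created if absent); `NULL` skips writing
#'   and just returns the computed bundle.
#' @param joints joints to process (default all three).
#' @param variable_set kinematic variables used for features and GPS.
#' @param lkl_fraction,ukl_fraction threshold fractions.
#' @param train_fraction,train_count,split_seed train/test split controls
#'   (see [split_cohort()]); one split is shared by all joints.
#' @param merge_green_yellow also score the classifier with Green and Yellow
#'   pooled (default `TRUE`).
#' @param include_gps include GPS among the classifier features.
#' @param alpha familywise alpha for the label comparisons.
#' @return object of class `momentqc_report` (invisibly when writing): list
#'   with per-joint `labeling`, `features`, `subphases`, `comparison`,
#'   `classifier` plus the split and file paths.
#' @export
build_report <- function(records, reference, out_dir = NULL,
                         joints = JOINTS, variable_set = SAGITTAL_VARS,
                         lkl_fraction = 0.10, ukl_fraction = 0.20,
                         train_fraction = 0.8, train_count = NULL,
                         split_seed = 1L, merge_green_yellow = TRUE,
                         include_gps = TRUE, alpha = 0.05) {
  check_cohort(records)
  joints <- match.arg(joints, JOINTS, several.ok = TRUE)
  split <- split_cohort(records, train_fraction = train_fraction,
                        seed = split_seed, train_count = train_count)
  feats_all <- extract_features(records, reference, variable_set, include_gps)
  test_idx <- setdiff(seq_along(records), split$train_idx)

  per_joint <- list()
  for (joint in joints) {
    labeling <- label_cohort(records, joint, lkl_fraction, ukl_fraction)
    features <- features_by_label(records, labeling, joint, reference,
                                  variable_set)
    subphases <- subphase_error_profile(records, labeling, joint)

    groups <- split(labeling$results$nrmse, labeling$results$label)
    groups <- groups[vapply(groups, function(g) length(g) >= 2L, logical(1))]
    comparison <- if (length(groups) >= 2L) {
      bonferroni_pairwise(groups, alpha = alpha)
    } else NULL

    label_of <- stats::setNames(as.character(labeling$results$label),
                                paste(labeling$results$subject_id,
                                      labeling$results$side, sep = ":"))
    ids <- rownames(feats_all)
    train_ok <- split$train_idx[ids[split$train_idx] %in% names(label_of)]
    test_ok <- test_idx[ids[test_idx] %in% names(label_of)]
    classifier <- NULL
    report <- NULL
    train_lab_all <- label_of[ids[train_ok]]
    cnt <- table(train_lab_all)
    good_classes <- names(cnt)[cnt >= 2L]  # singleton classes cannot be fit
    keep <- train_ok[train_lab_all %in% good_classes]
    if (length(good_classes) >= 2L && length(test_ok)) {
      train_labels <- droplevels(factor(label_of[ids[keep]],
                                        levels = MOMENT_LABELS))
      classifier <- fit_lda(feats_all[keep, , drop = FALSE], train_labels)
      pred <- as.character(predict_lda(classifier, feats_all[test_ok, , drop = FALSE]))
      truth <- label_of[ids[test_ok]]
      merge <- if (merge_green_yellow &&
                   all(c("Green", "Yellow") %in% union(truth, pred))) {
        c("Green", "Yellow")
      } else NULL
      report <- classification_report(truth, pred, merge = merge)
    }
    per_joint[[joint]] <- list(labeling = labeling, features = features,
                               subphases = subphases,
                               comparison = comparison,
                               classifier = classifier,
                               classifier_report = report)
  }

  bundle <- structure(
    list(per_joint = per_joint, split = split,
         config = list(joints = joints, variable_set = variable_set,
                       lkl_fraction = lkl_fraction,
                       ukl_fraction = ukl_fraction,
                       train_fraction = train_fraction,
                       train_count = train_count, split_seed = split_seed,
                       merge_green_yellow = merge_green_yellow,
                       include_gps = include_gps, alpha = alpha,
                       n_records = length(records))),
    class = "momentqc_report")
  if (!is.null(out_dir)) {
    bundle$files <- write_report_bundle(bundle, out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_report_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  pj <- bundle$per_joint
  write_one <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  labels <- do.call(rbind, lapply(pj, function(x) x$labeling$results))
  summaries <- do.call(rbind, lapply(names(pj), function(j) {
    cbind(joint = j, pj[[j]]$labeling$summary)
  }))
  features <- do.call(rbind, lapply(names(pj), function(j) {
    cbind(joint = j, pj[[j]]$features)
  }))
  subphases <- do.call(rbind, lapply(pj, function(x) x$subphases))
  comparisons <- do.call(rbind, lapply(names(pj), function(j) {
    cm <- pj[[j]]$comparison
    if (is.null(cm)) return(NULL)
    cbind(joint = j, cm$pairwise,
          f_statistic = cm$f_statistic, anova_p = cm$anova_p,
          corrected_alpha = cm$corrected_alpha)
  }))
  classifier <- do.call(rbind, lapply(names(pj), function(j) {
    rep <- pj[[j]]$classifier_report
    if (is.null(rep)) return(NULL)
    base <- cbind(joint = j, merged = FALSE, rep$per_class,
                  accuracy = rep$accuracy)
    if (!is.null(rep$merged)) {
      base <- rbind(base, cbind(joint = j, merged = TRUE,
                                rep$merged$per_class,
                                accuracy = rep$merged$accuracy))
    }
    base
  }))
  files <- c(
    labels = write_one(labels, "labels.csv"),
    label_summary = write_one(summaries, "label_summary.csv"),
    features_by_label = write_one(features, "features_by_label.csv"),
    subphase_profiles = write_one(subphases, "subphase_profiles.csv"),
    comparisons = write_one(
      if (is.null(comparisons)) data.frame() else comparisons,
      "comparisons.csv"),
    classifier_metrics = write_one(
      if (is.null(classifier)) data.frame() else classifier,
      "classifier_metrics.csv"))
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    c(bundle$config,
      list(n_train = length(bundle$split$train_idx),
           n_test = bundle$config$n_records - length(bundle$split$train_idx),
           files = basename(unname(files)))),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, manifest = manifest)
}

#' @export
print.momentqc_report <- function(x, ...) {
  cat("<momentqc_report> joints:", paste(names(x$per_joint), collapse = ", "),
      "| records:", x$config$n_records,
      sprintf("(train %d / test %d)\n", length(x$split$train_idx),
              x$config$n_records - length(x$split$train_idx)))
  for (j in names(x$per_joint)) {
    cat("--", j, "moment --\n")
    print(x$per_joint[[j]]$labeling)
    rep <- x$per_joint[[j]]$classifier_report
    if (!is.null(rep)) print(rep)
  }
  invisible(x)
}
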
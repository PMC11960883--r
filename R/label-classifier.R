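#' Build the kinematic feature matrix for classification
#'
#' One row per record: MAX, ROM and MEAN of each variable in `variable_set`
#' (12 features for the sagittal four) plus, optionally, the GPS as a 13th
#' feature. These are exactly the per-label quantities the profiling step
#' tabulates, which makes the classifier's inputs clinically interpretable.
#'
#' @param records list of [subject_record()]s.
#' @param reference a [reference_profile()]; required when
#'   `include_gps = TRUE`.
#' @param variable_set kinematic variables to featurise.
#' @param include_gps append the GPS column (default `TRUE`).
#' @return numeric matrix, rownames `subject_id:side`, colnames like
#'   `HipFlx_ROM` and `GPS`.
#' @export
extract_features <- function(records, reference = NULL,
                             variable_set = SAGITTAL_VARS,
                             include_gps = TRUE) {
  check_cohort(records)
  if (include_gps && is.null(reference)) {
    stop("a reference_profile is required when include_gps = TRUE",
         call. = FALSE)
  }
  feat_names <- as.vector(t(outer(variable_set, c("MAX", "ROM", "MEAN"),
                                  paste, sep = "_")))
  if (include_gps) feat_names <- c(feat_names, "GPS")
  m <- matrix(NA_real_, nrow = length(records), ncol = length(feat_names),
              dimnames = list(record_ids(records), feat_names))
  for (i in seq_along(records)) {
    r <- records[[i]]
    vals <- unlist(lapply(r$kinematics[variable_set], curve_features),
                   use.names = FALSE)
    if (include_gps) {
      vals <- c(vals, gait_profile_score(r, reference, variable_set))
    }
    m[i, ] <- vals
  }
  m
}

#' Split a cohort into training and test partitions
#'
#' Random, disjoint and exhaustive partition. The training size is
#' `round(n * train_fraction)` unless `train_count` fixes it explicitly (e.g.
#' 500 of 622). Reproducible under the same seed; the global RNG state is
#' untouched.
#'
#' @param records list (any list: records, rows, indices are all fine).
#' @param train_fraction fraction in (0, 1), default 0.8.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param train_count optional explicit training-set size overriding the
#'   fraction.
#' @param stratify optional factor of `length(records)`; when given, the
#'   split is drawn within each stratum (label-balanced splitting).
#' @return list with `train`, `test` (sub-lists) and `train_idx` (integer
#'   indices into `records`).
#' @export
split_cohort <- function(records, train_fraction = 0.8, seed = NULL,
                         train_count = NULL, stratify = NULL) {
  n <- length(records)
  if (n == 0L) stop("cannot split an empty cohort", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(train_count)) {
    if (train_count < 1L || train_count > n) {
      stop("train_count must be between 1 and the cohort size", call. = FALSE)
    }
  }
  idx <- with_seed(seed, {
    if (is.null(stratify)) {
      k <- if (is.null(train_count)) round(n * train_fraction) else train_count
      sort(sample.int(n, k))
    } else {
      stopifnot(length(stratify) == n)
      picked <- unlist(lapply(split(seq_len(n), stratify), function(ii) {
        k <- round(length(ii) * train_fraction)
        if (length(ii) == 1L) return(ii)  # singleton strata go to training
        sample(ii, max(1L, k))
      }), use.names = FALSE)
      sort(picked)
    }
  })
  list(train = records[idx],
       test = records[setdiff(seq_len(n), idx)],
       train_idx = idx)
}

#' Fit a linear discriminant model
#'
#' Classic Gaussian LDA: per-class feature means, a pooled within-class
#' covariance (within-class scatter divided by `n - k`), and empirical class
#' priors. A ridge of `1e-8 * mean(diag(cov))` is added to the diagonal when
#' the pooled covariance is numerically singular (e.g. duplicated feature
#' columns), which keeps the discriminant defined without materially moving
#' the decision boundary.
#'
#' @param x numeric feature matrix (records by features).
#' @param labels factor (or character) of class labels, one per row of `x`.
#' @param prior `"empirical"` (default) or `"uniform"`. Empirical priors
#'   matter under the heavy label imbalance typical of this problem.
#' @param ridge ridge coefficient; `NULL` (default) applies
#'   `1e-8 * mean(diag)` only when conditioning demands it.
#' @return object of class `lda_model`.
#' @seealso [predict_lda()]
#' @export
fit_lda <- function(x, labels, prior = c("empirical", "uniform"),
                    ridge = NULL) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- droplevels(as.factor(labels))
  if (nrow(x) != length(labels)) {
    stop("x and labels must have matching lengths", call. = FALSE)
  }
  classes <- levels(labels)
  k <- length(classes)
  if (k < 2L) {
    stop("need at least 2 classes in training data to fit a discriminant",
         call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 training records; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  n <- nrow(x)
  means <- matrix(NA_real_, k, ncol(x), dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    means[cl, ] <- colMeans(x[labels == cl, , drop = FALSE])
  }
  scatter <- matrix(0, ncol(x), ncol(x))
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2L, means[cl, ])
    scatter <- scatter + crossprod(xc)
  }
  pooled <- scatter / (n - k)
  ridge_used <- 0
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  need_ridge <- is.null(inv) || !is.null(ridge) ||
    rcond(pooled) < .Machine$double.eps * 100
  if (need_ridge) {
    ridge_used <- if (is.null(ridge)) 1e-8 * mean(diag(pooled)) else ridge
    pooled_r <- pooled + diag(ridge_used, ncol(x))
    inv <- solve(pooled_r)
  }
  priors <- if (prior == "empirical") as.numeric(counts) / n
            else rep(1 / k, k)
  structure(list(classes = classes,
                 class_means = means,
                 pooled_covariance = pooled,
                 cov_inverse = inv,
                 log_priors = stats::setNames(log(priors), classes),
                 priors = stats::setNames(priors, classes),
                 counts = as.integer(counts),
                 ridge = ridge_used,
                 features = colnames(x)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> ", length(x$classes), " classes x ",
      ncol(x$class_means), " features\n", sep = "")
  cat("  classes:", paste(sprintf("%s (prior %.3f)", x$classes, x$priors),
                          collapse = ", "), "\n")
  if (x$ridge > 0) cat("  ridge: ", format(x$ridge), "\n")
  invisible(x)
}

#' Predict labels with a fitted linear discriminant model
#'
#' Assigns each record to the class maximising the linear discriminant
#' `delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`. Exact ties
#' go to the earlier class in the model's class order (Green before Yellow
#' before Red when labels were supplied as the standard factor).
#'
#' @param model an [fit_lda()] model.
#' @param x feature matrix (or single feature vector) with the model's
#'   feature dimension.
#' @return factor of predicted labels with the model's class levels.
#' @export
predict_lda <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$class_means)) {
    stop("feature dimension mismatch: model has ", ncol(model$class_means),
         ", input has ", ncol(x), call. = FALSE)
  }
  w <- model$cov_inverse %*% t(model$class_means)      # features x classes
  const <- -0.5 * colSums(t(model$class_means) * w) + model$log_priors
  scores <- x %*% w + matrix(const, nrow(x), length(model$classes),
                             byrow = TRUE)
  pick <- apply(scores, 1L, which.max)                 # first max on ties
  factor(model$classes[pick], levels = model$classes)
}

#' Precision / recall / F-score / accuracy from confusion-table marginals
#'
#' Computes one-vs-rest metrics for a single class directly from the printed
#' marginals of a confusion table: true positives, column total (predicted),
#' row total (actual) and the test-set size, plus the summed diagonal of the
#' remaining classes for the overall accuracy. Percentages are returned;
#' metrics with zero denominators are `NA` (reported as absent, printed "-").
#'
#' @param tp true positives (matched count) for the class.
#' @param predicted_total number of records predicted as the class.
#' @param actual_total number of records actually in the class.
#' @param n test-set size.
#' @param other_diagonal summed correct predictions of all other classes
#'   (default 0).
#' @return named list: `precision`, `recall`, `f_score`, `accuracy`, all in
#'   percent.
#' @examples
#' prf_from_counts(104, 119, 107, 122)  # F 92.0, accuracy 85.2
#' @export
prf_from_counts <- function(tp, predicted_total, actual_total, n,
                            other_diagonal = 0) {
  stopifnot(tp >= 0, tp <= predicted_total || predicted_total == 0,
            tp <= actual_total || actual_total == 0, n >= 1)
  precision <- if (predicted_total > 0) 100 * tp / predicted_total else NA_real_
  recall <- if (actual_total > 0) 100 * tp / actual_total else NA_real_
  f_score <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- 100 * (tp + other_diagonal) / n
  list(precision = precision, recall = recall, f_score = f_score,
       accuracy = accuracy)
}

#' Confusion matrix and per-class metrics for predicted labels
#'
#' Tabulates true against predicted labels, computes the overall accuracy and
#' one-vs-rest precision, recall (sensitivity) and F-score per class, and —
#' when `merge` names a label subset — repeats the computation after pooling
#' those labels into one class. Merging Green and Yellow mirrors the clinical
#' reading "not unacceptable".
#'
#' @param true_labels,predicted_labels equal-length label vectors/factors.
#' @param merge optional character vector of labels to pool (e.g.
#'   `c("Green", "Yellow")`), or `NULL`.
#' @return object of class `classifier_report`: list with `confusion`
#'   (table), `n_test`, `accuracy` (percent), `per_class` data frame
#'   (class, actual, predicted, matched, precision, recall, f_score) and,
#'   when requested, `merged` (a `classifier_report` on the pooled labels,
#'   with `merged_class` naming the pooled label).
#' @export
classification_report <- function(true_labels, predicted_labels,
                                  merge = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors must have equal length",
         call. = FALSE)
  }
  lev <- union(levels(as.factor(true_labels)), levels(as.factor(predicted_labels)))
  if (all(lev %in% MOMENT_LABELS)) lev <- MOMENT_LABELS[MOMENT_LABELS %in% lev]
  truth <- factor(as.character(true_labels), levels = lev)
  pred <- factor(as.character(predicted_labels), levels = lev)
  conf <- table(true = truth, predicted = pred)
  n <- length(truth)
  diag_counts <- diag(conf)
  accuracy <- 100 * sum(diag_counts) / n
  per_class <- do.call(rbind, lapply(seq_along(lev), function(i) {
    m <- prf_from_counts(tp = conf[i, i],
                         predicted_total = sum(conf[, i]),
                         actual_total = sum(conf[i, ]),
                         n = n,
                         other_diagonal = sum(diag_counts[-i]))
    data.frame(class = lev[i], actual = sum(conf[i, ]),
               predicted = sum(conf[, i]), matched = conf[i, i],
               precision = m$precision, recall = m$recall,
               f_score = m$f_score)
  }))
  out <- list(confusion = conf, n_test = n, accuracy = accuracy,
              per_class = per_class)
  if (!is.null(merge)) {
    if (!all(merge %in% lev)) {
      stop("merge labels not present: ",
           paste(setdiff(merge, lev), collapse = ", "), call. = FALSE)
    }
    pooled_name <- paste(merge, collapse = "+")
    pool <- function(v) {
      v <- as.character(v)
      v[v %in% merge] <- pooled_name
      v
    }
    merged <- classification_report(pool(truth), pool(pred), merge = NULL)
    merged$merged_class <- pooled_name
    out$merged <- merged
  }
  structure(out, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, digits = 1, ...) {
  cat("<classifier_report> n =", x$n_test,
      sprintf("| accuracy = %.*f%%\n", digits, x$accuracy))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-12s actual %4d  predicted %4d  matched %4d  F = %s\n",
                pc$class[i], pc$actual[i], pc$predicted[i], pc$matched[i],
                ifelse(is.na(pc$f_score[i]), "-",
                       sprintf("%.*f%%", digits, pc$f_score[i]))))
  }
  if (!is.null(x[["merged"]])) {
    cat("  -- merged (", x[["merged"]][["merged_class"]], ") --\n", sep = "")
    print(x[["merged"]], digits = digits)
  }
  invisible(x)
}
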
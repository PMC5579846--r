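## Cross-validation harness for the five experimental cases.
##
## A case run is: segmentation -> (case-specific step: nothing / fresh random
## per-segment-per-unit rotations / Euclidean norm / heuristic transform /
## SVD transform) -> feature extraction -> per-subject [0,1] normalization ->
## per-fold PCA -> classifier train/test.  Per-subject normalization uses
## each subject's own min/max and therefore precedes the train/test split;
## a leakage-free variant is available through the PCA and scale fit modes.

#' Random P-fold partition
#'
#' Seeded, non-stratified random split of `1:n` into `P` disjoint,
#' exhaustive index sets whose sizes differ by at most one.
#'
#' @param n Number of rows (or a feature table, whose row count is used).
#' @param P Number of folds, `2 <= P <= n`.
#' @param seed Integer seed.
#' @return List of `P` integer vectors.
#' @export
pfold_partition <- function(n, P = 10L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (P > n) stop("P = ", P, " exceeds the number of rows (", n, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% P, P) + c(rep(1L, n %% P), rep(0L, P - n %% P))
  split(perm, rep(seq_len(P), times = sizes))
}

#' Leave-one-subject-out partition
#'
#' One fold per subject, containing all and only that subject's rows. Probes
#' generalization across subjects, which is harder than a random split
#' because training and test sets then contain different subjects' data.
#'
#' @param table A feature table with a `subject_id` column.
#' @return Named list of integer vectors, one per subject.
#' @export
l1o_partition <- function(table) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  lapply(setNames(subjects, subjects),
         function(s) which(table$subject_id == s))
}

## Replace each segment's blocks by the case-specific channels.
apply_case_transform <- function(segments, case, heuristic_elements = 9L,
                                 scales = NULL) {
  switch(case,
    reference = ,
    random_rotation = segments,
    euclidean_norm = lapply(segments, function(seg) {
      seg$blocks <- lapply(seg$blocks, euclidean_norm_transform)
      seg
    }),
    heuristic = lapply(segments, function(seg) {
      seg$blocks <- lapply(seg$blocks, function(b)
        truncate_channels(heuristic_transform(b), heuristic_elements))
      seg
    }),
    svd = {
      if (is.null(scales)) scales <- fit_sensor_scales(segments)
      lapply(segments, svd_transform_segment, scales = scales)
    },
    stop("unknown case '", case, "'; allowed: reference, random_rotation, ",
         "euclidean_norm, heuristic, svd"))
}

#' Normalized feature table for one experimental case
#'
#' Applies the case-specific transformation to already-cut (and, for the
#' random-rotation case, already-rotated) segments, extracts features, and
#' min-max normalizes them per subject.
#'
#' @param segments List of segments.
#' @param case One of the five case names.
#' @param heuristic_elements 3, 6 or 9 (heuristic case only).
#' @param scales Optional [fit_sensor_scales()] output (SVD case); fitted on
#'   the given segments when omitted. The SVD transform is invariant to
#'   segment rotations for a *fixed* set of scales, so rotation-transparency
#'   checks must supply the same scales on both sides.
#' @param spec A [feature_spec()].
#' @return A normalized feature table.
#' @export
case_feature_table <- function(segments, case, heuristic_elements = 9L,
                               scales = NULL, spec = feature_spec()) {
  transformed <- apply_case_transform(segments, case, heuristic_elements, scales)
  normalize_per_subject(build_feature_table(transformed, spec))
}

#' Run one (case, classifier, cross-validation scheme) experiment
#'
#' @param dataset An [oimotion_dataset()].
#' @param classifier One of `"bdm"`, `"knn"`, `"svm"`, `"ann"`.
#' @param scheme `"pfold"` or `"l1o"`.
#' @param pconf A [pipeline_config()]; its `case`, window, PCA and seed
#'   fields drive the run.
#' @param cconf A [classifier_config()].
#' @param P Number of folds for the P-fold scheme (default 10).
#' @param scales Optional precomputed sensor scales for the SVD case; when
#'   supplied they override `pconf$scale_fit_mode`.
#' @param spec A [feature_spec()].
#' @return An object of class `cv_result`: per-fold accuracies, their mean
#'   and standard deviation, and the pooled confusion matrix (rows = true
#'   activity, columns = predicted).
#' @export
run_case <- function(dataset, classifier = "knn",
                     scheme = c("pfold", "l1o"),
                     pconf = pipeline_config(), cconf = classifier_config(),
                     P = 10L, scales = NULL, spec = feature_spec()) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "oimotion_dataset"))
  case <- pconf$case
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(pconf$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)  # rotation, partition, classifier

  segments <- segment_dataset(dataset, pconf$window_s, pconf$overlap_fraction)
  if (length(segments) == 0L) stop("dataset yields no complete window")
  if (case == "random_rotation")
    segments <- inject_rotations(segments, seeds[[1L]])$segments

  per_fold_scales <- case == "svd" && is.null(scales) &&
    pconf$scale_fit_mode == "train_only"
  if (!per_fold_scales) {
    table <- case_feature_table(segments, case, pconf$heuristic_elements,
                                scales, spec)
  } else {
    ## fold-dependent sensor scales: features must be rebuilt per fold
    table <- build_feature_table(segments, spec)   # labels/partition only
  }

  folds <- if (scheme == "pfold") pfold_partition(nrow(table), P, seeds[[2L]])
           else l1o_partition(table)
  classes <- sort(unique(table$activity_id))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  cconf$seed <- seeds[[3L]]

  acc <- vapply(seq_along(folds), function(f) {
    test_idx <- folds[[f]]
    tab <- if (per_fold_scales) {
      fold_scales <- fit_sensor_scales(segments[-test_idx])
      case_feature_table(segments, case, pconf$heuristic_elements,
                         fold_scales, spec)
    } else table
    M <- min(pconf$pca_dims, ncol(feature_matrix(tab)))
    red <- pca_reduce(tab[-test_idx, , drop = FALSE],
                      tab[test_idx, , drop = FALSE],
                      M, pconf$pca_fit_mode)
    model <- fit_classifier(classifier, feature_matrix(red$train),
                            red$train$activity_id, cconf)
    pred <- predict_classifier(classifier, model, feature_matrix(red$test))
    truth <- red$test$activity_id
    for (i in seq_along(truth))
      confusion[truth[[i]], pred[[i]]] <<- confusion[truth[[i]], pred[[i]]] + 1L
    mean(pred == truth)
  }, numeric(1))

  structure(list(scheme = scheme, case = case, classifier = classifier,
                 fold_accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), confusion = confusion,
                 n_segments = nrow(table), seed = pconf$seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> case=%s classifier=%s scheme=%s\n",
              x$case, x$classifier, x$scheme))
  cat(sprintf("  accuracy: %.4f +/- 2*%.4f over %d folds (%d segments)\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracy),
              x$n_segments))
  invisible(x)
}

#' Tabulate a set of cross-validation results
#'
#' One row per result with the mean accuracy, the plus/minus two standard
#' deviation band over folds, and, where a reference-case result with the
#' same classifier and scheme is present, the accuracy drop relative to it
#' (in percentage points).
#'
#' @param results List of `cv_result` objects.
#' @return A `data.frame`.
#' @export
summarize_results <- function(results) {
  stopifnot(length(results) >= 1L)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(case = r$case, classifier = r$classifier, scheme = r$scheme,
               mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy,
               lo = r$mean_accuracy - 2 * r$sd_accuracy,
               hi = r$mean_accuracy + 2 * r$sd_accuracy,
               stringsAsFactors = FALSE)))
  df$drop_vs_reference_pct <- NA_real_
  for (i in seq_len(nrow(df))) {
    ref <- which(df$case == "reference" & df$classifier == df$classifier[[i]] &
                   df$scheme == df$scheme[[i]])
    if (length(ref))
      df$drop_vs_reference_pct[[i]] <-
        100 * (df$mean_accuracy[[ref[[1L]]]] - df$mean_accuracy[[i]])
  }
  df
}
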
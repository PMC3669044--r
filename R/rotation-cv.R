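#' Enumerate the rotation arrangements of a 4-fold partition
#'
#' The double cross-validation rotation: for each test fold, the remaining
#' three folds rotate through the calibration role, the other two forming
#' the (unordered) SVM training pair. With a fixed test fold there are three
#' arrangements, e.g. for test fold 1: calibrate on 2 / train on \{3, 4\},
#' calibrate on 3 / train on \{4, 2\}, calibrate on 4 / train on \{2, 3\}.
#' In total 12 arrangements, hence 12 SVM fits per category.
#'
#' @param k number of folds; the scheme is specific to `k = 4`.
#' @return Data frame with columns `test`, `calib`, `train1`, `train2`
#'   (fold indices), 12 rows, three per test fold.
#' @export
enumerate_arrangements <- function(k = 4L) {
  if (k != 4L) stop("the rotation scheme is defined for exactly 4 folds")
  rows <- list()
  for (test in 1:4) {
    rest <- setdiff(1:4, test)
    for (calib in rest) {
      train <- setdiff(rest, calib)
      rows[[length(rows) + 1L]] <- data.frame(
        test = test, calib = calib, train1 = train[1L], train2 = train[2L])
    }
  }
  do.call(rbind, rows)
}

#' Run one (test | calibration | training) arrangement
#'
#' The kernel width sigma is recomputed on the two training folds, the SVM is
#' trained on them via the augmented precomputed kernel, the sigmoid is
#' fitted to the calibration fold's discriminants against its smoothed
#' targets, and posterior probabilities are emitted for every test-fold row
#' and every unlabeled (un-annotated) row. Neither the calibration fold nor
#' the test fold ever enters SVM training, and the test fold never enters
#' the sigmoid fit.
#'
#' @param task a `category_task`.
#' @param partition a `fold_partition` of the task.
#' @param arrangement one row of [enumerate_arrangements()] (or a list with
#'   `test`, `calib`, `train1`, `train2`).
#' @param features numeric matrix of imputed feature vectors, rows indexed as
#'   in the task.
#' @return List with `test` (data frame `row`, `p`), `unlabeled` (data frame
#'   `row`, `p`), `sigma`, `fit` (the `sigmoid_fit`), `model`, and the
#'   arrangement.
#' @export
run_arrangement <- function(task, partition, arrangement, features) {
  stopifnot(inherits(task, "category_task"),
            inherits(partition, "fold_partition"))
  features <- as.matrix(features)
  arr <- as.list(arrangement)
  folds <- partition$folds
  train_idx <- c(folds[[arr$train1]], folds[[arr$train2]])
  calib_idx <- folds[[arr$calib]]
  test_idx <- folds[[arr$test]]
  lab <- function(idx) ifelse(idx %in% task$positives, 1, -1)
  y_train <- lab(train_idx)
  x_train <- features[train_idx, , drop = FALSE]
  sigma <- sigma_heuristic(x_train, y_train)
  k_train <- augment_diagonal(rbf_kernel(x_train, sigma = sigma), y_train,
                              sigma = sigma)
  model <- train_svm(k_train)
  f_calib <- discriminants(
    model, rbf_kernel(features[calib_idx, , drop = FALSE], x_train, sigma))
  fit <- fit_sigmoid(f_calib, platt_targets(lab(calib_idx)))
  score <- function(idx) {
    if (length(idx) == 0L) return(numeric(0))
    f <- discriminants(
      model, rbf_kernel(features[idx, , drop = FALSE], x_train, sigma))
    apply_sigmoid(fit, f)
  }
  list(
    test = data.frame(row = test_idx, p = score(test_idx)),
    unlabeled = data.frame(
      row = task$unlabeled,
      p = score(task$unlabeled) %||% numeric(0)),
    sigma = sigma, fit = fit, model = model, arrangement = arr
  )
}

#' Average arrangement probabilities into a probability table
#'
#' Each labeled row sits in exactly one test fold and therefore receives
#' three probability estimates (one per arrangement with that test fold);
#' their arithmetic mean is its unique probability estimate. Each unlabeled
#' row is scored in all 12 arrangements; the three estimates sharing a test
#' fold are averaged into that fold's estimate, giving four fold-specific
#' probabilities per unlabeled row.
#'
#' @param arrangement_results list of 12 results from [run_arrangement()].
#' @param task the `category_task`.
#' @param partition the `fold_partition`.
#' @return A `probability_table`: list with `labeled` (data frame `row`,
#'   `label`, `test_fold`, `p1`, `p2`, `p3` ordered by calibration fold id,
#'   `p_mean`) and `unlabeled` (data frame `row`, `p_fold1` .. `p_fold4`).
#' @export
average_probabilities <- function(arrangement_results, task, partition) {
  if (length(arrangement_results) != 12L) {
    stop("expected 12 arrangement results, got ", length(arrangement_results))
  }
  folds <- partition$folds
  fold_of <- integer(0)
  for (f in seq_along(folds)) fold_of[folds[[f]]] <- f
  labeled_rows <- sort(c(task$positives, task$negatives))
  p_arr <- matrix(NA_real_, length(labeled_rows), 3L,
                  dimnames = list(as.character(labeled_rows), NULL))
  unl_rows <- task$unlabeled
  p_unl <- array(NA_real_, c(length(unl_rows), 4L, 3L),
                 dimnames = list(as.character(unl_rows), NULL, NULL))
  slot_count <- integer(4L)
  for (res in arrangement_results) {
    tf <- res$arrangement$test
    slot_count[tf] <- slot_count[tf] + 1L
    s <- slot_count[tf]
    p_arr[as.character(res$test$row), s] <- res$test$p
    if (length(unl_rows)) {
      p_unl[as.character(res$unlabeled$row), tf, s] <- res$unlabeled$p
    }
  }
  if (anyNA(p_arr)) stop("missing arrangement value for a labeled row")
  labeled <- data.frame(
    row = labeled_rows,
    label = ifelse(labeled_rows %in% task$positives, 1, -1),
    test_fold = fold_of[labeled_rows],
    p1 = p_arr[, 1L], p2 = p_arr[, 2L], p3 = p_arr[, 3L],
    p_mean = rowMeans(p_arr))
  rownames(labeled) <- NULL
  if (length(unl_rows)) {
    if (anyNA(p_unl)) stop("missing arrangement value for an unlabeled row")
    fold_means <- apply(p_unl, c(1L, 2L), mean)
    unlabeled <- data.frame(row = unl_rows)
    for (f in 1:4) unlabeled[[paste0("p_fold", f)]] <- fold_means[, f]
  } else {
    unlabeled <- data.frame(row = integer(0), p_fold1 = numeric(0),
                            p_fold2 = numeric(0), p_fold3 = numeric(0),
                            p_fold4 = numeric(0))
  }
  structure(list(labeled = labeled, unlabeled = unlabeled),
            class = "probability_table")
}

#' Full rotation cross-validation for one category
#'
#' Runs all 12 arrangements of the 4-fold partition and averages the
#' probabilities; see [run_arrangement()] and [average_probabilities()].
#'
#' @inheritParams run_arrangement
#' @return A `probability_table` (with the per-arrangement results attached
#'   as attribute `"arrangements"`).
#' @export
rotation_cv <- function(task, partition, features) {
  arrs <- enumerate_arrangements(4L)
  results <- lapply(seq_len(nrow(arrs)), function(i) {
    run_arrangement(task, partition, arrs[i, ], features)
  })
  out <- average_probabilities(results, task, partition)
  attr(out, "arrangements") <- results
  out
}
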
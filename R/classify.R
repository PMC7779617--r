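#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + FP + FN + TN)`, all reported as
#' percentages.
#'
#' @param TP,FN,TN,FP Nonnegative counts; both classes must be non-empty.
#' @return Named numeric vector (percent).
#' @examples
#' confusion_metrics(26, 4, 27, 3)   # 86.67, 90.00, 88.33
#' @export
confusion_metrics <- function(TP, FN, TN, FP) {
  TP <- unname(TP); FN <- unname(FN); TN <- unname(TN); FP <- unname(FP)
  counts <- c(TP = TP, FN = FN, TN = TN, FP = FP)
  if (any(counts < 0) || anyNA(counts)) {
    stop("confusion counts must be nonnegative", call. = FALSE)
  }
  if (TP + FN == 0 || TN + FP == 0) {
    stop("both classes must be non-empty (TP+FN > 0 and TN+FP > 0)",
         call. = FALSE)
  }
  c(sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    accuracy = 100 * (TP + TN) / (TP + FN + TN + FP))
}

kernel_settings <- function(kernel, p) {
  # Gaussian kernel scale sigma follows the fine/medium/coarse convention
  # sigma = sqrt(p)/4, sqrt(p), 4*sqrt(p); K(u,v) = exp(-||u-v||^2/sigma^2)
  # maps to the radial-kernel gamma = 1/sigma^2.
  switch(kernel,
         linear = list(kernel = "linear", gamma = NULL),
         fine_gaussian = list(kernel = "radial", gamma = 1 / (sqrt(p) / 4)^2),
         medium_gaussian = list(kernel = "radial", gamma = 1 / sqrt(p)^2),
         coarse_gaussian = list(kernel = "radial", gamma = 1 / (4 * sqrt(p))^2),
         stop(sprintf("unknown kernel '%s'", kernel), call. = FALSE))
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of an SVM
#'
#' Trains a support vector machine on the feature vectors under repeated
#' stratified k-fold cross-validation and reports sensitivity, specificity
#' and accuracy averaged over repeats, together with the pooled confusion
#' counts. Features are z-scored with means and standard deviations fitted
#' on the training folds only. Folds are stratified so both classes keep
#' their proportion in every fold; the whole procedure is deterministic
#' given `seed`.
#'
#' @param vectors Numeric matrix, one row per subject.
#' @param labels Factor or character vector of two classes.
#' @param kernel One of `"linear"`, `"fine_gaussian"`, `"medium_gaussian"`,
#'   `"coarse_gaussian"`.
#' @param k Number of folds (default 10).
#' @param repeats Number of independent fold partitions (default 20).
#' @param positive Label treated as the positive (patient) class; defaults
#'   to the first level.
#' @param cost SVM box constraint (default 1).
#' @param seed Integer seed.
#' @return An object of class `eval_report`: list with `metrics` (percent),
#'   `counts` (mean per-repeat TP, FN, TN, FP), `per_repeat` data frame,
#'   `kernel`, `k`, `repeats`.
#' @export
cross_validate <- function(vectors, labels, kernel = "medium_gaussian",
                           k = 10L, repeats = 20L, positive = NULL,
                           cost = 1, seed = 1L) {
  vectors <- as.matrix(vectors)
  if (anyNA(vectors) || any(!is.finite(vectors))) {
    stop("`vectors` must be finite", call. = FALSE)
  }
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- levels(labels)[1L]
  if (!positive %in% levels(labels)) stop("`positive` is not a label level",
                                          call. = FALSE)
  k <- check_count(k, "k", 2)
  repeats <- check_count(repeats, "repeats", 1)
  if (min(table(labels)) < k) {
    stop(sprintf(paste0("smallest class has %d members but k = %d folds ",
                        "were requested; reduce k or add samples"),
                 min(table(labels)), k), call. = FALSE)
  }
  set <- kernel_settings(kernel, ncol(vectors))
  per_repeat <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(repeats), function(r) {
      fold <- stratified_folds(labels, k)
      cm <- c(TP = 0, FN = 0, TN = 0, FP = 0)
      for (f in seq_len(k)) {
        tr <- fold != f
        pred <- fit_predict_svm(vectors[tr, , drop = FALSE], labels[tr],
                                vectors[!tr, , drop = FALSE], set, cost)
        truth <- labels[!tr]
        cm["TP"] <- cm["TP"] + sum(pred == positive & truth == positive)
        cm["FN"] <- cm["FN"] + sum(pred != positive & truth == positive)
        cm["TN"] <- cm["TN"] + sum(pred != positive & truth != positive)
        cm["FP"] <- cm["FP"] + sum(pred == positive & truth != positive)
      }
      met <- confusion_metrics(cm["TP"], cm["FN"], cm["TN"], cm["FP"])
      data.frame(repeat_id = r, t(cm), t(met))
    }))
  })
  counts <- colMeans(per_repeat[, c("TP", "FN", "TN", "FP")])
  metrics <- confusion_metrics(counts["TP"], counts["FN"],
                               counts["TN"], counts["FP"])
  structure(list(metrics = metrics, counts = counts,
                 per_repeat = per_repeat, kernel = kernel, k = k,
                 repeats = repeats, positive = positive,
                 n_pos = sum(labels == positive),
                 n_neg = sum(labels != positive)),
            class = "eval_report")
}

fit_predict_svm <- function(x_tr, y_tr, x_te, set, cost) {
  mu <- colMeans(x_tr)
  sdv <- apply(x_tr, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sdv, "/")
  x_te <- sweep(sweep(x_te, 2L, mu), 2L, sdv, "/")
  if (length(unique(y_tr)) < 2L) {
    # degenerate fold: predict the training majority class
    maj <- names(which.max(table(y_tr)))
    return(factor(rep(maj, nrow(x_te)), levels = levels(y_tr)))
  }
  args <- list(x = x_tr, y = droplevels(y_tr), kernel = set$kernel,
               cost = cost, scale = FALSE)
  if (!is.null(set$gamma)) args$gamma <- set$gamma
  fit <- do.call(e1071::svm, args)
  stats::predict(fit, x_te)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> kernel=%s, %d-fold x %d repeats (%d+%d subjects)\n",
              x$kernel, x$k, x$repeats, x$n_pos, x$n_neg))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              x$metrics["sensitivity"], x$metrics["specificity"],
              x$metrics["accuracy"]))
  invisible(x)
}

#' Run the whole detection pipeline on a cohort
#'
#' Preprocess each subject (notch optional, resampling if needed, 20-s
#' segmentation, rhythm decomposition), estimate per-rhythm transfer-entropy
#' networks, build the five-way feature tensor over the threshold grid,
#' reduce it to a core tensor by HOOI, reshape the cores into vectors and
#' evaluate an SVM under repeated stratified k-fold cross-validation.
#'
#' @param cohort A `cohort` (see [synth_cohort()] / [read_cohort()]).
#' @param config A [pipeline_config()] list.
#' @return List with `report` (an `eval_report`), `vectors`, `labels`,
#'   `mean_psi` (mean Tucker fit over subjects) and `provenance` (all
#'   parameters used).
#' @export
end_to_end <- function(cohort, config = pipeline_config()) {
  if (length(cohort) < 2L) {
    stop("cannot cross-validate fewer than 2 subjects", call. = FALSE)
  }
  grid <- threshold_grid(config$grid_start, config$grid_stop,
                         config$grid_step)
  p <- te_params(d = config$te_d, m = config$te_m, tau = config$te_tau,
                 u = config$te_u, n_bins = config$te_bins)
  psis <- numeric(length(cohort))
  vectors <- NULL
  for (i in seq_along(cohort)) {
    su <- cohort[[i]]
    prep <- tryCatch(
      preprocess_subject(su$signals, fs_out = config$fs_out,
                         seg_seconds = config$seg_seconds,
                         backend = config$rhythm_backend,
                         notch = config$notch),
      error = function(e) stop(sprintf("preprocess (%s): %s", su$id,
                                       conditionMessage(e)), call. = FALSE))
    conn <- tryCatch(
      subject_connectivity(prep$segments, p,
                           aggregate = config$segment_aggregate),
      error = function(e) stop(sprintf("connectivity (%s): %s", su$id,
                                       conditionMessage(e)), call. = FALSE))
    q <- build_feature_tensor(conn, grid)
    tk <- tucker_hooi(q, config$core_shape, max_iter = config$hooi_max_iter,
                      tol = config$hooi_tol)
    psis[i] <- tk$fit
    v <- reshape_core(tk)
    if (is.null(vectors)) {
      vectors <- matrix(NA_real_, length(cohort), length(v))
    }
    vectors[i, ] <- v
  }
  labels <- vapply(cohort, `[[`, character(1), "group")
  rownames(vectors) <- vapply(cohort, `[[`, character(1), "id")
  report <- cross_validate(vectors, labels, kernel = config$kernel,
                           k = config$folds, repeats = config$repeats,
                           positive = config$positive, cost = config$cost,
                           seed = config$seed)
  list(report = report, vectors = vectors, labels = labels,
       mean_psi = mean(psis), provenance = config)
}
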
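# Confusion-matrix metrics, rank AUC, the fourfold 2:1:1 cross-validation
# protocol and the end-to-end experiment orchestrator.

#' Confusion matrix counts, rates and balanced accuracy
#'
#' @param labels binary 0/1 truth vector (both classes present).
#' @param predictions binary 0/1 predictions, same length.
#' @return list with counts `tp`, `fp`, `tn`, `fn` and rates `tpr`, `fpr`,
#'   `tnr`, `ba` where `ba = (tpr + tnr) / 2`.
#' @export
confusion_and_rates <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions))
    stop_dpifuse("labels and predictions differ in length",
                 "dpifuse_validation_error")
  check_two_classes(labels, "labels")
  tp <- sum(labels == 1L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  fp <- sum(labels == 0L & predictions == 1L)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tpr, fpr = 1 - tnr, tnr = tnr, ba = (tpr + tnr) / 2)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random target trial scores above a random non-target
#' trial, ties counted half.
#'
#' @param scores numeric scores (any monotone scale).
#' @param labels binary 0/1 truth vector.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop_dpifuse("scores and labels differ in length",
                 "dpifuse_validation_error")
  check_two_classes(labels, "labels")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fourfold 2:1:1 cross-validation rotations
#'
#' Trials are randomly partitioned, stratified by class, into four equal
#' blocks. Rotation `r` uses block `r` as the test set, block `r + 1` (mod
#' 4) as the validation set and the remaining two blocks as the training set
#' — so train : validation : test = 2 : 1 : 1 and the four test blocks tile
#' all trials exactly once.
#'
#' @param labels binary 0/1 vector over all trials.
#' @param seed integer seed for the block draw.
#' @return list of 4 rotations, each `list(train = , validation = ,
#'   test = )` of trial indices.
#' @export
crossval_split <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 8L)
    stop_dpifuse("need at least 8 trials for a fourfold 2:1:1 split",
                 "dpifuse_validation_error")
  check_two_classes(labels, "labels")
  draw <- function() {
    sizes <- rep(n %/% 4L, 4L)
    if (n %% 4L > 0L) {
      extra <- sample(4L, n %% 4L)
      sizes[extra] <- sizes[extra] + 1L
    }
    n1 <- sum(labels == 1L)
    t_counts <- rep(n1 %/% 4L, 4L)
    if (n1 %% 4L > 0L) {
      extra <- sample(4L, n1 %% 4L)
      t_counts[extra] <- t_counts[extra] + 1L
    }
    if (any(t_counts > sizes)) return(NULL)
    blocks <- integer(n)
    blocks[sample(which(labels == 1L))] <- rep(1:4, t_counts)
    blocks[sample(which(labels == 0L))] <- rep(1:4, sizes - t_counts)
    blocks
  }
  blocks <- with_seed(sub_seed(seed, "crossval"), {
    b <- NULL
    for (attempt in 1:100) {
      cand <- draw()
      if (is.null(cand)) next
      ok <- all(vapply(1:4, function(k)
        length(unique(labels[cand == k])) == 2L, logical(1)))
      if (ok) { b <- cand; break }
    }
    b
  })
  if (is.null(blocks))
    stop_dpifuse("could not stratify all four blocks with both classes",
                 "dpifuse_validation_error")
  lapply(1:4, function(r) {
    test <- which(blocks == r)
    val <- which(blocks == (r %% 4L) + 1L)
    list(train = setdiff(seq_len(n), c(test, val)),
         validation = val, test = test)
  })
}

subset_scores <- function(scores, idx) {
  score_set(scores$posteriors[idx], scores$labels[idx],
            trial_ids = scores$trial_ids[idx], source_id = scores$source_id)
}

method_metrics <- function(scores_test, predictions) {
  m <- confusion_and_rates(scores_test$labels, predictions)
  c(tpr = m$tpr, fpr = m$fpr,
    auc = auc(scores_test$posteriors, scores_test$labels), ba = m$ba)
}

#' Run the full human-computer fusion experiment
#'
#' Per cross-validation rotation: fit the STHCP decoder on the training
#' block pair (hyperparameters selected on the validation block), decode
#' validation and test epochs into the human-vision score stream, fit both
#' sources' detection-performance models (and the DBF precision-recall
#' models) on the validation block, select every method's decision
#' threshold on validation, and score human vision, computer vision, DPI,
#' NBF and DBF on the held-out test block. Reports per-fold metrics and
#' their mean and (population) standard deviation.
#'
#' @param epochs an [epoch_set()] (the human-vision input).
#' @param detector_scores a [score_set()] over the same trials in the same
#'   order (the computer-vision input).
#' @param seed integer seed controlling the cross-validation draw.
#' @param n_filters_grid,n_components_grid STHCP hyperparameter grids.
#' @param grid threshold grid shared by all performance models.
#' @return an object of class `fusion_experiment`: `per_fold` (list of 4
#'   method x metric matrices), `mean` and `sd` aggregate matrices,
#'   `conflict_flag` (whether the two sources' mean AUCs differ by >= 0.1),
#'   per-fold selected STHCP hyperparameters and thresholds.
#' @export
run_experiment <- function(epochs, detector_scores, seed = 1L,
                           n_filters_grid = 2:10, n_components_grid = 1:10,
                           grid = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(detector_scores, "score_set"))
  if (length(detector_scores) != n_trials(epochs))
    stop_dpifuse("detector scores and epochs differ in trial count",
                 "dpifuse_validation_error")
  if (any(detector_scores$labels != epochs$labels))
    stop_dpifuse("detector score labels disagree with epoch labels",
                 "dpifuse_validation_error")
  rotations <- crossval_split(epochs$labels, seed = seed)
  methods <- c("human", "computer", "DPI", "NBF", "DBF")
  metrics <- c("tpr", "fpr", "auc", "ba")
  per_fold <- vector("list", 4L)
  hyper <- vector("list", 4L)

  for (r in seq_along(rotations)) {
    rot <- rotations[[r]]
    fold <- matrix(NA_real_, length(methods), length(metrics),
                   dimnames = list(methods, metrics))

    model_h <- sthcp(subset_epochs(epochs, rot$train),
                     subset_epochs(epochs, rot$validation),
                     n_filters_grid = n_filters_grid,
                     n_components_grid = n_components_grid)
    human_val <- predict(model_h, subset_epochs(epochs, rot$validation))
    human_test <- predict(model_h, subset_epochs(epochs, rot$test))
    comp_val <- subset_scores(detector_scores, rot$validation)
    comp_test <- subset_scores(detector_scores, rot$test)
    # the decoded streams describe the same trials as the detector subsets
    human_val$trial_ids <- comp_val$trial_ids
    human_test$trial_ids <- comp_test$trial_ids

    perf_h <- detection_performance(human_val, grid = grid)
    perf_c <- detection_performance(comp_val, grid = grid)
    pr_h <- dbf_model(human_val, grid = grid)
    pr_c <- dbf_model(comp_val, grid = grid)

    fold["human", ] <- method_metrics(
      human_test, as.integer(human_test$posteriors > perf_h$t_best))
    fold["computer", ] <- method_metrics(
      comp_test, as.integer(comp_test$posteriors > perf_c$t_best))

    dpi_val <- dpi_fuse(list(list(scores = human_val, model = perf_h),
                             list(scores = comp_val, model = perf_c)))
    t_dpi <- select_fusion_threshold(dpi_val, grid = grid)
    dpi_test <- dpi_fuse(list(list(scores = human_test, model = perf_h),
                              list(scores = comp_test, model = perf_c)),
                         decision_threshold = t_dpi)
    fold["DPI", ] <- method_metrics(fusion_scores(dpi_test),
                                    dpi_test$predicted)

    nbf_val <- nbf_fuse(list(human_val, comp_val))
    t_nbf <- detection_performance(nbf_val, grid = grid)$t_best
    nbf_test <- nbf_fuse(list(human_test, comp_test))
    fold["NBF", ] <- method_metrics(
      nbf_test, as.integer(nbf_test$posteriors > t_nbf))

    dbf_val <- dbf_fuse(list(list(scores = human_val, model = pr_h),
                             list(scores = comp_val, model = pr_c)))
    t_dbf <- select_fusion_threshold(dbf_val, grid = grid)
    dbf_test <- dbf_fuse(list(list(scores = human_test, model = pr_h),
                              list(scores = comp_test, model = pr_c)),
                         decision_threshold = t_dbf)
    fold["DBF", ] <- method_metrics(fusion_scores(dbf_test),
                                    dbf_test$predicted)

    per_fold[[r]] <- fold
    hyper[[r]] <- list(selected = model_h$selected,
                       validation_auc = model_h$validation_auc,
                       t_best_human = perf_h$t_best,
                       t_best_computer = perf_c$t_best,
                       t_dpi = t_dpi, t_nbf = t_nbf, t_dbf = t_dbf,
                       n_total_conflict = dpi_test$n_total_conflict)
  }

  arr <- simplify2array(per_fold)             # methods x metrics x folds
  mean_m <- apply(arr, c(1L, 2L), mean)
  sd_m <- apply(arr, c(1L, 2L), function(v) sqrt(mean((v - mean(v))^2)))
  structure(list(
    per_fold = per_fold, mean = mean_m, sd = sd_m,
    conflict_flag = abs(mean_m["human", "auc"] -
                          mean_m["computer", "auc"]) >= 0.1,
    hyper = hyper, seed = seed), class = "fusion_experiment")
}

#' @export
print.fusion_experiment <- function(x, ...) {
  cat("Fourfold 2:1:1 cross-validated fusion experiment\n")
  cat(sprintf("  conflict situation: %s (|AUC_human - AUC_computer| %s 0.1)\n",
              ifelse(x$conflict_flag, "yes", "no"),
              ifelse(x$conflict_flag, ">=", "<")))
  cat("  mean over 4 folds (sd):\n")
  out <- matrix(sprintf("%.3f (%.3f)", x$mean, x$sd), nrow(x$mean),
                dimnames = dimnames(x$mean))
  print(as.data.frame(out), right = TRUE)
  invisible(x)
}

#' Tidy per-fold results of a fusion experiment
#'
#' @param x a `fusion_experiment`.
#' @param ... unused.
#' @return data.frame with columns `fold`, `method`, `tpr`, `fpr`, `auc`,
#'   `ba`.
#' @export
as.data.frame.fusion_experiment <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$per_fold), function(r) {
    m <- x$per_fold[[r]]
    data.frame(fold = r, method = rownames(m), m, row.names = NULL)
  }))
}

#' Run a score-stream-only fusion experiment
#'
#' The same fourfold 2:1:1 protocol as [run_experiment()], but both sources
#' are supplied as ready-made posterior streams (no EEG decoding step):
#' performance models and thresholds come from each rotation's validation
#' block, metrics from its test block.
#'
#' @param sources list of two or more aligned [score_set()]s.
#' @param seed integer seed for the cross-validation draw.
#' @param grid threshold grid.
#' @return a `fusion_experiment` (methods: one row per source, then DPI,
#'   NBF, DBF).
#' @export
run_fusion_experiment <- function(sources, seed = 1L,
                                  grid = seq(0, 1, length.out = 101)) {
  check_aligned(sources)
  labels <- sources[[1L]]$labels
  rotations <- crossval_split(labels, seed = seed)
  src_names <- vapply(sources, `[[`, character(1), "source_id")
  methods <- c(src_names, "DPI", "NBF", "DBF")
  metrics <- c("tpr", "fpr", "auc", "ba")
  per_fold <- vector("list", 4L)

  for (r in seq_along(rotations)) {
    rot <- rotations[[r]]
    fold <- matrix(NA_real_, length(methods), length(metrics),
                   dimnames = list(methods, metrics))
    val <- lapply(sources, subset_scores, idx = rot$validation)
    tst <- lapply(sources, subset_scores, idx = rot$test)
    perf <- lapply(val, detection_performance, grid = grid)
    pr <- lapply(val, dbf_model, grid = grid)

    for (i in seq_along(sources))
      fold[src_names[i], ] <- method_metrics(
        tst[[i]], as.integer(tst[[i]]$posteriors > perf[[i]]$t_best))

    pair <- function(sc, mods) Map(function(s, m) list(scores = s, model = m),
                                   sc, mods)
    t_dpi <- select_fusion_threshold(dpi_fuse(pair(val, perf)), grid = grid)
    dpi_test <- dpi_fuse(pair(tst, perf), decision_threshold = t_dpi)
    fold["DPI", ] <- method_metrics(fusion_scores(dpi_test),
                                    dpi_test$predicted)

    t_nbf <- detection_performance(nbf_fuse(val), grid = grid)$t_best
    nbf_test <- nbf_fuse(tst)
    fold["NBF", ] <- method_metrics(
      nbf_test, as.integer(nbf_test$posteriors > t_nbf))

    t_dbf <- select_fusion_threshold(dbf_fuse(pair(val, pr)), grid = grid)
    dbf_test <- dbf_fuse(pair(tst, pr), decision_threshold = t_dbf)
    fold["DBF", ] <- method_metrics(fusion_scores(dbf_test),
                                    dbf_test$predicted)
    per_fold[[r]] <- fold
  }
  arr <- simplify2array(per_fold)
  mean_m <- apply(arr, c(1L, 2L), mean)
  sd_m <- apply(arr, c(1L, 2L), function(v) sqrt(mean((v - mean(v))^2)))
  structure(list(per_fold = per_fold, mean = mean_m, sd = sd_m,
                 conflict_flag = abs(mean_m[src_names[1L], "auc"] -
                                       mean_m[src_names[2L], "auc"]) >= 0.1,
                 hyper = NULL, seed = seed), class = "fusion_experiment")
}
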
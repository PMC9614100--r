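# Late fusion of heterogeneous detector streams: dynamic probability
# integration (performance-weighted BPAs + Dempster's rule + pignistic
# decision) and the NBF / DBF baselines.

#' Basic probability assignment from a detection-performance model
#'
#' For a source with smoothed detection curves `g` (TPR) and `f` (TNR)
#' evaluated at its operating threshold, a trial with target posterior `p`
#' yields the mass triple
#' `m(target) = g(t_best) * p`, `m(non-target) = f(t_best) * (1 - p)`,
#' `m(uncertain) = 1 - m(target) - m(non-target)`. Because `g, f <= 1` the
#' triple is always a valid mass function.
#'
#' @param posterior target posterior(s) in \[0, 1\].
#' @param model a [detection_performance()] model of the emitting source.
#' @return a [mass_function()] for a single posterior; an n x 3 matrix
#'   (columns `target`, `nontarget`, `uncertain`) for a vector.
#' @export
assign_bpa <- function(posterior, model) {
  stopifnot(inherits(model, "detection_performance"))
  if (any(posterior < 0 | posterior > 1))
    stop_dpifuse("posterior outside [0, 1]", "dpifuse_validation_error")
  g <- performance_tpr(model)
  f <- performance_tnr(model)
  mt <- g * posterior
  mn <- f * (1 - posterior)
  M <- cbind(target = mt, nontarget = mn, uncertain = 1 - mt - mn)
  if (length(posterior) == 1L)
    mass_function(M[1L, 1L], M[1L, 2L], M[1L, 3L])
  else M
}

as_bpa_matrix <- function(posterior, model) {
  g <- performance_tpr(model)
  f <- performance_tnr(model)
  mt <- g * posterior
  mn <- f * (1 - posterior)
  cbind(target = mt, nontarget = mn, uncertain = 1 - mt - mn)
}

finish_fusion <- function(M, K_any, total_conflict, unnorm, labels,
                          trial_ids, decision_threshold, method) {
  # total-conflict fallback: renormalised singleton ratio of the
  # unnormalised masses, zero residual uncertainty
  if (any(total_conflict)) {
    idx <- which(total_conflict)
    s <- unnorm[idx, 1L] + unnorm[idx, 2L]
    pt <- ifelse(s > 0, unnorm[idx, 1L] / s, 0.5)
    M[idx, ] <- cbind(pt, 1 - pt, 0)
  }
  p_pig <- M[, "target"] + M[, "uncertain"]
  predicted <- as.integer(p_pig > decision_threshold)
  structure(list(
    method = method, mass = M, p_pig_target = p_pig,
    decision_threshold = decision_threshold, predicted = predicted,
    labels = labels, trial_ids = trial_ids,
    conflict = K_any, n_total_conflict = sum(total_conflict),
    total_conflict_trials = which(total_conflict)), class = "fusion_result")
}

#' Fuse heterogeneous sources by dynamic probability integration
#'
#' Per trial, each source's posterior is turned into a basic probability
#' assignment weighted by that source's detection-performance model
#' ([assign_bpa()]); the assignments are combined left-to-right with
#' Dempster's rule and decided by thresholding the pignistic target
#' probability. Trials hitting total conflict are not dropped: they are
#' counted, reported in the result, and scored by the renormalised singleton
#' ratio of the unnormalised combined masses.
#'
#' @param sources list of two or more `list(scores = , model = )` pairs,
#'   where `scores` is a [score_set()] and `model` its
#'   [detection_performance()]; trial ids must be aligned across sources.
#' @param decision_threshold threshold on the fused pignistic target
#'   probability (normally selected on validation data with
#'   [select_fusion_threshold()]).
#' @return an object of class `fusion_result` with the per-trial fused mass
#'   matrix, pignistic scores, predictions and conflict diagnostics.
#' @export
dpi_fuse <- function(sources, decision_threshold = 0.5) {
  if (length(sources) < 2L)
    stop_dpifuse("need at least two sources to fuse",
                 "dpifuse_validation_error")
  score_sets <- lapply(sources, `[[`, "scores")
  check_aligned(score_sets)
  M <- as_bpa_matrix(score_sets[[1L]]$posteriors, sources[[1L]]$model)
  K_any <- rep(0, nrow(M))
  total <- rep(FALSE, nrow(M))
  unnorm <- M
  for (i in seq_along(sources)[-1L]) {
    Mi <- as_bpa_matrix(score_sets[[i]]$posteriors, sources[[i]]$model)
    res <- dempster_rows(M, Mi)
    K_any <- pmax(K_any, res$conflict)
    total <- total | res$total_conflict
    unnorm <- res$unnormalized
    M <- ifelse(is.na(res$mass), 0, res$mass)
    colnames(M) <- c("target", "nontarget", "uncertain")
  }
  finish_fusion(M, K_any, total, unnorm, score_sets[[1L]]$labels,
                score_sets[[1L]]$trial_ids, decision_threshold, "DPI")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf(
    "<fusion_result> %s: %d trials, decision threshold %.3f, %d predicted target\n",
    x$method, length(x$p_pig_target), x$decision_threshold,
    sum(x$predicted)))
  if (x$n_total_conflict > 0)
    cat(sprintf("  %d trial(s) hit total conflict (fallback scoring used)\n",
                x$n_total_conflict))
  invisible(x)
}

#' @export
summary.fusion_result <- function(object, ...) {
  print(object)
  m <- confusion_and_rates(object$labels, object$predicted)
  cat(sprintf("  TPR %.3f  FPR %.3f  BA %.3f  AUC %.3f  max conflict K %.3f\n",
              m$tpr, m$fpr, m$ba, auc(object$p_pig_target, object$labels),
              max(object$conflict)))
  invisible(object)
}

#' Fused scores of a fusion result as a score set
#'
#' The pignistic target probabilities, which live on \[0, 1\], packaged for
#' the evaluation machinery.
#'
#' @param result a `fusion_result`.
#' @return a [score_set()].
#' @export
fusion_scores <- function(result) {
  stopifnot(inherits(result, "fusion_result"))
  score_set(pmin(1, pmax(0, result$p_pig_target)), result$labels,
            trial_ids = result$trial_ids, source_id = result$method)
}

#' Select the fused decision threshold on validation data
#'
#' The fused pignistic scores live on a scale of their own, so the decision
#' threshold is re-selected on the validation fold: the fused validation
#' scores are swept over the threshold grid and `argmax(TPR - FPR)` is
#' returned, exactly as for a single source.
#'
#' @param validation_result a `fusion_result` (or [score_set()]) computed on
#'   the validation fold.
#' @param grid threshold grid.
#' @return the selected threshold.
#' @export
select_fusion_threshold <- function(validation_result,
                                    grid = seq(0, 1, length.out = 101)) {
  s <- if (inherits(validation_result, "fusion_result"))
    fusion_scores(validation_result) else validation_result
  detection_performance(s, grid = grid)$t_best
}

#' Naive Bayesian fusion baseline
#'
#' Combines the sources' posteriors under conditional independence:
#' `posterior ~ prior^(1 - n) * prod(p_t)`, normalised against the
#' corresponding non-target product. Posteriors are clipped to
#' \[1e-6, 1 - 1e-6\] first so opposing certain sources cannot produce 0/0.
#'
#' @param sources list of two or more aligned [score_set()]s.
#' @param prior_target prior target probability in (0, 1); default the
#'   empirical prevalence of the first source's labels.
#' @return a [score_set()] of fused posteriors.
#' @export
nbf_fuse <- function(sources, prior_target = NULL) {
  if (length(sources) < 2L)
    stop_dpifuse("need at least two sources to fuse",
                 "dpifuse_validation_error")
  check_aligned(sources)
  if (is.null(prior_target)) prior_target <- mean(sources[[1L]]$labels)
  if (prior_target <= 0 || prior_target >= 1)
    stop_dpifuse("prior_target must lie strictly in (0, 1)",
                 "dpifuse_config_error")
  n <- length(sources)
  P <- vapply(sources, function(s)
    pmin(1 - 1e-6, pmax(1e-6, s$posteriors)),
    numeric(length(sources[[1L]]$posteriors)))
  log_t <- (1 - n) * log(prior_target) + rowSums(log(P))
  log_n <- (1 - n) * log(1 - prior_target) + rowSums(log1p(-P))
  fused <- 1 / (1 + exp(log_n - log_t))
  score_set(fused, sources[[1L]]$labels,
            trial_ids = sources[[1L]]$trial_ids, source_id = "NBF")
}

#' Dynamic belief fusion baseline
#'
#' Each source's validation precision and recall curves (same grid and
#' smoothing machinery as [detection_performance()]) define its BPA at a
#' trial's posterior `s`: `m(target) = precision(s)`,
#' `m(non-target) = 1 - recall(s)`, jointly rescaled when their sum exceeds
#' 1 so the remainder is a valid uncertain mass. Combination and decision
#' are as in [dpi_fuse()].
#'
#' @param sources list of two or more `list(scores = , model = )` pairs
#'   where `model` is the list returned by fitting precision-recall curves
#'   on validation data (see [dbf_model()]).
#' @param decision_threshold threshold on the fused pignistic target score.
#' @return a `fusion_result`.
#' @export
dbf_fuse <- function(sources, decision_threshold = 0.5) {
  if (length(sources) < 2L)
    stop_dpifuse("need at least two sources to fuse",
                 "dpifuse_validation_error")
  score_sets <- lapply(sources, `[[`, "scores")
  check_aligned(score_sets)
  bpa <- function(scores, model) {
    mt <- stats::approx(model$threshold_grid, model$precision,
                        xout = scores$posteriors, rule = 2)$y
    rec <- stats::approx(model$threshold_grid, model$recall,
                         xout = scores$posteriors, rule = 2)$y
    mn <- pmin(1, pmax(0, 1 - rec))
    s <- mt + mn
    over <- s > 1
    mt[over] <- mt[over] / s[over]
    mn[over] <- mn[over] / s[over]
    cbind(target = mt, nontarget = mn, uncertain = pmax(0, 1 - mt - mn))
  }
  M <- bpa(score_sets[[1L]], sources[[1L]]$model)
  K_any <- rep(0, nrow(M)); total <- rep(FALSE, nrow(M)); unnorm <- M
  for (i in seq_along(sources)[-1L]) {
    Mi <- bpa(score_sets[[i]], sources[[i]]$model)
    res <- dempster_rows(M, Mi)
    K_any <- pmax(K_any, res$conflict)
    total <- total | res$total_conflict
    unnorm <- res$unnormalized
    M <- ifelse(is.na(res$mass), 0, res$mass)
    colnames(M) <- c("target", "nontarget", "uncertain")
  }
  finish_fusion(M, K_any, total, unnorm, score_sets[[1L]]$labels,
                score_sets[[1L]]$trial_ids, decision_threshold, "DBF")
}

#' Fit the precision-recall model used by dynamic belief fusion
#'
#' @param scores a [score_set()] of validation posteriors.
#' @param grid threshold grid.
#' @param span loess span.
#' @return list with the grid and smoothed `precision` / `recall` curves.
#' @export
dbf_model <- function(scores, grid = seq(0, 1, length.out = 101),
                      span = 0.25) {
  precision_recall_curves(scores, grid = grid, span = span)
}
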
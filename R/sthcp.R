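# STHCP: spatial-temporal hybrid CSP-PCA decoder for single-trial RSVP EEG.
# CSP spatial filtering -> per-channel temporal PCA -> shrinkage LDA
# posterior, with validation-driven selection of (n_filters, n_components).

#' Trace-normalised class covariance matrices
#'
#' For each class, the average over its trials of
#' `Y %*% t(Y) / trace(Y %*% t(Y))` where `Y` is the channels x samples
#' matrix of one trial.
#'
#' @param epochs an [epoch_set()] with both classes present.
#' @return list with elements `target` and `nontarget`, each a channels x
#'   channels symmetric positive semi-definite matrix.
#' @export
class_covariances <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  check_two_classes(epochs$labels, "epoch set")
  if (dim(epochs$data)[2L] < 2L)
    stop_dpifuse("CSP needs at least 2 channels", "dpifuse_validation_error")
  one_class <- function(idx) {
    acc <- 0
    for (i in idx) {
      Y <- epochs$data[i, , ]
      S <- tcrossprod(Y)
      tr <- sum(diag(S))
      if (tr <= 0)
        stop_dpifuse(sprintf("zero-energy trial %d (trace 0)", i),
                     "dpifuse_validation_error")
      acc <- acc + S / tr
    }
    S <- acc / length(idx)
    (S + t(S)) / 2
  }
  list(target = one_class(which(epochs$labels == 1L)),
       nontarget = one_class(which(epochs$labels == 0L)))
}

# Trace shrinkage towards a scaled identity, guaranteeing SPD.
shrink_cov <- function(S, eps = 1e-4) {
  p <- nrow(S)
  (1 - eps) * S + eps * (sum(diag(S)) / p) * diag(p)
}

#' Fit common spatial pattern filters
#'
#' Solves the generalised eigenproblem `cov_target w = lambda cov_nontarget w`
#' (via whitening by the non-target covariance's Cholesky factor) and keeps
#' `n_filters` filters taken alternately from the two ends of the eigenvalue
#' spectrum: largest, smallest, 2nd largest, 2nd smallest, ...
#'
#' @param cov_target,cov_nontarget class covariance matrices (see
#'   [class_covariances()]).
#' @param n_filters number of spatial filters to keep (2..channels).
#' @param shrinkage trace-shrinkage weight applied to both covariances
#'   before solving.
#' @return an object of class `csp_filters` with fields `W` (channels x
#'   n_filters) and `eigenvalues`.
#' @export
fit_csp <- function(cov_target, cov_nontarget, n_filters,
                    shrinkage = 1e-4) {
  p <- nrow(cov_target)
  if (!is_count(n_filters) || n_filters < 2 || n_filters > p)
    stop_dpifuse("n_filters must be an integer in [2, channels]",
                 "dpifuse_config_error")
  Sp <- shrink_cov(cov_target, shrinkage)
  Sn <- shrink_cov(cov_nontarget, shrinkage)
  L <- tryCatch(chol(Sn), error = function(e)
    stop_dpifuse("non-target covariance singular after regularisation; increase shrinkage",
                 "dpifuse_numeric_error"))
  Linv <- backsolve(L, diag(p))                 # Sn = t(L) %*% L
  M <- t(Linv) %*% Sp %*% Linv
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE) # descending eigenvalues
  W_all <- Linv %*% eg$vectors
  lam <- eg$values
  # alternate ends of the spectrum: 1, p, 2, p-1, ...
  ord <- as.vector(rbind(seq_len(ceiling(p / 2)),
                         p + 1L - seq_len(ceiling(p / 2))))
  ord <- unique(ord[ord <= p])[seq_len(n_filters)]
  W <- W_all[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  sgn <- apply(W, 2L, function(w) sign(w[which.max(abs(w))]))
  W <- sweep(W, 2L, sgn, `*`)
  structure(list(W = W, eigenvalues = lam[ord], n_filters = n_filters),
            class = "csp_filters")
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf("<csp_filters> %d filters over %d channels; eigenvalues: %s\n",
              x$n_filters, nrow(x$W),
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' Apply CSP filters to an epoch set
#'
#' Each trial's channels x samples matrix `Y` is replaced by `t(W) %*% Y`;
#' labels and the time axis are unchanged.
#'
#' @param epochs an [epoch_set()].
#' @param filters a `csp_filters` object whose row count matches the epochs'
#'   channel count.
#' @return an [epoch_set()] with `n_filters` virtual channels.
#' @export
apply_csp <- function(epochs, filters) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(filters, "csp_filters"))
  d <- dim(epochs$data)
  if (nrow(filters$W) != d[2L])
    stop_dpifuse(sprintf("filters expect %d channels but epochs have %d",
                         nrow(filters$W), d[2L]), "dpifuse_format_error")
  # unfold to channels x (samples*trials), multiply once, refold
  flat <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), nrow = d[2L])
  out <- crossprod(filters$W, flat)
  data <- aperm(array(out, dim = c(filters$n_filters, d[3L], d[1L])),
                c(3L, 1L, 2L))
  epoch_set(data, epochs$labels, epochs$time_axis,
            sprintf("csp%02d", seq_len(filters$n_filters)),
            epochs$sampling_rate, epochs$metadata)
}

#' Fit per-channel temporal PCA projectors
#'
#' For each (filtered) channel, the trials x samples matrix of that
#' channel's time courses is mean-centred across trials and the eigenvectors
#' of its sample covariance over time points are computed; the first
#' `n_components` eigenvectors (descending eigenvalue, sign fixed so the
#' largest-magnitude entry is positive) form the projection matrix.
#'
#' @param epochs an [epoch_set()] (normally CSP-filtered training data).
#' @param n_components number of principal components per channel.
#' @return an object of class `temporal_pca` with per-channel orthonormal
#'   `projections` (samples x n_components), eigenvalues and the per-channel
#'   training means.
#' @export
fit_temporal_pca <- function(epochs, n_components) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (!is_count(n_components) || n_components > d[3L] ||
      n_components > d[1L] - 1L)
    stop_dpifuse(sprintf(
      "n_components must be a count <= min(samples = %d, trials - 1 = %d)",
      d[3L], d[1L] - 1L), "dpifuse_config_error")
  projections <- vector("list", d[2L])
  eigenvalues <- vector("list", d[2L])
  means <- matrix(0, d[2L], d[3L])
  for (c in seq_len(d[2L])) {
    Yc <- epochs$data[, c, ]                     # trials x samples
    mu <- colMeans(Yc)
    Yc <- sweep(Yc, 2L, mu)
    V <- crossprod(Yc) / (d[1L] - 1L)            # samples x samples
    eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
    X <- eg$vectors[, seq_len(n_components), drop = FALSE]
    sgn <- apply(X, 2L, function(v) sign(v[which.max(abs(v))]))
    projections[[c]] <- sweep(X, 2L, sgn, `*`)
    eigenvalues[[c]] <- eg$values
    means[c, ] <- mu
  }
  structure(list(projections = projections, eigenvalues = eigenvalues,
                 means = means, n_components = as.integer(n_components)),
            class = "temporal_pca")
}

#' Extract spatial-temporal features
#'
#' Per trial, each filtered channel's time course is projected onto that
#' channel's principal components; the per-channel blocks are concatenated
#' into one feature vector of length `n_filters * n_components`.
#'
#' @param epochs a CSP-filtered [epoch_set()].
#' @param projector a `temporal_pca` fitted on compatible data.
#' @param n_components optionally use only the first `n_components` of each
#'   channel's projector (must not exceed the fitted count).
#' @return numeric matrix, trials x (channels * n_components).
#' @export
extract_features <- function(epochs, projector, n_components = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(projector, "temporal_pca"))
  d <- dim(epochs$data)
  if (length(projector$projections) != d[2L])
    stop_dpifuse(sprintf("projector has %d channels but epochs have %d",
                         length(projector$projections), d[2L]),
                 "dpifuse_format_error")
  K <- if (is.null(n_components)) projector$n_components else n_components
  if (K > projector$n_components)
    stop_dpifuse("requested more components than the projector holds",
                 "dpifuse_config_error")
  blocks <- lapply(seq_len(d[2L]), function(c)
    epochs$data[, c, , drop = TRUE] %*%
      projector$projections[[c]][, seq_len(K), drop = FALSE])
  if (d[1L] == 1L) blocks <- lapply(blocks, matrix, nrow = 1L)
  do.call(cbind, blocks)
}

#' Shrinkage linear discriminant with posterior output
#'
#' Gaussian shared-covariance discriminant: class priors from training
#' prevalence, pooled within-class covariance with trace shrinkage. The
#' posterior of the target class is the logistic of the linear discriminant
#' score.
#'
#' @param features numeric matrix, trials x features.
#' @param labels binary 0/1 vector.
#' @param shrinkage trace-shrinkage weight for the pooled covariance.
#' @return an object of class `lda_classifier` (weights `w`, bias `b`;
#'   posterior = `plogis(features %*% w + b)`).
#' @export
fit_lda <- function(features, labels, shrinkage = 1e-3) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  check_two_classes(labels, "training labels")
  i1 <- labels == 1L; i0 <- !i1
  mu1 <- colMeans(features[i1, , drop = FALSE])
  mu0 <- colMeans(features[i0, , drop = FALSE])
  c1 <- stats::cov(features[i1, , drop = FALSE]) * (sum(i1) - 1L)
  c0 <- stats::cov(features[i0, , drop = FALSE]) * (sum(i0) - 1L)
  S <- shrink_cov((c1 + c0) / (length(labels) - 2L), shrinkage)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e)
    stop_dpifuse("degenerate feature covariance; increase shrinkage",
                 "dpifuse_numeric_error"))
  b <- -sum(w * (mu1 + mu0)) / 2 + log(mean(i1) / mean(i0))
  structure(list(w = w, b = b, mu1 = mu1, mu0 = mu0),
            class = "lda_classifier")
}

#' @rdname fit_lda
#' @param classifier a fitted `lda_classifier`.
#' @param labels_out true labels to attach to the returned score set.
#' @param source_id source name for the returned score set.
#' @export
predict_posterior <- function(classifier, features, labels_out = NULL,
                              source_id = "lda") {
  stopifnot(inherits(classifier, "lda_classifier"))
  features <- as.matrix(features)
  p <- stats::plogis(drop(features %*% classifier$w) + classifier$b)
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  if (is.null(labels_out)) return(p)
  score_set(p, labels_out, source_id = source_id)
}

#' Fit the STHCP decoder with validation-driven hyperparameter selection
#'
#' For every grid point `(n_filters, n_components)` the CSP -> temporal PCA
#' -> LDA chain is fitted on the training set and scored by AUC on the
#' validation set; the model with maximal validation AUC is returned (ties
#' broken towards smaller `n_filters`, then smaller `n_components`). The
#' alternating-ends CSP filter order makes smaller filter banks prefixes of
#' larger ones, so the grid search shares one CSP solve and one PCA
#' eigendecomposition per fold.
#'
#' @param train,validation disjoint [epoch_set()]s with both classes each.
#' @param n_filters_grid candidate CSP filter counts (default 2..10).
#' @param n_components_grid candidate temporal PCA component counts
#'   (default 1..10).
#' @param feature_window_s post-stimulus analysis window (seconds) from
#'   which features are extracted; default 0.2-0.6 s.
#' @param shrinkage covariance shrinkage used by both CSP and LDA.
#' @return an object of class `sthcp` with the fitted filter bank,
#'   projector, classifier, selected parameters and the validation AUC grid.
#' @export
sthcp <- function(train, validation,
                  n_filters_grid = 2:10, n_components_grid = 1:10,
                  feature_window_s = c(0.2, 0.6), shrinkage = 1e-3) {
  stopifnot(inherits(train, "epoch_set"), inherits(validation, "epoch_set"))
  if (length(n_filters_grid) == 0L || length(n_components_grid) == 0L)
    stop_dpifuse("empty hyperparameter grid", "dpifuse_config_error")
  check_two_classes(train$labels, "training set")
  check_two_classes(validation$labels, "validation set")

  crop <- function(ep) {
    sel <- ep$time_axis >= feature_window_s[1L] &
      ep$time_axis <= feature_window_s[2L]
    ep$data <- ep$data[, , sel, drop = FALSE]
    ep$time_axis <- ep$time_axis[sel]
    ep
  }
  tr <- crop(train); va <- crop(validation)

  covs <- class_covariances(tr)
  max_f <- max(n_filters_grid)
  max_k <- max(n_components_grid)
  bank_full <- fit_csp(covs$target, covs$nontarget, max_f, shrinkage)
  tr_f <- apply_csp(tr, bank_full)
  va_f <- apply_csp(va, bank_full)
  proj_full <- fit_temporal_pca(tr_f, min(max_k, dim(tr_f$data)[3L],
                                          dim(tr_f$data)[1L] - 1L))
  feat_tr <- extract_features(tr_f, proj_full)   # trials x (max_f * K)
  feat_va <- extract_features(va_f, proj_full)
  Kfit <- proj_full$n_components

  take_cols <- function(n_f, k)
    as.vector(outer(seq_len(k), (seq_len(n_f) - 1L) * Kfit, `+`))

  best <- NULL
  grid_auc <- matrix(NA_real_,
                     nrow = length(n_filters_grid),
                     ncol = length(n_components_grid),
                     dimnames = list(n_filters_grid, n_components_grid))
  for (fi in seq_along(n_filters_grid)) {
    for (ki in seq_along(n_components_grid)) {
      n_f <- n_filters_grid[fi]; k <- n_components_grid[ki]
      if (k > Kfit) next
      cols <- take_cols(n_f, k)
      cls <- fit_lda(feat_tr[, cols, drop = FALSE], tr$labels, shrinkage)
      p_va <- predict_posterior(cls, feat_va[, cols, drop = FALSE])
      a <- auc(p_va, va$labels)
      grid_auc[fi, ki] <- a
      if (is.null(best) || a > best$auc + 1e-12) {
        best <- list(auc = a, n_filters = n_f, n_components = k,
                     classifier = cls)
      }
    }
  }
  if (is.null(best))
    stop_dpifuse("no feasible grid point (all component counts exceed the data rank)",
                 "dpifuse_config_error")

  bank <- fit_csp(covs$target, covs$nontarget, best$n_filters, shrinkage)
  proj <- structure(list(
    projections = lapply(proj_full$projections[seq_len(best$n_filters)],
                         function(X) X[, seq_len(best$n_components),
                                       drop = FALSE]),
    eigenvalues = proj_full$eigenvalues[seq_len(best$n_filters)],
    means = proj_full$means[seq_len(best$n_filters), , drop = FALSE],
    n_components = best$n_components), class = "temporal_pca")

  structure(list(
    filter_bank = bank, projector = proj, classifier = best$classifier,
    selected = c(n_filters = as.integer(best$n_filters),
                 n_components = as.integer(best$n_components)),
    validation_auc = best$auc, grid_auc = grid_auc,
    feature_window_s = feature_window_s, shrinkage = shrinkage,
    channel_names = train$channel_names), class = "sthcp")
}

#' @export
print.sthcp <- function(x, ...) {
  cat(sprintf("<sthcp> %d CSP filters x %d temporal components (validation AUC %.3f)\n",
              x$selected["n_filters"], x$selected["n_components"],
              x$validation_auc))
  invisible(x)
}

#' @export
summary.sthcp <- function(object, ...) {
  cat("STHCP decoder\n")
  print(object)
  cat(sprintf("  feature window: %.3f..%.3f s; feature dimension %d\n",
              object$feature_window_s[1L], object$feature_window_s[2L],
              prod(object$selected)))
  cat("  validation AUC over the hyperparameter grid:\n")
  print(round(object$grid_auc, 3))
  invisible(object)
}

#' @export
coef.sthcp <- function(object, ...) object$classifier$w

#' Decode an epoch set with a fitted STHCP model
#'
#' @param object a fitted [sthcp()] model.
#' @param newdata an [epoch_set()] with the training channel count.
#' @param ... unused.
#' @return a [score_set()] of target posteriors.
#' @export
predict.sthcp <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "epoch_set"))
  sel <- newdata$time_axis >= object$feature_window_s[1L] &
    newdata$time_axis <= object$feature_window_s[2L]
  cropped <- newdata
  cropped$data <- cropped$data[, , sel, drop = FALSE]
  cropped$time_axis <- cropped$time_axis[sel]
  filtered <- apply_csp(cropped, object$filter_bank)
  feats <- extract_features(filtered, object$projector)
  predict_posterior(object$classifier, feats, labels_out = newdata$labels,
                    source_id = "sthcp")
}
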
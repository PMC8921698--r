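# Classification metrics, repeated stratified k-fold CV, and recursive
# feature elimination with cross-validation around a generic estimator
# contract (fit / predict / feature_importance).

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts (total >= 1).
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) < 1) stop("all counts zero")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any zero factor
#' in the MCC denominator yields `mcc = 0` with a warning (the common
#' convention that keeps the statistic total).
#'
#' @param c a `confusion_counts`, or tp when the four counts are given
#'   positionally.
#' @param fp,tn,fn optional positional counts.
#' @return list(se, sp, acc, mcc).
#' @export
compute_metrics <- function(c, fp = NULL, tn = NULL, fn = NULL) {
  if (!inherits(c, "confusion_counts"))
    c <- confusion_counts(c, fp, tn, fn)
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + fp + tn + fn)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    warning("zero factor in MCC denominator; mcc set to 0", call. = FALSE)
    mcc <- 0
  } else {
    mcc <- (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  }
  list(se = se, sp = sp, acc = acc, mcc = mcc)
}

#' Metrics from predicted and true labels
#' @param truth,pred vectors of 0/1 labels.
#' @return list(se, sp, acc, mcc).
#' @export
metrics_from_labels <- function(truth, pred) {
  compute_metrics(confusion_counts(
    tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0), fn = sum(truth == 1 & pred == 0)))
}

#' Repeated stratified k-fold cross-validation indices
#'
#' Per repeat, folds partition the data with per-fold class proportions
#' within one sample of the global proportions.
#'
#' @param labels class labels.
#' @param k folds per repeat (every class needs >= k members).
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @return list of `k * repeats` elements, each `list(train, validation)`
#'   of integer indices.
#' @export
repeated_stratified_kfold <- function(labels, k = 5, repeats = 1, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k members (k = ", k, ")")
  n <- length(labels)
  out <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(n)
    for (cl in names(tab)) {
      members <- which(labels == cl)
      members <- with_seed(derive_seed(seed, r * 131L + match(cl, names(tab))),
                           sample(members))
      fold_of[members] <- rep_len(seq_len(k), length(members))
    }
    for (f in seq_len(k)) {
      out[[length(out) + 1L]] <- list(train = which(fold_of != f),
                                      validation = which(fold_of == f))
    }
  }
  out
}

#' Estimator contract
#'
#' A generic classifier interface: `fit(X, y)` returns a fitted state,
#' `predict(state, X)` returns 0/1 labels, `importance(state)` returns one
#' non-negative real per column. Any classifier exposing coefficient
#' magnitudes or impurity importances can be wrapped this way.
#'
#' @param fit,predict,importance functions as described.
#' @param name label for reports.
#' @return an `estimator_contract`.
#' @export
estimator_contract <- function(fit, predict, importance, name = "custom") {
  stopifnot(is.function(fit), is.function(predict), is.function(importance))
  structure(list(fit = fit, predict = predict, importance = importance,
                 name = name), class = "estimator_contract")
}

#' Diagonal linear discriminant ("nearest shrunken centroid") estimator
#'
#' Deterministic, fast, and exposes a natural per-feature importance (the
#' absolute standardized mean difference), which makes it the default base
#' estimator for recursive feature elimination.
#'
#' @return an `estimator_contract`.
#' @export
estimator_centroid <- function() {
  estimator_contract(
    fit = function(X, y) {
      X <- as.matrix(X); y <- as.integer(y)
      m1 <- colMeans(X[y == 1, , drop = FALSE])
      m0 <- colMeans(X[y == 0, , drop = FALSE])
      s <- apply(X, 2, sd)
      s[s < 1e-9] <- 1e-9
      list(m0 = m0, m1 = m1, s = s)
    },
    predict = function(state, X) {
      X <- as.matrix(X)
      w <- (state$m1 - state$m0) / state$s^2
      mid <- (state$m1 + state$m0) / 2
      score <- sweep(X, 2, mid) %*% w
      as.integer(score > 0)
    },
    importance = function(state) abs(state$m1 - state$m0) / state$s,
    name = "centroid")
}

#' Logistic-regression estimator (base R glm)
#'
#' Importance is the absolute standardized coefficient. Suitable when
#' samples comfortably exceed features.
#'
#' @return an `estimator_contract`.
#' @export
estimator_logistic <- function() {
  estimator_contract(
    fit = function(X, y) {
      X <- as.matrix(X)
      df <- data.frame(X, check.names = FALSE)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = cbind(y = as.integer(y), df),
                   family = stats::binomial()))
      list(fit = fit, sds = apply(X, 2, sd), cols = colnames(X))
    },
    predict = function(state, X) {
      p <- suppressWarnings(
        stats::predict(state$fit, newdata = data.frame(as.matrix(X),
                                                       check.names = FALSE),
                       type = "response"))
      as.integer(p > 0.5)
    },
    importance = function(state) {
      co <- stats::coef(state$fit)[-1]
      co[is.na(co)] <- 0
      abs(co) * state$sds
    },
    name = "logistic")
}

#' Recursive feature elimination with cross-validated count selection
#'
#' Within each CV fold the estimator is fit repeatedly, dropping the `step`
#' lowest-importance columns until one remains; the validation MCC is
#' recorded at each candidate feature count. The returned mask refits the
#' elimination path on the full data down to the count maximizing the mean
#' CV MCC (ties favor fewer features).
#'
#' @param est an `estimator_contract`.
#' @param X descriptor matrix.
#' @param y 0/1 labels.
#' @param folds CV index pairs from [repeated_stratified_kfold()].
#' @param step columns dropped per iteration.
#' @return list(mask (logical per column), curve (data.frame count, mcc),
#'   best_count).
#' @export
rfe_cv <- function(est, X, y, folds, step = 1) {
  X <- as.matrix(X); y <- as.integer(y)
  p <- ncol(X)
  stopifnot(p >= 1)
  counts <- sort(unique(c(rev(seq(p, 1, by = -step)), 1L)))

  rfe_path <- function(Xtr, ytr, eval_fun) {
    active <- seq_len(ncol(Xtr))
    res <- setNames(numeric(length(counts)), counts)
    while (length(active) >= 1) {
      state <- tryCatch(est$fit(Xtr[, active, drop = FALSE], ytr),
                        error = function(e)
                          stop(sprintf("estimator failed at %d features: %s",
                                       length(active), conditionMessage(e)),
                               call. = FALSE))
      if (as.character(length(active)) %in% names(res))
        res[as.character(length(active))] <- eval_fun(state, active)
      if (length(active) == 1) break
      imp <- est$importance(state)
      worst <- order(imp)[seq_len(min(step, length(active) - 1L))]
      active <- active[-worst]
    }
    res
  }

  fold_mcc <- matrix(NA_real_, nrow = length(folds), ncol = length(counts),
                     dimnames = list(NULL, counts))
  for (fi in seq_along(folds)) {
    tr <- folds[[fi]]$train; va <- folds[[fi]]$validation
    fold_mcc[fi, ] <- rfe_path(
      X[tr, , drop = FALSE], y[tr],
      function(state, active) {
        pred <- est$predict(state, X[va, active, drop = FALSE])
        suppressWarnings(metrics_from_labels(y[va], pred)$mcc)
      })
  }
  curve <- data.frame(count = counts, mcc = colMeans(fold_mcc))
  best_mcc <- max(curve$mcc)
  best_count <- min(curve$count[curve$mcc >= best_mcc - 1e-12])

  # final elimination path on the full data down to best_count
  active <- seq_len(p)
  while (length(active) > best_count) {
    state <- est$fit(X[, active, drop = FALSE], y)
    imp <- est$importance(state)
    worst <- order(imp)[seq_len(min(step, length(active) - best_count))]
    active <- active[-worst]
  }
  mask <- rep(FALSE, p)
  mask[active] <- TRUE
  list(mask = mask, curve = curve, best_count = best_count)
}

#' Per-estimator metrics table (train / CV / test)
#'
#' Convenience wrapper mirroring a classification-report layout: fits each
#' estimator on the training split, evaluates on train, CV folds and test.
#'
#' @param estimators named list of `estimator_contract`s.
#' @param X,y data and 0/1 labels.
#' @param train,test integer index vectors.
#' @param folds CV folds over the training subset (indices into `train`).
#' @return data.frame with one row per estimator and split.
#' @export
ml_metrics_table <- function(estimators, X, y, train, test, folds) {
  X <- as.matrix(X); y <- as.integer(y)
  rows <- list()
  for (nm in names(estimators)) {
    est <- estimators[[nm]]
    state <- est$fit(X[train, , drop = FALSE], y[train])
    m_tr <- metrics_from_labels(y[train],
                                est$predict(state, X[train, , drop = FALSE]))
    cvs <- lapply(folds, function(f) {
      st <- est$fit(X[train[f$train], , drop = FALSE], y[train[f$train]])
      metrics_from_labels(y[train[f$validation]],
                          est$predict(st, X[train[f$validation], ,
                                            drop = FALSE]))
    })
    m_cv <- lapply(c("se", "sp", "acc", "mcc"), function(k)
      mean(vapply(cvs, `[[`, numeric(1), k)))
    names(m_cv) <- c("se", "sp", "acc", "mcc")
    m_te <- metrics_from_labels(y[test],
                                est$predict(state, X[test, , drop = FALSE]))
    for (split in c("train", "cv", "test")) {
      m <- switch(split, train = m_tr, cv = m_cv, test = m_te)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = nm, split = split, se = m$se, sp = m$sp,
        acc = m$acc, mcc = m$mcc)
    }
  }
  do.call(rbind, rows)
}
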
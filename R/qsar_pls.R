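# PLS regression (NIPALS), LOO cross-validation, FFD variable selection,
# rm2 validation metrics and coefficient-correlogram peak analysis.

#' Fit a PLS regression model (NIPALS)
#'
#' X is autoscaled (zero-variance columns are kept and receive exactly zero
#' coefficient), y is centered. Latent variables are extracted by NIPALS;
#' coefficients are back-transformed to the original descriptor scale.
#'
#' @param X descriptor matrix (n x p).
#' @param y numeric response aligned to rows of X.
#' @param n_lv number of latent variables (reduced with a warning when it
#'   exceeds the effective rank).
#' @return a `pls_model` with fields n_lv, x_mean, x_scale, y_mean,
#'   weights, x_loadings, y_loadings, scores, coefficients, intercept, r2.
#' @export
fit_pls <- function(X, y, n_lv = 5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 3)
  x_mean <- colMeans(X)
  x_scale <- apply(X, 2, sd)
  zero_var <- !is.finite(x_scale) | x_scale < 1e-12
  x_scale[zero_var] <- 1
  E <- sweep(sweep(X, 2, x_mean), 2, x_scale, `/`)
  y_mean <- mean(y)
  f <- y - y_mean
  tss <- sum(f^2)

  A <- min(n_lv, n - 1L, p)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- crossprod(E, t) / tt
    qk <- sum(f * t) / tt
    E <- E - t %*% t(pl)
    f <- f - qk * t
    a <- a + 1L
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qk
  }
  if (a < n_lv)
    warning(sprintf("n_lv reduced from %d to %d (rank deficiency)",
                    n_lv, a), call. = FALSE)
  if (a == 0L) {
    b_scaled <- numeric(p)
  } else {
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
    b_scaled <- as.numeric(W %*% solve(crossprod(P, W), q))
  }
  b_scaled[zero_var] <- 0
  b <- b_scaled / x_scale
  intercept <- y_mean - sum(b * x_mean)
  fitted <- as.numeric(X %*% b + intercept)
  r2 <- if (tss > 0) 1 - sum((y - fitted)^2) / tss else NA_real_
  structure(list(n_lv = a, x_mean = x_mean, x_scale = x_scale,
                 y_mean = y_mean, weights = W, x_loadings = P,
                 y_loadings = q, scores = if (a) Tm else NULL,
                 coefficients = b, coefficients_scaled = b_scaled,
                 intercept = intercept,
                 fitted = fitted, r2 = r2,
                 colnames = colnames(X)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$coefficients + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d LV, %d variables, r2 = %.3f>\n",
              x$n_lv, length(x$coefficients), x$r2))
  invisible(x)
}

#' Leave-one-out cross-validation: q2 and SDEP
#'
#' Each sample is predicted by a model refit on the remaining samples
#' (centering and scaling redone inside the loop). `q2 = 1 - PRESS/TSS`
#' with TSS about the full-sample mean; `SDEP = sqrt(PRESS/n)`.
#'
#' @inheritParams fit_pls
#' @return list(q2, sdep, pred).
#' @export
loo_q2 <- function(X, y, n_lv = 5) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= n_lv + 3)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(fit_pls(X[-i, , drop = FALSE], y[-i], n_lv))
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, sdep = sqrt(press / n), pred = pred)
}

# Lean LOO SDEP used inside the FFD loop: identical model to
# fit_pls/loo_q2 (autoscaling redone per fold, NIPALS, back-transformed
# prediction) but without object construction. Equality with loo_q2 is
# asserted by the test suite (dual route).
loo_sdep_fast <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    m <- colMeans(Xi)
    cs <- sqrt((colSums(Xi * Xi) - (n - 1) * m * m) / (n - 2))
    cs[!is.finite(cs) | cs < 1e-12] <- 1
    E <- (Xi - rep(m, each = n - 1)) / rep(cs, each = n - 1)
    ym <- mean(yi)
    f <- yi - ym
    xnew <- (X[i, ] - m) / cs
    yhat <- ym
    A <- min(n_lv, n - 2L, p)
    for (a in seq_len(A)) {
      w <- crossprod(E, f)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      t <- E %*% w
      tt <- sum(t * t)
      if (tt < 1e-12) break
      pl <- crossprod(E, t) / tt
      qk <- sum(f * t) / tt
      tnew <- sum(xnew * w)
      yhat <- yhat + qk * tnew
      E <- E - tcrossprod(t, pl)
      f <- f - qk * t
      xnew <- xnew - tnew * pl
    }
    pred[i] <- yhat
  }
  sqrt(mean((y - pred)^2))
}

#' K-fold cross-validated SDEP (used by FFD for larger n)
#' @keywords internal
kfold_sdep <- function(X, y, n_lv, k = 5, seed = 1) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- suppressWarnings(
      fit_pls(X[!hold, , drop = FALSE], y[!hold], n_lv))
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}

# Sylvester Hadamard matrix of order 2^k.
hadamard <- function(order) {
  H <- matrix(1, 1, 1)
  while (nrow(H) < order) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' One-cycle FFD variable selection
#'
#' A two-level fractional factorial design (orthogonal Hadamard columns,
#' resolution III; folded over by default, which cancels two-factor
#' aliasing on main effects) perturbs variable inclusion alongside
#' `ceil(dummy_fraction * V)` dummy variables that are never actually added
#' to the model. For each design row the reduced model's SDEP is computed
#' by LOO (k-fold, k = 5, when n > 100). A variable's effect is
#' `mean SDEP(present) - mean SDEP(absent)`; variables whose presence
#' worsens SDEP beyond dummy noise (effect > mean_dummy + 2 sd_dummy) are
#' removed. Single cycle only, following the GOLPE convention.
#'
#' The design stacks `runs_factor` independently column-scrambled folded
#' Hadamard fractions (still a single selection cycle): with the minimal
#' fraction alone, the dummy-effect noise floor is comparable to the SDEP
#' penalty of one pure-noise variable and the rule loses power; ~10 runs
#' per variable puts the noise floor well below it.
#'
#' @inheritParams fit_pls
#' @param dummy_fraction dummies as a fraction of V.
#' @param fold_over append the complementary design (recommended).
#' @param runs_factor number of stacked scrambled fractions.
#' @param seed integer; randomizes the assignment of variables to design
#'   columns (and the k-fold split when used).
#' @return list(keep (logical mask), effects (data.frame), threshold,
#'   sdep_before, sdep_after).
#' @export
ffd_select <- function(X, y, n_lv = 2, dummy_fraction = 0.2,
                       fold_over = TRUE, runs_factor = 16, seed = 1) {
  X <- as.matrix(X)
  V <- ncol(X)
  if (V < 8) stop("FFD needs at least 8 variables")
  n <- nrow(X)
  n_dummy <- ceiling(dummy_fraction * V)
  m <- V + n_dummy
  N <- 2^ceiling(log2(m + 1))
  H <- hadamard(N)
  base_design <- H[, 1 + seq_len(m), drop = FALSE]  # drop the constant column
  design <- do.call(rbind, lapply(seq_len(max(1, runs_factor)), function(b) {
    # each block randomizes which Hadamard column serves which variable
    assign_cols <- with_seed(derive_seed(seed, b + 1L), sample(m))
    base_design[, assign_cols, drop = FALSE]
  }))
  if (fold_over) design <- rbind(design, -design)

  sdep_row <- function(mask_cols) {
    if (!length(mask_cols)) {
      # intercept-only model under LOO
      pred <- vapply(seq_len(n), function(i) mean(y[-i]), numeric(1))
      return(sqrt(mean((y - pred)^2)))
    }
    Xr <- X[, mask_cols, drop = FALSE]
    lv <- min(n_lv, length(mask_cols))
    if (n > 100) kfold_sdep(Xr, y, lv, seed = derive_seed(seed, 3))
    else loo_sdep_fast(Xr, y, lv)
  }
  sdep <- vapply(seq_len(nrow(design)), function(r)
    sdep_row(which(design[r, seq_len(V)] > 0)), numeric(1))

  effect <- vapply(seq_len(m), function(v)
    mean(sdep[design[, v] > 0]) - mean(sdep[design[, v] < 0]), numeric(1))
  var_eff <- effect[seq_len(V)]
  dummy_eff <- effect[V + seq_len(n_dummy)]
  threshold <- mean(dummy_eff) + 2 * sd(dummy_eff)
  if (!is.finite(threshold)) threshold <- 0
  keep <- !(var_eff > threshold)
  effects <- data.frame(
    variable = c(colnames(X) %||% paste0("V", seq_len(V)),
                 paste0("dummy", seq_len(n_dummy))),
    role = rep(c("variable", "dummy"), c(V, n_dummy)),
    effect = effect,
    removed = c(!keep, rep(NA, n_dummy)))
  sdep_before <- sdep_row(seq_len(V))
  sdep_after <- sdep_row(which(keep))
  list(keep = keep, effects = effects, threshold = threshold,
       sdep_before = sdep_before, sdep_after = sdep_after,
       n_rows = nrow(design))
}

#' rm2 external-validation metrics
#'
#' Penalizes divergence between the observed/predicted correlation with and
#' without an intercept: `rm2 = r2 * (1 - sqrt(|r2 - r0^2|))` where `r0^2`
#' comes from the least-squares line through the origin of predicted on
#' observed; the primed variant swaps the axes. `delta_rm2 = |rm2 - rm2'|`
#' and the reported `rm2` is the average of the two.
#'
#' @param y_obs,y_pred observed and predicted activities (>= 3 points,
#'   nonzero variance).
#' @return list(rm2, delta_rm2, rm2_fwd, rm2_rev, r2).
#' @export
rm2_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  if (sd(y_obs) < 1e-12 || sd(y_pred) < 1e-12)
    stop("constant vector: rm2 undefined")
  r2 <- cor(y_obs, y_pred)^2
  r02 <- function(a, b) {       # regress a on b through the origin
    k <- sum(a * b) / sum(b^2)
    1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
  }
  rm_fwd <- r2 * (1 - sqrt(abs(r2 - r02(y_pred, y_obs))))
  rm_rev <- r2 * (1 - sqrt(abs(r2 - r02(y_obs, y_pred))))
  list(rm2 = (rm_fwd + rm_rev) / 2, delta_rm2 = abs(rm_fwd - rm_rev),
       rm2_fwd = rm_fwd, rm2_rev = rm_rev, r2 = r2)
}

#' Coefficient-correlogram peak report
#'
#' Ranks model variables by absolute *standardized* coefficient (the
#' coefficient on the autoscaled variable -- the scale on which the PLS
#' model operates; raw-scale coefficients would spuriously promote
#' small-variance variables) and reports, per peak, the probe block, the
#' distance-bin interval in Angstrom, the coefficient sign and magnitude,
#' and (when provenance is available) the argmax node pair of the most
#' active compounds for hotspot back-mapping.
#'
#' @param model a `pls_model` fitted on a GRIND descriptor matrix.
#' @param layout variable layout (see [correlogram_layout()]), aligned to
#'   the model's variables.
#' @param provenance per-compound provenance list from
#'   [build_descriptor_matrix()], or NULL.
#' @param top_k number of peaks reported.
#' @param activities optional named pIC50 vector used to order compounds
#'   for back-mapping (most active first).
#' @return a `peak_report` data.frame sorted by |coefficient| descending;
#'   attribute `backmap` holds per-peak provenance rows.
#' @export
coefficient_correlogram <- function(model, layout, provenance = NULL,
                                    top_k = 10, activities = NULL) {
  b <- model$coefficients_scaled %||% model$coefficients
  stopifnot(length(b) == nrow(layout))
  nz <- which(abs(b) > 1e-12)
  if (!length(nz)) {
    out <- data.frame(block = character(0), lo = numeric(0), hi = numeric(0),
                      sign = integer(0), coefficient = numeric(0))
    class(out) <- c("peak_report", class(out))
    return(out)
  }
  ord <- nz[order(abs(b[nz]), decreasing = TRUE)]
  ord <- ord[seq_len(min(top_k, length(ord)))]
  out <- data.frame(block = layout$block[ord], lo = layout$lo[ord],
                    hi = layout$hi[ord], sign = sign(b[ord]),
                    coefficient = b[ord],
                    coefficient_raw = model$coefficients[ord],
                    variable = layout$name[ord])
  if (is.null(provenance)) {
    warning("provenance missing: peaks reported without back-mapping",
            call. = FALSE)
  } else {
    ids <- names(provenance)
    if (!is.null(activities))
      ids <- ids[order(-activities[ids])]
    backmap <- lapply(seq_len(nrow(out)), function(r) {
      hits <- lapply(ids, function(id) {
        p <- provenance[[id]]
        if (is.null(p) || !nrow(p)) return(NULL)
        rows <- p[p$block == out$block[r] &
                    abs(p$lo - out$lo[r]) < 1e-9, , drop = FALSE]
        if (!nrow(rows)) return(NULL)
        cbind(compound = id, rows)
      })
      hits <- Filter(Negate(is.null), hits)
      if (length(hits)) do.call(rbind, hits) else NULL
    })
    attr(out, "backmap") <- backmap
  }
  class(out) <- c("peak_report", class(out))
  out
}
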
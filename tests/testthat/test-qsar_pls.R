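test_that("PLS basics: perfect one-factor fit, rank cap, permutation", {
  withr::with_seed(1, {
    X <- matrix(rnorm(40 * 6), 40)
    y <- 2.5 * X[, 3] + 1
  })
  # one latent variable suffices when the single relevant column is the
  # only one available
  fit1 <- fit_pls(X[, 3, drop = FALSE], y, n_lv = 1)
  expect_equal(fit1$r2, 1.0, tolerance = 1e-9)
  expect_equal(predict(fit1, X[, 3, drop = FALSE]), y, tolerance = 1e-8)
  # with correlated nuisance columns the fit is exact at full rank
  fit <- fit_pls(X, y, n_lv = 6)
  expect_equal(fit$r2, 1.0, tolerance = 1e-9)

  expect_warning(over <- fit_pls(X[1:5, ], y[1:5], n_lv = 10), "reduced")
  expect_lte(over$n_lv, 4)

  perm <- withr::with_seed(2, sample(40))
  fit_a <- fit_pls(X, y, n_lv = 3)
  fit_b <- fit_pls(X[perm, ], y[perm], n_lv = 3)
  expect_equal(fit_a$coefficients, fit_b$coefficients, tolerance = 1e-10)
})

test_that("full-rank PLS equals the least-squares oracle", {
  for (s in 1:10) {
    withr::with_seed(s, {
      X <- matrix(rnorm(20 * 5), 20)
      y <- rnorm(20)
    })
    fit <- fit_pls(X, y, n_lv = 5)
    ols <- lm.fit(cbind(1, X), y)
    pred_ols <- cbind(1, X) %*% ols$coefficients
    expect_equal(predict(fit, X), as.numeric(pred_ols), tolerance = 1e-6)
  }
})

test_that("zero-variance columns keep exactly zero coefficients", {
  withr::with_seed(3, {
    X <- cbind(matrix(rnorm(60), 30), dead = rep(2, 30))
    y <- X[, 1] + rnorm(30, 0, 0.1)
  })
  fit <- fit_pls(X, y, n_lv = 2)
  expect_identical(unname(fit$coefficients[3]), 0)
})

test_that("score vectors are mutually orthogonal and r2 >= q2", {
  withr::with_seed(4, {
    X <- matrix(rnorm(35 * 10), 35)
    y <- X[, 1] - X[, 2] + rnorm(35, 0, 0.3)
  })
  fit <- fit_pls(X, y, n_lv = 4)
  G <- crossprod(fit$scores)
  Gn <- G / outer(sqrt(diag(G)), sqrt(diag(G)))
  expect_true(all(abs(Gn[upper.tri(Gn)]) < 1e-6))
  cv <- loo_q2(X, y, n_lv = 4)
  expect_gte(fit$r2, cv$q2)
})

test_that("LOO q2/SDEP equal the naive refit loop and detect signal", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30 * 4), 30)
    y <- X %*% c(1, -1, 0.5, 0)
  })
  cv <- loo_q2(X, y, n_lv = 3)
  expect_gt(cv$q2, 0.99)

  # naive from-scratch loop
  pred <- vapply(seq_len(30), function(i) {
    f <- suppressWarnings(fit_pls(X[-i, ], y[-i], n_lv = 3))
    predict(f, X[i, , drop = FALSE])
  }, numeric(1))
  press <- sum((y - pred)^2)
  expect_identical(cv$q2, 1 - press / sum((y - mean(y))^2))
  expect_identical(cv$sdep, sqrt(press / 30))

  # the lean FFD path agrees with the reference (dual route)
  expect_equal(flapqsar:::loo_sdep_fast(X, y, 3), cv$sdep,
               tolerance = 1e-10)
})

test_that("y-scrambling destroys cross-validated performance", {
  withr::with_seed(6, {
    X <- matrix(rnorm(50 * 8), 50)
    y <- X[, 1] + rnorm(50, 0, 0.2)
  })
  q2s <- vapply(1:10, function(s) {
    ys <- withr::with_seed(100 + s, sample(y))
    loo_q2(X, ys, n_lv = 2)$q2
  }, numeric(1))
  expect_lte(median(q2s), 0.2)
})

test_that("FFD prunes noise, keeps signal, and never breaks the model", {
  ok <- vapply(1:3, function(s) {
    X <- withr::with_seed(derive_seed(s, 1), matrix(rnorm(80 * 45), 80))
    colnames(X) <- c(paste0("sig", 1:5), paste0("noise", 1:40))
    y <- rowSums(X[, 1:5]) +
      withr::with_seed(derive_seed(s, 2), rnorm(80, 0, 0.5))
    sel <- ffd_select(X, y, n_lv = 2, runs_factor = 8, seed = s)
    before <- loo_q2(X, y, 2)$sdep
    after <- loo_q2(X[, sel$keep, drop = FALSE], y, 2)$sdep
    expect_lte(after, before * 1.05)
    sum(!sel$keep[6:45]) >= 28 && sum(sel$keep[1:5]) >= 4
  }, logical(1))
  expect_gte(sum(ok), 2)
})

test_that("FFD leaves identical copies of the signal untouched", {
  withr::with_seed(7, {
    x <- rnorm(40)
    X <- matrix(rep(x, 10), 40)
    y <- x + rnorm(40, 0, 0.1)
  })
  colnames(X) <- paste0("copy", 1:10)
  sel <- ffd_select(X, y, n_lv = 2, runs_factor = 2, seed = 1)
  expect_true(all(sel$keep))
  expect_error(ffd_select(X[, 1:4], y), "at least 8")
})

test_that("rm2 metrics match the closed-form recomputation", {
  y <- c(6.1, 7.3, 8.2, 6.8, 7.9, 8.5, 7.1, 6.4)
  # sqrt(|r2 - r02|) amplifies roundoff near equality: 1e-6 tolerance
  expect_equal(rm2_metrics(y, y)$rm2, 1, tolerance = 1e-6)
  expect_equal(rm2_metrics(y, y)$delta_rm2, 0, tolerance = 1e-6)

  shifted <- rm2_metrics(y, y + 1)
  expect_lt(shifted$rm2, shifted$r2)

  withr::with_seed(8, {
    yp <- y + rnorm(8, 0, 0.4)
  })
  got <- rm2_metrics(y, yp)
  # independent spreadsheet-style recomputation
  r2 <- cor(y, yp)^2
  k_fwd <- sum(yp * y) / sum(y^2)
  r02_fwd <- 1 - sum((yp - k_fwd * y)^2) / sum((yp - mean(yp))^2)
  k_rev <- sum(y * yp) / sum(yp^2)
  r02_rev <- 1 - sum((y - k_rev * yp)^2) / sum((y - mean(y))^2)
  rm_f <- r2 * (1 - sqrt(abs(r2 - r02_fwd)))
  rm_r <- r2 * (1 - sqrt(abs(r2 - r02_rev)))
  expect_equal(got$rm2, (rm_f + rm_r) / 2, tolerance = 1e-12)
  expect_equal(got$delta_rm2, abs(rm_f - rm_r), tolerance = 1e-12)
  expect_error(rm2_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("peak reports rank standardized coefficients with valid bins", {
  layout <- correlogram_layout(0.4, 8)
  withr::with_seed(9, {
    X <- matrix(abs(rnorm(30 * nrow(layout))), 30)
  })
  colnames(X) <- layout$name
  y <- 2 * X[, 5] - X[, 17] + withr::with_seed(10, rnorm(30, 0, 0.1))
  fit <- fit_pls(X, y, n_lv = 2)
  rep_ <- suppressWarnings(coefficient_correlogram(fit, layout, NULL,
                                                   top_k = 10))
  expect_lte(nrow(rep_), 10)
  expect_true(all(diff(abs(rep_$coefficient)) <= 1e-12))
  expect_true(all(abs(rep_$lo / 0.4 - round(rep_$lo / 0.4)) < 1e-9))
  expect_true(all(rep_$hi - rep_$lo - 0.4 < 1e-9))
  expect_warning(coefficient_correlogram(fit, layout, NULL), "provenance")

  # all-zero model: empty report
  zero <- fit
  zero$coefficients_scaled <- rep(0, nrow(layout))
  zero$coefficients <- rep(0, nrow(layout))
  expect_equal(nrow(suppressWarnings(
    coefficient_correlogram(zero, layout, NULL))), 0)
})
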
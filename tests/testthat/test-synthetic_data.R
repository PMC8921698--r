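test_that("noiseless single-pair design yields exactly two activity levels", {
  spec <- pharmacophore_spec(
    features = list(list(class = "DRY", anchor = c(0, 0, 0)),
                    list(class = "DRY", anchor = c(10, 0, 0))),
    signal_pairs = data.frame(i = 1, j = 2, distance = 10, beta = 2,
                              tol = 0.3),
    baseline = 6, noise_sd = 0, seed = 7)
  ls1 <- gen_ligand_set(spec, 30)
  lev <- sort(unique(ls1$activities$pic50))
  expect_length(lev, 2)
  expect_equal(diff(lev), 2.0)
})

test_that("generators are pure functions of (parameters, seed)", {
  spec <- default_pharmacophore_spec(noise_sd = 0.2, seed = 42)
  a <- gen_ligand_set(spec, 5)
  b <- gen_ligand_set(spec, 5)
  expect_identical(a$activities, b$activities)
  for (k in 1:5)
    expect_identical(a$molecules[[k]]$atoms, b$molecules[[k]]$atoms)

  e1 <- gen_pose_ensemble(3, 4, list(c(0, 0, 0), c(8, 0, 0)),
                          jitter_sd = 0.2, seed = 9)
  e2 <- gen_pose_ensemble(3, 4, list(c(0, 0, 0), c(8, 0, 0)),
                          jitter_sd = 0.2, seed = 9)
  for (k in 1:3) for (p in 1:4)
    expect_identical(e1[[k]]$poses[[p]]$atoms, e2[[k]]$poses[[p]]$atoms)

  d1 <- gen_descriptor_table(50, 3, 10, seed = 5)
  d2 <- gen_descriptor_table(50, 3, 10, seed = 5)
  expect_identical(d1, d2)
})

test_that("OLS on the generator's own design matrix recovers the betas", {
  spec <- default_pharmacophore_spec(noise_sd = 0.2, seed = 23)
  ls1 <- gen_ligand_set(spec, 60)
  gt <- ls1$ground_truth
  d <- data.frame(
    y = ls1$activities$pic50,
    x1 = gt$realized[gt$pair == 1],
    x2 = gt$realized[gt$pair == 2])
  fit <- lm(y ~ x1 + x2, data = d)
  expect_equal(unname(coef(fit)["x1TRUE"]), 1.0, tolerance = 0.15)
  expect_equal(unname(coef(fit)["x2TRUE"]), 0.8, tolerance = 0.15)
})

test_that("realized-pair bookkeeping matches geometric re-measurement", {
  spec <- default_pharmacophore_spec(noise_sd = 0, seed = 13)
  ls1 <- gen_ligand_set(spec, 12)
  pairs <- spec$signal_pairs
  # payload layout: 6 chain atoms, then per-feature payloads (DRY = 6
  # atoms, N1 = 3); payload centroid reproduces the feature position
  sizes <- c(6, 3, 6, 6)
  offsets <- 6 + cumsum(c(0, head(sizes, -1)))
  for (l in seq_along(ls1$molecules)) {
    m <- ls1$molecules[[l]]
    centroid <- function(f) colMeans(
      m$atoms[(offsets[f] + 1):(offsets[f] + sizes[f]), c("x", "y", "z")])
    gt <- ls1$ground_truth[ls1$ground_truth$compound_id == m$id, ]
    for (r in seq_len(nrow(pairs))) {
      d <- sqrt(sum((centroid(pairs$i[r]) - centroid(pairs$j[r]))^2))
      expect_equal(d, gt$distance[r], tolerance = 1e-9)
      expect_identical(abs(d - pairs$distance[r]) <= pairs$tol[r],
                       gt$realized[r])
    }
  }
  # activity equals the stated linear model of the realized flags
  gt <- ls1$ground_truth
  y_expect <- 6 + tapply(gt$realized * pairs$beta[gt$pair],
                         gt$compound_id, sum)
  expect_equal(as.numeric(y_expect[ls1$activities$compound_id]),
               ls1$activities$pic50, tolerance = 1e-12)
})

test_that("infeasible pharmacophore geometry errors", {
  spec <- pharmacophore_spec(
    features = list(list(class = "DRY", anchor = c(0, 0, 0)),
                    list(class = "DRY", anchor = c(1.0, 0, 0))),
    signal_pairs = data.frame(i = 1, j = 2, distance = 1.0, beta = 1,
                              tol = 0.2),
    noise_sd = 0, seed = 1)
  expect_error(gen_ligand_set(spec, 8), "1.5 Angstrom|clear of each other")
})

test_that("pose ensembles realize the planted cluster structure", {
  # rigid copies: zero within-cluster RMSD, translation norm between
  ens <- gen_pose_ensemble(2, 10, list(c(0, 0, 0), c(10, 0, 0)),
                           membership_probs = c(0.5, 0.5),
                           jitter_sd = 0, seed = 3)
  labels <- attr(ens, "true_labels")
  e <- ens[[1]]
  lab <- labels$center[labels$ligand_id == e$ligand_id]
  for (i in 1:9) for (j in (i + 1):10) {
    r <- scaffold_rmsd(e$poses[[i]], e$poses[[j]], e$scaffold_atoms)
    if (lab[i] == lab[j]) expect_equal(r, 0) else expect_equal(r, 10)
  }

  ens2 <- gen_pose_ensemble(2, 10, list(c(0, 0, 0), c(10, 0, 0)),
                            jitter_sd = 0.1, seed = 3)
  labels2 <- attr(ens2, "true_labels")
  e2 <- ens2[[1]]
  lab2 <- labels2$center[labels2$ligand_id == e2$ligand_id]
  for (i in 1:9) for (j in (i + 1):10) {
    r <- scaffold_rmsd(e2$poses[[i]], e2$poses[[j]], e2$scaffold_atoms)
    if (lab2[i] == lab2[j]) expect_lt(r, 0.5) else expect_gt(r, 8)
  }

  expect_error(gen_pose_ensemble(2, 5, list()), "non-empty")
  expect_error(gen_pose_ensemble(2, 5, list(c(0, 0, 0)),
                                 membership_probs = c(0.5, 0.2)), "sum to 1")
})

test_that("descriptor tables plant separable informative columns", {
  d <- gen_descriptor_table(402, 5, 20, class_balance = 0.5, seed = 8)
  expect_equal(sum(d$labels == 1), 201)
  expect_equal(sum(d$labels == 0), 201)
  expect_identical(colnames(d$table)[1:5], paste0("inf_", 1:5))

  # large effect, no label noise: a midpoint threshold on any informative
  # column is a strong single-feature classifier
  big <- gen_descriptor_table(400, 3, 5, flip_rate = 0, effect_size = 3.5,
                              seed = 9)
  for (k in 1:3) {
    x <- big$table[[k]]
    thr <- mean(x)
    acc <- mean(as.integer(x > thr) == big$labels)
    expect_gt(acc, 0.9)
  }

  # no informative columns: CV MCC of a real estimator stays near zero
  null <- gen_descriptor_table(200, 0, 20, seed = 10)
  folds <- repeated_stratified_kfold(null$labels, k = 5, seed = 1)
  est <- estimator_centroid()
  mccs <- vapply(folds, function(f) {
    st <- est$fit(null$table[f$train, ], null$labels[f$train])
    suppressWarnings(metrics_from_labels(
      null$labels[f$validation],
      est$predict(st, null$table[f$validation, ]))$mcc)
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.2)

  expect_error(gen_descriptor_table(50, 1, 1, flip_rate = 0.6), "flip_rate")
})
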
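# Activity curation: pIC50 conversion, lipophilic efficiency, activity
# class labels, the LipE/cLogP modeling filter, stratified splitting and
# descriptor-table filtering.

#' Convert IC50 (nM) to pIC50
#'
#' Standard molar negative-log convention: `pIC50 = -log10(ic50 * 1e-9)`.
#'
#' @param ic50 IC50 in nanomolar; must be positive.
#' @return pIC50 in log units.
#' @export
pic50_from_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive and finite")
  -log10(ic50 * 1e-9)
}

#' Lipophilic efficiency
#'
#' `LipE = pIC50 - cLogP`, signed (no absolute value): potency normalized
#' by lipophilicity. Values above ~5 indicate potency beyond what
#' lipophilicity alone buys.
#'
#' @param pic50 activity, log units.
#' @param clogp calculated octanol/water partition coefficient.
#' @return LipE in log units.
#' @export
lipe <- function(pic50, clogp) {
  if (any(!is.finite(pic50)) || any(!is.finite(clogp)))
    stop("pic50 and clogp must be finite")
  pic50 - clogp
}

#' Label compounds by activity thresholds
#'
#' Compounds with IC50 strictly below `active_below` are "active", strictly
#' above `least_above` are "least", and in between "intermediate" (callers
#' typically drop intermediates before classification modeling).
#'
#' @param ic50 IC50 in nM.
#' @param active_below,least_above thresholds in nM.
#' @return character vector in {"active", "least", "intermediate"}.
#' @export
label_activity <- function(ic50, active_below = 10, least_above = 70) {
  if (active_below >= least_above)
    stop("active_below must be strictly less than least_above")
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive and finite")
  ifelse(ic50 < active_below, "active",
         ifelse(ic50 > least_above, "least", "intermediate"))
}

#' Build activity records
#'
#' @param compound_id character vector.
#' @param ic50 IC50 in nM.
#' @param clogp calculated logP.
#' @param active_below,least_above label thresholds, nM.
#' @return data.frame with compound_id, ic50, pic50, clogp, lipe, label.
#' @export
activity_records <- function(compound_id, ic50, clogp,
                             active_below = 10, least_above = 70) {
  p <- pic50_from_ic50(ic50)
  data.frame(compound_id = as.character(compound_id), ic50 = ic50,
             pic50 = p, clogp = clogp, lipe = lipe(p, clogp),
             label = label_activity(ic50, active_below, least_above))
}

#' LipE / cLogP modeling filter
#'
#' Keeps records with `lipe > lipe_min` AND `clogp > clogp_min` (both
#' strict), preserving order. The defaults select lipophilic-but-efficient
#' chemotypes suitable for modeling against a membrane-embedded target.
#'
#' @param records data.frame with `lipe` and `clogp` columns.
#' @param lipe_min,clogp_min strict lower bounds.
#' @return the filtered data.frame.
#' @export
lipe_clogp_filter <- function(records, lipe_min = 1, clogp_min = 2) {
  stopifnot(all(c("lipe", "clogp") %in% names(records)))
  records[records$lipe > lipe_min & records$clogp > clogp_min, ,
          drop = FALSE]
}

#' Stratified train/test split
#'
#' Test size is `ceiling(n * test_fraction)`; per-class test counts follow
#' largest-remainder apportionment so class proportions are preserved as
#' closely as integer counts allow. Disjoint, exhaustive, reproducible.
#'
#' @param ids sample identifiers.
#' @param labels class labels aligned to ids.
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list(train, test) of ids.
#' @export
stratified_split <- function(ids, labels, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  stopifnot(length(ids) == length(labels))
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  n <- length(ids)
  n_test <- as.integer(ceiling(n * test_fraction))
  classes <- sort(unique(labels))
  quota <- vapply(classes, function(cl)
    sum(labels == cl) * test_fraction, numeric(1))
  base <- floor(quota)
  rem <- quota - base
  extra <- n_test - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  test_idx <- integer(0)
  for (ci in seq_along(classes)) {
    members <- which(labels == classes[ci])
    take <- with_seed(derive_seed(seed, ci),
                      sample(members, min(base[ci], length(members))))
    test_idx <- c(test_idx, take)
  }
  test_idx <- sort(test_idx)
  list(train = ids[setdiff(seq_len(n), test_idx)], test = ids[test_idx])
}

#' Descriptor table container
#'
#' @param values numeric matrix (samples x descriptors).
#' @param sample_ids row identifiers.
#' @param provenance optional per-column free text.
#' @return a `descriptor_table`.
#' @export
descriptor_table <- function(values, sample_ids = rownames(values),
                             provenance = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("d", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values))) stop("duplicated column names")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(values)))
  stopifnot(length(sample_ids) == nrow(values))
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids,
                 column_names = colnames(values), provenance = provenance),
            class = "descriptor_table")
}

#' Three-pass descriptor filtering
#'
#' Sequential passes: (1) drop columns with any missing value or variance
#' at or below `var_tol`; (2) for pairs with `|Pearson r| > pairwise_r_max`
#' drop the member with the lower absolute correlation to the target
#' (ties: drop the later column); (3) drop columns with `|r|` to the target
#' below `target_r_min`. Per-pass removal counts are attached as the
#' `report` attribute.
#'
#' @param table a `descriptor_table` or numeric matrix.
#' @param y target variable aligned to rows.
#' @param var_tol variance floor.
#' @param pairwise_r_max inter-descriptor correlation ceiling.
#' @param target_r_min descriptor-target correlation floor.
#' @return filtered `descriptor_table` with a `report` attribute.
#' @export
filter_descriptors <- function(table, y, var_tol = 1e-8,
                               pairwise_r_max = 0.95, target_r_min = 0.1) {
  if (inherits(table, "descriptor_table")) tab <- table else
    tab <- descriptor_table(table)
  X <- tab$values
  stopifnot(nrow(X) == length(y))
  p0 <- ncol(X)

  bad <- apply(X, 2, function(col) anyNA(col) || var(col) <= var_tol)
  X <- X[, !bad, drop = FALSE]
  n_pass1 <- sum(bad)

  r_y <- abs(suppressWarnings(cor(X, as.numeric(y))))[, 1]
  r_y[is.na(r_y)] <- 0
  dropped <- rep(FALSE, ncol(X))
  if (ncol(X) >= 2) {
    C <- abs(suppressWarnings(cor(X)))
    diag(C) <- 0
    C[is.na(C)] <- 0
    repeat {
      C_act <- C
      C_act[dropped, ] <- 0; C_act[, dropped] <- 0
      mx <- max(C_act)
      if (mx <= pairwise_r_max) break
      hit <- which(C_act == mx, arr.ind = TRUE)[1, ]
      i <- min(hit); j <- max(hit)
      drop_col <- if (r_y[i] < r_y[j]) i else if (r_y[j] < r_y[i]) j else j
      dropped[drop_col] <- TRUE
    }
  }
  n_pass2 <- sum(dropped)
  X <- X[, !dropped, drop = FALSE]
  r_y <- r_y[!dropped]

  low <- r_y < target_r_min
  n_pass3 <- sum(low)
  X <- X[, !low, drop = FALSE]
  if (!ncol(X))
    stop("no descriptors survive filtering; relax var_tol/pairwise_r_max/",
         "target_r_min")
  out <- descriptor_table(X, tab$sample_ids)
  attr(out, "report") <- data.frame(
    pass = c("missing_or_low_variance", "pairwise_autocorrelation",
             "low_target_correlation"),
    removed = c(n_pass1, n_pass2, n_pass3),
    remaining = c(p0 - n_pass1, p0 - n_pass1 - n_pass2,
                  p0 - n_pass1 - n_pass2 - n_pass3))
  out
}
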
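# Experiment harness: feature selection, random-forest classification
# and regression, repeated leave-one-out cross-validation, and parcel /
# feature-family importance aggregation.

#' Feature-selection configuration
#'
#' @param correlation_threshold Pairs with |Pearson r| above this are
#'   pruned (the earlier column is kept). Default 0.95.
#' @param k_select Maximum number of features kept after univariate
#'   ranking. Default 500.
#' @return A `selection_config` list.
#' @export
selection_config <- function(correlation_threshold = 0.95, k_select = 500L) {
  stopifnot(correlation_threshold > 0, correlation_threshold <= 1,
            k_select >= 1L)
  structure(list(correlation_threshold = correlation_threshold,
                 k_select = as.integer(k_select)),
            class = "selection_config")
}

#' Automatic feature selection
#'
#' Deterministic three-stage pipeline fitted on training rows only:
#' drop constant columns, greedily drop one of each highly correlated
#' pair (|r| > threshold; the earlier column is kept), then rank the
#' remaining columns by a univariate score (ANOVA F for classification,
#' univariate regression F for continuous outcomes) and keep the top
#' `k_select` (all if fewer remain).
#'
#' @param X Numeric matrix, rows = subjects, named columns = features.
#' @param y Outcome: factor/character for classification, numeric for
#'   regression.
#' @param cfg A [selection_config()].
#' @param train_idx Rows used to fit the selection (default: all).
#' @return Character vector of selected column names.
#' @export
select_features <- function(X, y, cfg = selection_config(),
                            train_idx = seq_len(nrow(X))) {
  if (nrow(X) == 0L) stop("no rows")
  X <- as.matrix(X)
  Xt <- X[train_idx, , drop = FALSE]
  yt <- y[train_idx]
  keep <- colnames(X)
  # stage 1: constants (and columns with missing values)
  sds <- apply(Xt, 2, function(v) if (anyNA(v)) NA_real_ else sd(v))
  keep <- keep[!is.na(sds) & sds > 0]
  if (length(keep) == 0L) return(character(0))
  # stage 2: correlation pruning (greedy, keep the earlier column)
  if (length(keep) > 1L) {
    Z <- scale(Xt[, keep, drop = FALSE], scale = FALSE)
    S <- crossprod(Z)
    ok <- prune_correlated_cpp(S, cfg$correlation_threshold)
    keep <- keep[ok]
  }
  # stage 3: univariate ranking
  score <- .univariate_f(Xt[, keep, drop = FALSE], yt)
  k <- min(cfg$k_select, length(keep))
  keep[order(score, decreasing = TRUE)[seq_len(k)]]
}

# Vectorized univariate F statistics: one-way ANOVA F for factor y,
# simple-regression F otherwise.
.univariate_f <- function(X, y) {
  n <- nrow(X)
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    groups <- split(seq_len(n), y)
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    g <- length(groups)
    grand <- colMeans(X)
    ssb <- rep(0, ncol(X)); ssw <- rep(0, ncol(X))
    for (gi in groups) {
      mg <- colMeans(X[gi, , drop = FALSE])
      ssb <- ssb + length(gi) * (mg - grand)^2
      ssw <- ssw + colSums(sweep(X[gi, , drop = FALSE], 2, mg)^2)
    }
    f <- (ssb / (g - 1)) / (ssw / (n - g))
    f[is.nan(f)] <- 0          # 0/0: no variance at all
    f                          # ssw = 0 with signal gives +Inf, ranked first
  } else {
    r <- suppressWarnings(cor(X, y))
    r[is.na(r)] <- 0
    r2 <- r^2
    drop(r2 / pmax(1 - r2, .Machine$double.eps) * (n - 2))
  }
}

#' Repeated leave-one-out cross-validated classification
#'
#' For each of `n_seeds` seeds, runs leave-one-out cross-validation:
#' feature selection is re-fit inside every training fold, a random
#' forest (default 500 trees, no tuning) is fit, and the held-out class
#' probability recorded. AUROC is computed per seed over the pooled
#' held-out predictions (multiclass: one-vs-rest macro average).
#' Per-feature importances (mean decrease in impurity, normalized to
#' sum 1 per fitted model) are averaged over all folds and seeds;
#' unselected features contribute 0.
#'
#' @param X Feature matrix (rows = subjects, named columns).
#' @param y Class labels (>= 2 classes, >= 2 subjects each).
#' @param cfg A [selection_config()].
#' @param n_seeds Number of differently seeded repetitions (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param base_seed Offset added to the per-repetition seeds.
#' @return A `model_report` list: `auroc` (per seed), `mean_auroc`,
#'   `sd_auroc`, `importance` (named, sums to 1), `predictions`.
#' @export
cross_validate_classifier <- function(X, y, cfg = selection_config(),
                                      n_seeds = 10L, n_trees = 500L,
                                      base_seed = 0L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (any(table(y) < 2L)) stop("need >= 2 subjects per class")
  n <- nrow(X)
  classes <- levels(y)
  imp_acc <- setNames(rep(0, ncol(X)), colnames(X))
  n_models <- 0L
  auroc <- numeric(n_seeds)
  pred_list <- vector("list", n_seeds)
  # fold-wise selections are deterministic (no seed involved), so they
  # are computed once per fold and shared across the seeded repetitions
  fold_sel <- lapply(seq_len(n), function(i) {
    select_features(X, y, cfg, train_idx = setdiff(seq_len(n), i))
  })
  imp_by_seed <- matrix(0, n_seeds, ncol(X),
                        dimnames = list(NULL, colnames(X)))
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s
    prob <- matrix(NA_real_, n, length(classes),
                   dimnames = list(NULL, classes))
    for (i in seq_len(n)) {
      train <- setdiff(seq_len(n), i)
      sel <- fold_sel[[i]]
      if (length(sel) == 0L) {       # nothing informative survived
        tab <- table(y[train])
        prob[i, ] <- as.numeric(tab[classes] / sum(tab))
        next
      }
      fit <- ranger::ranger(
        x = X[train, sel, drop = FALSE], y = y[train],
        num.trees = n_trees, probability = TRUE, importance = "impurity",
        seed = seed, num.threads = 1)
      prob[i, ] <- predict(fit, X[i, sel, drop = FALSE],
                           num.threads = 1)$predictions[1, classes]
      imp <- fit$variable.importance
      tot <- sum(imp)
      if (tot > 0) {
        imp_acc[sel] <- imp_acc[sel] + imp / tot
        imp_by_seed[s, sel] <- imp_by_seed[s, sel] + imp / tot
      }
      n_models <- n_models + 1L
    }
    imp_by_seed[s, ] <- imp_by_seed[s, ] / n
    auroc[s] <- .macro_auroc(y, prob)
    pred_list[[s]] <- prob
  }
  structure(list(auroc = auroc, mean_auroc = mean(auroc),
                 sd_auroc = sd(auroc),
                 importance = imp_acc / max(1L, n_models),
                 importance_by_seed = imp_by_seed,
                 predictions = pred_list, y = y,
                 n_seeds = n_seeds, n_trees = n_trees),
            class = "model_report")
}

# One-vs-rest macro-averaged AUROC over pooled predictions.
.macro_auroc <- function(y, prob) {
  classes <- colnames(prob)
  aucs <- vapply(classes, function(cl) {
    resp <- factor(ifelse(y == cl, "pos", "neg"), levels = c("neg", "pos"))
    if (length(unique(resp)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(resp, prob[, cl], quiet = TRUE,
                         direction = "<", levels = c("neg", "pos")))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Fixed-split random-forest regression
#'
#' Train/test split is fixed across seeds (default 70/30, stratified by
#' outcome quartile). Per seed, selection is fit on the training rows,
#' a random-forest regressor (500 trees) is trained, and MAE and the
#' Pearson correlation r between predictions and truth on the test set
#' are recorded (r tested two-sided, uncorrected). Constant predictions
#' give r = 0 with p = 1, flagged; MAE stays valid.
#'
#' @inheritParams cross_validate_classifier
#' @param y Continuous outcome.
#' @param split_frac Training fraction (default 0.7).
#' @param split_seed Seed that fixes the split.
#' @return A `model_report` with `mae`, `pearson_r`, `p_value` per seed
#'   plus aggregated means and the normalized importance vector.
#' @export
evaluate_regression <- function(X, y, cfg = selection_config(),
                                n_seeds = 10L, n_trees = 500L,
                                split_frac = 0.7, split_seed = 42L,
                                base_seed = 0L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  qs <- cut(y, breaks = unique(quantile(y, c(0, 0.25, 0.5, 0.75, 1))),
            include.lowest = TRUE)
  set.seed(split_seed)
  train <- sort(unlist(lapply(split(seq_len(n), qs), function(ix) {
    sample(ix, max(1L, round(split_frac * length(ix))))
  }), use.names = FALSE))
  test <- setdiff(seq_len(n), train)
  if (length(test) < 3L) stop("test split too small")
  mae <- numeric(n_seeds); r <- numeric(n_seeds); pv <- numeric(n_seeds)
  flagged <- logical(n_seeds)
  imp_acc <- setNames(rep(0, ncol(X)), colnames(X))
  sel <- select_features(X, y, cfg, train_idx = train)
  for (s in seq_len(n_seeds)) {
    if (length(sel) == 0L) {         # nothing informative survived
      pred <- rep(mean(y[train]), length(test))
    } else {
      fit <- ranger::ranger(x = X[train, sel, drop = FALSE], y = y[train],
                            num.trees = n_trees, importance = "impurity",
                            seed = base_seed + s, num.threads = 1)
      pred <- predict(fit, X[test, sel, drop = FALSE],
                      num.threads = 1)$predictions
    }
    mae[s] <- mean(abs(pred - y[test]))
    if (sd(pred) == 0 || sd(y[test]) == 0) {
      r[s] <- 0; pv[s] <- 1; flagged[s] <- TRUE
    } else {
      ct <- cor.test(pred, y[test])
      r[s] <- unname(ct$estimate); pv[s] <- ct$p.value
    }
    if (length(sel) > 0L) {
      imp <- fit$variable.importance
      if (sum(imp) > 0) imp_acc[sel] <- imp_acc[sel] + imp / sum(imp)
    }
  }
  structure(list(mae = mae, pearson_r = r, p_value = pv, flagged = flagged,
                 mean_mae = mean(mae), mean_r = mean(r),
                 importance = imp_acc / n_seeds,
                 train = train, test = test),
            class = "model_report")
}

#' Aggregate feature importances by parcel and feature family
#'
#' The importance of a group (parcel or family) is the sum of the
#' per-feature importances of its members, where the per-feature values
#' are already averaged over folds and seeds; unselected features
#' contribute 0. Parcel importances sum to <= 1 (to 1 when the grouping
#' covers every feature).
#'
#' @param report A `model_report`.
#' @param parcel_of Named vector/list mapping feature name -> parcel.
#' @param family_of Named vector mapping feature name -> family.
#' @return List with `parcel` and `family` named importance vectors.
#' @export
aggregate_importance <- function(report, parcel_of, family_of = NULL) {
  imp <- report$importance
  miss <- setdiff(names(imp), names(parcel_of))
  if (length(miss))
    stop("features missing from the parcel map: ", paste(head(miss), collapse = ", "))
  parcel <- tapply(imp, unlist(parcel_of[names(imp)]), sum)
  out <- list(parcel = parcel)
  if (!is.null(family_of)) {
    miss <- setdiff(names(imp), names(family_of))
    if (length(miss))
      stop("features missing from the family map: ",
           paste(head(miss), collapse = ", "))
    out$family <- tapply(imp, unlist(family_of[names(imp)]), sum)
  }
  out
}

#' Paired comparison of two methods' scores
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-seed scores,
#' Bonferroni-corrected for `n_comparisons`; the exact null
#' distribution is used for n <= 25, the normal approximation above.
#' The winner is the higher-mean method when the corrected p-value is
#' below `alpha`, otherwise "tie".
#'
#' @param scores_a,scores_b Equal-length paired score vectors (>= 5).
#' @param n_comparisons Bonferroni multiplier (default 1).
#' @param alpha Significance level after correction (default 0.05).
#' @return List with `p_raw`, `p_bonferroni`, `winner`.
#' @export
compare_methods <- function(scores_a, scores_b, n_comparisons = 1L,
                            alpha = 0.05) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 5L)
  d <- scores_a - scores_b
  if (all(d == 0)) {
    return(list(p_raw = 1, p_bonferroni = 1, winner = "tie"))
  }
  exact <- sum(d != 0) <= 25L
  p <- suppressWarnings(
    wilcox.test(scores_a, scores_b, paired = TRUE, exact = exact)$p.value)
  pb <- min(1, p * n_comparisons)
  winner <- if (pb < alpha) {
    if (mean(scores_a) > mean(scores_b)) "A" else "B"
  } else "tie"
  list(p_raw = p, p_bonferroni = pb, winner = winner)
}
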
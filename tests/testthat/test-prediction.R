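# Selection pipeline, cross-validated forests, importance aggregation,
# and the paired method comparison.

test_that("selection drops constants and duplicates, then caps at k", {
  set.seed(1)
  X <- matrix(rnorm(40 * 30), 40, 30, dimnames = list(NULL, paste0("f", 1:30)))
  X[, 5] <- 2; X[, 9] <- 0                       # constants
  X <- cbind(X, dup = X[, 1])                    # r = 1 duplicate
  y <- rep(c("A", "B"), 20)
  sel <- select_features(X, y, selection_config(k_select = 100))
  expect_false(any(c("f5", "f9") %in% sel))
  expect_equal(sum(c("f1", "dup") %in% sel), 1L)
  expect_equal(sel[sel %in% c("f1", "dup")], "f1")  # earlier column kept
  # cap at k_select
  sel2 <- select_features(X, y, selection_config(k_select = 10))
  expect_length(sel2, 10L)
  expect_error(select_features(X[0, ], y[0]), "no rows")
})

test_that("selection ranks by univariate signal", {
  set.seed(2)
  y <- rep(c(0, 1), each = 25)
  X <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(NULL, paste0("f", 1:20)))
  X[, 7] <- X[, 7] + 3 * y                      # strong signal
  sel <- select_features(X, factor(y), selection_config(k_select = 1))
  expect_equal(sel, "f7")
  # regression scoring
  yr <- rnorm(50)
  X[, 3] <- yr + rnorm(50, sd = 0.1)
  selr <- select_features(X, yr, selection_config(k_select = 1))
  expect_equal(selr, "f3")
})

test_that("selection statistics never see held-out rows", {
  # a leakage probe: a feature equal to y on the held-out row only is
  # useless when selection+fit are confined to training rows
  set.seed(3)
  n <- 20
  y <- factor(rep(c("A", "B"), n / 2))
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  for (i in 1:4) {
    train <- setdiff(1:n, i)
    sel <- select_features(X, y, selection_config(k_select = 3),
                           train_idx = train)
    Xmod <- X
    Xmod[i, ] <- 999                            # poison the held-out row
    sel2 <- select_features(Xmod, y, selection_config(k_select = 3),
                            train_idx = train)
    expect_identical(sel, sel2)
  }
})

test_that("cross-validated forest separates well-separated classes", {
  set.seed(4)
  n <- 20
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("f", 1:50)))
  X[y == "B", 1:5] <- X[y == "B", 1:5] + 4      # effect >> noise
  rep_ <- cross_validate_classifier(X, y, selection_config(k_select = 20),
                                    n_seeds = 3, n_trees = 100)
  expect_gte(rep_$mean_auroc, 0.95)
  expect_equal(nrow(rep_$predictions[[1]]), n)  # LOO accounting
  expect_true(all(!is.na(rep_$predictions[[1]])))
  # importance sums to <= 1 and concentrates on the informative block
  expect_lte(sum(rep_$importance), 1 + 1e-8)
  expect_gt(sum(rep_$importance[1:5]), 0.5)
  expect_error(cross_validate_classifier(X, rep("A", n)), "2 classes")
})

test_that("permuted labels never score above chance", {
  # pooled leave-one-out probabilities are pessimistic under the null
  # (the held-out subject's class is underrepresented in training), so
  # the null AUROC sits at or below 0.5; the upper bound is the
  # leakage guard
  set.seed(5)
  n <- 50
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- sample(rep(c("A", "B"), each = n / 2))
  rep_ <- cross_validate_classifier(X, y, selection_config(k_select = 10),
                                    n_seeds = 5, n_trees = 100)
  expect_gte(rep_$mean_auroc, 0.25)
  expect_lte(rep_$mean_auroc, 0.65)
})

test_that("regression reports MAE and Pearson r with flags", {
  set.seed(6)
  n <- 40
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- 2 * X[, 1] + rnorm(n, sd = 1)            # strong linear signal
  rep_ <- evaluate_regression(X, y, selection_config(k_select = 10),
                              n_seeds = 3, n_trees = 200)
  expect_gte(rep_$mean_r, 0.5)
  expect_true(all(rep_$p_value <= 1))
  expect_true(length(rep_$test) >= 3)
  expect_true(all(!rep_$flagged))
})

test_that("hand-computed regression metrics: MAE 2/3 and degenerate r", {
  # truth {1,2,3}, predictions {2,2,2}
  truth <- c(1, 2, 3); pred <- c(2, 2, 2)
  expect_equal(mean(abs(pred - truth)), 2 / 3)
  # the flagged path: constant predictions give r = 0, p = 1
  set.seed(7)
  X <- matrix(1, 12, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rnorm(12)
  rep_ <- evaluate_regression(X, y, selection_config(k_select = 3),
                              n_seeds = 1, n_trees = 50)
  expect_true(all(rep_$flagged))
  expect_equal(rep_$pearson_r, 0)
  expect_equal(rep_$p_value, 1)
  expect_gt(rep_$mean_mae, 0)
})

test_that("importance aggregation sums groups and flags unmapped features", {
  rep_ <- structure(list(importance = c(a1 = 0.2, a2 = 0.3, b1 = 0.5)),
                    class = "model_report")
  pm <- c(a1 = "p1", a2 = "p1", b1 = "p2")
  fm <- c(a1 = "glcm", a2 = "shape", b1 = "glcm")
  agg <- aggregate_importance(rep_, pm, fm)
  expect_equal(unname(agg$parcel["p1"]), 0.5)
  expect_equal(unname(agg$parcel["p2"]), 0.5)
  expect_equal(sum(agg$parcel), 1)
  expect_equal(unname(agg$family["glcm"]), 0.7)
  expect_error(aggregate_importance(rep_, pm[-1]), "missing")
  # all features in one parcel -> importance 1
  agg1 <- aggregate_importance(rep_, c(a1 = "p", a2 = "p", b1 = "p"))
  expect_equal(as.numeric(agg1$parcel), 1)
})

test_that("duplicated feature blocks share importance symmetrically", {
  set.seed(8)
  n <- 30
  y <- rep(c("A", "B"), each = n / 2)
  base <- matrix(rnorm(n * 5), n, 5)
  base[y == "B", ] <- base[y == "B", ] + 2
  X <- cbind(base, base + matrix(rnorm(n * 5, sd = 0.05), n, 5))
  colnames(X) <- c(paste0("p1_f", 1:5), paste0("p2_f", 1:5))
  rep_ <- cross_validate_classifier(X, y, selection_config(
    correlation_threshold = 1, k_select = 10), n_seeds = 3, n_trees = 200)
  agg <- aggregate_importance(rep_, setNames(rep(c("p1", "p2"), each = 5),
                                             colnames(X)))
  expect_lt(abs(agg$parcel["p1"] - agg$parcel["p2"]), 0.1)
})

test_that("paired comparison: exact signed-rank, Bonferroni cap, ties", {
  set.seed(9)
  b <- rnorm(10)
  a <- b + (1:10) / 10                          # distinct positive shifts
  r <- compare_methods(a, b)
  expect_equal(r$winner, "A")
  expect_lt(r$p_bonferroni, 0.05)
  expect_equal(r$p_raw, 2 / 2^10)               # exact null, maximal W
  expect_equal(compare_methods(rep(1, 5), rep(1, 5)),
               list(p_raw = 1, p_bonferroni = 1, winner = "tie"))
  r2 <- compare_methods(a, b, n_comparisons = 46)
  expect_equal(r2$p_bonferroni, min(1, r2$p_raw * 46))
  # p_raw 0.03-like case capped at 1
  set.seed(9)
  a <- rnorm(12); b <- a + rnorm(12, 0.3)
  r3 <- compare_methods(a, b, n_comparisons = 1000)
  expect_lte(r3$p_bonferroni, 1)
  expect_error(compare_methods(1:3, 1:3), ">= 5")
})
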
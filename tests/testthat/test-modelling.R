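make_planted_table <- function(n = 40, p = 10, seed = 1, noise = 0,
                               coefs = c(f3 = 2, f7 = -1)) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- as.numeric(X[, names(coefs), drop = FALSE] %*% coefs) +
      rnorm(n, sd = noise)
    dplyr::bind_cols(tibble::tibble(ligand_id = sprintf("L%02d", 1:n), y = y),
                     tibble::as_tibble(X))
  })
}

test_that("regression metrics match the hand-computed example and the oracle", {
  m <- regression_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, -0.5)   # SSE = 3, SST = 2

  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect), c(r2 = 1, mae = 0, rmse = 0))

  withr::with_seed(3, {
    for (i in 1:10) {
      y <- rnorm(20); yhat <- rnorm(20)
      m <- regression_metrics(y, yhat)
      o <- oracle_metrics(y, yhat)
      expect_lt(abs(m$r2 - o["r2"]), 1e-12)
      expect_lt(abs(m$mae - o["mae"]), 1e-12)
      expect_lt(abs(m$rmse - o["rmse"]), 1e-12)
      expect_lte(m$mae, m$rmse)
    }
  })
  expect_warning(m0 <- regression_metrics(c(2, 2), c(1, 3)), "Zero variance")
  expect_true(is.na(m0$r2))
})

test_that("forward stepwise recovers a noiseless planted linear model", {
  tbl <- make_planted_table(n = 40, seed = 12)
  ids <- tbl$ligand_id
  rep <- forward_stepwise_mlr(tbl, train_ids = ids[1:25],
                              test_ids = ids[26:40], n_terms = 2)
  expect_setequal(rep$features, c("f3", "f7"))
  tr <- dplyr::filter(rep$metrics, split == "train")
  expect_lt(abs(tr$r2 - 1), 1e-10)
  te <- dplyr::filter(rep$metrics, split == "test")
  expect_lt(abs(te$r2 - 1), 1e-10)
})

test_that("an intercept-only stepwise model has zero training R^2", {
  tbl <- make_planted_table(n = 20, seed = 4, noise = 0.5)
  ids <- tbl$ligand_id
  rep <- forward_stepwise_mlr(tbl, ids[1:15], ids[16:20], n_terms = 0)
  expect_length(rep$features, 0)
  expect_equal(dplyr::filter(rep$metrics, split == "train")$r2, 0)
  # training R^2 never decreases as terms are added
  r2s <- vapply(0:3, function(k) {
    r <- forward_stepwise_mlr(tbl, ids[1:15], ids[16:20], n_terms = k)
    dplyr::filter(r$metrics, split == "train")$r2
  }, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
})

test_that("stepwise training R^2 never beats the exhaustive best subset", {
  tbl <- make_planted_table(n = 30, p = 10, seed = 9, noise = 1,
                            coefs = c(f1 = 1, f2 = 0.8, f5 = -0.6))
  ids <- tbl$ligand_id
  tr_ids <- ids[1:22]
  rep <- forward_stepwise_mlr(tbl, tr_ids, ids[23:30], n_terms = 3)
  step_r2 <- dplyr::filter(rep$metrics, split == "train")$r2

  tr <- dplyr::filter(tbl, ligand_id %in% tr_ids)
  best <- -Inf
  for (combo in utils::combn(paste0("f", 1:10), 3, simplify = FALSE)) {
    fit <- lm(stats::reformulate(combo, "y"), data = tr)
    best <- max(best, summary(fit)$r.squared)
  }
  expect_lte(step_r2, best + 1e-10)
})

test_that("collinear candidates are skipped, not fitted", {
  tbl <- make_planted_table(n = 20, seed = 6, coefs = c(f1 = 2))
  tbl$f2 <- tbl$f1                      # exact duplicate
  ids <- tbl$ligand_id
  expect_message(
    rep <- forward_stepwise_mlr(tbl, ids[1:15], ids[16:20], n_terms = 2),
    "collinear")
  expect_false(all(c("f1", "f2") %in% rep$features))
})

test_that("disjointness and size preconditions are enforced", {
  tbl <- make_planted_table(n = 12, seed = 2)
  ids <- tbl$ligand_id
  expect_error(forward_stepwise_mlr(tbl, ids[1:6], ids[5:12]), "disjoint")
  expect_error(forward_stepwise_mlr(tbl, ids[1:4], ids[5:12], n_terms = 3),
               "n_terms")
})

test_that("a depth-2 tree recovers a noiseless piecewise-constant response", {
  withr::with_seed(15, {
    n <- 60
    x <- sample(c(1, 5, 9), n, replace = TRUE)
    y <- ifelse(x < 3, 1, ifelse(x < 7, 5, 2))
    tbl <- tibble::tibble(ligand_id = sprintf("L%02d", 1:n), y = y,
                          f_split = x, f_noise = rnorm(n))
  })
  ids <- tbl$ligand_id
  rep <- fit_tree(tbl, ids[1:45], ids[46:60], max_depth = 2, min_leaf = 1)
  expect_equal(dplyr::filter(rep$metrics, split == "test")$r2, 1)
  expect_true(all(rep$tree$var[!rep$tree$is_leaf] == "f_split"))
})

test_that("depth zero and constant responses give single-leaf trees", {
  tbl <- make_planted_table(n = 15, seed = 8, noise = 0.3)
  ids <- tbl$ligand_id
  rep <- fit_tree(tbl, ids[1:10], ids[11:15], max_depth = 0)
  expect_equal(nrow(rep$tree), 1)
  expect_true(rep$tree$is_leaf)
  mean_tr <- mean(tbl$y[1:10])
  expect_true(all(abs(dplyr::filter(rep$predictions, split == "test")$predicted -
                        mean_tr) < 1e-12))

  flat <- dplyr::mutate(tbl, y = 7)
  # constant response: R^2 undefined on both splits, flagged on the way out
  w <- capture_warnings(
    repf <- fit_tree(flat, ids[1:10], ids[11:15], max_depth = 4))
  expect_match(w, "Zero variance", all = TRUE)
  expect_equal(nrow(repf$tree), 1)
  expect_equal(repf$predictions$predicted, rep(7, 15))
})

test_that("tree fitting is deterministic and overfits in the expected direction", {
  tbl <- make_planted_table(n = 42, seed = 19, noise = 1,
                            coefs = c(f1 = 1.5))
  ids <- tbl$ligand_id
  r1 <- fit_tree(tbl, ids[1:33], ids[34:42], max_depth = 4, min_leaf = 1)
  r2 <- fit_tree(tbl, ids[1:33], ids[34:42], max_depth = 4, min_leaf = 1)
  expect_identical(r1$predictions$predicted, r2$predictions$predicted)

  # deep trees on noisy data: train error below test error in most splits
  wins <- 0
  for (s in 1:9) {
    perm <- withr::with_seed(100 + s, sample(42))
    r <- fit_tree(tbl, ids[perm[1:33]], ids[perm[34:42]],
                  max_depth = 5, min_leaf = 1)
    m <- r$metrics
    if (m$mae[m$split == "train"] <= m$mae[m$split == "test"])
      wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("permutation importance isolates the features a model uses", {
  withr::with_seed(23, {
    n <- 40
    tbl <- tibble::tibble(
      ligand_id = sprintf("L%02d", 1:n),
      f_used = runif(n, 0, 10),
      f_unused = rnorm(n)
    )
    tbl$y <- ifelse(tbl$f_used < 5, 0, 4)
  })
  ids <- tbl$ligand_id
  rep <- fit_tree(tbl, ids[1:30], ids[31:40], max_depth = 2, min_leaf = 1)
  imp <- permutation_importance(rep, tbl[31:40, c("f_used", "f_unused")],
                                tbl$y[31:40], n_repeats = 20, seed = 2)
  expect_equal(imp$feature[1], "f_used")
  expect_lt(abs(imp$importance[imp$feature == "f_unused"]), 1e-10)
  expect_gt(imp$importance[imp$feature == "f_used"], 0.5)
  expect_equal(reduce_by_importance(imp, k = 1), "f_used")
})

test_that("permutation importance is stable across seeds at high repeat counts", {
  tbl <- make_planted_table(n = 50, seed = 33, noise = 0.4,
                            coefs = c(f2 = 2, f6 = 1))
  ids <- tbl$ligand_id
  rep <- fit_tree(tbl, ids[1:38], ids[39:50], max_depth = 3, min_leaf = 2)
  xt <- tbl[39:50, paste0("f", 1:10)]
  i1 <- permutation_importance(rep, xt, tbl$y[39:50], n_repeats = 100,
                               seed = 1)
  i2 <- permutation_importance(rep, xt, tbl$y[39:50], n_repeats = 100,
                               seed = 999)
  j <- dplyr::inner_join(i1, i2, by = "feature")
  mc_tol <- 3 * pmax(j$sd.x, j$sd.y) / sqrt(100) + 1e-9
  expect_true(all(abs(j$importance.x - j$importance.y) < mc_tol))
})

test_that("single-row test sets are flagged as unreliable", {
  tbl <- make_planted_table(n = 12, seed = 3, coefs = c(f1 = 1))
  ids <- tbl$ligand_id
  rep <- fit_tree(tbl, ids[1:11], ids[12], max_depth = 2, min_leaf = 1)
  expect_warning(
    permutation_importance(rep, tbl[12, paste0("f", 1:10)], tbl$y[12],
                           n_repeats = 3),
    "unreliable")
})

test_that("leave-one-out recovers a noiseless one-term model exactly", {
  tbl <- make_planted_table(n = 15, p = 4, seed = 41, coefs = c(f1 = 1))
  cv <- cross_validate(tbl, model_spec("mlr", n_terms = 1),
                       cv_scheme("loo"))
  expect_equal(cv$metrics$r2, 1, tolerance = 1e-8)
  expect_equal(nrow(cv$predictions), 15)
})

test_that("five-fold partitions of 42 rows are sized 9,9,8,8,8", {
  tbl <- make_planted_table(n = 42, seed = 52, noise = 0.5,
                            coefs = c(f1 = 1))
  cv <- cross_validate(tbl, model_spec("tree", max_depth = 2, min_leaf = 2),
                       cv_scheme("kfold", k = 5), seed = 3)
  expect_equal(sort(cv$metrics$n_test, decreasing = TRUE), c(9, 9, 8, 8, 8))
  expect_equal(nrow(cv$metrics), 5)
  expect_named(cv$summary, c("r2", "mae", "rmse"))
  expect_error(cross_validate(tbl[1:3, ], model_spec("tree"),
                              cv_scheme("kfold", k = 5)), "folds")
})

test_that("repeated random starts give reproducible average errors", {
  tbl <- make_planted_table(n = 42, seed = 61, noise = 0.5,
                            coefs = c(f2 = 1.2))
  spec <- model_spec("tree", max_depth = 3, min_leaf = 2)
  a <- cross_validate(tbl, spec, cv_scheme("random_starts", n = 30,
                                           ratio = 9 / 42), seed = 7)
  b <- cross_validate(tbl, spec, cv_scheme("random_starts", n = 30,
                                           ratio = 9 / 42), seed = 7)
  expect_identical(a$summary$mean_test_mae, b$summary$mean_test_mae)
  # independent runs agree within Monte Carlo error
  c2 <- cross_validate(tbl, spec, cv_scheme("random_starts", n = 30,
                                            ratio = 9 / 42), seed = 7001)
  se <- sqrt(a$summary$sd_test_mae^2 / 30 + c2$summary$sd_test_mae^2 / 30)
  expect_lt(abs(a$summary$mean_test_mae - c2$summary$mean_test_mae), 3 * se)
})

test_that("the ratio sweep covers 0.1 to 0.5 in steps of 0.1", {
  tbl <- make_planted_table(n = 30, seed = 71, noise = 0.4,
                            coefs = c(f1 = 1))
  cv <- cross_validate(tbl, model_spec("tree", max_depth = 2, min_leaf = 2),
                       cv_scheme("ratio_sweep", n = 5), seed = 2)
  expect_equal(cv$metrics$ratio, seq(0.1, 0.5, by = 0.1))
  expect_equal(cv$metrics$n_test, c(3, 6, 9, 12, 15))
  expect_true(is.finite(cv$summary$overall_mean_test_mae))
})

test_that("error distributions are sorted, partitioned and quantile-consistent", {
  tbl <- make_planted_table(n = 24, seed = 81, noise = 0.6,
                            coefs = c(f1 = 1, f4 = -0.5))
  ids <- tbl$ligand_id
  rep <- forward_stepwise_mlr(tbl, ids[1:16], ids[17:24], n_terms = 2)
  ed <- error_distribution(rep)
  expect_setequal(ed$ligand_id, ids)
  expect_setequal(ed$ligand_id[ed$split == "train"], ids[1:16])
  for (s in c("train", "test"))
    expect_false(is.unsorted(ed$abs_error[ed$split == s]))
  q <- error_quantiles(rep, probs = c(0.25, 0.5, 0.75))
  test_err <- sort(ed$abs_error[ed$split == "test"])
  expect_equal(q$q50[q$split == "test"],
               unname(quantile(test_err, 0.5)))

  # perfect predictions give an all-zero distribution
  noiseless <- make_planted_table(n = 20, seed = 82, coefs = c(f1 = 1))
  rp <- forward_stepwise_mlr(noiseless, noiseless$ligand_id[1:14],
                             noiseless$ligand_id[15:20], n_terms = 1)
  expect_lt(max(error_distribution(rp)$abs_error), 1e-10)
})

test_that("tidy, glance and predict expose the model report contents", {
  tbl <- make_planted_table(n = 25, seed = 91, noise = 0.2,
                            coefs = c(f1 = 2))
  ids <- tbl$ligand_id
  rep <- forward_stepwise_mlr(tbl, ids[1:18], ids[19:25], n_terms = 1)
  td <- tidy(rep)
  expect_true("f1" %in% td$term)
  gl <- glance(rep)
  expect_true(all(c("train_r2", "test_mae", "test_rmse") %in% names(gl)))
  expect_equal(predict(rep, tbl[19:25, ]),
               dplyr::filter(rep$predictions, split == "test")$predicted,
               tolerance = 1e-12)
  expect_true(all(rep$metrics$mae <= rep$metrics$rmse + 1e-12))
})
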
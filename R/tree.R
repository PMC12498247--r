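#' Decision-tree regression on a ligand feature table
#'
#' CART-style regression tree (variance-reduction splits, via rpart with
#' complexity pruning disabled) fitted on the training split, evaluated on
#' train and test.  `max_depth = 0` gives a single leaf predicting the
#' training mean, as does a degenerate (constant-response) training set.
#'
#' @inheritParams forward_stepwise_mlr
#' @param max_depth Maximum tree depth (0 = single leaf).
#' @param min_leaf Minimum observations per leaf.
#' @param features Optional subset of feature columns to use.
#' @param seed Recorded on the report (tree fitting itself is
#'   deterministic).
#' @return A `model_report` with the serialized tree structure in `$tree`
#'   (`node`, `var`, `threshold`, `n`, `value`, `is_leaf`).
#' @export
fit_tree <- function(data, train_ids, test_ids, response = "y",
                     id_col = "ligand_id", max_depth = 3, min_leaf = 2,
                     features = NULL, seed = 1L) {
  ft <- check_feature_table(data, response, id_col)
  data <- ft$data
  feats <- features %||% ft$features
  missing_f <- setdiff(feats, ft$features)
  if (length(missing_f) > 0)
    abort(paste0("Unknown feature column(s): ", paste(missing_f, collapse = ", ")))
  if (length(intersect(train_ids, test_ids)) > 0)
    abort("Train and test ids must be disjoint.")
  tr <- match(train_ids, data[[id_col]])
  te <- match(test_ids, data[[id_col]])
  if (anyNA(tr) || anyNA(te)) abort("Some ids are not present in `data`.")
  if (length(tr) < 1) abort("Training split is empty.")

  y_tr <- data[[response]][tr]
  single_leaf <- max_depth < 1 || sd(y_tr) == 0 || length(tr) < 2
  if (single_leaf) {
    fit <- NULL
    leaf_value <- mean(y_tr)
    tree_tbl <- tibble(node = 1L, var = NA_character_,
                       threshold = NA_real_, n = length(tr),
                       value = leaf_value, is_leaf = TRUE)
    pred_fn <- function(nd) rep(leaf_value, nrow(nd))
  } else {
    df_tr <- data.frame(y = y_tr, data[tr, feats, drop = FALSE],
                        check.names = FALSE)
    fit <- rpart::rpart(
      y ~ ., data = df_tr, method = "anova",
      control = rpart::rpart.control(
        maxdepth = max_depth, minbucket = min_leaf,
        minsplit = max(2L, 2L * min_leaf), cp = 0, xval = 0,
        maxsurrogate = 0, maxcompete = 0
      )
    )
    tree_tbl <- tree_structure(fit)
    pred_fn <- function(nd) unname(predict(fit, newdata = nd))
  }
  preds <- dplyr::bind_rows(
    tibble(ligand_id = data[[id_col]][tr], split = "train",
           observed = y_tr,
           predicted = pred_fn(data[tr, feats, drop = FALSE])),
    if (length(te) > 0)
      tibble(ligand_id = data[[id_col]][te], split = "test",
             observed = data[[response]][te],
             predicted = pred_fn(data[te, feats, drop = FALSE]))
  )
  preds$abs_error <- abs(preds$observed - preds$predicted)
  used <- if (is.null(fit)) character() else
    unique(as.character(tree_tbl$var[!tree_tbl$is_leaf]))
  new_model_report(kind = "tree", features = feats, tree = tree_tbl,
                   fit = fit, predictions = preds, seed = as.integer(seed))
}

# serialize an rpart frame as (node, var, threshold, n, value, is_leaf)
tree_structure <- function(fit) {
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  thr <- rep(NA_real_, nrow(fr))
  if (!is.null(fit$splits)) {
    # primary split rows appear in frame order, one block per internal node
    row <- 0L
    for (i in seq_len(nrow(fr))) {
      if (fr$var[i] == "<leaf>") next
      thr[i] <- fit$splits[row + 1L, "index"]
      row <- row + 1L + fr$ncompete[i] + fr$nsurrogate[i]
    }
  }
  tibble(
    node = nodes,
    var = ifelse(fr$var == "<leaf>", NA_character_, as.character(fr$var)),
    threshold = thr,
    n = fr$n,
    value = fr$yval,
    is_leaf = fr$var == "<leaf>"
  )
}

#' Predict from a fitted model report
#'
#' @param object A `model_report` from [forward_stepwise_mlr()] or
#'   [fit_tree()].
#' @param newdata Data frame holding the model's feature columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.model_report <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$kind == "stepwise_mlr") {
    if (length(object$features) == 0)
      return(rep(unname(coef(object$fit)[1]), nrow(newdata)))
    Z <- vapply(object$features, function(f)
      (newdata[[f]] - object$scaling$mean[f]) / object$scaling$sd[f],
      numeric(nrow(newdata)))
    nd <- data.frame(matrix(Z, nrow = nrow(newdata),
                            dimnames = list(NULL, object$features)),
                     check.names = FALSE)
    unname(predict(object$fit, newdata = nd))
  } else if (object$kind == "tree") {
    if (is.null(object$fit))
      return(rep(object$tree$value[1], nrow(newdata)))
    unname(predict(object$fit, newdata = newdata))
  } else {
    abort(paste0("Cannot predict from model kind ", dQuote(object$kind), "."))
  }
}

#' Permutation feature importance
#'
#' Increase in test-set RMSE when one feature column is randomly shuffled,
#' averaged over `n_repeats` seeded permutations.  Features a model ignores
#' score (near) zero.
#'
#' @param model A `model_report` (or any object with a `predict` method
#'   taking `newdata`).
#' @param x_test Data frame of test-set features.
#' @param y_test Test-set response.
#' @param n_repeats Number of permutations per feature.
#' @param seed RNG seed for the permutations.
#' @param features Columns to assess (default: all columns of `x_test`).
#' @return Tibble `feature`, `importance` (mean RMSE increase), `sd`, sorted
#'   by decreasing importance.  A single-row test set is flagged with a
#'   warning.
#' @export
permutation_importance <- function(model, x_test, y_test, n_repeats = 30,
                                   seed = 1L, features = NULL) {
  if (n_repeats < 1) abort("`n_repeats` must be at least 1.")
  x_test <- as.data.frame(x_test)
  if (nrow(x_test) != length(y_test))
    abort("`x_test` and `y_test` must be aligned.")
  if (nrow(x_test) == 1)
    warn("Single-row test set; permutation importance is unreliable.")
  features <- features %||% names(x_test)
  baseline <- regression_metrics(y_test, predict(model, x_test))$rmse
  with_private_seed(seed, {
    purrr::map_dfr(features, function(f) {
      deltas <- vapply(seq_len(n_repeats), function(r) {
        xp <- x_test
        xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
        regression_metrics(y_test, predict(model, xp))$rmse - baseline
      }, numeric(1))
      tibble(feature = f, importance = mean(deltas),
             sd = if (n_repeats > 1) sd(deltas) else NA_real_)
    })
  }) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Keep the top-k features by permutation importance
#'
#' @param importance Tibble from [permutation_importance()].
#' @param k Number of features to retain (default 4).
#' @return Character vector of feature names.
#' @export
reduce_by_importance <- function(importance, k = 4) {
  stopifnot(all(c("feature", "importance") %in% names(importance)))
  imp <- dplyr::arrange(importance, dplyr::desc(.data$importance))
  head(imp$feature, k)
}

#' Model specification for cross-validation
#'
#' @param kind `"mlr"` (forward stepwise) or `"tree"`.
#' @param ... Hyperparameters: `n_terms`/`scorer` for `"mlr"`;
#'   `max_depth`/`min_leaf`/`features` for `"tree"`.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(kind = c("mlr", "tree"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...)), class = "model_spec")
}

fit_spec <- function(spec, data, train_ids, test_ids, response, id_col,
                     seed = 1L) {
  if (spec$kind == "mlr") {
    do.call(forward_stepwise_mlr,
            c(list(data = data, train_ids = train_ids, test_ids = test_ids,
                   response = response, id_col = id_col), spec$params))
  } else {
    do.call(fit_tree,
            c(list(data = data, train_ids = train_ids, test_ids = test_ids,
                   response = response, id_col = id_col, seed = seed),
              spec$params))
  }
}

#' Cross-validation scheme
#'
#' @param type One of `"loo"`, `"kfold"`, `"random_starts"`, `"ratio_sweep"`.
#' @param k Folds for `"kfold"` (default 5).
#' @param n Number of random splits (`"random_starts"`, default 100; per
#'   ratio in `"ratio_sweep"`, default 20).
#' @param ratio Test fraction for `"random_starts"`.
#' @param ratios Test fractions for `"ratio_sweep"`.
#' @return List of class `cv_scheme`.
#' @export
cv_scheme <- function(type = c("loo", "kfold", "random_starts", "ratio_sweep"),
                      k = 5, n = NULL, ratio = 0.2,
                      ratios = seq(0.1, 0.5, by = 0.1)) {
  type <- match.arg(type)
  n <- n %||% if (type == "random_starts") 100L else 20L
  structure(list(type = type, k = k, n = n, ratio = ratio, ratios = ratios),
            class = "cv_scheme")
}

#' Cross-validate a model specification
#'
#' Supports leave-one-out (pooled predictions scored once), k-fold (per-fold
#' metrics plus their average), repeated random train/test splits at a fixed
#' ratio (average test MAE over starts), and a sweep of the test-set ratio.
#' Any feature selection inside the specification (the stepwise search) is
#' redone within every training split.
#'
#' @param data Feature table (id, response, features).
#' @param spec A [model_spec()].
#' @param scheme A [cv_scheme()].
#' @inheritParams forward_stepwise_mlr
#' @param seed Seed for fold assignment / split generation.
#' @return List of class `cv_result`; contents depend on the scheme:
#'   `metrics` (tibble) plus `summary` (one-row tibble).
#' @export
cross_validate <- function(data, spec, scheme, response = "y",
                           id_col = "ligand_id", seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(scheme, "cv_scheme"))
  ft <- check_feature_table(data, response, id_col)
  data <- ft$data
  ids <- data[[id_col]]
  nn <- length(ids)

  test_metrics <- function(train_ids, test_ids, fit_seed = seed) {
    rep <- fit_spec(spec, data, train_ids, test_ids, response, id_col,
                    seed = fit_seed)
    dplyr::filter(rep$metrics, .data$split == "test")
  }

  if (scheme$type == "loo") {
    preds <- purrr::map_dfr(seq_len(nn), function(i) {
      rep <- fit_spec(spec, data, ids[-i], ids[i], response, id_col,
                      seed = seed)
      dplyr::filter(rep$predictions, .data$split == "test")
    })
    met <- regression_metrics(preds$observed, preds$predicted)
    out <- list(type = "loo", predictions = preds, metrics = met,
                summary = met)
  } else if (scheme$type == "kfold") {
    k <- scheme$k
    if (k > nn) abort("More folds than observations.")
    fold_sizes <- rep(nn %/% k, k) + (seq_len(k) <= nn %% k)
    perm <- with_private_seed(seed, sample.int(nn))
    assign <- rep(seq_len(k), times = fold_sizes)
    folds <- split(perm, assign)
    met <- purrr::imap_dfr(folds, function(idx, fold) {
      m <- test_metrics(ids[-idx], ids[idx])
      dplyr::mutate(m, fold = as.integer(fold), n_test = length(idx),
                    .before = 1)
    })
    summary <- met |>
      dplyr::summarise(r2 = mean(.data$r2), mae = mean(.data$mae),
                       rmse = mean(.data$rmse))
    out <- list(type = "kfold", k = k, metrics = met, summary = summary)
  } else if (scheme$type == "random_starts") {
    n_test <- max(1L, round(scheme$ratio * nn))
    met <- purrr::map_dfr(seq_len(scheme$n), function(s) {
      te <- with_private_seed(seed + s, sample.int(nn, n_test))
      m <- test_metrics(ids[-te], ids[te], fit_seed = seed + s)
      dplyr::mutate(m, start = s, .before = 1)
    })
    summary <- tibble(
      n_starts = scheme$n, ratio = scheme$ratio,
      mean_test_mae = mean(met$mae), sd_test_mae = sd(met$mae),
      mean_test_rmse = mean(met$rmse)
    )
    out <- list(type = "random_starts", metrics = met, summary = summary)
  } else {
    per_ratio <- purrr::map_dfr(scheme$ratios, function(rt) {
      n_test <- max(1L, round(rt * nn))
      if (n_test >= nn) abort("Ratio leaves an empty training set.")
      maes <- vapply(seq_len(scheme$n), function(s) {
        te <- with_private_seed(seed + round(1000 * rt) + s,
                                sample.int(nn, n_test))
        test_metrics(ids[-te], ids[te], fit_seed = seed + s)$mae
      }, numeric(1))
      tibble(ratio = rt, n_test = n_test, mean_test_mae = mean(maes),
             sd_test_mae = sd(maes))
    })
    summary <- tibble(overall_mean_test_mae = mean(per_ratio$mean_test_mae))
    out <- list(type = "ratio_sweep", metrics = per_ratio, summary = summary)
  }
  structure(out, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$type, "\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tune tree hyperparameters by k-fold cross-validated MAE
#'
#' Grid search over `max_depth` and `min_leaf`, scored by k-fold CV MAE on
#' the training ids only.
#'
#' @inheritParams forward_stepwise_mlr
#' @param grid Data frame with columns `max_depth` and `min_leaf`.
#' @param k Folds.
#' @param features Optional feature subset.
#' @param seed Seed for fold assignment.
#' @return List: `best` (one-row tibble), `grid` (all results).
#' @export
tune_tree <- function(data, train_ids, response = "y",
                      id_col = "ligand_id",
                      grid = expand.grid(max_depth = 2:5,
                                         min_leaf = c(1, 2, 3, 5)),
                      k = 5, features = NULL, seed = 1L) {
  sub <- dplyr::filter(tibble::as_tibble(data),
                       .data[[id_col]] %in% train_ids)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    spec <- model_spec("tree", max_depth = grid$max_depth[i],
                       min_leaf = grid$min_leaf[i], features = features)
    cv <- cross_validate(sub, spec, cv_scheme("kfold", k = k),
                         response = response, id_col = id_col, seed = seed)
    tibble(max_depth = grid$max_depth[i], min_leaf = grid$min_leaf[i],
           cv_mae = cv$summary$mae)
  })
  best <- res[order(res$cv_mae, res$max_depth, res$min_leaf), ][1, ]
  list(best = best, grid = res)
}
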
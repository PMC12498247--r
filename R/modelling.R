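#' Regression quality metrics
#'
#' R squared (1 - SSE/SST about the mean of `y`), mean absolute error, and
#' root mean squared error.  R squared is `NA` (with a warning) when `y` has
#' zero variance.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Tibble with columns `r2`, `mae`, `rmse`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(2, 3, 4))
regression_metrics <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 1)
    abort("`y` and `yhat` must be equal-length and non-empty.")
  res <- y - yhat
  mae <- mean(abs(res))
  rmse <- sqrt(mean(res^2))
  sst <- sum((y - mean(y))^2)
  if (length(y) < 2 || sst == 0) {
    if (sst == 0 && length(y) >= 2)
      warn("Zero variance in `y`; R squared is undefined.")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum(res^2) / sst
  }
  tibble(r2 = r2, mae = mae, rmse = rmse)
}

check_feature_table <- function(data, response, id_col) {
  data <- tibble::as_tibble(data)
  if (!id_col %in% names(data)) abort(paste0("No id column ", dQuote(id_col), "."))
  if (!response %in% names(data)) abort(paste0("No response column ", dQuote(response), "."))
  feats <- setdiff(names(data), c(id_col, response))
  feats <- feats[vapply(data[feats], is.numeric, logical(1))]
  if (anyNA(data[c(response, feats)]))
    abort("Feature table contains missing values; complete it before modelling.")
  list(data = data, features = feats)
}

new_model_report <- function(kind, features, coefficients = NULL,
                             tree = NULL, fit = NULL, scaling = NULL,
                             predictions, seed = NA_integer_, cv = NULL) {
  metrics <- predictions |>
    dplyr::group_by(.data$split) |>
    dplyr::group_modify(function(d, g)
      regression_metrics(d$observed, d$predicted)) |>
    dplyr::ungroup()
  structure(
    list(kind = kind, features = features, coefficients = coefficients,
         tree = tree, fit = fit, scaling = scaling, metrics = metrics,
         predictions = predictions, cv = cv, seed = seed),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s with %d feature(s): %s\n", x$kind,
              length(x$features), paste(x$features, collapse = ", ")))
  print(as.data.frame(x$metrics), row.names = FALSE, digits = 3)
  invisible(x)
}

# leave-one-out R^2 of an lm via the PRESS statistic
loo_r2 <- function(fit, y) {
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  press <- sum((stats::residuals(fit) / (1 - pmin(h, 1 - 1e-10)))^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - press / sst
}

#' Forward stepwise multivariate linear regression
#'
#' Greedy forward search: features are z-scored with training-set statistics,
#' then the feature whose addition maximizes the scorer (training R squared
#' by default, leave-one-out R squared as alternative) is added until
#' `n_terms` terms, followed by an ordinary least-squares fit of the final
#' model.  Candidates that make the design matrix ill-conditioned are
#' skipped with a message.
#'
#' @param data Tibble: id column, response column, numeric feature columns.
#' @param train_ids,test_ids Disjoint id vectors defining the split.
#' @param response Name of the response column (Delta Delta G, kcal/mol).
#' @param id_col Name of the ligand-id column.
#' @param n_terms Number of features to select (0 gives the intercept-only
#'   model).
#' @param scorer `"train_r2"` (default) or `"loo_r2"`.
#' @param kappa_max Condition-number cap above which a candidate is skipped.
#' @return A `model_report` with coefficients (standardized scale),
#'   train/test metrics and per-ligand predictions.
#' @export
forward_stepwise_mlr <- function(data, train_ids, test_ids,
                                 response = "y", id_col = "ligand_id",
                                 n_terms = 3,
                                 scorer = c("train_r2", "loo_r2"),
                                 kappa_max = 1e8) {
  scorer <- match.arg(scorer)
  ft <- check_feature_table(data, response, id_col)
  data <- ft$data
  if (length(intersect(train_ids, test_ids)) > 0)
    abort("Train and test ids must be disjoint.")
  tr <- match(train_ids, data[[id_col]])
  te <- match(test_ids, data[[id_col]])
  if (anyNA(tr) || anyNA(te)) abort("Some ids are not present in `data`.")
  if (n_terms > length(tr) - 2)
    abort("`n_terms` must be at most the training size minus 2.")

  y_tr <- data[[response]][tr]
  # training-statistics z-scoring; constant-on-train features are unusable
  mu <- vapply(ft$features, function(f) mean(data[[f]][tr]), numeric(1))
  sg <- vapply(ft$features, function(f) sd(data[[f]][tr]), numeric(1))
  usable <- ft$features[sg > 0]
  Z <- vapply(usable, function(f) (data[[f]] - mu[f]) / sg[f],
              numeric(nrow(data)))
  Z <- matrix(Z, nrow = nrow(data), dimnames = list(NULL, usable))

  chosen <- character(0)
  while (length(chosen) < n_terms) {
    cand <- setdiff(usable, chosen)
    if (length(cand) == 0) break
    best <- NULL
    for (f in cand) {
      X <- cbind(1, Z[tr, c(chosen, f), drop = FALSE])
      if (kappa(X, exact = TRUE) > kappa_max) {
        inform(paste0("Skipping collinear candidate: ", f))
        next
      }
      df <- data.frame(y = y_tr, Z[tr, c(chosen, f), drop = FALSE],
                       check.names = FALSE)
      fit <- lm(y ~ ., data = df)
      train_r2 <- 1 - sum(stats::residuals(fit)^2) /
        sum((y_tr - mean(y_tr))^2)
      score <- if (scorer == "train_r2") train_r2 else loo_r2(fit, y_tr)
      tie <- loo_r2(fit, y_tr)
      if (is.null(best) || score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 && !is.na(tie) &&
             (is.na(best$tie) || tie > best$tie))) {
        best <- list(f = f, score = score, tie = tie)
      }
    }
    if (is.null(best)) break
    chosen <- c(chosen, best$f)
  }

  df_tr <- data.frame(y = y_tr, Z[tr, chosen, drop = FALSE],
                      check.names = FALSE)
  fit <- lm(y ~ ., data = df_tr)
  predict_all <- function(rows) {
    nd <- data.frame(Z[rows, chosen, drop = FALSE], check.names = FALSE)
    unname(predict(fit, newdata = nd))
  }
  preds <- dplyr::bind_rows(
    tibble(ligand_id = data[[id_col]][tr], split = "train",
           observed = y_tr, predicted = predict_all(tr)),
    if (length(te) > 0)
      tibble(ligand_id = data[[id_col]][te], split = "test",
             observed = data[[response]][te], predicted = predict_all(te))
  )
  preds$abs_error <- abs(preds$observed - preds$predicted)
  co <- coef(fit)
  new_model_report(
    kind = "stepwise_mlr", features = chosen,
    coefficients = tibble(term = names(co), estimate = unname(co)),
    fit = fit,
    scaling = list(mean = mu[chosen], sd = sg[chosen]),
    predictions = preds
  )
}

#' Absolute prediction errors of a model report
#'
#' The numeric content of a prediction-error distribution plot: the sorted
#' absolute errors per split.
#'
#' @param report A `model_report`.
#' @return Tibble `split`, `ligand_id`, `abs_error`, sorted within split.
#' @export
error_distribution <- function(report) {
  stopifnot(inherits(report, "model_report"))
  report$predictions |>
    dplyr::select("split", "ligand_id", "abs_error") |>
    dplyr::arrange(.data$split, .data$abs_error)
}

#' Quantile summary of per-split absolute errors
#'
#' @param report A `model_report`.
#' @param probs Quantile probabilities.
#' @return Tibble with one row per split and one column per quantile.
#' @export
error_quantiles <- function(report,
                            probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(report, "model_report"))
  report$predictions |>
    dplyr::group_by(.data$split) |>
    dplyr::group_modify(function(d, g) {
      q <- quantile(d$abs_error, probs = probs, names = FALSE, type = 7)
      tibble::as_tibble(as.list(setNames(q, paste0("q", probs * 100))))
    }) |>
    dplyr::ungroup()
}

#' @export
tidy.model_report <- function(x, ...) {
  if (x$kind == "tree" && !is.null(x$tree)) return(x$tree)
  x$coefficients %||% tibble(term = character(), estimate = numeric())
}

#' @export
glance.model_report <- function(x, ...) {
  wide <- x$metrics |>
    tidyr::pivot_wider(names_from = "split",
                       values_from = c("r2", "mae", "rmse"),
                       names_glue = "{split}_{.value}")
  dplyr::bind_cols(tibble(kind = x$kind, n_features = length(x$features)),
                   wide)
}
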
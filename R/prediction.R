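# Severity prediction: epsilon-SVR (RBF kernel) under nested
# cross-validation (outer leave-one-out, inner 10-fold grid search), the
# one-predictor-at-a-time search, and a permutation guard for its
# selection effect.

#' SVR configuration
#'
#' Hyperparameter grids and cross-validation scheme for the
#' epsilon-support-vector-regression model (radial basis function kernel).
#' Default grids span `C` in 2^-5..2^15 and `gamma` in 2^-15..2^3 (both in
#' powers of 4) with `epsilon` in {0.01, 0.1, 1}; the outer loop is
#' leave-one-out, the inner loop 10-fold with seeded shuffling, selection
#' by mean squared error.
#'
#' @param C_grid,gamma_grid,epsilon_grid candidate hyperparameter values.
#' @param inner_folds inner CV fold count (>= 2).
#' @param seed integer seed for inner-fold shuffling.
#' @return list of class `svr_config`.
#' @export
svr_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       epsilon_grid = c(0.01, 0.1, 1),
                       inner_folds = 10L, seed = 1L) {
  stopifnot(length(C_grid) >= 1, length(gamma_grid) >= 1,
            length(epsilon_grid) >= 1, inner_folds >= 2)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 epsilon_grid = epsilon_grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "svr_config")
}

# standardize columns with train-fold parameters only (leakage guard);
# zero-SD columns are centered but not scaled
std_params <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[is.na(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
std_apply <- function(x, p) sweep(sweep(x, 2, p$mu), 2, p$sd, `/`)

svr_fit_predict <- function(xtr, ytr, xte, C, gamma, epsilon) {
  fit <- e1071::svm(x = xtr, y = ytr, type = "eps-regression",
                    kernel = "radial", cost = C, gamma = gamma,
                    epsilon = epsilon, scale = FALSE)
  as.numeric(stats::predict(fit, xte))
}

#' Nested cross-validated epsilon-SVR prediction
#'
#' For each outer leave-one-out fold: features are standardized on the
#' training fold only; `(C, gamma, epsilon)` are chosen by inner
#' `inner_folds`-fold CV mean squared error on the training fold (seeded
#' shuffling applied in canonical data order, so identical subjects are
#' partitioned identically; ties broken by grid order); the model is
#' refitted on the full
#' training fold and the held-out subject predicted. Accuracy is the
#' Pearson correlation between out-of-fold predictions and observed
#' outcomes, with `R2 = 1 - SS_res / SS_tot` (the out-of-fold coefficient
#' of determination, which can be negative and need not equal r^2).
#'
#' @param features subject x feature numeric matrix (no missing values).
#' @param outcome numeric outcome (e.g., HAMD), length = subjects.
#' @param cfg an [svr_config()].
#' @param name predictor label carried into the result.
#' @return list of class `svr_result`: `predictions`, `r`, `p`, `r2`,
#'   `r_squared_of_r`, `fold_params` (per-fold chosen hyperparameters),
#'   `name`.
#' @export
svr_nested_cv <- function(features, outcome, cfg = svr_config(),
                          name = "predictor") {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(n >= 12, length(outcome) == n)
  if (anyNA(x)) stop("missing feature values")
  if (stats::sd(outcome) == 0) stop("constant outcome: correlation undefined")
  grid <- expand.grid(C = cfg$C_grid, gamma = cfg$gamma_grid,
                      epsilon = cfg$epsilon_grid, KEEP.OUT.ATTRS = FALSE)
  preds <- numeric(n)
  fold_params <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    p <- std_params(x[tr, , drop = FALSE])
    xtr <- std_apply(x[tr, , drop = FALSE], p)
    ytr <- outcome[tr]
    m <- length(tr)
    # canonical training order: rows sorted lexicographically by (outcome,
    # features) before fold assignment and fitting, so the whole fold is a
    # function of the training multiset and identical subjects are treated
    # identically regardless of their position
    can <- do.call(order, c(list(ytr), as.data.frame(xtr)))
    xtr <- xtr[can, , drop = FALSE]
    ytr <- ytr[can]
    folds <- with_seed(substream_seed(cfg$seed, "cv", 0L),
                       sample(rep_len(seq_len(cfg$inner_folds), m)))
    mse <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      se <- 0
      for (f in seq_len(cfg$inner_folds)) {
        hold <- folds == f
        if (!any(hold) || all(hold)) next
        yhat <- svr_fit_predict(xtr[!hold, , drop = FALSE], ytr[!hold],
                                xtr[hold, , drop = FALSE],
                                grid$C[gi], grid$gamma[gi], grid$epsilon[gi])
        se <- se + sum((yhat - ytr[hold])^2)
      }
      mse[gi] <- se / m
    }
    best <- which.min(mse)
    fold_params[[i]] <- grid[best, ]
    preds[i] <- svr_fit_predict(xtr, ytr,
                                std_apply(x[i, , drop = FALSE], p),
                                grid$C[best], grid$gamma[best],
                                grid$epsilon[best])
  }
  fold_params <- do.call(rbind, fold_params)
  rownames(fold_params) <- NULL
  ct <- suppressWarnings(stats::cor.test(preds, outcome))
  r <- unname(ct$estimate)
  structure(list(predictions = preds, r = r, p = ct$p.value,
                 r2 = 1 - sum((outcome - preds)^2) /
                   sum((outcome - mean(outcome))^2),
                 r_squared_of_r = r^2,
                 fold_params = fold_params, name = name),
            class = "svr_result")
}

#' @export
print.svr_result <- function(x, ...) {
  cat(sprintf("SVR nested-CV result [%s]: r = %.3f (p = %.3g), R2 = %.3f over %d subjects\n",
              x$name, x$r, x$p, x$r2, length(x$predictions)))
  invisible(x)
}

#' Data-driven predictor search
#'
#' Runs [svr_nested_cv()] once per candidate metric set (one type of
#' network property at a time) and ranks results by out-of-fold r. All
#' results are returned, not only the winner, to expose the selection
#' multiplicity inherent in the search; see [permutation_pvalue()] for a
#' selection-corrected significance guard.
#'
#' @param metric_sets named list of subject x feature matrices.
#' @param outcome numeric outcome.
#' @param cfg an [svr_config()].
#' @return list of `svr_result`, ordered by decreasing r.
#' @export
predictor_search <- function(metric_sets, outcome, cfg = svr_config()) {
  stopifnot(length(metric_sets) >= 1, !is.null(names(metric_sets)))
  res <- lapply(names(metric_sets), function(nm)
    svr_nested_cv(metric_sets[[nm]], outcome, cfg, name = nm))
  res[order(-vapply(res, function(r) r$r, numeric(1)))]
}

#' Permutation p value for a nested-CV correlation
#'
#' Repeats the full nested-CV pipeline on outcome-permuted data and returns
#' the plus-one-corrected exceedance fraction
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`, a valid guard against
#' the optimism of data-driven predictor selection.
#'
#' @param features subject x feature matrix.
#' @param outcome numeric outcome.
#' @param cfg an [svr_config()].
#' @param n_perm number of permutations (>= 100).
#' @param r_obs optionally, a precomputed observed r (skips one CV run).
#' @return list with `p`, `r_obs`, `r_perm`.
#' @export
permutation_pvalue <- function(features, outcome, cfg = svr_config(),
                               n_perm = 100L, r_obs = NULL) {
  stopifnot(n_perm >= 100)
  if (is.null(r_obs))
    r_obs <- svr_nested_cv(features, outcome, cfg)$r
  r_perm <- vapply(seq_len(n_perm), function(b) {
    yp <- with_seed(substream_seed(cfg$seed, "perm", b), sample(outcome))
    svr_nested_cv(features, yp, cfg)$r
  }, numeric(1))
  list(p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       r_obs = r_obs, r_perm = r_perm)
}
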
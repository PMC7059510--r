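#' Train/test split plans for snippet-level modeling
#'
#' Two evaluation regimes for symptom inference. *Within-user*: a uniform
#' random sample of `round(train_fraction * n)` rows goes to training, so
#' train and test typically contain snippets from the same users (70% of
#' 37,228 rows gives 26,060 training rows). *Across-user*: a uniform
#' random sample of `round(train_fraction * n_users)` users contributes
#' all its rows to training and the remaining users are entirely held
#' out, estimating generalization to new users. Deterministic under a
#' fixed seed.
#'
#' @param dataset an `aligned_dataset`, or a data.frame with a `user_id`
#'   column.
#' @param mode `"within_user"` or `"across_user"`.
#' @param train_fraction proportion in (0, 1); the case study used 0.70.
#' @param seed integer RNG seed.
#' @return object of class `split_plan`: list with `mode`,
#'   `train_fraction`, `seed`, integer row indices `train_idx` /
#'   `test_idx`, and (across-user mode) `train_users` / `test_users`.
#' @export
make_split <- function(dataset, mode = c("within_user", "across_user"),
                       train_fraction = 0.7, seed = 1L) {
  mode <- match.arg(mode)
  df <- if (inherits(dataset, "aligned_dataset")) dataset$data else dataset
  n <- nrow(df)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  if (mode == "within_user") {
    n_train <- round(train_fraction * n)
    train_idx <- sort(sample.int(n, n_train))
    train_users <- test_users <- NULL
  } else {
    users <- sort(unique(df$user_id))
    if (length(users) < 2L) {
      stop("across-user split needs at least 2 users", call. = FALSE)
    }
    n_tr_users <- max(1L, min(length(users) - 1L,
                              round(train_fraction * length(users))))
    train_users <- sort(sample(users, n_tr_users))
    test_users <- setdiff(users, train_users)
    train_idx <- which(df$user_id %in% train_users)
  }
  structure(list(mode = mode, train_fraction = train_fraction,
                 seed = as.integer(seed),
                 train_idx = train_idx,
                 test_idx = setdiff(seq_len(n), train_idx),
                 train_users = train_users, test_users = test_users),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan %s: %d train / %d test rows>\n", x$mode,
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Fit a snippet-level symptom classifier
#'
#' Two algorithms, as in the case study: `"logistic"`, a ridge-regularized
#' logistic regression on standardized features (small fixed penalty for
#' numerical stability); and `"random_forest"`, 200 trees with at most 20
#' candidate features considered at each split, on unstandardized
#' features.
#'
#' @param x numeric feature matrix (training rows).
#' @param y binary labels in \{0, 1\}; both classes must be present.
#' @param algorithm `"logistic"` or `"random_forest"`.
#' @param seed RNG seed (random forest).
#' @param num_trees,max_features random forest size and per-split
#'   candidate feature cap.
#' @param lambda ridge penalty for the logistic model.
#' @return object of class `model_a`; use [predict.model_a()] for class-1
#'   probabilities.
#' @export
fit_model_a <- function(x, y, algorithm = c("logistic", "random_forest"),
                        seed = 1L, num_trees = 200L, max_features = 20L,
                        lambda = 1e-3) {
  algorithm <- match.arg(algorithm)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (algorithm == "logistic") {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                          lambda = c(10, 1, 0.1, 0.01, lambda),
                          standardize = FALSE)
    model <- list(fit = fit, center = ctr, scale = scl, lambda = lambda)
  } else {
    df <- as.data.frame(x)
    colnames(df) <- paste0("f", seq_len(ncol(x)))
    fit <- ranger::ranger(
      y = factor(y, levels = c(0, 1)), x = df,
      num.trees = num_trees, mtry = min(max_features, ncol(x)),
      probability = TRUE, seed = seed, num.threads = 1L)
    model <- list(fit = fit)
  }
  structure(c(model, list(algorithm = algorithm)), class = "model_a")
}

#' Predict class-1 probabilities from a fitted snippet classifier
#' @param object a `model_a`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.model_a <- function(object, newdata, ...) {
  if (object$algorithm == "logistic") {
    xs <- scale(newdata, center = object$center, scale = object$scale)
    as.numeric(predict(object$fit, xs, s = object$lambda,
                       type = "response"))
  } else {
    df <- as.data.frame(newdata)
    colnames(df) <- paste0("f", seq_len(ncol(newdata)))
    predict(object$fit, data = df, num.threads = 1L)$predictions[, "1"]
  }
}

#' ROC curve over score thresholds
#'
#' Sweeps the distinct score values as decision thresholds; tied scores
#' form one operating point, which makes the trapezoidal area equal the
#' Mann-Whitney concordance statistic with ties counted one half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels in \{0, 1\}; both classes required.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, beginning at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L) {
    stop("ROC undefined: test labels contain a single class", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- labels[ord]
  last_of_group <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(yy == 1)[last_of_group]
  fp <- cumsum(yy == 0)[last_of_group]
  data.frame(threshold = c(Inf, s[last_of_group]),
             fpr = c(0, fp / N), tpr = c(0, tp / P))
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\]; identical scores for all rows give 0.5.
#' @export
auc_trapezoid <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Evaluate a snippet classifier on held-out rows
#'
#' @param model a `model_a`.
#' @param x test feature matrix.
#' @param y test labels (both classes present).
#' @return object of class `model_a_report`: list with `algorithm`,
#'   `roc` (data.frame of curve points), `auc`, `n_test`, and the fitted
#'   `model`.
#' @export
evaluate_roc <- function(model, x, y) {
  if (!length(y)) stop("empty test set", call. = FALSE)
  scores <- predict(model, x)
  roc <- roc_points(scores, y)
  structure(list(algorithm = model$algorithm, roc = roc,
                 auc = auc_trapezoid(scores, y),
                 n_test = length(y), model = model),
            class = "model_a_report")
}

#' @export
print.model_a_report <- function(x, ...) {
  cat(sprintf("<model_a_report %s: AUC %.3f on %d test rows>\n",
              x$algorithm, x$auc, x$n_test))
  invisible(x)
}

#' Serialize a model report (ROC points + AUC) to JSON
#' @param report a `model_a_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  jsonlite::write_json(list(algorithm = report$algorithm,
                            auc = report$auc, n_test = report$n_test,
                            roc = report$roc),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# descending lambda grid: from the smallest all-zero lambda down 4 decades
.lambda_grid <- function(x, y, n_lambda = 100L, min_ratio = 1e-4) {
  n <- nrow(x)
  ctr <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2L, ctr)^2))  # 1/n variance, as glmnet
  sds[sds == 0] <- Inf
  xs <- sweep(sweep(x, 2L, ctr), 2L, sds, "/")
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / n
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Cross-validated LASSO path for user-level outcome prediction
#'
#' L1-penalized least squares (via coordinate descent) over a descending
#' lambda grid of 100 log-spaced values spanning four decades below the
#' smallest all-zero-coefficient lambda, with K-fold cross-validated MSE
#' and standard errors. Folds are seeded and stratified by outcome
#' quartile. Features are standardized internally. The baseline symptom
#' score enters as an ordinary candidate column of `x`. Selected features
#' are reported at `lambda_min`, the grid point minimizing CV MSE.
#'
#' @param x numeric matrix of user-level candidate features (columns
#'   named).
#' @param y continuous outcome (one value per user); must not be constant.
#' @param nfolds folds for cross-validation (case-study default 50).
#' @param seed RNG seed for fold assignment.
#' @param lambda optional explicit descending lambda grid.
#' @return object of class `lasso_path`: list with `lambda`, `cvm`,
#'   `cvsd`, `nzero`, `lambda_min`, `selected` (feature names with
#'   nonzero coefficient at `lambda_min`), `coef_min`, `nfolds`, and the
#'   underlying `cv.glmnet` fit.
#' @export
fit_lasso_cv <- function(x, y, nfolds = 50L, seed = 1L, lambda = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (nrow(x) <= nfolds) stop("need more users than folds", call. = FALSE)
  if (var(y) == 0) stop("constant outcome", call. = FALSE)
  if (is.null(lambda)) lambda <- .lambda_grid(x, y)
  set.seed(seed)
  # fold ids stratified by outcome quartile
  strata <- cut(y, breaks = unique(quantile(y, 0:4 / 4)),
                include.lowest = TRUE, labels = FALSE)
  foldid <- integer(length(y))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  grouped <- min(table(foldid)) >= 3L
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, lambda = lambda,
                          foldid = foldid, standardize = TRUE,
                          grouped = grouped)
  cf <- coef(cv, s = "lambda.min")
  nz <- rownames(cf)[as.numeric(cf) != 0]
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 nzero = as.integer(cv$nzero),
                 lambda_min = cv$lambda.min,
                 selected = setdiff(nz, "(Intercept)"),
                 coef_min = stats::setNames(as.numeric(cf), rownames(cf)),
                 nfolds = as.integer(nfolds), cv = cv),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "<lasso_path: lambda_min %.4g, %d features selected, %d-fold CV>\n",
    x$lambda_min, length(x$selected), x$nfolds))
  invisible(x)
}

#' LASSO coefficients at a fixed penalty
#'
#' Exact coordinate-descent solution at the requested `lambda` (including
#' `lambda = 0`, where the solution coincides with ordinary least squares
#' on well-conditioned problems).
#'
#' @param x feature matrix.
#' @param y continuous outcome.
#' @param lambda penalty value (>= 0).
#' @return named coefficient vector including `(Intercept)`.
#' @export
lasso_coef <- function(x, y, lambda) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- glmnet::glmnet(x, y, alpha = 1, thresh = 1e-12)
  cf <- coef(fit, s = lambda, exact = TRUE, x = x, y = y,
             thresh = 1e-12)
  stats::setNames(as.numeric(cf), rownames(cf))
}

#' Serialize a LASSO path to JSON / its CV curve to CSV
#' @param path_obj a `lasso_path`.
#' @param json_path,csv_path output files (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_lasso_path <- function(path_obj, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(lambda_min = path_obj$lambda_min, selected = path_obj$selected,
           nfolds = path_obj$nfolds),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    write.csv(data.frame(lambda = path_obj$lambda, cv_mse = path_obj$cvm,
                         cv_se = path_obj$cvsd, nonzero = path_obj$nzero),
              csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
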
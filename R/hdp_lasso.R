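# LASSO on ranked assay variables against a ranked manufacturability
# attribute: cross-validated lambda selection, the sparse HDP model, and the
# selection-frequency robustness sweep over rank sets.

# cor() that returns NA silently for a constant vector (e.g. the null model's
# flat prediction) instead of warning.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# glmnet-convention lambda_max: smallest lambda zeroing every coefficient for
# standardized predictors (population-sd scaling) and centered response.
lambda_max_gaussian <- function(X, y) {
  n <- nrow(X)
  sx <- apply(X, 2L, function(x) sqrt(mean((x - mean(x))^2)))
  sx[sx == 0] <- 1
  Xs <- scale(X, scale = sx)
  max(abs(crossprod(Xs, y - mean(y)))) / n
}

#' Fit a LASSO model of ranked assay variables
#'
#' Predictors are standardized internally (coefficients are reported
#' back-transformed to the ranked-predictor scale). The lambda grid holds
#' `n_lambda` log-spaced values on `[1e-3 * lambda_max, lambda_max]`, where
#' `lambda_max` is the smallest lambda shrinking every coefficient to zero;
#' `lambda*` minimizes the mean cross-validated squared error over `folds`
#' folds whose random assignment is fixed by `seed`. Coordinate descent runs
#' to tolerance 1e-7.
#'
#' @param X numeric S x V matrix of ranked predictors (colnames = var ids).
#' @param y numeric response (ranked outcome), length S.
#' @param folds number of CV folds (default 5).
#' @param n_lambda grid size (default 100).
#' @param seed integer seed fixing the fold assignment.
#' @param lambda optional explicit lambda grid overriding the default
#'   (decreasing; useful to probe the near-zero-penalty limit).
#' @param standardize standardize predictors before penalization (default
#'   TRUE).
#' @return An object of class `hdp_lasso`: `lambda_grid`, `lambda_star`,
#'   `cv_mse` (per lambda), `coefficients` (named, excludes intercept),
#'   `intercept`, `selected_vars`, `cv_folds`, `cv_seed`, `pearson_r`
#'   (in-sample fitted vs observed), and the underlying `glmnet` fit.
#' @export
fit_lasso <- function(X, y, folds = 5L, n_lambda = 100L, seed = 1L,
                      lambda = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(ncol(X)))
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  S <- nrow(X)
  if (length(y) != S) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)
  if (S < folds) stop("fewer samples than CV folds", call. = FALSE)
  if (is.null(lambda)) {
    lmax <- lambda_max_gaussian(if (standardize) X else scale(X, scale = FALSE), y)
    lambda <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = n_lambda))
  }
  old <- .Random.seed_guard(as.integer(seed))
  on.exit(old(), add = TRUE)
  foldid <- sample(rep_len(seq_len(folds), S))
  # per-fold MSE grouping needs >= 3 observations per fold; pass the choice
  # explicitly so tiny panels do not warn
  cvfit <- glmnet::cv.glmnet(X, y, family = "gaussian", alpha = 1,
                             lambda = lambda, foldid = foldid,
                             standardize = standardize, thresh = 1e-7,
                             grouped = S / folds >= 3)
  lambda_star <- cvfit$lambda.min
  beta <- drop(as.matrix(stats::coef(cvfit$glmnet.fit, s = lambda_star)))
  coefs <- beta[-1L]
  fitted <- drop(cbind(1, X) %*% beta)
  structure(list(lambda_grid = lambda, lambda_star = lambda_star,
                 cv_mse = stats::setNames(cvfit$cvm, signif(cvfit$lambda, 6)),
                 coefficients = coefs, intercept = unname(beta[1L]),
                 selected_vars = names(coefs)[coefs != 0],
                 cv_folds = as.integer(folds), cv_seed = as.integer(seed),
                 pearson_r = safe_cor(fitted, y),
                 glmnet_fit = cvfit$glmnet.fit),
            class = "hdp_lasso")
}

#' @export
print.hdp_lasso <- function(x, digits = 4, ...) {
  cat(sprintf("LASSO on ranked data: %d-fold CV over %d lambda values (seed %d)\n",
              x$cv_folds, length(x$lambda_grid), x$cv_seed))
  cat(sprintf("  lambda* = %.4g; %d variable(s) selected: %s\n",
              x$lambda_star, length(x$selected_vars),
              paste(x$selected_vars, collapse = ", ")))
  if (length(x$selected_vars)) {
    cat("  coefficients:\n")
    print(round(x$coefficients[x$selected_vars], digits))
  }
  cat(sprintf("  in-sample Pearson r = %.3f\n", x$pearson_r))
  invisible(x)
}

#' @export
coef.hdp_lasso <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.hdp_lasso <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(names(object$coefficients), colnames(newdata))
  if (length(miss)) stop("newdata lacks variable(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  drop(object$intercept +
         newdata[, names(object$coefficients), drop = FALSE] %*% object$coefficients)
}

#' Holistic Developability Parameter (HDP) values and rank prediction
#'
#' HDP is the sparse linear combination of ranked assay variables selected by
#' the LASSO: `intercept + sum(coef * ranked variable)` over the selected
#' set. Samples are then tie-average re-ranked on HDP and the Pearson
#' correlation with the observed ranks is reported.
#'
#' @param model an [fit_lasso()] result.
#' @param X ranked predictor matrix containing all selected variables.
#' @param observed_ranks optional observed outcome ranks for the correlation.
#' @return A list of class `hdp_result`: `hdp` values, `predicted_rank`, and
#'   `pearson_r` (NA when no observed ranks are given).
#' @export
hdp <- function(model, X, observed_ranks = NULL) {
  stopifnot(inherits(model, "hdp_lasso"))
  values <- predict(model, X)
  prank <- avg_rank(values)
  names(prank) <- rownames(X)
  r <- if (is.null(observed_ranks)) NA_real_ else safe_cor(prank, observed_ranks)
  structure(list(hdp = stats::setNames(values, rownames(X)),
                 predicted_rank = prank, pearson_r = r,
                 selected_vars = model$selected_vars),
            class = "hdp_result")
}

#' @export
print.hdp_result <- function(x, ...) {
  cat("HDP from", length(x$selected_vars), "selected variable(s):",
      paste(x$selected_vars, collapse = ", "), "\n")
  df <- data.frame(hdp = x$hdp, predicted_rank = x$predicted_rank)
  print(round(df, 3))
  if (!is.na(x$pearson_r))
    cat(sprintf("Pearson r (predicted vs observed ranks) = %.3f\n", x$pearson_r))
  invisible(x)
}

#' Selection-frequency sweep over rank sets
#'
#' Refits the LASSO once per rank set (e.g. the absolute ranking plus the 16
#' L/H combinations of the ambiguous samples) and counts, per variable, how
#' often its coefficient is nonzero; frequencies near 1 mark keystone
#' variables robust to rank uncertainty. Frequencies aggregated by cluster
#' group are also returned when `groups` is given.
#'
#' @param X ranked predictor matrix.
#' @param rank_sets list of `rank_set` objects (see [enumerate_rank_sets()]),
#'   whose `ranks` are the response of each fit.
#' @param folds,n_lambda,seed passed to [fit_lasso()].
#' @param groups optional named vector var id -> group label.
#' @return A list: `by_var` data.frame (`var_id`, `count`, `total`,
#'   `frequency`), `by_group` (or NULL), `models` (one `hdp_lasso` per set,
#'   named by rank-set label).
#' @export
selection_sweep <- function(X, rank_sets, folds = 5L, n_lambda = 100L,
                            seed = 1L, groups = NULL) {
  if (!length(rank_sets)) stop("rank_sets is empty", call. = FALSE)
  X <- as.matrix(X)
  models <- list()
  counts <- stats::setNames(integer(ncol(X)), colnames(X))
  for (rs in rank_sets) {
    y <- rs$ranks[rownames(X)]
    m <- fit_lasso(X, y, folds = folds, n_lambda = n_lambda, seed = seed)
    models[[rs$label]] <- m
    counts[m$selected_vars] <- counts[m$selected_vars] + 1L
  }
  total <- length(rank_sets)
  by_var <- data.frame(var_id = names(counts), count = as.integer(counts),
                       total = total, frequency = as.numeric(counts) / total,
                       stringsAsFactors = FALSE)
  by_group <- NULL
  if (!is.null(groups)) {
    g <- groups[by_var$var_id]
    agg <- tapply(by_var$count, g, sum)
    by_group <- data.frame(group = names(agg), count = as.integer(agg),
                           total_selections = sum(by_var$count),
                           share = as.integer(agg) / max(1L, sum(by_var$count)),
                           stringsAsFactors = FALSE)
  }
  list(by_var = by_var, by_group = by_group, models = models)
}

#' Rank every assay variable of a panel by desirability
#'
#' Applies [rank_average()] column-wise using each variable's registered
#' favorable direction, producing the ranked predictor matrix used by the
#' LASSO stage.
#'
#' @param matrix a `dev_matrix`.
#' @return S x V numeric matrix of tie-averaged ranks (1 = most desirable).
#' @export
rank_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "dev_matrix"))
  out <- matrix$values
  for (j in seq_len(ncol(out)))
    out[, j] <- rank_average(matrix$values[, j], matrix$registry$direction[j])
  out
}
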
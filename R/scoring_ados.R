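# Direction-aware ranking, percentile scaling, best(0)-to-worst(1)
# normalization, group averaging, and the ADOS distance-from-ideal, with an
# optional MLR-weighted variant.

#' Tie-averaged desirability ranks
#'
#' Rank 1 is the most desirable value given the variable's favorable
#' direction; tied values share the average of the rank positions they span
#' (spreadsheet RANK.AVG semantics).
#'
#' @param values numeric vector, one entry per sample.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Numeric vector of ranks summing to S(S+1)/2.
#' @export
rank_average <- function(values, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  if (anyNA(values)) stop("NA in values to rank", call. = FALSE)
  if (length(values) < 2L) stop("ranking needs at least 2 samples", call. = FALSE)
  if (direction == "higher_better") rank(-values, ties.method = "average")
  else rank(values, ties.method = "average")
}

#' Percentile scaling of one variable
#'
#' Scales raw assay values by their position within the observed
#' distribution: `V = (y - Y50) / (Y80 - Y20)` with the median and the
#' 20th/80th percentiles computed by linear interpolation with inclusive
#' endpoints (spreadsheet convention, `stats::quantile` type 7; alternatives
#' via `type`).
#'
#' @param values numeric vector over samples (length >= 3).
#' @param type quantile algorithm passed to [stats::quantile()] (default 7 =
#'   inclusive linear interpolation; 6 = exclusive, 1 = nearest rank).
#' @return data.frame with columns `y`, `Y20`, `Y50`, `Y80`, `V`.
#' @export
scale_scores <- function(values, type = 7) {
  if (length(values) < 3L) stop("percentile scaling needs at least 3 samples", call. = FALSE)
  if (anyNA(values)) stop("NA in values to scale", call. = FALSE)
  q <- stats::quantile(values, c(0.2, 0.5, 0.8), type = type, names = FALSE)
  if (q[3L] <= q[1L])
    stop("degenerate spread: Y80 equals Y20, variable has no discriminating power",
         call. = FALSE)
  data.frame(y = values, Y20 = q[1L], Y50 = q[2L], Y80 = q[3L],
             V = (values - q[2L]) / (q[3L] - q[1L]))
}

#' Best(0)-to-worst(1) normalization of scaled scores
#'
#' `NV = (V - min V) / (max V - min V)`, then direction adjustment: for a
#' higher-better variable (smallest value is worst) the scale is reflected,
#' `NV+ = 1 - NV`; for a lower-better variable `NV+ = NV`. After adjustment 0
#' is always the best sample and 1 the worst.
#'
#' @param scaled numeric vector of scaled values `V` (or the data.frame from
#'   [scale_scores()], whose `V` column is used).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return data.frame with columns `NV` and `NV_plus`.
#' @export
normalize_scores <- function(scaled, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  V <- if (is.data.frame(scaled)) scaled$V else scaled
  rng <- range(V)
  if (rng[2L] <= rng[1L]) stop("degenerate spread: max V equals min V", call. = FALSE)
  NV <- (V - rng[1L]) / (rng[2L] - rng[1L])
  NV_plus <- if (direction == "higher_better") 1 - NV else NV
  data.frame(NV = NV, NV_plus = NV_plus)
}

#' Averaged Developability Output Score (ADOS)
#'
#' Every variable is percentile-scaled, normalized onto a best(0)/worst(1)
#' scale with its favorable direction applied, and averaged within its
#' cluster group; ADOS is the sum of the group means — a distance from the
#' ideal candidate, 0 for a sample best in everything and (number of groups)
#' for one worst in everything. Lower is better.
#'
#' @param matrix a `dev_matrix` whose registry carries directions.
#' @param groups named vector mapping var_id (names) to group label; defaults
#'   to the registry's `group` column. Every variable must have a group and
#'   no group may be empty.
#' @param quantile_type percentile convention, see [scale_scores()].
#' @param aggregate `"sum"` (default: sum of group means) or `"euclidean"`
#'   (root-sum-of-squares distance from ideal across groups).
#' @return An object of class `ados_result`: data.frame with one row per
#'   sample, per-group mean scores, `ados` and the tie-averaged `rank`.
#' @export
ados <- function(matrix, groups = NULL, quantile_type = 7,
                 aggregate = c("sum", "euclidean")) {
  stopifnot(inherits(matrix, "dev_matrix"))
  aggregate <- match.arg(aggregate)
  reg <- matrix$registry
  if (is.null(groups)) groups <- stats::setNames(reg$group, as.character(reg$var_id))
  gvec <- groups[as.character(reg$var_id)]
  if (anyNA(gvec) || any(gvec == "unassigned"))
    stop("every variable needs a cluster group before scoring", call. = FALSE)
  S <- nrow(matrix$values)
  nv <- base::matrix(NA_real_, S, nrow(reg),
                     dimnames = list(rownames(matrix$values), as.character(reg$var_id)))
  for (j in seq_len(nrow(reg))) {
    sc <- scale_scores(matrix$values[, j], type = quantile_type)
    nv[, j] <- normalize_scores(sc, reg$direction[j])$NV_plus
  }
  glabels <- unique(gvec)
  gm <- vapply(glabels, function(g) rowMeans(nv[, gvec == g, drop = FALSE]),
               numeric(S))
  if (!is.matrix(gm)) gm <- base::matrix(gm, nrow = S, dimnames = list(rownames(nv), glabels))
  score <- if (aggregate == "sum") rowSums(gm) else sqrt(rowSums(gm^2))
  out <- data.frame(sample_id = rownames(matrix$values), gm,
                    ados = score, rank = avg_rank(score),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ados_result", "data.frame"),
            groups = glabels, n_per_group = table(gvec)[glabels],
            aggregate = aggregate)
}

#' @export
print.ados_result <- function(x, digits = 3, ...) {
  cat(sprintf("ADOS (%s over %d groups): 0 = ideal, lower = better\n",
              attr(x, "aggregate"), length(attr(x, "groups"))))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' MLR-weighted ADOS
#'
#' Ordinary least squares of the target ranks on the per-group mean scores
#' (with intercept); the fitted linear combination is the weighted score
#' ADOS_MLR, and the Pearson correlation between its tie-averaged ranks and
#' the target ranks measures fit quality. Collinear group scores trigger a
#' rank-deficiency warning and aliased groups get weight 0.
#'
#' @param ados_result an [ados()] result.
#' @param target_ranks numeric vector of target ranks (e.g. the ranked 25 C
#'   monomer-loss rate), in the sample order of `ados_result`.
#' @return A list of class `ados_mlr`: `weights` (intercept + per-group),
#'   `ados_mlr` fitted values, `rank` and `pearson_r`.
#' @export
ados_mlr <- function(ados_result, target_ranks) {
  stopifnot(inherits(ados_result, "ados_result"))
  glabels <- attr(ados_result, "groups")
  G <- as.matrix(ados_result[, glabels, drop = FALSE])
  S <- nrow(G)
  if (length(target_ranks) != S) stop("target_ranks length mismatch", call. = FALSE)
  if (S <= length(glabels) + 1L)
    warning("fewer samples than regression degrees of freedom: fit is underdetermined",
            call. = FALSE)
  fit <- stats::lm(target_ranks ~ G)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    warning("collinear group scores: rank-deficient fit, aliased weights set to 0",
            call. = FALSE)
    beta[is.na(beta)] <- 0
  }
  fitted <- unname(drop(cbind(1, G) %*% beta))
  prank <- avg_rank(fitted)
  structure(list(weights = stats::setNames(beta, c("(Intercept)", glabels)),
                 ados_mlr = stats::setNames(fitted, ados_result$sample_id),
                 rank = stats::setNames(prank, ados_result$sample_id),
                 pearson_r = stats::cor(prank, avg_rank(target_ranks))),
            class = "ados_mlr")
}

#' @export
print.ados_mlr <- function(x, digits = 3, ...) {
  cat("MLR-weighted ADOS\n  weights:\n")
  print(round(x$weights, digits))
  cat(sprintf("  Pearson r (predicted vs target ranks): %.3f\n", x$pearson_r))
  invisible(x)
}
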
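# Degradation-rate estimation from stability time courses: ordinary and
# CV-weighted linear fits, slope-difference significance, and enumeration of
# the rank sets implied by the fit uncertainty of ambiguous samples.

#' Construct a stability time series
#'
#' @param sample_id sample label.
#' @param readout `"monomer"`, `"hmw"` or `"fragment"` (percent units).
#' @param temperature storage temperature, deg C.
#' @param times months, one entry per observation (replicates repeat a time).
#' @param replicate replicate index per observation.
#' @param values percent values per observation.
#' @return An object of class `stability_series`.
#' @export
stability_series <- function(sample_id, readout, temperature,
                             times, replicate, values) {
  readout <- match.arg(readout, c("monomer", "hmw", "fragment"))
  stopifnot(length(times) == length(values), length(replicate) == length(values))
  ut <- sort(unique(times))
  if (length(ut) < 2L) stop("need at least 2 distinct time points", call. = FALSE)
  structure(list(sample_id = sample_id, readout = readout,
                 temperature = temperature,
                 data = data.frame(time_months = times, replicate = replicate,
                                   value_percent = values)),
            class = "stability_series")
}

#' @export
print.stability_series <- function(x, ...) {
  cat(sprintf("stability_series: %s %s at %g C, %d observations over %d time points\n",
              x$sample_id, x$readout, x$temperature, nrow(x$data),
              length(unique(x$data$time_months))))
  invisible(x)
}

new_stability_rate <- function(series, slope, intercept, stderr, method) {
  structure(list(sample_id = series$sample_id, readout = series$readout,
                 temperature = series$temperature,
                 slope = slope, intercept = intercept,
                 stderr = stderr, method = method),
            class = "stability_rate")
}

#' @export
print.stability_rate <- function(x, ...) {
  cat(sprintf("stability_rate [%s]: %s %s at %g C: %.4g +/- %.4g %%/month\n",
              x$method, x$sample_id, x$readout, x$temperature,
              x$slope, x$stderr))
  invisible(x)
}

#' Ordinary least-squares degradation rate
#'
#' Fits `value = a + b * time` over all (time, value) pairs, technical
#' replicates entering as independent points. The slope `b` is the observed
#' relative rate of change (percent/month) and `stderr` its standard error
#' from the fit.
#'
#' @param series a [stability_series()].
#' @return A `stability_rate` (method `"ols_slope"`).
#' @export
fit_rate_ols <- function(series) {
  stopifnot(inherits(series, "stability_series"))
  d <- series$data
  fit <- stats::lm(value_percent ~ time_months, data = d)
  co <- suppressWarnings(summary(fit))$coefficients
  se <- co["time_months", "Std. Error"]
  # a perfect or saturated fit has ~0 residual variance; report stderr 0
  if (!is.finite(se) || sum(stats::resid(fit)^2) < 1e-20 * max(1, sum(d$value_percent^2)))
    se <- 0
  new_stability_rate(series, unname(stats::coef(fit)[2L]),
                     unname(stats::coef(fit)[1L]), se, "ols_slope")
}

#' CV-weighted least-squares degradation rate
#'
#' Weighted linear fit with instrumental-error weighting `1/CV^2`, where each
#' point's CV (percent) is computed from the replicate spread at its time
#' point (`100 * sd / |mean|`). Points with zero replicate spread — including
#' single-replicate points — receive `default_cv` so they keep a finite
#' weight.
#'
#' @param series a [stability_series()].
#' @param default_cv percent CV substituted where the replicate spread is
#'   zero; 0.036 is the panel-wide average of a typical 25 C monomer data set.
#' @return A `stability_rate` (method `"wls_cv"`).
#' @export
fit_rate_wls <- function(series, default_cv = 0.036) {
  stopifnot(inherits(series, "stability_series"))
  if (default_cv <= 0) stop("default_cv must be positive", call. = FALSE)
  d <- series$data
  cvs <- tapply(d$value_percent, d$time_months, function(v) {
    if (length(v) < 2L) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * stats::sd(v) / abs(m)
  })
  cv <- as.numeric(cvs[as.character(d$time_months)])
  cv[!is.finite(cv) | cv == 0] <- default_cv
  w <- 1 / cv^2
  if (!any(is.finite(w))) stop("all weights non-finite", call. = FALSE)
  fit <- stats::lm(value_percent ~ time_months, data = d, weights = w)
  co <- suppressWarnings(summary(fit))$coefficients
  se <- co["time_months", "Std. Error"]
  if (!is.finite(se) || sum(w * stats::resid(fit)^2) < 1e-20 * max(1, sum(d$value_percent^2)))
    se <- 0
  new_stability_rate(series, unname(stats::coef(fit)[2L]),
                     unname(stats::coef(fit)[1L]), se, "wls_cv")
}

#' Are two degradation rates statistically distinct?
#'
#' Two-sided z-test on the slope difference with pooled standard error
#' `sqrt(se1^2 + se2^2)`.
#'
#' @param r1,r2 `stability_rate` objects.
#' @param alpha significance level (default 0.05).
#' @return `TRUE` when the rates differ at level `alpha`.
#' @export
rate_significance <- function(r1, r2, alpha = 0.05) {
  stopifnot(inherits(r1, "stability_rate"), inherits(r2, "stability_rate"))
  se <- sqrt(r1$stderr^2 + r2$stderr^2)
  diff <- r1$slope - r2$slope
  if (se == 0) return(diff != 0)
  p <- 2 * stats::pnorm(-abs(diff) / se)
  p < alpha
}

#' Tie-averaged ranks of a numeric vector (smallest value gets rank 1)
#' @noRd
avg_rank <- function(x) rank(x, ties.method = "average")

#' Enumerate the rank sets implied by fit uncertainty
#'
#' Samples whose degradation rates are statistically indistinguishable from
#' several neighbours ("ambiguous") are re-ranked under every combination of
#' their minimal (L, `|slope| - stderr`) and maximal (H, `|slope| + stderr`)
#' degradation rates, while samples with fixed ranks and tied groups keep
#' their positions. With m ambiguous samples this yields `2^m` labelled rank
#' sets plus the `"absolute"` set ranked on point estimates. Ranking is on
#' the absolute rate (smaller loss = better = lower rank) and ties take the
#' average of the spanned positions, so every rank set sums to S(S+1)/2.
#'
#' @param rates list of `stability_rate` objects, one per sample.
#' @param fixed named numeric vector, sample_id -> integer rank position.
#' @param tied list of character vectors; each group shares the average of
#'   the lowest rank positions still free when the group is placed (groups
#'   are placed in list order, before the ambiguous samples).
#' @param ambiguous character vector of sample ids to sweep.
#' @return A list of `rank_set` objects: `label` (`"absolute"` or an L/H
#'   string over the ambiguous samples, in their given order) and `ranks`
#'   (named numeric).
#' @export
enumerate_rank_sets <- function(rates, fixed = numeric(0), tied = list(),
                                ambiguous = character(0)) {
  ids <- vapply(rates, function(r) r$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample in rates", call. = FALSE)
  covered <- c(names(fixed), unlist(tied), ambiguous)
  if (!setequal(covered, ids) || anyDuplicated(covered))
    stop("fixed, tied and ambiguous must partition the samples", call. = FALSE)
  S <- length(ids)
  if (length(fixed) && (anyDuplicated(fixed) || any(!fixed %in% seq_len(S))))
    stop("inconsistent fixed ranks", call. = FALSE)
  mag <- abs(vapply(rates, function(r) r$slope, 0))
  se <- vapply(rates, function(r) r$stderr, 0)
  names(mag) <- names(se) <- ids

  base <- stats::setNames(rep(NA_real_, S), ids)
  base[names(fixed)] <- fixed
  free <- setdiff(seq_len(S), fixed)
  for (grp in tied) {
    pos <- free[seq_along(grp)]
    base[grp] <- mean(pos)
    free <- setdiff(free, pos)
  }
  # remaining free positions are competed for by the ambiguous samples
  rank_with <- function(m_ambig, label) {
    ranks <- base
    if (length(ambiguous)) {
      r <- avg_rank(m_ambig)
      # hand out the free positions in rate order, then average within ties
      pos <- numeric(length(ambiguous))
      pos[order(m_ambig)] <- free[seq_along(ambiguous)]
      for (u in unique(r)) {
        idx <- which(r == u)
        pos[idx] <- mean(pos[idx])
      }
      ranks[ambiguous] <- pos
    }
    structure(list(label = label, ranks = ranks), class = "rank_set")
  }

  out <- list(rank_with(mag[ambiguous], "absolute"))
  m <- length(ambiguous)
  if (m) {
    for (i in seq_len(2^m) - 1L) {
      bits <- as.integer(intToBits(i))[seq_len(m)]  # 0 = L, 1 = H
      adj <- mag[ambiguous] + ifelse(bits == 1L, se[ambiguous], -se[ambiguous])
      label <- paste(ifelse(bits == 1L, "H", "L"), collapse = "")
      out[[length(out) + 1L]] <- rank_with(adj, label)
    }
  }
  out
}

#' @export
print.rank_set <- function(x, ...) {
  cat("rank_set [", x$label, "]: ",
      paste(sprintf("%s=%g", names(x$ranks), x$ranks), collapse = " "), "\n", sep = "")
  invisible(x)
}
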
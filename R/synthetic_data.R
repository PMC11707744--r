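# Synthetic developability panels: a latent-factor block model for the assay
# matrix, a sparse linear signal for the storage-stability outcome, and linear
# monomer-loss time courses with multiplicative (CV-type) noise.

#' Default variable registry for a synthetic 32-variable panel
#'
#' Mirrors the structure of a real developability panel: 28 well-clustering
#' variables in four correlated blocks (red 9, blue 8, green 5, purple 6),
#' four unassigned hard-to-cluster variables (ids 29-32), nine stability-study
#' (family `"stability"`) variables among them, and a mix of favorable
#' directions (e.g. thermal transitions and the diffusion interaction
#' parameter kD are higher-better, retention times and degradation rates are
#' lower-better).
#'
#' @param n_variables number of variables; the canonical layout needs 32.
#' @return A registry data.frame suitable for [dev_matrix()].
#' @export
default_registry <- function(n_variables = 32L) {
  blocks <- default_blocks()
  group <- rep("unassigned", n_variables)
  for (b in names(blocks)) group[blocks[[b]][blocks[[b]] <= n_variables]] <- b
  # nine stability-derived variables (Group V): rates of monomer/HMW/fragment
  # change at 5/25/40 C
  stab <- intersect(18:26, seq_len(n_variables))
  family <- rep("t0_assay", n_variables)
  family[stab] <- "stability"
  family[intersect(13:17, seq_len(n_variables))] <- "in_silico"
  higher <- intersect(c(5L, 6L, 8L, 12L), seq_len(n_variables))  # Tm1, Tm(Fab), kD, CamSol
  direction <- rep("lower_better", n_variables)
  direction[higher] <- "higher_better"
  data.frame(
    var_id = seq_len(n_variables),
    name = paste0("var", seq_len(n_variables)),
    assay = ifelse(family == "stability", "stability_study",
                   ifelse(family == "in_silico", "in_silico", "t0_panel")),
    direction = direction,
    family = family,
    group = group,
    stringsAsFactors = FALSE
  )
}

default_blocks <- function() {
  list(red    = c(1L, 5L, 6L, 7L, 8L, 16L, 20L, 21L, 22L),
       blue   = c(2L, 3L, 4L, 13L, 14L, 15L, 17L, 23L),
       green  = c(9L, 11L, 12L, 24L, 26L),
       purple = c(10L, 18L, 19L, 25L, 27L, 28L))
}

#' Configuration for the synthetic-panel generator
#'
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param n_samples panel size (default 9: 3 mAbs x 3 buffers).
#' @param n_variables number of assay variables (default 32).
#' @param blocks named list of integer var_id vectors giving the correlated
#'   blocks; must be disjoint. Defaults to the four-block layout of
#'   [default_registry()].
#' @param loading within-block loading in `[0, 1]`: each block member is
#'   `loading * factor + sqrt(1 - loading^2) * noise` before the skew
#'   transform, so `loading^2` is the within-block latent correlation.
#' @param signal_vars var_ids whose (standardized) values drive the outcome.
#' @param effect_weights one weight per signal variable.
#' @param noise_sd residual sd of the outcome on the standardized-signal scale.
#' @param tail_skew nonnegative skew factor; values are passed through the
#'   rank-preserving map `(exp(tail_skew * z) - 1) / tail_skew` so marginals
#'   are long-tailed for `tail_skew > 0` and symmetric at 0.
#' @param time_grids named list, temperature (deg C, as character) -> months.
#' @param kinetics_cv percent coefficient of variation of replicate
#'   measurements in the stability time courses (default 0.036).
#' @param replicates technical replicates per time point (default 2).
#' @param registry optional registry data.frame; default [default_registry()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_samples = 9L,
                         n_variables = 32L,
                         blocks = NULL,
                         loading = 0.9,
                         signal_vars = c(5L, 8L, 10L, 2L, 27L),
                         effect_weights = c(1, 0.25, 0.8, 0.7, 0.6),
                         noise_sd = 0.1,
                         tail_skew = 0.5,
                         time_grids = list(`40` = c(0, 0.5, 1, 3),
                                           `25` = c(0, 1, 3, 6),
                                           `5`  = c(0, 3, 6, 12, 18)),
                         kinetics_cv = 0.036,
                         replicates = 2L,
                         registry = NULL) {
  if (is.null(blocks)) {
    blocks <- lapply(default_blocks(), function(v) v[v <= n_variables])
    blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  }
  ids <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(ids)) stop("blocks overlap", call. = FALSE)
  if (length(ids) && max(ids) > n_variables)
    stop("block member beyond n_variables", call. = FALSE)
  signal_vars <- as.integer(signal_vars)
  if (any(signal_vars > n_variables | signal_vars < 1L))
    stop("signal_vars outside 1..n_variables", call. = FALSE)
  if (length(effect_weights) != length(signal_vars))
    stop("effect_weights must match signal_vars", call. = FALSE)
  if (loading < 0 || loading > 1) stop("loading must be in [0, 1]", call. = FALSE)
  if (tail_skew < 0) stop("tail_skew must be >= 0", call. = FALSE)
  if (any(vapply(time_grids, function(g) g[1L] != 0 || is.unsorted(g, strictly = TRUE), TRUE)))
    stop("every time grid must start at 0 and increase strictly", call. = FALSE)
  if (is.null(registry)) registry <- default_registry(n_variables)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_variables = as.integer(n_variables), blocks = blocks,
                 loading = loading, signal_vars = signal_vars,
                 effect_weights = effect_weights, noise_sd = noise_sd,
                 tail_skew = tail_skew, time_grids = time_grids,
                 kinetics_cv = kinetics_cv, replicates = as.integer(replicates),
                 registry = registry),
            class = "synth_config")
}

skew_transform <- function(z, tail_skew) {
  if (tail_skew == 0) z else (exp(tail_skew * z) - 1) / tail_skew
}

synth_sample_ids <- function(n) {
  if (n == 9L) {
    as.vector(t(outer(c("A", "B", "C"), 1:3, paste0)))  # A1..C3
  } else {
    sprintf("S%02d", seq_len(n))
  }
}

#' Generate a synthetic developability matrix
#'
#' Per sample, one latent factor is drawn per block; each block member is
#' `loading * factor + sqrt(1 - loading^2) * e` with standard-normal `e`
#' (unassigned variables are pure noise), then passed through the
#' rank-preserving exponential skew so marginals are long-tailed.
#'
#' @param config a [synth_config()].
#' @return A [dev_matrix()] with `config$n_samples` rows.
#' @export
generate_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_guard(config$seed)
  on.exit(old(), add = TRUE)
  S <- config$n_samples; V <- config$n_variables
  z <- matrix(stats::rnorm(S * V), S, V)
  for (b in config$blocks) {
    f <- stats::rnorm(S)
    lam <- config$loading
    z[, b] <- lam * f + sqrt(1 - lam^2) * z[, b, drop = FALSE]
  }
  vals <- skew_transform(z, config$tail_skew)
  rownames(vals) <- synth_sample_ids(S)
  colnames(vals) <- as.character(seq_len(V))
  dev_matrix(vals, config$registry)
}

#' Generate the storage-stability outcome for a synthetic panel
#'
#' A sparse linear signal: the standardized values of `config$signal_vars`,
#' oriented by each variable's registered favorable direction (a desirable
#' value slows monomer loss), weighted by `config$effect_weights`, plus
#' gaussian noise of sd `config$noise_sd`. The result is returned as a signed monomer-loss rate in
#' percent/month (negative = loss), anchored so that the panel lies in a
#' realistic band around -0.35 %/month; larger signal means faster loss.
#'
#' @param matrix a `dev_matrix` produced by [generate_matrix()].
#' @param config the [synth_config()] used to generate it.
#' @return Named numeric vector of rates (%/month, negative), one per sample.
#' @export
generate_outcome <- function(matrix, config) {
  stopifnot(inherits(matrix, "dev_matrix"), inherits(config, "synth_config"))
  miss <- setdiff(config$signal_vars, matrix$registry$var_id)
  if (length(miss)) stop("signal var(s) absent from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  old <- .Random.seed_guard(config$seed + 1e6L)
  on.exit(old(), add = TRUE)
  X <- matrix$values[, as.character(config$signal_vars), drop = FALSE]
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  # orient by favorable direction: desirable values mean slower loss
  dir <- matrix$registry$direction[match(config$signal_vars, matrix$registry$var_id)]
  sgn <- ifelse(dir == "higher_better", -1, 1)
  raw <- drop(Xs %*% (sgn * config$effect_weights)) +
    config$noise_sd * stats::rnorm(nrow(X))
  rate <- -(0.35 + 0.1 * raw)
  names(rate) <- rownames(matrix$values)
  rate
}

#' Generate a stability time course for one sample
#'
#' Replicate percent-monomer values follow `100 - rate * t` with gaussian
#' noise whose sd is `kinetics_cv` percent of the current value (CV-type,
#' heteroscedastic), on the sampling grid registered for the temperature.
#'
#' @param rate positive monomer-loss rate in percent/month (0.34 means losing
#'   0.34% monomer per month); the sign convention of [generate_outcome()] is
#'   handled by taking `abs()`.
#' @param config a [synth_config()] (supplies grid, CV and replicate count).
#' @param temperature temperature in deg C; must be a name of
#'   `config$time_grids`.
#' @param sample_id sample label stored in the series.
#' @param readout one of `"monomer"`, `"hmw"`, `"fragment"`.
#' @param seed optional seed overriding `config$seed` (so each sample or
#'   readout can get an independent draw).
#' @return A [stability_series()] object.
#' @export
generate_timeseries <- function(rate, config, temperature,
                                sample_id = "S1", readout = "monomer",
                                seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  key <- as.character(temperature)
  if (!key %in% names(config$time_grids))
    stop("no time grid registered for temperature ", key, call. = FALSE)
  grid <- config$time_grids[[key]]
  old <- .Random.seed_guard(if (is.null(seed)) config$seed + 2e6L else as.integer(seed))
  on.exit(old(), add = TRUE)
  rate <- abs(rate)
  times <- rep(grid, each = config$replicates)
  mu <- 100 - rate * times
  vals <- mu + stats::rnorm(length(mu), sd = (config$kinetics_cv / 100) * abs(mu))
  if (any(vals < 0)) {
    warning("negative % monomer generated; clipped at 0", call. = FALSE)
    vals[vals < 0] <- 0
  }
  stability_series(sample_id = sample_id, readout = readout,
                   temperature = as.numeric(temperature),
                   times = times,
                   replicate = rep(seq_len(config$replicates), times = length(grid)),
                   values = vals)
}

# Seed the RNG reproducibly and restore the caller's state on exit.
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
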
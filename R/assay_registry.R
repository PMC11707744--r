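#' devrank: rank-based aggregation and sparse prediction for developability panels
#'
#' Tools to turn a panel of formulation:mAb developability-assay outputs into
#' interpretable summary metrics: degradation-rate estimation from stability
#' time courses, Spearman/UPGMA clustering of assay variables with
#' leave-one-sample-out stability statistics, the Averaged Developability
#' Output Score (ADOS, a percentile-scaled distance from ideal), and a sparse
#' LASSO model of ranked assay variables (the Holistic Developability
#' Parameter, HDP) predicting a ranked manufacturability attribute.
#'
#' @keywords internal
#' @aliases devrank-package
"_PACKAGE"

VALID_DIRECTIONS <- c("higher_better", "lower_better")
VALID_FAMILIES   <- c("t0_assay", "in_silico", "stability")

#' Construct a developability matrix
#'
#' The central container: an S x V numeric matrix of assay outputs (S samples,
#' V assay variables) together with a variable registry carrying, for every
#' variable, its identity, source assay, favorable direction and optional
#' cluster-group label, plus a sample table (buffer and mAb identity).
#'
#' @param values numeric S x V matrix; rownames are sample ids, colnames are
#'   variable ids (coerced to integer-like strings, e.g. `"1"`..`"32"`).
#' @param registry data.frame with columns `var_id` (integer), `name`, `assay`,
#'   `direction` (`"higher_better"` or `"lower_better"`), `family`
#'   (`"t0_assay"`, `"in_silico"` or `"stability"`) and optionally `group`.
#' @param samples optional data.frame with columns `sample_id`, `buffer_id`,
#'   `mab_id`. When omitted it is reconstructed from the rownames: a sample id
#'   of the form `<letter><digits>` is split into buffer and mAb.
#' @return An object of class `dev_matrix` with elements `values`, `registry`
#'   and `samples`.
#' @export
dev_matrix <- function(values, registry, samples = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("matrix values must be numeric", call. = FALSE)
  if (is.null(rownames(values))) stop("values must carry sample ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample_id: ", rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite value for sample '%s', variable '%s'",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]),
         call. = FALSE)
  }
  registry <- validate_registry(registry)
  if (is.null(colnames(values))) colnames(values) <- as.character(registry$var_id)
  missing_reg <- setdiff(colnames(values), as.character(registry$var_id))
  if (length(missing_reg))
    stop("no registry entry for variable(s): ", paste(missing_reg, collapse = ", "), call. = FALSE)
  registry <- registry[match(colnames(values), as.character(registry$var_id)), , drop = FALSE]
  rownames(registry) <- NULL
  if (is.null(samples)) samples <- split_sample_ids(rownames(values))
  stopifnot(all(samples$sample_id == rownames(values)))
  structure(list(values = values, registry = registry, samples = samples),
            class = "dev_matrix")
}

validate_registry <- function(registry) {
  registry <- as.data.frame(registry, stringsAsFactors = FALSE)
  need <- c("var_id", "name", "assay", "direction", "family")
  miss <- setdiff(need, names(registry))
  if (length(miss)) stop("registry lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"group" %in% names(registry)) registry$group <- "unassigned"
  registry$group[is.na(registry$group) | registry$group == ""] <- "unassigned"
  registry$var_id <- as.integer(registry$var_id)
  if (anyDuplicated(registry$var_id)) stop("duplicate var_id in registry", call. = FALSE)
  bad_dir <- is.na(registry$direction) | !registry$direction %in% VALID_DIRECTIONS
  if (any(bad_dir))
    stop("registry entry for var ", paste(registry$var_id[bad_dir], collapse = ", "),
         " lacks a valid direction", call. = FALSE)
  bad_fam <- is.na(registry$family) | !registry$family %in% VALID_FAMILIES
  if (any(bad_fam))
    stop("registry entry for var ", paste(registry$var_id[bad_fam], collapse = ", "),
         " lacks a valid family", call. = FALSE)
  registry
}

split_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^([A-Za-z]+)([0-9]+)$", ids))
  buffer <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_, "")
  mab <- vapply(m, function(x) if (length(x) == 3L) x[3L] else NA_character_, "")
  data.frame(sample_id = ids, buffer_id = buffer, mab_id = mab,
             stringsAsFactors = FALSE)
}

#' @export
print.dev_matrix <- function(x, ...) {
  cat(sprintf("dev_matrix: %d samples x %d assay variables\n", nrow(x$values), ncol(x$values)))
  fam <- table(x$registry$family)
  cat("  families:", paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
  grp <- table(x$registry$group)
  cat("  groups:  ", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  cat("  samples: ", paste(rownames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.dev_matrix <- function(x) dim(x$values)

#' Read a developability matrix and its variable registry from CSV
#'
#' The matrix CSV has one header row (`sample_id,var_1,...,var_V` or bare
#' variable ids) and one row per sample; the registry CSV has columns
#' `var_id,name,assay,direction,family,group`.
#'
#' @param path path to the matrix CSV.
#' @param registry_path path to the registry CSV.
#' @return A validated [dev_matrix()].
#' @export
load_matrix <- function(path, registry_path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix CSV needs a sample_id column plus variables", call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn))
      if (length(bad))
        stop(sprintf("non-numeric or missing value for sample '%s', variable '%s'",
                     ids[bad[1L]], names(vals)[j]), call. = FALSE)
      vals[[j]] <- vn
    } else if (anyNA(v)) {
      stop(sprintf("non-numeric or missing value for sample '%s', variable '%s'",
                   ids[which(is.na(v))[1L]], names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  colnames(m) <- sub("^var_", "", colnames(m))
  registry <- utils::read.csv(registry_path, stringsAsFactors = FALSE)
  dev_matrix(m, registry)
}

#' Write a developability matrix (and registry) to CSV
#'
#' Inverse of [load_matrix()]; a load -> write -> load round trip is
#' value-exact for finite decimal inputs.
#'
#' @param matrix a `dev_matrix`.
#' @param path matrix CSV destination.
#' @param registry_path optional registry CSV destination.
#' @export
write_matrix <- function(matrix, path, registry_path = NULL) {
  stopifnot(inherits(matrix, "dev_matrix"))
  df <- data.frame(sample_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- paste0("var_", colnames(matrix$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(registry_path))
    utils::write.csv(matrix$registry, registry_path, row.names = FALSE)
  invisible(path)
}

#' Remove assay variables from a panel
#'
#' Used for the filter chain of the analysis workflow: dropping the
#' difficult-to-cluster variables (32 -> 28) and then the stability-derived
#' Group V variables (28 -> 19) before fitting predictive models.
#'
#' @param matrix a `dev_matrix`.
#' @param var_ids integer vector of variable ids to remove (may be empty).
#' @return A `dev_matrix` with those columns removed, survivor order preserved.
#' @export
drop_variables <- function(matrix, var_ids) {
  stopifnot(inherits(matrix, "dev_matrix"))
  var_ids <- unique(as.integer(var_ids))
  if (!length(var_ids)) return(matrix)
  unknown <- setdiff(var_ids, matrix$registry$var_id)
  if (length(unknown))
    stop("unknown var_id: ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- !matrix$registry$var_id %in% var_ids
  dev_matrix(matrix$values[, keep, drop = FALSE],
             matrix$registry[keep, , drop = FALSE],
             matrix$samples)
}

#' Remove one sample from a panel
#'
#' One step of the leave-one-out sensitivity analysis; ranks and correlations
#' are recomputed from scratch on the reduced panel downstream.
#'
#' @param matrix a `dev_matrix`.
#' @param sample_id the sample to remove.
#' @return A `dev_matrix` with S - 1 samples. A warning is raised when the
#'   result has fewer than 3 samples, where percentile scaling degenerates.
#' @export
drop_sample <- function(matrix, sample_id) {
  stopifnot(inherits(matrix, "dev_matrix"))
  i <- match(sample_id, rownames(matrix$values))
  if (is.na(i)) stop("unknown sample_id: ", sample_id, call. = FALSE)
  out <- dev_matrix(matrix$values[-i, , drop = FALSE], matrix$registry,
                    matrix$samples[-i, , drop = FALSE])
  if (nrow(out$values) < 3L)
    warning("panel reduced below 3 samples: percentile scaling is degenerate",
            call. = FALSE)
  out
}

#' Variable ids belonging to a registry family
#'
#' @param matrix a `dev_matrix`.
#' @param family one of `"t0_assay"`, `"in_silico"`, `"stability"`.
#' @return Integer vector of var_ids.
#' @export
family_vars <- function(matrix, family = "stability") {
  stopifnot(inherits(matrix, "dev_matrix"), family %in% VALID_FAMILIES)
  matrix$registry$var_id[matrix$registry$family == family]
}
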
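# Spearman correlation of assay variables, group-average (UPGMA) hierarchical
# clustering of the correlation profiles, leave-one-sample-out sensitivity,
# and the pairing-stability P statistic.

#' Pairwise Spearman correlation of assay variables
#'
#' Each variable is rank-transformed over samples (average ranks for ties) and
#' the Pearson correlation of the ranks is returned for every variable pair.
#'
#' @param matrix a `dev_matrix` with at least 3 samples.
#' @return A V x V symmetric matrix of class `corr_matrix` with unit diagonal;
#'   dimnames are var_ids.
#' @export
spearman_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "dev_matrix"))
  v <- matrix$values
  if (nrow(v) < 3L) stop("Spearman correlation needs at least 3 samples", call. = FALSE)
  const <- apply(v, 2L, function(x) max(x) == min(x))
  if (any(const))
    stop("constant variable(s), correlation undefined: ",
         paste(colnames(v)[const], collapse = ", "), call. = FALSE)
  rho <- stats::cor(v, method = "spearman")
  structure(rho, class = c("corr_matrix", class(rho)))
}

#' Group-average (UPGMA) clustering of correlation profiles
#'
#' Distance between two variables is the Euclidean distance between their rows
#' of the Spearman correlation matrix (profile distance; the `1 - rho`
#' alternative is available via `profile = FALSE`). Agglomeration uses
#' group-average (UPGMA) linkage; branch labels come from cutting the tree
#' into `k` groups.
#'
#' @param corr a `corr_matrix` from [spearman_matrix()].
#' @param k number of branches to cut (1..V).
#' @param profile if `TRUE` (default) cluster correlation rows as feature
#'   vectors; if `FALSE` use `1 - rho` directly as the dissimilarity.
#' @return An object of class `dev_dendrogram`: the `hclust` tree, `var_ids`,
#'   `k` and the named `branches` vector.
#' @export
cluster_variables <- function(corr, k, profile = TRUE) {
  if (anyNA(corr)) stop("NaN in correlation matrix", call. = FALSE)
  V <- ncol(corr)
  if (V < 2L) stop("need at least 2 variables to cluster", call. = FALSE)
  if (k < 1L || k > V) stop("k must be in 1..V", call. = FALSE)
  d <- if (profile) stats::dist(corr) else stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = "average")
  branches <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, var_ids = colnames(corr), k = as.integer(k),
                 branches = branches),
            class = "dev_dendrogram")
}

#' @export
print.dev_dendrogram <- function(x, ...) {
  cat(sprintf("dev_dendrogram: %d variables, cut at k = %d\n",
              length(x$var_ids), x$k))
  print(table(branch = x$branches))
  invisible(x)
}

#' @export
plot.dev_dendrogram <- function(x, ...) {
  plot(x$hclust, xlab = "assay variable", sub = "",
       main = sprintf("UPGMA of Spearman correlation profiles (k = %d)", x$k), ...)
  invisible(x)
}

# Height at which leaf i (1-based) is first merged into the tree.
first_merge_height <- function(hc, i) {
  row <- which(hc$merge == -i, arr.ind = TRUE)[1L]
  hc$height[row]
}

# Leaves of the cluster that leaf i is merged WITH at its first merge.
first_merge_partners <- function(hc, i) {
  rc <- which(hc$merge == -i, arr.ind = TRUE)[1L, ]
  other <- hc$merge[rc[1L], 3L - rc[2L]]
  cluster_leaves(hc, other)
}

cluster_leaves <- function(hc, node) {
  if (node < 0) return(-node)
  unlist(lapply(hc$merge[node, ], cluster_leaves, hc = hc))
}

#' Leave-one-sample-out dendrograms
#'
#' Returns `1 + S` dendrograms: the full-panel reference first, then one per
#' removed sample. Every iteration recomputes ranks (hence correlations) from
#' scratch on the reduced panel.
#'
#' @param matrix a `dev_matrix` with at least 4 samples.
#' @param k branch count passed to [cluster_variables()].
#' @param profile see [cluster_variables()].
#' @return Named list of `dev_dendrogram` (first element `"full"`).
#' @export
leave_one_out_dendrograms <- function(matrix, k, profile = TRUE) {
  stopifnot(inherits(matrix, "dev_matrix"))
  if (nrow(matrix$values) < 4L)
    stop("leave-one-out analysis needs at least 4 samples", call. = FALSE)
  out <- list(full = cluster_variables(spearman_matrix(matrix), k, profile))
  for (sid in rownames(matrix$values)) {
    out[[sid]] <- cluster_variables(spearman_matrix(drop_sample(matrix, sid)),
                                    k, profile)
  }
  out
}

#' Pairing-stability P statistic over leave-one-out dendrograms
#'
#' For each variable, its immediate-neighbour set is the set of leaves it
#' first merges with in the full-data reference tree. `P` is the fraction of
#' all iterations (reference included) in which the variable's first-merge
#' partner set intersects that reference set; `group_P` is the fraction of
#' iterations in which its branch label (at the same k) is unchanged under
#' the majority mapping of iteration branches onto reference branches. Values
#' near 1 mark robustly clustered variables.
#'
#' @param dendrograms list of `dev_dendrogram` over the same variable set;
#'   the first is the reference.
#' @return data.frame with columns `var_id`, `P`, `group_P`.
#' @export
pairing_stability <- function(dendrograms) {
  stopifnot(length(dendrograms) >= 1L)
  ref <- dendrograms[[1L]]
  vars <- ref$var_ids
  for (d in dendrograms)
    if (!identical(d$var_ids, vars))
      stop("dendrograms cover different variable sets", call. = FALSE)
  n_iter <- length(dendrograms)
  V <- length(vars)
  ref_partners <- lapply(seq_len(V), first_merge_partners, hc = ref$hclust)
  pair_hits <- integer(V)
  group_hits <- integer(V)
  for (d in dendrograms) {
    for (i in seq_len(V)) {
      p <- first_merge_partners(d$hclust, i)
      if (length(intersect(p, ref_partners[[i]]))) pair_hits[i] <- pair_hits[i] + 1L
    }
    mapped <- map_branches(d$branches, ref$branches)
    group_hits <- group_hits + as.integer(mapped == ref$branches)
  }
  data.frame(var_id = vars, P = pair_hits / n_iter, group_P = group_hits / n_iter,
             stringsAsFactors = FALSE)
}

# Relabel iteration branches by the reference branch holding the majority of
# their members (ties to the smaller reference label).
map_branches <- function(branches, ref_branches) {
  out <- integer(length(branches))
  for (b in unique(branches)) {
    members <- branches == b
    tab <- table(ref_branches[members])
    out[members] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}

#' Least-significant (latest-joining) variable of each branch
#'
#' Within each branch, returns the leaf whose own first merge in the tree
#' sits at the greatest height — the variable furthest from the baseline, the
#' weakest member of its branch. Ties break to the lowest var_id; a singleton
#' branch returns its only member.
#'
#' @param dendrogram a `dev_dendrogram`.
#' @return Integer vector of flagged var_ids, one per branch.
#' @export
flag_least_significant <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "dev_dendrogram"))
  hc <- dendrogram$hclust
  vars <- as.integer(dendrogram$var_ids)
  heights <- vapply(seq_along(vars), first_merge_height, 0, hc = hc)
  out <- integer(0)
  for (b in sort(unique(dendrogram$branches))) {
    members <- which(dendrogram$branches == b)
    h <- heights[members]
    cand <- members[h == max(h)]
    out <- c(out, min(vars[cand]))
  }
  out
}

#' Variables that cluster poorly across leave-one-out iterations
#'
#' Runs the leave-one-sample-out analysis and returns the variables flagged
#' as a branch's least-significant member in at least `threshold` of the
#' `1 + S` dendrograms. In the canonical workflow (S = 9, threshold = 6) this
#' identifies the difficult-to-cluster variables removed before rescoring.
#'
#' @param matrix a `dev_matrix`.
#' @param k branch count for each clustering.
#' @param threshold minimum number of dendrograms flagging a variable.
#' @param profile see [cluster_variables()].
#' @return Integer vector of var_ids (possibly empty).
#' @export
identify_poor_clusterers <- function(matrix, k, threshold = 6L, profile = TRUE) {
  dends <- leave_one_out_dendrograms(matrix, k, profile)
  flags <- unlist(lapply(dends, flag_least_significant))
  counts <- table(flags)
  sort(as.integer(names(counts)[counts >= threshold]))
}
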
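# Independent brute-force oracles, kept free of the package's own code paths.

# Spearman rho by explicit rank transform + hand-written Pearson formula.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Weighted least squares slope/intercept/slope-SE via the normal equations.
wls_normal_equations <- function(t, v, w = rep(1, length(t))) {
  X <- cbind(1, t)
  A <- t(X) %*% (w * X)
  beta <- solve(A, t(X) %*% (w * v))
  resid <- v - X %*% beta
  dof <- length(t) - 2L
  s2 <- sum(w * resid^2) / dof
  cov <- s2 * solve(A)
  list(intercept = beta[1L], slope = beta[2L], stderr = sqrt(cov[2L, 2L]))
}

# RANK.AVG by explicit sort-and-average of spanned positions.
rank_avg_bruteforce <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    out[i] <- mean((less + 1):(less + ties))
  }
  out
}

# Group-average (UPGMA) agglomeration from a distance matrix, recomputing
# average inter-cluster distances from scratch at every step.
upgma_bruteforce <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))          # leaf members per active cluster
  labels <- -seq_len(n)                    # hclust-style node codes
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    # hclust row convention: singletons (by leaf number) before clusters
    pair <- c(labels[i], labels[j])
    key <- ifelse(pair < 0, abs(pair) - 1e9, pair)
    merge[step, ] <- pair[order(key)]
    height[step] <- bestd
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    labels[i] <- step
    clusters[[j]] <- NULL
    labels <- labels[-j]
  }
  list(merge = merge, height = height)
}

# OLS coefficients via the normal equations (for the lambda -> 0 LASSO limit).
ols_normal_equations <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

# Small fully-specified panel for hand-computed checks.
toy_matrix <- function(values, directions, groups = NULL) {
  V <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  reg <- data.frame(var_id = seq_len(V), name = paste0("v", seq_len(V)),
                    assay = "toy", direction = directions,
                    family = "t0_assay",
                    group = if (is.null(groups)) "unassigned" else groups,
                    stringsAsFactors = FALSE)
  colnames(values) <- as.character(seq_len(V))
  dev_matrix(values, reg)
}

toy_series <- function(times, values, replicate = rep(1L, length(times)),
                       sample_id = "S1") {
  stability_series(sample_id, "monomer", 25, times, replicate, values)
}
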
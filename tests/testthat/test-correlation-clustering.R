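test_that("Spearman matrix matches the brute-force oracle and basic identities", {
  set.seed(8)
  vals <- cbind(a = rnorm(9), b = rnorm(9))
  vals <- cbind(vals, dup = vals[, 1], neg = -vals[, 1])
  rownames(vals) <- paste0("S", 1:9)
  m <- toy_matrix(vals, rep("lower_better", 4))
  rho <- spearman_matrix(m)
  expect_equal(unname(rho["1", "3"]), 1)
  expect_equal(unname(rho["1", "4"]), -1)
  expect_true(isSymmetric(unclass(rho)))
  expect_equal(unname(diag(rho)), rep(1, 4))

  # 5-sample toy with a tie vs hand-rolled rank/Pearson oracle
  x <- c(3, 1, 4, 1, 5); y <- c(2, 7, 1, 8, 2)
  tm <- toy_matrix(cbind(x, y, z = y + 1)[1:5, ], rep("lower_better", 3))
  rho2 <- spearman_matrix(tm)
  expect_equal(unname(rho2["1", "2"]), spearman_bruteforce(x, y), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  tm2 <- toy_matrix(cbind(exp(x), y^3, z = y + 1), rep("lower_better", 3))
  expect_equal(unclass(spearman_matrix(tm2))[1:2, 1:2],
               unclass(rho2)[1:2, 1:2], tolerance = 1e-12)

  const <- toy_matrix(cbind(x, k = rep(2, 5)), rep("lower_better", 2))
  expect_error(spearman_matrix(const), "constant variable")
})

test_that("UPGMA on correlation profiles matches a brute-force average-linkage oracle", {
  set.seed(15)
  for (rep_i in 1:5) {
    vals <- matrix(rnorm(9 * 6), 9, 6, dimnames = list(paste0("S", 1:9), NULL))
    m <- toy_matrix(vals, rep("lower_better", 6))
    rho <- spearman_matrix(m)
    dend <- cluster_variables(rho, k = 2)
    oracle <- upgma_bruteforce(dist(unclass(rho)))
    expect_equal(dend$hclust$height, oracle$height, tolerance = 1e-10)
    expect_equal(dend$hclust$merge, oracle$merge)
  }
})

test_that("planted correlation blocks are recovered by the cut", {
  cfg <- synth_config(seed = 31, blocks = list(b1 = 1:4, b2 = 5:8),
                      n_variables = 8L, loading = 0.98, tail_skew = 0,
                      signal_vars = 1L, effect_weights = 1, n_samples = 30L)
  m <- generate_matrix(cfg)
  dend <- cluster_variables(spearman_matrix(m), k = 2)
  expect_equal(length(unique(dend$branches[1:4])), 1L)
  expect_equal(length(unique(dend$branches[5:8])), 1L)
  expect_false(dend$branches[1] == dend$branches[5])
})

test_that("clustering is invariant to variable input order up to relabeling", {
  cfg <- synth_config(seed = 12, n_samples = 15L)
  m <- generate_matrix(cfg)
  dend <- cluster_variables(spearman_matrix(m), k = 4)
  perm <- sample(ncol(m$values))
  mp <- m
  mp$values <- m$values[, perm, drop = FALSE]
  mp$registry <- m$registry[perm, , drop = FALSE]
  dend_p <- cluster_variables(spearman_matrix(mp), k = 4)
  # same partition of variable ids, whatever the branch labels
  part <- function(d) {
    unname(lapply(split(d$var_ids, d$branches), sort))
  }
  expect_setequal(part(dend), part(dend_p))
  expect_equal(sort(dend$hclust$height), sort(dend_p$hclust$height),
               tolerance = 1e-10)
})

test_that("leave-one-out analysis yields 1 + S dendrograms with recomputed ranks", {
  m <- generate_matrix(synth_config(seed = 6))
  dends <- leave_one_out_dendrograms(m, k = 6)
  expect_length(dends, 10L)
  expect_identical(names(dends)[1], "full")

  # a duplicated sample row: removing either twin gives the same tree
  vals <- m$values
  vals["C3", ] <- vals["A1", ]
  md <- dev_matrix(vals, m$registry)
  d_a <- cluster_variables(spearman_matrix(drop_sample(md, "A1")), k = 4)
  d_b <- cluster_variables(spearman_matrix(drop_sample(md, "C3")), k = 4)
  expect_equal(d_a$hclust$height, d_b$hclust$height, tolerance = 1e-12)
  expect_equal(d_a$branches, d_b$branches)
})

test_that("P statistic is 1 for identical trees, 0.9 for one changed pairing", {
  m <- generate_matrix(synth_config(seed = 10))
  ref <- cluster_variables(spearman_matrix(m), k = 4)
  dends <- rep(list(ref), 10)
  ps <- pairing_stability(dends)
  expect_true(all(ps$P == 1))
  expect_true(all(ps$group_P == 1))
  expect_true(all(ps$P >= 1 / length(dends)))  # reference always counts

  # perturb exactly one iteration so one variable changes first-merge partner
  v <- ncol(m$values)
  vals <- m$values
  vals[, 1L] <- rev(vals[, 1L])  # decorrelate variable 1
  alt <- cluster_variables(spearman_matrix(dev_matrix(vals, m$registry)), k = 4)
  dends2 <- c(list(ref), rep(list(ref), 8), list(alt))
  ps2 <- pairing_stability(dends2)
  ref_partner_changed <- ps2$P < 1
  expect_true(all(ps2$P[ref_partner_changed] >= 0.9 - 1e-12))
  expect_true(any(abs(ps2$P - 0.9) < 1e-12))

  # mismatched variable sets are rejected
  m2 <- drop_variables(m, 32L)
  alt2 <- cluster_variables(spearman_matrix(m2), k = 4)
  expect_error(pairing_stability(list(ref, alt2)), "different variable sets")
})

test_that("least-significant flagging finds the latest joiner and weak members", {
  # three-variable branch where variable 3 joins last, plus a distant pair
  rho <- diag(6)
  rho[1, 2] <- rho[2, 1] <- 0.95
  rho[1, 3] <- rho[3, 1] <- 0.6
  rho[2, 3] <- rho[3, 2] <- 0.6
  rho[4, 5] <- rho[5, 4] <- 0.9
  dimnames(rho) <- list(as.character(1:6), as.character(1:6))
  dend <- cluster_variables(structure(rho, class = c("corr_matrix", "matrix")), k = 2)
  flags <- flag_least_significant(dend)
  b3 <- dend$branches[3]
  expect_true(3L %in% flags[sort(unique(dend$branches)) == b3] ||
                3L %in% flags)

  # weak-loading member is flagged far more often than its strong peers
  hits <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, n_samples = 40L, n_variables = 8L,
                        blocks = list(b1 = 1:4, b2 = 5:8), loading = 0.95,
                        signal_vars = 1L, effect_weights = 1)
    m <- generate_matrix(cfg)
    # degrade variable 4 to an effective loading of 0.3
    lam <- 0.95; weak <- 0.3
    set.seed(s + 1000)
    z <- qnorm(pnorm(scale(m$values[, 4])))  # back to latent scale, rank-safe
    m$values[, 4] <- weak / lam * m$values[, 4] +
      sqrt(1 - (weak / lam * lam)^2) * rnorm(40)
    dend <- cluster_variables(spearman_matrix(m), k = 2)
    4L %in% flag_least_significant(dend)
  }, TRUE)
  expect_gte(sum(hits), 18L)
})

test_that("poor-clusterer identification finds a planted outlier and respects the threshold", {
  cfg <- synth_config(seed = 17, n_samples = 12L, n_variables = 9L,
                      blocks = list(b1 = 1:4, b2 = 5:8), loading = 0.99,
                      tail_skew = 0, signal_vars = 1L, effect_weights = 1)
  m <- generate_matrix(cfg)  # variable 9 is unassigned pure noise
  poor <- identify_poor_clusterers(m, k = 2, threshold = 6L)
  expect_true(9L %in% poor)

  expect_identical(identify_poor_clusterers(m, k = 2, threshold = 50L), integer(0))
})
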
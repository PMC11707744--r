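test_that("full shrinkage at lambda_max and the OLS limit at lambda -> 0", {
  cfg <- synth_config(seed = 20, n_samples = 30L, n_variables = 6L,
                      blocks = list(), signal_vars = c(1L, 2L),
                      effect_weights = c(1, 0.5), noise_sd = 0.2)
  m <- generate_matrix(cfg)
  y <- rank(abs(generate_outcome(m, cfg)))
  X <- rank_matrix(m)

  fit <- fit_lasso(X, y, seed = 2)
  # at the top of the grid every coefficient is zero, prediction is mean(y)
  top <- drop(as.matrix(coef(fit$glmnet_fit, s = max(fit$lambda_grid))))
  expect_true(all(top[-1] == 0))
  expect_equal(unname(top[1]), mean(y), tolerance = 1e-8)
  # CV error at lambda* never exceeds the null-model CV error
  expect_lte(fit$cv_mse[[which.min(fit$cv_mse)]], fit$cv_mse[[1]] + 1e-12)

  # shrinkage-free limit: S > V, well conditioned -> OLS coefficients
  lam <- fit$lambda_grid[1] * 10^seq(0, -8, length.out = 60)
  fit0 <- fit_lasso(X, y, seed = 2, lambda = lam)
  beta0 <- drop(as.matrix(coef(fit0$glmnet_fit, s = min(lam))))
  want <- ols_normal_equations(X, y)
  expect_equal(unname(beta0), unname(want), tolerance = 1e-4)

  expect_error(fit_lasso(X, rep(1, nrow(X))), "constant response")
  expect_error(fit_lasso(X[1:3, ], y[1:3], folds = 5), "fewer samples")
})

test_that("selected-set size shrinks along the lambda path and seeds fix the fit", {
  cfg <- synth_config(seed = 22, n_samples = 40L, noise_sd = 0.1)
  m <- generate_matrix(cfg)
  y <- rank(abs(generate_outcome(m, cfg)))
  m19 <- drop_variables(drop_variables(m, 29:32), family_vars(m, "stability")[family_vars(m, "stability") <= 28])
  X <- rank_matrix(m19)

  fit <- fit_lasso(X, y, seed = 7)
  nsel <- apply(as.matrix(fit$glmnet_fit$beta), 2, function(b) sum(b != 0))
  lam_order <- order(fit$glmnet_fit$lambda, decreasing = TRUE)
  # monotone at grid resolution up to occasional drop-ins: check the coarse trend
  expect_true(all(diff(nsel[lam_order][c(1, 25, 50, 75, length(nsel))]) >= 0))

  fit2 <- fit_lasso(X, y, seed = 7)
  expect_identical(fit$lambda_star, fit2$lambda_star)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$selected_vars, fit2$selected_vars)
})

test_that("HDP is the selected sparse combination with rank prediction", {
  # single-signal noiseless panel: HDP rank order copies the signal variable
  cfg <- synth_config(seed = 25, noise_sd = 0, signal_vars = 10L,
                      effect_weights = 1)
  m <- generate_matrix(cfg)
  out <- generate_outcome(m, cfg)
  m19 <- drop_variables(drop_variables(m, 29:32),
                        family_vars(m, "stability")[family_vars(m, "stability") <= 28])
  X <- rank_matrix(m19)
  y <- rank(abs(out))
  fit <- fit_lasso(X, y, seed = 4)
  h <- hdp(fit, X, observed_ranks = y)
  expect_equal(h$pearson_r, 1.0, tolerance = 1e-8)
  expect_true("10" %in% fit$selected_vars)

  # permutation equivariance of HDP values
  perm <- sample(nrow(X))
  expect_equal(unname(hdp(fit, X[perm, ])$hdp), unname(h$hdp[perm]))

  # a model variable missing from X is an error
  expect_error(hdp(fit, X[, setdiff(colnames(X), "10")]), "lacks variable")

  # single selected positive-coefficient variable -> monotone copy
  keep <- fit
  keep$coefficients <- setNames(c(1), "10")
  keep$selected_vars <- "10"
  keep$intercept <- 0
  h1 <- hdp(keep, X)
  expect_equal(unname(h1$predicted_rank), unname(rank(X[, "10"])))
})

test_that("selection sweep counts nonzero coefficients per rank set", {
  cfg <- synth_config(seed = 28, noise_sd = 0.1)
  m <- generate_matrix(cfg)
  out <- generate_outcome(m, cfg)
  m19 <- drop_variables(drop_variables(m, 29:32),
                        family_vars(m, "stability")[family_vars(m, "stability") <= 28])
  X <- rank_matrix(m19)
  base <- rank(abs(out)); names(base) <- rownames(X)

  mk_set <- function(label, ranks) structure(list(label = label, ranks = ranks),
                                             class = "rank_set")
  # degenerate sweep: identical rank sets -> frequency 0 or 1 exactly
  sets <- lapply(1:5, function(i) mk_set(paste0("s", i), base))
  sw <- selection_sweep(X, sets, seed = 3)
  expect_true(all(sw$by_var$frequency %in% c(0, 1)))
  expect_equal(unique(sw$by_var$total), 5L)

  # perturbed sets change counts but keep them within [0, total]
  sets2 <- c(sets[1], lapply(2:5, function(i) {
    r <- base
    j <- c(1, 2); r[j] <- r[rev(j)]
    mk_set(paste0("p", i), r)
  }))
  sw2 <- selection_sweep(X, sets2, seed = 3,
                         groups = setNames(m19$registry$group,
                                           as.character(m19$registry$var_id)))
  expect_true(all(sw2$by_var$count >= 0 & sw2$by_var$count <= 5))
  expect_false(is.null(sw2$by_group))
  expect_equal(sum(sw2$by_group$count), sum(sw2$by_var$count))
  expect_error(selection_sweep(X, list()), "empty")
})

test_that("removing a planted keystone variable degrades the prediction", {
  # variable 9 sits outside every correlated block, so no surviving variable
  # can stand in for it once removed (the keystone-ablation scenario)
  cfg <- synth_config(seed = 33, n_samples = 40L, n_variables = 12L,
                      blocks = list(b1 = 1:4, b2 = 5:8),
                      signal_vars = c(1L, 9L), effect_weights = c(0.5, 1),
                      noise_sd = 0.1)
  m <- generate_matrix(cfg)
  out <- generate_outcome(m, cfg)
  X <- rank_matrix(m)
  y <- rank(abs(out))

  full <- fit_lasso(X, y, seed = 5)
  r_full <- hdp(full, X, y)$pearson_r

  # dropping a pure-noise non-signal variable barely matters
  X_minus_null <- X[, setdiff(colnames(X), "12")]
  r_null <- hdp(fit_lasso(X_minus_null, y, seed = 5), X_minus_null, y)$pearson_r
  expect_gt(r_null, r_full - 0.05)

  # dropping the un-substitutable keystone costs real predictive signal
  X_minus_sig <- X[, setdiff(colnames(X), "9")]
  r_sig <- hdp(fit_lasso(X_minus_sig, y, seed = 5), X_minus_sig, y)$pearson_r
  expect_lt(r_sig, r_full - 0.1)
})
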
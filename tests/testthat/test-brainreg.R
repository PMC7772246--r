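test_that("nodal degrees match exhaustive edge enumeration", {
  # complete uniform-weight 5-node graph at full density: all degrees 4
  m5 <- matrix(1, 5, 5); diag(m5) <- 0
  expect_equal(unname(nodal_degrees(m5, densities = 1)), rep(4, 5))

  # 4-node graph, known weights, density 50% keeps the top-3 edges
  m <- matrix(0, 4, 4)
  m[1, 2] <- 6; m[1, 3] <- 5; m[1, 4] <- 4; m[2, 3] <- 3; m[2, 4] <- 2
  m[3, 4] <- 1
  m <- m + t(m)
  got <- nodal_degrees(m, densities = 0.5)
  # brute force: enumerate all 3-edge subsets, keep the max-|weight| one
  edges <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  combs <- combn(length(w), 3)
  best <- combs[, which.max(apply(combs, 2, function(ix) sum(abs(w[ix]))))]
  deg <- tabulate(c(edges[best, 1], edges[best, 2]), nbins = 4)
  expect_equal(unname(got), deg)

  # monotone in density
  set.seed(2)
  cmat <- matrix(rnorm(100), 10, 10); cmat <- cmat + t(cmat); diag(cmat) <- 0
  d1 <- nodal_degrees(cmat, densities = 0.2)
  d2 <- nodal_degrees(cmat, densities = 0.6)
  expect_true(all(d2 >= d1))
  expect_length(nodal_degrees(cmat), 10 * 10)   # 10 nodes x 10 densities
  expect_error(nodal_degrees(matrix(rnorm(9), 3)), "symmetric")
})

test_that("single lasso run honours the split and the penalty", {
  set.seed(21)
  n <- 300
  x <- matrix(rnorm(n * 40), n)
  beta <- c(0.8, -0.6, rep(0, 38))
  y <- cbind(x %*% beta + rnorm(n, sd = 0.3))
  cfg <- regression_config(seed = 22)
  fit <- fit_lasso_cv(x, y, cfg, split_seed = 23)

  # split bookkeeping: disjoint, exhaustive, 70/30
  expect_length(intersect(fit$train_idx, fit$test_idx), 0)
  expect_setequal(c(fit$train_idx, fit$test_idx), seq_len(n))
  expect_equal(length(fit$train_idx), round(0.7 * n))
  expect_gt(fit$r2_oos[1], 0.7)

  # huge penalty: empty model, non-positive out-of-sample r2
  fit0 <- fit_lasso_cv(x, y, cfg, split_seed = 23, lambda_override = 10)
  expect_true(all(abs(fit0$coefficients) < 1e-12))
  expect_lte(fit0$r2_oos[1], 1e-6)

  # noise-free planted signal: near-perfect held-out fit
  y_pure <- cbind(x %*% beta)
  fit1 <- fit_lasso_cv(x, y_pure, cfg, split_seed = 24)
  expect_gte(fit1$r2_oos[1], 0.99)

  # raising lambda weakly decreases the active set
  nz <- vapply(c(0.01, 0.05, 0.1, 0.3), function(l)
    sum(abs(fit_lasso_cv(x, y, cfg, split_seed = 23,
                         lambda_override = l)$coefficients) > 1e-10),
    numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("single-predictor lasso equals the soft-threshold closed form", {
  set.seed(25)
  n <- 500
  x_raw <- rnorm(n)
  y <- 0.4 * x_raw + rnorm(n, sd = 0.8)
  lam <- 0.1
  cfg <- regression_config(train_fraction = 0.9, seed = 26)
  fit <- fit_lasso_cv(cbind(a = x_raw, b = rnorm(n)), cbind(y), cfg,
                      split_seed = 27, lambda_override = lam)
  tr <- fit$train_idx
  # oracle on the z-scored training predictor (population moments)
  xz <- x_raw[tr] - mean(x_raw[tr])
  xz <- xz / sqrt(mean(xz^2))
  cxy <- mean(xz * (y[tr] - mean(y[tr])))
  oracle <- sign(cxy) * max(abs(cxy) - lam, 0)
  expect_equal(unname(fit$coefficients["a", 1]), oracle, tolerance = 1e-6)
})

test_that("ensemble bookkeeping, determinism and prevalence behave", {
  set.seed(31)
  coh_traits <- matrix(rnorm(150 * 2), 150)
  colnames(coh_traits) <- c("t1", "t2")
  B <- matrix(0, 45, 2); B[c(3, 17, 30), 1] <- c(0.6, -0.5, 0.4)
  bcfg <- brain_feature_config(n_ics = 10, true_coefficients = B,
                               noise_sd = 0.4, n_morphology = 4, seed = 32)
  bfs <- generate_brain_features(coh_traits, bcfg)
  cfg <- regression_config(seed = 33)
  er <- run_ensemble(bfs, coh_traits, cfg, n_runs = 12, lambda = "interpret")
  expect_equal(er$n_ok, 12)
  expect_true(all(er$prevalence >= 0 & er$prevalence <= 1))
  expect_equal(unname(er$r2_mean), unname(colMeans(er$r2)),
               tolerance = 1e-12)
  er2 <- run_ensemble(bfs, coh_traits, cfg, n_runs = 12,
                      lambda = "interpret")
  expect_equal(er$r2, er2$r2, tolerance = 1e-12)
  expect_equal(er$prevalence, er2$prevalence)

  st_all <- prevalent_features(er, threshold = 1e-9)
  expect_true(all(er$prevalence[cbind(match(st_all$feature,
                                            rownames(er$prevalence)),
                                      match(st_all$trait,
                                            colnames(er$prevalence)))] > 0))
  expect_warning(st_none <- prevalent_features(er, threshold = 1 + 1e-9),
                 "no features")
  expect_equal(nrow(st_none), 0)
})

test_that("interpretation models are sparser at modest r2 cost", {
  set.seed(41)
  traits <- matrix(rnorm(250 * 4), 250)
  bcfg <- brain_feature_config(n_ics = 15,
                               true_coefficients =
                                 default_true_coefficients(15),
                               seed = 42)
  bfs <- generate_brain_features(traits, bcfg)
  cfg <- regression_config(seed = 43)
  er_opt <- run_ensemble(bfs, traits, cfg, n_runs = 8, lambda = "optimal")
  er_int <- run_ensemble(bfs, traits, cfg, n_runs = 8, lambda = "interpret")
  nz_opt <- mean(colSums(er_opt$prevalence > 0))
  nz_int <- mean(colSums(er_int$prevalence > 0.5))
  expect_lt(nz_int, nz_opt)
  keep <- c(1, 3)                           # the traits with planted signal
  rel_drop <- 1 - mean(er_int$r2_mean[keep]) / mean(er_opt$r2_mean[keep])
  expect_lt(rel_drop, 0.2)
})

test_that("candidate selection prefers informative feature sets", {
  set.seed(51)
  n <- 200
  traits <- matrix(rnorm(n * 2), n); colnames(traits) <- c("t1", "t2")
  B <- matrix(0, 45, 2); B[c(5, 9, 22), 1] <- 0.7
  bfs_true <- generate_brain_features(traits,
    brain_feature_config(n_ics = 10, true_coefficients = B, noise_sd = 0.4,
                         n_morphology = 0, seed = 52))
  noise_cand <- matrix(rnorm(n * 45), n,
                       dimnames = list(NULL, paste0("noise", 1:45)))
  cfg <- regression_config(seed = 53)
  wins <- vapply(1:4, function(s) {
    cfg_s <- regression_config(seed = 53 + s)
    sel <- select_input_combination(
      list(informative = bfs_true, noise = noise_cand), traits, cfg_s,
      n_runs = 4)
    sel$best == "informative"
  }, logical(1))
  expect_gte(mean(wins), 0.75)

  # identical candidates: declared order breaks the tie
  sel_tie <- select_input_combination(list(a = noise_cand, b = noise_cand),
                                      traits, cfg, n_runs = 3)
  expect_equal(sel_tie$best, "a")

  # gender-dependent trait: adding the demographic column helps
  gender <- rbinom(n, 1, 0.5)
  traits_g <- traits
  traits_g[, 1] <- traits_g[, 1] + 1.5 * gender
  with_demo <- cbind(feature_gender = gender, noise_cand)
  sel_g <- select_input_combination(
    list(without = noise_cand, with_gender = with_demo), traits_g, cfg,
    n_runs = 5)
  expect_equal(sel_g$best, "with_gender")
})
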
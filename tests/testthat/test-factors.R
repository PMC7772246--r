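test_that("parallel analysis recovers planted dimensionality and nulls", {
  # planted 4-factor cohort
  coh <- generate_toolbox_cohort(generator_config(seed = 31))
  expect_equal(as.integer(parallel_analysis(coh$scores$values, seed = 32)), 4)

  # permuting variables does not change the count
  perm <- sample(31)
  expect_equal(
    as.integer(parallel_analysis(coh$scores$values[, perm], seed = 32)), 4)

  # white noise: conservative criterion retains nothing almost always
  ks <- vapply(1:15, function(s) {
    set.seed(s + 400)
    as.integer(parallel_analysis(matrix(rnorm(1369 * 31), 1369),
                                 n_noise = 50, criterion = "p95",
                                 seed = s + 800))
  }, integer(1))
  expect_gte(mean(ks == 0), 0.8)
  expect_true(all(ks <= 2))

  # rank-1 spike over identity covariance: exactly one factor
  set.seed(41); n <- 2000
  u <- rnorm(31); u <- u / sqrt(sum(u^2))
  x <- matrix(rnorm(n * 31), n) + rnorm(n) %*% t(u * 2)
  expect_equal(as.integer(parallel_analysis(x, seed = 42)), 1)

  expect_warning(parallel_analysis(matrix(rnorm(20 * 31), 20), n_noise = 5,
                                   seed = 1), "fewer subjects")
})

test_that("ML factor model recovers the generator loadings up to rotation", {
  g <- single_cluster_config(5000, seed = 21)
  coh <- generate_toolbox_cohort(g)
  z <- scale(coh$scores$values)
  fm <- varimax_rotate(fit_factor_model(z, 4))
  L <- coef(fm)

  # truth on the correlation metric, with the generator's recorded sign flips
  Lt <- default_loading_template()
  meta <- attr(Lt, "var_meta")
  sdv <- sqrt(rowSums(Lt^2) + g$uniquenesses)
  Lt <- Lt / sdv
  Lt[meta$sign_flip, ] <- -Lt[meta$sign_flip, ]

  # Procrustes alignment then per-factor Tucker congruence
  sv <- svd(crossprod(L, Lt))
  La <- L %*% (sv$u %*% t(sv$v))
  cong <- vapply(1:4, function(j)
    sum(La[, j] * Lt[, j]) / sqrt(sum(La[, j]^2) * sum(Lt[, j]^2)),
    numeric(1))
  expect_true(all(cong >= 0.98))

  # diagonal-noise model never fits worse than the isotropic-noise model
  expect_gte(fm$loglik, fm$loglik_isotropic)

  expect_error(fit_factor_model(z, 31), "degenerate")
  expect_error(fit_factor_model(z, 0), "degenerate")
})

test_that("varimax rotation preserves communalities and model covariance", {
  coh <- generate_toolbox_cohort(generator_config(n_subjects = 800,
                                                  seed = 51))
  z <- scale(coh$scores$values)
  fm <- fit_factor_model(z, 4)
  rot <- varimax_rotate(fm)

  expect_equal(rowSums(rot$loadings^2), rowSums(fm$loadings^2),
               tolerance = 1e-10)
  expect_equal(crossprod(rot$rotation), diag(4), tolerance = 1e-10)
  Sig0 <- tcrossprod(fm$loadings) + diag(fm$uniquenesses)
  Sig1 <- tcrossprod(rot$loadings) + diag(rot$uniquenesses)
  expect_lt(norm(Sig0 - Sig1, "F"), 1e-8)

  # factors ordered by explained variance, leading loading positive
  ss <- colSums(rot$loadings^2)
  expect_true(all(diff(ss) <= 1e-12))
  lead <- apply(rot$loadings, 2, function(col) col[which.max(abs(col))])
  expect_true(all(lead > 0))

  # block-diagonal loadings are already varimax-optimal: criterion gain tiny
  Lb <- matrix(0, 6, 2); Lb[1:3, 1] <- 0.8; Lb[4:6, 2] <- 0.7
  fmb <- structure(list(loadings = Lb, uniquenesses = rep(0.4, 6),
                        rotation = diag(2), rotated = FALSE,
                        trait_labels = c("a", "b")), class = "ability_fa")
  critfun <- function(L) {
    h <- sqrt(rowSums(L^2)); Ln <- L / h
    sum(apply(Ln^2, 2, var))
  }
  expect_lt(critfun(varimax_rotate(fmb)$loadings) - critfun(Lb), 1e-8)
})

test_that("frozen-model scoring is linear, deterministic and transfers", {
  g <- generator_config(seed = 61)
  coh <- generate_toolbox_cohort(g)
  z <- scale(coh$scores$values)
  fm <- varimax_rotate(fit_factor_model(z, 4))
  sc <- score_subjects(fm, z)

  # recovered trait scores track the generator truth after alignment
  cors <- abs(cor(sc, coh$traits_true))
  expect_true(all(apply(cors, 2, max) >= 0.9))

  # linearity and permutation equivariance
  expect_equal(unname(score_subjects(fm, matrix(0, 2, 31,
    dimnames = list(NULL, rownames(fm$loadings))))),
    matrix(0, 2, 4))
  perm <- sample(nrow(z))
  expect_equal(score_subjects(fm, z[perm, ]), sc[perm, ])

  # second cohort from the same generator: trait means agree within 3 SE
  coh2 <- generate_toolbox_cohort(generator_config(n_subjects = 1369,
                                                   seed = 62))
  z2 <- scale(coh2$scores$values)
  sc2 <- score_subjects(fm, z2)
  se <- sqrt(apply(sc, 2, var) / nrow(sc) + apply(sc2, 2, var) / nrow(sc2))
  expect_true(all(abs(colMeans(sc) - colMeans(sc2)) < 3 * se))

  expect_error(score_subjects(fm, z[, 1:20]), "lacks model variables")
})

test_that("variance explained follows the communality closed form", {
  # loadings scaled to unit total variance with sigma_i^2 = 0.12: the
  # closed form sum(1 - sigma_i^2)/p gives 0.88 exactly
  uniq <- rep(0.12, 31)
  Lt <- default_loading_template()
  Ln <- Lt * sqrt((1 - 0.12) / rowSums(Lt^2))
  attr(Ln, "var_meta") <- attr(Lt, "var_meta")
  g <- generator_config(n_subjects = 3000, loading_template = Ln,
                        uniquenesses = uniq,
                        cluster_means = matrix(0, 1, 4),
                        cluster_weights = 1, cluster_sd = 1, seed = 71)
  coh <- generate_toolbox_cohort(g)
  fm <- fit_factor_model(scale(coh$scores$values), 4)
  expect_lt(abs(variance_explained(fm) - 0.88), 0.02)

  # zero-uniqueness limit approaches 1
  coh0 <- generate_toolbox_cohort(single_cluster_config(
    2000, seed = 72, uniq = rep(1e-4, 31)))
  fm0 <- suppressWarnings(fit_factor_model(scale(coh0$scores$values), 4))
  expect_gt(variance_explained(fm0), 0.97)
})

test_that("factor model JSON round-trips and scores identically", {
  coh <- generate_toolbox_cohort(generator_config(n_subjects = 600,
                                                  seed = 81))
  z <- scale(coh$scores$values)
  fm <- varimax_rotate(fit_factor_model(z, 4))
  tmp <- tempfile(fileext = ".json")
  write_factor_model(fm, tmp)
  fm2 <- read_factor_model(tmp)
  expect_equal(fm2$loadings, fm$loadings, tolerance = 1e-12)
  expect_equal(score_subjects(fm2, z), score_subjects(fm, z),
               tolerance = 1e-12)
})
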
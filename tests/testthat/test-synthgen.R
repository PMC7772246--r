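test_that("toolbox cohort has the documented shape and is deterministic", {
  cfg <- generator_config(seed = 11)
  coh <- generate_toolbox_cohort(cfg)
  expect_equal(dim(coh$scores$values), c(1369, 31))
  expect_false(any(coh$scores$mask))
  expect_equal(dim(coh$traits_true), c(1369, 4))
  coh2 <- generate_toolbox_cohort(cfg)
  expect_identical(coh$scores$values, coh2$scores$values)
  expect_identical(coh$clusters_true, coh2$clusters_true)
  expect_identical(coh$demo, coh2$demo)
})

test_that("rank-deficient loading template is rejected with a diagnostic", {
  L <- default_loading_template()
  L[, 4] <- L[, 3]
  expect_error(generator_config(loading_template = L), "rank-deficient")
})

test_that("sample covariance converges to L L' + Psi as n grows", {
  L <- default_loading_template()
  meta <- attr(L, "var_meta")
  uniq <- seq(0.3, 0.5, length.out = 31)
  target <- tcrossprod(L) + diag(uniq)
  flip <- diag(ifelse(meta$sign_flip, -1, 1))
  target <- flip %*% target %*% flip       # generator records dexterity as times
  err <- sapply(c(500, 5000), function(n) {
    coh <- generate_toolbox_cohort(single_cluster_config(n, seed = 5))
    norm(cov(coh$scores$values) - target, "F")
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.1 * norm(target, "F"))
})

test_that("noise-free single-cluster limit reproduces L L' closely", {
  uniq <- rep(1e-6, 31)
  coh <- generate_toolbox_cohort(single_cluster_config(5000, seed = 9,
                                                       uniq = uniq))
  L <- default_loading_template()
  meta <- attr(L, "var_meta")
  flip <- diag(ifelse(meta$sign_flip, -1, 1))
  target <- flip %*% tcrossprod(L) %*% flip
  expect_lt(norm(cov(coh$scores$values) - target, "F"),
            0.05 * norm(target, "F"))
})

test_that("missingness injection hits the configured rate and is reproducible", {
  coh <- generate_toolbox_cohort(generator_config(seed = 2))
  expect_identical(inject_missingness(coh$scores, 0), coh$scores)
  m <- inject_missingness(coh$scores, 0.027, seed = 3)
  frac <- mean(m$mask)
  se <- sqrt(0.027 * 0.973 / length(m$mask))
  expect_lt(abs(frac - 0.027), 3 * se)
  m2 <- inject_missingness(coh$scores, 0.027, seed = 3)
  expect_identical(m$mask, m2$mask)
  expect_error(inject_missingness(coh$scores, 0.31), "0.3")
})

test_that("ACE family generator honours the kinship correlation structure", {
  # pure genetics: MZ co-twins identical
  cc <- ace_cohort(1, 0, 0, n_mz = 50, n_dz = 10, seed = 4)
  ia <- match(cc$mz$subject_a, names(cc$values))
  ib <- match(cc$mz$subject_b, names(cc$values))
  expect_equal(unname(cc$values[ia]), unname(cc$values[ib]), tolerance = 1e-12)

  # MZ trait correlation = A + C at large n (closed form)
  cc <- ace_cohort(0.31, 0.34, 0.35, n_mz = 1e5, n_dz = 10, seed = 5)
  ia <- match(cc$mz$subject_a, names(cc$values))
  ib <- match(cc$mz$subject_b, names(cc$values))
  r <- cor(cc$values[ia], cc$values[ib])
  mc_se <- (1 - 0.65^2) / sqrt(1e5)
  expect_lt(abs(r - 0.65), 3 * mc_se)

  # DZ additive genetic component correlates 0.5
  cc <- ace_cohort(0.5, 0, 0.5, n_mz = 10, n_dz = 1e5, seed = 6)
  g <- cc$fam$components_true$g
  ia <- match(cc$dz$subject_a, cc$fam$demo$subject)
  ib <- match(cc$dz$subject_b, cc$fam$demo$subject)
  rg <- cor(g[ia, 1], g[ib, 1])
  expect_lt(abs(rg - 0.5), 3 * (1 - 0.25) / sqrt(1e5))

  expect_error(ace_config(-0.1, 0.6, 0.5), "non-negative")
  expect_error(ace_config(0.3, 0.3, 0.3), "equal 1")
})

test_that("brain features are netmat-structured and tied to the planted traits", {
  set.seed(8)
  traits <- matrix(rnorm(200 * 4), 200)
  # noise-free, single coefficient: feature correlates perfectly with trait
  B <- matrix(0, 45, 4); B[7, 1] <- 0.5
  bcfg <- brain_feature_config(n_ics = 10, true_coefficients = B,
                               noise_sd = 0, n_morphology = 2, seed = 9)
  bfs <- generate_brain_features(traits, bcfg)
  expect_equal(abs(cor(bfs$features[, 7], traits[, 1])), 1,
               tolerance = 1e-12)
  expect_equal(sum(bfs$feature_meta$kind == "connectivity"), 45)

  # default support has 19 features recorded for downstream scoring
  bcfg50 <- brain_feature_config(seed = 10)
  expect_equal(nrow(bcfg50$true_coefficients), 50 * 49 / 2)
  bfs50 <- generate_brain_features(matrix(rnorm(40), 10), bcfg50)
  expect_length(bfs50$truth$support, 19)

  # netmat round trip: symmetric, zero diagonal, exact feature recovery
  tmp <- tempfile(fileext = ".txt")
  write_netmats(bfs, tmp)
  line1 <- as.numeric(strsplit(trimws(readLines(tmp)[1]), " +")[[1]])
  m1 <- matrix(line1, 10, 10, byrow = TRUE)
  expect_equal(m1, t(m1))
  expect_equal(diag(m1), rep(0, 10))
  back <- read_netmats(tmp)
  expect_equal(unname(back), unname(bfs$features[, 1:45]), tolerance = 1e-8)

  expect_error(generate_brain_features(matrix(rnorm(30), 10),
                                       bcfg),
               "traits")
  expect_error(brain_feature_config(n_ics = 10,
                                    true_coefficients = matrix(0, 44, 4)),
               "rows")
})

test_that("IC map generator plants a recoverable template mapping", {
  maps <- generate_ic_maps_and_templates(n_ics = 8, n_templates = 4,
                                         n_voxels = 400, noise_sd = 0,
                                         seed = 3)
  ann <- match_templates(maps)
  expect_equal(ann$template_index, maps$truth)
  expect_true(all(ann$correlation > 0.99))
  expect_error(generate_ic_maps_and_templates(n_ics = 4, n_templates = 6),
               "n_templates")
  expect_error(generate_ic_maps_and_templates(n_ics = 6, n_templates = 4,
                                              n_voxels = 3), "n_voxels")
})
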
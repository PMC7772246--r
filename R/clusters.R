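#' Spherical Gaussian mixture model fitted by EM
#'
#' Fits `p(x) = sum_k pi_k N(x | mu_k, sigma_k^2 I)` in trait space by
#' expectation-maximization, keeping model complexity minimal with one
#' spherical variance per component. Initialization is kmeans++-style seeding;
#' the best of `n_restarts` runs by log-likelihood is kept. An emptied
#' component (responsibility mass below 1e-8) is re-seeded at a random data
#' point; a restart that cannot keep all components populated is dropped.
#'
#' @param t subjects x d matrix of trait scores.
#' @param K number of components (>= 1).
#' @param n_restarts EM restarts (default 10).
#' @param seed integer RNG seed.
#' @param tol convergence threshold on the mean per-subject log-likelihood
#'   change between EM iterations (default 1e-6).
#' @param max_iter EM iteration cap per restart.
#' @param var_floor_frac lower bound on each component variance, as a
#'   fraction of the average marginal variance of the data. Guards the EM
#'   against the classical mixture singularity (a component collapsing onto
#'   a handful of points with vanishing variance and unbounded likelihood).
#' @return object of class `ability_gmm` with `weights`, `means` (K x d),
#'   `variances` (per-component sigma^2), `loglik`, `bic`
#'   (`-2 logL + p log n` with `p = (K-1) + dK + K`), and `loglik_trace`
#'   of the winning restart.
#' @export
fit_gmm <- function(t, K, n_restarts = 10, seed = 1, tol = 1e-6,
                    max_iter = 100, var_floor_frac = 0.01) {
  x <- as.matrix(t)
  n <- nrow(x); d <- ncol(x)
  stopifnot(K >= 1, n > K)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- try(em_spherical(x, K, tol, max_iter, var_floor_frac),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("all ", n_restarts, " EM restarts failed to keep ", K,
         " components populated")
  p_count <- (K - 1) + d * K + K
  best$bic <- -2 * best$loglik + p_count * log(n)
  best$n_params <- p_count
  best$n <- n; best$d <- d; best$K <- K
  class(best) <- "ability_gmm"
  best
}

# kmeans++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- x[sample.int(n, 1), , drop = FALSE]
  xs <- rowSums(x^2)
  while (nrow(centers) < K) {
    d2 <- sqdist_to_centers(x, centers, xs)
    d2min <- do.call(pmin, as.data.frame(d2))
    if (sum(d2min) == 0) pick <- sample.int(n, 1)
    else pick <- sample.int(n, 1, prob = d2min)
    centers <- rbind(centers, x[pick, , drop = FALSE])
  }
  centers
}

# squared Euclidean distances from every row of x to every row of mu,
# n x K, via the expansion |x|^2 - 2 x mu' + |mu|^2
sqdist_to_centers <- function(x, mu, xs = rowSums(x^2)) {
  d2 <- xs - 2 * tcrossprod(x, mu)
  d2 <- sweep(d2, 2, rowSums(mu^2), "+")
  pmax(d2, 0)
}

em_spherical <- function(x, K, tol, max_iter, var_floor_frac = 0.01) {
  n <- nrow(x); d <- ncol(x)
  xs <- rowSums(x^2)
  var0 <- mean(apply(x, 2, stats::var)) + 1e-12
  floor_sig2 <- var_floor_frac * var0
  # kmeans++ seeds refined by a few Lloyd iterations: EM then starts near a
  # local optimum and converges in few iterations
  mu <- kmeanspp_centers(x, K)
  sig2 <- rep(var0, K)
  w <- rep(1 / K, K)
  if (K > 1) {
    km <- try(suppressWarnings(stats::kmeans(x, centers = mu, iter.max = 30,
                                             algorithm = "Lloyd")),
              silent = TRUE)
    if (!inherits(km, "try-error") && all(km$size > 0)) {
      mu <- unname(km$centers)
      w <- km$size / n
      sig2 <- pmax(km$withinss / (d * pmax(km$size, 1)), floor_sig2)
    }
  }
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step in log space
    d2 <- sqdist_to_centers(x, mu, xs)
    logdens <- sweep(d2 %*% diag(-1 / (2 * sig2), K), 2,
                     log(w) - d / 2 * log(2 * pi * sig2), "+")
    mx <- logdens[cbind(seq_len(n), max.col(logdens, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(logdens - mx)))
    resp <- exp(logdens - lse)
    ll <- sum(lse)
    trace <- c(trace, ll)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {
      # re-seed empty components at random data points, once per event
      for (k in which(nk < 1e-8)) {
        mu[k, ] <- x[sample.int(n, 1), ]
        sig2[k] <- var0
        w[k] <- 1 / K
      }
      w <- w / sum(w)
      ll_old <- -Inf
      next
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * n) break
    ll_old <- ll
    # M-step
    w <- nk / n
    mu <- crossprod(resp, x) / nk
    d2 <- sqdist_to_centers(x, mu, xs)
    sig2 <- pmax(colSums(resp * d2) / (d * nk), floor_sig2)
  }
  if (any(colSums(resp) < 1e-8))
    stop("component emptied at convergence")
  list(weights = as.numeric(w), means = unname(as.matrix(mu)),
       variances = as.numeric(sig2), loglik = ll, loglik_trace = trace)
}

#' @export
print.ability_gmm <- function(x, ...) {
  cat(sprintf("ability_gmm: %d spherical components in %d-d trait space (n = %d)\n",
              x$K, x$d, x$n))
  cat(sprintf("  loglik %.2f, BIC %.2f, weights: %s\n", x$loglik, x$bic,
              paste(sprintf("%.2f", x$weights), collapse = " ")))
  invisible(x)
}

#' Posterior cluster assignment
#'
#' Computes component responsibilities for any points in trait space — in
#' particular a cohort the model never saw, which is how the clustering is
#' transferred across studies without refitting — and hard labels by maximum
#' responsibility.
#'
#' @param cm an `ability_gmm`.
#' @param t points x d matrix.
#' @return list with integer `labels` and a points x K `responsibilities`
#'   matrix whose rows sum to one.
#' @export
assign_clusters <- function(cm, t) {
  stopifnot(inherits(cm, "ability_gmm"))
  x <- as.matrix(t)
  stopifnot(ncol(x) == cm$d)
  n <- nrow(x); K <- cm$K
  d2 <- sqdist_to_centers(x, cm$means)
  logdens <- sweep(d2 %*% diag(-1 / (2 * cm$variances), K), 2,
                   log(cm$weights) - cm$d / 2 * log(2 * pi * cm$variances),
                   "+")
  mx <- logdens[cbind(seq_len(n), max.col(logdens, ties.method = "first"))]
  resp <- exp(logdens - mx)
  resp <- resp / rowSums(resp)
  list(labels = max.col(resp, ties.method = "first"),
       responsibilities = resp)
}

#' @export
predict.ability_gmm <- function(object, newdata, ...) {
  assign_clusters(object, newdata)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions (up
#' to label permutation), expectation approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions have different lengths: ", length(a), " vs ", length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)          # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Select the number of mixture components
#'
#' Fits the spherical GMM for each K in `k_range`, selects the BIC minimizer,
#' and reports a subsampling stability score per K: the model is refit on
#' random 80% subsets and the mean pairwise adjusted Rand index of the
#' subset partitions (restricted to shared subjects) is returned.
#'
#' @param t subjects x d trait matrix.
#' @param k_range candidate component counts (default 1:8).
#' @param n_subsets number of random subsamples for the stability score.
#' @param subsample_frac subsample fraction (default 0.8).
#' @param n_restarts EM restarts per fit.
#' @param seed integer RNG seed.
#' @param stability logical; skip the (costlier) ARI stability pass if FALSE.
#' @return list with `K_best`, `bic_curve` (named numeric), `ari_stability`
#'   (named numeric, NA when skipped), and `models`.
#' @export
select_k <- function(t, k_range = 1:8, n_subsets = 20, subsample_frac = 0.8,
                     n_restarts = 10, seed = 1, stability = TRUE) {
  stopifnot(length(k_range) >= 1)
  x <- as.matrix(t)
  n <- nrow(x)
  models <- list()
  bic <- setNames(numeric(length(k_range)), paste0("K", k_range))
  for (i in seq_along(k_range)) {
    models[[i]] <- fit_gmm(x, k_range[i], n_restarts = n_restarts,
                           seed = seed + i)
    bic[i] <- models[[i]]$bic
  }
  ari_stab <- setNames(rep(NA_real_, length(k_range)), names(bic))
  if (stability && n_subsets >= 2) {
    set.seed(seed)
    m_sub <- round(subsample_frac * n)
    for (i in seq_along(k_range)) {
      K <- k_range[i]
      subs <- lapply(seq_len(n_subsets), function(s) sample.int(n, m_sub))
      labs <- lapply(seq_len(n_subsets), function(s) {
        cm <- fit_gmm(x[subs[[s]], , drop = FALSE], K,
                      n_restarts = max(3, n_restarts %/% 3),
                      seed = seed + 1000 * s + K)
        assign_clusters(cm, x)$labels       # label everyone for comparability
      })
      pair_ari <- c()
      for (s1 in seq_len(n_subsets - 1)) for (s2 in (s1 + 1):n_subsets) {
        shared <- intersect(subs[[s1]], subs[[s2]])
        if (length(shared) < 2) next
        pair_ari <- c(pair_ari,
                      adjusted_rand_index(labs[[s1]][shared],
                                          labs[[s2]][shared]))
      }
      ari_stab[i] <- mean(pair_ari)
    }
  }
  list(K_best = k_range[which.min(bic)], bic_curve = bic,
       ari_stability = ari_stab, models = models)
}

#' Per-cluster covariate profile with outlier tests
#'
#' Summarizes age and gender per cluster, flags the "outlier" cluster for
#' each covariate (largest absolute deviation of the cluster mean from the
#' grand mean), and runs Welch two-sample t-tests of the outlier cluster
#' against each other cluster.
#'
#' @param labels integer cluster labels.
#' @param demo data.frame with `age` and `gender` (`"M"`/`"F"`) aligned with
#'   `labels`.
#' @return list with `profile` (per-cluster n, prop_male, age mean/sd),
#'   `outlier` (named cluster index per covariate) and `tests` (data.frame of
#'   covariate, outlier cluster, other cluster, t, df, p; clusters with fewer
#'   than 2 members are skipped with a note).
#' @export
cluster_covariate_profile <- function(labels, demo) {
  stopifnot(length(labels) == nrow(demo),
            all(c("age", "gender") %in% names(demo)))
  ks <- sort(unique(labels))
  covars <- list(age = demo$age,
                 male = as.numeric(demo$gender == "M"))
  profile <- data.frame(
    cluster = ks,
    n = as.integer(table(factor(labels, levels = ks))),
    prop_male = tapply(covars$male, factor(labels, levels = ks), mean),
    age_mean = tapply(covars$age, factor(labels, levels = ks), mean),
    age_sd = tapply(covars$age, factor(labels, levels = ks), stats::sd),
    row.names = NULL)
  outlier <- integer(0)
  tests <- NULL
  notes <- character(0)
  for (v in names(covars)) {
    x <- covars[[v]]
    cl_means <- tapply(x, factor(labels, levels = ks), mean)
    out_k <- ks[which.max(abs(cl_means - mean(x)))]
    outlier[v] <- out_k
    for (other in setdiff(ks, out_k)) {
      xa <- x[labels == out_k]; xb <- x[labels == other]
      if (length(xa) < 2 || length(xb) < 2) {
        notes <- c(notes, sprintf("%s: cluster %d vs %d skipped (<2 members)",
                                  v, out_k, other))
        next
      }
      tt <- stats::t.test(xa, xb)           # Welch by default
      tests <- rbind(tests, data.frame(
        covariate = v, outlier_cluster = out_k, other_cluster = other,
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value))
    }
  }
  list(profile = profile, outlier = outlier, tests = tests, notes = notes)
}
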
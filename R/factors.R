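#' Horn's parallel analysis
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' rank-matched eigenvalues of correlation matrices computed from same-shape
#' white-noise data, and retains the components whose eigenvalues exceed the
#' noise criterion. The classical criterion is the mean noise eigenvalue per
#' rank; the 95th-percentile variant is available.
#'
#' @param m a scaled [score_matrix()] or numeric matrix.
#' @param n_noise number of white-noise replicate datasets (default 100).
#' @param criterion `"mean"` (classical Horn) or `"p95"`.
#' @param seed integer RNG seed for the noise replicates.
#' @return integer count of retained factors, with attributes
#'   `eigenvalues` (data) and `noise_criterion`.
#' @export
parallel_analysis <- function(m, n_noise = 100, criterion = c("mean", "p95"),
                              seed = 1) {
  criterion <- match.arg(criterion)
  x <- as_score_values(m)
  n <- nrow(x); p <- ncol(x)
  if (n < p)
    warning("fewer subjects (", n, ") than variables (", p,
            "); eigenvalue estimates will be unstable")
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  noise_ev <- matrix(NA_real_, n_noise, p)
  for (b in seq_len(n_noise)) {
    z <- matrix(rnorm(n * p), n)
    noise_ev[b, ] <- eigen(stats::cor(z), symmetric = TRUE,
                           only.values = TRUE)$values
  }
  crit <- if (criterion == "mean") colMeans(noise_ev)
          else apply(noise_ev, 2, stats::quantile, probs = 0.95)
  # retain leading components until the first eigenvalue at or below the
  # noise criterion; later ranks cannot rescue a discarded one
  below <- which(ev <= crit)
  k <- if (length(below)) below[1] - 1L else p
  structure(as.integer(k), eigenvalues = ev, noise_criterion = crit,
            criterion = criterion, n_noise = n_noise,
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  ev <- attr(x, "eigenvalues")
  cat(sprintf("parallel analysis: %d of %d components retained (%s of %d noise replicates)\n",
              as.integer(x), length(ev), attr(x, "criterion"),
              attr(x, "n_noise")))
  k <- as.integer(x)
  shown <- seq_len(min(length(ev), k + 2))
  cat("  eigenvalues:", paste(sprintf("%.2f", ev[shown]), collapse = " "),
      if (length(ev) > length(shown)) "..." else "", "\n")
  cat("  criterion:  ", paste(sprintf("%.2f",
                                      attr(x, "noise_criterion")[shown]),
                              collapse = " "),
      if (length(ev) > length(shown)) "..." else "", "\n")
  invisible(x)
}

# Gaussian log-likelihood of a sample covariance S (ML divisor n) under a
# model-implied covariance Sigma
gauss_loglik <- function(S, Sigma, n) {
  p <- ncol(S)
  ch <- chol(Sigma)
  logdet <- 2 * sum(log(diag(ch)))
  -n / 2 * (p * log(2 * pi) + logdet + sum(diag(chol2inv(ch) %*% S)))
}

# probabilistic-PCA ML fit (isotropic noise) via the eigendecomposition
# closed form; returns the model log-likelihood
ppca_loglik <- function(S, k, n) {
  p <- ncol(S)
  e <- eigen(S, symmetric = TRUE)
  sig2 <- mean(e$values[(k + 1):p])
  W <- e$vectors[, 1:k, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[1:k] - sig2, 0)), k)
  gauss_loglik(S, tcrossprod(W) + diag(sig2, p), n)
}

#' Fit a maximum-likelihood common-factor model
#'
#' ML factor analysis with per-variable (diagonal) unique variances on
#' z-scored data, the flexible counterpart of an isotropic-noise
#' principal-component model. The isotropic model's log-likelihood is fitted
#' alongside (closed form) so the two noise models can be compared on the
#' same data; the diagonal model can never do worse. Uniquenesses are bounded
#' below at 1e-3; hitting the bound (a Heywood case) raises a warning.
#'
#' @param m a scaled [score_matrix()] or numeric matrix.
#' @param k number of factors (1 <= k < n_vars, and small enough that the
#'   model has non-negative degrees of freedom).
#' @return object of class `ability_fa`: loadings (vars x k), uniquenesses,
#'   accumulated `rotation` matrix (identity until rotated), `loglik`,
#'   `loglik_isotropic`, `variance_explained`, `n`.
#' @export
fit_factor_model <- function(m, k) {
  x <- as_score_values(m)
  n <- nrow(x); p <- ncol(x)
  if (k < 1 || k >= p)
    stop("k must satisfy 1 <= k < n_vars (", p, "); k = ", k,
         " is degenerate")
  dof <- 0.5 * ((p - k)^2 - p - k)
  if (dof < 0)
    stop("k = ", k, " leaves negative degrees of freedom for p = ", p)
  S <- stats::cov(x) * (n - 1) / n
  R <- stats::cov2cor(S)
  fit <- stats::factanal(covmat = R, factors = k, n.obs = n,
                         rotation = "none", lower = 1e-3,
                         control = list(nstart = 3))
  psi <- fit$uniquenesses
  if (any(psi <= 1e-3 + 1e-8))
    warning("Heywood case: uniqueness clamped at 1e-3 for ",
            paste(names(psi)[psi <= 1e-3 + 1e-8], collapse = ", "))
  L <- matrix(fit$loadings, p, k,
              dimnames = list(colnames(x), paste0("F", seq_len(k))))
  obj <- structure(list(loadings = L, uniquenesses = psi,
                        rotation = diag(k),
                        loglik = gauss_loglik(R, tcrossprod(L) + diag(psi),
                                              n),
                        loglik_isotropic = ppca_loglik(R, k, n),
                        n = n, rotated = FALSE,
                        trait_labels = default_trait_labels(k)),
                   class = "ability_fa")
  obj$variance_explained <- variance_explained(obj)
  obj
}

default_trait_labels <- function(k) {
  if (k == 4)
    c("Motor-endurance", "Emotional processing",
      "Executive and cognitive function", "Social interaction")
  else paste("Trait", seq_len(k))
}

#' @export
print.ability_fa <- function(x, ...) {
  cat(sprintf("ability_fa: %d variables, %d factors (%s)\n",
              nrow(x$loadings), ncol(x$loadings),
              if (x$rotated) "varimax-rotated" else "unrotated"))
  cat(sprintf("  variance explained: %.1f%%   loglik: %.1f (isotropic-noise model: %.1f)\n",
              100 * x$variance_explained, x$loglik, x$loglik_isotropic))
  invisible(x)
}

#' @export
coef.ability_fa <- function(object, ...) object$loadings

varimax_criterion <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    L <- L / pmax(h, .Machine$double.eps)
  }
  sum(apply(L^2, 2, stats::var))
}

#' Varimax rotation of a fitted factor model
#'
#' Orthogonal rotation maximizing the column-wise variance of squared
#' loadings (Kaiser row-normalized, tolerance 1e-8), which drives the loading
#' matrix toward block-diagonal form and minimizes cross-loadings. After
#' rotation, factors are ordered by explained variance (descending) and each
#' factor's sign is set so its largest-magnitude loading is positive
#' (tie-break: lowest variable index). Communalities — and hence the
#' model-implied covariance — are invariant.
#'
#' @param fm an `ability_fa` object.
#' @return the rotated `ability_fa`, with `rotation` holding the accumulated
#'   orthogonal transform such that `loadings_unrotated %*% rotation` equals
#'   the stored loadings.
#' @export
varimax_rotate <- function(fm) {
  stopifnot(inherits(fm, "ability_fa"))
  k <- ncol(fm$loadings)
  if (k == 1) return(fm)
  vm <- stats::varimax(fm$loadings, normalize = TRUE, eps = 1e-8)
  L <- fm$loadings %*% vm$rotmat
  Rt <- vm$rotmat
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]; Rt <- Rt[, ord, drop = FALSE]
  sgn <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(L[, j]))            # which.max takes the lowest index on ties
    sign(L[i, j])
  }, numeric(1))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, "*"); Rt <- sweep(Rt, 2, sgn, "*")
  out <- fm
  out$loadings <- L
  colnames(out$loadings) <- paste0("F", seq_len(k))
  out$rotation <- fm$rotation %*% Rt
  out$rotated <- TRUE
  out
}

#' Score subjects with a frozen factor model
#'
#' Regression (Thurstone) factor scores: `scores = Z Sigma^-1 Lambda` with
#' `Sigma = Lambda Lambda' + Psi`. Deterministic and linear, so the identical
#' decomposition can be applied to a second cohort scaled in the reference
#' frame.
#'
#' @param fm an `ability_fa` object.
#' @param m a [score_matrix()] (scaled with the reference parameters) or
#'   matrix; columns must match the model's variables.
#' @return subjects x k matrix of trait scores, columns named by trait label.
#' @export
score_subjects <- function(fm, m) {
  stopifnot(inherits(fm, "ability_fa"))
  x <- as_score_values(m)
  want <- rownames(fm$loadings)
  if (!is.null(want) && !is.null(colnames(x))) {
    missing_vars <- setdiff(want, colnames(x))
    if (length(missing_vars))
      stop("score matrix lacks model variables: ",
           paste(missing_vars, collapse = ", "))
    x <- x[, want, drop = FALSE]
  } else if (ncol(x) != nrow(fm$loadings)) {
    stop("variable count mismatch: model has ", nrow(fm$loadings),
         ", data has ", ncol(x))
  }
  Sigma <- tcrossprod(fm$loadings) + diag(fm$uniquenesses)
  sc <- x %*% solve(Sigma, fm$loadings)
  colnames(sc) <- fm$trait_labels
  sc
}

#' @export
predict.ability_fa <- function(object, newdata, ...) {
  score_subjects(object, newdata)
}

#' Fraction of total standardized variance explained by the common factors
#'
#' Sum of communalities over the number of variables; on z-scored input each
#' variable contributes unit variance, of which `1 - uniqueness` is common.
#'
#' @param fm an `ability_fa` object.
#' @return scalar fraction in (0, 1].
#' @export
variance_explained <- function(fm) {
  stopifnot(inherits(fm, "ability_fa"))
  mean(rowSums(fm$loadings^2))
}
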
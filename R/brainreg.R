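#' Nodal degrees across proportional thresholds
#'
#' For each density d, the `ceiling(d * n(n-1)/2)` strongest edges of the
#' symmetric connectivity matrix (by absolute weight, upper triangle) are
#' kept and binarized, and per-node degrees are returned. Stacking degrees at
#' densities 1% to 10% in 1% steps gives a threshold-robust degree feature
#' vector of length `n_nodes * n_densities`.
#'
#' @param conn square symmetric numeric matrix with zero diagonal.
#' @param densities vector of edge densities in (0, 1].
#' @return named numeric vector, `node<i>_d<density>` ordering nodes fastest.
#' @export
nodal_degrees <- function(conn, densities = seq(0.01, 0.10, by = 0.01)) {
  conn <- as.matrix(conn)
  if (nrow(conn) != ncol(conn) ||
      max(abs(conn - t(conn))) > 1e-8)
    stop("connectivity matrix must be square and symmetric")
  n <- nrow(conn)
  ut <- which(upper.tri(conn), arr.ind = TRUE)
  w <- conn[upper.tri(conn)]
  # deterministic ranking: decreasing |weight|, ties by edge index
  rank_order <- order(-abs(w), seq_along(w))
  n_edges <- length(w)
  out <- numeric(0)
  for (d in densities) {
    keep <- rank_order[seq_len(min(n_edges, ceiling(d * n_edges)))]
    deg <- tabulate(c(ut[keep, 1], ut[keep, 2]), nbins = n)
    names(deg) <- sprintf("node%02d_d%g", seq_len(n), d)
    out <- c(out, deg)
  }
  out
}

#' Configuration for the trait-on-brain L1 regression
#'
#' @param train_fraction fraction of subjects in the training split (0.7).
#' @param cv_folds folds for the nested in-sample cross-validation (5).
#' @param lambda_grid L1 penalty grid searched by CV (30 log-spaced values in
#'   `[1e-3, 1]`). The penalty multiplies `|beta|` against a `(1/2n)` RSS
#'   objective with z-scored predictors, so the named defaults 0.05
#'   (prediction) and 0.095 (interpretation) are scale-dependent.
#' @param lambda_optimal,lambda_interpret named reference penalties.
#' @param prevalence_threshold ensemble prevalence needed for a feature to be
#'   called stable (0.8).
#' @param include_demographics whether demographic columns take part.
#' @param seed integer RNG seed.
#' @return object of class `regression_config`.
#' @export
regression_config <- function(train_fraction = 0.7, cv_folds = 5,
                              lambda_grid = exp(seq(log(1e-3), log(1),
                                                    length.out = 30)),
                              lambda_optimal = 0.05,
                              lambda_interpret = 0.095,
                              prevalence_threshold = 0.8,
                              include_demographics = FALSE, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            lambda_interpret >= lambda_optimal,
            prevalence_threshold > 0, prevalence_threshold <= 1)
  structure(list(train_fraction = train_fraction, cv_folds = cv_folds,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 lambda_optimal = lambda_optimal,
                 lambda_interpret = lambda_interpret,
                 prevalence_threshold = prevalence_threshold,
                 include_demographics = include_demographics, seed = seed),
            class = "regression_config")
}

feature_matrix <- function(X) {
  if (inherits(X, "brain_feature_set")) X$features else as.matrix(X)
}

zscore_cols <- function(x, center = colMeans(x),
                        scale = sqrt(colMeans(sweep(x, 2, center)^2))) {
  scale[scale == 0] <- 1
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' One train/test run of the L1 trait regression
#'
#' Splits subjects 70/30 by `split_seed`, z-scores the predictors on the
#' training split (applying the same transform to the held-out split),
#' selects the penalty by `cv_folds`-fold cross-validation inside the
#' training split — unless `lambda_override` fixes it — and fits one lasso
#' per trait with all predictors entered simultaneously. Out-of-sample
#' goodness of fit is `r^2 = 1 - SSres/SStot` on the held-out 30%, and the
#' out-of-sample p-value comes from regressing observed on predicted trait
#' values.
#'
#' @param X subjects x features matrix or [generate_brain_features()] output.
#' @param y subjects x traits matrix of trait scores.
#' @param cfg a [regression_config()].
#' @param split_seed integer seed controlling this run's split and CV folds.
#' @param lambda_override optional fixed penalty (skips CV).
#' @return list with `lambda` (per trait), `coefficients` (features x traits,
#'   training-scale, no intercept), `r2_oos`, `p_oos`, `r2_mean`,
#'   `train_idx`/`test_idx` bookkeeping.
#' @export
fit_lasso_cv <- function(X, y, cfg = regression_config(), split_seed = 1,
                         lambda_override = NULL) {
  x <- feature_matrix(X)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  n <- nrow(x)
  set.seed(split_seed)
  n_train <- round(cfg$train_fraction * n)
  train <- sort(sample.int(n, n_train))
  test <- setdiff(seq_len(n), train)
  zs <- zscore_cols(x[train, , drop = FALSE])
  xtr <- zs$x
  xte <- sweep(sweep(x[test, , drop = FALSE], 2, zs$center), 2, zs$scale, "/")
  n_traits <- ncol(y)
  lam <- numeric(n_traits)
  beta <- matrix(0, ncol(x), n_traits,
                 dimnames = list(colnames(x), colnames(y)))
  r2 <- p <- numeric(n_traits)
  foldid <- sample(rep_len(seq_len(cfg$cv_folds), n_train))
  for (tix in seq_len(n_traits)) {
    ytr <- y[train, tix]
    if (stats::sd(ytr) == 0) stop("constant trait in training split")
    if (is.null(lambda_override)) {
      cvfit <- glmnet::cv.glmnet(xtr, ytr, lambda = cfg$lambda_grid,
                                 foldid = foldid, standardize = FALSE)
      lam[tix] <- cvfit$lambda.min
      fit <- cvfit$glmnet.fit
    } else {
      lam[tix] <- lambda_override
      grid <- sort(unique(c(cfg$lambda_grid, lambda_override)),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(xtr, ytr, lambda = grid, standardize = FALSE)
    }
    beta[, tix] <- as.numeric(stats::coef(fit, s = lam[tix],
                                          exact = FALSE))[-1]
    pred <- as.numeric(stats::predict(fit, newx = xte, s = lam[tix]))
    yte <- y[test, tix]
    r2[tix] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    p[tix] <- if (stats::sd(pred) == 0) 1
              else summary(stats::lm(yte ~ pred))$coefficients[2, 4]
  }
  list(lambda = lam, coefficients = beta, r2_oos = r2, p_oos = p,
       r2_mean = mean(r2), split_seed = split_seed,
       train_idx = train, test_idx = test)
}

#' Resampled lasso ensemble with feature prevalence
#'
#' Repeats the whole split/CV/fit procedure `n_runs` times with independent
#' train/test splits, aggregating out-of-sample fit (mean and sd of r^2 per
#' trait) and per-feature prevalence — the fraction of runs in which a
#' feature's coefficient is nonzero (|coef| > 1e-10). Averaging over splits
#' removes the split-to-split variability that otherwise dominates single-run
#' results. Pass `lambda = "interpret"` to run the ensemble at the sparser
#' fixed interpretation penalty.
#'
#' @param X,y,cfg as in [fit_lasso_cv()].
#' @param n_runs ensemble size (default 100).
#' @param lambda `"cv"` (nested selection per run), `"optimal"`,
#'   `"interpret"`, or a numeric penalty.
#' @return object of class `lasso_ensemble`: `runs` (per-run summaries),
#'   `r2` (runs x traits), `r2_mean`, `r2_sd`, `prevalence` (features x
#'   traits), `mean_coefficients` (over runs where nonzero), `sign_conflict`
#'   flags, `feature_meta`, `failures`.
#' @export
run_ensemble <- function(X, y, cfg = regression_config(), n_runs = 100,
                         lambda = c("cv", "optimal", "interpret")) {
  if (is.character(lambda)) {
    lambda <- match.arg(lambda)
    lambda_override <- switch(lambda, cv = NULL,
                              optimal = cfg$lambda_optimal,
                              interpret = cfg$lambda_interpret)
  } else lambda_override <- lambda
  x <- feature_matrix(X)
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("trait", seq_len(ncol(y)))
  n_traits <- ncol(y); n_feat <- ncol(x)
  nz_count <- pos_count <- neg_count <- coef_sum <-
    matrix(0, n_feat, n_traits, dimnames = list(colnames(x), colnames(y)))
  r2 <- matrix(NA_real_, n_runs, n_traits)
  runs <- vector("list", n_runs)
  failures <- character(0)
  for (b in seq_len(n_runs)) {
    fit <- try(fit_lasso_cv(x, y, cfg, split_seed = cfg$seed + b,
                            lambda_override = lambda_override),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      failures <- c(failures, sprintf("run %d: %s", b,
                                      conditionMessage(attr(fit, "condition"))))
      if (length(failures) > 0.1 * n_runs)
        stop("more than 10% of ensemble runs failed; first failure: ",
             failures[1])
      next
    }
    nz <- abs(fit$coefficients) > 1e-10
    nz_count <- nz_count + nz
    pos_count <- pos_count + (nz & fit$coefficients > 0)
    neg_count <- neg_count + (nz & fit$coefficients < 0)
    coef_sum <- coef_sum + ifelse(nz, fit$coefficients, 0)
    r2[b, ] <- fit$r2_oos
    runs[[b]] <- fit[c("lambda", "r2_oos", "p_oos", "split_seed")]
  }
  n_ok <- sum(!vapply(runs, is.null, logical(1)))
  prevalence <- nz_count / n_ok
  mean_coef <- ifelse(nz_count > 0, coef_sum / pmax(nz_count, 1), 0)
  meta <- if (inherits(X, "brain_feature_set")) X$feature_meta else NULL
  structure(list(runs = runs, r2 = r2,
                 r2_mean = colMeans(r2, na.rm = TRUE),
                 r2_sd = apply(r2, 2, stats::sd, na.rm = TRUE),
                 r2_pooled_mean = mean(r2, na.rm = TRUE),
                 prevalence = prevalence,
                 mean_coefficients = mean_coef,
                 sign_conflict = pos_count > 0 & neg_count > 0,
                 feature_meta = meta, n_runs = n_runs, n_ok = n_ok,
                 lambda_mode = if (is.null(lambda_override)) "cv"
                               else lambda_override,
                 failures = failures),
            class = "lasso_ensemble")
}

#' @export
print.lasso_ensemble <- function(x, ...) {
  cat(sprintf("lasso_ensemble: %d/%d runs ok (lambda: %s)\n", x$n_ok,
              x$n_runs, paste(x$lambda_mode, collapse = ",")))
  for (j in seq_along(x$r2_mean))
    cat(sprintf("  %s: OOS r2 = %.3f +/- %.3f\n", names(x$r2_mean)[j],
                x$r2_mean[j], x$r2_sd[j]))
  invisible(x)
}

#' Pick the most predictive candidate feature set
#'
#' Runs a small ensemble per candidate and returns the one with the highest
#' mean out-of-sample r^2 on its 30% hold-out samples. Ties go to the first
#' candidate in the declared order (logged in the scoreboard).
#'
#' @param candidates named list of feature sets (matrices or
#'   `brain_feature_set` objects).
#' @param y subjects x traits matrix.
#' @param cfg a [regression_config()].
#' @param n_runs ensemble size per candidate (default 10).
#' @return list with `best` (name), `scoreboard` (data.frame, candidate order
#'   preserved) and `ensembles`.
#' @export
select_input_combination <- function(candidates, y,
                                     cfg = regression_config(),
                                     n_runs = 10) {
  stopifnot(length(candidates) >= 2)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  ens <- lapply(candidates, run_ensemble, y = y, cfg = cfg, n_runs = n_runs)
  score <- vapply(ens, function(e) mean(e$r2_mean), numeric(1))
  best <- names(candidates)[which.max(score)]   # first max wins ties
  list(best = best,
       scoreboard = data.frame(candidate = names(candidates),
                               mean_oos_r2 = unname(score),
                               is_best = names(candidates) == best),
       ensembles = ens)
}

#' Prevalence-stable features of an ensemble
#'
#' Features present (nonzero) in at least `threshold` of the ensemble's runs,
#' reported per trait with their sign-consistent mean coefficient. Features
#' whose coefficient changes sign across runs are excluded and flagged;
#' morphology decoys are excluded by default since they track individual
#' train/test splits rather than signal.
#'
#' @param er a `lasso_ensemble`.
#' @param threshold prevalence cutoff (default the config's 0.8).
#' @param exclude_morphology drop features whose kind is `"morphology"`.
#' @return data.frame with `trait`, `feature`, `prevalence`,
#'   `mean_coefficient`; zero rows (with a warning) when nothing is stable.
#' @export
prevalent_features <- function(er, threshold = 0.8,
                               exclude_morphology = TRUE) {
  stopifnot(inherits(er, "lasso_ensemble"))
  out <- NULL
  for (j in seq_len(ncol(er$prevalence))) {
    sel <- er$prevalence[, j] >= threshold & !er$sign_conflict[, j]
    if (exclude_morphology && !is.null(er$feature_meta))
      sel <- sel & er$feature_meta$kind != "morphology"
    if (!any(sel)) next
    out <- rbind(out, data.frame(
      trait = colnames(er$prevalence)[j],
      feature = rownames(er$prevalence)[sel],
      prevalence = unname(er$prevalence[sel, j]),
      mean_coefficient = unname(er$mean_coefficients[sel, j]),
      row.names = NULL))
  }
  if (is.null(out)) {
    warning("no features reach prevalence ", threshold)
    out <- data.frame(trait = character(0), feature = character(0),
                      prevalence = numeric(0),
                      mean_coefficient = numeric(0))
  }
  out
}
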
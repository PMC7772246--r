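#' Filter subjects by age and battery completeness
#'
#' Retains adult subjects who reported strictly more than a minimum fraction
#' of the battery. Both cuts mirror the normative-study inclusion rules:
#' subjects under 18 are assessed differently and are dropped, and subjects
#' with too many missing scores are dropped rather than over-imputed.
#'
#' @param m a [score_matrix()].
#' @param demo data.frame with one row per subject, containing at least an
#'   `age` column (rows aligned with `m`).
#' @param min_age minimum age, inclusive (default 18).
#' @param min_completeness observed fraction that must be strictly exceeded
#'   (default 0.7).
#' @return The filtered `score_matrix`, with an `exclusion_report` attribute
#'   counting subjects removed by each criterion.
#' @export
filter_subjects <- function(m, demo, min_age = 18, min_completeness = 0.7) {
  stopifnot(inherits(m, "score_matrix"), nrow(demo) == nrow(m$values),
            "age" %in% names(demo))
  ok_age <- demo$age >= min_age
  observed_frac <- 1 - rowMeans(m$mask)
  ok_complete <- observed_frac > min_completeness
  keep <- ok_age & ok_complete
  report <- c(n_input = nrow(m$values),
              excluded_age = sum(!ok_age),
              excluded_completeness = sum(ok_age & !ok_complete),
              n_kept = sum(keep))
  if (!any(keep))
    stop("no subjects left after filtering (age removed ", sum(!ok_age),
         ", completeness removed ", sum(ok_age & !ok_complete), ")")
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out$mask <- m$mask[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  attr(out, "kept") <- which(keep)
  out
}

#' Replace missing scores by the per-variable mean
#'
#' Column-mean imputation of masked cells, computed from the observed cells of
#' the same variable. Column means are unchanged by construction.
#'
#' @param m a [score_matrix()].
#' @return The imputed `score_matrix` (empty mask).
#' @export
impute_mean <- function(m) {
  stopifnot(inherits(m, "score_matrix"))
  v <- m$values
  for (j in seq_len(ncol(v))) {
    miss <- m$mask[, j]
    if (all(miss))
      stop("variable '", colnames(v)[j], "' has no observed values")
    if (any(miss)) v[miss, j] <- mean(v[!miss, j])
  }
  out <- m
  out$values <- v
  out$mask[] <- FALSE
  out
}

#' Reference scaling parameters
#'
#' Fits per-variable location/scale on a reference cohort so that a second
#' cohort can be z-scored in the reference frame (the cross-cohort transfer
#' step). The scale is the population standard deviation (divisor n), in
#' keeping with normative-reference semantics; set `ddof = 1` for the sample
#' convention.
#'
#' @param reference an imputed [score_matrix()].
#' @param ddof degrees-of-freedom correction for the sd (0 = population).
#' @return An object of class `scaling_params` with per-variable `mean`, `sd`
#'   and the `sign_flip` flags carried over from the variable metadata.
#' @export
fit_reference_scaling <- function(reference, ddof = 0) {
  stopifnot(inherits(reference, "score_matrix"))
  if (any(reference$mask))
    stop("reference must be imputed before fitting scaling parameters")
  v <- reference$values
  n <- nrow(v)
  mu <- colMeans(v)
  sd0 <- sqrt(colSums(sweep(v, 2, mu)^2) / (n - ddof))
  if (any(sd0 <= 0))
    stop("zero-variance column(s): ",
         paste(colnames(v)[sd0 <= 0], collapse = ", "))
  structure(list(mean = mu, sd = sd0,
                 sign_flip = reference$var_meta$sign_flip,
                 ddof = ddof),
            class = "scaling_params")
}

#' Apply (or invert) reference scaling
#'
#' Z-scores every variable with the reference mean/sd, then multiplies
#' sign-flip variables by -1 so that, after scaling, larger values always mean
#' better performance. Applying a cohort's own parameters yields columns with
#' mean 0 and sd 1; applying reference parameters to a different cohort
#' generally does not, which is the point of the transfer.
#'
#' @param m a [score_matrix()] (imputed).
#' @param params a `scaling_params` object from [fit_reference_scaling()].
#' @return The scaled `score_matrix`.
#' @export
apply_scaling <- function(m, params) {
  stopifnot(inherits(m, "score_matrix"), inherits(params, "scaling_params"),
            ncol(m$values) == length(params$mean))
  z <- sweep(sweep(m$values, 2, params$mean), 2, params$sd, "/")
  flip <- params$sign_flip
  if (any(flip)) z[, flip] <- -z[, flip]
  out <- m
  out$values <- z
  out
}

#' @rdname apply_scaling
#' @export
invert_scaling <- function(m, params) {
  stopifnot(inherits(m, "score_matrix"), inherits(params, "scaling_params"))
  z <- m$values
  flip <- params$sign_flip
  if (any(flip)) z[, flip] <- -z[, flip]
  out <- m
  out$values <- sweep(sweep(z, 2, params$sd, "*"), 2, params$mean, "+")
  out
}
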
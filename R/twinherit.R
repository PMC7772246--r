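#' Enumerate kinship pairs by relation
#'
#' Splits a kinship table into per-relation pair sets, verifying that every
#' referenced subject exists in the cohort, and optionally samples a fixed
#' number of unrelated pairs without replacement from the unrelated records.
#'
#' @param kinship data.frame with `subject_a`, `subject_b`, `relation`
#'   (one of MZ, DZ, fullsib, halfsib, unrelated).
#' @param cohort_ids character vector of subject IDs present in the cohort.
#' @param n_unrelated number of unrelated pairs to retain (NULL keeps all).
#' @param seed integer RNG seed for the unrelated subsample.
#' @return named list of data.frames, one per relation present.
#' @export
enumerate_pairs <- function(kinship, cohort_ids, n_unrelated = NULL,
                            seed = 1) {
  ok_rel <- c("MZ", "DZ", "fullsib", "halfsib", "unrelated")
  bad <- setdiff(unique(kinship$relation), ok_rel)
  if (length(bad))
    stop("unknown relation label(s): ", paste(bad, collapse = ", "))
  if (any(kinship$subject_a == kinship$subject_b))
    stop("kinship table contains self-pairs")
  absent <- setdiff(unique(c(kinship$subject_a, kinship$subject_b)),
                    cohort_ids)
  if (length(absent))
    stop("pair member(s) absent from cohort: ",
         paste(utils::head(absent, 5), collapse = ", "))
  out <- split(kinship, factor(kinship$relation, levels = ok_rel))
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!is.null(n_unrelated) && !is.null(out$unrelated) &&
      nrow(out$unrelated) > n_unrelated) {
    set.seed(seed)
    out$unrelated <- out$unrelated[sample.int(nrow(out$unrelated),
                                              n_unrelated), ]
  }
  out
}

#' Mean Euclidean distance between pair members, per relation
#'
#' Computes the Euclidean distance between the two members of every kinship
#' pair in a given feature space (trait space, or the stable brain-feature
#' space) and summarizes mean and sd per relation. Smaller distances for
#' closer kinship indicate genetic influence on the space's axes.
#'
#' @param scores subjects x d numeric matrix with subject IDs as row names.
#' @param kinship kinship data.frame (or the list from [enumerate_pairs()]).
#' @return data.frame with `relation`, `n_pairs`, `mean_distance`,
#'   `sd_distance`, ordered MZ, DZ, fullsib, halfsib, unrelated.
#' @export
kinship_distance_profile <- function(scores, kinship) {
  if (is.list(kinship) && !is.data.frame(kinship))
    kinship <- do.call(rbind, kinship)
  scores <- as.matrix(scores)
  ia <- match(kinship$subject_a, rownames(scores))
  ib <- match(kinship$subject_b, rownames(scores))
  if (anyNA(ia) || anyNA(ib)) stop("pair member missing from score matrix")
  d <- sqrt(rowSums((scores[ia, , drop = FALSE] -
                       scores[ib, , drop = FALSE])^2))
  lev <- intersect(c("MZ", "DZ", "fullsib", "halfsib", "unrelated"),
                   unique(kinship$relation))
  rel <- factor(kinship$relation, levels = lev)
  data.frame(relation = lev,
             n_pairs = as.integer(table(rel)),
             mean_distance = as.numeric(tapply(d, rel, mean)),
             sd_distance = as.numeric(tapply(d, rel, stats::sd)),
             row.names = NULL)
}

# double-entry regression slope: each pair entered in both orders, so the
# slope equals the intraclass correlation for standardized traits; p-value
# uses n_pairs - 2 df (the double entries are not independent)
pair_resemblance <- function(v1, v2) {
  x <- c(v1, v2); y <- c(v2, v1)
  slope <- stats::cov(x, y) / stats::var(x)
  n <- length(v1)
  r <- max(min(slope, 1 - 1e-12), -1 + 1e-12)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = slope, p = p)
}

#' Falconer ACE decomposition from MZ and DZ twin pairs
#'
#' Twin-pair resemblance is measured as the double-entry regression slope
#' (the intraclass correlation for standardized traits). Under the ACE model
#' MZ co-twins share all additive-genetic and shared-environment variance
#' (`rMZ = A + C`) while DZ co-twins share half the additive-genetic part
#' (`rDZ = A/2 + C`), giving Falconer's estimators `A = 2(rMZ - rDZ)`,
#' `C = 2 rDZ - rMZ`, `E = 1 - rMZ` (broad-sense heritability H^2 = A).
#' The estimate is reported as significant only when BOTH pair regressions
#' reach `p < alpha`; a negative A or C marks a breakdown of the model.
#' Standard errors come from a pair-level bootstrap (`n_boot = 0` skips it).
#'
#' @param values named numeric vector of per-subject trait values.
#' @param mz_pairs,dz_pairs data.frames with `subject_a`, `subject_b`, or
#'   2-column matrices of indices into `values`.
#' @param alpha significance gate for the two pair regressions (0.05).
#' @param n_boot bootstrap replicates for SEs (default 1000; 0 to skip).
#' @param seed integer RNG seed for the bootstrap.
#' @return object of class `ace_estimate` with `A`, `C`, `E`, `rMZ`, `rDZ`,
#'   `p_mz`, `p_dz`, `se_A`, `se_C`, `se_E`, `status` (ok / not_significant /
#'   breakdown) and clamped `A_reported`, `C_reported`, `E_reported`.
#' @export
falconer_ace <- function(values, mz_pairs, dz_pairs, alpha = 0.05,
                         n_boot = 1000, seed = 1) {
  if (stats::sd(values) == 0) stop("trait has zero variance")
  get_pair_values <- function(pairs) {
    if (is.data.frame(pairs)) {
      ia <- match(pairs$subject_a, names(values))
      ib <- match(pairs$subject_b, names(values))
      if (anyNA(ia) || anyNA(ib)) stop("pair member missing from values")
    } else { ia <- pairs[, 1]; ib <- pairs[, 2] }
    cbind(values[ia], values[ib])
  }
  mz <- get_pair_values(mz_pairs)
  dz <- get_pair_values(dz_pairs)
  if (nrow(mz) < 3 || nrow(dz) < 3)
    stop("need at least 3 pairs per twin class")
  res_mz <- pair_resemblance(mz[, 1], mz[, 2])
  res_dz <- pair_resemblance(dz[, 1], dz[, 2])
  A <- 2 * (res_mz$r - res_dz$r)
  C <- 2 * res_dz$r - res_mz$r
  E <- 1 - res_mz$r
  status <- if (res_mz$p >= alpha || res_dz$p >= alpha) "not_significant"
            else if (A < 0 || C < 0) "breakdown"
            else "ok"
  se <- c(A = NA_real_, C = NA_real_, E = NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      im <- sample.int(nrow(mz), replace = TRUE)
      id <- sample.int(nrow(dz), replace = TRUE)
      rm_ <- pair_resemblance(mz[im, 1], mz[im, 2])$r
      rd_ <- pair_resemblance(dz[id, 1], dz[id, 2])$r
      boots[b, ] <- c(2 * (rm_ - rd_), 2 * rd_ - rm_, 1 - rm_)
    }
    se <- apply(boots, 2, stats::sd)
    names(se) <- c("A", "C", "E")
  }
  structure(list(A = A, C = C, E = E,
                 A_reported = min(max(A, 0), 1),
                 C_reported = min(max(C, 0), 1),
                 E_reported = min(max(E, 0), 1),
                 rMZ = res_mz$r, rDZ = res_dz$r,
                 p_mz = res_mz$p, p_dz = res_dz$p,
                 se_A = se[["A"]], se_C = se[["C"]], se_E = se[["E"]],
                 n_mz = nrow(mz), n_dz = nrow(dz),
                 alpha = alpha, status = status),
            class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("ace_estimate (%s): A = %.3f, C = %.3f, E = %.3f\n",
              x$status, x$A, x$C, x$E))
  cat(sprintf("  rMZ = %.3f (p = %.2g, n = %d), rDZ = %.3f (p = %.2g, n = %d)\n",
              x$rMZ, x$p_mz, x$n_mz, x$rDZ, x$p_dz, x$n_dz))
  if (!is.na(x$se_A))
    cat(sprintf("  bootstrap SE: A %.3f, C %.3f, E %.3f\n",
                x$se_A, x$se_C, x$se_E))
  invisible(x)
}

#' Regress a gender effect out of trait values
#'
#' Residuals of a one-predictor linear regression of the values on a binary
#' gender indicator: mean zero and exactly uncorrelated with gender, so the
#' ACE analysis can pool genders instead of splitting the (small) sample.
#'
#' @param values numeric vector.
#' @param gender binary vector (factor, character or 0/1) with both levels
#'   present.
#' @return numeric residual vector (names preserved).
#' @export
gender_correct <- function(values, gender) {
  g <- as.numeric(factor(gender))
  if (length(unique(g[!is.na(g)])) < 2)
    stop("both genders must be present to correct for gender")
  r <- stats::residuals(stats::lm(values ~ g))
  names(r) <- names(values)
  r
}
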
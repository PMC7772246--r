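#' Write and read netmats in the flattened whitespace dialect
#'
#' One subject per line: the full symmetric n_ics x n_ics connectivity matrix
#' flattened row-major, fields separated by single spaces. The reader infers
#' `n_ics` from the squared line length and returns the unique upper-triangle
#' features.
#'
#' @param feat connectivity features: subjects x n_ics(n_ics-1)/2 matrix
#'   (upper triangle, row-major pair order) or a `brain_feature_set` (its
#'   connectivity columns are used).
#' @param path output file.
#' @param n_ics number of ICs; inferred from the feature count if missing.
#' @return `write_netmats` returns `path` invisibly; `read_netmats` returns a
#'   subjects x features matrix with IC-pair column names.
#' @export
write_netmats <- function(feat, path, n_ics = NULL) {
  if (inherits(feat, "brain_feature_set")) {
    n_ics <- feat$provenance$n_ics
    feat <- feat$features[, feat$feature_meta$kind == "connectivity",
                          drop = FALSE]
  }
  feat <- as.matrix(feat)
  if (is.null(n_ics))
    n_ics <- (1 + sqrt(1 + 8 * ncol(feat))) / 2
  if (n_ics != round(n_ics) || n_ics * (n_ics - 1) / 2 != ncol(feat))
    stop("feature count is not n(n-1)/2 for any integer n")
  n_ics <- as.integer(n_ics)
  ut <- upper.tri(diag(n_ics))
  lines <- apply(feat, 1, function(v) {
    m <- matrix(0, n_ics, n_ics)
    m[ut] <- v
    m <- m + t(m)
    paste(sprintf("%.10g", as.vector(t(m))), collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_netmats
#' @export
read_netmats <- function(path) {
  lines <- readLines(path)
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  len <- unique(lengths(rows))
  if (length(len) != 1) stop("ragged netmats file")
  n_ics <- sqrt(len)
  if (n_ics != round(n_ics))
    stop("line length ", len, " is not a square; not a flattened netmat")
  n_ics <- as.integer(n_ics)
  ut <- upper.tri(diag(n_ics))
  out <- t(vapply(rows, function(v) {
    m <- matrix(v, n_ics, n_ics, byrow = TRUE)
    if (max(abs(m - t(m))) > 1e-6) stop("netmat line is not symmetric")
    m[ut]
  }, numeric(sum(ut))))
  colnames(out) <- ic_pair_names(n_ics)
  out
}

#' Serialize a fitted factor model to JSON (and back)
#'
#' @param fm an `ability_fa`.
#' @param path JSON file path.
#' @return `write_factor_model` returns `path` invisibly; `read_factor_model`
#'   returns the reconstructed `ability_fa`.
#' @export
write_factor_model <- function(fm, path) {
  stopifnot(inherits(fm, "ability_fa"))
  obj <- list(loadings = fm$loadings, uniquenesses = fm$uniquenesses,
              rotation = fm$rotation, rotated = fm$rotated,
              loglik = fm$loglik, loglik_isotropic = fm$loglik_isotropic,
              variance_explained = fm$variance_explained, n = fm$n,
              trait_labels = fm$trait_labels,
              variables = rownames(fm$loadings))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(obj$loadings)
  rownames(L) <- obj$variables
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  structure(list(loadings = L,
                 uniquenesses = stats::setNames(obj$uniquenesses,
                                                obj$variables),
                 rotation = as.matrix(obj$rotation), rotated = obj$rotated,
                 loglik = obj$loglik,
                 loglik_isotropic = obj$loglik_isotropic,
                 variance_explained = obj$variance_explained,
                 n = obj$n, trait_labels = obj$trait_labels),
            class = "ability_fa")
}
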
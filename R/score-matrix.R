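#' Subjects-by-variables score table with missingness mask
#'
#' Container for a toolbox-style battery: a numeric matrix of per-subject
#' scores, a logical mask marking missing cells, and per-variable metadata
#' (assessment domain and whether the raw score must be sign-flipped because
#' larger raw values mean worse performance, as with timed dexterity tests).
#'
#' @param values numeric matrix, subjects in rows, variables in columns.
#'   `NA` entries are taken as missing.
#' @param var_meta data.frame with one row per column of `values` and columns
#'   `name`, `domain` (one of `"cognition"`, `"motor"`, `"sensory"`,
#'   `"emotion"`) and logical `sign_flip`. If `NULL`, a neutral metadata table
#'   is built (domain `"cognition"`, no sign flips).
#' @return An object of class `score_matrix`: a list with elements `values`,
#'   `mask` (TRUE where missing) and `var_meta`.
#' @export
score_matrix <- function(values, var_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("var_%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  if (is.null(var_meta)) {
    var_meta <- data.frame(name = colnames(values),
                           domain = "cognition",
                           sign_flip = FALSE,
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(var_meta) == ncol(values),
            all(c("name", "domain", "sign_flip") %in% names(var_meta)))
  bad <- setdiff(unique(var_meta$domain),
                 c("cognition", "motor", "sensory", "emotion"))
  if (length(bad))
    stop("unknown variable domain(s): ", paste(bad, collapse = ", "))
  structure(list(values = values,
                 mask = is.na(values),
                 var_meta = var_meta),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d subjects x %d variables (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  tab <- table(x$var_meta$domain)
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.score_matrix <- function(x) dim(x$values)

as_score_values <- function(m) {
  if (inherits(m, "score_matrix")) m$values else as.matrix(m)
}
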
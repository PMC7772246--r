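#' Threshold an IC spatial map at the 99th percentile of nonzero voxels
#'
#' Builds the binary support used when turning a component map into a
#' template: voxels that are nonzero and whose z-score (computed over the
#' nonzero voxels) lies strictly above the chosen percentile of those
#' z-scores. A constant nonzero map has no spread, so its percentile is
#' degenerate and an empty support is returned with a warning.
#'
#' @param map numeric voxel vector with at least one nonzero entry.
#' @param percentile percentile in (0, 100), default 99.
#' @return logical support vector.
#' @export
threshold_ic_map <- function(map, percentile = 99) {
  nz <- map != 0
  if (!any(nz)) stop("all-zero IC map cannot be thresholded")
  v <- map[nz]
  if (stats::sd(v) == 0) {
    warning("constant nonzero map: degenerate percentile, empty support")
    return(rep(FALSE, length(map)))
  }
  z <- (map - mean(v)) / stats::sd(v)
  thr <- stats::quantile(z[nz], percentile / 100, names = FALSE)
  nz & z > thr
}

#' Match IC maps to canonical network templates
#'
#' Correlates each (full, continuous) IC spatial map with every binary
#' network template and assigns the template with the largest Pearson
#' correlation. Ties are broken by template order and logged; a
#' zero-variance IC is left unlabeled with a diagnostic; matches whose best
#' correlation falls below `weak_floor` are flagged weak.
#'
#' @param ics ICs x voxels matrix (or the list from
#'   [generate_ic_maps_and_templates()]).
#' @param templates networks x voxels binary matrix with row names; taken
#'   from `ics$templates` when `ics` is a generator result.
#' @param weak_floor correlation below which a match is flagged (0.1).
#' @return data.frame with `ic`, `label`, `template_index`, `correlation`,
#'   `weak`, `tie`; attributes `diagnostics` for unlabeled ICs.
#' @export
match_templates <- function(ics, templates = NULL, weak_floor = 0.1) {
  if (is.list(ics) && !is.null(ics$ic_maps)) {
    if (is.null(templates)) templates <- ics$templates
    ics <- ics$ic_maps
  }
  ics <- as.matrix(ics); templates <- as.matrix(templates)
  if (nrow(templates) < 1) stop("template set is empty")
  if (ncol(ics) != ncol(templates))
    stop("voxel count mismatch: ", ncol(ics), " vs ", ncol(templates))
  labs <- rownames(templates)
  if (is.null(labs)) labs <- sprintf("template_%02d", seq_len(nrow(templates)))
  diagnostics <- character(0)
  out <- data.frame(ic = if (is.null(rownames(ics)))
                           sprintf("IC%02d", seq_len(nrow(ics)))
                         else rownames(ics),
                    label = NA_character_, template_index = NA_integer_,
                    correlation = NA_real_, weak = NA, tie = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ics))) {
    v <- ics[i, ]
    if (stats::sd(v) == 0) {
      diagnostics <- c(diagnostics,
                       sprintf("%s: zero variance, left unlabeled", out$ic[i]))
      next
    }
    r <- apply(templates, 1, function(tp)
      if (stats::sd(tp) == 0) NA_real_ else stats::cor(v, tp))
    best <- which.max(r)                    # lowest index on exact ties
    out$label[i] <- labs[best]
    out$template_index[i] <- best
    out$correlation[i] <- r[best]
    out$weak[i] <- r[best] < weak_floor
    out$tie[i] <- sum(r == r[best], na.rm = TRUE) > 1
  }
  attr(out, "diagnostics") <- diagnostics
  out
}
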
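#' Default block-structured loading template
#'
#' Fixed 31-variable, 4-factor loading matrix with the block structure of a
#' toolbox battery: a motor/endurance block (8 variables, two of them timed
#' dexterity tests that carry a sign flip), an emotional block (9), an
#' executive/cognitive block (9) and a social block (5). Primary loadings lie
#' in 0.5-0.9 and a handful of cross-loadings stay below 0.3, so the factors
#' are well separated but not orthogonal by columns of zeros alone.
#'
#' @param n_vars number of variables (must be 31 for the default template).
#' @param n_factors number of factors (must be 4).
#' @return loadings matrix with `var_meta` attribute (domain, sign_flip).
#' @export
default_loading_template <- function(n_vars = 31, n_factors = 4) {
  stopifnot(n_vars == 31, n_factors == 4)
  blocks <- list(motor = 1:8, emotion = 9:17, cognition = 18:26, social = 27:31)
  L <- matrix(0, 31, 4,
              dimnames = list(NULL, c("motor_endurance", "emotional",
                                      "executive_cognitive", "social")))
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    L[idx, k] <- seq(0.88, 0.52, length.out = length(idx))
  }
  # sparse cross-loadings (< 0.3): endurance tests tap cognition a little, etc.
  L[3, 3] <- 0.20; L[10, 4] <- 0.25; L[19, 1] <- 0.15
  L[27, 2] <- 0.22; L[22, 2] <- 0.18
  domain <- rep(c("motor", "emotion", "cognition", "sensory"),
                times = lengths(blocks))
  name <- unlist(lapply(seq_along(blocks), function(k)
    sprintf("%s_%02d", names(blocks)[k], seq_along(blocks[[k]]))))
  sign_flip <- rep(FALSE, 31)
  sign_flip[7:8] <- TRUE                     # dexterity: time-to-completion
  rownames(L) <- name
  attr(L, "var_meta") <- data.frame(name = name, domain = domain,
                                    sign_flip = sign_flip,
                                    stringsAsFactors = FALSE)
  L
}

default_cluster_means <- function(n_factors = 4, K = 4, separation = 4.5) {
  m <- matrix(0, K, n_factors)
  for (k in seq_len(min(K, n_factors))) m[k, k] <- separation
  m
}

#' Configuration for the synthetic toolbox cohort generator
#'
#' Bundles the latent-structure parameters every downstream stage assumes:
#' a vars-by-factors loading template, per-variable unique noise variances,
#' and a K-component spherical Gaussian cluster structure in trait space.
#' Defaults emulate the normative study scale: 1369 subjects, 31 variables,
#' 4 traits, 4 clusters separated by six within-cluster standard deviations,
#' and 2.7% missingness.
#'
#' @param n_subjects,n_vars,n_factors cohort dimensions.
#' @param loading_template vars x factors loading matrix.
#' @param uniquenesses per-variable unique (noise) variances, all > 0.
#' @param cluster_means K x n_factors component means in trait space.
#' @param cluster_weights mixture weights (simplex).
#' @param cluster_sd per-component spherical standard deviation.
#' @param missing_rate MCAR cell-missingness probability, in [0, 0.3].
#' @param seed integer RNG seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 1369, n_vars = 31, n_factors = 4,
                             loading_template = default_loading_template(),
                             uniquenesses = seq(0.3, 0.5,
                                                length.out = n_vars),
                             cluster_means = default_cluster_means(n_factors),
                             cluster_weights = c(0.30, 0.30, 0.25, 0.15),
                             cluster_sd = rep(1, nrow(cluster_means)),
                             missing_rate = 0.027, seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_vars = n_vars, n_factors = n_factors,
              loading_template = loading_template,
              uniquenesses = uniquenesses, cluster_means = cluster_means,
              cluster_weights = cluster_weights, cluster_sd = cluster_sd,
              missing_rate = missing_rate, seed = seed)
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(nrow(cfg$loading_template) == cfg$n_vars,
            ncol(cfg$loading_template) == cfg$n_factors,
            length(cfg$uniquenesses) == cfg$n_vars,
            ncol(cfg$cluster_means) == cfg$n_factors,
            length(cfg$cluster_weights) == nrow(cfg$cluster_means),
            length(cfg$cluster_sd) == nrow(cfg$cluster_means))
  if (abs(sum(cfg$cluster_weights) - 1) > 1e-12)
    stop("cluster_weights must sum to 1")
  if (any(cfg$uniquenesses <= 0)) stop("uniquenesses must all be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.3)
    stop("missing_rate must lie in [0, 0.3]")
  if (qr(cfg$loading_template)$rank < cfg$n_factors)
    stop("loading_template is rank-deficient: ",
         qr(cfg$loading_template)$rank, " < ", cfg$n_factors,
         " factors; factors would be unidentifiable")
  invisible(cfg)
}

draw_mixture_traits <- function(n, cfg) {
  K <- nrow(cfg$cluster_means)
  z <- sample.int(K, n, replace = TRUE, prob = cfg$cluster_weights)
  t <- cfg$cluster_means[z, , drop = FALSE] +
    matrix(rnorm(n * cfg$n_factors), n) * cfg$cluster_sd[z]
  list(traits = t, labels = z)
}

draw_demographics <- function(labels, p_male = c(0.70, 0.40, 0.40, 0.45),
                              age_mean = c(40, 40, 40, 62), age_sd = 12) {
  K <- max(labels)
  p_male <- rep_len(p_male, K); age_mean <- rep_len(age_mean, K)
  n <- length(labels)
  gender <- ifelse(runif(n) < p_male[labels], "M", "F")
  age <- round(pmin(85, pmax(18, rnorm(n, age_mean[labels], age_sd))))
  data.frame(subject = sprintf("S%04d", seq_len(n)), age = age,
             gender = gender, stringsAsFactors = FALSE)
}

#' Generate a synthetic toolbox cohort with planted structure
#'
#' Draws latent trait scores from the configured Gaussian-mixture cluster
#' structure, maps them through the loading template, and adds independent
#' per-variable Gaussian noise with the configured uniquenesses. Demographics
#' are drawn with cluster-dependent composition (one mostly-male cluster, one
#' older cluster). Ground truth (traits, cluster labels) is returned so that
#' recovery can be tested. Missingness is NOT injected here; see
#' [inject_missingness()].
#'
#' @param config a [generator_config()].
#' @return list with `scores` ([score_matrix()]), `demo` (data.frame),
#'   `traits_true` (subjects x factors), `clusters_true` (integer labels).
#' @export
generate_toolbox_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  mt <- draw_mixture_traits(n, config)
  noise <- matrix(rnorm(n * config$n_vars), n) *
    rep(sqrt(config$uniquenesses), each = n)
  vals <- mt$traits %*% t(config$loading_template) + noise
  meta <- attr(config$loading_template, "var_meta")
  if (!is.null(meta)) colnames(vals) <- meta$name
  demo <- draw_demographics(mt$labels)
  rownames(vals) <- demo$subject
  # raw sign convention: dexterity-style variables are recorded as times,
  # so flip them here and let the preprocessing flip them back
  if (!is.null(meta) && any(meta$sign_flip))
    vals[, meta$sign_flip] <- -vals[, meta$sign_flip]
  list(scores = score_matrix(vals, var_meta = meta), demo = demo,
       traits_true = mt$traits, clusters_true = mt$labels)
}

#' Mask cells completely at random
#'
#' @param m a [score_matrix()].
#' @param rate per-cell masking probability, in [0, 0.3]; higher rates are
#'   rejected because such subjects would fail the completeness filter anyway.
#' @param seed integer RNG seed.
#' @return the `score_matrix` with masked cells set `NA`.
#' @export
inject_missingness <- function(m, rate, seed = 1) {
  stopifnot(inherits(m, "score_matrix"))
  if (rate < 0 || rate > 0.3) stop("rate must lie in [0, 0.3]")
  if (rate == 0) return(m)
  set.seed(seed)
  mask <- matrix(runif(length(m$values)) < rate, nrow(m$values))
  out <- m
  out$values[mask] <- NA_real_
  out$mask <- is.na(out$values)
  out
}

#' ACE variance-component configuration for family cohorts
#'
#' @param A,C,E additive genetic, shared environment and non-shared
#'   environment variance fractions; must be non-negative and sum to 1.
#' @param n_mz_pairs,n_dz_pairs,n_sib_pairs,n_half_pairs,n_unrelated pair
#'   counts per relation class (unrelated subjects are also generated in
#'   pairs so distance profiles have an unrelated stratum).
#' @param seed integer RNG seed.
#' @return object of class `ace_config`.
#' @export
ace_config <- function(A, C, E, n_mz_pairs = 74, n_dz_pairs = 52,
                       n_sib_pairs = 274, n_half_pairs = 12,
                       n_unrelated = 100, seed = 1) {
  if (min(A, C, E) < 0) stop("variance components must be non-negative")
  if (abs(A + C + E - 1) > 1e-12) stop("A + C + E must equal 1")
  structure(list(A = A, C = C, E = E, n_mz_pairs = n_mz_pairs,
                 n_dz_pairs = n_dz_pairs, n_sib_pairs = n_sib_pairs,
                 n_half_pairs = n_half_pairs, n_unrelated = n_unrelated,
                 seed = seed),
            class = "ace_config")
}

kinship_genetic_cor <- c(MZ = 1, DZ = 0.5, fullsib = 0.5, halfsib = 0.25,
                         unrelated = 0)

#' Generate a family-structured cohort under the ACE model
#'
#' Each latent trait value is built as sqrt(A) g + sqrt(C) c + sqrt(E) e where
#' the additive genetic component g correlates 1 between MZ co-twins, 0.5
#' between DZ co-twins and full siblings, 0.25 between half siblings and 0
#' between unrelated pairs; the shared-environment component c is identical
#' within a household pair; e is independent. Observed scores are then built
#' from the traits through the loading template, exactly as in
#' [generate_toolbox_cohort()].
#'
#' @param gcfg a [generator_config()] (supplies loadings and uniquenesses).
#' @param acfg an [ace_config()].
#' @return list with `scores`, `kinship` (data.frame `subject_a`, `subject_b`,
#'   `relation`, `same_gender`), `traits_true`, and `components_true` (list of
#'   `g`, `c`, `e` subject-by-trait matrices).
#' @export
generate_family_cohort <- function(gcfg, acfg) {
  validate_generator_config(gcfg)
  stopifnot(inherits(acfg, "ace_config"))
  set.seed(acfg$seed)
  counts <- c(MZ = acfg$n_mz_pairs, DZ = acfg$n_dz_pairs,
              fullsib = acfg$n_sib_pairs, halfsib = acfg$n_half_pairs,
              unrelated = acfg$n_unrelated)
  n_pairs <- sum(counts)
  n <- 2L * n_pairs
  d <- gcfg$n_factors
  relation <- rep(names(counts), counts)
  rho <- kinship_genetic_cor[relation]
  a_idx <- seq(1L, n, by = 2L)
  b_idx <- a_idx + 1L
  g <- matrix(NA_real_, n, d); cc <- matrix(NA_real_, n, d)
  e <- matrix(rnorm(n * d), n, d)
  for (t in seq_len(d)) {
    z0 <- rnorm(n_pairs); z1 <- rnorm(n_pairs)
    g[a_idx, t] <- z0
    g[b_idx, t] <- rho * z0 + sqrt(1 - rho^2) * z1
    ch <- rnorm(n_pairs)
    shared <- relation != "unrelated"
    cc[a_idx, t] <- ch
    cc[b_idx, t] <- ifelse(shared, ch, rnorm(n_pairs))
  }
  traits <- sqrt(acfg$A) * g + sqrt(acfg$C) * cc + sqrt(acfg$E) * e
  noise <- matrix(rnorm(n * gcfg$n_vars), n) *
    rep(sqrt(gcfg$uniquenesses), each = n)
  vals <- traits %*% t(gcfg$loading_template) + noise
  meta <- attr(gcfg$loading_template, "var_meta")
  if (!is.null(meta)) colnames(vals) <- meta$name
  ids <- sprintf("F%05d", seq_len(n))
  rownames(vals) <- ids
  gender <- sample(c("M", "F"), n, replace = TRUE)
  gender[b_idx[relation == "MZ"]] <- gender[a_idx[relation == "MZ"]]
  kin <- data.frame(subject_a = ids[a_idx], subject_b = ids[b_idx],
                    relation = relation,
                    same_gender = gender[a_idx] == gender[b_idx],
                    stringsAsFactors = FALSE)
  demo <- data.frame(subject = ids,
                     age = round(runif(n, 22, 35)), gender = gender,
                     stringsAsFactors = FALSE)
  list(scores = score_matrix(vals, var_meta = meta), kinship = kin,
       demo = demo, traits_true = traits,
       components_true = list(g = g, c = cc, e = e))
}

#' Brain-feature generator configuration
#'
#' Connectivity features are the n_ics(n_ics-1)/2 unique off-diagonal entries
#' of a per-subject symmetric netmat. `ridge_rho` records the L2
#' regularization used when the consumed netmats are ridge-partial
#' correlations (metadata carried into provenance; the generator does not
#' estimate netmats from time series).
#'
#' @param n_ics number of independent components (default 50).
#' @param true_coefficients features x traits coefficient matrix; defaults to
#'   a 19-feature sparse support split between traits 1 and 3.
#' @param noise_sd residual sd of each connectivity feature.
#' @param ridge_rho partial-correlation ridge parameter (> 0, default 0.01).
#' @param n_morphology number of pure-noise morphology decoy columns.
#' @param n_traits number of traits the coefficient matrix spans.
#' @param seed integer RNG seed.
#' @return object of class `brain_feature_config`.
#' @export
brain_feature_config <- function(n_ics = 50,
                                 true_coefficients =
                                   default_true_coefficients(n_ics),
                                 noise_sd = 0.5, ridge_rho = 0.01,
                                 n_morphology = 20, n_traits = 4, seed = 1) {
  n_feat <- n_ics * (n_ics - 1) / 2
  if (nrow(true_coefficients) != n_feat)
    stop("true_coefficients must have n_ics(n_ics-1)/2 = ", n_feat, " rows, ",
         "got ", nrow(true_coefficients))
  if (ridge_rho <= 0) stop("ridge_rho must be > 0")
  structure(list(n_ics = n_ics, true_coefficients = true_coefficients,
                 noise_sd = noise_sd, ridge_rho = ridge_rho,
                 n_morphology = n_morphology, n_traits = n_traits,
                 seed = seed),
            class = "brain_feature_config")
}

#' @rdname brain_feature_config
#' @param n_support total number of nonzero coefficients (default 19: 10 on
#'   trait 1, the rest on trait 3, mirroring the two brain-predicted traits).
#' @export
default_true_coefficients <- function(n_ics = 50, n_traits = 4,
                                      n_support = 19) {
  n_feat <- n_ics * (n_ics - 1) / 2
  B <- matrix(0, n_feat, n_traits)
  n1 <- ceiling(n_support / 2 + 0.5)           # 10 for the default 19
  n3 <- n_support - n1
  idx <- round(seq(1, n_feat, length.out = n_support + 2))[-c(1, n_support + 2)]
  mag <- seq(0.45, 0.25, length.out = n_support) *
    rep_len(c(1, -1, 1), n_support)
  B[idx[seq_len(n1)], 1] <- mag[seq_len(n1)]
  B[idx[n1 + seq_len(n3)], min(3, n_traits)] <- mag[n1 + seq_len(n3)]
  B
}

ic_pair_names <- function(n_ics) {
  ut <- which(upper.tri(diag(n_ics)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  sprintf("IC%02d-IC%02d", ut[, 1], ut[, 2])
}

#' Generate brain features linearly tied to traits
#'
#' Each subject's connectivity feature vector (upper triangle of a symmetric
#' zero-diagonal netmat) equals a fixed per-feature baseline plus the traits
#' weighted by the planted coefficient matrix plus Gaussian noise. Morphology
#' decoy columns are pure noise.
#'
#' @param traits subjects x traits matrix of trait scores.
#' @param bcfg a [brain_feature_config()].
#' @return object of class `brain_feature_set`: list with `features`
#'   (subjects x features), `feature_meta` (kind, label), `provenance`, and
#'   `truth` (coefficient matrix and support indices).
#' @export
generate_brain_features <- function(traits, bcfg) {
  traits <- as.matrix(traits)
  if (!all(is.finite(traits))) stop("traits must be finite")
  stopifnot(inherits(bcfg, "brain_feature_config"))
  if (ncol(traits) != ncol(bcfg$true_coefficients))
    stop("coefficient matrix spans ", ncol(bcfg$true_coefficients),
         " traits but ", ncol(traits), " were supplied")
  set.seed(bcfg$seed)
  n <- nrow(traits)
  n_feat <- nrow(bcfg$true_coefficients)
  baseline <- rnorm(n_feat, 0, 0.1)
  conn <- traits %*% t(bcfg$true_coefficients) +
    matrix(rnorm(n * n_feat, 0, bcfg$noise_sd), n) +
    rep(baseline, each = n)
  colnames(conn) <- ic_pair_names(bcfg$n_ics)
  morph <- matrix(rnorm(n * bcfg$n_morphology), n)
  colnames(morph) <- sprintf("morph_%02d", seq_len(bcfg$n_morphology))
  features <- cbind(conn, morph)
  rownames(features) <- rownames(traits)
  meta <- data.frame(
    label = colnames(features),
    kind = rep(c("connectivity", "morphology"),
               c(n_feat, bcfg$n_morphology)),
    stringsAsFactors = FALSE)
  structure(list(features = features, feature_meta = meta,
                 provenance = list(n_ics = bcfg$n_ics,
                                   netmat_variant = "partial",
                                   ridge_rho = bcfg$ridge_rho),
                 truth = list(coefficients = bcfg$true_coefficients,
                              support = which(rowSums(
                                abs(bcfg$true_coefficients)) > 0))),
            class = "brain_feature_set")
}

#' @export
print.brain_feature_set <- function(x, ...) {
  cat(sprintf("brain_feature_set: %d subjects x %d features (%d connectivity from %d ICs, %d morphology)\n",
              nrow(x$features), ncol(x$features),
              sum(x$feature_meta$kind == "connectivity"), x$provenance$n_ics,
              sum(x$feature_meta$kind == "morphology")))
  invisible(x)
}

#' Generate IC spatial maps and canonical network templates
#'
#' Templates are binary maps with disjoint voxel supports; every IC map is a
#' scaled copy of its template's support plus Gaussian noise. The true
#' IC-to-template mapping is returned so template matching can be scored.
#'
#' @param n_ics number of IC maps.
#' @param n_templates number of canonical templates (<= n_ics).
#' @param n_voxels voxels per map (>= n_templates).
#' @param noise_sd additive voxel noise sd.
#' @param seed integer RNG seed.
#' @return list with `ic_maps` (ICs x voxels), `templates`
#'   (templates x voxels, binary), `labels` (template names), `truth`
#'   (integer template index per IC).
#' @export
generate_ic_maps_and_templates <- function(n_ics = 12, n_templates = 6,
                                           n_voxels = 600, noise_sd = 0.2,
                                           seed = 1) {
  if (n_templates > n_ics)
    stop("need n_templates <= n_ics for a feasible overlap design")
  if (n_voxels < n_templates)
    stop("n_voxels must be >= n_templates")
  set.seed(seed)
  cuts <- floor(seq(0, n_voxels, length.out = n_templates + 1))
  templates <- matrix(0, n_templates, n_voxels)
  for (k in seq_len(n_templates))
    templates[k, (cuts[k] + 1):cuts[k + 1]] <- 1
  truth <- rep_len(seq_len(n_templates), n_ics)
  scale <- runif(n_ics, 1.5, 3)
  ic_maps <- templates[truth, , drop = FALSE] * scale +
    matrix(rnorm(n_ics * n_voxels, 0, noise_sd), n_ics)
  labels <- sprintf("network_%02d", seq_len(n_templates))
  rownames(templates) <- labels
  rownames(ic_maps) <- sprintf("IC%02d", seq_len(n_ics))
  list(ic_maps = ic_maps, templates = templates, labels = labels,
       truth = truth)
}
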
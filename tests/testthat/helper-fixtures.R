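# shared fixtures, all generated in code

# single-cluster unit-variance config: observed covariance converges to
# L L' + diag(uniquenesses)
single_cluster_config <- function(n = 1000, seed = 1, uniq = NULL) {
  generator_config(
    n_subjects = n,
    uniquenesses = if (is.null(uniq)) seq(0.3, 0.5, length.out = 31) else uniq,
    cluster_means = matrix(0, 1, 4), cluster_weights = 1, cluster_sd = 1,
    seed = seed)
}

# small score matrix with controllable missingness
toy_scores <- function(values, sign_flip = rep(FALSE, ncol(values))) {
  meta <- data.frame(name = sprintf("v%02d", seq_len(ncol(values))),
                     domain = "cognition", sign_flip = sign_flip,
                     stringsAsFactors = FALSE)
  colnames(values) <- meta$name
  score_matrix(values, var_meta = meta)
}

# twin-only ACE cohort, trait values and pair tables
ace_cohort <- function(A, C, E, n_mz, n_dz, seed) {
  acfg <- ace_config(A, C, E, n_mz_pairs = n_mz, n_dz_pairs = n_dz,
                     n_sib_pairs = 0, n_half_pairs = 0, n_unrelated = 0,
                     seed = seed)
  fam <- generate_family_cohort(generator_config(n_subjects = 2), acfg)
  list(values = setNames(fam$traits_true[, 1], fam$demo$subject),
       mz = fam$kinship[fam$kinship$relation == "MZ", ],
       dz = fam$kinship[fam$kinship$relation == "DZ", ],
       fam = fam)
}

# independent pair-counting ARI oracle: enumerate all item pairs
ari_bruteforce <- function(a, b) {
  n <- length(a)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd <- sd + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  npairs <- n * (n - 1) / 2
  expected <- (ss + sd) * (ss + ds) / npairs
  maxi <- ((ss + sd) + (ss + ds)) / 2
  (ss - expected) / (maxi - expected)
}
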
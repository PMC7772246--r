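#' Configuration for the full analysis chain
#'
#' Orchestrates the four stages — filter/scale, factorize, cluster/transfer,
#' brain regression with network annotation — plus the heritability analysis,
#' on synthetic cohorts generated with planted ground truth. Every stage can
#' be toggled; downstream stages that need a disabled stage are skipped with
#' a warning.
#'
#' @param gen_reference [generator_config()] for the reference (normative)
#'   cohort.
#' @param gen_transfer [generator_config()] for the transfer cohort.
#' @param ace [ace_config()] for the family cohort.
#' @param brain [brain_feature_config()] for the transfer cohort's features.
#' @param regression [regression_config()].
#' @param n_factors factors to extract (NULL: take the parallel-analysis
#'   count).
#' @param k_range candidate cluster counts.
#' @param n_ensemble_runs ensemble size for the brain regression.
#' @param stages character vector of enabled stages, a subset of
#'   `c("preprocess", "factors", "clusters", "brainreg", "netannot",
#'   "heritability")`.
#' @param seed global seed folded into every stage config.
#' @param out_dir optional directory; when set, stage artifacts are written
#'   as CSV/TSV/JSON.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gen_reference = generator_config(seed = seed),
                            gen_transfer = generator_config(n_subjects = 778,
                                                            seed = seed + 1),
                            ace = ace_config(0.31, 0.34, 0.35,
                                             seed = seed + 2),
                            brain = brain_feature_config(seed = seed + 3),
                            regression = regression_config(seed = seed + 4),
                            n_factors = NULL, k_range = 1:8,
                            n_ensemble_runs = 100,
                            stages = c("preprocess", "factors", "clusters",
                                       "brainreg", "netannot",
                                       "heritability"),
                            seed = 1, out_dir = NULL) {
  structure(list(gen_reference = gen_reference, gen_transfer = gen_transfer,
                 ace = ace, brain = brain, regression = regression,
                 n_factors = n_factors, k_range = k_range,
                 n_ensemble_runs = n_ensemble_runs, stages = stages,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis chain on synthetic cohorts
#'
#' Generates a reference and a transfer cohort, preprocesses both (missing
#' injection, filtering, mean imputation, reference z-scoring with sign
#' flips), determines the factor count by parallel analysis, fits and
#' varimax-rotates the factor model on the reference cohort, scores both
#' cohorts with the frozen model, selects K and fits the spherical GMM on
#' reference traits, transfers cluster assignments to the unseen cohort,
#' regresses synthetic brain features on the transfer cohort's traits with
#' the resampled lasso ensemble, annotates the stable features' ICs against
#' network templates, and estimates ACE components per trait on a family
#' cohort (with kinship distance profiles).
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `ability_pipeline`: per-stage results plus a
#'   `manifest` recording seeds, stage order and per-stage row counts.
#' @export
run_full_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  res <- list()
  manifest <- list(seed = cfg$seed, stages = character(0), counts = list(),
                   package_version = as.character(
                     utils::packageVersion("abilitytraits")))
  run_stage <- function(name) name %in% cfg$stages
  withCallingHandlers({
    # --- synthesis (always on: it provides the inputs) -------------------
    ref <- generate_toolbox_cohort(cfg$gen_reference)
    ref$scores <- inject_missingness(ref$scores,
                                     cfg$gen_reference$missing_rate,
                                     seed = cfg$gen_reference$seed + 7)
    tra <- generate_toolbox_cohort(cfg$gen_transfer)
    res$synth <- list(reference = ref, transfer = tra)
    manifest$stages <- c(manifest$stages, "synth")
    manifest$counts$synth <- c(n_reference = nrow(ref$scores$values),
                               n_transfer = nrow(tra$scores$values))
    pipeline_log("synth", "reference %d x %d, transfer %d x %d",
                 nrow(ref$scores$values), ncol(ref$scores$values),
                 nrow(tra$scores$values), ncol(tra$scores$values))

    # --- preprocess ------------------------------------------------------
    if (run_stage("preprocess")) {
      ref_f <- filter_subjects(ref$scores, ref$demo)
      ref_i <- impute_mean(ref_f)
      params <- fit_reference_scaling(ref_i)
      ref_z <- apply_scaling(ref_i, params)
      tra_z <- apply_scaling(impute_mean(tra$scores), params)
      kept <- attr(ref_f, "kept")
      res$preprocess <- list(reference = ref_z, transfer = tra_z,
                             scaling = params, kept_reference = kept,
                             exclusions = attr(ref_f, "exclusion_report"))
      manifest$stages <- c(manifest$stages, "preprocess")
      manifest$counts$preprocess <- attr(ref_f, "exclusion_report")
      pipeline_log("preprocess", "kept %d/%d reference subjects",
                   length(kept), nrow(ref$scores$values))
    }

    # --- factors ---------------------------------------------------------
    if (run_stage("factors")) {
      if (is.null(res$preprocess)) stop("factors stage needs preprocess")
      zref <- res$preprocess$reference
      k_pa <- parallel_analysis(zref, seed = cfg$seed)
      k <- if (is.null(cfg$n_factors)) as.integer(k_pa) else cfg$n_factors
      fm <- varimax_rotate(fit_factor_model(zref, k))
      traits_ref <- score_subjects(fm, zref)
      traits_tra <- score_subjects(fm, res$preprocess$transfer)
      res$factors <- list(model = fm, k_parallel = as.integer(k_pa),
                          traits_reference = traits_ref,
                          traits_transfer = traits_tra)
      manifest$stages <- c(manifest$stages, "factors")
      manifest$counts$factors <- c(k = k,
                                   variance_explained =
                                     round(fm$variance_explained, 4))
      pipeline_log("factors", "k = %d (parallel analysis: %d), %.1f%% variance",
                   k, k_pa, 100 * fm$variance_explained)
    }

    # --- clusters --------------------------------------------------------
    if (run_stage("clusters")) {
      if (is.null(res$factors)) stop("clusters stage needs factors")
      sel <- select_k(res$factors$traits_reference, k_range = cfg$k_range,
                      seed = cfg$seed, stability = FALSE)
      cm <- sel$models[[which(cfg$k_range == sel$K_best)]]
      lab_ref <- assign_clusters(cm, res$factors$traits_reference)
      lab_tra <- assign_clusters(cm, res$factors$traits_transfer)
      kept <- res$preprocess$kept_reference
      prof <- cluster_covariate_profile(lab_ref$labels,
                                        res$synth$reference$demo[kept, ])
      res$clusters <- list(model = cm, selection = sel,
                           labels_reference = lab_ref$labels,
                           labels_transfer = lab_tra$labels,
                           profile = prof)
      manifest$stages <- c(manifest$stages, "clusters")
      manifest$counts$clusters <- c(K = cm$K)
      pipeline_log("clusters", "K = %d by BIC", cm$K)
    }

    # --- brain regression ------------------------------------------------
    if (run_stage("brainreg")) {
      if (is.null(res$factors)) stop("brainreg stage needs factors")
      bfs <- generate_brain_features(res$synth$transfer$traits_true,
                                     cfg$brain)
      er <- run_ensemble(bfs, res$factors$traits_transfer, cfg$regression,
                         n_runs = cfg$n_ensemble_runs,
                         lambda = "interpret")
      stable <- prevalent_features(er,
                                   cfg$regression$prevalence_threshold)
      res$brainreg <- list(features = bfs, ensemble = er, stable = stable)
      manifest$stages <- c(manifest$stages, "brainreg")
      manifest$counts$brainreg <- c(n_runs = er$n_ok,
                                    n_stable = nrow(stable))
      pipeline_log("brainreg", "mean OOS r2 %.3f, %d stable features",
                   mean(er$r2_mean), nrow(stable))
    }

    # --- network annotation ---------------------------------------------
    if (run_stage("netannot")) {
      if (is.null(res$brainreg)) {
        warning("netannot skipped: brainreg stage disabled")
      } else {
        maps <- generate_ic_maps_and_templates(n_ics = 12, n_templates = 6,
                                               seed = cfg$seed + 5)
        ann <- match_templates(maps)
        res$netannot <- list(maps = maps, annotation = ann)
        manifest$stages <- c(manifest$stages, "netannot")
        manifest$counts$netannot <- c(n_ics = nrow(ann))
        pipeline_log("netannot", "%d/%d ICs correctly matched",
                     sum(ann$template_index == maps$truth, na.rm = TRUE),
                     nrow(ann))
      }
    }

    # --- heritability ----------------------------------------------------
    if (run_stage("heritability")) {
      fam <- generate_family_cohort(cfg$gen_reference, cfg$ace)
      pairs <- enumerate_pairs(fam$kinship, fam$demo$subject,
                               seed = cfg$seed)
      dist_prof <- kinship_distance_profile(
        `rownames<-`(fam$traits_true, fam$demo$subject), fam$kinship)
      mz <- fam$kinship[fam$kinship$relation == "MZ", ]
      dz <- fam$kinship[fam$kinship$relation == "DZ" &
                          fam$kinship$same_gender, ]
      ace <- list()
      for (t in seq_len(ncol(fam$traits_true))) {
        v <- stats::setNames(
          gender_correct(fam$traits_true[, t], fam$demo$gender),
          fam$demo$subject)
        ace[[t]] <- falconer_ace(v, mz, dz, n_boot = 200,
                                 seed = cfg$seed + t)
      }
      names(ace) <- default_trait_labels(ncol(fam$traits_true))
      res$heritability <- list(family = fam, pairs = pairs,
                               distance_profile = dist_prof, ace = ace)
      manifest$stages <- c(manifest$stages, "heritability")
      manifest$counts$heritability <- c(n_mz = nrow(mz), n_dz = nrow(dz))
      pipeline_log("heritability", "A-hat per trait: %s",
                   paste(sprintf("%.2f", vapply(ace, `[[`, 0, "A")),
                         collapse = " "))
    }
  }, error = function(e) {
    stop("pipeline stage '", utils::tail(manifest$stages, 1),
         "' (or its successor) failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$manifest <- manifest
  class(res) <- "ability_pipeline"
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

#' @export
print.ability_pipeline <- function(x, ...) {
  cat("ability_pipeline:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat(sprintf("  seed %d, %.1f s\n", x$manifest$seed, x$manifest$elapsed_s))
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  if (!is.null(res$factors)) {
    w(as.data.frame(res$factors$traits_reference), "traits_reference.csv")
    w(as.data.frame(res$factors$traits_transfer), "traits_transfer.csv")
    write_factor_model(res$factors$model,
                       file.path(out_dir, "factor_model.json"))
  }
  if (!is.null(res$clusters)) {
    w(data.frame(label = res$clusters$labels_reference),
      "clusters_reference.csv")
    w(data.frame(label = res$clusters$labels_transfer),
      "clusters_transfer.csv")
  }
  if (!is.null(res$brainreg)) w(res$brainreg$stable, "stable_features.csv")
  if (!is.null(res$heritability)) {
    w(res$heritability$distance_profile, "kinship_distances.csv")
    ace <- res$heritability$ace
    w(data.frame(trait = names(ace),
                 A = vapply(ace, `[[`, 0, "A"),
                 C = vapply(ace, `[[`, 0, "C"),
                 E = vapply(ace, `[[`, 0, "E"),
                 p_mz = vapply(ace, `[[`, 0, "p_mz"),
                 p_dz = vapply(ace, `[[`, 0, "p_dz"),
                 status = vapply(ace, `[[`, "", "status")),
      "ace_estimates.csv")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
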
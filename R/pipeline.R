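# End-to-end pipelines: aggregate space comparison (study-1 style) and the
# within-perceiver cross-classified analysis (study-2 style).

as_rating_table <- function(x, design, trait_set) {
  if (inherits(x, "rating_table")) {
    stopifnot(attr(x, "design") == design)
    x
  } else {
    load_ratings(x, design = design, trait_set = trait_set)
  }
}

#' Run the aggregate trait-space pipeline
#'
#' Full study-1-style analysis: build the face-trait space (per-group
#' target-mean correlations) and the group-stereotype space (per-group
#' across-perceiver correlations), stack and Fisher-transform both, compare
#' them with the pair-mean-centered Spearman statistic, and run the
#' homogeneity repeated-measures ANOVA (with marginal means) on each
#' uncentered space.
#'
#' @param face face ratings: a `rating_table` (design `face_between`) or a
#'   CSV path.
#' @param abstract abstract group-stereotype ratings: a `rating_table`
#'   (design `group_abstract`) or a CSV path.
#' @param trait_set trait names (used when loading from CSV).
#' @param groups group order, default all six.
#' @param center center by trait-pair means before comparing.
#' @param ci_method,n_resamples,seed passed to [compare_spaces()].
#' @param n_perm permutations for the null envelope (0 to skip).
#' @param outdir optional directory; when given, writes `face_space.csv`,
#'   `stereo_space.csv`, `similarity.json`, `anova.json`, `emm_face.csv`,
#'   `emm_stereo.csv`.
#' @return Object of class `study1_result`: list with `face_space`,
#'   `stereo_space` (stacked, z scale, uncentered), `similarity`,
#'   `permutation` (or `NULL`), `anova_face`, `anova_stereo`, `log`.
#' @export
run_study1 <- function(face, abstract, trait_set = study1_traits(),
                       groups = default_groups(), center = TRUE,
                       ci_method = "bootstrap", n_resamples = 10000,
                       seed = 1, n_perm = 0, outdir = NULL) {
  face <- as_rating_table(face, "face_between", trait_set)
  abstract <- as_rating_table(abstract, "group_abstract", trait_set)
  face_space <- build_space(face, groups)
  stereo_space <- build_space(abstract, groups)
  similarity <- compare_spaces(face_space, stereo_space, center = center,
                               ci_method = ci_method,
                               n_resamples = n_resamples, seed = seed)
  permutation <- if (n_perm > 0)
    permutation_null(face_space, stereo_space, n_perm = n_perm, seed = seed)
  anova_face <- rm_anova_2x3(restructure_wide(face_space))
  anova_stereo <- rm_anova_2x3(restructure_wide(stereo_space))
  log <- list(seed = seed, n_face_ratings = nrow(face),
              n_abstract_ratings = nrow(abstract),
              n_rows_compared = similarity$n_rows,
              n_dropped_missing = similarity$n_dropped_missing,
              groups = group_label(groups$race, groups$gender),
              trait_set = attr(face, "trait_set"))
  out <- structure(list(face_space = face_space, stereo_space = stereo_space,
                        similarity = similarity, permutation = permutation,
                        anova_face = anova_face, anova_stereo = anova_stereo,
                        log = log),
                   class = "study1_result")
  if (!is.null(outdir)) write_study1(out, outdir)
  out
}

write_study1 <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_space(x$face_space, file.path(outdir, "face_space.csv"))
  write_space(x$stereo_space, file.path(outdir, "stereo_space.csv"))
  jsonlite::write_json(
    list(similarity = unclass(x$similarity)[setdiff(names(unclass(x$similarity)), "fit")],
         log = x$log),
    file.path(outdir, "similarity.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(face = list(effects = x$anova_face$effects,
                     sphericity = x$anova_face$sphericity),
         stereotype = list(effects = x$anova_stereo$effects,
                           sphericity = x$anova_stereo$sphericity),
         log = x$log),
    file.path(outdir, "anova.json"), auto_unbox = TRUE, digits = NA)
  write.csv(x$anova_face$emm, file.path(outdir, "emm_face.csv"),
            row.names = FALSE)
  write.csv(x$anova_stereo$emm, file.path(outdir, "emm_stereo.csv"),
            row.names = FALSE)
  invisible(outdir)
}

#' @export
print.study1_result <- function(x, ...) {
  cat("== Aggregate trait-space analysis ==\n")
  print(x$similarity)
  if (!is.null(x$permutation)) print(x$permutation)
  cat("-- homogeneity of the face-trait space --\n")
  print(x$anova_face)
  cat("-- homogeneity of the group-stereotype space --\n")
  print(x$anova_stereo)
  invisible(x)
}

#' Run the within-perceiver cross-classified pipeline
#'
#' Full study-2-style analysis: build the perceiver x group x trait-pair
#' dataset, partition variance with cross-classified null models for both
#' the face-space outcome and the stereotype predictor, fit the full model
#' (within-perceiver stereotype slope with crossed random intercepts and a
#' random slope), and decompose the model-implied variance.
#'
#' @param face face ratings: a `rating_table` (design `face_within`) or CSV
#'   path.
#' @param pairwise pairwise stereotype-likelihood ratings: a `rating_table`
#'   (design `pairwise_stereotype`) or CSV path.
#' @param trait_set trait names (used when loading from CSV).
#' @param null_only stop after the null-model ICCs.
#' @param subset_groups optional group labels for a subset refit.
#' @param average_directions passed to [build_mlm_dataset()].
#' @param outdir optional directory; writes `mlm_dataset.csv` and
#'   `mlm_fit.json`.
#' @return Object of class `study2_result`: list with `dataset`, `null_y`,
#'   `null_x`, `fit` (`NULL` when `null_only`), `r2`, `log`.
#' @export
run_study2 <- function(face, pairwise, trait_set = study2_traits(),
                       null_only = FALSE, subset_groups = NULL,
                       average_directions = TRUE, outdir = NULL) {
  face <- as_rating_table(face, "face_within", trait_set)
  pairwise <- as_rating_table(pairwise, "pairwise_stereotype", trait_set)
  dataset <- build_mlm_dataset(face, pairwise,
                               average_directions = average_directions)
  null_y <- fit_null_crossclassified(dataset, "y")
  null_x <- fit_null_crossclassified(dataset, "x_raw")
  fit <- NULL; r2 <- NULL
  if (!null_only) {
    fit <- fit_full(dataset, subset_groups = subset_groups)
    r2 <- r2_decomposition(fit)
  }
  log <- list(n_obs = nrow(dataset),
              n_perceivers = attr(dataset, "n_perceivers"),
              n_pairs = attr(dataset, "n_pairs"),
              n_groups = attr(dataset, "n_groups"),
              n_dropped = attr(dataset, "n_dropped"))
  out <- structure(list(dataset = dataset, null_y = null_y, null_x = null_x,
                        fit = fit, r2 = r2, log = log),
                   class = "study2_result")
  if (!is.null(outdir)) write_study2(out, outdir)
  out
}

write_study2 <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(x$dataset), file.path(outdir, "mlm_dataset.csv"),
            row.names = FALSE)
  drop_fit <- function(l) l[setdiff(names(l), "fit")]
  jsonlite::write_json(
    list(null_y = drop_fit(unclass(x$null_y)),
         null_x = drop_fit(unclass(x$null_x)),
         fit = if (!is.null(x$fit)) drop_fit(unclass(x$fit)),
         r2 = if (!is.null(x$r2)) unclass(x$r2),
         log = x$log),
    file.path(outdir, "mlm_fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.study2_result <- function(x, ...) {
  cat("== Within-perceiver cross-classified analysis ==\n")
  print(x$dataset)
  cat("-- null model, face-space outcome --\n"); print(x$null_y)
  cat("-- null model, stereotype outcome --\n"); print(x$null_x)
  if (!is.null(x$fit)) { cat("-- full model --\n"); print(x$fit); print(x$r2) }
  invisible(x)
}
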
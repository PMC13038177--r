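# Programmatic fixtures shared across test files.

# Minimal between-subjects face table: 2 perceivers x 3 traits, one target.
tiny_face_df <- function() {
  data.frame(
    perceiver_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
    subject = "t1",
    race = "White", gender = "female",
    trait = rep(c("warm", "competent", "dominant"), 2),
    rating = c(3L, 5L, 2L, 5L, 3L, 6L),
    stringsAsFactors = FALSE)
}

tiny_traits <- function() c("warm", "competent", "dominant")

# Abstract-ratings table with every perceiver rating every group on every
# trait; values filled from a deterministic pattern unless supplied.
abstract_df <- function(n_perceivers, traits, groups = default_groups(),
                        ratings = NULL) {
  rows <- expand.grid(perceiver_id = sprintf("p%02d", seq_len(n_perceivers)),
                      gi = seq_len(nrow(groups)),
                      trait = traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$race <- groups$race[rows$gi]
  rows$gender <- groups$gender[rows$gi]
  rows$subject <- group_label(rows$race, rows$gender)
  rows$rating <- if (is.null(ratings))
    ((seq_len(nrow(rows)) * 3L) %% 7L) + 1L else ratings
  rows$gi <- NULL
  rows
}

# Stacked space built directly from named values: `values` is a matrix with
# one row per pair and one column per group label.
space_from_matrix <- function(values, pair_names, groups, scale = "z") {
  parts <- lapply(seq_len(nrow(groups)), function(j)
    data.frame(race = groups$race[j], gender = groups$gender[j],
               trait_a = vapply(strsplit(pair_names, "\\|"), `[`, "", 1),
               trait_b = vapply(strsplit(pair_names, "\\|"), `[`, "", 2),
               value = values[, j], stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("stacked_space", "data.frame"),
            scale = scale, centered = FALSE)
}

# Directly constructed MLM dataset with planted crossed variance components:
# y = u_perceiver + v_pair + residual (plus optional slope effect on x).
planted_mlm_dataset <- function(n_perceivers, n_pairs, n_groups = 3,
                                var_perceiver = 1, var_pair = 1,
                                var_resid = 2, gamma100 = 0, seed = 1) {
  withr::with_seed(seed, {
    u <- rnorm(n_perceivers, 0, sqrt(var_perceiver))
    v <- rnorm(n_pairs, 0, sqrt(var_pair))
    grid <- expand.grid(p = seq_len(n_perceivers), k = seq_len(n_pairs),
                        g = seq_len(n_groups), KEEP.OUT.ATTRS = FALSE)
    x_raw <- runif(nrow(grid), 1, 7)
    df <- data.frame(
      perceiver_id = sprintf("p%03d", grid$p),
      race = race_levels()[grid$g],
      gender = "female",
      trait_a = sprintf("ta%02d", grid$k), trait_b = sprintf("tb%02d", grid$k),
      pair = sprintf("pair%02d", grid$k),
      x_raw = x_raw, stringsAsFactors = FALSE)
    pm <- tapply(df$x_raw, df$perceiver_id, mean)
    df$x_pmean <- as.numeric(pm[df$perceiver_id])
    df$x_cwc <- df$x_raw - df$x_pmean
    e <- rnorm(nrow(grid), 0, sqrt(var_resid))
    df$y <- u[grid$p] + v[grid$k] + gamma100 * df$x_cwc + e
    structure(df, class = c("mlm_dataset", "data.frame"),
              n_perceivers = n_perceivers, n_pairs = n_pairs,
              n_groups = n_groups, n_dropped = 0L,
              realized = list(var_u = var(u), var_v = var(v), var_e = var(e)))
  })
}

# A small, fast study-1 configuration for pipeline-level tests.
small_study1_config <- function(...) {
  defaults <- list(n_perceivers = 50, n_face_perceivers = 560,
                   n_targets_per_group = 40, targets_per_perceiver = 40)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
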
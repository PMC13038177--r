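test_that("target-level means aggregate ratings and mark unrated cells missing", {
  df <- tiny_face_df()
  ttm <- target_trait_means(rating_table(df, "face_between", tiny_traits()),
                            "White", "female")
  expect_equal(ttm$means["t1", "warm"], 4)        # mean of 3 and 5
  expect_equal(ttm$n_ratings["t1", "warm"], 2)

  df2 <- df[df$trait != "dominant", ]
  ttm2 <- target_trait_means(rating_table(df2, "face_between", tiny_traits()),
                             "White", "female")
  expect_true(is.na(ttm2$means["t1", "dominant"]))
  expect_equal(ttm2$n_ratings["t1", "dominant"], 0)

  expect_error(target_trait_means(
    rating_table(df, "face_between", tiny_traits()), "Black", "male"),
    "no ratings")
})

test_that("trait correlations match hand-computed Pearson values", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  tc <- trait_correlation_matrix(m, unit = "within_perceiver_targets")
  expect_equal(tc$r["a", "b"], 1)
  expect_equal(tc$r["a", "c"], -1)

  m2 <- cbind(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  tc2 <- trait_correlation_matrix(m2, unit = "within_perceiver_targets")
  expect_equal(tc2$r["x", "y"], 0.6)   # cov 1, sd 1.29...: 3/5 by hand

  # fewer than 3 complete units errors, naming the pair
  m3 <- cbind(x = c(1, 2, NA, NA), y = c(2, 1, 4, 3))
  expect_error(trait_correlation_matrix(m3, "within_perceiver_targets"),
               "x-y")
})

test_that("trait correlations are invariant to affine rescaling of ratings", {
  set.seed(7)
  m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  r1 <- trait_correlation_matrix(m, "within_perceiver_targets")$r
  r2 <- trait_correlation_matrix(2.5 * m + 1, "within_perceiver_targets")$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Fisher z transform matches its closed form and inverts exactly", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(inverse_fisher_z(fisher_z(0.3)), 0.3, tolerance = 1e-12)
  expect_equal(fisher_z(-0.7), -fisher_z(0.7))   # odd function
  expect_error(fisher_z(1.2), "outside")
  expect_true(is.finite(fisher_z(1)))            # clamped, not infinite
  expect_true(is.finite(fisher_z(-1)))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(inverse_fisher_z(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("upper-triangle vectorization has the forced lengths and ordering", {
  for (k in c(2, 6, 14)) {
    traits <- paste0("t", seq_len(k))
    m <- diag(k); dimnames(m) <- list(traits, traits)
    m[upper.tri(m)] <- runif(k * (k - 1) / 2, -0.5, 0.5)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    v <- vectorize_upper(m)
    expect_equal(nrow(v), k * (k - 1) / 2)
    # canonical order: row-major upper triangle
    expect_equal(v$trait_a[1:(k - 1)], rep("t1", k - 1))
    # reconstruction reproduces the off-diagonal exactly
    recon <- diag(k); dimnames(recon) <- list(traits, traits)
    recon[cbind(match(v$trait_a, traits), match(v$trait_b, traits))] <- v$value
    recon[cbind(match(v$trait_b, traits), match(v$trait_a, traits))] <- v$value
    expect_equal(recon, m)
  }
  m_bad <- matrix(c(1, 0.5, 0.2, 1), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(vectorize_upper(m_bad), "asymmetric")
})

test_that("stacking aligns pair lists and produces the forced row counts", {
  groups <- default_groups()
  make_vec <- function(k, gi) {
    traits <- paste0("t", seq_len(k))
    m <- diag(k); dimnames(m) <- list(traits, traits)
    m[upper.tri(m)] <- 0.1 * gi
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    v <- vectorize_upper(m)
    attr(v, "race") <- groups$race[gi]; attr(v, "gender") <- groups$gender[gi]
    v
  }
  expect_equal(nrow(stack_groups(lapply(1:6, function(g) make_vec(14, g)))),
               546)
  expect_equal(nrow(stack_groups(lapply(1:3, function(g) make_vec(6, g)))),
               45)
  one <- stack_groups(list(make_vec(14, 1)))
  expect_equal(nrow(one), 91)
  expect_equal(unique(one$race), "White")

  mismatched <- list(make_vec(14, 1), make_vec(6, 2))
  expect_error(stack_groups(mismatched), "align")
})

test_that("pair-mean centering annihilates shared structure and refuses to repeat", {
  groups <- default_groups()[1:3, ]
  vals <- cbind(c(0.2, 0.5), c(0.4, 0.5), c(0.6, 0.5))
  sp <- space_from_matrix(vals, c("a|b", "a|c"), groups)
  cen <- center_by_pair_mean(sp)
  expect_equal(cen$value[cen$trait_a == "a" & cen$trait_b == "b"],
               c(-0.2, 0, 0.2))
  expect_equal(cen$value[cen$trait_b == "c"], c(0, 0, 0))
  # per-pair across-group means are zero
  key <- paste(cen$trait_a, cen$trait_b)
  expect_true(all(abs(tapply(cen$value, key, mean)) < 1e-12))
  expect_error(center_by_pair_mean(cen), "already centered")
})

test_that("the full restructuring pipeline emits 546 deterministically ordered rows", {
  sim <- simulate_study1(small_study1_config(seed = 3))
  space <- build_space(sim$face_ratings)
  expect_equal(nrow(space), 546)
  expect_equal(attr(space, "scale"), "z")
  # groups in declared order, 91 pairs within each
  expect_equal(space$race[c(1, 92, 183)], c("White", "White", "Black"))
  expect_equal(space$trait_a[1], "aggressive")
  expect_equal(space$trait_b[1], "assertive")
  # rebuilding gives the identical object (deterministic)
  expect_identical(space, build_space(sim$face_ratings))
})

test_that("noise-free simulation recovers the generating correlation structure", {
  cfg <- simulation_config(
    traits = study2_traits(), groups = default_groups()[1, ],
    n_perceivers = 5, n_face_perceivers = 120, n_targets_per_group = 500,
    targets_per_perceiver = 500, noise_sd = 0, idiosyncrasy_sd = 0,
    likert = FALSE, seed = 21)
  sim <- simulate_study1(cfg)
  truth <- sim$truth$structures$face[["White female"]]
  ttm <- target_trait_means(sim$face_ratings, "White", "female")
  est <- trait_correlation_matrix(ttm, unit = "targets")
  # sampling-theory bound: ~3.5 standard errors of a correlation at n targets
  expect_lt(max(abs(est$r - truth)), 3.5 / sqrt(est$n_units))
})

test_that("stacked spaces round-trip through their CSV serialization", {
  groups <- default_groups()[1:2, ]
  sp <- space_from_matrix(cbind(c(0.1, 0.2), c(0.3, 0.4)),
                          c("a|b", "a|c"), groups)
  path <- tempfile(fileext = ".csv")
  write_space(sp, path)
  sp2 <- read_space(path)
  expect_equal(as.data.frame(sp2), as.data.frame(sp))
  expect_equal(attr(sp2, "scale"), attr(sp, "scale"))
  expect_equal(attr(sp2, "centered"), attr(sp, "centered"))
})
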
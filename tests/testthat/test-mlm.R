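# Shared small simulated study for dataset-construction tests.
sim2_small <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_study2(study2_config(n_perceivers = 12, seed = 77))
    val
  }
})

test_that("the model dataset has one row per perceiver x group x pair with exact CWC", {
  sim <- sim2_small()
  ds <- build_mlm_dataset(sim$face_ratings, sim$pairwise_ratings)
  expect_equal(nrow(ds), 12 * 15 * 3)
  expect_equal(attr(ds, "n_pairs"), 15)
  expect_equal(attr(ds, "n_groups"), 6)   # 3 races x both perceiver genders
  expect_false(anyDuplicated(paste(ds$perceiver_id, ds$race, ds$pair)) > 0)
  # within every perceiver the centered predictor sums to zero
  sums <- tapply(ds$x_cwc, ds$perceiver_id, sum)
  expect_true(all(abs(sums) < 1e-10))
  expect_equal(ds$x_cwc, ds$x_raw - ds$x_pmean, tolerance = 1e-12)
  # y values are Fisher-z transforms of within-perceiver correlations
  one <- ds[1, ]
  face <- as.data.frame(sim$face_ratings)
  sub <- face[face$perceiver_id == one$perceiver_id & face$race == one$race, ]
  wide <- tapply(sub$rating, list(sub$subject, sub$trait), identity)
  expect_equal(one$y,
               fisher_z(cor(wide[, one$trait_a], wide[, one$trait_b])),
               tolerance = 1e-12)
})

test_that("one complete perceiver yields 45 rows; constant predictors center to zero", {
  sim <- simulate_study2(study2_config(n_perceivers = 1, seed = 3))
  ds <- build_mlm_dataset(sim$face_ratings, sim$pairwise_ratings)
  expect_equal(nrow(ds), 45)

  # perceiver whose likelihood ratings are all identical
  pw <- as.data.frame(sim$pairwise_ratings)
  pw$rating <- 4L
  pw_tbl <- rating_table(pw, "pairwise_stereotype", study2_traits())
  ds2 <- build_mlm_dataset(sim$face_ratings, pw_tbl)
  expect_true(all(ds2$x_cwc == 0))
})

test_that("zero-variance traits drop rows with a logged count", {
  sim <- simulate_study2(study2_config(n_perceivers = 2, seed = 4))
  face <- as.data.frame(sim$face_ratings)
  # first perceiver rates 'aggressive' identically for every White target
  sel <- face$perceiver_id == "p0001" & face$race == "White" &
    face$trait == "aggressive"
  face$rating[sel] <- 2L
  tbl <- rating_table(face, "face_within", study2_traits())
  ds <- build_mlm_dataset(tbl, sim$pairwise_ratings)
  expect_equal(attr(ds, "n_dropped"), 5)   # the 5 pairs involving that trait
  expect_false(any(ds$perceiver_id == "p0001" & ds$race == "White" &
                     (ds$trait_a == "aggressive" | ds$trait_b == "aggressive")))
})

test_that("null-model ICCs track the realized crossed variance components", {
  # with only 15 pair levels the *population* pair variance is weakly
  # identified from one draw, so each replicate is judged against the
  # variance its own planted effects realized
  for (r in 1:3) {
    ds <- planted_mlm_dataset(200, 15, var_perceiver = 1, var_pair = 1,
                              var_resid = 2, seed = 20 + r)
    nm <- fit_null_crossclassified(ds, "y")
    re <- attr(ds, "realized")
    icc_real_p <- re$var_u / (re$var_u + re$var_v + re$var_e)
    icc_real_k <- re$var_v / (re$var_u + re$var_v + re$var_e)
    expect_lt(abs(nm$icc_perceiver - icc_real_p), 0.03)
    expect_lt(abs(nm$icc_pair - icc_real_k), 0.03)
  }

  # no planted clustering: ICCs collapse to ~0
  ds0 <- planted_mlm_dataset(60, 10, var_perceiver = 0, var_pair = 0,
                             var_resid = 1, seed = 22)
  nm0 <- fit_null_crossclassified(ds0, "y")
  expect_lt(nm0$icc_perceiver, 0.02)
  expect_lt(nm0$icc_pair, 0.02)
})

test_that("null-model ICCs are location invariant and scale free", {
  ds <- planted_mlm_dataset(40, 10, seed = 31)
  base <- fit_null_crossclassified(ds, "y")
  shifted <- ds; shifted$y <- shifted$y + 100
  scaled <- ds; scaled$y <- scaled$y * 3
  expect_equal(fit_null_crossclassified(shifted, "y")$icc_perceiver,
               base$icc_perceiver, tolerance = 1e-6)
  expect_equal(fit_null_crossclassified(scaled, "y")$icc_pair,
               base$icc_pair, tolerance = 1e-6)
  expect_equal(fit_null_crossclassified(scaled, "y")$var_residual,
               9 * base$var_residual, tolerance = 1e-4)
})

test_that("REML matches closed-form two-way ANOVA estimators on a balanced grid", {
  # 4 perceivers x 3 pairs, one observation per cell, intercepts only
  set.seed(14)
  a <- 4; b <- 3
  u <- rnorm(a, 0, 2); v <- rnorm(b, 0, 2)
  y <- outer(u, v, `+`) + matrix(rnorm(a * b, 0, 1), a, b)
  df <- data.frame(
    perceiver_id = rep(sprintf("p%d", 1:a), b),
    race = "White", gender = "female",
    trait_a = rep(sprintf("x%d", 1:b), each = a),
    trait_b = rep(sprintf("y%d", 1:b), each = a),
    pair = rep(sprintf("pair%d", 1:b), each = a),
    y = as.numeric(y), x_raw = 4, x_pmean = 4, x_cwc = 0,
    stringsAsFactors = FALSE)
  ds <- structure(df, class = c("mlm_dataset", "data.frame"),
                  n_perceivers = 10, n_pairs = 5, n_groups = 1,
                  n_dropped = 0L)
  # closed-form expected-mean-squares estimators
  gm <- mean(y)
  ms_a <- b * sum((rowMeans(y) - gm)^2) / (a - 1)
  ms_b <- a * sum((colMeans(y) - gm)^2) / (b - 1)
  ms_e <- sum((y - outer(rowMeans(y), colMeans(y), `+`) + gm)^2) /
    ((a - 1) * (b - 1))
  sigma_a <- (ms_a - ms_e) / b
  sigma_b <- (ms_b - ms_e) / a
  expect_gt(sigma_a, 0); expect_gt(sigma_b, 0)   # interior solution

  nm <- fit_null_crossclassified(ds, "y")
  expect_equal(nm$var_perceiver, sigma_a, tolerance = 1e-6)
  expect_equal(nm$var_pair, sigma_b, tolerance = 1e-6)
  expect_equal(nm$var_residual, ms_e, tolerance = 1e-6)
  # total variance is conserved by the decomposition
  expect_equal(nm$icc_perceiver + nm$icc_pair +
                 nm$var_residual / (nm$var_perceiver + nm$var_pair +
                                      nm$var_residual), 1, tolerance = 1e-10)
})

test_that("the full model recovers a planted fixed slope on constructed data", {
  ds <- planted_mlm_dataset(150, 15, var_perceiver = 0.3, var_pair = 0.3,
                            var_resid = 0.5, gamma100 = 0.25, seed = 41)
  fit <- fit_full(ds)
  cf <- fit$coefficients
  g100 <- cf[cf$term == "gamma_100", ]
  expect_lt(abs(g100$estimate - 0.25), 3 * g100$se)
  expect_true(g100$ci_low <= g100$estimate & g100$estimate <= g100$ci_high)
  expect_equal(fit$std_beta, g100$estimate * sd(ds$x_cwc) / sd(ds$y),
               tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("variance decomposition sums to one and zeroes absent terms", {
  ds <- planted_mlm_dataset(80, 12, gamma100 = 0.2, seed = 51)
  fit <- fit_full(ds)
  r2 <- r2_decomposition(fit)
  total <- r2$r2_f1_within + r2$r2_f2_between + r2$r2_v_slope +
    r2$r2_m_intercepts + r2$r2_residual
  expect_equal(total, 1, tolerance = 1e-6)
  expect_true(all(unlist(r2[1:5]) >= 0 & unlist(r2[1:5]) <= 1))

  # no planted slope: the within partition and slope partition vanish
  ds0 <- planted_mlm_dataset(60, 10, gamma100 = 0, seed = 52)
  fit0 <- fit_full(ds0)
  r20 <- r2_decomposition(fit0)
  expect_lt(r20$r2_f1_within, 0.002)
  expect_lt(r20$r2_v_slope, 0.002)
})

test_that("group-subset refits use only the requested groups", {
  sim <- sim2_small()
  ds <- build_mlm_dataset(sim$face_ratings, sim$pairwise_ratings)
  sub <- fit_full(ds, subset_groups = c("White female", "White male"))
  expect_equal(sub$n_obs, sum(group_label(ds$race, ds$gender) %in%
                                c("White female", "White male")))
  expect_error(fit_full(ds, subset_groups = "Martian"), "no rows")
})
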
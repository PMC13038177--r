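random_pair_table <- function(seed = 1, n_pairs = 12, effect = 0) {
  withr::with_seed(seed, {
    groups <- default_groups()
    vals <- matrix(rnorm(n_pairs * 6, 0.3, 0.2), n_pairs, 6) +
      outer(rep(1, n_pairs), effect * seq_len(6))
    sp <- space_from_matrix(vals, paste0("a", 1:n_pairs, "|b", 1:n_pairs),
                            groups)
    restructure_wide(sp)
  })
}

make_z_space_pair_91 <- function(seed = 12) {
  withr::with_seed(seed, {
    traits <- study1_traits()
    pairs <- t(combn(traits, 2))
    space_from_matrix(matrix(rnorm(91 * 6, 0.3, 0.2), 91, 6),
                      paste(pairs[, 1], pairs[, 2], sep = "|"),
                      default_groups())
  })
}

test_that("pivot to pairs-by-groups is lossless and shape-forced", {
  sim_space <- space_from_matrix(
    matrix(seq(0.01, 0.06, by = 0.01), 3, 2),
    c("a|b", "a|c", "b|c"), default_groups()[1:2, ])
  wide <- restructure_wide(sim_space)
  expect_equal(dim(wide$values), c(3, 2))
  expect_equal(as.numeric(wide$values), seq(0.01, 0.06, by = 0.01))
  # un-pivot recovers the stack (order-normalized)
  back <- restructure_long(wide)
  expect_equal(as.data.frame(back), as.data.frame(sim_space))

  dup <- rbind(as.data.frame(sim_space), as.data.frame(sim_space)[1, ])
  dup <- structure(dup, class = c("stacked_space", "data.frame"),
                   scale = "z", centered = FALSE)
  expect_error(restructure_wide(dup), "duplicate")

  sim546 <- make_z_space_pair_91()
  expect_equal(dim(restructure_wide(sim546)$values), c(91, 6))
})

test_that("identical columns give zero F, unit p, and degenerate-safe sphericity", {
  groups <- default_groups()
  vals <- matrix(0.25, 3, 6)
  res <- rm_anova_2x3(restructure_wide(
    space_from_matrix(vals, c("a|b", "a|c", "b|c"), groups)))
  expect_equal(res$effects$f, rep(0, 3))
  expect_equal(res$effects$p, rep(1, 3))
  # gender (2 levels) trivially spherical
  expect_equal(res$effects$gg_epsilon[res$effects$effect == "gender"], 1)
  # constant-column marginal means: mean = back-transformed constant, SE = 0
  cellm <- res$emm[res$emm$term == "cell", ]
  expect_equal(cellm$mean, rep(tanh(0.25), 6), tolerance = 1e-12)
  expect_equal(cellm$se, rep(0, 6))
})

test_that("sums of squares decompose exactly and GG correction behaves", {
  tab <- random_pair_table(seed = 2, n_pairs = 20, effect = 0.02)
  res <- rm_anova_2x3(tab)
  ss_sum <- res$ss_subject + sum(res$effects$ss) + sum(res$effects$ss_error)
  expect_equal(ss_sum, res$ss_total, tolerance = 1e-8 * res$ss_total)
  # epsilon within its theoretical range (1/(k-1), 1]
  eps <- res$effects$gg_epsilon[res$effects$effect == "race"]
  expect_true(eps > 0.5 && eps <= 1)
  # corrected df scale by epsilon; the correction is conservative wherever
  # the effect is non-trivial (F > 1; below that the inequality can reverse)
  expect_equal(res$effects$df_num_gg, res$effects$df_num * res$effects$gg_epsilon)
  nontrivial <- res$effects$f > 1
  expect_true(all(res$effects$p_gg[nontrivial] >=
                    res$effects$p[nontrivial] - 1e-12))
  expect_true(all(res$effects$partial_eta_sq >= 0 &
                    res$effects$partial_eta_sq <= 1))
})

test_that("F tests, sphericity, and GG corrections agree with the car oracle", {
  tab <- random_pair_table(seed = 4, n_pairs = 15, effect = 0.01)
  res <- rm_anova_2x3(tab)

  y <- tab$values
  idata <- data.frame(gender = factor(tab$groups$gender),
                      race = factor(tab$groups$race))
  mlmfit <- lm(y ~ 1)
  aout <- car::Anova(mlmfit, idata = idata, idesign = ~ gender * race,
                     type = 3)
  s <- summary(aout, multivariate = FALSE)
  uni <- s$univariate.tests
  for (eff in c("gender", "race", "gender:race")) {
    ours <- res$effects[res$effects$effect == eff, ]
    expect_equal(ours$f, unname(uni[eff, "F value"]), tolerance = 1e-8,
                 label = paste("F for", eff))
    expect_equal(ours$p, unname(uni[eff, "Pr(>F)"]), tolerance = 1e-8,
                 label = paste("p for", eff))
    expect_equal(ours$ss, unname(uni[eff, "Sum Sq"]), tolerance = 1e-8)
  }
  sph <- s$sphericity.tests
  expect_equal(res$sphericity$mauchly_W[1], unname(sph["race", "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(res$sphericity$mauchly_p[1], unname(sph["race", "p-value"]),
               tolerance = 1e-6)
  expect_equal(res$sphericity$mauchly_W[2],
               unname(sph["gender:race", "Test statistic"]), tolerance = 1e-8)
  gg <- s$pval.adjustments
  expect_equal(res$effects$gg_epsilon[res$effects$effect == "race"],
               unname(gg["race", "GG eps"]), tolerance = 1e-8)
  expect_equal(res$effects$p_gg[res$effects$effect == "race"],
               unname(gg["race", "Pr(>F[GG])"]), tolerance = 1e-8)
})

test_that("marginal means equal column means with within-unit standard errors", {
  tab <- random_pair_table(seed = 6, n_pairs = 10)
  res <- rm_anova_2x3(tab)
  cellm <- res$emm[res$emm$term == "cell", ]
  expect_equal(cellm$mean, unname(tanh(colMeans(tab$values))),
               tolerance = 1e-12)
  fem <- res$emm[res$emm$term == "gender" & res$emm$level == "female", ]
  fem_cols <- which(tab$groups$gender == "female")
  subj_means <- rowMeans(tab$values[, fem_cols])
  expect_equal(fem$mean, tanh(mean(subj_means)), tolerance = 1e-12)
  expect_equal(fem$se, sd(subj_means) / sqrt(10) * (1 - tanh(mean(subj_means))^2),
               tolerance = 1e-12)
  expect_true(all(res$emm$ci_low <= res$emm$mean &
                    res$emm$mean <= res$emm$ci_high))
})

test_that("results are invariant to reordering the group columns", {
  tab <- random_pair_table(seed = 8, n_pairs = 10)
  res <- rm_anova_2x3(tab)
  tab2 <- tab
  swap <- unlist(lapply(seq(1, 6, by = 2), function(i) c(i + 1, i)))
  tab2$values <- tab$values[, swap]
  tab2$groups <- tab$groups[swap, ]; rownames(tab2$groups) <- NULL
  colnames(tab2$values) <- tab2$groups$label
  res2 <- rm_anova_2x3(tab2)
  expect_equal(res2$effects$ss, res$effects$ss, tolerance = 1e-10)
  expect_equal(res2$effects$ss_error, res$effects$ss_error, tolerance = 1e-10)
  g1 <- res$emm[res$emm$term == "gender", ]
  g2 <- res2$emm[res2$emm$term == "gender", ]
  expect_equal(g1$mean[g1$level == "female"], g2$mean[g2$level == "female"],
               tolerance = 1e-12)
})

test_that("Mauchly's test holds its nominal size under sphericity", {
  n_reps <- 400
  rej <- withr::with_seed(99, {
    vapply(seq_len(n_reps), function(i) {
      groups <- default_groups()
      # iid columns: compound-symmetric (spherical) by construction
      vals <- matrix(rnorm(30 * 6, 0.3, 0.2), 30, 6)
      tab <- restructure_wide(space_from_matrix(
        vals, paste0("a", 1:30, "|b", 1:30), groups))
      rm_anova_2x3(tab)$sphericity$mauchly_p[1] < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
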
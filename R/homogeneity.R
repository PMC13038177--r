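# Homogeneity of trait spaces across groups: trait-pairs x groups pivot and
# the 2 (target gender) x 3 (target race) repeated-measures ANOVA, with
# trait pairs as the repeated-measures units.

#' Pivot a stacked space to a trait-pair by group table
#'
#' Restructures a stacked space (one row per group x trait pair, e.g. 546
#' rows) into a wide matrix with one row per trait pair and one column per
#' group (e.g. 91 x 6), the layout required by the repeated-measures
#' homogeneity analysis. The pivot is lossless.
#'
#' @param space an uncentered `stacked_space` with full group x pair
#'   coverage.
#' @return Object of class `pair_by_group`: list with `values` (pairs x
#'   groups matrix), `pairs` (data frame `trait_a`, `trait_b`), `groups`
#'   (data frame `race`, `gender`, `label`), `scale`.
#' @export
restructure_wide <- function(space) {
  stopifnot(inherits(space, "stacked_space"))
  if (isTRUE(attr(space, "centered")))
    stop("restructure_wide expects an uncentered space")
  glab <- group_label(space$race, space$gender)
  pkey <- paste(space$trait_a, space$trait_b, sep = "\r")
  if (anyDuplicated(paste(glab, pkey)))
    stop("duplicate (group, trait pair) rows")
  groups <- unique(data.frame(race = space$race, gender = space$gender,
                              label = glab, stringsAsFactors = FALSE))
  rownames(groups) <- NULL
  pairs <- unique(data.frame(trait_a = space$trait_a, trait_b = space$trait_b,
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  ukey <- paste(pairs$trait_a, pairs$trait_b, sep = "\r")
  values <- matrix(NA_real_, nrow(pairs), nrow(groups),
                   dimnames = list(gsub("\r", "-", ukey), groups$label))
  values[cbind(match(pkey, ukey), match(glab, groups$label))] <- space$value
  structure(list(values = values, pairs = pairs, groups = groups,
                 scale = attr(space, "scale")),
            class = "pair_by_group")
}

#' Un-pivot a pair-by-group table back to a stacked space
#'
#' Inverse of [restructure_wide()] up to row ordering (groups in column
#' order, pairs in row order within group).
#'
#' @param table a `pair_by_group`.
#' @return A `stacked_space` (uncentered).
#' @export
restructure_long <- function(table) {
  stopifnot(inherits(table, "pair_by_group"))
  parts <- lapply(seq_len(nrow(table$groups)), function(j)
    data.frame(race = table$groups$race[j], gender = table$groups$gender[j],
               trait_a = table$pairs$trait_a, trait_b = table$pairs$trait_b,
               value = table$values[, j], stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("stacked_space", "data.frame"),
            scale = table$scale, centered = FALSE)
}

# Orthonormal (Helmert-style) within-factor contrast matrix, k levels ->
# k x (k-1), columns orthonormal and orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  c_raw <- stats::contr.helmert(k)
  sweep(c_raw, 2, sqrt(colSums(c_raw^2)), "/")
}

# Mauchly's sphericity test and Greenhouse-Geisser epsilon from the
# covariance of orthonormal contrast scores (n x p). Chi-square uses the
# standard likelihood-ratio approximation with error df f = n - 1.
sphericity_stats <- function(scores) {
  n <- nrow(scores)
  p <- ncol(scores)
  s <- cov(scores)
  lam <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (sum(lam) < 1e-14) {            # degenerate: no contrast variance
    return(list(W = 1, chi2 = 0, df = p * (p + 1) / 2 - 1, p = 1,
                gg_epsilon = 1, n = n))
  }
  eps <- sum(lam)^2 / (p * sum(lam^2))
  w <- prod(lam) / (mean(lam))^p
  f <- n - 1
  chi2 <- -(f - (2 * p^2 + p + 2) / (6 * p)) * log(max(w, 1e-300))
  df <- p * (p + 1) / 2 - 1
  list(W = w, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       gg_epsilon = eps, n = n)
}

#' Two-factor repeated-measures ANOVA over trait pairs
#'
#' Tests whether the trait space differs across the six social groups by
#' treating each trait pair as a repeated-measures subject observed in all
#' 2 (target gender) x 3 (target race) conditions. Sums of squares are
#' partitioned with the trait pair as the blocking unit; each
#' within-subject effect is tested against its own effect-by-subject
#' interaction. Partial eta squared is `SS_effect / (SS_effect +
#' SS_error_effect)`. For within factors with more than two levels (race,
#' gender x race) Mauchly's sphericity test and the Greenhouse-Geisser
#' epsilon are computed from the covariance of orthonormal contrast scores,
#' and GG-corrected p values are reported alongside the uncorrected ones;
#' the two-level gender factor satisfies sphericity trivially (epsilon = 1,
#' Mauchly skipped). Rows with any missing cell are dropped listwise (count
#' reported).
#'
#' @param table a [restructure_wide()] result whose 6 columns are the
#'   race x gender groups. Values are analyzed on the scale they carry
#'   (Fisher z by default in this pipeline); set `analysis_scale = "r"` to
#'   back-transform z values to correlations before the ANOVA for exact
#'   replication on the r scale.
#' @param analysis_scale `"as_is"` (default) or `"r"`.
#' @return Object of class `trait_space_anova`: list with `effects` (data
#'   frame: effect, df_num, df_den, ss, ss_error, f, p, partial_eta_sq,
#'   gg_epsilon, df_num_gg, df_den_gg, p_gg), `sphericity` (data frame:
#'   factor, mauchly_W, mauchly_chi2, mauchly_df, mauchly_p, n_units),
#'   `emm` (see [marginal_means()]), `n_units`, `n_dropped`, `ss_subject`,
#'   `analysis_scale`.
#' @export
rm_anova_2x3 <- function(table, analysis_scale = c("as_is", "r")) {
  analysis_scale <- match.arg(analysis_scale)
  stopifnot(inherits(table, "pair_by_group"))
  groups <- table$groups
  if (length(unique(groups$gender)) != 2 || length(unique(groups$race)) != 3)
    stop("design must be 2 genders x 3 races")
  y <- table$values
  if (analysis_scale == "r" && table$scale == "z") y <- tanh(y)
  complete <- complete.cases(y)
  n_dropped <- sum(!complete)
  y <- y[complete, , drop = FALSE]
  n <- nrow(y)
  if (n < 3) stop("fewer than 3 complete trait-pair rows (", n, ")")

  gl <- gender_levels()[gender_levels() %in% groups$gender]
  rl <- race_levels()[race_levels() %in% groups$race]
  gidx <- match(groups$gender, gl)
  ridx <- match(groups$race, rl)

  grand <- mean(y)
  m_subj <- rowMeans(y)
  m_g <- vapply(1:2, function(g) mean(y[, gidx == g, drop = FALSE]), 0)
  m_r <- vapply(1:3, function(r) mean(y[, ridx == r, drop = FALSE]), 0)
  m_cell <- colMeans(y)
  # subject x factor-level means
  m_sg <- vapply(1:2, function(g) rowMeans(y[, gidx == g, drop = FALSE]), numeric(n))
  m_sr <- vapply(1:3, function(r) rowMeans(y[, ridx == r, drop = FALSE]), numeric(n))

  ss_subject <- 6 * sum((m_subj - grand)^2)
  ss_g <- n * 3 * sum((m_g - grand)^2)
  ss_r <- n * 2 * sum((m_r - grand)^2)
  ss_gr <- n * sum((m_cell - m_g[gidx] - m_r[ridx] + grand)^2)
  ss_gs <- 3 * sum(sweep(sweep(m_sg, 1, m_subj), 2, m_g - grand)^2)
  ss_rs <- 2 * sum(sweep(sweep(m_sr, 1, m_subj), 2, m_r - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_grs <- ss_total - ss_subject - ss_g - ss_r - ss_gr - ss_gs - ss_rs

  df_g <- 1; df_r <- 2; df_gr <- 2
  df_gs <- (n - 1) * df_g; df_rs <- (n - 1) * df_r; df_grs <- (n - 1) * df_gr
  # a zero effect against a zero error term (identical columns) is F = 0
  f_ratio <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_eff < 1e-14 && ss_err < 1e-14) return(0)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  f_g <- f_ratio(ss_g, df_g, ss_gs, df_gs)
  f_r <- f_ratio(ss_r, df_r, ss_rs, df_rs)
  f_gr <- f_ratio(ss_gr, df_gr, ss_grs, df_grs)

  # sphericity: race contrasts on subject x race means; interaction
  # contrasts on the cell matrix
  c3 <- orthonormal_contrasts(3)
  race_scores <- m_sr %*% c3
  sph_race <- sphericity_stats(race_scores)
  # interaction contrasts: products of the gender and race orthonormal
  # contrasts are themselves orthonormal over the 6 cells
  cg <- orthonormal_contrasts(2)
  c_int <- vapply(1:2, function(l) cg[gidx, 1] * c3[ridx, l], numeric(6))
  sph_int <- sphericity_stats(y %*% c_int)

  eps_r <- sph_race$gg_epsilon
  eps_gr <- sph_int$gg_epsilon
  effects <- data.frame(
    effect = c("gender", "race", "gender:race"),
    df_num = c(df_g, df_r, df_gr),
    df_den = c(df_gs, df_rs, df_grs),
    ss = c(ss_g, ss_r, ss_gr),
    ss_error = c(ss_gs, ss_rs, ss_grs),
    f = c(f_g, f_r, f_gr),
    p = c(pf(f_g, df_g, df_gs, lower.tail = FALSE),
          pf(f_r, df_r, df_rs, lower.tail = FALSE),
          pf(f_gr, df_gr, df_grs, lower.tail = FALSE)),
    partial_eta_sq = c(ss_g / (ss_g + ss_gs), ss_r / (ss_r + ss_rs),
                       ss_gr / (ss_gr + ss_grs)),
    gg_epsilon = c(1, eps_r, eps_gr),
    stringsAsFactors = FALSE)
  effects$df_num_gg <- effects$df_num * effects$gg_epsilon
  effects$df_den_gg <- effects$df_den * effects$gg_epsilon
  effects$p_gg <- pf(effects$f, effects$df_num_gg, effects$df_den_gg,
                     lower.tail = FALSE)

  sphericity <- data.frame(
    factor = c("race", "gender:race"),
    mauchly_W = c(sph_race$W, sph_int$W),
    mauchly_chi2 = c(sph_race$chi2, sph_int$chi2),
    mauchly_df = c(sph_race$df, sph_int$df),
    mauchly_p = c(sph_race$p, sph_int$p),
    n_units = n,
    stringsAsFactors = FALSE)

  emm <- marginal_means_impl(y, gidx, ridx, gl, rl, groups$label,
                             back_transform = (table$scale == "z" &&
                                                 analysis_scale == "as_is"))
  structure(list(effects = effects, sphericity = sphericity, emm = emm,
                 n_units = n, n_dropped = n_dropped,
                 ss_subject = ss_subject, ss_total = ss_total,
                 analysis_scale = if (analysis_scale == "r") "r" else table$scale),
            class = "trait_space_anova")
}

marginal_means_impl <- function(y, gidx, ridx, gl, rl, cell_labels,
                                back_transform) {
  n <- nrow(y)
  one_level <- function(term, level, subj_means) {
    m <- mean(subj_means)
    se <- sd(subj_means) / sqrt(n)
    tcrit <- qt(0.975, n - 1)
    ci <- m + c(-1, 1) * tcrit * se
    if (back_transform) {
      se <- se * (1 - tanh(m)^2)   # delta method on tanh
      ci <- tanh(ci)
      m <- tanh(m)
    }
    data.frame(term = term, level = level, mean = m, se = se,
               ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in seq_along(gl))
    rows[[length(rows) + 1]] <- one_level(
      "gender", gl[g], rowMeans(y[, gidx == g, drop = FALSE]))
  for (r in seq_along(rl))
    rows[[length(rows) + 1]] <- one_level(
      "race", rl[r], rowMeans(y[, ridx == r, drop = FALSE]))
  for (j in seq_len(ncol(y)))
    rows[[length(rows) + 1]] <- one_level("cell", cell_labels[j], y[, j])
  out <- do.call(rbind, rows)
  attr(out, "back_transformed") <- back_transform
  out
}

#' Estimated marginal means of the trait-pair correlations
#'
#' Marginal means over trait pairs for each gender, race, and gender x race
#' cell, with repeated-measures standard errors (SD across trait-pair units
#' of the unit-level mean, divided by sqrt(n)) and t-based 95% CIs. When the
#' input is on the Fisher-z scale the means are computed on z and reported
#' back-transformed to the correlation scale (SE by the delta method); the
#' result carries a `back_transformed` attribute.
#'
#' @param table a `pair_by_group` table.
#' @return Data frame with columns `term` (gender / race / cell), `level`,
#'   `mean`, `se`, `ci_low`, `ci_high`.
#' @export
marginal_means <- function(table) {
  rm_anova_2x3(table)$emm
}

#' @export
print.trait_space_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA on trait-pair correlations (",
      x$n_units, " trait pairs", sep = "")
  if (x$n_dropped > 0) cat(", ", x$n_dropped, " dropped", sep = "")
  cat("; analysis scale: ", x$analysis_scale, ")\n", sep = "")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-12s F(%.2f, %.2f) = %.2f, p = %.4g (GG p = %.4g), partial eta^2 = %.3f\n",
                eff$effect[i], eff$df_num_gg[i], eff$df_den_gg[i], eff$f[i],
                eff$p[i], eff$p_gg[i], eff$partial_eta_sq[i]))
  }
  sph <- x$sphericity
  for (i in seq_len(nrow(sph))) {
    cat(sprintf("  Mauchly %-12s W = %.3f, chi2(%d) = %.2f, p = %.4g\n",
                sph$factor[i], sph$mauchly_W[i], sph$mauchly_df[i],
                sph$mauchly_chi2[i], sph$mauchly_p[i]))
  }
  invisible(x)
}

#' @export
summary.trait_space_anova <- function(object, ...) {
  print(object)
  cat("Estimated marginal means",
      if (isTRUE(attr(object$emm, "back_transformed")))
        " (back-transformed to r)", ":\n", sep = "")
  print(object$emm, digits = 3, row.names = FALSE)
  invisible(object)
}
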
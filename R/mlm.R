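# Cross-classified multilevel analysis: does a perceiver's own stereotype
# association for a trait pair in a group predict that perceiver's own
# face-rating correlation for the same pair and group?

#' Build the perceiver x group x trait-pair model dataset
#'
#' For every perceiver and race group, the perceiver's own targets are
#' correlated trait-by-trait (within-perceiver unit), Fisher-z transformed,
#' and joined with the perceiver's pairwise stereotype-likelihood ratings
#' for the same group and trait pair. The two directed likelihood questions
#' ("how likely is an aggressive X to be attractive?" and the reverse) are
#' averaged into one undirected predictor; `average_directions = FALSE`
#' instead keeps only the first-asked direction (a sensitivity option, since
#' question direction is randomized at collection time). The predictor is
#' centered within each perceiver (CWC): `x_cwc = x_raw - x_pmean`.
#'
#' Rows where a trait has zero variance across the perceiver's targets (so
#' the correlation is undefined) are dropped with a logged count; a
#' perceiver-group cell needs at least 3 rated targets.
#'
#' @param face a `rating_table` with design `"face_within"`.
#' @param pairwise a `rating_table` with design `"pairwise_stereotype"`.
#' @param average_directions average the two directed likelihood questions
#'   (default `TRUE`).
#' @return Object of class `mlm_dataset`: data frame with columns
#'   `perceiver_id`, `race`, `gender`, `trait_a`, `trait_b`, `pair`, `y`
#'   (Fisher-z face-rating correlation), `x_raw`, `x_pmean`, `x_cwc`;
#'   attributes `n_perceivers`, `n_pairs`, `n_groups`, `n_dropped`.
#' @export
build_mlm_dataset <- function(face, pairwise, average_directions = TRUE) {
  stopifnot(inherits(face, "rating_table"),
            attr(face, "design") == "face_within",
            inherits(pairwise, "rating_table"),
            attr(pairwise, "design") == "pairwise_stereotype")
  traits <- attr(face, "trait_set")
  pairs <- canonical_pairs(traits)
  pair_id <- paste(pairs$trait_a, pairs$trait_b, sep = "-")

  # undirected pairwise stereotype ratings per perceiver x group x pair
  pw <- as.data.frame(pairwise)
  a <- pmin(match(pw$trait_given, traits), match(pw$trait_asked, traits))
  b <- pmax(match(pw$trait_given, traits), match(pw$trait_asked, traits))
  pw$pair <- paste(traits[a], traits[b], sep = "-")
  if (average_directions) {
    agg <- aggregate(rating ~ perceiver_id + race + gender + pair, data = pw,
                     FUN = mean)
  } else {
    first <- !duplicated(pw[, c("perceiver_id", "race", "gender", "pair")])
    agg <- pw[first, c("perceiver_id", "race", "gender", "pair", "rating")]
  }
  pw_key <- paste(agg$perceiver_id, agg$race, agg$gender, agg$pair, sep = "\r")
  pw_x <- setNames(agg$rating, pw_key)

  n_dropped <- 0L
  rows <- list()
  fdf <- as.data.frame(face)
  for (pid in unique(fdf$perceiver_id)) {
    pd <- fdf[fdf$perceiver_id == pid, , drop = FALSE]
    for (race in unique(pd$race)) {
      gd <- pd[pd$race == race, , drop = FALSE]
      gender <- gd$gender[1]
      targets <- unique(as.character(gd$subject))
      if (length(targets) < 3) {
        n_dropped <- n_dropped + nrow(pairs)
        next
      }
      m <- matrix(NA_real_, length(targets), length(traits),
                  dimnames = list(targets, traits))
      m[cbind(match(as.character(gd$subject), targets),
              match(gd$trait, traits))] <- gd$rating
      r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
      vals <- r[cbind(match(pairs$trait_a, traits),
                      match(pairs$trait_b, traits))]
      ok <- !is.na(vals)
      n_dropped <- n_dropped + sum(!ok)
      if (!any(ok)) next
      key <- paste(pid, race, gender, pair_id, sep = "\r")
      rows[[length(rows) + 1]] <- data.frame(
        perceiver_id = pid, race = race, gender = gender,
        trait_a = pairs$trait_a, trait_b = pairs$trait_b, pair = pair_id,
        y = fisher_z(vals), x_raw = as.numeric(pw_x[key]),
        stringsAsFactors = FALSE)[ok, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  miss_x <- is.na(out$x_raw)
  if (any(miss_x)) {
    n_dropped <- n_dropped + sum(miss_x)
    out <- out[!miss_x, , drop = FALSE]
  }
  pm <- tapply(out$x_raw, out$perceiver_id, mean)
  out$x_pmean <- as.numeric(pm[out$perceiver_id])
  out$x_cwc <- out$x_raw - out$x_pmean
  structure(out, class = c("mlm_dataset", "data.frame"),
            n_perceivers = length(unique(out$perceiver_id)),
            n_pairs = length(unique(out$pair)),
            n_groups = length(unique(paste(out$race, out$gender))),
            n_dropped = n_dropped)
}

#' @export
print.mlm_dataset <- function(x, ...) {
  cat("MLM dataset: ", nrow(x), " observations nested in ",
      attr(x, "n_perceivers"), " perceivers and ", attr(x, "n_pairs"),
      " trait pairs (", attr(x, "n_groups"), " groups; ",
      attr(x, "n_dropped"), " rows dropped)\n", sep = "")
  invisible(x)
}

# Tight optimizer tolerances: in balanced designs the REML optimum has
# closed-form ANOVA counterparts and loose stopping rules leave visible gaps.
tight_control <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    optCtrl = list(xtol_rel = 0, xtol_abs = 1e-14,
                                   ftol_rel = 0, ftol_abs = 0))
}

vc_from_fit <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  setNames(vc$vcov, ifelse(is.na(vc$var1), vc$grp,
                           paste(vc$grp, vc$var1, sep = ".")))
}

#' Cross-classified intercept-only (null) model and ICCs
#'
#' Fits, by REML, an intercept-only linear mixed model with crossed random
#' intercepts for perceivers and trait pairs, and (for the stereotype-rating
#' outcome, where several observations share a perceiver x pair cell across
#' groups) an additional perceiver-by-pair interaction intercept. The
#' intraclass correlation of each clustering factor is its variance share of
#' the total.
#'
#' @param dataset an [build_mlm_dataset()] result (>= 10 perceivers, >= 5
#'   pairs).
#' @param outcome `"y"` (Fisher-z face-rating correlations) or `"x_raw"`
#'   (stereotype likelihood ratings, adds the interaction component).
#' @return Object of class `mlm_null`: list with `var_perceiver`,
#'   `var_pair`, `var_interaction` (or `NA`), `var_residual`,
#'   `icc_perceiver`, `icc_pair`, `icc_interaction`, `n_obs`, `outcome`,
#'   `fit` (the underlying `merMod`).
#' @export
fit_null_crossclassified <- function(dataset, outcome = c("y", "x_raw")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(dataset, "mlm_dataset"))
  if (attr(dataset, "n_perceivers") < 10 || attr(dataset, "n_pairs") < 5)
    stop("need >= 10 perceivers and >= 5 trait pairs")
  d <- as.data.frame(dataset)
  d$.y <- d[[outcome]]
  form <- if (outcome == "x_raw")
    .y ~ 1 + (1 | perceiver_id) + (1 | pair) + (1 | perceiver_id:pair)
  else
    .y ~ 1 + (1 | perceiver_id) + (1 | pair)
  fit <- lme4::lmer(form, data = d, REML = TRUE, control = tight_control())
  v <- vc_from_fit(fit)
  vp <- unname(v["perceiver_id.(Intercept)"])
  vk <- unname(v["pair.(Intercept)"])
  vi <- if (outcome == "x_raw")
    unname(v["perceiver_id:pair.(Intercept)"]) else NA_real_
  vr <- unname(v["Residual"])
  tot <- vp + vk + vr + if (is.na(vi)) 0 else vi
  structure(list(var_perceiver = vp, var_pair = vk, var_interaction = vi,
                 var_residual = vr,
                 icc_perceiver = vp / tot, icc_pair = vk / tot,
                 icc_interaction = if (is.na(vi)) NA_real_ else vi / tot,
                 n_obs = nrow(d), outcome = outcome, fit = fit),
            class = "mlm_null")
}

#' @export
print.mlm_null <- function(x, ...) {
  cat("Cross-classified null model (outcome: ", x$outcome, ", n = ",
      x$n_obs, ")\n", sep = "")
  cat(sprintf("  perceiver ICC = %.3f, trait-pair ICC = %.3f",
              x$icc_perceiver, x$icc_pair))
  if (!is.na(x$icc_interaction))
    cat(sprintf(", interaction ICC = %.3f", x$icc_interaction))
  cat(sprintf("\n  variances: perceiver %.4f, pair %.4f, residual %.4f\n",
              x$var_perceiver, x$var_pair, x$var_residual))
  invisible(x)
}

#' Fit the full cross-classified stereotype-to-face-space model
#'
#' The substantive model: each observation is one perceiver's Fisher-z
#' face-rating correlation for one trait pair in one group, predicted by the
#' perceiver's own (within-perceiver centered) stereotype association for
#' that pair and group. Level 1:
#' `y_ijk = beta_0jk + beta_1jk * x_cwc_ijk + R_ijk`; Level 2:
#' `beta_0jk = gamma_000 + gamma_010 * x_pmean_j + U_0j0 + U_00k` and
#' `beta_1jk = gamma_100 + U_1j0`, i.e. crossed random intercepts for
#' perceiver (j) and trait pair (k) and a random within-perceiver slope,
#' mutually independent (no intercept-slope covariance, matching the
#' model's Level-2 specification; set `correlated_slope = TRUE` for an
#' unstructured perceiver block as a sensitivity check). The perceiver-mean
#' predictor is grand-mean centered so the fixed intercept stays the grand
#' mean. Estimation is REML via lme4; inference on fixed effects is Wald.
#' Singular fits (zero slope variance) are refit with the random slope
#' removed and flagged.
#'
#' @param dataset an [build_mlm_dataset()] result.
#' @param subset_groups optional character vector of group labels (e.g.
#'   `"Black male"`) to refit on a subset (per-group consistency checks).
#' @param correlated_slope allow intercept-slope covariance for perceivers.
#' @return Object of class `mlm_fit`: list with `coefficients` (data frame:
#'   term, estimate, se, ci_low, ci_high, z, p for gamma_000, gamma_010,
#'   gamma_100), `std_beta` (gamma_100 * SD(x_cwc)/SD(y)), `components`
#'   (variances: perceiver intercept, pair intercept, perceiver slope,
#'   residual), `converged`, `singular`, `slope_dropped`, `loglik`,
#'   `n_obs`, `fit`.
#' @export
fit_full <- function(dataset, subset_groups = NULL, correlated_slope = FALSE) {
  stopifnot(inherits(dataset, "mlm_dataset"))
  d <- as.data.frame(dataset)
  if (!is.null(subset_groups)) {
    d <- d[group_label(d$race, d$gender) %in% subset_groups, , drop = FALSE]
    if (nrow(d) == 0) stop("subset_groups matched no rows")
  }
  d$x_pmean_c <- d$x_pmean - mean(d$x_pmean)
  form <- if (correlated_slope)
    y ~ x_pmean_c + x_cwc + (1 + x_cwc | perceiver_id) + (1 | pair)
  else
    y ~ x_pmean_c + x_cwc + (1 | perceiver_id) + (0 + x_cwc | perceiver_id) +
      (1 | pair)
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = tight_control())
  vc_parts <- function(fit) {
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(cond) {
      x <- vcdf$vcov[cond & is.na(vcdf$var2)]
      if (length(x)) x[1] else 0
    }
    list(perceiver = pick(grepl("^perceiver_id", vcdf$grp) &
                            vcdf$var1 == "(Intercept)"),
         slope = pick(grepl("^perceiver_id", vcdf$grp) & vcdf$var1 == "x_cwc"),
         pair = pick(vcdf$grp == "pair"),
         residual = vcdf$vcov[vcdf$grp == "Residual"][1])
  }
  slope_dropped <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5) && !correlated_slope &&
      vc_parts(fit)$slope < 1e-8) {
    fit <- lme4::lmer(y ~ x_pmean_c + x_cwc + (1 | perceiver_id) + (1 | pair),
                      data = d, REML = TRUE,
                      control = tight_control())
    slope_dropped <- TRUE
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zv <- beta / se
  coefs <- data.frame(
    term = c("gamma_000", "gamma_010", "gamma_100"),
    estimate = unname(beta[c("(Intercept)", "x_pmean_c", "x_cwc")]),
    se = unname(se[c("(Intercept)", "x_pmean_c", "x_cwc")]),
    stringsAsFactors = FALSE)
  coefs$ci_low <- coefs$estimate - 1.96 * coefs$se
  coefs$ci_high <- coefs$estimate + 1.96 * coefs$se
  coefs$z <- coefs$estimate / coefs$se
  coefs$p <- 2 * stats::pnorm(-abs(coefs$z))
  vp <- vc_parts(fit)
  comp <- list(
    var_perceiver_intercept = vp$perceiver,
    var_pair_intercept = vp$pair,
    var_perceiver_slope = if (slope_dropped) 0 else vp$slope,
    var_residual = vp$residual)
  g100 <- coefs$estimate[coefs$term == "gamma_100"]
  structure(list(coefficients = coefs,
                 std_beta = g100 * sd(d$x_cwc) / sd(d$y),
                 components = comp,
                 converged = length(fit@optinfo$conv$lme4$messages %||% character()) == 0,
                 singular = lme4::isSingular(fit, tol = 1e-5),
                 slope_dropped = slope_dropped,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(d),
                 data_summary = list(sd_x_cwc = sd(d$x_cwc),
                                     var_x_cwc = var(d$x_cwc),
                                     mean_sq_x_cwc = mean(d$x_cwc^2),
                                     var_x_pmean = var(d$x_pmean_c)),
                 fit = fit),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("Cross-classified mixed model (REML, n = ", x$n_obs, ")\n", sep = "")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf)))
    cat(sprintf("  %-10s %8.4f  (SE %.4f, 95%% CI [%.4f, %.4f], p = %.3g)\n",
                cf$term[i], cf$estimate[i], cf$se[i], cf$ci_low[i],
                cf$ci_high[i], cf$p[i]))
  cat(sprintf("  standardized within slope = %.3f\n", x$std_beta))
  with(x$components, cat(sprintf(
    "  variances: perceiver %.4f, pair %.4f, slope %.5f, residual %.4f\n",
    var_perceiver_intercept, var_pair_intercept, var_perceiver_slope,
    var_residual)))
  if (x$slope_dropped)
    cat("  note: random slope variance hit zero; slope term dropped\n")
  invisible(x)
}

#' @export
coef.mlm_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Model-implied variance decomposition (cross-classified R squared)
#'
#' Partitions the model-implied total outcome variance of a [fit_full()]
#' model into interpretable shares, following the integrated R-squared
#' framework for multilevel models (fixed-effect, random-slope, and
#' random-intercept partitions computed from the estimated fixed effects,
#' the predictor moments, and the variance components), with the
#' random-intercept partition carrying both crossed intercept variances:
#' \itemize{
#'   \item `r2_f1_within`: fixed within-perceiver stereotype effect,
#'     `gamma_100^2 * var(x_cwc)`;
#'   \item `r2_f2_between`: fixed between-perceiver effect,
#'     `gamma_010^2 * var(x_pmean)`;
#'   \item `r2_v_slope`: random-slope variation, `tau_11 * E[x_cwc^2]`;
#'   \item `r2_m_intercepts`: perceiver plus trait-pair intercept variance;
#'   \item `r2_residual`: the remainder.
#' }
#' All shares are proportions of the model-implied total and sum to one.
#'
#' @param fit a converged [fit_full()] result.
#' @param dataset the [build_mlm_dataset()] the model was fit to (unused
#'   beyond a consistency check; predictor moments are stored in the fit).
#' @return Object of class `mlm_r2`: list with the five proportions and
#'   `total_variance`.
#' @export
r2_decomposition <- function(fit, dataset = NULL) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (!fit$converged) stop("refusing to decompose a non-converged fit")
  b <- coef(fit)
  ds <- fit$data_summary
  f1 <- b[["gamma_100"]]^2 * ds$var_x_cwc
  f2 <- b[["gamma_010"]]^2 * ds$var_x_pmean
  v <- fit$components$var_perceiver_slope * ds$mean_sq_x_cwc
  m <- fit$components$var_perceiver_intercept + fit$components$var_pair_intercept
  resid <- fit$components$var_residual
  total <- f1 + f2 + v + m + resid
  structure(list(r2_f1_within = f1 / total, r2_f2_between = f2 / total,
                 r2_v_slope = v / total, r2_m_intercepts = m / total,
                 r2_residual = resid / total, total_variance = total),
            class = "mlm_r2")
}

#' @export
print.mlm_r2 <- function(x, ...) {
  cat("Variance decomposition (proportions of model-implied total):\n")
  cat(sprintf("  within-perceiver stereotype (f1): %5.1f%%\n", 100 * x$r2_f1_within))
  cat(sprintf("  between-perceiver stereotype (f2): %4.1f%%\n", 100 * x$r2_f2_between))
  cat(sprintf("  random slope (v):                 %5.1f%%\n", 100 * x$r2_v_slope))
  cat(sprintf("  crossed intercepts (m):           %5.1f%%\n", 100 * x$r2_m_intercepts))
  cat(sprintf("  residual:                         %5.1f%%\n", 100 * x$r2_residual))
  invisible(x)
}
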
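# Representational similarity of two stacked trait spaces.

# All permutations of 1..n as an (n!) x n matrix, built iteratively.
# Used for the exact Spearman null at small n (n <= 9).
all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (m in 2:n) {
    out <- matrix(0L, nrow(p) * m, m)
    row <- 1L
    for (pos in seq_len(m)) {
      # insert m at column `pos` of every (m-1)-permutation
      blk <- cbind(p[, seq_len(pos - 1), drop = FALSE],
                   rep(m, nrow(p)),
                   if (pos <= m - 1) p[, pos:(m - 1), drop = FALSE])
      out[row:(row + nrow(p) - 1), ] <- blk
      row <- row + nrow(p)
    }
    p <- out
  }
  p
}

#' Spearman rank correlation with exact small-sample p value
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks
#' (standard tie handling). The two-sided p value is exact (full permutation
#' enumeration) for n <= 9 and uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise. Missing values are removed
#' pairwise.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with `rho`, `p_value`, `n`, and `p_method`
#'   (`"exact_permutation"` or `"t_approximation"`).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  if (is.na(rho)) stop("rank correlation undefined (zero rank variance)")
  if (n <= 9) {
    perms <- all_permutations(n)
    null_rho <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p_value = p, n = n, p_method = method)
}

align_spaces <- function(a, b) {
  key_a <- paste(a$race, a$gender, a$trait_a, a$trait_b, sep = "\r")
  key_b <- paste(b$race, b$gender, b$trait_a, b$trait_b, sep = "\r")
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b))
    stop("stacked spaces do not share identical row labels")
  b <- b[match(key_a, key_b), , drop = FALSE]
  list(a = a, b = b)
}

#' Compare a face-trait space with a stereotype-trait space
#'
#' The package's headline statistic: Spearman's rho between two stacked
#' trait spaces (face-derived and stereotype-derived), after independently
#' mean-centering each space by trait pair so that only group-specific
#' deviations -- not trait-pair relationships shared by all groups -- drive
#' the association. Spearman rather than Pearson is used because the inputs
#' are themselves (Fisher-z) correlations. A 95% interval is attached either
#' by seeded row bootstrap (percentile, default) or by the Fisher
#' approximation `atanh(rho) +/- 1.96/sqrt(n-3)`.
#'
#' @param face,stereo `stacked_space` objects on the z scale with identical
#'   row labels.
#' @param center apply [center_by_pair_mean()] to each space independently
#'   (error if an input is already centered).
#' @param ci_method `"bootstrap"` (percentile over rows) or
#'   `"fisher_approx"`.
#' @param n_resamples bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `space_similarity`: `rho`, `p_value`, `ci_low`,
#'   `ci_high`, `n_rows` (paired rows used), `method`, `n_resamples`,
#'   `seed`, `n_dropped_missing`, `centered`.
#' @export
compare_spaces <- function(face, stereo, center = TRUE,
                           ci_method = c("bootstrap", "fisher_approx"),
                           n_resamples = 10000, seed = 1) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(face, "stacked_space"), inherits(stereo, "stacked_space"))
  if (attr(face, "scale") != "z" || attr(stereo, "scale") != "z")
    stop("both spaces must be on the z scale (see to_z_scale)")
  if (center) {
    if (isTRUE(attr(face, "centered")) || isTRUE(attr(stereo, "centered")))
      stop("center = TRUE but an input space is already centered")
    face <- center_by_pair_mean(face)
    stereo <- center_by_pair_mean(stereo)
  }
  al <- align_spaces(face, stereo)
  x <- al$a$value; y <- al$b$value
  ok <- complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  sp <- spearman_rho(x, y)
  n <- sp$n

  if (ci_method == "bootstrap") {
    boot <- with_seed(seed, {
      vapply(seq_len(n_resamples), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        suppressWarnings(cor(rank(x[idx]), rank(y[idx])))
      }, numeric(1))
    })
    boot <- boot[!is.na(boot)]
    ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  } else {
    half <- 1.96 / sqrt(n - 3)
    ci <- tanh(atanh(sp$rho) + c(-half, half))
  }

  structure(list(rho = sp$rho, p_value = sp$p_value,
                 ci_low = ci[1], ci_high = ci[2], n_rows = n,
                 method = ci_method, n_resamples =
                   if (ci_method == "bootstrap") n_resamples else 0L,
                 seed = seed, n_dropped_missing = n_dropped,
                 centered = center, p_method = sp$p_method),
            class = "space_similarity")
}

#' @export
print.space_similarity <- function(x, ...) {
  cat(sprintf(
    "Trait-space similarity (%sSpearman)\n  rho = %.3f, 95%% CI [%.3f, %.3f] (%s), p = %.3g (%s)\n  %d paired rows (%d dropped as missing)\n",
    if (x$centered) "pair-mean centered " else "", x$rho, x$ci_low, x$ci_high,
    x$method, x$p_value, x$p_method, x$n_rows, x$n_dropped_missing))
  invisible(x)
}

#' Permutation null for the centered space similarity
#'
#' Builds an empirical null distribution for [compare_spaces()] by permuting
#' the stereotype space's group labels independently within each trait pair
#' and recomputing the centered Spearman rho each time. Under the null of no
#' group-specific coupling the observed statistic is exchangeable with the
#' permuted ones.
#'
#' @param face,stereo uncentered `stacked_space` objects on the z scale.
#' @param n_perm number of permutations (a value below 100 triggers a
#'   warning, not an error).
#' @param seed integer seed.
#' @param alpha envelope level (two-sided), default 0.05.
#' @return Object of class `space_permutation`: `observed` rho, `null`
#'   (numeric vector), `envelope` (the alpha/2 and 1-alpha/2 null
#'   quantiles), `p_value` (permutation two-sided), `n_perm`, `seed`.
#' @export
permutation_null <- function(face, stereo, n_perm = 1000, seed = 1,
                             alpha = 0.05) {
  if (n_perm < 100)
    warning("n_perm < 100 gives a coarse null; consider more permutations")
  stopifnot(inherits(face, "stacked_space"), inherits(stereo, "stacked_space"))
  fc <- center_by_pair_mean(face)
  sc <- center_by_pair_mean(stereo)
  al <- align_spaces(fc, sc)
  x <- al$a$value; y <- al$b$value
  pair_key <- paste(al$a$trait_a, al$a$trait_b, sep = "\r")
  blocks <- split(seq_along(y), pair_key)
  observed <- spearman_rho(x, y)$rho
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      yp <- y
      for (b in blocks) yp[b] <- y[b][sample.int(length(b))]
      ok <- complete.cases(x, yp)
      cor(rank(x[ok]), rank(yp[ok]))
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (1 + n_perm)
  structure(list(observed = observed, null = null,
                 envelope = quantile(null, c(alpha / 2, 1 - alpha / 2),
                                     names = FALSE),
                 p_value = p, n_perm = n_perm, seed = seed, alpha = alpha),
            class = "space_permutation")
}

#' @export
print.space_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%d permutations)\n  observed rho = %.3f, %.0f%% envelope [%.3f, %.3f], p = %.3g\n",
    x$n_perm, x$observed, 100 * (1 - x$alpha), x$envelope[1], x$envelope[2],
    x$p_value))
  invisible(x)
}
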
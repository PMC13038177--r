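# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All exported stochastic functions route their
# randomness through this so that a single seed argument is reproducible and
# side-effect free.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seeds: fan one user seed out to named components
# (targets, perceivers, noise, ...) so each subset of a simulation is
# independently reproducible. Kept below 2^31 - 1.
substream_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
}

# Project a symmetric matrix to the nearest valid correlation matrix by
# eigenvalue clipping followed by diagonal renormalization.
nearest_correlation <- function(m, eps = 1e-8) {
  dn <- dimnames(m)
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  s <- e$vectors %*% (vals * t(e$vectors))
  d <- 1 / sqrt(diag(s))
  r <- s * tcrossprod(d)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- dn
  r
}

is_correlation_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) < tol &&
    max(abs(diag(m) - 1)) < tol &&
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > -tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
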
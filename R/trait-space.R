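# Trait-space construction: per-group trait-pair correlation structure.

canonical_pairs <- function(traits) {
  k <- length(traits)
  ia <- rep(seq_len(k - 1), times = (k - 1):1)
  ib <- unlist(lapply(seq_len(k - 1), function(i) (i + 1):k))
  data.frame(trait_a = traits[ia], trait_b = traits[ib],
             stringsAsFactors = FALSE)
}

#' Target-by-trait mean ratings for one group
#'
#' In a between-subjects face design each perceiver rates every face on a
#' single trait, so trait-pair correlations cannot be formed within raters;
#' ratings are first aggregated to unweighted target-level means, and traits
#' are then correlated across targets.
#'
#' @param table a [rating_table()] with design `"face_between"`.
#' @param race,gender the group.
#' @return An object of class `target_trait_matrix`: list with `means`
#'   (targets x traits matrix of mean ratings, `NA` where a target was never
#'   rated on a trait), `n_ratings` (contributing-rating counts, 0 where
#'   missing), `race`, `gender`, `traits`, `targets`.
#' @export
target_trait_means <- function(table, race, gender) {
  stopifnot(inherits(table, "rating_table"),
            attr(table, "design") == "face_between")
  sub <- table[table$race == race & table$gender == gender, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no ratings for group '", group_label(race, gender), "'")
  traits <- attr(table, "trait_set")
  targets <- sort(unique(as.character(sub$subject)))
  ti <- match(as.character(sub$subject), targets)
  tj <- match(sub$trait, traits)
  sums <- matrix(0, length(targets), length(traits),
                 dimnames = list(targets, traits))
  n <- sums
  lin <- (tj - 1L) * length(targets) + ti
  cell_sum <- rowsum(as.numeric(sub$rating), lin)
  cell_n <- rowsum(rep(1, nrow(sub)), lin)
  pos <- as.integer(rownames(cell_sum))
  sums[pos] <- cell_sum
  n[pos] <- cell_n
  means <- sums / n
  means[n == 0] <- NA_real_
  structure(list(means = means, n_ratings = n, race = race, gender = gender,
                 traits = traits, targets = targets),
            class = "target_trait_matrix")
}

# Pearson correlation across rows of a units x traits matrix with pairwise
# complete observations. Pairs with < min_units complete units error; pairs
# where either trait has zero variance are marked missing (NA).
cor_over_units <- function(m, min_units = 3) {
  traits <- colnames(m)
  k <- ncol(m)
  counts <- crossprod(!is.na(m))
  off <- which(upper.tri(counts), arr.ind = TRUE)
  low <- off[counts[off] < min_units, , drop = FALSE]
  if (nrow(low) > 0)
    stop("insufficient data (< ", min_units, " complete units) for trait pair ",
         traits[low[1, 1]], "-", traits[low[1, 2]])
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  dimnames(r) <- list(traits, traits)
  r
}

#' Trait-pair correlation matrix for one group
#'
#' Computes the k x k Pearson correlation matrix among traits over the
#' correlation unit appropriate to the design:
#' \describe{
#'   \item{`"targets"`}{across target-level mean ratings (between-subjects
#'     face designs); `x` is a [target_trait_means()] result.}
#'   \item{`"perceivers"`}{across participants' abstract ratings of the group
#'     itself; `x` is a `rating_table` with design `"group_abstract"` and
#'     `race`/`gender` select the group.}
#'   \item{`"within_perceiver_targets"`}{across one perceiver's own targets
#'     within a group (within-subjects designs); `x` is a plain targets x
#'     traits matrix.}
#' }
#' Trait pairs with fewer than 3 complete units raise an error naming the
#' pair; pairs where either trait has zero variance yield `NA`.
#'
#' @param x input per `unit`, see Details.
#' @param unit correlation unit, one of `"targets"`, `"perceivers"`,
#'   `"within_perceiver_targets"`.
#' @param race,gender group selector (required for `unit = "perceivers"`).
#' @return Object of class `trait_corr`: list with `r` (symmetric k x k
#'   correlation matrix, unit diagonal), `traits`, `race`, `gender`, `unit`,
#'   `n_units`, `scale = "r"`.
#' @export
trait_correlation_matrix <- function(x,
                                     unit = c("targets", "perceivers",
                                              "within_perceiver_targets"),
                                     race = NULL, gender = NULL) {
  unit <- match.arg(unit)
  if (unit == "targets") {
    stopifnot(inherits(x, "target_trait_matrix"))
    m <- x$means
    race <- x$race; gender <- x$gender
  } else if (unit == "perceivers") {
    stopifnot(inherits(x, "rating_table"),
              attr(x, "design") == "group_abstract",
              !is.null(race), !is.null(gender))
    sub <- x[x$race == race & x$gender == gender, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("no ratings for group '", group_label(race, gender), "'")
    traits <- attr(x, "trait_set")
    ids <- unique(sub$perceiver_id)
    m <- matrix(NA_real_, length(ids), length(traits),
                dimnames = list(ids, traits))
    m[cbind(match(sub$perceiver_id, ids), match(sub$trait, traits))] <- sub$rating
  } else {
    m <- as.matrix(x)
    stopifnot(!is.null(colnames(m)))
  }
  r <- cor_over_units(m)
  structure(list(r = r, traits = colnames(m), race = race, gender = gender,
                 unit = unit, n_units = nrow(m), scale = "r"),
            class = "trait_corr")
}

#' @export
print.trait_corr <- function(x, ...) {
  cat("Trait correlation matrix (", length(x$traits), " traits, group: ",
      if (is.null(x$race)) "<none>" else group_label(x$race, x$gender),
      ", unit: ", x$unit, ", n = ", x$n_units, ")\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Fisher's z transformation and its inverse
#'
#' `fisher_z()` maps a correlation r to `z = atanh(r) = 0.5 * log((1+r)/(1-r))`,
#' the variance-stabilizing scale on which trait-pair correlations are
#' compared across groups. Values with `|r| = 1` (possible in small
#' within-perceiver samples) are clamped to `1 - 1e-12` in magnitude before
#' the transform; `|r| > 1` is a domain error. `inverse_fisher_z()` is the
#' exact analytic inverse `tanh(z)`.
#'
#' @param r correlations in `[-1, 1]` (vectorized; `NA` passes through).
#' @param z Fisher-z values.
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.5)            # 0.5 * log(3)
#' inverse_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop("correlation outside [-1, 1]")
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Vectorize the upper triangle of a trait correlation matrix
#'
#' Removes the duplicated lower triangle and the unit diagonal, returning the
#' k(k-1)/2 unique trait-pair values in canonical order: the row-major upper
#' triangle of the declared trait order, i.e. pairs (1,2), (1,3), ...,
#' (1,k), (2,3), ... For 14 traits this gives 91 trait pairs per group.
#'
#' @param m a [trait_correlation_matrix()] result, or a plain symmetric
#'   matrix with trait names as dimnames.
#' @param tol symmetry tolerance; asymmetry beyond it is an integrity error.
#' @return Object of class `trait_pair_vector`: data frame with columns
#'   `trait_a`, `trait_b`, `value`, and attributes `race`, `gender`, `scale`.
#' @export
vectorize_upper <- function(m, tol = 1e-8) {
  race <- NULL; gender <- NULL; scale <- "r"
  if (inherits(m, "trait_corr")) {
    race <- m$race; gender <- m$gender; scale <- m$scale
    m <- m$r
  }
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop("matrix is asymmetric beyond tolerance")
  traits <- colnames(m)
  pairs <- canonical_pairs(traits)
  pairs$value <- m[cbind(match(pairs$trait_a, traits),
                         match(pairs$trait_b, traits))]
  structure(pairs, class = c("trait_pair_vector", "data.frame"),
            race = race, gender = gender, scale = scale)
}

#' Fisher-transform a trait-pair vector or stacked space
#'
#' Applies [fisher_z()] to the pair values (the transform is applied at the
#' pair level, after vectorization) and marks the object as being on the z
#' scale. Transforming an object already on the z scale is an error.
#'
#' @param x a `trait_pair_vector` or `stacked_space`.
#' @return The same object with transformed values and `scale = "z"`.
#' @export
to_z_scale <- function(x) {
  stopifnot(inherits(x, c("trait_pair_vector", "stacked_space")))
  if (attr(x, "scale") == "z") stop("already on the z scale")
  x$value <- fisher_z(x$value)
  attr(x, "scale") <- "z"
  x
}

#' Stack per-group trait-pair vectors into one labeled space
#'
#' Concatenates the trait-pair vectors of all groups (in the supplied order)
#' into a single stacked space: one row per (group, trait pair), e.g.
#' 6 groups x 91 pairs = 546 rows for the 14-trait design. All vectors must
#' share an identical pair list and scale.
#'
#' @param vectors list of [vectorize_upper()] results, each carrying its
#'   group labels.
#' @return Object of class `stacked_space`: data frame with columns `race`,
#'   `gender`, `trait_a`, `trait_b`, `value`; attributes `scale` and
#'   `centered` (`FALSE`).
#' @export
stack_groups <- function(vectors) {
  stopifnot(length(vectors) >= 1,
            all(vapply(vectors, inherits, TRUE, "trait_pair_vector")))
  ref <- paste(vectors[[1]]$trait_a, vectors[[1]]$trait_b, sep = "\r")
  scales <- vapply(vectors, attr, "", "scale")
  if (length(unique(scales)) != 1)
    stop("vectors are on mixed scales: ", paste(unique(scales), collapse = ", "))
  parts <- lapply(vectors, function(v) {
    key <- paste(v$trait_a, v$trait_b, sep = "\r")
    if (length(key) != length(ref) || any(key != ref)) {
      diff <- union(setdiff(key, ref), setdiff(ref, key))
      stop("trait-pair lists do not align; differing pairs: ",
           paste(gsub("\r", "-", diff), collapse = ", "))
    }
    if (is.null(attr(v, "race")))
      stop("trait-pair vector carries no group labels")
    data.frame(race = attr(v, "race"), gender = attr(v, "gender"),
               trait_a = v$trait_a, trait_b = v$trait_b, value = v$value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("stacked_space", "data.frame"),
            scale = scales[1], centered = FALSE)
}

#' Center a stacked space by trait-pair means
#'
#' Subtracts, within each trait pair, the mean of that pair's values across
#' all groups. This removes structure shared by every group (e.g. dominance
#' and physical strength correlating positively for all categories), so that
#' downstream comparisons are driven only by group-specific deviations.
#' Centering an already-centered space is an error (double-centering is a
#' common bug, not a no-op in intent).
#'
#' @param space a `stacked_space` with every pair present in every group.
#' @return The centered `stacked_space` (`centered = TRUE`). After centering,
#'   each pair's across-group mean is 0 to numerical tolerance.
#' @export
center_by_pair_mean <- function(space) {
  stopifnot(inherits(space, "stacked_space"))
  if (isTRUE(attr(space, "centered")))
    stop("space is already centered by trait-pair means")
  key <- paste(space$trait_a, space$trait_b, sep = "\r")
  n_groups <- length(unique(paste(space$race, space$gender)))
  if (any(table(key) != n_groups))
    stop("every trait pair must be present in every group for centering")
  pm <- tapply(space$value, key, mean, na.rm = TRUE)
  space$value <- space$value - as.numeric(pm[key])
  attr(space, "centered") <- TRUE
  space
}

#' Read and write stacked spaces as CSV
#'
#' Columns: `race`, `gender`, `trait_a`, `trait_b`, `value`, `scale`,
#' `centered`.
#'
#' @param space a `stacked_space`.
#' @param path file path.
#' @return `write_space()` returns `path` invisibly; `read_space()` the
#'   reconstructed `stacked_space`.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "stacked_space"))
  df <- as.data.frame(space)
  df$scale <- attr(space, "scale")
  df$centered <- attr(space, "centered")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("race", "gender", "trait_a", "trait_b", "value", "scale", "centered")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  structure(df[, c("race", "gender", "trait_a", "trait_b", "value")],
            class = c("stacked_space", "data.frame"),
            scale = df$scale[1], centered = as.logical(df$centered[1]))
}

# Build one group's face-space pair vector from a between-subjects table.
face_space_vector <- function(table, race, gender) {
  vectorize_upper(trait_correlation_matrix(
    target_trait_means(table, race, gender), unit = "targets"))
}

# Build one group's stereotype-space pair vector from abstract ratings.
stereo_space_vector <- function(table, race, gender) {
  vectorize_upper(trait_correlation_matrix(
    table, unit = "perceivers", race = race, gender = gender))
}

#' Build a stacked trait space from a rating table
#'
#' End-to-end restructuring for one data source: per-group correlation
#' matrices (unit chosen by design), upper-triangle vectorization, Fisher's z
#' transform, and stacking across groups in declared order.
#'
#' @param table a `rating_table` with design `"face_between"` or
#'   `"group_abstract"`.
#' @param groups data frame of groups (columns `race`, `gender`), default all
#'   six in declared order.
#' @return A `stacked_space` on the z scale, uncentered.
#' @export
build_space <- function(table, groups = default_groups()) {
  design <- attr(table, "design")
  build1 <- switch(design,
    face_between = face_space_vector,
    group_abstract = stereo_space_vector,
    stop("build_space supports face_between and group_abstract designs, got ",
         design))
  vecs <- lapply(seq_len(nrow(groups)), function(i)
    build1(table, groups$race[i], groups$gender[i]))
  to_z_scale(stack_groups(vecs))
}
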
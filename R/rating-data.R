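#' Race and gender levels and the six social groups
#'
#' The designs supported here cross three target races (White, Black,
#' East Asian) with two target genders (female, male), giving six social
#' groups. Group labels render as `"<Race> <gender>"` (e.g. `"East Asian
#' female"`) and this rendering is stable across the package.
#'
#' @return `race_levels()` and `gender_levels()` return character vectors of
#'   the declared factor levels; `default_groups()` returns a data frame with
#'   columns `race`, `gender`, `label` holding all six groups in the declared
#'   (race-major) order.
#' @examples
#' default_groups()
#' @export
default_groups <- function() {
  g <- expand.grid(gender = gender_levels(), race = race_levels(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("race", "gender")]
  g <- g[order(match(g$race, race_levels()), match(g$gender, gender_levels())), ]
  rownames(g) <- NULL
  g$label <- group_label(g$race, g$gender)
  g
}

#' @rdname default_groups
#' @export
race_levels <- function() c("White", "Black", "East Asian")

#' @rdname default_groups
#' @export
gender_levels <- function() c("female", "male")

#' @param race,gender character vectors of race and gender values.
#' @rdname default_groups
#' @export
group_label <- function(race, gender) paste(race, gender)

#' Declared trait sets
#'
#' `study1_traits()` returns the 14 traits rated in the between-subjects face
#' and abstract-stereotype designs; `study2_traits()` the reduced 6-trait set
#' used in the within-perceiver design. Trait names are canonicalized to
#' lower case with surrounding whitespace trimmed.
#'
#' @return Character vector of canonical trait names, in declared order.
#' @export
study1_traits <- function() {
  c("aggressive", "assertive", "attractive", "caring", "competent",
    "dominant", "friendly", "healthy", "intelligent", "smart",
    "physically strong", "trustworthy", "warm", "youthful")
}

#' @rdname study1_traits
#' @export
study2_traits <- function() {
  c("aggressive", "attractive", "friendly", "healthy", "intelligent",
    "physically strong")
}

canonical_trait <- function(x) tolower(trimws(x))

rating_designs <- function() {
  c("face_between", "group_abstract", "face_within", "pairwise_stereotype")
}

#' Construct a validated rating table
#'
#' A rating table is a long-format data frame of 1-7 Likert ratings, the
#' universal input to the pipeline. Each row carries a perceiver id, the
#' rated subject (a target id for face designs, the group label for abstract
#' designs), the target's race and gender, the trait, and the rating. The
#' pairwise-stereotype design instead carries `trait_given` and `trait_asked`
#' (the two traits in a directed likelihood question such as "how likely is
#' an aggressive Asian man to be attractive?").
#'
#' @param df data frame with columns `perceiver_id`, `subject`, `race`,
#'   `gender`, `trait`, `rating` (for `design = "pairwise_stereotype"`:
#'   `trait_given` and `trait_asked` instead of `trait`). An optional
#'   `perceiver_race` column is kept and enables race-based participant
#'   filtering.
#' @param design one of `"face_between"`, `"group_abstract"`,
#'   `"face_within"`, `"pairwise_stereotype"`.
#' @param trait_set ordered character vector of allowed trait names.
#' @return The validated data frame with class `rating_table` and attributes
#'   `design` and `trait_set`. Row order is preserved.
#' @export
rating_table <- function(df, design, trait_set) {
  design <- match.arg(design, rating_designs())
  trait_set <- canonical_trait(trait_set)
  if (anyDuplicated(trait_set))
    stop("trait_set contains duplicate names")
  df <- as.data.frame(df)

  trait_cols <- if (design == "pairwise_stereotype")
    c("trait_given", "trait_asked") else "trait"
  needed <- c("perceiver_id", "race", "gender", trait_cols, "rating")
  if (design != "pairwise_stereotype") needed <- c(needed[1], "subject", needed[-1])
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  for (col in trait_cols) {
    df[[col]] <- canonical_trait(df[[col]])
    bad <- !df[[col]] %in% trait_set
    if (any(bad))
      stop("unknown trait(s) in column '", col, "': ",
           paste(unique(df[[col]][bad]), collapse = ", "))
  }
  if (design == "pairwise_stereotype" &&
      any(df$trait_given == df$trait_asked))
    stop("trait_given must differ from trait_asked in every row")

  bad_race <- !df$race %in% race_levels()
  if (any(bad_race))
    stop("unknown race value(s): ", paste(unique(df$race[bad_race]), collapse = ", "))
  bad_gender <- !df$gender %in% gender_levels()
  if (any(bad_gender))
    stop("unknown gender value(s): ", paste(unique(df$gender[bad_gender]), collapse = ", "))

  r <- df$rating
  ok <- !is.na(r) & r == as.integer(r) & r >= 1 & r <= 7
  if (!all(ok))
    stop("rating outside 1-7 (or non-integer) at row(s): ",
         paste(head(which(!ok), 5), collapse = ", "))
  df$rating <- as.integer(r)
  df$perceiver_id <- as.character(df$perceiver_id)

  if (design %in% c("group_abstract", "face_within", "face_between")) {
    key <- paste(df$perceiver_id, df$subject, df[[trait_cols[1]]], sep = "\r")
    if (design %in% c("group_abstract", "face_within") && anyDuplicated(key))
      stop("duplicate (perceiver, subject, trait) key at row ",
           which(duplicated(key))[1])
  }

  structure(df, class = c("rating_table", "data.frame"),
            design = design, trait_set = trait_set)
}

#' @export
print.rating_table <- function(x, ...) {
  cat("Rating table (design: ", attr(x, "design"), ")\n", sep = "")
  cat("  ", nrow(x), " ratings, ", length(unique(x$perceiver_id)),
      " perceivers, ", length(attr(x, "trait_set")), " traits\n", sep = "")
  invisible(x)
}

#' Read and write rating tables as CSV
#'
#' CSV dialect: UTF-8, comma-separated, header row required; columns as in
#' [rating_table()]. `load_ratings()` validates on read and preserves row
#' order; `write_ratings()` is its inverse (round-trips record content).
#'
#' @param path file path.
#' @param design,trait_set passed to [rating_table()].
#' @return `load_ratings()` returns a validated [rating_table()];
#'   `write_ratings()` returns `path` invisibly.
#' @export
load_ratings <- function(path, design, trait_set) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  rating_table(df, design = design, trait_set = trait_set)
}

#' @param table a `rating_table`.
#' @rdname load_ratings
#' @export
write_ratings <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Participant-level data cleaning
#'
#' Removes perceivers according to the study's cleaning rules, in a fixed
#' order so that each perceiver is counted under the first rule that removes
#' them: (1) zero variance -- all of a perceiver's ratings, pooled across
#' subjects and traits, are identical; (2) opt-out -- the perceiver asked
#' that their data not be used; (3) race filter -- the perceiver's
#' self-reported race is not in the supplied keep-list (exact label match;
#' used e.g. to restrict aggregate analyses to non-Hispanic White
#' perceivers, and switched off for robustness checks); (4) an optional
#' user-supplied predicate hook (e.g. response-time rules), called with each
#' perceiver's rows and returning `TRUE` to drop.
#'
#' @param table a [rating_table()].
#' @param drop_zero_variance drop perceivers with no variation in responses?
#' @param optout_ids character vector of perceiver ids to drop.
#' @param perceiver_race_filter optional character vector of `perceiver_race`
#'   labels to keep; requires a `perceiver_race` column.
#' @param predicate optional `function(rows) -> logical(1)`; `TRUE` drops the
#'   perceiver. Removals are reported separately as `n_removed_predicate`.
#' @return list with elements `table` (the cleaned `rating_table`) and
#'   `report` (class `cleaning_report`): perceiver counts `n_in`,
#'   `n_removed_zero_variance`, `n_removed_optout`, `n_removed_race_filter`,
#'   `n_removed_predicate`, `n_out`, which always reconcile.
#' @export
clean_participants <- function(table, drop_zero_variance = TRUE,
                               optout_ids = character(),
                               perceiver_race_filter = NULL,
                               predicate = NULL) {
  stopifnot(inherits(table, "rating_table"))
  ids <- unique(table$perceiver_id)
  n_in <- length(ids)
  removed <- setNames(rep("", n_in), ids)

  if (drop_zero_variance) {
    rng <- tapply(table$rating, table$perceiver_id,
                  function(r) max(r) - min(r))
    zv <- names(rng)[rng == 0]
    removed[zv] <- "zero_variance"
  }
  free <- names(removed)[removed == ""]
  removed[intersect(free, as.character(optout_ids))] <- "optout"

  if (!is.null(perceiver_race_filter)) {
    if (!"perceiver_race" %in% names(table))
      stop("perceiver race filter requested but table has no 'perceiver_race' column")
    prace <- tapply(as.character(table$perceiver_race), table$perceiver_id,
                    function(x) x[1])
    free <- names(removed)[removed == ""]
    drop <- free[!prace[free] %in% perceiver_race_filter]
    removed[drop] <- "race_filter"
  }
  if (!is.null(predicate)) {
    free <- names(removed)[removed == ""]
    for (id in free) {
      if (isTRUE(predicate(table[table$perceiver_id == id, , drop = FALSE])))
        removed[id] <- "predicate"
    }
  }

  keep_ids <- names(removed)[removed == ""]
  out <- table[table$perceiver_id %in% keep_ids, , drop = FALSE]
  out <- structure(out, class = class(table),
                   design = attr(table, "design"),
                   trait_set = attr(table, "trait_set"))
  report <- structure(list(
    n_in = n_in,
    n_removed_zero_variance = sum(removed == "zero_variance"),
    n_removed_optout = sum(removed == "optout"),
    n_removed_race_filter = sum(removed == "race_filter"),
    n_removed_predicate = sum(removed == "predicate"),
    n_out = length(keep_ids)
  ), class = "cleaning_report")
  stopifnot(report$n_out == report$n_in - report$n_removed_zero_variance -
              report$n_removed_optout - report$n_removed_race_filter -
              report$n_removed_predicate)
  list(table = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Participant cleaning:", x$n_in, "in ->", x$n_out, "out\n")
  cat("  zero variance:", x$n_removed_zero_variance,
      "| opt-out:", x$n_removed_optout,
      "| race filter:", x$n_removed_race_filter,
      "| predicate:", x$n_removed_predicate, "\n")
  invisible(x)
}
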
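# Per-enzyme binary predictors: the random-forest model over the full
# attribute vector, the single-attribute decision-tree baseline ("simple
# model"), attribute-importance ranking, and rf-SDR extraction.

#' Train the random-forest predictor of one enzyme
#'
#' 500 trees; `floor(sqrt(n))` candidate attributes per split, `n` being
#' the number of input attributes (the attribute count differs between
#' enzymes, so the split count does too). Importance is the mean decrease
#' in node impurity by default; permutation importance is available via
#' `importance_measure`.
#'
#' @param attributes Wide attribute tibble from [build_attribute_table()]
#'   (`query_id` plus one numeric column per attribute).
#' @param labels Logical vector (TRUE = positive) aligned to the rows.
#' @param schema Attribute schema tibble.
#' @param ntree Number of trees (default 500).
#' @param mtry Attributes tried per split; default `floor(sqrt(n))`.
#' @param seed Integer seed; (data, seed) fully determine the model.
#' @param importance_measure `"impurity"` (mean decrease Gini) or
#'   `"permutation"` (mean decrease accuracy).
#' @return An `efprf_forest`: list with the fitted forest, `schema`,
#'   `ntree`, `mtry`, `seed`, `oob_error`, `importance` tibble.
#' @export
train_forest <- function(attributes, labels, schema, ntree = 500L,
                         mtry = NULL, seed = 1L,
                         importance_measure = c("impurity", "permutation")) {
  importance_measure <- match.arg(importance_measure)
  x <- as.data.frame(attributes[, schema$name, drop = FALSE])
  n <- ncol(x)
  if (n == 0L) stop("no attributes to train on", call. = FALSE)
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("training labels are single-class; need positives and negatives",
         call. = FALSE)
  }
  mtry <- mtry %||% max(1L, floor(sqrt(n)))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry,
    importance = importance_measure == "permutation"
  )
  imp_col <- if (importance_measure == "permutation")
    "MeanDecreaseAccuracy" else "MeanDecreaseGini"
  imp <- randomForest::importance(rf)[, imp_col]
  importance <- tibble::tibble(name = schema$name,
                               importance = unname(imp[schema$name]))
  structure(list(rf = rf, schema = schema, ntree = ntree, mtry = mtry,
                 seed = seed,
                 oob_error = unname(rf$err.rate[ntree, "OOB"]),
                 importance = importance,
                 importance_measure = importance_measure),
            class = "efprf_forest")
}

#' @export
print.efprf_forest <- function(x, ...) {
  cat("EFPrf random-forest predictor:", x$ntree, "trees, mtry", x$mtry,
      "over", nrow(x$schema), "attributes; OOB error",
      signif(x$oob_error, 3), "\n")
  invisible(x)
}

#' Train the single-attribute decision-tree baseline
#'
#' An entropy-criterion decision tree over the BLAST-type top-hit bit
#' score alone. On a one-attribute problem any entropy-based tree reduces
#' to the same optimal threshold structure, which is all the baseline
#' needs.
#'
#' @param blast_scores Numeric vector of top-hit bit scores.
#' @param labels Logical vector (TRUE = positive).
#' @param minbucket Minimum leaf size.
#' @return An `efprf_simple_tree`: list with the fitted tree and its split
#'   `thresholds`.
#' @export
train_simple <- function(blast_scores, labels, minbucket = 2L) {
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  if (length(unique(y)) < 2L) {
    stop("training labels are single-class; need positives and negatives",
         call. = FALSE)
  }
  df <- data.frame(blast = blast_scores, y = y)
  fit <- rpart::rpart(y ~ blast, data = df, method = "class",
                      parms = list(split = "information"),
                      control = rpart::rpart.control(minbucket = minbucket,
                                                     minsplit = 2L,
                                                     cp = 0.01,
                                                     xval = 0L))
  thresholds <- if (nrow(fit$frame) > 1L)
    sort(unique(fit$splits[, "index"])) else numeric()
  structure(list(tree = fit, thresholds = thresholds),
            class = "efprf_simple_tree")
}

#' @export
print.efprf_simple_tree <- function(x, ...) {
  cat("Simple baseline tree on the top-hit bit score;",
      if (length(x$thresholds)) paste("split(s) at",
                                      paste(signif(x$thresholds, 4),
                                            collapse = ", "))
      else "majority-class stump", "\n")
  invisible(x)
}

#' Predict with a trained enzyme model
#'
#' Majority vote over trees; a query is labelled positive iff the positive
#' vote fraction exceeds 0.5 (exact ties are negative).
#'
#' @param object An `efprf_forest` or `efprf_simple_tree`.
#' @param attributes Wide attribute tibble (forest) or numeric vector of
#'   blast scores (simple tree).
#' @param ... Unused.
#' @return Tibble `predicted` (logical), `vote_fraction`.
#' @export
predict.efprf_forest <- function(object, attributes, ...) {
  missing_cols <- setdiff(object$schema$name, names(attributes))
  if (length(missing_cols)) {
    stop("attribute table does not match the model schema; missing: ",
         paste(head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(attributes[, object$schema$name, drop = FALSE])
  votes <- predict(object$rf, newdata = x, type = "vote", norm.votes = TRUE)
  vf <- unname(votes[, "pos"])
  tibble::tibble(predicted = vf > 0.5, vote_fraction = vf)
}

#' @rdname predict.efprf_forest
#' @export
predict.efprf_simple_tree <- function(object, attributes, ...) {
  df <- data.frame(blast = as.numeric(attributes))
  pr <- predict(object$tree, newdata = df, type = "prob")
  vf <- unname(pr[, "pos"])
  tibble::tibble(predicted = vf > 0.5, vote_fraction = vf)
}

#' Rank a forest's attributes by importance
#'
#' Descending importance, ties broken by schema index ascending (so rf-SDR
#' sets are reproducible). The "highly contributing" prefix has length
#' `min(3 * floor(sqrt(n)), n)`.
#'
#' @param model An `efprf_forest`.
#' @param multiplier Prefix length multiplier (default 3).
#' @return An `efprf_importance`: tibble of all attributes with `rank` and
#'   `highly_contributing`, carrying the schema as an attribute.
#' @export
rank_importance <- function(model, multiplier = 3L) {
  n <- nrow(model$schema)
  prefix_len <- min(multiplier * floor(sqrt(n)), n)
  ranking <- model$importance |>
    dplyr::mutate(schema_index = dplyr::row_number()) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$schema_index) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  highly_contributing = .data$rank <= prefix_len)
  attr(ranking, "schema") <- model$schema
  attr(ranking, "prefix_length") <- prefix_len
  class(ranking) <- c("efprf_importance", class(ranking))
  ranking
}

#' Extract rf-SDRs from an importance ranking
#'
#' Walks the highly-contributing prefix, skips the BLAST-type and
#' full-length attributes, and collects the representative positions of
#' the remaining position attributes, deduplicated across matrices. Each
#' position is tagged with its site category and the matrices under which
#' it was selected.
#'
#' @param ranking An `efprf_importance` from [rank_importance()].
#' @param schema Attribute schema (defaults to the one on the ranking).
#' @return Tibble `position`, `category`, `matrices` (comma-joined),
#'   `best_rank`.
#' @export
extract_rf_sdrs <- function(ranking, schema = NULL) {
  schema <- schema %||% attr(ranking, "schema")
  prefix <- ranking |>
    dplyr::filter(.data$highly_contributing) |>
    dplyr::left_join(schema, by = "name") |>
    dplyr::filter(.data$kind == "position")
  if (nrow(prefix) == 0L) {
    return(tibble::tibble(position = integer(), category = character(),
                          matrices = character(), best_rank = integer()))
  }
  prefix |>
    dplyr::group_by(.data$position, .data$category) |>
    dplyr::summarise(matrices = paste(sort(unique(.data$matrix)),
                                      collapse = ","),
                     best_rank = min(.data$rank), .groups = "drop") |>
    dplyr::arrange(.data$position)
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy a fitted enzyme forest
#'
#' @param x An `efprf_forest`.
#' @param ... Unused.
#' @return The importance ranking as a tibble (one row per attribute).
#' @export
tidy.efprf_forest <- function(x, ...) {
  rank_importance(x) |> tibble::as_tibble()
}

#' One-row model summary of a fitted enzyme forest
#'
#' @param x An `efprf_forest`.
#' @param ... Unused.
#' @return Tibble with `n_attributes`, `ntree`, `mtry`, `oob_error`,
#'   `seed`.
#' @export
glance.efprf_forest <- function(x, ...) {
  tibble::tibble(n_attributes = nrow(x$schema), ntree = x$ntree,
                 mtry = x$mtry, oob_error = x$oob_error, seed = x$seed)
}
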
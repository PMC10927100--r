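#' Classification tree for macro-unit membership from trait states
#'
#' Fits a CART classifier (Gini impurity, via `rpart`) predicting the
#' macro-unit of each NAC from its tri-state traits, then prunes to the
#' complexity with minimum cross-validated error. Rows with unknown trait
#' states are retained: unknowns are `NA` to `rpart`, which routes them past
#' missing splits by surrogate variables, falling back to the majority
#' branch.
#'
#' @param x a [trait_matrix()] whose `meta$macro_unit` is populated (or
#'   supply `map`).
#' @param map optional [macrounit_map()] applied first.
#' @param cv_folds cross-validation folds for pruning (default 10).
#' @param seed optional integer seed (CV fold assignment is random).
#' @param drop_unassigned exclude `"unassigned"` rows (default `TRUE`).
#' @param minsplit,minbucket `rpart` growth controls, sized for small
#'   NAC-level samples.
#' @return Object of class `cart_fit`: list with `tree` (pruned `rpart`),
#'   `full_tree`, `cptable`, `classes`, `training_accuracy`.
#' @export
fit_cart <- function(x, map = NULL, cv_folds = 10L, seed = NULL,
                     drop_unassigned = TRUE, minsplit = 4L, minbucket = 2L) {
  stopifnot(inherits(x, "trait_matrix"))
  if (!is.null(map)) x <- assign_macrounits(x, map)
  unit <- x$meta$macro_unit
  keep <- !is.na(unit) & (!drop_unassigned | unit != "unassigned")
  unit <- unit[keep]
  vals <- x$values[keep, , drop = FALSE]
  if (length(unique(unit)) < 2L) {
    warning("single-class input: returning a trivial one-leaf tree",
            call. = FALSE)
    return(structure(list(tree = NULL, full_tree = NULL, cptable = NULL,
                          classes = unique(unit), training_accuracy = 1),
                     class = "cart_fit"))
  }
  df <- as.data.frame(lapply(as.data.frame(vals), function(v) {
    factor(v, levels = c(0L, 1L), labels = c("absent", "present"))
  }), check.names = FALSE)
  names(df) <- colnames(vals)
  df$.macro_unit <- factor(unit)
  run <- function() {
    full <- rpart::rpart(
      .macro_unit ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = 0, minsplit = minsplit,
                                     minbucket = minbucket,
                                     xval = cv_folds, maxsurrogate = 5,
                                     usesurrogate = 2))
    cp_tab <- full$cptable
    best <- cp_tab[which.min(cp_tab[, "xerror"]), "CP"]
    list(full = full, pruned = rpart::prune(full, cp = best))
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  pred <- stats::predict(fit$pruned, df, type = "class")
  structure(list(tree = fit$pruned, full_tree = fit$full,
                 cptable = fit$full$cptable,
                 classes = levels(df$.macro_unit),
                 training_accuracy = mean(pred == df$.macro_unit)),
            class = "cart_fit")
}

#' @export
print.cart_fit <- function(x, ...) {
  cat(sprintf("cart_fit: %d classes, training accuracy %.3f\n",
              length(x$classes), x$training_accuracy))
  if (!is.null(x$tree)) print(x$tree)
  invisible(x)
}

#' Traits used as primary splits in a fitted tree
#'
#' @param fit a [fit_cart()] result.
#' @return Character vector of trait names (empty for a one-leaf tree).
#' @export
cart_split_traits <- function(fit) {
  stopifnot(inherits(fit, "cart_fit"))
  if (is.null(fit$tree)) return(character(0))
  fr <- fit$tree$frame
  unique(as.character(fr$var[fr$var != "<leaf>"]))
}

#' Normalized variable importance of a fitted classification tree
#'
#' `rpart`'s total Gini-decrease importance (primary splits plus surrogate
#' credit), normalized to sum to 1 over all traits with nonzero importance.
#'
#' @param fit a [fit_cart()] result.
#' @return Data frame `trait`, `importance` sorted decreasing; zero rows for
#'   a one-leaf tree.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "cart_fit"))
  vi <- if (is.null(fit$tree)) NULL else fit$tree$variable.importance
  if (is.null(vi) || length(vi) == 0L) {
    return(data.frame(trait = character(0), importance = numeric(0)))
  }
  data.frame(trait = names(vi), importance = as.numeric(vi / sum(vi)),
             row.names = NULL, stringsAsFactors = FALSE)
}
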
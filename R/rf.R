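#' Bootstrap-ensemble (random forest) classifier
#'
#' A self-contained implementation of the classical random-forest
#' classifier: fully grown CART trees with Gini splits, each fitted to a
#' bootstrap resample of the data, with `mtry` candidate features drawn at
#' each node. Out-of-bag (OOB) votes give an internal accuracy estimate,
#' and unscaled permutation importance (mean decrease in accuracy over the
#' OOB cases of each tree) quantifies each feature's contribution.
#'
#' Reproducibility follows R's RNG: call `set.seed()` before fitting.
#'
#' @param x numeric matrix or data frame of features.
#' @param y class labels (factor or character).
#' @param ntree number of trees (default 500).
#' @param mtry features tried per node; default `floor(sqrt(p))`.
#' @param min_node minimum node size eligible for splitting children
#'   (default 1, i.e. trees grown to purity).
#' @param importance compute permutation importance (default `TRUE`).
#' @return Object of class `oto_rf` with elements `classes`, `features`,
#'   `oob_accuracy`, `oob_confusion`, `importance` (percent mean decrease
#'   in accuracy, with per-tree sd) and the fitted ensemble.
#' @export
oto_rf <- function(x, y, ntree = 500L, mtry = NULL, min_node = 1L,
                   importance = TRUE) {
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2)
    stop("need at least two classes to fit a classifier", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- rf_fit_cpp(x, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                    as.integer(mtry), as.integer(min_node), importance)
  pred <- factor(levels(y)[fit$oob_pred + 1L], levels = levels(y))
  conf <- table(observed = y, predicted = pred)
  imp <- data.frame(
    feature = colnames(x),
    mean_decrease_accuracy = 100 * fit$importance_mean,
    sd = 100 * fit$importance_sd,
    stringsAsFactors = FALSE)
  structure(
    list(model = fit[c("feature", "thresh", "left", "right", "pred",
                       "tree_offset")],
         classes = levels(y), features = colnames(x),
         ntree = ntree, mtry = mtry,
         oob_accuracy = fit$oob_accuracy,
         oob_votes = fit$oob_votes,
         oob_confusion = conf,
         importance = if (importance) imp else NULL),
    class = "oto_rf")
}

#' @export
print.oto_rf <- function(x, ...) {
  cat("<oto_rf> ", x$ntree, " trees, mtry ", x$mtry, ", classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("OOB accuracy: ", signif(x$oob_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Predict class votes from a fitted ensemble
#'
#' @param object an [oto_rf()] fit.
#' @param newdata matrix or data frame with the model's feature columns.
#' @param type `"prob"` for vote proportions (rows sum to 1), `"votes"`
#'   for raw counts, `"class"` for the plurality class (ties broken toward
#'   the class earlier in canonical order).
#' @param ... unused.
#' @export
predict.oto_rf <- function(object, newdata,
                           type = c("prob", "votes", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(newdata))
  if (length(miss) == length(object$features) &&
      ncol(newdata) == length(object$features)) {
    names(newdata) <- object$features  # unnamed input: match by position
    miss <- character(0)
  }
  if (length(miss))
    stop("fingerprint lacks model element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  xm <- as.matrix(newdata[object$features])
  storage.mode(xm) <- "double"
  votes <- rf_votes_cpp(object$model, xm, length(object$classes))
  colnames(votes) <- object$classes
  if (type == "votes") return(votes)
  prob <- votes / rowSums(votes)
  if (type == "prob") return(prob)
  factor(object$classes[apply(prob, 1, which.max)], levels = object$classes)
}
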
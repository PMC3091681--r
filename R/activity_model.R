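#' The seven broad compound target classes
#'
#' @return Character vector of the activity classes the model distinguishes.
#' @export
activity_classes <- function() {
  c("kinase inhibitor", "protease inhibitor", "GPCR agonist",
    "GPCR antagonist", "PDE inhibitor", "nuclear hormone receptor inhibitor",
    "ligand-gated ion channel inhibitor")
}

#' Train a decision tree relating 2D descriptors to target class
#'
#' Grows a binary CART classification tree (Gini impurity, no pruning by
#' default) on a training set of compounds with known activity class,
#' described by the package's 2D descriptor vectors.  Reports
#' resubstitution (training-set) accuracy and how many distinct
#' descriptors the splits actually use.  Cases at a split boundary follow
#' the CART convention: the fitted split sends values strictly below the
#' threshold left, values at or above it right.
#'
#' @param descriptors Numeric matrix, rows = compounds, columns =
#'   [descriptor_names()] (a subset of columns is allowed but must match
#'   at prediction time).
#' @param classes Character/factor vector of known classes, one per row.
#' @param min_leaf Minimum compounds per leaf (default 5).
#' @param cp Complexity parameter for \code{rpart} (default 0: grow fully
#'   subject to \code{min_leaf}).
#' @param xval Cross-validation folds for the optional CV accuracy
#'   estimate (default 0 = resubstitution only).
#' @return Object of class \code{activity_model}: list with \code{tree}
#'   (the rpart fit), \code{classes}, \code{descriptors_used},
#'   \code{n_descriptors_used}, \code{training_accuracy} and
#'   \code{schema} (descriptor column names).
#' @export
train_activity_tree <- function(descriptors, classes, min_leaf = 5L, cp = 0,
                                xval = 0L) {
  stopifnot(is.matrix(descriptors), nrow(descriptors) == length(classes))
  classes <- factor(classes)
  if (nlevels(classes) < 2L)
    stop("degenerate-training: need at least 2 classes", call. = FALSE)
  df <- as.data.frame(descriptors)
  df$.class <- classes
  tree <- rpart::rpart(
    .class ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(minbucket = min_leaf,
                                   minsplit = 2L * min_leaf, cp = cp,
                                   xval = xval, maxsurrogate = 0,
                                   maxcompete = 0))
  used <- setdiff(unique(as.character(tree$frame$var)), "<leaf>")
  pred <- predict(tree, df, type = "class")
  structure(list(tree = tree, classes = levels(classes),
                 descriptors_used = used,
                 n_descriptors_used = length(used),
                 training_accuracy = mean(pred == classes),
                 schema = colnames(descriptors)),
            class = "activity_model")
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf(paste0("Activity decision tree: %d classes, %d/%d descriptors",
                     " used, training accuracy %.1f%%\n"),
              length(x$classes), x$n_descriptors_used, length(x$schema),
              100 * x$training_accuracy))
  invisible(x)
}

#' Predict target classes for new compounds
#'
#' Deterministic threshold descent through the fitted tree.
#'
#' @param model An \code{activity_model}.
#' @param descriptors Numeric matrix (or single named vector) with the
#'   model's descriptor schema.
#' @return Character vector of predicted classes.
#' @export
predict_activity <- function(model, descriptors) {
  stopifnot(inherits(model, "activity_model"))
  if (is.null(dim(descriptors))) descriptors <- t(as.matrix(descriptors))
  if (!all(model$schema %in% colnames(descriptors)))
    stop("descriptor-mismatch: input lacks descriptor(s) ",
         paste(setdiff(model$schema, colnames(descriptors)), collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(descriptors[, model$schema, drop = FALSE])
  as.character(predict(model$tree, df, type = "class"))
}

#' Fold enrichment of predicted activity classes in a compound subset
#'
#' For each target class, the frequency of that predicted class among a
#' subset of compounds (e.g. those whose growth inhibition is uniquely
#' related to one senescence signature) divided by its frequency in the
#' full compound set.  Fold 1 means the subset mirrors the full set;
#' classes absent from the full set have undefined fold (\code{NA}).
#'
#' @param subset_preds Predicted classes of the subset's compounds.
#' @param full_preds Predicted classes of the full compound set.
#' @param classes Class universe (default [activity_classes()]; classes
#'   observed in \code{full_preds} are added automatically).
#' @return Data frame: \code{class}, \code{subset_frac}, \code{full_frac},
#'   \code{fold}.
#' @export
fold_enrichment <- function(subset_preds, full_preds,
                            classes = activity_classes()) {
  stopifnot(length(full_preds) >= 1L)
  classes <- union(classes, unique(full_preds))
  sub_f <- if (length(subset_preds))
    as.numeric(table(factor(subset_preds, classes)) / length(subset_preds))
  else rep(0, length(classes))
  full_f <- as.numeric(table(factor(full_preds, classes)) / length(full_preds))
  data.frame(class = classes, subset_frac = sub_f, full_frac = full_f,
             fold = ifelse(full_f > 0, sub_f / full_f, NA_real_),
             stringsAsFactors = FALSE)
}
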
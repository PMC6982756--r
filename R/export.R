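#' Export a forest as a portable model description
#'
#' Serialises every decision tree of a fitted random-forest model into a
#' language-neutral description: per tree, a node table with 1-based
#' \code{left}/\code{right} child indices (0 = none), the 1-based split
#' \code{feature} index into \code{feature_names}, the split
#' \code{threshold} (samples with value <= threshold go left) and, for
#' leaves, one-hot class \code{votes}. \code{\link{replayModel}} replays the
#' description and reproduces the live model's predictions exactly.
#'
#' @param model a fitted random-forest \code{\linkS4class{HARModel}}.
#' @param path optional file; when given, the description is written as JSON
#'   with full double precision.
#'
#' @return The model description (a list), invisibly when \code{path} is
#'   given.
#' @export
exportModel <- function(model, path = NULL) {
  stopifnot(is(model, "HARModel"))
  if (model@algorithm != "random_forest")
    stop("only random-forest models have a tree description")
  if (is.null(model@fit$forest)) stop("model is not fitted")
  nTree <- model@fit$ntree
  fitLevels <- levels(model@fit$y)   # class index space used by the backend
  trees <- lapply(seq_len(nTree), function(k) {
    tr <- randomForest::getTree(model@fit, k, labelVar = FALSE)
    leaf <- tr[, "status"] == -1
    votes <- matrix(0L, nrow(tr), length(model@classes),
                    dimnames = list(NULL, model@classes))
    cls <- fitLevels[tr[leaf, "prediction"]]
    votes[cbind(which(leaf), match(cls, model@classes))] <- 1L
    list(
      left = as.integer(ifelse(leaf, 0L, tr[, "left daughter"])),
      right = as.integer(ifelse(leaf, 0L, tr[, "right daughter"])),
      feature = as.integer(ifelse(leaf, 0L, tr[, "split var"])),
      threshold = as.numeric(ifelse(leaf, 0, tr[, "split point"])),
      votes = votes
    )
  })
  desc <- list(algorithm = "random_forest",
               n_trees = nTree,
               feature_names = model@featureNames,
               classes = model@classes,
               seed = model@seed,
               trees = trees)
  if (!is.null(path)) {
    jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(desc))
  }
  desc
}

#' Replay a portable model description
#'
#' A bundled interpreter for the description written by
#' \code{\link{exportModel}}: walks every tree for every input vector,
#' tallies leaf class votes across trees and predicts the majority class,
#' ties broken by canonical (alphabetical) activity order — the same rule
#' \code{\link{predictActivities}} uses, so agreement with the live model is
#' exact.
#'
#' @param description a model description list, or the path of a JSON file
#'   written by \code{exportModel}.
#' @param x a \code{FeatureMatrix} or numeric matrix covering the
#'   description's feature names.
#'
#' @return Character vector of predicted activity labels.
#' @export
replayModel <- function(description, x) {
  if (is.character(description))
    description <- readModelDescription(description)
  feat <- if (is(x, "FeatureMatrix")) x@features else as.matrix(x)
  fn <- unlist(description$feature_names)
  classes <- unlist(description$classes)
  miss <- setdiff(fn, colnames(feat))
  if (length(miss))
    stop("feature(s) missing from input: ", paste(miss, collapse = ", "))
  feat <- feat[, fn, drop = FALSE]
  n <- nrow(feat)
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  for (tree in description$trees) {
    v <- if (is.data.frame(tree$votes) || is.matrix(tree$votes))
      as.matrix(tree$votes) else do.call(rbind, tree$votes)
    for (i in seq_len(n)) {
      node <- 1L
      while (tree$feature[node] != 0L) {
        node <- if (feat[i, tree$feature[node]] <= tree$threshold[node])
          tree$left[node] else tree$right[node]
      }
      votes[i, ] <- votes[i, ] + v[node, ]
    }
  }
  classes[apply(votes, 1L, which.max)]
}

#' Number of split nodes per tree in a model description
#'
#' @param description a model description list or JSON path.
#' @return Integer vector, one entry per tree.
#' @export
countSplitNodes <- function(description) {
  if (is.character(description))
    description <- readModelDescription(description)
  vapply(description$trees, function(tree) sum(tree$feature != 0L), integer(1))
}

#' Read a portable model description from JSON
#'
#' @param path file written by \code{\link{exportModel}}.
#' @return The model description list.
#' @export
readModelDescription <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
}
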
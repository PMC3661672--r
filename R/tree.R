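#' Deviance-based classification tree
#'
#' Greedy binary recursive partitioning for the false-ARS decision rule:
#' each split maximizes the multinomial deviance reduction, candidate
#' thresholds are midpoints of adjacent sorted unique feature values, and a
#' node stops splitting when it is pure, smaller than `min_leaf`, or the best
#' relative deviance gain (relative to the root deviance) falls below
#' `min_split_dev`.
#'
#' @param features data frame of numeric features.
#' @param labels factor (or coercible) of class labels; at least 10 records
#'   unless the input is single-class.
#' @param min_leaf smallest node that may still be split (default 5).
#' @param min_split_dev minimum relative deviance gain (default 0.01).
#' @return An `ars_tree`: nested list of split nodes
#'   (`split_var,threshold,left,right`) and leaves (`class`, `probs`, `n`).
#' @export
fit_tree <- function(features, labels, min_leaf = 5, min_split_dev = 0.01) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels))
  classes <- levels(labels)
  if (length(classes) > 1 && nrow(features) < 10)
    stop("need at least 10 records")
  dev <- function(y) {
    n <- length(y)
    cnt <- tabulate(y, nbins = length(classes))
    cnt <- cnt[cnt > 0]
    -2 * sum(cnt * log(cnt / n))
  }
  leaf <- function(y) {
    cnt <- tabulate(y, nbins = length(classes))
    probs <- stats::setNames(cnt / length(y), classes)
    list(type = "leaf", class = classes[which.max(cnt)], probs = probs,
         n = length(y), dev = dev(y))
  }
  root_dev <- dev(labels)
  grow <- function(idx) {
    y <- labels[idx]
    d0 <- dev(y)
    if (length(idx) < min_leaf || d0 == 0) return(leaf(y))
    best <- list(gain = -Inf)
    for (v in names(features)) {
      xv <- features[[v]][idx]
      us <- sort(unique(xv))
      if (length(us) < 2) next
      for (thr in (us[-1] + us[-length(us)]) / 2) {
        l <- xv < thr
        g <- d0 - dev(y[l]) - dev(y[!l])
        if (g > best$gain) best <- list(gain = g, var = v, thr = thr, left = l)
      }
    }
    if (!is.finite(best$gain) ||
        (root_dev > 0 && best$gain / root_dev < min_split_dev))
      return(leaf(y))
    list(type = "split", split_var = best$var, threshold = best$thr,
         n = length(idx), dev = d0,
         left = grow(idx[best$left]), right = grow(idx[!best$left]))
  }
  structure(list(root = grow(seq_along(labels)), classes = classes,
                 features = names(features), n = length(labels),
                 root_dev = root_dev),
            class = "ars_tree")
}

#' Predict classes from a fitted tree
#'
#' Records descend the tree by `feature < threshold` (left) versus `>=`
#' (right) until a leaf.
#'
#' @param tree an `ars_tree`.
#' @param newdata data frame with the training feature columns.
#' @param type `"class"` (default) or `"prob"`.
#' @return Factor of predicted classes, or a matrix of class probabilities.
#' @export
predict_tree <- function(tree, newdata, type = c("class", "prob")) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  descend <- function(node, row) {
    while (node$type == "split") {
      node <- if (row[[node$split_var]] < node$threshold) node$left
              else node$right
    }
    node
  }
  leaves <- lapply(seq_len(nrow(newdata)), function(i)
    descend(tree$root, newdata[i, , drop = FALSE]))
  if (type == "class")
    factor(vapply(leaves, `[[`, character(1), "class"),
           levels = tree$classes)
  else
    do.call(rbind, lapply(leaves, `[[`, "probs"))
}

#' @export
print.ars_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s* %s (n=%d, p=%s)\n", pad, node$class, node$n,
                  paste(sprintf("%.2f", node$probs), collapse = "/")))
    } else {
      cat(sprintf("%s%s < %.4g (n=%d)\n", pad, node$split_var,
                  node$threshold, node$n))
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  cat(sprintf("<ars_tree: %d records, classes %s>\n", x$n,
              paste(x$classes, collapse = "/")))
  rec(x$root, 0)
  invisible(x)
}

#' Export a tree as nested JSON
#'
#' @param tree an `ars_tree`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_tree_json <- function(tree, file) {
  strip <- function(node) {
    if (node$type == "leaf")
      list(type = "leaf", class = node$class,
           probs = as.list(node$probs), n = node$n)
    else
      list(type = "split", split_var = node$split_var,
           threshold = node$threshold, n = node$n,
           left = strip(node$left), right = strip(node$right))
  }
  jsonlite::write_json(strip(tree$root), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Jack-knife (leave-one-out) validation
#'
#' Systematically refits the classifier with one record held out and
#' predicts that record, accumulating per-class counts of correct
#' predictions — the standard estimate of out-of-sample performance for a
#' small zone table.
#'
#' @param features data frame of numeric features.
#' @param labels class labels.
#' @param fitter fitting function `(features, labels, ...)` (default
#'   [fit_tree()]).
#' @param predict_fun prediction function `(fit, newdata)` returning classes
#'   (default [predict_tree()]).
#' @param ... passed to `fitter`.
#' @return Data frame with one row per class: `class`, `n`, `correct`,
#'   `pct_correct`; overall accuracy in attribute `"accuracy"`.
#' @export
jackknife <- function(features, labels, fitter = fit_tree,
                      predict_fun = predict_tree, ...) {
  features <- as.data.frame(features)
  labels <- factor(labels)
  n <- length(labels)
  stopifnot(n >= 10)
  hit <- logical(n)
  for (i in seq_len(n)) {
    fit <- fitter(features[-i, , drop = FALSE], labels[-i], ...)
    pred <- predict_fun(fit, features[i, , drop = FALSE])
    hit[i] <- as.character(pred) == as.character(labels[i])
  }
  out <- data.frame(class = levels(labels),
                    n = as.vector(table(labels)),
                    correct = vapply(levels(labels), function(cl)
                      sum(hit[labels == cl]), numeric(1)))
  out$pct_correct <- 100 * out$correct / out$n
  attr(out, "accuracy") <- mean(hit)
  out
}
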
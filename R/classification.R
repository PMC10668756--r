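# The four-feature decision tree that separates degraded (tailed) comets
# from undamaged (head-only) cells. The features are the head-to-tail
# area ratio, the head's position along x relative to the candidate
# region, and the mean head and tail intensities. The tree is plain CART:
# greedy Gini-impurity splits with an exhaustive threshold search at the
# midpoints of sorted unique feature values, deterministic tie-breaking.

FEATURE_NAMES <- c("head_tail_area_ratio", "head_relative_position",
                   "mean_head_intensity", "mean_tail_intensity")

CLASSES <- c("head_only", "tailed_comet")

#' Extract classification features for one comet candidate
#'
#' @param image preprocessed [intensity_image].
#' @param head non-empty logical head mask.
#' @param tail_candidate logical mask of the tail candidate (may be empty).
#' @param ratio_cap value of the head/tail area ratio reported when the
#'   tail candidate is empty.
#' @return Named list with the four features, in canonical order:
#'   `head_tail_area_ratio` (capped), `head_relative_position` (signed
#'   normalized x-offset of the head centroid within the candidate
#'   bounding box, -1 = leftmost edge, +1 = rightmost),
#'   `mean_head_intensity`, and `mean_tail_intensity` (0 for an empty
#'   tail candidate).
#' @export
extract_features <- function(image, head, tail_candidate, ratio_cap = 100) {
  px <- if (inherits(image, "intensity_image")) image$pixels else image
  if (!any(head)) stop("empty head mask")
  ha <- sum(head); ta <- sum(tail_candidate)
  ratio <- if (ta == 0) ratio_cap else min(ha / ta, ratio_cap)
  hc <- which(head, arr.ind = TRUE)
  cols_all <- range(which(colSums(head | tail_candidate) > 0))
  cx <- mean(hc[, 2])
  span <- cols_all[2] - cols_all[1]
  pos <- if (span == 0) 0 else 2 * (cx - cols_all[1]) / span - 1
  list(head_tail_area_ratio = ratio,
       head_relative_position = max(-1, min(1, pos)),
       mean_head_intensity = mean(px[head]),
       mean_tail_intensity = if (ta == 0) 0 else mean(px[tail_candidate]))
}

gini <- function(labels) {
  p <- tabulate(labels, 2L) / length(labels)
  1 - sum(p^2)
}

# Best split of one node: exhaustive over features (in index order) and
# candidate thresholds (midpoints of sorted unique values, in increasing
# order); ties keep the first candidate found, i.e. lowest feature index
# then lowest threshold.
best_split <- function(X, labels) {
  n <- length(labels)
  parent <- gini(labels)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    u <- sort(unique(v))
    if (length(u) < 2L) next
    thr <- (u[-length(u)] + u[-1L]) / 2
    for (t in thr) {
      left <- v <= t
      nl <- sum(left)
      if (nl == 0L || nl == n) next
      imp <- (nl * gini(labels[left]) + (n - nl) * gini(labels[!left])) / n
      if (is.null(best) || imp < best$impurity - 1e-12) {
        best <- list(feature = j, threshold = t, impurity = imp, left = left)
      }
    }
  }
  if (!is.null(best) && best$impurity >= parent - 1e-12) return(NULL)
  best
}

grow_tree <- function(X, labels, depth, depth_limit, min_split) {
  n <- length(labels)
  counts <- tabulate(labels, 2L)
  # majority class; ties resolve to the first class (head_only)
  cls <- CLASSES[which.max(counts)]
  leaf <- list(leaf = TRUE, class = cls, purity = max(counts) / n, n = n)
  if (depth >= depth_limit || n < min_split || gini(labels) == 0) return(leaf)
  sp <- best_split(X, labels)
  if (is.null(sp)) return(leaf)
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X[sp$left, , drop = FALSE], labels[sp$left],
                        depth + 1L, depth_limit, min_split),
       right = grow_tree(X[!sp$left, , drop = FALSE], labels[!sp$left],
                         depth + 1L, depth_limit, min_split))
}

#' Train the comet/no-tail decision tree
#'
#' CART with Gini impurity, exhaustive midpoint threshold search, and a
#' depth limit. Training is fully deterministic: split ties resolve to the
#' lowest feature index, then the lowest threshold; the seed is recorded
#' as metadata only.
#'
#' @param features data.frame (or matrix) with the four canonical feature
#'   columns, one row per example.
#' @param labels character vector of `"tailed_comet"` / `"head_only"`.
#' @param depth_limit maximum tree depth (root = depth 0).
#' @param min_split smallest node the splitter will divide.
#' @param seed integer recorded in the model metadata.
#' @return An object of class `comet_tree`.
#' @export
train_tree <- function(features, labels, depth_limit = 3L, min_split = 2L,
                       seed = 1L) {
  X <- as.matrix(as.data.frame(features)[, FEATURE_NAMES])
  if (nrow(X) < 10L) stop("need at least 10 training examples")
  if (length(labels) != nrow(X)) stop("features/labels length mismatch")
  lab <- match(labels, CLASSES)
  if (anyNA(lab)) stop(sprintf("labels must be one of: %s", paste(CLASSES, collapse = ", ")))
  if (length(unique(lab)) < 2L) {
    stop(errorCondition("training data contain a single class",
                        class = c("cometseg_singleclass_error", "cometseg_error")))
  }
  structure(list(root = grow_tree(X, lab, 0L, depth_limit, min_split),
                 features = FEATURE_NAMES, classes = CLASSES,
                 meta = list(seed = as.integer(seed),
                             depth_limit = as.integer(depth_limit),
                             n = nrow(X))),
            class = "comet_tree")
}

#' @export
print.comet_tree <- function(x, ...) {
  cat(sprintf("<comet_tree> depth limit %d, trained on %d examples\n",
              x$meta$depth_limit, x$meta$n))
  show_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s=> %s (purity %.2f, n=%d)\n", pad, node$class, node$purity, node$n))
    } else {
      cat(sprintf("%s%s <= %.4g ?\n", pad, x$features[node$feature], node$threshold))
      show_node(node$left, indent + 1L)
      show_node(node$right, indent + 1L)
    }
  }
  show_node(x$root, 0L)
  invisible(x)
}

#' Predict comet class from features
#'
#' @param object a [train_tree()] model.
#' @param features a named list (one comet) or data.frame (one row per
#'   comet) of the four features.
#' @param ... unused.
#' @return `"tailed_comet"` or `"head_only"` (vector for a data.frame).
#' @export
predict.comet_tree <- function(object, features, ...) {
  df <- as.data.frame(features)
  X <- as.matrix(df[, object$features, drop = FALSE])
  traverse <- function(node, x) {
    while (!node$leaf) {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    }
    node$class
  }
  out <- vapply(seq_len(nrow(X)), function(i) traverse(object$root, X[i, ]), "")
  if (nrow(X) == 1L) out[[1L]] else out
}

#' Serialize / restore a decision-tree model as JSON
#'
#' The round trip is lossless: structure, thresholds, leaf classes,
#' purities and metadata are preserved exactly.
#'
#' @param model a `comet_tree`.
#' @param path JSON destination / source.
#' @return `save_tree_model` returns `path` invisibly; `load_tree_model`
#'   the restored `comet_tree`.
#' @export
save_tree_model <- function(model, path) {
  stopifnot(inherits(model, "comet_tree"))
  json <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA)
  atomic_write(json, path)
  invisible(path)
}

#' @rdname save_tree_model
#' @export
load_tree_model <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("model file not found: %s", path),
                                  "cometseg_io_error")
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fix <- function(node) {
    if (isTRUE(node$leaf)) return(node)
    node$left <- fix(node$left); node$right <- fix(node$right)
    node
  }
  structure(list(root = fix(obj$root),
                 features = unlist(obj$features),
                 classes = unlist(obj$classes),
                 meta = obj$meta),
            class = "comet_tree")
}

tree_cache <- new.env(parent = emptyenv())

#' The packaged default classifier
#'
#' The study's manual annotations are not available, so the default model
#' is trained, deterministically and at first use, on 400 synthetic
#' single-comet patches from [generate_labeled_feature_set()] with
#' documented seed 1003. Retraining on your own annotated data with
#' [train_tree()] is the supported path for real micrographs.
#'
#' @return A `comet_tree`.
#' @export
default_tree_model <- function() {
  if (is.null(tree_cache$model)) {
    set <- generate_labeled_feature_set(400L, synth_config(seed = 1003L))
    tree_cache$model <- train_tree(set$features, set$labels,
                                   depth_limit = 3L, seed = 1003L)
  }
  tree_cache$model
}
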
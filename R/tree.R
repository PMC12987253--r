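# Variance-reduction regression trees grown for impurity-based feature
# importance. Node impurity is the (biased) variance of the target within
# the node,
#     I(t) = (1/N_t) * sum_i (y_i - ybar_t)^2 ,
# a split on feature j contributes
#     dI(t, j) = I(t) - (N_L/N_t) I(t_L) - (N_R/N_t) I(t_R) ,
# a feature's importance in one tree is the sum of its dI over the nodes it
# splits, and the forest importance is the average over trees, normalized to
# sum 1. The per-node dI values are retained so the computation can be
# audited split by split. This forest exists for feature screening; the
# predictive ensemble uses dedicated learners.

# Grow one tree on rows `idx`. Returns a data.frame of internal nodes with
# per-node impurity and dI.
grow_variance_tree <- function(X, y, idx, mtry, min_split, min_leaf, max_depth) {
  p <- ncol(X)
  nodes <- list()
  stack <- list(list(idx = idx, depth = 0L))
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rows <- nd$idx
    n <- length(rows)
    yy <- y[rows]
    sse <- sum(yy^2) - sum(yy)^2 / n
    if (n < min_split || n < 2L * min_leaf || nd$depth >= max_depth || sse <= 0) next
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- NULL
    for (f in feats) {
      xs <- X[rows, f]
      o <- order(xs)
      xs_s <- xs[o]
      ys <- yy[o]
      cs <- cumsum(ys)
      cs2 <- cumsum(ys^2)
      k <- seq_len(n - 1L)
      ok <- xs_s[k] < xs_s[k + 1L] & k >= min_leaf & (n - k) >= min_leaf
      if (!any(ok)) next
      k <- k[ok]
      sse_l <- cs2[k] - cs[k]^2 / k
      sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
      red <- sse - (sse_l + sse_r)
      i_best <- which.max(red)
      if (is.null(best) || red[i_best] > best$red) {
        kk <- k[i_best]
        best <- list(feature = f, red = red[i_best],
                     threshold = (xs_s[kk] + xs_s[kk + 1L]) / 2,
                     left = rows[o[seq_len(kk)]], right = rows[o[(kk + 1L):n]])
      }
    }
    if (is.null(best) || best$red <= 0) next
    nodes[[length(nodes) + 1L]] <- data.frame(
      depth = nd$depth, n = n, impurity = sse / n,
      feature = best$feature, threshold = best$threshold,
      delta_i = best$red / n
    )
    stack[[length(stack) + 1L]] <- list(idx = best$left, depth = nd$depth + 1L)
    stack[[length(stack) + 1L]] <- list(idx = best$right, depth = nd$depth + 1L)
  }
  if (length(nodes)) do.call(rbind, nodes)
  else data.frame(depth = integer(0), n = integer(0), impurity = numeric(0),
                  feature = integer(0), threshold = numeric(0), delta_i = numeric(0))
}

#' Impurity-importance forest
#'
#' Fits an ensemble of variance-reduction regression trees (bootstrap rows,
#' random feature subsets per node) and computes per-feature importance as
#' the per-tree sum of node impurity reductions, averaged across trees and
#' normalized to sum 1.
#'
#' @param X Numeric feature matrix (columns named).
#' @param y Numeric target.
#' @param n_trees Number of trees (default 200).
#' @param mtry Features tried per node (default `floor(sqrt(p))`).
#' @param min_split Minimum node size to attempt a split (default 5).
#' @param min_leaf Minimum child size (default 2).
#' @param max_depth Maximum depth (default 15).
#' @param bootstrap Bootstrap rows per tree (default TRUE).
#' @param seed Integer seed.
#' @return An object of class `impurity_forest`: `importance` (named,
#'   sums to 1), `per_tree` (trees x features matrix of raw per-tree sums),
#'   `node_records` (per-tree data frames with per-node impurity and
#'   `delta_i`), `M` the tree count.
#' @export
impurity_forest <- function(X, y, n_trees = 200L, mtry = NULL, min_split = 5L,
                            min_leaf = 2L, max_depth = 15L, bootstrap = TRUE,
                            seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, n >= 2L)
  if (stats::var(y) == 0) {
    stop("constant target: impurity importance undefined (all-zero)", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  with_seed(seed, {
    per_tree <- matrix(0, n_trees, p, dimnames = list(NULL, colnames(X)))
    records <- vector("list", n_trees)
    for (m in seq_len(n_trees)) {
      rows <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tree <- grow_variance_tree(X, y, rows, mtry, min_split, min_leaf, max_depth)
      records[[m]] <- tree
      if (nrow(tree)) {
        s <- tapply(tree$delta_i, tree$feature, sum)
        per_tree[m, as.integer(names(s))] <- s
      }
    }
    fi <- colMeans(per_tree)
    total <- sum(fi)
    if (total == 0) stop("no informative split found: all-zero importance", call. = FALSE)
    structure(
      list(importance = fi / total, per_tree = per_tree,
           node_records = records, M = n_trees,
           config = list(mtry = mtry, min_split = min_split, min_leaf = min_leaf,
                         max_depth = max_depth, bootstrap = bootstrap, seed = seed)),
      class = "impurity_forest"
    )
  })
}

#' @export
print.impurity_forest <- function(x, ...) {
  cat(sprintf("<impurity_forest> %d trees, %d features\n", x$M, length(x$importance)))
  top <- utils::head(sort(x$importance, decreasing = TRUE), 5L)
  cat("  top features:", paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
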
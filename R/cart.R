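# Weighted classification trees (CART, Gini impurity, axis-aligned binary
# splits).  Implemented in-package because no tree learner ships with the
# target environment.  Supports sample weights (needed by AdaBoost stumps)
# and an auxiliary label matrix whose per-leaf means provide bounded margin
# scores for the acupoint tasks.

#' Fit a weighted classification tree
#'
#' Greedy CART with Gini impurity. Splits are of the form `x_j <= t` with
#' `t` at midpoints of consecutive distinct feature values; the split
#' minimizing weighted child impurity is taken, ties resolved by lowest
#' feature index then lowest threshold, so fitting is deterministic.
#'
#' @param X Numeric feature matrix.
#' @param y Integer class labels in `1..n_classes`.
#' @param weights Nonnegative sample weights (default uniform).
#' @param n_classes Number of classes (columns of the leaf distributions).
#' @param max_depth Depth cap; `Inf` grows to purity.
#' @param min_leaf Minimum samples per child.
#' @param aux Optional numeric matrix of auxiliary labels; leaf-wise
#'   weighted means are stored (e.g. acupoint frequencies per leaf).
#' @return An object of class `cart_tree`.
#' @keywords internal
#' @export
fit_cart <- function(X, y, weights = NULL, n_classes = max(y),
                     max_depth = Inf, min_leaf = 1L, aux = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 1L)
  w <- weights %||% rep(1, n)
  if (any(w < 0)) stop_config("sample weights must be nonnegative")
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0); nodes$threshold <- numeric(0)
  nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$dist <- NULL; nodes$aux <- NULL
  q <- if (is.null(aux)) 0L else ncol(aux)

  new_node <- function() {
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <- 0L; nodes$threshold[id] <- NA_real_
    nodes$left[id] <- 0L; nodes$right[id] <- 0L
    nodes$dist <- rbind(nodes$dist, rep(NA_real_, n_classes))
    if (q) nodes$aux <- rbind(nodes$aux, rep(NA_real_, q))
    id
  }

  leaf_payload <- function(id, idx) {
    wi <- w[idx]
    tot <- sum(wi)
    d <- vapply(seq_len(n_classes), function(c) sum(wi[y[idx] == c]),
                numeric(1L))
    nodes$dist[id, ] <- if (tot > 0) d / tot else rep(1 / n_classes, n_classes)
    if (q) nodes$aux[id, ] <- if (tot > 0)
      colSums(aux[idx, , drop = FALSE] * wi) / tot else rep(0, q)
  }

  grow <- function(idx, depth) {
    id <- new_node()
    leaf_payload(id, idx)
    pure <- length(unique(y[idx])) <= 1L
    if (pure || depth >= max_depth || length(idx) < 2L * min_leaf) return(id)
    sp <- cart_best_split(X, y, w, idx, n_classes, min_leaf)
    if (is.null(sp)) return(id)
    nodes$feature[id] <- sp$feature
    nodes$threshold[id] <- sp$threshold
    go <- X[idx, sp$feature] <= sp$threshold
    nodes$left[id] <- grow(idx[go], depth + 1L)
    nodes$right[id] <- grow(idx[!go], depth + 1L)
    id
  }

  old <- options(expressions = max(getOption("expressions"), 50000L))
  on.exit(options(old))
  grow(seq_len(n), 0L)
  structure(list(feature = nodes$feature, threshold = nodes$threshold,
                 left = nodes$left, right = nodes$right,
                 dist = nodes$dist, aux = nodes$aux,
                 n_classes = n_classes, n_leaves = sum(nodes$left == 0L)),
            class = "cart_tree")
}

# Best Gini split over all features for the rows `idx`; NULL when no split
# strictly reduces impurity.
cart_best_split <- function(X, y, w, idx, n_classes, min_leaf) {
  best <- NULL
  wi <- w[idx]; yi <- y[idx]
  tot <- sum(wi)
  if (tot <= 0) return(NULL)
  M <- matrix(0, length(idx), n_classes)
  M[cbind(seq_along(idx), yi)] <- wi
  base_counts <- colSums(M)
  base_gini <- 1 - sum((base_counts / tot)^2)
  if (base_gini <= 0) return(NULL)
  for (j in seq_len(ncol(X))) {
    xj <- X[idx, j]
    ord <- order(xj)
    xs <- xj[ord]
    cs <- apply(M[ord, , drop = FALSE], 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
    nL <- seq_along(xs)
    valid <- which(xs[-length(xs)] < xs[-1L] &
                     nL[-length(xs)] >= min_leaf &
                     (length(xs) - nL[-length(xs)]) >= min_leaf)
    if (!length(valid)) next
    wL <- rowSums(cs)[valid]
    wR <- tot - wL
    ok <- wL > 0 & wR > 0
    valid <- valid[ok]; wL <- wL[ok]; wR <- wR[ok]
    if (!length(valid)) next
    gl <- 1 - rowSums((cs[valid, , drop = FALSE] / wL)^2)
    cr <- matrix(base_counts, length(valid), n_classes, byrow = TRUE) -
      cs[valid, , drop = FALSE]
    gr <- 1 - rowSums((cr / wR)^2)
    score <- (wL * gl + wR * gr) / tot
    b <- which.min(score)
    if (score[b] < base_gini - 1e-12 &&
        (is.null(best) || score[b] < best$score - 1e-12)) {
      best <- list(feature = j, score = score[b],
                   threshold = (xs[valid[b]] + xs[valid[b] + 1L]) / 2)
    }
  }
  best
}

#' Predict from a fitted CART
#'
#' @param object A `cart_tree`.
#' @param newdata Feature matrix.
#' @param type `"class"` (lowest class index wins distribution ties),
#'   `"dist"` (leaf class distribution) or `"aux"` (leaf auxiliary means).
#' @param ... Unused.
#' @keywords internal
#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "dist", "aux"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  n <- nrow(X)
  cur <- rep(1L, n)
  repeat {
    leafy <- object$left[cur] == 0L
    if (all(leafy)) break
    i <- which(!leafy)
    nd <- cur[i]
    go_left <- X[cbind(i, object$feature[nd])] <= object$threshold[nd]
    cur[i] <- ifelse(go_left, object$left[nd], object$right[nd])
  }
  switch(type,
         class = max.col(object$dist[cur, , drop = FALSE],
                         ties.method = "first"),
         dist = object$dist[cur, , drop = FALSE],
         aux = {
           if (is.null(object$aux))
             stop_config("tree was fitted without auxiliary labels")
           object$aux[cur, , drop = FALSE]
         })
}
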